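#' Construct a species-patch grid for one vegetation plot
#'
#' A species grid is the raw spatial observation unit: a regular raster of
#' integer species codes over a square vegetation plot (by convention a
#' 1 m x 1 m plot divided into 100 x 100 cells of 1 cm), where 0 marks bare
#' substrate. Coordinates are 0-based `(row, col)` with row 0 at the top.
#' Each cell holds exactly one species; mixed occupancy is not supported.
#'
#' @param values Integer matrix of species codes (rows x cols); 0 = bare.
#' @param plot_id Plot identifier.
#' @param cell_size Cell edge length in cm (default 1).
#' @param terrain_age_class Optional terrain-age class, one of
#'   `"ta1"`, `"ta2"`, `"ta3"`.
#' @param cobble_class Optional cobble-cover class, one of
#'   `"ts1"`, `"ts2"`, `"ts3"`.
#' @param registry Optional [species_registry()]; when supplied every nonzero
#'   code in `values` must appear in it.
#' @return An object of class `species_grid`.
#' @export
#' @examples
#' m <- matrix(0L, 10, 10)
#' m[2:4, 2:3] <- 1L
#' species_grid(m, plot_id = "p01")
species_grid <- function(values, plot_id = "plot", cell_size = 1,
                         terrain_age_class = NA_character_,
                         cobble_class = NA_character_,
                         registry = NULL) {
  if (!is.matrix(values)) abort("`values` must be a matrix of species codes.")
  if (nrow(values) < 1 || ncol(values) < 1) abort("grid must have at least one row and column.")
  if (anyNA(values)) abort("grid values must not be missing; use 0 for bare substrate.")
  if (any(values != round(values)) || any(values < 0)) {
    abort("species codes must be nonnegative integers (0 = bare substrate).")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    abort("`cell_size` must be a single positive number (cm).")
  }
  check_class_level(terrain_age_class, c("ta1", "ta2", "ta3"), "terrain_age_class")
  check_class_level(cobble_class, c("ts1", "ts2", "ts3"), "cobble_class")
  storage.mode(values) <- "integer"
  if (!is.null(registry)) {
    codes <- setdiff(unique(as.vector(values)), 0L)
    unknown <- setdiff(codes, registry$code)
    if (length(unknown)) {
      abort(paste0("species codes not in registry: ", paste(unknown, collapse = ", ")))
    }
  }
  structure(
    list(values = values, plot_id = as.character(plot_id),
         cell_size = as.numeric(cell_size),
         terrain_age_class = terrain_age_class,
         cobble_class = cobble_class),
    class = "species_grid"
  )
}

check_class_level <- function(x, levels, name) {
  if (length(x) != 1) abort(paste0("`", name, "` must be length 1."))
  if (!is.na(x) && !x %in% levels) {
    abort(paste0("`", name, "` must be one of ", paste(levels, collapse = ", "),
                 " or NA, not '", x, "'."))
  }
  invisible(x)
}

#' @export
print.species_grid <- function(x, ...) {
  d <- dim(x$values)
  occ <- sum(x$values != 0L)
  cat("<species_grid> plot ", x$plot_id, ": ", d[1], " x ", d[2],
      " cells of ", x$cell_size, " cm; ",
      occ, " vegetated (", round(100 * occ / prod(d), 1), "%), ",
      length(setdiff(unique(as.vector(x$values)), 0L)), " species\n", sep = "")
  invisible(x)
}

#' @export
dim.species_grid <- function(x) dim(x$values)

#' Species code registry
#'
#' Maps integer species codes to short labels (e.g. `"PoaAlp"`) and optional
#' full names. Code 0 is reserved for bare substrate.
#'
#' @param code Integer codes (unique, all > 0).
#' @param label Short species labels (unique).
#' @param name Optional full species names.
#' @return A tibble with columns `code`, `label`, `name`.
#' @export
species_registry <- function(code, label, name = label) {
  code <- as.integer(code)
  if (anyNA(code) || any(code <= 0)) abort("registry codes must be positive integers (0 is reserved).")
  if (anyDuplicated(code)) abort("registry codes must be unique.")
  if (anyDuplicated(label)) abort("registry labels must be unique.")
  tibble::tibble(code = code, label = as.character(label), name = as.character(name))
}

grid_formats <- c("long_csv", "ascii_grid")

#' Read a species-patch grid
#'
#' Two plain-text formats are supported. `long_csv` is the canonical
#' interchange format: a CSV with header `plot_id,row,col,species_code`
#' listing nonzero cells with 0-based coordinates (unlisted cells default to
#' bare), optionally preceded by `#`-comment metadata lines carrying the grid
#' dimensions, cell size and plot covariates. `ascii_grid` is the ESRI ASCII
#' raster dialect (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/
#' `NODATA_value` header, then `nrows` lines of codes, top row first);
#' NODATA cells map to 0.
#'
#' @param path File to read.
#' @param format `"long_csv"` or `"ascii_grid"`.
#' @param plot_id Plot identifier; for `ascii_grid` defaults to the file name
#'   without extension, for `long_csv` it selects among multiple plots if the
#'   file holds more than one.
#' @param nrow,ncol Grid dimensions used when the file carries none.
#' @param cell_size Cell size (cm) used when the file carries none.
#' @param registry Optional [species_registry()] used for validation.
#' @return A [species_grid()].
#' @export
read_species_grid <- function(path, format = c("long_csv", "ascii_grid"),
                              plot_id = NULL, nrow = 100, ncol = 100,
                              cell_size = 1, registry = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  switch(format,
    long_csv = read_grid_long_csv(path, plot_id, nrow, ncol, cell_size, registry),
    ascii_grid = read_grid_ascii(path, plot_id, cell_size, registry)
  )
}

read_grid_long_csv <- function(path, plot_id, nrow, ncol, cell_size, registry) {
  lines <- readLines(path)
  meta <- parse_grid_meta(lines)
  nrow <- meta$nrow %||% nrow
  ncol <- meta$ncol %||% ncol
  cell_size <- meta$cell_size %||% cell_size
  df <- tryCatch(
    readr::read_csv(I(lines), comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(
                      plot_id = readr::col_character(),
                      row = readr::col_integer(),
                      col = readr::col_integer(),
                      species_code = readr::col_integer()
                    )),
    error = function(e) abort(paste0("cannot parse long CSV ", path, ": ", conditionMessage(e)))
  )
  need <- c("plot_id", "row", "col", "species_code")
  if (!all(need %in% names(df))) {
    abort(paste0("long CSV must have columns ", paste(need, collapse = ", ")))
  }
  if (anyNA(df[need])) {
    bad <- which(apply(is.na(df[need]), 1, any))[1]
    abort(paste0("malformed long CSV ", path, ": missing value in data row ", bad))
  }
  plots <- unique(df$plot_id)
  if (is.null(plot_id)) {
    if (length(plots) > 1) {
      abort(paste0("file holds several plots (", paste(plots, collapse = ", "),
                   "); pass `plot_id` to pick one."))
    }
    plot_id <- if (length(plots)) plots else "plot"
  } else {
    df <- df[df$plot_id == plot_id, , drop = FALSE]
  }
  if (any(df$row < 0 | df$row >= nrow | df$col < 0 | df$col >= ncol)) {
    abort(paste0("cell coordinates outside the ", nrow, " x ", ncol,
                 " grid (coordinates are 0-based)."))
  }
  dup <- duplicated(df[c("row", "col")])
  if (any(dup)) {
    d <- df[dup, , drop = FALSE][1, ]
    abort(paste0("duplicate cell (", d$row, ",", d$col, ") in ", path))
  }
  values <- matrix(0L, nrow, ncol)
  values[cbind(df$row + 1L, df$col + 1L)] <- df$species_code
  species_grid(values, plot_id = plot_id, cell_size = cell_size,
               terrain_age_class = meta$terrain_age_class %||% NA_character_,
               cobble_class = meta$cobble_class %||% NA_character_,
               registry = registry)
}

parse_grid_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    kv <- regmatches(ln, regexec("^#\\s*(\\w+)\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(kv) == 3) {
      key <- kv[2]; val <- kv[3]
      out[[key]] <- switch(key,
        nrow = , ncol = as.integer(val),
        cell_size = as.numeric(val),
        val)
    }
  }
  out
}

read_grid_ascii <- function(path, plot_id, cell_size, registry) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) abort(paste0("malformed ESRI ASCII header at line ", i, " of ", path))
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows")) {
    if (is.null(hdr[[key]])) abort(paste0("ESRI ASCII header misses ", key, " in ", path))
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nodata <- hdr$nodata_value %||% -9999
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) {
    abort(paste0("ESRI ASCII body has ", length(body), " data rows, expected ", nr,
                 " (line ", i, " onward of ", path, ")"))
  }
  vals <- lapply(seq_along(body), function(k) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[k]), "\\s+")[[1]]))
    if (length(v) != nc || anyNA(v)) {
      abort(paste0("malformed ESRI ASCII data at line ", i + k - 1, " of ", path))
    }
    v
  })
  values <- do.call(rbind, vals)
  values[values == nodata] <- 0
  if (is.null(plot_id)) plot_id <- sub("\\.[^.]*$", "", basename(path))
  cs <- if (!is.null(hdr$cellsize)) hdr$cellsize else cell_size
  species_grid(values, plot_id = plot_id, cell_size = cs, registry = registry)
}

#' Write a species-patch grid
#'
#' Inverse of [read_species_grid()]; a write/read round trip reproduces the
#' grid exactly in both formats (the ESRI ASCII format carries no plot
#' covariates, which therefore survive only in `long_csv`).
#'
#' @param grid A [species_grid()].
#' @param path Output file.
#' @param format `"long_csv"` or `"ascii_grid"`.
#' @return `path`, invisibly.
#' @export
write_species_grid <- function(grid, path, format = c("long_csv", "ascii_grid")) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "species_grid"))
  if (format == "long_csv") {
    idx <- which(grid$values != 0L, arr.ind = TRUE)
    hdr <- c(
      paste0("# nrow=", nrow(grid$values)),
      paste0("# ncol=", ncol(grid$values)),
      paste0("# cell_size=", format(grid$cell_size, digits = 15)),
      if (!is.na(grid$terrain_age_class)) paste0("# terrain_age_class=", grid$terrain_age_class),
      if (!is.na(grid$cobble_class)) paste0("# cobble_class=", grid$cobble_class),
      "plot_id,row,col,species_code"
    )
    rows <- if (nrow(idx)) {
      ord <- order(idx[, 1], idx[, 2])
      idx <- idx[ord, , drop = FALSE]
      paste(grid$plot_id, idx[, 1] - 1L, idx[, 2] - 1L,
            grid$values[idx], sep = ",")
    } else character()
    writeLines(c(hdr, rows), path)
  } else {
    hdr <- c(
      paste("ncols", ncol(grid$values)),
      paste("nrows", nrow(grid$values)),
      "xllcorner 0",
      "yllcorner 0",
      paste("cellsize", format(grid$cell_size, digits = 15)),
      "NODATA_value -9999"
    )
    rows <- apply(grid$values, 1, paste, collapse = " ")
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}

#' Read plot covariates (terrain-age and cobble-cover classes)
#'
#' @param path CSV with header `plot_id,terrain_age_class,cobble_class`.
#' @return A tibble with one row per plot.
#' @export
read_covariates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("plot_id", "terrain_age_class", "cobble_class")
  if (!all(need %in% names(df))) {
    abort(paste0("covariate file must have columns ", paste(need, collapse = ", ")))
  }
  validate_covariates(df[need])
}

validate_covariates <- function(df) {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$plot_id)) abort("duplicated plot_id in covariates.")
  bad_ta <- !is.na(df$terrain_age_class) & !df$terrain_age_class %in% c("ta1", "ta2", "ta3")
  bad_ts <- !is.na(df$cobble_class) & !df$cobble_class %in% c("ts1", "ts2", "ts3")
  if (any(bad_ta)) abort(paste0("invalid terrain_age_class: ",
                                paste(unique(df$terrain_age_class[bad_ta]), collapse = ", ")))
  if (any(bad_ts)) abort(paste0("invalid cobble_class: ",
                                paste(unique(df$cobble_class[bad_ts]), collapse = ", ")))
  df
}
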