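#' Identify species patches under the four-neighbour rule
#'
#' A patch is a maximal set of same-species cells connected through shared
#' edges (rook / four-neighbour adjacency; diagonal contact does not join
#' patches). The perimeter of a patch counts every unit cell edge between one
#' of its cells and anything outside the patch: bare substrate, a cell of
#' another species, or the plot boundary. Areas are reported in cm^2
#' (cells x cell_size^2), perimeters in cm.
#'
#' @param grid A [species_grid()].
#' @return A tibble with one row per patch: `plot_id`, `patch_id`,
#'   `species_code`, `area` (cm^2), `perimeter` (cm), `shape_index`.
#' @export
#' @examples
#' m <- matrix(0L, 5, 5); m[2, 2:4] <- 1L
#' label_patches(species_grid(m))
label_patches <- function(grid) {
  stopifnot(inherits(grid, "species_grid"))
  lab <- label_patches_cpp(grid$values)
  cs <- grid$cell_size
  n <- length(lab$species_code)
  tibble::tibble(
    plot_id = rep(grid$plot_id, n),
    patch_id = seq_len(n),
    species_code = lab$species_code,
    area = lab$area_cells * cs^2,
    perimeter = lab$perimeter_edges * cs,
    shape_index = if (n) shape_index(lab$area_cells, lab$perimeter_edges) else numeric()
  )
}

#' Raster shape index of a patch
#'
#' `perimeter / (4 * sqrt(area))`, the square-normalised raster form: exactly
#' 1 for any n x n square and increasing without bound as the patch becomes
#' more irregular. The ratio is scale-free, so area/perimeter may be given in
#' cells/edges or cm^2/cm as long as the two use the same cell size.
#'
#' @param area Patch areas (> 0).
#' @param perimeter Patch perimeters (> 0).
#' @return Numeric vector of shape indices.
#' @export
shape_index <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0)) {
    abort("`area` and `perimeter` must be positive.")
  }
  perimeter / (4 * sqrt(area))
}

#' Plot-level landscape metrics
#'
#' Aggregates per-patch records into the seven metrics used to describe a
#' plot's patch mosaic:
#' * `MPS` mean patch size (cm^2);
#' * `PSCV` patch-size coefficient of variation (%, population sd; 0 when all
#'   patches are equal-sized or there is a single patch);
#' * `TE` total edge (cm, summed per-patch perimeters, so an edge shared by
#'   two patches of different species counts once for each);
#' * `NP` number of patches;
#' * `MSI` mean shape index (1 = all patches square);
#' * `PR` patch-type (species) richness;
#' * `SHDI` Shannon diversity (nats) over the proportional *vegetated* area of
#'   each species, so `SHDI = 0` whenever `PR = 1` regardless of cover.
#'
#' @param patches Tibble from [label_patches()] (possibly several plots).
#' @param plot_ids Optional character vector of plots that must appear in the
#'   output; plots without patches get `NP = 0` and missing metrics.
#' @return A tibble with one row per plot and columns
#'   `plot_id, MPS, PSCV, TE, NP, MSI, PR, SHDI`.
#' @export
plot_metrics <- function(patches, plot_ids = NULL) {
  out <- patches |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(
      MPS = mean(.data$area),
      PSCV = 100 * sqrt(mean((.data$area - mean(.data$area))^2)) / mean(.data$area),
      TE = sum(.data$perimeter),
      NP = dplyr::n(),
      MSI = mean(.data$shape_index),
      PR = dplyr::n_distinct(.data$species_code),
      SHDI = shannon_diversity(.data$area, .data$species_code),
      .groups = "drop"
    )
  if (!is.null(plot_ids)) {
    empty <- setdiff(plot_ids, out$plot_id)
    if (length(empty)) {
      out <- dplyr::bind_rows(
        out,
        tibble::tibble(plot_id = empty, MPS = NA_real_, PSCV = NA_real_,
                       TE = NA_real_, NP = 0L, MSI = NA_real_,
                       PR = NA_integer_, SHDI = NA_real_)
      )
    }
    out <- out[match(plot_ids, out$plot_id), ]
  }
  out
}

shannon_diversity <- function(area, species) {
  by_sp <- tapply(area, species, sum)
  p <- by_sp / sum(by_sp)
  -sum(p * log(p))
}

#' Species-level landscape metrics across plots
#'
#' Aggregates all patches of each species over the study: frequency of
#' occurrence (% of plots occupied), mean patch size with its standard
#' deviation, total cover `CA` (cm^2), mean shape index with sd, patch count
#' `NP` and total edge `TE`. Patch size and shape are the two metrics that
#' exist per patch and can therefore serve as species-specific traits.
#'
#' @param patches Tibble from [label_patches()] over all plots.
#' @param n_plots Total number of plots surveyed (frequency denominator).
#' @param registry Optional [species_registry()]; adds a `species` label
#'   column and errors on codes outside the registry.
#' @return A tibble with one row per species.
#' @export
species_metrics <- function(patches, n_plots, registry = NULL) {
  if (!is.null(registry)) {
    unknown <- setdiff(unique(patches$species_code), registry$code)
    if (length(unknown)) {
      abort(paste0("species codes not in registry: ", paste(unknown, collapse = ", ")))
    }
  }
  out <- patches |>
    dplyr::group_by(.data$species_code) |>
    dplyr::summarise(
      frequency = 100 * dplyr::n_distinct(.data$plot_id) / n_plots,
      MPS = mean(.data$area),
      MPS_sd = sd(.data$area),
      CA = sum(.data$area),
      MSI = mean(.data$shape_index),
      MSI_sd = sd(.data$shape_index),
      NP = dplyr::n(),
      TE = sum(.data$perimeter),
      .groups = "drop"
    )
  if (!is.null(registry)) {
    out <- dplyr::mutate(out,
      species = registry$label[match(.data$species_code, registry$code)],
      .after = "species_code")
  }
  out
}

#' Distribution summary of patch-level values
#'
#' Mean, standard deviation, type-7 quartiles, maximum and moment-based
#' skewness (g1 = m3 / m2^1.5) of a vector of patch-level values such as
#' areas or shape indices. With fewer than 2 values sd and skewness are
#' reported missing; skewness is also missing when the values are constant.
#'
#' @param x Numeric vector (nonempty).
#' @return A one-row tibble.
#' @export
distribution_summary <- function(x) {
  if (!length(x) || anyNA(x)) abort("`x` must be nonempty with no missing values.")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  m2 <- mean((x - mean(x))^2)
  skew <- if (length(x) < 2 || m2 == 0) NA_real_ else mean((x - mean(x))^3) / m2^1.5
  tibble::tibble(
    n = length(x),
    mean = mean(x),
    sd = if (length(x) < 2) NA_real_ else sd(x),
    q25 = q[1], median = q[2], q75 = q[3],
    max = max(x),
    skewness = skew
  )
}

#' Pairwise Pearson correlations among landscape metrics
#'
#' @param metrics Plot-by-metric table ([plot_metrics()] output, a data frame
#'   with identifier first column, or a numeric matrix). Needs at least 3
#'   plots.
#' @return A tibble of all unordered metric pairs (including the unit
#'   diagonal) with columns `metric_a`, `metric_b`, `r`, `p_value`; constant
#'   metrics yield missing correlations.
#' @export
metric_correlations <- function(metrics) {
  m <- as_id_matrix(metrics, what = "metrics")
  if (nrow(m) < 3) abort("need at least 3 plots for correlations.")
  vars <- colnames(m)
  pairs <- which(upper.tri(diag(length(vars)), diag = TRUE), arr.ind = TRUE)
  purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    a <- vars[pairs[k, 1]]; b <- vars[pairs[k, 2]]
    xa <- m[, a]; xb <- m[, b]
    if (var(xa) == 0 || var(xb) == 0) {
      return(tibble::tibble(metric_a = a, metric_b = b, r = NA_real_, p_value = NA_real_))
    }
    if (a == b) {
      return(tibble::tibble(metric_a = a, metric_b = b, r = 1, p_value = NA_real_))
    }
    ct <- cor.test(xa, xb, method = "pearson")
    tibble::tibble(metric_a = a, metric_b = b,
                   r = unname(ct$estimate), p_value = ct$p.value)
  })
}
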