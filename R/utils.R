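# Internal numeric helpers shared across modules.

# weighted mean with weights summing to anything positive
wmean <- function(x, w) sum(w * x) / sum(w)

# population-style weighted variance (divisor = sum of weights)
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

# weighted Pearson correlation
wcor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  sxy <- sum(w * (x - mx) * (y - my))
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

# run `expr` under a fixed seed when `seed` is supplied, otherwise as-is
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# coerce a tibble/data.frame whose first column is an identifier into a
# numeric matrix with rownames; numeric matrices pass through unchanged
as_id_matrix <- function(x, id_col = NULL, what = "table") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) {
    abort(paste0("`", what, "` must be a data frame or matrix."))
  }
  x <- as.data.frame(x)
  if (is.null(id_col)) {
    id_col <- names(x)[1]
  }
  ids <- as.character(x[[id_col]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated identifiers in `", what, "`: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  num <- x[setdiff(names(x), id_col)]
  not_num <- names(num)[!vapply(num, is.numeric, logical(1))]
  if (length(not_num)) {
    abort(paste0("non-numeric columns in `", what, "`: ",
                 paste(not_num, collapse = ", ")))
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  m
}

# matrix -> tibble with an identifier first column
matrix_to_tbl <- function(m, id_col) {
  tibble::as_tibble(m, rownames = id_col)
}
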