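#' Correspondence-analysis weights of an abundance table
#'
#' Scales `L` to the relative-frequency table `P = L / sum(L)` and returns
#' its margins: row (plot) weights `r` and column (species) weights `c`,
#' each summing to 1. These margins carry the sample and species weighting
#' through the whole coupled-ordination pipeline.
#'
#' @param l Plot-by-species table (data frame, matrix or [study_tables()]).
#' @return List with `P` (matrix), `row_w`, `col_w`.
#' @export
correspondence_weights <- function(l) {
  if (inherits(l, "study_tables")) l <- l$L
  m <- as_id_matrix(l, what = "L")
  if (any(m < 0)) abort("L must be nonnegative.")
  tot <- sum(m)
  if (tot <= 0) abort("L has zero grand total.")
  P <- m / tot
  list(P = P, row_w = rowSums(P), col_w = colSums(P))
}

#' Weighted centring and norming of table columns
#'
#' Returns the table whose columns have weighted mean 0 and weighted
#' variance 1 under the supplied weights (population-style, divisor = sum of
#' weights). This is the "centred normed" scaling of a principal component
#' analysis with row weights.
#'
#' @param x Data frame (identifier first column) or numeric matrix.
#' @param w Positive weights, one per row.
#' @return A numeric matrix with the input rownames.
#' @export
weighted_standardize <- function(x, w) {
  m <- as_id_matrix(x, what = "table")
  if (length(w) != nrow(m)) abort("one weight per row is required.")
  if (any(w <= 0)) abort("weights must be positive.")
  w <- w / sum(w)
  mu <- colSums(w * m)
  ctr <- sweep(m, 2, mu)
  s2 <- colSums(w * ctr^2)
  zero <- s2 <= .Machine$double.eps * max(s2, 1)
  if (any(zero)) {
    abort(paste0("constant column(s) cannot be normed: ",
                 paste(colnames(m)[zero], collapse = ", ")))
  }
  sweep(ctr, 2, sqrt(s2), "/")
}

# shared engine for basic and partial RLQ: takes the (possibly conditioned)
# standardized R and Q and the CA of L, returns the full fit
rlq_engine <- function(Rs, Qs, cw, R_raw, Q_raw, zero_tol = 1e-12) {
  X <- crossprod(Rs, cw$P %*% Qs)  # metrics x traits cross table
  sv <- svd(X)
  lambda <- sv$d^2
  keep <- which(lambda > zero_tol * max(lambda, zero_tol))
  lambda <- lambda[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # canonical orientation: the metric with the largest |loading| loads positive
  for (a in seq_along(keep)) {
    i <- which.max(abs(U[, a]))
    if (U[i, a] < 0) {
      U[, a] <- -U[, a]
      V[, a] <- -V[, a]
    }
  }
  axes <- paste0("axis", seq_along(keep))
  dimnames(U) <- list(colnames(R_raw), axes)
  dimnames(V) <- list(colnames(Q_raw), axes)
  plot_scores <- Rs %*% U
  species_scores <- Qs %*% V
  colnames(plot_scores) <- colnames(species_scores) <- axes

  cor_mat <- function(raw, scores, w) {
    out <- sapply(seq_len(ncol(scores)), function(a) {
      apply(raw, 2, wcor, y = scores[, a], w = w)
    })
    out <- matrix(out, ncol = ncol(scores),
                  dimnames = list(colnames(raw), axes))
    out
  }
  structure(
    list(
      eigenvalues = lambda,
      percent = 100 * lambda / sum(lambda),
      sum_inertia = sum(lambda),
      cross_table = X,
      metric_loadings = U,
      trait_loadings = V,
      plot_scores = plot_scores,
      species_scores = species_scores,
      metric_cor = cor_mat(R_raw, plot_scores, cw$row_w),
      trait_cor = cor_mat(Q_raw, species_scores, cw$col_w),
      row_w = cw$row_w,
      col_w = cw$col_w
    ),
    class = "rlq_fit"
  )
}

#' RLQ analysis: coupled ordination of metrics, abundances and traits
#'
#' Couples the plot-by-metric table `R` and the species-by-trait table `Q`
#' through the abundance table `L`: `L` is scaled as in correspondence
#' analysis, `R` and `Q` are centred and normed under the corresponding
#' row/column weights, and the cross table `X = t(R') P Q'` (metrics x
#' traits) is decomposed by singular value decomposition. The eigenvalues
#' (squared singular values) decompose the total co-inertia, which equals the
#' sum of squared fourth-corner statistics over all trait-metric pairs; axes
#' maximise the squared cross-covariance between metric-driven plot scores
#' and trait-driven species scores. Axis signs are fixed canonically (the
#' metric with the largest absolute loading on an axis loads positive), since
#' singular-vector signs are otherwise arbitrary.
#'
#' @param tables A [study_tables()] object.
#' @param zero_tol Relative tolerance below which an eigenvalue is treated as
#'   zero and its axis dropped (default `1e-12`).
#' @return An object of class `rlq_fit` with eigenvalues, percent co-inertia
#'   per axis, plot/species scores, metric/trait loadings and weighted
#'   variable-axis Pearson correlations. Use [tidy()] / [glance()] /
#'   [autoplot()] to extract results.
#' @export
rlq <- function(tables, zero_tol = 1e-12) {
  stopifnot(inherits(tables, "study_tables"))
  cw <- correspondence_weights(tables$L)
  Rs <- weighted_standardize(tables$R, cw$row_w)
  Qs <- weighted_standardize(tables$Q, cw$col_w)
  fit <- rlq_engine(Rs, Qs, cw, tables$R, tables$Q, zero_tol)
  fit$tables <- tables
  fit$call <- match.call()
  fit
}

#' @export
print.rlq_fit <- function(x, ...) {
  cat("<", class(x)[1], "> total co-inertia ", signif(x$sum_inertia, 4),
      "; axis shares (%): ", paste(round(x$percent, 1), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-variable contributions to the co-inertia of the leading axes
#'
#' The squared loading of a variable on an axis gives its percentage
#' contribution to that axis's inertia (each axis sums to 100%); the
#' reported value is the sum over the first `n_axes` axes (so the column
#' totals `100 * n_axes`).
#'
#' @param fit An `rlq_fit`.
#' @param n_axes Number of leading axes to accumulate (default 2).
#' @return A tibble with `side` (`"metric"`/`"trait"`), `variable`,
#'   `contribution`.
#' @export
inertia_contributions <- function(fit, n_axes = 2) {
  stopifnot(inherits(fit, "rlq_fit"))
  if (n_axes < 1 || n_axes > length(fit$eigenvalues)) {
    abort(paste0("`n_axes` must be between 1 and ", length(fit$eigenvalues), "."))
  }
  contrib <- function(loadings, side) {
    tibble::tibble(
      side = side,
      variable = rownames(loadings),
      contribution = unname(rowSums(100 * loadings[, seq_len(n_axes), drop = FALSE]^2))
    )
  }
  dplyr::bind_rows(contrib(fit$metric_loadings, "metric"),
                   contrib(fit$trait_loadings, "trait"))
}

#' @exportS3Method generics::tidy
#' @rdname rlq
#' @param x,object An `rlq_fit` object.
#' @param type Which component to return: `"eigenvalues"` (default),
#'   `"scores"` (plots and species), `"loadings"` (metrics and traits) or
#'   `"correlations"` (variable-axis weighted Pearson correlations).
#' @param ... Unused.
tidy.rlq_fit <- function(x, type = c("eigenvalues", "scores", "loadings",
                                     "correlations"), ...) {
  type <- match.arg(type)
  if (type == "eigenvalues") {
    return(tibble::tibble(
      axis = seq_along(x$eigenvalues),
      eigenvalue = x$eigenvalues,
      percent = x$percent,
      cumulative_percent = cumsum(x$percent)
    ))
  }
  long <- function(m, kind) {
    matrix_to_tbl(m, "label") |>
      dplyr::mutate(type = kind, .before = 1) |>
      tidyr::pivot_longer(dplyr::starts_with("axis"),
                          names_to = "axis", values_to = "value") |>
      dplyr::mutate(axis = as.integer(sub("axis", "", .data$axis)))
  }
  if (type == "scores") {
    dplyr::bind_rows(long(x$plot_scores, "plot"),
                     long(x$species_scores, "species"))
  } else if (type == "loadings") {
    dplyr::bind_rows(long(x$metric_loadings, "metric"),
                     long(x$trait_loadings, "trait"))
  } else {
    dplyr::bind_rows(long(x$metric_cor, "metric"),
                     long(x$trait_cor, "trait")) |>
      dplyr::rename(correlation = "value")
  }
}

#' @exportS3Method generics::glance
#' @rdname rlq
glance.rlq_fit <- function(x, ...) {
  tibble::tibble(
    sum_inertia = x$sum_inertia,
    axis1_percent = x$percent[1],
    axes12_percent = sum(x$percent[seq_len(min(2, length(x$percent)))]),
    n_axes = length(x$eigenvalues)
  )
}
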