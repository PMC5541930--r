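#' Weighted within-class centring of table columns
#'
#' Removes the class means from every column: within each class of the
#' partition, each column gets weighted mean 0 under the supplied row
#' weights restricted to that class. With a single class this reduces to
#' global weighted centring.
#'
#' @param x Data frame (identifier first column) or numeric matrix.
#' @param classes Factor-like vector assigning every row to a class.
#' @param w Positive row weights.
#' @return A numeric matrix.
#' @export
within_class_center <- function(x, classes, w) {
  m <- as_id_matrix(x, what = "table")
  classes <- as.factor(classes)
  if (length(classes) != nrow(m)) abort("one class per row is required.")
  if (anyNA(classes)) abort("classes must not be missing.")
  if (any(table(classes) == 0)) abort("empty class in the partition.")
  if (length(w) != nrow(m) || any(w <= 0)) abort("weights must be positive, one per row.")
  out <- m
  for (cl in levels(classes)) {
    idx <- classes == cl
    mu <- colSums(w[idx] * m[idx, , drop = FALSE]) / sum(w[idx])
    out[idx, ] <- sweep(m[idx, , drop = FALSE], 2, mu)
  }
  out
}

#' Partial RLQ: condition the ordination on a plot covariate
#'
#' Re-runs the RLQ decomposition after removing the effect of a categorical
#' covariate that partitions the plots (terrain-age class or cobble-cover
#' class): the metric table `R` is first centred and normed globally (as in
#' the basic analysis) and then centred within each covariate class using the
#' correspondence row weights, removing every between-class difference in
#' metric means, while `Q` is untouched (the covariate partitions samples,
#' not species). No re-norming follows the class centring, so a metric fully
#' determined by the classes contributes nothing after conditioning.
#' The diagnostic of covariate relevance is comparative: if the share of
#' co-inertia on the leading partial axis were much higher than in the basic
#' analysis, the covariate would structure the trait-metric coupling.
#' With a single-class covariate the result equals the basic [rlq()].
#'
#' @param tables A [study_tables()] with covariates attached (or pass
#'   `classes`).
#' @param covariate `"terrain_age"` or `"cobble"`, selecting the covariate
#'   column.
#' @param classes Optional explicit class vector (one per plot, in the row
#'   order of `tables$L`), overriding `covariate`.
#' @param zero_tol See [rlq()].
#' @return An object of class `partial_rlq_fit` (inherits `rlq_fit`), with
#'   the covariate name and class sizes attached.
#' @export
partial_rlq <- function(tables, covariate = c("terrain_age", "cobble"),
                        classes = NULL, zero_tol = 1e-12) {
  stopifnot(inherits(tables, "study_tables"))
  if (is.null(classes)) {
    covariate <- match.arg(covariate)
    if (is.null(tables$covariates)) {
      abort("no covariates attached to the study tables; pass `classes`.")
    }
    col <- switch(covariate, terrain_age = "terrain_age_class", cobble = "cobble_class")
    classes <- tables$covariates[[col]]
    if (anyNA(classes)) {
      abort(paste0("covariate '", covariate, "' missing for plots: ",
                   paste(tables$covariates$plot_id[is.na(classes)], collapse = ", ")))
    }
  } else {
    covariate <- "custom"
    if (length(classes) != nrow(tables$L)) abort("one class per plot is required.")
  }
  classes <- as.factor(classes)
  cw <- correspondence_weights(tables$L)
  # norm globally first, then remove the class means of the normed metrics;
  # a second norming is deliberately omitted (see Details)
  Rs <- within_class_center(weighted_standardize(tables$R, cw$row_w),
                            classes, cw$row_w)
  Qs <- weighted_standardize(tables$Q, cw$col_w)
  fit <- rlq_engine(Rs, Qs, cw, tables$R, tables$Q, zero_tol)
  class(fit) <- c("partial_rlq_fit", class(fit))
  fit$tables <- tables
  fit$covariate <- covariate
  fit$class_sizes <- table(classes)
  fit$classes <- classes
  fit$call <- match.call()
  fit
}

#' @export
print.partial_rlq_fit <- function(x, ...) {
  cat("<partial_rlq_fit> covariate '", x$covariate, "' (",
      paste(names(x$class_sizes), x$class_sizes, sep = ":", collapse = ", "),
      ")\n", sep = "")
  NextMethod()
}
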