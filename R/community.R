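#' Bray-Curtis dissimilarity between plots
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over species abundances;
#' 0 for identical plots, 1 for plots with disjoint species sets.
#'
#' @param l Plot-by-species abundance table (data frame with identifier first
#'   column, numeric matrix with rownames, or a [study_tables()] object).
#' @return A `dist` object labelled by plot.
#' @export
bray_curtis <- function(l) {
  if (inherits(l, "study_tables")) l <- l$L
  m <- as_id_matrix(l, what = "L")
  if (any(m < 0)) abort("abundances must be nonnegative.")
  if (any(rowSums(m) == 0)) {
    abort(paste0("Bray-Curtis is undefined for all-zero plots: ",
                 paste(rownames(m)[rowSums(m) == 0], collapse = ", ")))
  }
  vegan::vegdist(m, method = "bray")
}

#' Cluster vegetation releves
#'
#' Agglomerative hierarchical clustering of plots on Bray-Curtis
#' dissimilarities with Ward linkage, cut into `k` groups. The classic
#' `"ward.D"` criterion applied to the (unsquared) dissimilarities is the
#' default, matching the historical default behaviour of standard
#' hierarchical-clustering routines; `"ward.D2"` squares them.
#'
#' Cluster labels are canonical: each cluster's *characteristic species* is
#' the species whose mean abundance inside the cluster most exceeds its mean
#' abundance outside, and clusters are labelled `CL1, CL2, ...` by descending
#' within-cluster mean abundance of that species, so labels are stable under
#' reordering of the input plots.
#'
#' @param l Plot-by-species table (or [study_tables()]).
#' @param k Number of clusters (default 3).
#' @param variant Ward linkage variant, `"ward.D"` (default) or `"ward.D2"`.
#' @return An object of class `releve_clusters`: list with the `hclust` tree,
#'   an `assignment` tibble (`plot_id`, `cluster`), a `characteristic` tibble,
#'   `k` and `variant`.
#' @export
cluster_releves <- function(l, k = 3, variant = c("ward.D", "ward.D2")) {
  variant <- match.arg(variant)
  if (inherits(l, "study_tables")) l <- l$L
  m <- as_id_matrix(l, what = "L")
  if (k < 1 || k > nrow(m)) abort("`k` must be between 1 and the number of plots.")
  d <- bray_curtis(m)
  tree <- hclust(d, method = variant)
  raw <- cutree(tree, k = k)

  # canonicalise labels by the characteristic species of each cluster
  char <- purrr::map_dfr(sort(unique(raw)), function(g) {
    inside <- colMeans(m[raw == g, , drop = FALSE])
    outside <- if (sum(raw != g)) colMeans(m[raw != g, , drop = FALSE]) else 0 * inside
    sp <- names(which.max(inside - outside))
    tibble::tibble(raw = g, species = sp, mean_abundance = inside[[sp]])
  })
  ord <- order(-char$mean_abundance, char$raw)
  relabel <- setNames(paste0("CL", seq_len(k)), char$raw[ord])
  assignment <- tibble::tibble(
    plot_id = rownames(m),
    cluster = unname(relabel[as.character(raw)])
  )
  char <- char[ord, ]
  char$cluster <- paste0("CL", seq_len(k))
  structure(
    list(tree = tree, assignment = assignment,
         characteristic = char[c("cluster", "species", "mean_abundance")],
         k = k, variant = variant),
    class = "releve_clusters"
  )
}

#' @export
print.releve_clusters <- function(x, ...) {
  cat("<releve_clusters> ", nrow(x$assignment), " plots in ", x$k,
      " clusters (", x$variant, " on Bray-Curtis)\n", sep = "")
  print(dplyr::count(x$assignment, .data$cluster))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @rdname cluster_releves
#' @param x,object A `releve_clusters` object.
#' @param ... Unused.
tidy.releve_clusters <- function(x, ...) x$assignment

#' @exportS3Method generics::glance
#' @rdname cluster_releves
glance.releve_clusters <- function(x, ...) {
  tibble::tibble(n_plots = nrow(x$assignment), k = x$k, variant = x$variant)
}

#' @export
plot.releve_clusters <- function(x, ...) {
  plot(x$tree, ...)
  stats::rect.hclust(x$tree, k = x$k)
  invisible(x)
}

#' One-way analysis of variance of a response across groups
#'
#' Classical one-way fixed-effects ANOVA: F on (k - 1, n - k) degrees of
#' freedom with the p-value from the F distribution, plus per-group means
#' with t-based 95% confidence intervals. Zero within-group variance yields
#' an infinite F (flagged, p = 0).
#'
#' @param data A data frame.
#' @param response,group Column names (tidy-eval) of the numeric response and
#'   the grouping factor; at least two non-empty groups are required.
#' @return An object of class `anova_oneway`; `glance()` gives the one-row
#'   test summary, `tidy()` the per-group means and intervals.
#' @export
anova_oneway <- function(data, response, group) {
  y <- dplyr::pull(data, {{ response }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("need at least 2 groups.")
  if (any(table(g) < 1)) abort("every group needs at least one observation.")
  n <- length(y); k <- nlevels(g)
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df1 <- k - 1; df2 <- n - k
  if (ss_within <= .Machine$double.eps * sum(y^2)) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  sds <- tapply(y, g, sd)
  half <- qt(0.975, pmax(ns - 1, 1)) * sds / sqrt(ns)
  groups <- tibble::tibble(
    group = levels(g), n = as.integer(ns), mean = as.numeric(means),
    ci_low = as.numeric(means - half), ci_high = as.numeric(means + half)
  )
  structure(
    list(response = rlang::as_name(rlang::enquo(response)),
         grouping = rlang::as_name(rlang::enquo(group)),
         statistic = f, p_value = p, df = c(df1, df2), groups = groups),
    class = "anova_oneway"
  )
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat("One-way ANOVA: ", x$response, " ~ ", x$grouping,
      "  F(", x$df[1], ",", x$df[2], ") = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @rdname anova_oneway
#' @param x,object An `anova_oneway` object.
#' @param ... Unused.
tidy.anova_oneway <- function(x, ...) {
  dplyr::mutate(x$groups, response = x$response, grouping = x$grouping,
                .before = 1)
}

#' @exportS3Method generics::glance
#' @rdname anova_oneway
glance.anova_oneway <- function(x, ...) {
  tibble::tibble(response = x$response, grouping = x$grouping,
                 statistic = x$statistic, p_value = x$p_value,
                 df_between = x$df[1], df_within = x$df[2])
}

#' ANOVA of every landscape metric across a plot grouping
#'
#' Convenience wrapper running [anova_oneway()] for each metric column
#' against a grouping of the plots (releve cluster, terrain-age class,
#' cobble-cover class, ...).
#'
#' @param metrics Plot-by-metric tibble with a `plot_id` column.
#' @param grouping Data frame with `plot_id` and a grouping column, or a
#'   `releve_clusters` object.
#' @param group_col Name of the grouping column (default: first non-id
#'   column).
#' @return A tibble with one row per metric: `response`, `grouping`,
#'   `statistic`, `p_value`, degrees of freedom, and a `groups` list-column
#'   of per-group means and confidence intervals.
#' @export
anova_metrics <- function(metrics, grouping, group_col = NULL) {
  if (inherits(grouping, "releve_clusters")) {
    grouping <- grouping$assignment
    group_col <- "cluster"
  }
  group_col <- group_col %||% setdiff(names(grouping), "plot_id")[1]
  joined <- dplyr::inner_join(metrics, grouping[c("plot_id", group_col)], by = "plot_id")
  responses <- setdiff(names(metrics), "plot_id")
  purrr::map_dfr(responses, function(v) {
    fit <- anova_oneway(joined, !!rlang::sym(v), !!rlang::sym(group_col))
    dplyr::mutate(glance(fit), response = v, grouping = group_col,
                  groups = list(fit$groups))
  })
}
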