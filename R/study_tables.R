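#' Bundle the three coupled study tables
#'
#' The trait--spatial-configuration analysis couples three tables: `R`
#' (plots x landscape metrics), `L` (plots x species abundances, here the
#' number of 1 cm^2 cells each species occupies per plot) and `Q`
#' (species x traits), optionally with per-plot covariate classes.
#' Rows are aligned by label: the plot labels of `L` must match those of `R`
#' (and of the covariates), the species labels of `L` those of `Q`; input row
#' order is irrelevant. Species with all-zero abundance are dropped from `L`
#' and `Q` with a warning, mirroring the field practice of omitting species of
#' negligible frequency and cover.
#'
#' @param r Plot-by-metric table: data frame with identifier first column, or
#'   numeric matrix with rownames.
#' @param l Plot-by-species abundance table, same conventions.
#' @param q Species-by-trait table, same conventions.
#' @param covariates Optional data frame with columns
#'   `plot_id`, `terrain_age_class`, `cobble_class`.
#' @return An object of class `study_tables` with matrix components
#'   `R`, `L`, `Q` and a `covariates` tibble (or `NULL`).
#' @export
study_tables <- function(r, l, q, covariates = NULL) {
  R <- as_id_matrix(r, what = "R")
  L <- as_id_matrix(l, what = "L")
  Q <- as_id_matrix(q, what = "Q")

  miss_rl <- setdiff(rownames(L), rownames(R))
  extra_rl <- setdiff(rownames(R), rownames(L))
  if (length(miss_rl) || length(extra_rl)) {
    abort(paste0("plot labels of R and L differ; only in L: [",
                 paste(miss_rl, collapse = ", "), "], only in R: [",
                 paste(extra_rl, collapse = ", "), "]"))
  }
  miss_lq <- setdiff(colnames(L), rownames(Q))
  extra_lq <- setdiff(rownames(Q), colnames(L))
  if (length(miss_lq) || length(extra_lq)) {
    abort(paste0("species labels of L and Q differ; only in L: [",
                 paste(miss_lq, collapse = ", "), "], only in Q: [",
                 paste(extra_lq, collapse = ", "), "]"))
  }
  R <- R[rownames(L), , drop = FALSE]
  Q <- Q[colnames(L), , drop = FALSE]

  if (any(L < 0)) abort("L must be nonnegative.")
  zero_sp <- colSums(L) == 0
  if (any(zero_sp)) {
    warn(paste0("dropping species with all-zero abundance: ",
                paste(colnames(L)[zero_sp], collapse = ", ")))
    L <- L[, !zero_sp, drop = FALSE]
    Q <- Q[!zero_sp, , drop = FALSE]
  }
  zero_pl <- rowSums(L) == 0
  if (any(zero_pl)) {
    abort(paste0("plots with no vegetated cells cannot enter the analysis: ",
                 paste(rownames(L)[zero_pl], collapse = ", ")))
  }
  if (ncol(L) < 2 || nrow(L) < 2) abort("need at least 2 plots and 2 species.")

  cov <- NULL
  if (!is.null(covariates)) {
    cov <- validate_covariates(covariates)
    miss <- setdiff(rownames(L), cov$plot_id)
    if (length(miss)) {
      abort(paste0("covariates missing for plots: ", paste(miss, collapse = ", ")))
    }
    cov <- cov[match(rownames(L), cov$plot_id), ]
  }
  structure(list(R = R, L = L, Q = Q, covariates = cov), class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  cat("<study_tables> ", nrow(x$L), " plots, ", ncol(x$L), " species, ",
      ncol(x$R), " landscape metrics, ", ncol(x$Q), " traits",
      if (!is.null(x$covariates)) "; covariates attached", "\n", sep = "")
  invisible(x)
}

#' Load the study tables from CSV files
#'
#' Each file is a CSV whose first column holds the row labels (plots for the
#' R and L tables, species for the Q table). See [study_tables()] for the
#' alignment rules.
#'
#' @param r_path,l_path,q_path Paths to the R, L and Q tables.
#' @param covariate_path Optional path to a covariate CSV with header
#'   `plot_id,terrain_age_class,cobble_class`.
#' @return A [study_tables()] object.
#' @export
load_study_tables <- function(r_path, l_path, q_path, covariate_path = NULL) {
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE)
  cov <- if (!is.null(covariate_path)) read_covariates(covariate_path)
  study_tables(rd(r_path), rd(l_path), rd(q_path), covariates = cov)
}

#' Derive study tables from species-patch grids
#'
#' Computes the landscape-metric table R via [label_patches()] and
#' [plot_metrics()] and the abundance table L as per-species occupied-cell
#' counts, then bundles them with a trait table.
#'
#' @param grids List of [species_grid()] objects (one per plot).
#' @param q Species-by-trait table; its species labels are matched to grid
#'   codes through `registry`.
#' @param registry A [species_registry()] translating integer codes to the
#'   species labels used in `q`.
#' @return A [study_tables()] object.
#' @export
study_from_grids <- function(grids, q, registry) {
  stopifnot(is.list(grids), all(vapply(grids, inherits, logical(1), "species_grid")))
  patches <- purrr::map_dfr(grids, label_patches)
  plot_ids <- vapply(grids, function(g) g$plot_id, character(1))
  R <- plot_metrics(patches, plot_ids = plot_ids)
  Rm <- as_id_matrix(as.data.frame(R), what = "R")

  L <- abundance_from_grids(grids, registry)
  cov <- tibble::tibble(
    plot_id = plot_ids,
    terrain_age_class = vapply(grids, function(g) g$terrain_age_class, character(1)),
    cobble_class = vapply(grids, function(g) g$cobble_class, character(1))
  )
  if (all(is.na(cov$terrain_age_class)) && all(is.na(cov$cobble_class))) cov <- NULL
  study_tables(Rm, L, q, covariates = cov)
}

#' Per-species occupied-cell counts from grids
#'
#' @inheritParams study_from_grids
#' @return A tibble with `plot_id` and one abundance column per species label.
#' @export
abundance_from_grids <- function(grids, registry) {
  counts <- purrr::map_dfr(grids, function(g) {
    tab <- table(factor(as.vector(g$values), levels = registry$code))
    tibble::tibble(plot_id = g$plot_id,
                   label = registry$label,
                   cells = as.integer(tab))
  })
  tidyr::pivot_wider(counts, names_from = "label", values_from = "cells")
}
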