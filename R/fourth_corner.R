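# positional fourth-corner cross table (traits x metrics); inputs are bare
# matrices so that permuted copies of L can be passed without re-labelling
fc_stat_mat <- function(R, L, Q) {
  tot <- sum(L)
  P <- L / tot
  rw <- rowSums(P)
  cw <- colSums(P)
  Rs <- weighted_standardize(R, rw)
  Qs <- weighted_standardize(Q, cw)
  crossprod(Qs, crossprod(P, Rs))
}

#' Fourth-corner statistic matrix
#'
#' The fourth-corner table `X` crosses the traits (`Q`) with the landscape
#' metrics (`R`) through the abundances (`L`):
#' `X[j, k] = sum_i sum_s P[i, s] * R'[i, k] * Q'[s, j]`, with `P = L/sum(L)`
#' and `R`, `Q` centred and normed under the correspondence row/column
#' weights. Each entry is a weighted Pearson correlation over the
#' abundance-inflated table, so entries lie in `[-1, 1]`, and the sum of the
#' squared entries equals the total co-inertia of [rlq()] on the same tables.
#'
#' @param tables A [study_tables()] object.
#' @return A traits-by-metrics numeric matrix.
#' @export
fourth_corner_matrix <- function(tables) {
  stopifnot(inherits(tables, "study_tables"))
  fc_stat_mat(tables$R, tables$L, tables$Q)
}

# one permutation-model run: returns per-cell exceedance counts and the
# global exceedance count for the sum-of-squares statistic
fc_perm_counts <- function(R, L, Q, model, n_perm, obs, obs_global) {
  count_cell <- matrix(0L, nrow(obs), ncol(obs))
  count_global <- 0L
  for (b in seq_len(n_perm)) {
    Lb <- if (model == 2) L[sample(nrow(L)), , drop = FALSE]
          else L[, sample(ncol(L)), drop = FALSE]
    Xb <- fc_stat_mat(R, Lb, Q)
    count_cell <- count_cell + (abs(Xb) >= abs(obs))
    count_global <- count_global + (sum(Xb^2) >= obs_global)
  }
  list(cell = count_cell, global = count_global)
}

#' Permutation test of one fourth-corner null model
#'
#' Model 2 permutes whole plot rows of `L` (equivalently, reassigns the
#' abundance profiles to the plots), testing the link between abundances and
#' spatial configuration (L-R); model 4 permutes species columns of `L`
#' (equivalently, reassigns trait syndromes to species), testing the link
#' between abundances and traits (L-Q). Per-cell p-values are two-sided on
#' the absolute statistic; the global statistic is the total co-inertia
#' `sum(X^2)`. All p-values use the add-one estimator
#' `(b + 1) / (n_perm + 1)` and so never return 0.
#'
#' @param tables A [study_tables()] object.
#' @param model Permutation model, 2 or 4.
#' @param n_perm Number of permutations (the study convention is 49,999).
#' @param seed Optional integer seed for reproducible permutations.
#' @return A list with `cell_p` (traits x metrics matrix), `global_statistic`
#'   and `global_p`.
#' @export
permutation_test <- function(tables, model, n_perm = 49999, seed = NULL) {
  stopifnot(inherits(tables, "study_tables"))
  if (!model %in% c(2, 4)) abort("`model` must be 2 (permute plots) or 4 (permute species).")
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  obs <- fourth_corner_matrix(tables)
  obs_global <- sum(obs^2)
  counts <- with_seed_if(seed,
    fc_perm_counts(tables$R, tables$L, tables$Q, model, n_perm, obs, obs_global))
  list(
    statistic = obs,
    cell_p = (counts$cell + 1) / (n_perm + 1),
    global_statistic = obs_global,
    global_p = (counts$global + 1) / (n_perm + 1),
    model = model, n_perm = n_perm, seed = seed
  )
}

#' Combined fourth-corner test of trait-metric associations
#'
#' Runs both permutation models and combines them cell-wise by the max-p
#' rule: an association is declared only when *both* null hypotheses
#' (abundances unlinked to metrics; abundances unlinked to traits) are
#' rejected, i.e. when `max(p_model2, p_model4)` falls below the
#' significance level. Because the two p-values are close to independent
#' under the complete null, testing each at level `sqrt(alpha)` gives the
#' combined decision an overall level near `alpha`; results are therefore
#' flagged under both conventions, `alpha = sqrt(0.05)` and `alpha = 0.05`.
#'
#' @inheritParams permutation_test
#' @param alphas Two significance levels for the flags
#'   (default `c(sqrt(0.05), 0.05)`).
#' @param fdr If `TRUE`, Benjamini-Hochberg-adjust the combined p-values
#'   across cells before flagging (off by default; the study convention is
#'   raw combined p-values against both alpha settings).
#' @return An object of class `fourth_corner_fit`. `tidy()` returns the
#'   per-cell table (`trait`, `metric`, `statistic`, `p_model2`, `p_model4`,
#'   `p_combined`, `sig_sqrt05`, `sig_05`); `glance()` the two global tests.
#' @export
fourth_corner <- function(tables, n_perm = 49999, seed = NULL,
                          alphas = c(sqrt(0.05), 0.05), fdr = FALSE) {
  stopifnot(inherits(tables, "study_tables"))
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  if (length(alphas) != 2) abort("`alphas` must hold exactly two levels.")
  obs <- fourth_corner_matrix(tables)
  obs_global <- sum(obs^2)
  counts <- with_seed_if(seed, list(
    m2 = fc_perm_counts(tables$R, tables$L, tables$Q, 2, n_perm, obs, obs_global),
    m4 = fc_perm_counts(tables$R, tables$L, tables$Q, 4, n_perm, obs, obs_global)
  ))
  p2 <- (counts$m2$cell + 1) / (n_perm + 1)
  p4 <- (counts$m4$cell + 1) / (n_perm + 1)
  pc <- pmax(p2, p4)
  cells <- tibble::tibble(
    trait = rep(rownames(obs), times = ncol(obs)),
    metric = rep(colnames(obs), each = nrow(obs)),
    statistic = as.vector(obs),
    p_model2 = as.vector(p2),
    p_model4 = as.vector(p4),
    p_combined = as.vector(pc)
  )
  if (fdr) cells$p_combined <- p.adjust(cells$p_combined, method = "BH")
  cells$sig_sqrt05 <- cells$p_combined < alphas[1]
  cells$sig_05 <- cells$p_combined < alphas[2]
  global <- tibble::tibble(
    model = c("L-R (model 2)", "L-Q (model 4)"),
    statistic = obs_global,
    p_value = c((counts$m2$global + 1) / (n_perm + 1),
                (counts$m4$global + 1) / (n_perm + 1))
  )
  structure(
    list(cells = cells, global = global, statistic = obs,
         n_perm = n_perm, seed = seed, alphas = alphas, fdr = fdr),
    class = "fourth_corner_fit"
  )
}

#' @export
print.fourth_corner_fit <- function(x, ...) {
  cat("<fourth_corner_fit> ", nrow(x$cells), " trait-metric pairs, ",
      x$n_perm, " permutations\n", sep = "")
  cat("  flagged at alpha = sqrt(0.05): ", sum(x$cells$sig_sqrt05),
      "; at alpha = 0.05: ", sum(x$cells$sig_05), "\n", sep = "")
  cat("  global: ", paste0(x$global$model, " p = ", signif(x$global$p_value, 3),
                           collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @rdname fourth_corner
#' @param x,object A `fourth_corner_fit`.
#' @param ... Unused.
tidy.fourth_corner_fit <- function(x, ...) x$cells

#' @exportS3Method generics::glance
#' @rdname fourth_corner
glance.fourth_corner_fit <- function(x, ...) {
  tibble::tibble(
    statistic = x$global$statistic[1],
    p_lr = x$global$p_value[1],
    p_lq = x$global$p_value[2],
    n_sig_sqrt05 = sum(x$cells$sig_sqrt05),
    n_sig_05 = sum(x$cells$sig_05),
    n_perm = x$n_perm
  )
}

# plot and species scores of an RLQ decomposition of bare matrices; used to
# rebuild axes under permutation
rlq_scores_mat <- function(R, L, Q, n_axes) {
  tot <- sum(L)
  P <- L / tot
  rw <- rowSums(P)
  cw <- colSums(P)
  Rs <- weighted_standardize(R, rw)
  Qs <- weighted_standardize(Q, cw)
  sv <- svd(crossprod(Rs, P %*% Qs), nu = n_axes, nv = n_axes)
  list(plot = Rs %*% sv$u, species = Qs %*% sv$v, row_w = rw, col_w = cw)
}

#' Association of individual variables with the RLQ axes
#'
#' Measures the strength of association of every landscape metric and every
#' trait with the leading ordination axes as a weighted Pearson correlation:
#' metrics against the plot scores (correspondence row weights), traits
#' against the species scores (column weights). Significance comes from the
#' matching fourth-corner permutation model (model 2 for metrics, model 4
#' for traits); the ordination is recomputed under every permutation and the
#' test is two-sided on the absolute correlation.
#'
#' @inheritParams fourth_corner
#' @param fit An [rlq()] fit of the same tables.
#' @param axes Axis indices to test (default `1:2`).
#' @return A tibble with `side`, `variable`, `axis`, `correlation`,
#'   `p_value`, `sig_sqrt05`, `sig_05`.
#' @export
axes_association <- function(tables, fit, n_perm = 49999, seed = NULL,
                             axes = 1:2, alphas = c(sqrt(0.05), 0.05)) {
  stopifnot(inherits(tables, "study_tables"), inherits(fit, "rlq_fit"))
  if (any(axes < 1) || any(axes > length(fit$eigenvalues))) {
    abort(paste0("`axes` must be within 1..", length(fit$eigenvalues), "."))
  }
  n_axes <- max(axes)
  obs_r <- fit$metric_cor[, axes, drop = FALSE]
  obs_q <- fit$trait_cor[, axes, drop = FALSE]
  counts <- with_seed_if(seed, {
    cr <- matrix(0L, nrow(obs_r), ncol(obs_r))
    cq <- matrix(0L, nrow(obs_q), ncol(obs_q))
    for (b in seq_len(n_perm)) {
      # model 2: reassign abundance profiles to plots, re-derive the axes
      L2 <- tables$L[sample(nrow(tables$L)), , drop = FALSE]
      s2 <- rlq_scores_mat(tables$R, L2, tables$Q, n_axes)
      null_r <- sapply(seq_along(axes), function(a) {
        apply(tables$R, 2, wcor, y = s2$plot[, axes[a]], w = s2$row_w)
      })
      cr <- cr + (abs(null_r) >= abs(obs_r))
      # model 4: reassign trait syndromes to species
      L4 <- tables$L[, sample(ncol(tables$L)), drop = FALSE]
      s4 <- rlq_scores_mat(tables$R, L4, tables$Q, n_axes)
      null_q <- sapply(seq_along(axes), function(a) {
        apply(tables$Q, 2, wcor, y = s4$species[, axes[a]], w = s4$col_w)
      })
      cq <- cq + (abs(null_q) >= abs(obs_q))
    }
    list(r = cr, q = cq)
  })
  assemble <- function(obs, cnt, side) {
    tibble::tibble(
      side = side,
      variable = rep(rownames(obs), times = length(axes)),
      axis = rep(axes, each = nrow(obs)),
      correlation = as.vector(obs),
      p_value = as.vector((cnt + 1) / (n_perm + 1))
    )
  }
  out <- dplyr::bind_rows(assemble(obs_r, counts$r, "metric"),
                          assemble(obs_q, counts$q, "trait"))
  out$sig_sqrt05 <- out$p_value < alphas[1]
  out$sig_05 <- out$p_value < alphas[2]
  out
}
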