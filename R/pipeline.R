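#' Run the full patch-trait analysis and write its result tables
#'
#' End-to-end driver: starting from study tables, a list of species-patch
#' grids (plus trait table and registry), or a [simulation_config()], it
#' computes plot and species landscape metrics (grid input), clusters the
#' releves and runs the metric ANOVAs, fits the basic RLQ, the partial RLQs
#' for the available covariates, and the combined fourth-corner and
#' variable-axis permutation tests, writing every result as a CSV with
#' stable headers plus a plain-text run manifest. Given the same input and
#' seed the outputs are identical across runs.
#'
#' @param input A [study_tables()], a list of [species_grid()] objects, or a
#'   [simulation_config()].
#' @param output_dir Directory for the result files (created if needed).
#' @param q,registry Trait table and [species_registry()], required when
#'   `input` is a list of grids.
#' @param k Number of releve clusters (default 3).
#' @param ward_variant `"ward.D"` (default) or `"ward.D2"`.
#' @param n_perm Permutations for all tests (default 49,999).
#' @param seed Integer seed controlling every stochastic stage.
#' @param covariates Covariates to condition the partial RLQs on (those
#'   missing from the input are skipped with a message).
#' @return Invisibly, a list with all fitted objects and result tibbles.
#' @export
run_study <- function(input, output_dir, q = NULL, registry = NULL,
                      k = 3, ward_variant = c("ward.D", "ward.D2"),
                      n_perm = 49999, seed = NULL,
                      covariates = c("terrain_age", "cobble")) {
  ward_variant <- match.arg(ward_variant)
  t0 <- Sys.time()
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  grids <- NULL
  if (inherits(input, "simulation_config")) {
    study <- generate_study(input)
    grids <- study$grids
    tables <- study$tables
    out$study <- study
  } else if (inherits(input, "study_tables")) {
    tables <- input
  } else if (is.list(input) && all(vapply(input, inherits, logical(1), "species_grid"))) {
    if (is.null(q) || is.null(registry)) {
      abort("grid input needs `q` (trait table) and `registry`.")
    }
    grids <- input
    tables <- study_from_grids(grids, q, registry)
  } else {
    abort("`input` must be study_tables, a list of species_grid, or a simulation_config.")
  }
  wr <- function(x, name) readr::write_csv(x, file.path(output_dir, name))

  if (!is.null(grids)) {
    patches <- purrr::map_dfr(grids, label_patches)
    out$patches <- patches
    wr(dplyr::rename(patches, area_cm2 = "area", perimeter_cm = "perimeter"),
       "patches.csv")
    out$species_metrics <- species_metrics(patches, n_plots = length(grids),
                                           registry = if (!is.null(registry)) registry else NULL)
    wr(out$species_metrics, "species_metrics.csv")
  }
  out$plot_metrics <- matrix_to_tbl(tables$R, "plot_id")
  wr(out$plot_metrics, "plot_metrics.csv")

  out$clusters <- cluster_releves(tables$L, k = k, variant = ward_variant)
  wr(tidy(out$clusters), "clusters.csv")

  groupings <- list(cluster = tidy(out$clusters))
  if (!is.null(tables$covariates)) {
    cov <- tables$covariates
    if (!all(is.na(cov$terrain_age_class))) {
      groupings$terrain_age <- dplyr::tibble(plot_id = cov$plot_id,
                                             terrain_age = cov$terrain_age_class)
    }
    if (!all(is.na(cov$cobble_class))) {
      groupings$cobble <- dplyr::tibble(plot_id = cov$plot_id,
                                        cobble = cov$cobble_class)
    }
  }
  out$anova <- purrr::map_dfr(groupings, function(g) {
    anova_metrics(out$plot_metrics, g)
  })
  wr(tidyr::unnest(out$anova, "groups", names_sep = "_"), "anova.csv")

  out$rlq <- rlq(tables)
  wr(tidy(out$rlq, "eigenvalues"), "rlq_eigen.csv")
  wr(tidy(out$rlq, "scores"), "rlq_scores.csv")
  wr(tidy(out$rlq, "correlations"), "rlq_correlations.csv")

  out$partial <- list()
  for (cv in covariates) {
    fit_cv <- tryCatch(partial_rlq(tables, covariate = cv),
                       error = function(e) {
                         message("skipping partial RLQ on '", cv, "': ",
                                 conditionMessage(e))
                         NULL
                       })
    if (!is.null(fit_cv)) {
      out$partial[[cv]] <- fit_cv
      wr(tidy(fit_cv, "eigenvalues"), paste0("rlq_eigen_", cv, ".csv"))
    }
  }

  out$fourth_corner <- fourth_corner(tables, n_perm = n_perm, seed = seed)
  wr(tidy(out$fourth_corner), "fourthcorner.csv")
  wr(glance(out$fourth_corner), "fourthcorner_global.csv")

  out$axes <- axes_association(tables, out$rlq, n_perm = n_perm,
                               seed = if (is.null(seed)) NULL else seed + 1L)
  wr(out$axes, "axes_association.csv")

  manifest <- c(
    timestamp = format(t0, "%Y-%m-%d %H:%M:%S"),
    seed = if (is.null(seed)) "none" else as.character(seed),
    n_perm = as.character(n_perm),
    k = as.character(k),
    ward_variant = ward_variant,
    n_plots = as.character(nrow(tables$L)),
    n_species = as.character(ncol(tables$L)),
    package_version = as.character(utils::packageVersion("patchtraits")),
    elapsed_s = as.character(round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  )
  writeLines(paste(names(manifest), manifest, sep = ": "),
             file.path(output_dir, "manifest.txt"))
  invisible(out)
}
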