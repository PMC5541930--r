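#' Configuration of a synthetic patch-trait study
#'
#' Describes a simulated field campaign shaped like the glacier-foreland
#' survey the package is built around: `n_plots` square plots rasterised at
#' `cell_size` cm, `n_species` species whose patches are grown as random
#' 4-connected blobs with positively skewed (lognormal) target areas, a trait
#' table correlated around one latent axis, and three-level terrain-age and
#' cobble-cover classes assigned independently of everything else (the null
#' scenario for the covariates).
#'
#' The coupling `beta` ties the latent trait axis to patch geometry through
#' two channels: species sorting (a plot-level gradient multiplies the latent
#' score in the occupancy model, so plots differ in which trait syndromes
#' dominate) and patch size (the latent score shifts the log expected patch
#' area). At `beta = 0` traits are unrelated to the spatial mosaic, giving a
#' complete null for type-I studies; `beta` around 2 produces strong,
#' reliably detectable coupling.
#'
#' @param n_plots Number of plots (default 46).
#' @param grid_dim Raster rows/cols per plot (default `c(100, 100)`).
#' @param cell_size Cell edge, cm (default 1).
#' @param n_species Number of species (default 16).
#' @param n_traits Number of traits (default 9); the third trait is emitted
#'   as an ordinal 1-6 score to exercise ordinal trait coding.
#' @param beta Trait-to-patch-geometry coupling, >= 0 (default 1).
#' @param occupancy Baseline probability that a species occurs in a plot
#'   (default 0.35, giving realistic per-plot species richness).
#' @param patches_per_occupied Mean number of patches of a species present in
#'   a plot (default 5).
#' @param patch_area_meanlog,patch_area_sdlog Lognormal target patch area in
#'   cells (defaults `log(28)` and 0.9: mean area near 43 cells with strong
#'   positive skew).
#' @param area_coupling Scale of the latent-score effect on log patch area
#'   per unit `beta` (default 0.35).
#' @param trait_loadings Loadings of the traits on the latent axis, recycled
#'   to `n_traits`.
#' @param covariate_effect Effect of the terrain-age class on the plot
#'   gradient (default 0 = classes carry no signal).
#' @param seed Optional integer seed; a seeded configuration regenerates the
#'   identical study.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_plots = 46, grid_dim = c(100, 100),
                              cell_size = 1, n_species = 16, n_traits = 9,
                              beta = 1, occupancy = 0.35,
                              patches_per_occupied = 5,
                              patch_area_meanlog = log(28),
                              patch_area_sdlog = 0.9,
                              area_coupling = 0.35,
                              trait_loadings = c(0.8, -0.7, 0.6, -0.5, 0.75,
                                                 0.4, -0.6, 0.7, 0.3),
                              covariate_effect = 0, seed = NULL) {
  if (n_plots < 2 || n_species < 2 || n_traits < 1) {
    abort("need at least 2 plots, 2 species and 1 trait.")
  }
  if (length(grid_dim) != 2 || any(grid_dim < 4)) abort("`grid_dim` must be two values >= 4.")
  if (beta < 0) abort("`beta` must be nonnegative.")
  if (occupancy <= 0 || occupancy >= 1) abort("`occupancy` must lie in (0, 1).")
  if (patches_per_occupied < 1) abort("`patches_per_occupied` must be >= 1.")
  if (patch_area_sdlog < 0) abort("`patch_area_sdlog` must be >= 0.")
  structure(
    list(n_plots = n_plots, grid_dim = as.integer(grid_dim),
         cell_size = cell_size, n_species = n_species, n_traits = n_traits,
         beta = beta, occupancy = occupancy,
         patches_per_occupied = patches_per_occupied,
         patch_area_meanlog = patch_area_meanlog,
         patch_area_sdlog = patch_area_sdlog,
         area_coupling = area_coupling,
         trait_loadings = rep_len(trait_loadings, n_traits),
         covariate_effect = covariate_effect, seed = seed),
    class = "simulation_config"
  )
}

#' Generate a synthetic patch-trait study
#'
#' Draws a complete study from a [simulation_config()]: latent species
#' scores, a correlated trait table, per-plot occupancy and patch counts,
#' lognormal target patch areas, and one species-patch raster per plot grown
#' by random frontier accretion (Eden growth) with first-come overlap
#' resolution. The abundance table `L` is counted from the emitted grids and
#' the metric table `R` is computed from them via [label_patches()] and
#' [plot_metrics()], so the tables are exactly self-consistent with the
#' rasters. Every plot is guaranteed at least one patch (an empty plot has
#' no defined metrics). The generating truth (latent scores, plot gradient,
#' `beta`) is retained for recovery analyses.
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_study`: list with `grids`,
#'   `tables` (a [study_tables()]), `registry`, `truth` and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed_if(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  n_sp <- cfg$n_species
  n_pl <- cfg$n_plots
  sp_labels <- sprintf("sp%02d", seq_len(n_sp))
  plot_labels <- sprintf("p%02d", seq_len(n_pl))
  registry <- species_registry(seq_len(n_sp), sp_labels)

  # latent axis and traits
  z <- rnorm(n_sp)
  lam <- cfg$trait_loadings
  traits <- sapply(seq_len(cfg$n_traits), function(j) {
    lam[j] * z + sqrt(max(0, 1 - lam[j]^2)) * rnorm(n_sp)
  })
  traits <- matrix(traits, nrow = n_sp)
  if (cfg$n_traits >= 3) {
    # ordinal 1-6 coding (lateral-spread style trait)
    traits[, 3] <- as.integer(cut(traits[, 3], breaks = quantile(
      traits[, 3], probs = seq(0, 1, length.out = 7), type = 7),
      include.lowest = TRUE, labels = FALSE))
  }
  dimnames(traits) <- list(sp_labels, sprintf("trait%02d", seq_len(cfg$n_traits)))

  # plot gradient and null-effect covariates
  u <- rnorm(n_pl)
  ta <- sample(rep_len(c("ta1", "ta2", "ta3"), n_pl))
  ts <- sample(rep_len(c("ts1", "ts2", "ts3"), n_pl))
  if (cfg$covariate_effect != 0) {
    u <- u + cfg$covariate_effect * scale(as.integer(factor(ta)))[, 1]
  }

  # occupancy and patch counts: species sorting along the gradient
  eta <- qlogis(cfg$occupancy) + cfg$beta * outer(u, z)
  occupied <- matrix(rbinom(n_pl * n_sp, 1, plogis(eta)), n_pl, n_sp)
  empty <- rowSums(occupied) == 0
  if (any(empty)) {  # guarantee at least one patch per plot
    occupied[cbind(which(empty), sample.int(n_sp, sum(empty), replace = TRUE))] <- 1L
  }
  n_patches <- occupied * (1 + matrix(rpois(n_pl * n_sp, cfg$patches_per_occupied - 1),
                                      n_pl, n_sp))

  n_cells <- prod(cfg$grid_dim)
  grids <- vector("list", n_pl)
  for (i in seq_len(n_pl)) {
    sp_codes <- rep(seq_len(n_sp), times = n_patches[i, ])
    areas <- pmax(1, round(rlnorm(
      length(sp_codes),
      meanlog = cfg$patch_area_meanlog + cfg$area_coupling * cfg$beta * z[sp_codes],
      sdlog = cfg$patch_area_sdlog)))
    areas <- pmin(areas, floor(n_cells / 4))
    if (sum(areas) > 0.95 * n_cells) {
      abort(paste0("requested cover (", sum(areas), " cells) exceeds grid capacity in plot ",
                   plot_labels[i], "; lower occupancy, patch counts or areas."))
    }
    ord <- sample(length(sp_codes))  # first-come overlap resolution in random order
    values <- grow_blobs_cpp(cfg$grid_dim[1], cfg$grid_dim[2],
                             as.integer(sp_codes[ord]), as.integer(areas[ord]),
                             200L)
    grids[[i]] <- species_grid(values, plot_id = plot_labels[i],
                               cell_size = cfg$cell_size,
                               terrain_age_class = ta[i], cobble_class = ts[i],
                               registry = registry)
  }

  q_tbl <- matrix_to_tbl(traits, "species")
  tables <- withCallingHandlers(
    study_from_grids(grids, q_tbl, registry),
    warning = function(w) invokeRestart("muffleWarning")
  )
  keep <- colnames(tables$L)  # species that realised nonzero cover
  structure(
    list(grids = grids, tables = tables, registry = registry,
         truth = list(beta = cfg$beta,
                      latent = setNames(z, sp_labels)[keep],
                      plot_gradient = setNames(u, plot_labels)),
         config = cfg),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> beta = ", x$config$beta, "; ", sep = "")
  print(x$tables)
  invisible(x)
}

#' Signal recovery of the pipeline on a synthetic study
#'
#' Summarises how well the analysis recovers the generating coupling: the
#' total co-inertia and leading-axis share of the RLQ fit, the absolute
#' weighted correlation between the generating latent species scores and the
#' species scores on axis 1, and (when a [fourth_corner()] fit is supplied)
#' the number of flagged trait-metric cells and the global p-values.
#'
#' @param study A [generate_study()] result.
#' @param fit An [rlq()] fit of `study$tables` (computed if missing).
#' @param fc Optional [fourth_corner()] fit of the same tables.
#' @return A one-row tibble.
#' @export
recovery_report <- function(study, fit = NULL, fc = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  fit <- fit %||% rlq(study$tables)
  sc <- fit$species_scores[names(study$truth$latent), 1]
  out <- tibble::tibble(
    beta = study$truth$beta,
    sum_inertia = fit$sum_inertia,
    axis1_percent = fit$percent[1],
    latent_axis_cor = abs(wcor(study$truth$latent, sc, fit$col_w))
  )
  if (!is.null(fc)) {
    g <- glance(fc)
    out <- dplyr::bind_cols(out, g[c("p_lr", "p_lq", "n_sig_sqrt05", "n_sig_05")])
  }
  out
}
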