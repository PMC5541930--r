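#' Species data from the Nardis glacier-foreland survey
#'
#' Two small tables for the 16 vascular plant species analysed in the
#' 46-plot Nardis foreland survey the package is modelled on.
#' `nardis_trait_table()` returns the nine quantitative functional traits per
#' species, compiled from alpine trait databases: canopy height `CH` (mm),
#' leaf dry matter content `LDMC` (%), lateral spread `LS` (ordinal 1-6),
#' leaf dry weight `LDW` (mg), specific leaf area `SLA` (mm^2/mg), leaf
#' nitrogen content `LNC` (%), leaf area `LA` (mm^2), leaf fresh weight
#' `LFW` (mg) and leaf carbon content `LCC` (%). This is the Q-table of the
#' survey's coupled ordination. `nardis_patch_summary()` returns the
#' field-measured species-level patch summaries over all plots: frequency of
#' occurrence (%), mean patch size `MPS` (cm^2, with sd), total cover `CA`
#' (cm^2), mean shape index `MSI` (with sd), patch count `NP` and total edge
#' `TE` (cm). Species are keyed by the customary six-letter abbreviations
#' (e.g. `PoaAlp`, *Poa alpina*).
#'
#' The survey's plot-level tables (plot-by-metric, plot-by-species, per-plot
#' covariates) and its per-patch database are separate deposited files that
#' are not redistributed with the package; functions and tests that
#' reproduce the published plot-level results look for those files under
#' `inst/extdata/nardis/` (see [nardis_deposited_tables()]).
#'
#' @return A tibble keyed by `species`.
#' @export
nardis_trait_table <- function() {
  readr::read_csv(system.file("extdata", "nardis_species_traits.csv",
                              package = "patchtraits"),
                  show_col_types = FALSE)
}

#' @rdname nardis_trait_table
#' @export
nardis_patch_summary <- function() {
  readr::read_csv(system.file("extdata", "nardis_species_patch_summary.csv",
                              package = "patchtraits"),
                  show_col_types = FALSE)
}

#' Locate the deposited Nardis plot-level tables, if installed
#'
#' The plot-level survey data are deposited alongside the original study and
#' are not redistributed here. To reproduce the published plot-level results,
#' download them and place four CSVs under `<package>/extdata/nardis/`:
#' `r_table.csv` (plot-by-metric, identifier first column), `l_table.csv`
#' (plot-by-species abundances), `covariates.csv`
#' (`plot_id,terrain_age_class,cobble_class`) and optionally `patches.csv`
#' (per-patch records with `species` and `area` columns). The Q-table ships
#' with the package ([nardis_trait_table()]).
#'
#' @return A [study_tables()] object when the files are present, otherwise
#'   `NULL`.
#' @export
nardis_deposited_tables <- function() {
  dir <- system.file("extdata", "nardis", package = "patchtraits")
  if (dir == "") return(NULL)
  paths <- file.path(dir, c("r_table.csv", "l_table.csv", "covariates.csv"))
  if (!all(file.exists(paths))) return(NULL)
  load_study_tables(paths[1], paths[2],
                    system.file("extdata", "nardis_species_traits.csv",
                                package = "patchtraits"),
                    covariate_path = paths[3])
}
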