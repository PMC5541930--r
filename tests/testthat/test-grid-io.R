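test_that("long CSV reading defaults unlisted cells to bare substrate", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plot_id,row,col,species_code",
               "p01,0,0,1",
               "p01,99,99,1"), f)
  g <- read_species_grid(f, "long_csv")
  expect_identical(dim(g), c(100L, 100L))
  expect_identical(sum(g$values != 0L), 2L)
  expect_identical(g$values[1, 1], 1L)
  expect_identical(g$values[100, 100], 1L)
  expect_identical(g$plot_id, "p01")
})

test_that("write/read round trip is exact in both formats", {
  withr::local_seed(7)
  vals <- rand_grid_values(17, 23, n_species = 4)
  g <- species_grid(vals, plot_id = "pX", cell_size = 2,
                    terrain_age_class = "ta2", cobble_class = "ts1")
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_species_grid(g, f1, "long_csv")
  g1 <- read_species_grid(f1, "long_csv")
  expect_identical(g1, g)

  f2 <- withr::local_tempfile(fileext = ".asc")
  write_species_grid(g, f2, "ascii_grid")
  g2 <- read_species_grid(f2, "ascii_grid", plot_id = "pX")
  expect_identical(g2$values, g$values)
  expect_identical(g2$cell_size, g$cell_size)
  expect_identical(g2$plot_id, g$plot_id)
})

test_that("ESRI ASCII NODATA tokens map to bare substrate cell-by-cell", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "1 -9999 2",
               "-9999 0 1"), f)
  g <- read_species_grid(f, "ascii_grid", plot_id = "p")
  expect_identical(g$values,
                   matrix(c(1L, 0L, 0L, 0L, 2L, 1L), 2, 3))
})

test_that("malformed and inconsistent grid files fail with located errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plot_id,row,col,species_code",
               "p,1,1,1", "p,1,1,2"), f)
  expect_error(read_species_grid(f, "long_csv"), "duplicate cell \\(1,1\\)")

  writeLines(c("plot_id,row,col,species_code", "p,120,0,1"), f)
  expect_error(read_species_grid(f, "long_csv"), "outside")

  writeLines(c("plot_id,row,col,species_code", "p,0,0,9"), f)
  reg <- species_registry(1:2, c("a", "b"))
  expect_error(read_species_grid(f, "long_csv", registry = reg), "not in registry")

  writeLines(c("plot_id,row,col,species_code", "p1,0,0,1", "p2,0,0,1"), f)
  expect_error(read_species_grid(f, "long_csv"), "several plots")

  fa <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "cellsize 1",
               "1 2", "1 x"), fa)
  expect_error(read_species_grid(fa, "ascii_grid"), "line 5")
})

test_that("grid construction validates codes, dimensions and covariates", {
  expect_error(species_grid(matrix(-1L, 2, 2)), "nonnegative")
  expect_error(species_grid(matrix(1L, 2, 2), cell_size = 0), "positive")
  expect_error(species_grid(matrix(1L, 2, 2), terrain_age_class = "old"), "ta1")
  reg <- species_registry(1, "a")
  expect_error(species_grid(matrix(2L, 2, 2), registry = reg), "not in registry")
  expect_error(species_registry(c(1, 1), c("a", "b")), "unique")
  expect_error(species_registry(0, "bare"), "reserved")
})

test_that("study table alignment is label-based and order-invariant", {
  withr::local_seed(42)
  tab <- make_tables(8, 5, 3, 2)
  perm <- sample(nrow(tab$L))
  shuffled <- study_tables(tab$R[perm, ], tab$L[perm, ], tab$Q)
  expect_identical(shuffled$L[rownames(tab$L), ], tab$L)
  st_perm <- study_tables(tab$R, tab$L[perm, ], tab$Q)
  expect_equal(st_perm$L[rownames(tab$L), ], tab$L)
  expect_equal(st_perm$R, tab$R[rownames(st_perm$L), ])

  # missing species in Q is an alignment error naming the offender
  expect_error(study_tables(tab$R, tab$L, tab$Q[-2, , drop = FALSE]),
               "only in L: \\[s02\\]")
  # all-zero species are dropped with a warning
  L2 <- tab$L; L2[, 3] <- 0
  expect_warning(st <- study_tables(tab$R, L2, tab$Q), "s03")
  expect_false("s03" %in% colnames(st$L))
  expect_false("s03" %in% rownames(st$Q))
  # all-zero plots are rejected
  L3 <- tab$L; L3[2, ] <- 0
  expect_error(suppressWarnings(study_tables(tab$R, L3, tab$Q)), "p02")
})

test_that("CSV table loading reproduces the in-memory bundle", {
  withr::local_seed(11)
  tab <- make_tables(6, 4, 3, 2, covariates = TRUE)
  dir <- withr::local_tempdir()
  p <- function(x) file.path(dir, x)
  readr::write_csv(tibble::as_tibble(tab$R, rownames = "plot_id"), p("r.csv"))
  readr::write_csv(tibble::as_tibble(tab$L, rownames = "plot_id"), p("l.csv"))
  readr::write_csv(tibble::as_tibble(tab$Q, rownames = "species"), p("q.csv"))
  readr::write_csv(tab$covariates, p("cov.csv"))
  st <- load_study_tables(p("r.csv"), p("l.csv"), p("q.csv"), p("cov.csv"))
  expect_equal(st$R, tab$R)
  expect_equal(st$L, tab$L)
  expect_equal(st$Q, tab$Q)
  expect_equal(st$covariates, tab$covariates)
})

test_that("the packaged species trait table aligns with matching abundances", {
  q <- nardis_trait_table()
  expect_identical(dim(q), c(16L, 10L))  # species column + 9 traits
  withr::local_seed(3)
  L <- matrix(rpois(5 * 16, 3) + 1, 5, 16,
              dimnames = list(paste0("p", 1:5), q$species))
  R <- matrix(rnorm(5 * 2), 5, 2, dimnames = list(rownames(L), c("MPS", "SHDI")))
  st <- study_tables(R, L, q)
  expect_identical(rownames(st$Q), colnames(st$L))
  expect_identical(ncol(st$Q), 9L)
})
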