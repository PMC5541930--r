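test_that("elementary patch geometries are measured exactly", {
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  p <- label_patches(species_grid(m))
  expect_equal(nrow(p), 1)
  expect_equal(p$area, 1)
  expect_equal(p$perimeter, 4)
  expect_equal(p$shape_index, 1)

  # diagonal contact does not join patches under the four-neighbour rule
  m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[2, 2] <- 1L
  expect_equal(nrow(label_patches(species_grid(m))), 2)

  # 1 x 3 bar: area 3, perimeter 8, shape index 8 / (4 sqrt(3))
  m <- matrix(0L, 4, 5); m[2, 2:4] <- 2L
  p <- label_patches(species_grid(m))
  expect_equal(p$area, 3)
  expect_equal(p$perimeter, 8)
  expect_equal(p$shape_index, 8 / (4 * sqrt(3)), tolerance = 1e-12)

  # adjacent patches of different species each count the shared edge
  m <- matrix(0L, 3, 4); m[2, 1:2] <- 1L; m[2, 3:4] <- 2L
  p <- label_patches(species_grid(m))
  expect_equal(sort(p$perimeter), c(6, 6))
})

test_that("shape index is 1 for squares and validates its domain", {
  expect_equal(shape_index(4, 8), 1)
  expect_equal(shape_index(3, 8), 8 / (4 * sqrt(3)))
  for (n in 1:5) {
    m <- matrix(0L, n + 2, n + 2)
    m[seq_len(n) + 1, seq_len(n) + 1] <- 1L
    expect_equal(label_patches(species_grid(m))$shape_index, 1)
  }
  expect_error(shape_index(0, 4), "positive")
  expect_error(shape_index(4, -1), "positive")
})

test_that("labelling agrees with the exhaustive graph-component oracle", {
  withr::local_seed(101)
  for (rep in 1:20) {
    vals <- rand_grid_values(12, 12, n_species = 3, p_occupied = runif(1, 0.2, 0.8))
    got <- label_patches(species_grid(vals))
    got <- got[order(got$species_code, got$area, got$perimeter), ]
    want <- oracle_label_patches(vals)
    expect_equal(got$species_code, want$species_code)
    expect_equal(got$area, want$area)
    expect_equal(got$perimeter, want$perimeter)
    # conservation: patch areas partition the vegetated cells
    expect_equal(sum(got$area), sum(vals != 0))
  }
})

test_that("patch records are invariant under rotation and mirroring", {
  withr::local_seed(55)
  vals <- rand_grid_values(10, 14, n_species = 4)
  base <- label_patches(species_grid(vals))
  key <- function(p) p[order(p$species_code, p$area, p$perimeter),
                       c("species_code", "area", "perimeter")]
  rot90 <- t(vals)[ncol(vals):1, , drop = FALSE]
  mirror <- vals[, ncol(vals):1, drop = FALSE]
  for (v in list(rot90, mirror)) {
    p <- label_patches(species_grid(v))
    expect_equal(key(p), key(base), ignore_attr = TRUE)
  }
})

test_that("plot metrics follow their defining identities", {
  m <- matrix(0L, 6, 6)
  m[2:3, 2:3] <- 1L           # 2x2 square, species 1
  m[5, 2:5] <- 2L             # 1x4 bar, species 2
  pm <- plot_metrics(label_patches(species_grid(m, plot_id = "A")))
  expect_equal(pm$NP, 2L)
  expect_equal(pm$PR, 2L)
  expect_equal(pm$MPS, 4)
  expect_equal(pm$MPS * pm$NP, sum(m != 0))
  expect_equal(pm$TE, 8 + 10)
  expect_equal(pm$SHDI, log(2), tolerance = 1e-12)  # equal species areas

  # single patch: PSCV = 0; single species: SHDI = 0
  single <- plot_metrics(label_patches(species_grid(matrix(c(0L, 1L, 0L, 0L), 2))))
  expect_equal(single$PSCV, 0)
  expect_equal(single$SHDI, 0)
  expect_equal(single$NP, 1L)

  # empty plots are reported as defined-empty records
  both <- plot_metrics(label_patches(species_grid(m, plot_id = "A")),
                       plot_ids = c("A", "B"))
  expect_equal(both$NP, c(2L, 0L))
  expect_true(is.na(both$MPS[2]))
})

test_that("Shannon diversity is capped by log richness", {
  withr::local_seed(77)
  for (rep in 1:10) {
    vals <- rand_grid_values(15, 15, n_species = 5)
    pm <- plot_metrics(label_patches(species_grid(vals)))
    expect_lte(pm$SHDI, log(pm$PR) + 1e-12)
  }
})

test_that("species metrics aggregate across plots", {
  g1 <- species_grid(matrix(c(1L, 1L, 0L, 0L), 2), plot_id = "p1")
  g2 <- species_grid(matrix(c(1L, 1L, 0L, 2L), 2), plot_id = "p2")
  patches <- dplyr::bind_rows(label_patches(g1), label_patches(g2))
  sm <- species_metrics(patches, n_plots = 4)
  r1 <- sm[sm$species_code == 1, ]
  expect_equal(r1$frequency, 100 * 2 / 4)
  expect_equal(r1$MPS, 2)        # two identical 2-cell patches
  expect_equal(r1$MPS_sd, 0)
  expect_equal(r1$CA, 4)
  expect_equal(r1$NP, 2L)
  expect_error(species_metrics(patches, 4, registry = species_registry(1, "a")),
               "not in registry")
})

test_that("distribution summaries report moments, quartiles and skewness", {
  s <- distribution_summary(c(1, 2, 3))
  expect_equal(s$skewness, 0)
  expect_equal(s$mean, 2)
  s2 <- distribution_summary(c(1, 2, 3, 4, 10))
  expect_equal(c(s2$q25, s2$median, s2$q75), c(2, 3, 4))
  expect_equal(s2$max, 10)
  withr::local_seed(5)
  expect_gt(distribution_summary(rlnorm(500, 0, 1))$skewness, 0)
  expect_true(is.na(distribution_summary(7)$sd))
  expect_true(is.na(distribution_summary(rep(2, 5))$skewness))
})

test_that("metric correlations match the direct formula", {
  withr::local_seed(9)
  m <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("p", 1:5), c("a", "b", "c")))
  m <- cbind(m, d = m[, "a"], e = -2 * m[, "b"] + 3)
  mc <- metric_correlations(m)
  pick <- function(x, y) mc$r[mc$metric_a == x & mc$metric_b == y]
  expect_equal(pick("a", "d"), 1, tolerance = 1e-12)
  expect_equal(pick("b", "e"), -1, tolerance = 1e-12)
  expect_equal(pick("a", "a"), 1)
  # direct formula evaluation for one generic pair
  r_ab <- sum((m[, "a"] - mean(m[, "a"])) * (m[, "b"] - mean(m[, "b"]))) /
    sqrt(sum((m[, "a"] - mean(m[, "a"]))^2) * sum((m[, "b"] - mean(m[, "b"]))^2))
  expect_equal(pick("a", "b"), r_ab, tolerance = 1e-12)
  # constant metric is flagged missing
  mc2 <- metric_correlations(cbind(m, f = 1))
  expect_true(all(is.na(mc2$r[mc2$metric_a == "f" | mc2$metric_b == "f"])))
  expect_error(metric_correlations(m[1:2, ]), "at least 3")
})
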