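test_that("the statistic matrix matches the inflated-table correlation oracle", {
  # worked micro-table: 2 plots, 2 species, 1 trait, 1 metric
  L <- matrix(c(3, 1, 0, 2), 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  R <- matrix(c(1, -1), 2, 1, dimnames = list(rownames(L), "m"))
  Q <- matrix(c(0.5, 2), 2, 1, dimnames = list(colnames(L), "t"))
  tab <- study_tables(R, L, Q)
  expect_equal(fourth_corner_matrix(tab), oracle_fourth_corner(R, L, Q),
               tolerance = 1e-12)

  withr::local_seed(61)
  for (rep in 1:5) {
    tabs <- make_tables(7, 5, 3, 4)
    expect_equal(fourth_corner_matrix(tabs),
                 oracle_fourth_corner(tabs$R, tabs$L, tabs$Q),
                 tolerance = 1e-10)
    expect_true(all(abs(fourth_corner_matrix(tabs)) <= 1 + 1e-12))
  }
})

test_that("total co-inertia equals the sum of squared fourth-corner statistics", {
  withr::local_seed(62)
  for (rep in 1:8) {
    tabs <- make_tables(sample(5:10, 1), sample(4:8, 1), sample(2:5, 1),
                        sample(2:5, 1))
    expect_equal(sum(fourth_corner_matrix(tabs)^2), rlq(tabs)$sum_inertia,
                 tolerance = 1e-10)
  }
})

test_that("a near-constant trait produces a near-zero statistic", {
  withr::local_seed(63)
  tabs <- make_tables(8, 6, 2, 2)
  Q2 <- tabs$Q
  Q2[, 1] <- 1 + rnorm(6, sd = 1e-6)
  x <- fourth_corner_matrix(study_tables(tabs$R, tabs$L, Q2))
  expect_true(all(is.finite(x)))
  Q3 <- tabs$Q; Q3[, 1] <- 1
  expect_error(fourth_corner_matrix(study_tables(tabs$R, tabs$L, Q3)), "constant")
})

test_that("permutation p-values are valid, seeded and use the add-one rule", {
  withr::local_seed(64)
  tabs <- make_tables(8, 6, 3, 3)
  pt <- permutation_test(tabs, model = 2, n_perm = 49, seed = 5)
  expect_true(all(pt$cell_p > 0 & pt$cell_p <= 1))
  expect_true(all(abs(pt$cell_p * 50 - round(pt$cell_p * 50)) < 1e-9))  # multiples of 1/(B+1)
  expect_equal(permutation_test(tabs, model = 2, n_perm = 49, seed = 5)$cell_p,
               pt$cell_p)
  expect_error(permutation_test(tabs, model = 3), "model")
  pt1 <- permutation_test(tabs, model = 4, n_perm = 1, seed = 1)
  expect_true(all(pt1$cell_p %in% c(0.5, 1)))
})

test_that("a joint plot relabelling leaves statistics and seeded p-values unchanged", {
  withr::local_seed(65)
  tabs <- make_tables(9, 5, 3, 3, covariates = TRUE)
  perm <- sample(9)
  tabs2 <- study_tables(tabs$R[perm, ], tabs$L[perm, ], tabs$Q,
                        covariates = tabs$covariates[perm, ])
  x1 <- fourth_corner_matrix(tabs)
  x2 <- fourth_corner_matrix(tabs2)
  expect_equal(x1, x2, tolerance = 1e-12)
  # permutation p-values are equal in distribution (the drawn permutations
  # act on positions, so seeded runs agree only up to Monte-Carlo error)
  f1 <- fourth_corner(tabs, n_perm = 999, seed = 11)
  f2 <- fourth_corner(tabs2, n_perm = 999, seed = 11)
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-12)
  expect_lt(abs(glance(f1)$p_lr - glance(f2)$p_lr), 0.1)
  expect_lt(abs(glance(f1)$p_lq - glance(f2)$p_lq), 0.1)
})

test_that("the combined decision applies the max-p rule at both conventions", {
  withr::local_seed(66)
  fc <- fourth_corner(make_tables(10, 7, 3, 3), n_perm = 99, seed = 9)
  cells <- tidy(fc)
  expect_equal(cells$p_combined, pmax(cells$p_model2, cells$p_model4))
  expect_identical(cells$sig_sqrt05, cells$p_combined < sqrt(0.05))
  expect_identical(cells$sig_05, cells$p_combined < 0.05)
  # a cell passing one model but not the other is never flagged
  one_sided <- cells$p_model2 < sqrt(0.05) & cells$p_model4 >= sqrt(0.05)
  expect_false(any(cells$sig_sqrt05[one_sided]))
  g <- glance(fc)
  expect_true(all(c(g$p_lr, g$p_lq) > 0 & c(g$p_lr, g$p_lq) <= 1))
})

test_that("fourth-corner runs are reproducible from the seed", {
  withr::local_seed(67)
  tabs <- make_tables(8, 6, 3, 3)
  a <- fourth_corner(tabs, n_perm = 199, seed = 42)
  b <- fourth_corner(tabs, n_perm = 199, seed = 42)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$global, b$global)
})

test_that("axis associations recover a metric aligned with the axis", {
  withr::local_seed(68)
  st <- generate_study(scaled_config(beta = 2, seed = 6))
  fit <- rlq(st$tables)
  # append the fitted axis-1 plot score as an extra metric; it must correlate
  # almost perfectly with the re-fitted leading axis
  R2 <- cbind(st$tables$R, AX = fit$plot_scores[, 1])
  tab2 <- study_tables(R2, st$tables$L, st$tables$Q)
  fit2 <- rlq(tab2)
  aa <- axes_association(tab2, fit2, n_perm = 59, seed = 2)
  ax_row <- aa[aa$variable == "AX" & aa$axis == 1, ]
  expect_gt(abs(ax_row$correlation), 0.99)
  expect_true(all(abs(aa$correlation) <= 1 + 1e-12))
  expect_true(all(aa$p_value > 0 & aa$p_value <= 1))
  expect_setequal(unique(aa$side), c("metric", "trait"))
  expect_error(axes_association(tab2, fit2, axes = 1:99), "within")
})
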