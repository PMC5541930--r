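test_that("Bray-Curtis dissimilarity matches its defining formula", {
  L <- rbind(a = c(2, 0, 1), b = c(1, 1, 0), c = c(2, 0, 1), d = c(0, 5, 0))
  colnames(L) <- paste0("s", 1:3)
  d <- as.matrix(bray_curtis(L))
  expect_equal(d["a", "b"], 3 / 5)        # (|2-1|+|0-1|+|1-0|) / (3+2)
  expect_equal(d["a", "c"], 0)            # identical plots
  expect_equal(d["a", "d"], 1)            # disjoint species sets
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  # direct double-loop oracle on random abundances
  withr::local_seed(21)
  M <- matrix(rpois(30, 2) + 1, 5, 6)
  rownames(M) <- paste0("p", 1:5); colnames(M) <- paste0("s", 1:6)
  got <- as.matrix(bray_curtis(M))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(got[i, j], sum(abs(M[i, ] - M[j, ])) / sum(M[i, ] + M[j, ]),
                 tolerance = 1e-12)
  }
  M[2, ] <- 0
  expect_error(bray_curtis(M), "all-zero")
})

test_that("Ward clustering recovers separated groups and the oracle heights", {
  withr::local_seed(8)
  # two tight, well-separated composition blobs
  L <- rbind(matrix(rpois(5 * 3, 8) + 20, 5, 3),
             matrix(rpois(5 * 3, 1), 5, 3))
  L <- cbind(L, rbind(matrix(rpois(5 * 3, 1), 5, 3),
                      matrix(rpois(5 * 3, 8) + 20, 5, 3)))
  dimnames(L) <- list(paste0("p", 1:10), paste0("s", 1:6))
  cl <- cluster_releves(L, k = 2)
  groups <- split(cl$assignment$plot_id, cl$assignment$cluster)
  expect_setequal(groups[[1]], paste0("p", 1:5))
  expect_setequal(groups[[2]], paste0("p", 6:10))

  # k = n gives singletons
  expect_equal(dplyr::n_distinct(cluster_releves(L, k = 10)$assignment$cluster), 10)

  # merge heights match the naive Lance-Williams Ward oracle on a fixture
  L6 <- matrix(rpois(6 * 4, 3) + 1, 6, 4,
               dimnames = list(paste0("p", 1:6), paste0("s", 1:4)))
  d <- bray_curtis(L6)
  tree <- cluster_releves(L6, k = 2)$tree
  expect_equal(tree$height, ward_oracle_heights(d), tolerance = 1e-10)
})

test_that("cluster labels are canonical under plot reordering", {
  withr::local_seed(30)
  st <- generate_study(scaled_config(beta = 1, seed = 14))
  L <- st$tables$L
  cl1 <- cluster_releves(L, k = 3)
  perm <- sample(nrow(L))
  cl2 <- cluster_releves(L[perm, ], k = 3)
  j <- dplyr::inner_join(cl1$assignment, cl2$assignment, by = "plot_id")
  expect_identical(j$cluster.x, j$cluster.y)
  # labels CL1..CLk ordered by the characteristic species' mean abundance
  expect_identical(cl1$characteristic$cluster, paste0("CL", 1:3))
  expect_true(all(diff(cl1$characteristic$mean_abundance) <= 0))
})

test_that("one-way ANOVA matches the sum-of-squares decomposition", {
  withr::local_seed(4)
  df <- tibble::tibble(
    y = rnorm(30, rep(c(0, 1, 3), each = 10)),
    g = rep(c("a", "b", "c"), each = 10)
  )
  fit <- anova_oneway(df, y, g)
  # independent SS computation
  grand <- mean(df$y)
  mns <- tapply(df$y, df$g, mean)
  ssb <- sum(10 * (mns - grand)^2)
  ssw <- sum((df$y - mns[df$g])^2)
  f_manual <- (ssb / 2) / (ssw / 27)
  expect_equal(fit$statistic, f_manual, tolerance = 1e-12)
  expect_equal(fit$p_value, pf(f_manual, 2, 27, lower.tail = FALSE))
  expect_equal(fit$df, c(2, 27))

  # affine invariance of F
  df2 <- dplyr::mutate(df, y = 3.7 * y - 11)
  expect_equal(anova_oneway(df2, y, g)$statistic, fit$statistic, tolerance = 1e-10)

  # equal group means with positive within-variance: F = 0
  df3 <- tibble::tibble(y = rep(c(-1, 1), 6), g = rep(c("a", "b", "c"), each = 4))
  expect_equal(anova_oneway(df3, y, g)$statistic, 0)

  # zero within-group variance is flagged as infinite F
  df4 <- tibble::tibble(y = rep(c(1, 2), each = 5), g = rep(c("a", "b"), each = 5))
  fit4 <- anova_oneway(df4, y, g)
  expect_identical(fit4$statistic, Inf)
  expect_equal(fit4$p_value, 0)

  expect_error(anova_oneway(tibble::tibble(y = 1:3, g = "a"), y, g), "2 groups")

  # group intervals are t-based
  g_a <- fit$groups[fit$groups$group == "a", ]
  expect_equal(g_a$ci_high - g_a$mean,
               qt(0.975, 9) * sd(df$y[df$g == "a"]) / sqrt(10))
})

test_that("anova_metrics screens every landscape metric against a grouping", {
  withr::local_seed(19)
  st <- generate_study(scaled_config(beta = 2, seed = 3))
  cl <- cluster_releves(st$tables$L, k = 3)
  pm <- tibble::as_tibble(st$tables$R, rownames = "plot_id")
  res <- anova_metrics(pm, cl)
  expect_setequal(res$response, colnames(st$tables$R))
  expect_true(all(res$statistic >= 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(vapply(res$groups, nrow, integer(1)) == 3))
})
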