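# Independent oracles and small fixture builders shared by the tests.

# Exhaustive patch oracle: components of the equal-code 4-adjacency graph
# (igraph) plus face-by-face perimeter counting. Deliberately independent of
# the package's labelling code path.
oracle_label_patches <- function(values) {
  nr <- nrow(values); nc <- ncol(values)
  idx <- function(i, j) (j - 1L) * nr + i
  from <- integer(); to <- integer()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (values[i, j] == 0) next
      if (i < nr && values[i + 1, j] == values[i, j]) {
        from <- c(from, idx(i, j)); to <- c(to, idx(i + 1, j))
      }
      if (j < nc && values[i, j + 1] == values[i, j]) {
        from <- c(from, idx(i, j)); to <- c(to, idx(i, j + 1))
      }
    }
  }
  occ <- which(values != 0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE, vertices = data.frame(name = as.character(occ)))
  comp <- igraph::components(g)
  cells_of <- split(as.integer(igraph::V(g)$name), comp$membership)
  recs <- lapply(cells_of, function(cells) {
    i <- (cells - 1L) %% nr + 1L
    j <- (cells - 1L) %/% nr + 1L
    code <- values[cells[1]]
    perim <- 0L
    for (k in seq_along(cells)) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- i[k] + d[1]; nj <- j[k] + d[2]
        outside <- ni < 1 || ni > nr || nj < 1 || nj > nc ||
          values[ni, nj] != code
        perim <- perim + outside
      }
    }
    data.frame(species_code = code, area = length(cells), perimeter = perim)
  })
  out <- do.call(rbind, recs)
  out[order(out$species_code, out$area, out$perimeter), , drop = FALSE]
}

# random species raster
rand_grid_values <- function(nr = 12, nc = 12, n_species = 3, p_occupied = 0.45) {
  codes <- sample(0:n_species, nr * nc, replace = TRUE,
                  prob = c(1 - p_occupied, rep(p_occupied / n_species, n_species)))
  matrix(as.integer(codes), nr, nc)
}

# small random study tables built directly (no rasters) for fast ordination
# and permutation tests
make_tables <- function(n_plots = 10, n_species = 6, n_metrics = 4,
                        n_traits = 3, covariates = FALSE) {
  repeat {
    L <- matrix(rpois(n_plots * n_species, 1.2), n_plots, n_species)
    if (all(rowSums(L) > 0) && all(colSums(L) > 0)) break
  }
  dimnames(L) <- list(sprintf("p%02d", 1:n_plots), sprintf("s%02d", 1:n_species))
  R <- matrix(rnorm(n_plots * n_metrics), n_plots, n_metrics,
              dimnames = list(rownames(L), sprintf("m%d", 1:n_metrics)))
  Q <- matrix(rnorm(n_species * n_traits), n_species, n_traits,
              dimnames = list(colnames(L), sprintf("t%d", 1:n_traits)))
  cov <- NULL
  if (covariates) {
    cov <- tibble::tibble(
      plot_id = rownames(L),
      terrain_age_class = sample(rep_len(c("ta1", "ta2", "ta3"), n_plots)),
      cobble_class = sample(rep_len(c("ts1", "ts2", "ts3"), n_plots))
    )
  }
  study_tables(R, L, Q, covariates = cov)
}

# study-shaped but scaled-down generator configuration used where many
# replicates are needed
scaled_config <- function(beta = 0, seed = NULL, n_plots = 24, ...) {
  simulation_config(n_plots = n_plots, grid_dim = c(40, 40), n_species = 8,
                    n_traits = 4, beta = beta,
                    patch_area_meanlog = log(10), patch_area_sdlog = 0.8,
                    seed = seed, ...)
}

# naive Ward (ward.D) agglomeration via the Lance-Williams update, used as an
# independent oracle for small fixtures; returns successive merge heights
ward_oracle_heights <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1)) {
        i <- active[a]; j <- active[b]
        if (m[i, j] < bh) { bh <- m[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bh)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      m[i, k] <- m[k, i] <-
        ((ni + nk) * m[i, k] + (nj + nk) * m[j, k] - nk * m[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# brute-force fourth-corner statistic: weighted Pearson correlation over the
# explicitly inflated (plot, species) table
oracle_fourth_corner <- function(R, L, Q) {
  out <- matrix(NA_real_, ncol(Q), ncol(R),
                dimnames = list(colnames(Q), colnames(R)))
  w <- as.vector(L / sum(L))
  for (j in seq_len(ncol(Q))) {
    for (k in seq_len(ncol(R))) {
      x <- rep(R[, k], times = ncol(L))        # plot value for each (i, s)
      y <- rep(Q[, j], each = nrow(L))         # species value for each (i, s)
      mx <- sum(w * x); my <- sum(w * y)
      out[j, k] <- sum(w * (x - mx) * (y - my)) /
        sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
    }
  }
  out
}
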