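atlas <- load_region_atlas("raichle36")

test_that("Watts-Strogatz generator builds the exact ring lattice at p = 0", {
  u <- ws_weighted_graph(36, 6, p = 0, seed = 2)
  a <- u$matrix > 0
  deg <- rowSums(a)
  expect_true(all(deg == 6))
  idx <- which(a & upper.tri(a), arr.ind = TRUE)
  ring <- pmin(idx[, 2] - idx[, 1], 36 - (idx[, 2] - idx[, 1]))
  expect_true(all(ring <= 3))
  expect_identical(u$matrix, ws_weighted_graph(36, 6, p = 0, seed = 2)$matrix)
  expect_error(ws_weighted_graph(10, 10, 0.1), "smaller than n")
  expect_error(ws_weighted_graph(10, 3, 0.1), "even")
})

test_that("rewiring destroys clustering: p = 0 beats p = 1 on average", {
  c0 <- c1 <- numeric(20)
  for (s in 1:20) {
    c0[s] <- weighted_clustering(ws_weighted_graph(36, 6, 0, w_par = c(1, 1),
                                                   seed = s))
    c1[s] <- weighted_clustering(ws_weighted_graph(36, 6, 1, w_par = c(1, 1),
                                                   seed = s))
  }
  expect_gt(mean(c0), mean(c1))
})

test_that("synthetic group ECM honors density, sign and block structure", {
  sp <- synthetic_spec(seed = 5)
  e <- sample_group_ecm(sp)
  expect_identical(e$matrix, sample_group_ecm(sp)$matrix)  # pure in the seed
  off <- row(e$matrix) != col(e$matrix)
  nz <- sum(e$matrix[off] == 0)
  # density 0.94 on 1260 slots: ~76 pruned entries, binomial sd ~ 8.4
  expect_gt(nz, 76 - 4 * 8.5)
  expect_lt(nz, 76 + 4 * 8.5)
  expect_true(any(e$matrix[off] < 0) && any(e$matrix[off] > 0))

  e0 <- sample_group_ecm(synthetic_spec(density = 0, seed = 5))
  expect_true(all(e0$matrix[row(e0$matrix) != col(e0$matrix)] == 0))

  # within-network dominance shows up in the RSN strength matrix
  rs <- rsn_metric_matrix(ecm_to_wdcm(e), atlas, "strength")
  sizes <- table(factor(atlas$network, levels = RSN_LEVELS))
  slots_within <- sizes * (sizes - 1)
  per_edge_within <- diag(rs$values) / as.numeric(slots_within)
  slots_between <- outer(as.numeric(sizes), as.numeric(sizes))
  per_edge_between <- rs$values[upper.tri(rs$values)] /
    slots_between[upper.tri(slots_between)] / 2
  expect_gt(mean(per_edge_within), mean(per_edge_between))
})

test_that("cohorts are seeded, preserve zeros, and average back to the group", {
  g <- sample_group_ecm(synthetic_spec(seed = 6))
  same <- sample_cohort(g, 3, subject_sd = 0, seed = 1)
  for (s in same) expect_equal(s$matrix, g$matrix)
  coh <- sample_cohort(g, 200, subject_sd = 0.05, seed = 2)
  expect_identical(coh[[5]]$matrix,
                   sample_cohort(g, 200, subject_sd = 0.05, seed = 2)[[5]]$matrix)
  avg <- Reduce(`+`, lapply(coh, function(x) x$matrix)) / 200
  nzmask <- g$matrix != 0
  expect_true(all(avg[!nzmask] == 0))   # pruning structure survives
  dev <- abs(avg - g$matrix)[nzmask]
  # CLT: nearly all element-wise means within 3 * 0.05 / sqrt(200)
  expect_gte(mean(dev <= 3 * 0.05 / sqrt(200)), 0.99)
})

test_that("planted differences return exact ground truth", {
  g <- sample_group_ecm(synthetic_spec(seed = 7))
  pl <- plant_difference(g, edges = matrix(character(0), 0, 2), delta = 0.05)
  expect_true(all(pl$diff$matrix == 0))

  edges <- cbind(c("PCC", "lIPL", "MDT", "lITG", "rITG", "lPCer"), "rMTG")
  pl <- plant_difference(g, edges, delta = 0.05)
  rd <- regional_diff(pl$diff)
  # rMTG attains the maximal average increase (each source ties at one entry)
  expect_equal(rd$avg_increase[rd$region == "rMTG"], max(rd$avg_increase))
  expect_equal(rd$n_pos[rd$region == "rMTG"], 6L)
  # recomputing the difference from the two ECMs reproduces the returned one
  dm <- pl$ecm_b$matrix - g$matrix; diag(dm) <- 0
  expect_equal(dm, pl$diff$matrix)
  expect_true("rMTG" %in% pl$truth_regions)
  expect_error(plant_difference(g, cbind("PCC", "PCC"), 0.1), "off-diagonal")
})

test_that("neuronal forward simulation integrates the linear system", {
  # deterministic single-region decay against the closed-form solution
  sim <- simulate_neuronal(matrix(-0.5, 1, 1), duration = 10, dt = 0.01,
                           noise_sd = 0, x0 = 1)
  expect_lt(max(abs(sim$states[1, ] - exp(-0.5 * sim$times))), 1e-3)
  # zero initial state and zero noise stays at zero
  sim0 <- simulate_neuronal(diag(-0.5, 3), duration = 1, noise_sd = 0)
  expect_true(all(sim0$states == 0))
  # unstable coupling matrix is refused without force
  expect_error(simulate_neuronal(matrix(0.2, 1, 1), duration = 1), "stable")
  expect_silent(simulate_neuronal(matrix(0.2, 1, 1), duration = 0.1,
                                  force = TRUE))
})

test_that("stationary covariance solves the continuous Lyapunov equation", {
  set.seed(14)
  n <- 4
  a <- matrix(rnorm(n * n, 0, 0.2), n, n)
  diag(a) <- -0.8
  q <- 0.3
  # vec(Sigma) solves (I (x) A + A (x) I) vec(Sigma) = -vec(Q)
  kp <- kronecker(diag(n), a) + kronecker(a, diag(n))
  sigma <- matrix(solve(kp, -as.vector(diag(q^2, n))), n, n)
  sim <- simulate_neuronal(a, duration = 5000, dt = 0.01, noise_sd = q,
                           seed = 3)
  burn <- sim$times > 50
  emp <- cov(t(sim$states[, burn]))
  expect_lt(norm(emp - sigma, "F") / norm(sigma, "F"), 0.10)
})
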