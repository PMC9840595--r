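atlas <- load_region_atlas("raichle36")

test_that("total strength: ordered sum is twice the pair sum", {
  m <- matrix(0, 2, 2); m[1, 2] <- m[2, 1] <- 0.3
  u <- wucm(m)
  expect_equal(total_strength(u, "ordered_sum")$s, 0.6)
  expect_equal(total_strength(u, "pair_sum")$s, 0.3)
  z <- wucm(matrix(0, 4, 4))
  expect_equal(total_strength(z)$s, 0)
  expect_equal(total_strength(z, "pair_sum")$s, 0)
})

test_that("weighted clustering matches brute-force triple enumeration", {
  # unit triangle is fully clustered; 3-node path has no triangle
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(weighted_clustering(tri), 1)
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(weighted_clustering(path3), 0)
  for (n in c(4, 6, 8, 10, 12)) {
    for (s in 1:4) {
      m <- rand_sym_matrix(n, density = 0.6, seed = 100 * n + s)
      expect_equal(weighted_clustering(m), oracle_clustering(m),
                   tolerance = 1e-10)
    }
  }
})

test_that("characteristic path length matches independent shortest-path oracles", {
  m2 <- matrix(0, 2, 2); m2[1, 2] <- m2[2, 1] <- 0.5
  expect_equal(characteristic_path_length(m2), 2)
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(characteristic_path_length(tri), 1)
  for (n in c(5, 8, 10, 12)) {
    for (s in 1:4) {
      m <- rand_sym_matrix(n, density = 0.7, seed = 200 * n + s)
      expect_equal(characteristic_path_length(m), oracle_cpl_fw(m),
                   tolerance = 1e-10)
    }
  }
  # exhaustive simple-path enumeration on a 5-node weighted toy
  m5 <- rand_sym_matrix(5, density = 0.8, seed = 99)
  expect_equal(characteristic_path_length(m5), oracle_cpl_enum(m5),
               tolerance = 1e-10)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "no edges")
})

test_that("lattice null is a deterministic fixed point preserving weights", {
  u <- ws_weighted_graph(20, 4, p = 0.3, seed = 5)
  l1 <- lattice_null(u)
  expect_identical(l1$matrix, lattice_null(l1)$matrix) # fixed point
  expect_equal(sort(l1$matrix[upper.tri(l1$matrix)]),
               sort(u$matrix[upper.tri(u$matrix)]))    # multiset preserved
  # largest weights sit at the smallest ring distances: the smallest weight
  # of every ring-distance class dominates the largest of the next class
  n <- 20
  idx <- which(upper.tri(l1$matrix), arr.ind = TRUE)
  ring <- pmin(idx[, 2] - idx[, 1], n - (idx[, 2] - idx[, 1]))
  w <- l1$matrix[idx]
  mins <- tapply(w, ring, min)
  maxs <- tapply(w, ring, max)
  k <- length(mins)
  expect_true(all(mins[-k] >= maxs[-1] - 1e-12))
})

test_that("random null is seeded, reproducible, and weight-preserving", {
  u <- ws_weighted_graph(20, 4, p = 0.3, seed = 5)
  r1 <- random_null(u, seed = 11)
  r2 <- random_null(u, seed = 11)
  expect_identical(r1$matrix, r2$matrix)
  expect_equal(sort(r1$matrix[upper.tri(r1$matrix)]),
               sort(u$matrix[upper.tri(u$matrix)]))
  expect_equal(mean(r1$matrix), mean(u$matrix))
  # lattice nulls cluster more strongly than random nulls: instance-wise on
  # sparse graphs, in the mean on dense ones (the clipping in the SWP formula
  # exists precisely because single dense instances can invert)
  cls <- crs <- numeric(20)
  for (s in 1:20) {
    uu <- ws_weighted_graph(36, 6, 1, seed = 500 + s)
    cls[s] <- weighted_clustering(lattice_null(uu))
    crs[s] <- weighted_clustering(random_null(uu, seed = s))
  }
  expect_true(all(cls >= crs))
  cld <- numeric(40)
  for (s in 1:40) {
    uu <- wucm(rand_sym_matrix(12, density = 0.8, seed = 300 + s))
    cld[s] <- weighted_clustering(lattice_null(uu)) -
      weighted_clustering(random_null(uu, seed = s))
  }
  expect_gt(mean(cld), 0)
})

test_that("SWP of a lattice-identical graph is 1 - 1/sqrt(2)", {
  u <- ws_weighted_graph(24, 6, p = 0, seed = 3)
  latt <- lattice_null(u)   # lattice-ordered by construction
  res <- small_world_propensity(latt, n_null = 50, seed = 17)
  # dC = 0 exactly (C_obs == C_latt), dL clips to 1
  expect_equal(res$dC, 0)
  expect_equal(res$dL, 1)
  expect_equal(res$swp_mean, 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_true(res$swp_mean >= 0 && res$swp_mean <= 1)
})

test_that("SWP of a random-like graph approaches 1 - 1/sqrt(2) from the other corner", {
  set.seed(8)
  m <- rand_sym_matrix(36, density = 0.5, seed = 8)
  u <- wucm(m)
  rnd <- random_null(u, seed = 2)
  res <- small_world_propensity(rnd, n_null = 200, seed = 4)
  # observed graph is itself a draw from the random null: dC ~ 1, dL ~ 0
  expect_gt(res$dC, 0.7)
  expect_lt(res$dL, 0.3)
  expect_equal(res$swp_mean, 1 - 1 / sqrt(2), tolerance = 0.12)
})

test_that("SWP is deterministic given the seed", {
  u <- ws_weighted_graph(24, 6, p = 0.2, seed = 9)
  a <- small_world_propensity(u, n_null = 30, seed = 21)
  b <- small_world_propensity(u, n_null = 30, seed = 21)
  expect_identical(a, b)
})

test_that("weighted assortativity matches the edge-list correlation oracle", {
  # undirected unit-weight star: hubs connect to leaves only -> r = -1
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(weighted_assortativity(wucm(star)), -1, tolerance = 1e-12)
  # two disjoint unit triangles: all strengths equal -> undefined
  t2 <- matrix(0, 6, 6)
  t2[1:3, 1:3] <- 1; t2[4:6, 4:6] <- 1; diag(t2) <- 0
  expect_error(weighted_assortativity(wucm(t2)), "zero variance")
  # random directed instances up to n = 12, full and subset scope
  for (n in c(5, 8, 12)) {
    for (s in 1:4) {
      m <- rand_dir_matrix(n, density = 0.7, seed = 400 * n + s)
      w <- wdcm(m)
      expect_equal(weighted_assortativity(w), oracle_assortativity(m),
                   tolerance = 1e-10)
      set.seed(s)
      edges <- which(m > 0, arr.ind = TRUE)
      sub <- edges[sample(nrow(edges), ceiling(nrow(edges) / 2)), ]
      expect_equal(weighted_assortativity(w, edges = sub),
                   oracle_assortativity(m, edges = sub), tolerance = 1e-10)
      expect_equal(weighted_assortativity(w, edges = sub,
                                          strength_scope = "subset"),
                   oracle_assortativity(m, edges = sub, scope = "subset"),
                   tolerance = 1e-10)
    }
  }
})

test_that("balance test agrees with numerically integrated Student density", {
  set.seed(31)
  for (s in 1:6) {
    x <- rnorm(5 + 5 * s, mean = 0.02 * s, sd = 0.1)
    b <- balance_test(x)
    o <- oracle_t_pvalue(x)
    expect_equal(b$t_stat, o$t, tolerance = 1e-12)
    expect_equal(b$p_value, o$p, tolerance = 1e-12)
    expect_equal(b$neg_log10_p, -log10(max(o$p, 1e-16)), tolerance = 1e-10)
  }
})

test_that("balance test handles degenerate inputs as documented", {
  expect_equal(balance_test(rep(0, 10))$neg_log10_p, 0)
  expect_equal(balance_test(rep(0, 10))$p_value, 1)
  b <- balance_test(rep(c(0.1, -0.1), 10))   # exactly balanced
  expect_equal(b$t_stat, 0)
  expect_equal(b$p_value, 1)
  deg <- balance_test(rep(0.2, 5))           # zero variance, nonzero mean
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1e-16)
  expect_equal(deg$neg_log10_p, 16)
  expect_error(balance_test(0.1), "at least 2")
})
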