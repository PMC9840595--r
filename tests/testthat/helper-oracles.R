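# Independent brute-force oracles used to validate the metric implementations.
# Each one is written from the defining formula with explicit loops, never by
# calling the code path under test.

# Onnela weighted clustering by exhaustive enumeration of node triples
oracle_clustering <- function(m) {
  n <- nrow(m)
  mx <- max(m)
  if (mx == 0) return(0)
  wn <- m / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(m[i, ] > 0)
    if (k < 2) next
    tot <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      tot <- tot + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    }
    ci[i] <- tot / (k * (k - 1))
  }
  mean(ci)
}

# all-pairs shortest paths by hand-rolled Floyd-Warshall on 1/weight distances
oracle_cpl_fw <- function(m) {
  n <- nrow(m)
  d <- matrix(Inf, n, n)
  d[m > 0] <- 1 / m[m > 0]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

# shortest paths by exhaustive enumeration of simple paths (tiny n only)
oracle_cpl_enum <- function(m) {
  n <- nrow(m)
  best <- matrix(Inf, n, n)
  walk <- function(path, len) {
    i <- path[1]; j <- path[length(path)]
    if (len < best[i, j]) best[i, j] <<- len
    for (nxt in seq_len(n)) {
      if (m[j, nxt] > 0 && !(nxt %in% path)) {
        walk(c(path, nxt), len + 1 / m[j, nxt])
      }
    }
  }
  for (s in seq_len(n)) walk(s, 0)
  vals <- best[upper.tri(best)]
  mean(vals[is.finite(vals)])
}

# weighted Pearson correlation over an explicit directed edge list; entry
# (row i, col j) means source j -> target i, so out-strength is a column sum
oracle_assortativity <- function(m, edges = NULL, scope = "full") {
  if (is.null(edges)) edges <- which(m > 0 & !diag(nrow(m)), arr.ind = TRUE)
  wt <- m[edges]
  keep <- wt > 0
  edges <- edges[keep, , drop = FALSE]
  wt <- wt[keep]
  sm <- m
  if (scope == "subset") {
    sm <- matrix(0, nrow(m), ncol(m))
    sm[edges] <- m[edges]
  }
  x <- y <- numeric(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    src <- edges[r, 2]; tgt <- edges[r, 1]
    x[r] <- sum(sm[, src])   # out-strength of source
    y[r] <- sum(sm[tgt, ])   # in-strength of target
  }
  sw <- sum(wt)
  mx <- sum(wt * x) / sw; my <- sum(wt * y) / sw
  cov <- sum(wt * (x - mx) * (y - my)) / sw
  vx <- sum(wt * (x - mx)^2) / sw; vy <- sum(wt * (y - my)^2) / sw
  cov / sqrt(vx * vy)
}

# two-sided one-sample t-test p-value from the Student density integrated
# numerically (gamma-function normalization written out, no pt())
oracle_t_pvalue <- function(x) {
  n <- length(x)
  tval <- mean(x) / (sd(x) / sqrt(n))
  nu <- n - 1
  dens <- function(t) {
    gamma((nu + 1) / 2) / (sqrt(nu * pi) * gamma(nu / 2)) *
      (1 + t^2 / nu)^(-(nu + 1) / 2)
  }
  tail <- stats::integrate(dens, abs(tval), Inf, rel.tol = 1e-13,
                           abs.tol = 0)$value
  list(t = tval, p = 2 * tail)
}

# random symmetric nonnegative test matrix (connected with high probability)
rand_sym_matrix <- function(n, density = 0.6, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m))
  on <- runif(length(ut)) < density
  m[ut[on]] <- runif(sum(on), 0.1, 2)
  m + t(m)
}

# random directed nonnegative test matrix with zero diagonal
rand_dir_matrix <- function(n, density = 0.6, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0.1, 2) * (runif(n * n) < density), n, n)
  diag(m) <- 0
  m
}

# small ECM with handpicked values for IO and transform tests
toy_ecm <- function(atlas) {
  n <- nrow(atlas)
  set.seed(42)
  m <- matrix(round(rnorm(n * n, 0, 0.02), 6), n, n)
  diag(m) <- round(rnorm(n, 0.2, 0.1), 6)
  ecm(m, atlas$abbrev, group_tag = "toy")
}
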