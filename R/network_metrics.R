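#' Total connection strength of an undirected connectivity matrix
#'
#' The global strength S sums the WUCM entries. Because the matrix is
#' symmetric the sum over all ordered (i, j) is exactly twice the sum over
#' unordered pairs; both conventions are exposed since reported strengths in
#' the literature use either.
#'
#' @param u a \code{wucm}.
#' @param mode \code{"ordered_sum"} (sum over all ordered index pairs, the
#'   literal double-sum) or \code{"pair_sum"} (sum over unordered pairs).
#' @return A list of class \code{strength_result} with \code{s} (Hz) and
#'   \code{mode}.
#' @export
total_strength <- function(u, mode = c("ordered_sum", "pair_sum")) {
  stopifnot(inherits(u, "wucm"))
  mode <- match.arg(mode)
  s <- sum(u$matrix)
  if (mode == "pair_sum") s <- s / 2
  structure(list(s = s, mode = mode), class = "strength_result")
}

#' Weighted clustering coefficient
#'
#' Mean weighted clustering over nodes. The default is the Onnela
#' geometric-mean triangle intensity on weights normalized by the maximum
#' weight: C_i = sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1)),
#' with w' = w / max(w) and k_i the number of neighbors. Nodes with fewer
#' than two neighbors contribute 0 to the mean. A Barrat-style
#' (arithmetic-mean) variant is available.
#'
#' @param u a \code{wucm}, or a plain symmetric nonnegative matrix.
#' @param variant \code{"onnela"} (default) or \code{"barrat"}.
#' @return Mean clustering coefficient, dimensionless in [0, 1].
#' @export
weighted_clustering <- function(u, variant = c("onnela", "barrat")) {
  variant <- match.arg(variant)
  m <- if (inherits(u, "conn_matrix")) u$matrix else as.matrix(u)
  n <- nrow(m)
  if (n == 0L) stop("empty graph")
  a <- (m > 0) + 0
  k <- rowSums(a)
  ci <- numeric(n)
  if (variant == "onnela") {
    mx <- max(m)
    if (mx == 0) return(0)
    w3 <- (m / mx)^(1 / 3)
    tri <- diag(w3 %*% w3 %*% w3)
    ok <- k >= 2
    ci[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  } else {
    # Barrat: C_i = 1/(s_i (k_i - 1)) * sum_{j,h} (w_ij + w_ih)/2 * a_ij a_ih a_jh
    s <- rowSums(m)
    for (i in seq_len(n)) {
      if (k[i] < 2) next
      nb <- which(a[i, ] > 0)
      tot <- 0
      for (jx in seq_along(nb)) for (hx in seq_along(nb)) {
        j <- nb[jx]; h <- nb[hx]
        if (j != h && a[j, h] > 0) tot <- tot + (m[i, j] + m[i, h]) / 2
      }
      ci[i] <- tot / (s[i] * (k[i] - 1))
    }
  }
  mean(ci)
}

#' Characteristic path length
#'
#' Converts connection weights to distances as 1/weight (strong couplings are
#' short), runs all-pairs shortest paths, and averages over connected ordered
#' pairs of distinct nodes. Disconnected pairs are excluded with a warning.
#'
#' @param u a \code{wucm} or plain symmetric nonnegative matrix.
#' @return Mean shortest-path length (dimensionless).
#' @export
characteristic_path_length <- function(u) {
  m <- if (inherits(u, "conn_matrix")) u$matrix else as.matrix(u)
  if (all(m == 0)) stop("graph has no edges")
  dist_w <- m
  dist_w[m > 0] <- 1 / m[m > 0]
  g <- igraph::graph_from_adjacency_matrix(dist_w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  vals <- d[upper.tri(d)]
  inf <- !is.finite(vals)
  if (any(inf)) {
    warning(sum(inf), " disconnected pair(s) excluded from path length")
    vals <- vals[!inf]
  }
  if (!length(vals)) stop("graph has no connected pairs")
  mean(vals)
}

# upper-triangle slot indices ordered by ring distance, stable row-major
# tie-break; used by the lattice null
.ring_slots <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ring <- pmin(idx[, 2] - idx[, 1], n - (idx[, 2] - idx[, 1]))
  idx[order(ring, (idx[, 1] - 1) * n + idx[, 2]), , drop = FALSE]
}

#' Lattice null model
#'
#' Deterministic regular-network surrogate: the multiset of weights (zeros
#' included) is reassigned over the upper-triangle slots so that the largest
#' weights sit at the smallest ring distances |i - j| mod n, i.e. the
#' weighted analogue of a ring lattice. Ties broken stably by descending
#' weight and row-major slot order.
#'
#' @param u a \code{wucm}.
#' @return A \code{wucm} with the same weight multiset, lattice-ordered.
#' @export
lattice_null <- function(u) {
  stopifnot(inherits(u, "wucm"))
  n <- nrow(u$matrix)
  slots <- .ring_slots(n)
  w <- u$matrix[upper.tri(u$matrix)]
  w <- sort(w, decreasing = TRUE, method = "radix")
  out <- matrix(0, n, n)
  out[slots] <- w
  out <- out + t(out)
  wucm(out, u$labels, tag = paste0(u$tag, " [lattice null]"))
}

#' Random null model
#'
#' Degree-agnostic random surrogate: the multiset of weights (zeros included)
#' is randomly permuted over the upper-triangle slots, preserving the weight
#' distribution exactly while destroying all topological structure.
#'
#' @param u a \code{wucm}.
#' @param seed optional integer; when given, the permutation is drawn from a
#'   private RNG stream and the global RNG state is untouched.
#' @return A \code{wucm} with the same weight multiset, randomly placed.
#' @export
random_null <- function(u, seed = NULL) {
  stopifnot(inherits(u, "wucm"))
  n <- nrow(u$matrix)
  w <- u$matrix[upper.tri(u$matrix)]
  perm <- if (is.null(seed)) sample.int(length(w))
          else .with_seed(seed, sample.int(length(w)))
  out <- matrix(0, n, n)
  out[upper.tri(out)] <- w[perm]
  out <- out + t(out)
  wucm(out, u$labels, tag = paste0(u$tag, " [random null]"))
}

# run expr under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Small-world propensity (SWP)
#'
#' Density-independent small-worldness of a weighted undirected network.
#' For each of \code{n_null} realizations a random null is drawn and the
#' clipped deviations of observed clustering and path length from the
#' (deterministic) lattice and random references are combined:
#' \deqn{dC = (C_{latt} - C_{obs}) / (C_{latt} - C_{rand}),\quad
#'       dL = (L_{obs} - L_{rand}) / (L_{latt} - L_{rand}),}
#' both clipped to [0, 1], and
#' \deqn{SWP = 1 - \sqrt{(dC^2 + dL^2)/2}.}
#' Realizations with a degenerate denominator are dropped and counted.
#'
#' @param u a \code{wucm}; must be connected.
#' @param n_null number of random-null realizations (default 1000).
#' @param seed integer seed (required; every realization is derived from it).
#' @return A list of class \code{swp_result}: \code{swp_mean}, \code{swp_sd},
#'   \code{dC}, \code{dL} (means over realizations), \code{n_null},
#'   \code{n_dropped}, \code{seed}.
#' @export
small_world_propensity <- function(u, n_null = 1000L, seed) {
  stopifnot(inherits(u, "wucm"))
  if (missing(seed)) stop("seed is required for the random null ensemble")
  c_obs <- weighted_clustering(u)
  l_obs <- characteristic_path_length(u)
  latt <- lattice_null(u)
  c_latt <- weighted_clustering(latt)
  l_latt <- characteristic_path_length(latt)
  res <- .with_seed(seed, {
    swp <- dc <- dl <- rep(NA_real_, n_null)
    for (r in seq_len(n_null)) {
      rnd <- random_null(u)
      c_rand <- weighted_clustering(rnd)
      l_rand <- suppressWarnings(characteristic_path_length(rnd))
      den_c <- c_latt - c_rand
      den_l <- l_latt - l_rand
      if (den_c == 0 || den_l == 0) next  # degenerate realization dropped
      dc[r] <- min(max((c_latt - c_obs) / den_c, 0), 1)
      dl[r] <- min(max((l_obs - l_rand) / den_l, 0), 1)
      swp[r] <- 1 - sqrt((dc[r]^2 + dl[r]^2) / 2)
    }
    list(swp = swp, dc = dc, dl = dl)
  })
  keep <- !is.na(res$swp)
  if (!any(keep)) stop("all null realizations degenerate; SWP undefined")
  structure(list(swp_mean = mean(res$swp[keep]),
                 swp_sd = stats::sd(res$swp[keep]),
                 dC = mean(res$dc[keep]), dL = mean(res$dl[keep]),
                 n_null = as.integer(n_null),
                 n_dropped = as.integer(sum(!keep)),
                 seed = seed),
            class = "swp_result")
}

#' Weighted assortativity
#'
#' Correlation, over edges, of the connectivity strengths of the two endpoint
#' nodes; the weighted extension computes a Pearson correlation in which each
#' edge contributes with weight equal to its connection strength. For a
#' directed matrix the default endpoint values are the source node's
#' out-strength and the target node's in-strength; for a symmetric matrix
#' these coincide with the node strength.
#'
#' @param w a \code{wdcm} or \code{wucm}.
#' @param edges optional 2-column integer matrix of directed edges (source,
#'   target) restricting the correlation to a subset; default all nonzero
#'   off-diagonal entries.
#' @param assort_mode endpoint values: \code{"out-in"} (default),
#'   \code{"out-out"} or \code{"in-in"}.
#' @param strength_scope \code{"full"} (strengths from the full matrix,
#'   default) or \code{"subset"} (strengths from the matrix restricted to
#'   \code{edges}, the within-subset assortment).
#' @return Assortativity coefficient r in [-1, 1].
#' @export
weighted_assortativity <- function(w, edges = NULL,
                                   assort_mode = c("out-in", "out-out", "in-in"),
                                   strength_scope = c("full", "subset")) {
  stopifnot(inherits(w, "conn_matrix"))
  assort_mode <- match.arg(assort_mode)
  strength_scope <- match.arg(strength_scope)
  m <- w$matrix
  if (is.null(edges)) {
    edges <- which(m > 0 & !diag(nrow(m)), arr.ind = TRUE)
  } else {
    edges <- as.matrix(edges)
  }
  wt <- m[edges]
  nz <- wt > 0
  edges <- edges[nz, , drop = FALSE]
  wt <- wt[nz]
  if (nrow(edges) < 2) stop("need at least 2 nonzero edges for assortativity")
  sm <- m
  if (strength_scope == "subset") {
    sm <- matrix(0, nrow(m), ncol(m))
    sm[edges] <- m[edges]
  }
  # orientation: entry (i, j) means column j -> row i, so for edge slot
  # (row i, col j) the source is j and the target is i; out-strength of a
  # node as source = its column sum, in-strength = its row sum
  s_out <- colSums(sm)
  s_in <- rowSums(sm)
  src <- edges[, 2]
  tgt <- edges[, 1]
  x <- switch(assort_mode,
              "out-in" = s_out[src],
              "out-out" = s_out[src],
              "in-in" = s_in[src])
  y <- switch(assort_mode,
              "out-in" = s_in[tgt],
              "out-out" = s_out[tgt],
              "in-in" = s_in[tgt])
  .weighted_pearson(x, y, wt)
}

.weighted_pearson <- function(x, y, wt) {
  sw <- sum(wt)
  mx <- sum(wt * x) / sw
  my <- sum(wt * y) / sw
  vx <- sum(wt * (x - mx)^2) / sw
  vy <- sum(wt * (y - my)^2) / sw
  if (vx <= 0 || vy <= 0)
    stop("assortativity undefined: zero variance of endpoint strengths ",
         "(regular graph)")
  sum(wt * (x - mx) * (y - my)) / sw / sqrt(vx * vy)
}

#' Balance test on reciprocal connection differences
#'
#' Two-sided one-sample t-test of whether the reciprocal directed
#' connection-strength differences (w_ij - w_ji over region pairs) have zero
#' mean. The negative log10 p-value is the network balance statistic: large
#' values indicate systematically asymmetric coupling. p is floored at 1e-16
#' so the statistic stays finite.
#'
#' @param diffs numeric vector of signed differences (Hz), length >= 2.
#' @return A list of class \code{balance_result}: \code{mean_diff},
#'   \code{t_stat}, \code{p_value}, \code{neg_log10_p}, \code{n_pairs},
#'   \code{degenerate} (TRUE when variance is zero with nonzero mean).
#' @export
balance_test <- function(diffs) {
  if (length(diffs) < 2) stop("need at least 2 pair differences")
  n <- length(diffs)
  m <- mean(diffs)
  s <- stats::sd(diffs)
  degenerate <- FALSE
  if (s == 0) {
    if (m == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(m) * Inf; p <- 1e-16; degenerate <- TRUE
    }
  } else {
    tt <- stats::t.test(diffs, mu = 0, alternative = "two.sided")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(mean_diff = m, t_stat = t_stat, p_value = p,
                 neg_log10_p = -log10(max(p, 1e-16)),
                 n_pairs = as.integer(n), degenerate = degenerate),
            class = "balance_result")
}
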