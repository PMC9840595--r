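#' Specification for a synthetic group-level connectivity matrix
#'
#' Defines the generative conditions for an atlas-conforming synthetic ECM:
#' off-diagonal couplings are drawn from Gaussian laws whose parameters differ
#' between within-RSN and between-RSN slots (block structure), a fraction of
#' slots is set to exact zero to emulate model-reduction pruning, a fraction
#' of couplings is inhibitory (negative), and the diagonal log-scaling
#' self-inhibition parameters are Gaussian.
#'
#' Default magnitudes put the synthetic matrices on the scale observed for
#' group-level effective connectivity: coupling magnitudes of a few
#' thousandths to a hundredth of a Hz (global pair-sum strength of a few Hz),
#' ~6\% of the 1260 off-diagonal slots pruned to zero, and diagonal
#' parameters around N(0.2, 0.1).
#'
#' @param atlas a \code{region_atlas} (default the packaged 36-region atlas).
#' @param within_mean,within_sd Gaussian law (Hz) for couplings inside an RSN.
#' @param between_mean,between_sd Gaussian law (Hz) for couplings between
#'   RSNs.
#' @param negative_fraction probability that a coupling is inhibitory.
#' @param density probability that an off-diagonal slot is nonzero.
#' @param diag_mean,diag_sd Gaussian law (dimensionless) for the diagonal
#'   log-scaling parameters.
#' @param seed integer seed.
#' @return A list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(atlas = load_region_atlas("raichle36"),
                           within_mean = 0.01, within_sd = 0.004,
                           between_mean = 0.003, between_sd = 0.0015,
                           negative_fraction = 0.4, density = 0.94,
                           diag_mean = 0.2, diag_sd = 0.1, seed = 1L) {
  stopifnot(within_sd >= 0, between_sd >= 0, diag_sd >= 0,
            negative_fraction >= 0, negative_fraction <= 1,
            density >= 0, density <= 1)
  structure(list(atlas = atlas, within_mean = within_mean,
                 within_sd = within_sd, between_mean = between_mean,
                 between_sd = between_sd,
                 negative_fraction = negative_fraction, density = density,
                 diag_mean = diag_mean, diag_sd = diag_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample a synthetic group-level ECM
#'
#' Pure function of the spec's seed: two calls with the same spec give
#' bit-identical matrices and the caller's RNG state is untouched.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return An \code{ecm} in atlas order.
#' @export
sample_group_ecm <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  atlas <- spec$atlas
  n <- nrow(atlas)
  .with_seed(spec$seed, {
    same_net <- outer(atlas$network, atlas$network, "==")
    mu <- ifelse(same_net, spec$within_mean, spec$between_mean)
    sg <- ifelse(same_net, spec$within_sd, spec$between_sd)
    mag <- abs(matrix(stats::rnorm(n * n, mu, sg), n, n))
    sign_flip <- matrix(stats::rbinom(n * n, 1L, spec$negative_fraction),
                        n, n)
    keep <- matrix(stats::rbinom(n * n, 1L, spec$density), n, n)
    m <- mag * ifelse(sign_flip == 1L, -1, 1) * keep
    diag(m) <- stats::rnorm(n, spec$diag_mean, spec$diag_sd)
    ecm(m, atlas$abbrev, group_tag = sprintf("synthetic seed=%d", spec$seed))
  })
}

#' Sample a cohort of subject-level ECMs around a group matrix
#'
#' Each subject is the group matrix plus i.i.d. Gaussian noise added only on
#' the nonzero slots, so pruning structure (exact zeros) survives cohort
#' averaging.
#'
#' @param group an \code{ecm}.
#' @param n_subjects cohort size (>= 1).
#' @param subject_sd between-subject noise sd (Hz).
#' @param seed integer seed.
#' @return List of \code{ecm} objects of length \code{n_subjects}.
#' @export
sample_cohort <- function(group, n_subjects, subject_sd, seed) {
  stopifnot(inherits(group, "ecm"), n_subjects >= 1, subject_sd >= 0)
  n <- nrow(group$matrix)
  nz <- group$matrix != 0
  .with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      noise <- matrix(stats::rnorm(n * n, 0, subject_sd), n, n)
      noise[!nz] <- 0
      ecm(group$matrix + noise, group$labels,
          group_tag = sprintf("%s subject %d", group$tag, s))
    })
  })
}

#' Plant a group difference on chosen directed edges
#'
#' Builds a second group matrix by adding a known delta on selected directed
#' couplings, returning the exact element-wise difference as ground truth for
#' recovery tests.
#'
#' @param base an \code{ecm}.
#' @param edges 2-column matrix of directed edges (source, target), labels or
#'   indices; diagonal edges are rejected.
#' @param delta numeric delta (Hz), scalar or one per edge.
#' @return List with \code{ecm_b} (base + planted deltas), \code{diff} (a
#'   \code{diff_matrix}, ecm_b - base with zero diagonal) and
#'   \code{truth_regions} (labels of all regions incident to a planted edge).
#' @export
plant_difference <- function(base, edges, delta) {
  stopifnot(inherits(base, "ecm"))
  edges <- as.matrix(edges)
  if (is.character(edges)) {
    edges <- matrix(match(edges, base$labels), ncol = 2)
    if (anyNA(edges)) stop("unknown region label in edges")
  }
  if (any(edges[, 1] == edges[, 2]))
    stop("planted edges must be off-diagonal")
  delta <- rep_len(delta, nrow(edges))
  m <- base$matrix
  # directed edge (source, target) lives at slot (row = target, col = source)
  slots <- cbind(edges[, 2], edges[, 1])
  m[slots] <- m[slots] + delta
  dm <- m - base$matrix
  diag(dm) <- 0
  truth <- unique(base$labels[as.vector(edges)])
  list(ecm_b = ecm(m, base$labels,
                   group_tag = paste0(base$tag, " + planted difference")),
       diff = diff_matrix(dm, base$labels,
                          tag = "positive = higher in planted group"),
       truth_regions = truth)
}

#' Weighted Watts-Strogatz test graph
#'
#' Ring lattice with n vertices and k neighbors per vertex, each edge rewired
#' with probability p (p = 0 regular, p = 1 fully random), with i.i.d. edge
#' weights. Used to validate the small-world machinery on graphs with known
#' structure.
#'
#' @param n number of vertices.
#' @param k even number of neighbors per vertex, k < n.
#' @param p rewiring probability.
#' @param weight_law \code{"uniform"} or \code{"lognormal"}.
#' @param w_par parameters of the law: \code{c(lo, hi)} for uniform,
#'   \code{c(mu, sigma)} of the underlying normal for lognormal.
#' @param seed integer seed.
#' @return A \code{wucm} on n nodes.
#' @export
ws_weighted_graph <- function(n, k, p, weight_law = c("uniform", "lognormal"),
                              w_par = c(0.5, 1.5), seed = 1L) {
  weight_law <- match.arg(weight_law)
  if (k %% 2 != 0) stop("k must be even")
  if (k >= n) stop("k must be smaller than n")
  .with_seed(seed, {
    g <- igraph::sample_smallworld(1, n, k / 2, p, loops = FALSE,
                                   multiple = FALSE)
    ne <- igraph::ecount(g)
    w <- switch(weight_law,
                uniform = stats::runif(ne, w_par[1], w_par[2]),
                lognormal = stats::rlnorm(ne, w_par[1], w_par[2]))
    m <- as.matrix(igraph::as_adjacency_matrix(
      igraph::set_edge_attr(g, "weight", value = w),
      attr = "weight", sparse = FALSE))
    wucm(m, paste0("V", seq_len(n)),
         tag = sprintf("WS n=%d k=%d p=%g seed=%d", n, k, p, seed))
  })
}

#' Forward simulation of the linear neuronal-state model
#'
#' Integrates dx/dt = A x + v(t) with Euler-Maruyama steps, where A is the
#' endogenous coupling matrix (Hz; negative diagonal for stability) and v(t)
#' is white noise of standard deviation \code{noise_sd}.
#'
#' @param a_hz n x n coupling matrix (Hz).
#' @param duration total simulated time (s).
#' @param dt integration step (s), > 0 (default 0.01).
#' @param noise_sd sd of the stochastic fluctuations (Hz).
#' @param x0 initial state vector (default zeros).
#' @param seed integer seed (used when \code{noise_sd > 0}).
#' @param force set \code{TRUE} to integrate an unstable A anyway.
#' @return List with \code{times} (length duration/dt) and \code{states}
#'   (n x length(times) matrix of states after each step).
#' @export
simulate_neuronal <- function(a_hz, duration, dt = 0.01, noise_sd = 0,
                              x0 = NULL, seed = 1L, force = FALSE) {
  a_hz <- as.matrix(a_hz)
  n <- nrow(a_hz)
  stopifnot(n == ncol(a_hz), dt > 0, duration > 0)
  re <- max(Re(eigen(a_hz, only.values = TRUE)$values))
  if (re >= 0 && !force)
    stop("coupling matrix is not stable (max Re(eigenvalue) = ",
         format(re, digits = 4), "); pass force = TRUE to integrate anyway")
  steps <- floor(duration / dt)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  stopifnot(length(x) == n)
  states <- matrix(0, n, steps)
  .with_seed(seed, {
    sq <- sqrt(dt) * noise_sd
    for (s in seq_len(steps)) {
      drift <- a_hz %*% x
      x <- x + dt * as.numeric(drift) +
        if (noise_sd > 0) sq * stats::rnorm(n) else 0
      states[, s] <- x
    }
  })
  list(times = dt * seq_len(steps), states = states)
}
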