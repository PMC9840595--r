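#' ECM to weighted directed connectivity matrix (WDCM)
#'
#' Loops (self-connections) distort degree and path-length computations, and
#' negative couplings break shortest-path logic, so the graph representation
#' (1) removes the diagonal and (2) takes absolute values of all couplings:
#' the energetic cost of an inhibitory influence is taken to scale with the
#' magnitude of its strength.
#'
#' @param e an \code{ecm}.
#' @return A \code{wdcm}: nonnegative, zero diagonal, same labels.
#' @export
ecm_to_wdcm <- function(e) {
  stopifnot(inherits(e, "ecm") || inherits(e, "wdcm"))
  if (inherits(e, "diff_matrix"))
    stop("a difference matrix is not a connectivity matrix")
  m <- abs(e$matrix)
  diag(m) <- 0
  wdcm(m, e$labels, tag = e$tag)
}

#' WDCM to weighted undirected connectivity matrix (WUCM)
#'
#' Reciprocal directed connections are collapsed by summing the two
#' orientations of each region pair, giving a symmetric matrix.
#'
#' @param w a \code{wdcm}.
#' @return A \code{wucm} with entry (i, j) = w(i, j) + w(j, i).
#' @export
wdcm_to_wucm <- function(w) {
  stopifnot(inherits(w, "wdcm"))
  wucm(w$matrix + t(w$matrix), w$labels, tag = w$tag)
}

#' Self-inhibition summary from the ECM diagonal
#'
#' Diagonal ECM entries are dimensionless log-scaling parameters z scaling a
#' default self-inhibition of -0.5 Hz: the effective regional self-connection
#' is -0.5 * exp(z) Hz, so z = 0 corresponds to -0.5 Hz and positive z
#' strengthens self-inhibition.
#'
#' @param e an \code{ecm}.
#' @param mode \code{"mean"} (default) or \code{"sum"} aggregation of the
#'   diagonal into the scalar summary \code{s_diag}.
#' @return A list of class \code{self_inhibition_summary} with \code{s_diag}
#'   (dimensionless), \code{per_region_hz} (named, all strictly negative) and
#'   \code{mode}.
#' @export
self_inhibition_summary <- function(e, mode = c("mean", "sum")) {
  stopifnot(inherits(e, "ecm"))
  mode <- match.arg(mode)
  z <- diag(e$matrix)
  s_diag <- if (mode == "mean") mean(z) else sum(z)
  per_region_hz <- -0.5 * exp(z)
  names(per_region_hz) <- e$labels
  structure(list(s_diag = s_diag, per_region_hz = per_region_hz, mode = mode),
            class = "self_inhibition_summary")
}

#' Reciprocal connection-strength differences
#'
#' For each unordered region pair \{i, j\} with i < j in atlas order, returns
#' the upper-triangle entry minus the lower-triangle entry,
#' w(i, j) - w(j, i): the asymmetry of the two directed couplings. The sign
#' depends on the canonical ordering, but the balance test applied downstream
#' is two-sided.
#'
#' @param w a \code{wdcm}.
#' @param pairs optional 2-column matrix of region indices or labels (one
#'   unordered pair per row); default is all n(n-1)/2 pairs.
#' @return Named numeric vector of signed differences (Hz), one per pair,
#'   names \code{"i|j"} with i before j in atlas order.
#' @export
reciprocal_differences <- function(w, pairs = NULL) {
  stopifnot(inherits(w, "wdcm"))
  n <- nrow(w$matrix)
  if (is.null(pairs)) {
    idx <- which(upper.tri(w$matrix), arr.ind = TRUE)
    pairs <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  } else {
    pairs <- as.matrix(pairs)
    if (is.character(pairs)) {
      pairs <- matrix(match(pairs, w$labels), ncol = 2)
      if (anyNA(pairs)) stop("unknown region label in pairs")
    }
    if (any(pairs[, 1] == pairs[, 2]))
      stop("pairs must be off-diagonal (i != j)")
    # canonicalize so i < j (upper triangle)
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, 2:1]
  }
  d <- w$matrix[pairs] - w$matrix[pairs[, 2:1, drop = FALSE]]
  names(d) <- paste(w$labels[pairs[, 1]], w$labels[pairs[, 2]], sep = "|")
  d
}
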