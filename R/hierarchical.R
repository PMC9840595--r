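#' Region-pair and directed-edge subsets of an RSN block
#'
#' Enumerates the unordered region pairs of a block of the 7x7 RSN partition
#' and the corresponding directed-edge slots (both orientations of each
#' pair). For \code{net_a == net_b} the block is the within-network set of
#' pairs; otherwise the between-network set (one endpoint in each).
#'
#' @param atlas a \code{region_atlas}.
#' @param net_a,net_b network labels from \code{RSN_LEVELS}.
#' @return List with \code{pairs} (2-column index matrix, i < j in atlas
#'   order) and \code{directed_edges} (2-column slot matrix (row, col), both
#'   orientations of every pair).
#' @export
block_pairs <- function(atlas, net_a, net_b = net_a) {
  for (nt in c(net_a, net_b)) {
    if (!nt %in% RSN_LEVELS) stop("unknown network: ", nt)
  }
  ia <- which(atlas$network == net_a)
  ib <- which(atlas$network == net_b)
  if (identical(net_a, net_b)) {
    cmb <- t(utils::combn(ia, 2L))
  } else {
    cmb <- as.matrix(expand.grid(i = ia, j = ib))
    swap <- cmb[, 1] > cmb[, 2]
    cmb[swap, ] <- cmb[swap, 2:1]
    cmb <- unname(cmb)
  }
  colnames(cmb) <- NULL
  directed <- rbind(cmb, cmb[, 2:1, drop = FALSE])
  list(pairs = cmb, directed_edges = directed)
}

#' RSN-level metric matrix
#'
#' Aggregates a global graph property into a 7x7 matrix over the RSN
#' partition: the diagonal holds within-network values, off-diagonal cells
#' the between-network values.
#' \itemize{
#'   \item \code{strength}: sum of the directed WDCM entries over the block's
#'     directed edges.
#'   \item \code{assortativity}: weighted assortativity restricted to the
#'     block's directed edges, with endpoint strengths computed on the
#'     block-induced edge set; undefined cells are \code{NA}.
#'   \item \code{balance}: negative log10 p of the balance test on the
#'     block's reciprocal differences; blocks with fewer than two pairs
#'     (within a 2-region network) are undefined and reported \code{NA}.
#' }
#'
#' @param w a \code{wdcm}.
#' @param atlas a \code{region_atlas} matching \code{w}'s labels.
#' @param metric one of \code{"strength"}, \code{"assortativity"},
#'   \code{"balance"}.
#' @return An object of class \code{rsn_metric_matrix}: list with
#'   \code{values} (7x7, RSN labels), \code{metric}, \code{networks}.
#' @export
rsn_metric_matrix <- function(w, atlas,
                              metric = c("strength", "assortativity",
                                         "balance")) {
  stopifnot(inherits(w, "wdcm"))
  metric <- match.arg(metric)
  if (!identical(w$labels, atlas$abbrev))
    stop("matrix labels do not match the atlas ordering")
  k <- length(RSN_LEVELS)
  vals <- matrix(NA_real_, k, k, dimnames = list(RSN_LEVELS, RSN_LEVELS))
  for (a in seq_len(k)) for (b in a:k) {
    bp <- block_pairs(atlas, RSN_LEVELS[a], RSN_LEVELS[b])
    cell <- switch(metric,
      strength = sum(w$matrix[bp$directed_edges]),
      assortativity = tryCatch(
        weighted_assortativity(w, edges = bp$directed_edges,
                               strength_scope = "subset"),
        error = function(e) NA_real_),
      # a 2-region network has a single reciprocal pair: t-test undefined
      balance = tryCatch(
        balance_test(reciprocal_differences(w, bp$pairs))$neg_log10_p,
        error = function(e) NA_real_))
    vals[a, b] <- vals[b, a] <- cell
  }
  structure(list(values = vals, metric = metric, networks = RSN_LEVELS),
            class = "rsn_metric_matrix")
}

#' @export
print.rsn_metric_matrix <- function(x, digits = 4, ...) {
  cat("RSN-level", x$metric, "matrix (diagonal = within-network)\n")
  print(round(x$values, digits))
  invisible(x)
}

#' Within- and between-network summary of an RSN metric matrix
#'
#' @param m an \code{rsn_metric_matrix}.
#' @return A list of class \code{block_summary} with \code{within_mean},
#'   \code{within_max}, \code{within_min} over the 7 diagonal cells and
#'   \code{inter_mean}, \code{inter_max}, \code{inter_min} over the 21
#'   off-diagonal unordered cells; \code{NA} cells are excluded.
#' @export
block_summary <- function(m) {
  stopifnot(inherits(m, "rsn_metric_matrix"))
  within <- diag(m$values)
  inter <- m$values[upper.tri(m$values)]
  if (all(is.na(within)) && all(is.na(inter)))
    stop("all RSN cells are missing")
  agg <- function(v, f) if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE)
  structure(list(metric = m$metric,
                 within_mean = agg(within, mean),
                 within_max = agg(within, max),
                 within_min = agg(within, min),
                 inter_mean = agg(inter, mean),
                 inter_max = agg(inter, max),
                 inter_min = agg(inter, min)),
            class = "block_summary")
}

#' Regional increase/decrease screening of a difference matrix
#'
#' For each region, collects the incident off-diagonal entries of the
#' group-difference matrix (row and column, 2(n-1) values by default) and
#' averages the strictly positive and strictly negative ones separately:
#' the average connectivity increase and decrease the region takes part in.
#'
#' @param d a \code{diff_matrix}; the diagonal is ignored.
#' @param incident which incident entries to use: \code{"both"} (row union
#'   column, default), \code{"row"} (afferent only) or \code{"column"}
#'   (efferent only).
#' @return Data frame with one row per region: \code{region},
#'   \code{avg_increase} (Hz, >= 0), \code{avg_decrease} (Hz, <= 0, signed),
#'   \code{n_pos}, \code{n_neg}.
#' @export
regional_diff <- function(d, incident = c("both", "row", "column")) {
  stopifnot(inherits(d, "diff_matrix"))
  incident <- match.arg(incident)
  m <- d$matrix
  n <- nrow(m)
  out <- data.frame(region = d$labels,
                    avg_increase = 0, avg_decrease = 0,
                    n_pos = 0L, n_neg = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    vals <- switch(incident,
                   both = c(m[i, -i], m[-i, i]),
                   row = m[i, -i],
                   column = m[-i, i])
    pos <- vals[vals > 0]
    neg <- vals[vals < 0]
    out$avg_increase[i] <- if (length(pos)) mean(pos) else 0
    out$avg_decrease[i] <- if (length(neg)) mean(neg) else 0
    out$n_pos[i] <- length(pos)
    out$n_neg[i] <- length(neg)
  }
  out
}

#' Flag regions with outlying average connectivity change
#'
#' Regions strictly below the q-quantile of the average decrease (most
#' negative) and strictly above the (1-q)-quantile of the average increase
#' are flagged. Quantiles are linear-interpolation sample quantiles
#' (\code{stats::quantile} type 7) over the regional averages.
#'
#' @param rd data frame from \code{\link{regional_diff}}.
#' @param q quantile level in (0, 0.5); default 0.05.
#' @return List with \code{high_increase} and \code{high_decrease} (region
#'   labels) and the two thresholds \code{increase_threshold},
#'   \code{decrease_threshold}.
#' @export
flag_regions <- function(rd, q = 0.05) {
  if (!(q > 0 && q < 0.5)) stop("q must be in (0, 0.5)")
  thr_dec <- unname(stats::quantile(rd$avg_decrease, q, type = 7))
  thr_inc <- unname(stats::quantile(rd$avg_increase, 1 - q, type = 7))
  list(high_increase = rd$region[rd$avg_increase > thr_inc],
       high_decrease = rd$region[rd$avg_decrease < thr_dec],
       increase_threshold = thr_inc,
       decrease_threshold = thr_dec)
}
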