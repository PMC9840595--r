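#' Full hierarchical graph analysis of one group-level ECM
#'
#' Runs the whole characterization chain on a group-level effective
#' connectivity matrix: matrix transforms (WDCM, WUCM), brain-level metrics
#' (self-inhibition summary, total strength under both summation conventions,
#' small-world propensity against lattice/random nulls, weighted
#' assortativity, reciprocal balance), and the 7x7 RSN-level matrices with
#' their within/between summaries.
#'
#' @param e an \code{ecm}, or a file path readable by
#'   \code{\link{read_matrix}}.
#' @param atlas a \code{region_atlas} (default the packaged 36-region atlas).
#' @param n_null number of random-null realizations for the SWP ensemble.
#' @param seed integer seed for the null ensemble (required).
#' @param sdiag_mode aggregation of the diagonal, \code{"mean"} or
#'   \code{"sum"}.
#' @param assort_mode endpoint convention for directed assortativity, see
#'   \code{\link{weighted_assortativity}}.
#' @param transpose passed to \code{\link{read_matrix}} when \code{e} is a
#'   path.
#' @return A list of class \code{analysis_report} with elements
#'   \code{global}, \code{rsn}, \code{block_summary} and \code{provenance}.
#'   Metrics that are undefined on the input (e.g. SWP of an edgeless graph)
#'   are reported as \code{NA} with a note in \code{provenance$warnings}.
#' @export
analyze <- function(e, atlas = load_region_atlas("raichle36"),
                    n_null = 1000L, seed, sdiag_mode = "mean",
                    assort_mode = "out-in", transpose = FALSE) {
  if (missing(seed)) stop("seed is required (SWP null ensemble)")
  if (is.character(e))
    e <- read_matrix(e, atlas, kind = "ecm", transpose = transpose)
  stopifnot(inherits(e, "ecm"))
  warnings <- character()
  w <- ecm_to_wdcm(e)
  u <- wdcm_to_wucm(w)
  sis <- self_inhibition_summary(e, mode = sdiag_mode)

  swp <- tryCatch(small_world_propensity(u, n_null = n_null, seed = seed),
                  error = function(err) {
                    warnings <<- c(warnings, paste("SWP:", conditionMessage(err)))
                    NULL
                  })
  assort <- tryCatch(weighted_assortativity(w, assort_mode = assort_mode),
                     error = function(err) {
                       warnings <<- c(warnings,
                                      paste("assortativity:", conditionMessage(err)))
                       NA_real_
                     })
  bal <- balance_test(reciprocal_differences(w))

  global <- list(
    s_diag = sis$s_diag,
    sdiag_mode = sdiag_mode,
    strength_ordered_sum = total_strength(u, "ordered_sum")$s,
    strength_pair_sum = total_strength(u, "pair_sum")$s,
    swp_mean = if (is.null(swp)) NA_real_ else swp$swp_mean,
    swp_sd = if (is.null(swp)) NA_real_ else swp$swp_sd,
    dC = if (is.null(swp)) NA_real_ else swp$dC,
    dL = if (is.null(swp)) NA_real_ else swp$dL,
    assortativity = assort,
    balance_neg_log10_p = bal$neg_log10_p,
    balance_mean_diff = bal$mean_diff,
    balance_t_stat = bal$t_stat)

  rsn <- list()
  summ <- list()
  for (metric in c("strength", "assortativity", "balance")) {
    rm7 <- rsn_metric_matrix(w, atlas, metric)
    rsn[[metric]] <- rm7$values
    summ[[metric]] <- tryCatch(unclass(block_summary(rm7)),
                               error = function(err) {
                                 warnings <<- c(warnings,
                                                paste0("block_summary[", metric,
                                                       "]: ",
                                                       conditionMessage(err)))
                                 list(metric = metric,
                                      within_mean = NA_real_,
                                      within_max = NA_real_,
                                      within_min = NA_real_,
                                      inter_mean = NA_real_,
                                      inter_max = NA_real_,
                                      inter_min = NA_real_)
                               })
  }

  prov <- list(group_tag = e$tag,
               input_digest = .matrix_digest(e),
               n_null = as.integer(n_null), seed = as.integer(seed),
               sdiag_mode = sdiag_mode, assort_mode = assort_mode,
               n_regions = nrow(e$matrix),
               swp_dropped = if (is.null(swp)) NA_integer_ else swp$n_dropped,
               warnings = warnings)
  structure(list(global = global, rsn = rsn, block_summary = summ,
                 provenance = prov),
            class = "analysis_report")
}

# canonical md5 digest of a matrix via its round-trippable text form
.matrix_digest <- function(m) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  write_matrix(m, tf)
  unname(tools::md5sum(tf))
}

#' Regional comparison of two groups
#'
#' Screens a group-difference matrix for regions with outlying average
#' connectivity increase or decrease. Accepts either a ready difference
#' matrix or two group ECMs, whose element-wise difference (B minus A,
#' diagonal zeroed) is taken.
#'
#' @param d a \code{diff_matrix}, or \code{NULL} when \code{ecm_a}/\code{ecm_b}
#'   are given.
#' @param ecm_a,ecm_b two \code{ecm} objects (difference = B - A).
#' @param atlas a \code{region_atlas}.
#' @param q flagging quantile (default 0.05).
#' @param incident incident-entry convention, see \code{\link{regional_diff}}.
#' @return A list of class \code{compare_report} with \code{regional} (the
#'   per-region table), \code{flags}, \code{q} and \code{provenance}.
#' @export
compare_groups <- function(d = NULL, ecm_a = NULL, ecm_b = NULL,
                           atlas = load_region_atlas("raichle36"), q = 0.05,
                           incident = "both") {
  if (is.null(d)) {
    stopifnot(inherits(ecm_a, "ecm"), inherits(ecm_b, "ecm"))
    if (!identical(dim(ecm_a$matrix), dim(ecm_b$matrix)))
      stop("the two ECMs have different dimensions")
    dm <- ecm_b$matrix - ecm_a$matrix
    diag(dm) <- 0
    d <- diff_matrix(dm, ecm_a$labels,
                     tag = "positive = higher in group B")
  }
  stopifnot(inherits(d, "diff_matrix"))
  if (is.character(d$labels) && !identical(d$labels, atlas$abbrev))
    stop("difference-matrix labels do not match the atlas ordering")
  rd <- regional_diff(d, incident = incident)
  fl <- flag_regions(rd, q = q)
  structure(list(regional = rd, flags = fl, q = q,
                 provenance = list(tag = d$tag, incident = incident,
                                   input_digest = .matrix_digest(d))),
            class = "compare_report")
}

#' Write an analysis or comparison report to disk
#'
#' Emits a machine-readable JSON report (stable key order, full precision), a
#' set of CSV tables (7x7 RSN matrices, block summaries, regional table) and
#' a human-readable markdown summary. Re-running on identical inputs
#' reproduces the files byte for byte.
#'
#' @param r an \code{analysis_report} or \code{compare_report}.
#' @param out_dir output directory (created if missing).
#' @param prefix filename prefix, e.g. a group tag (default \code{"report"}).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(r, out_dir, prefix = "report") {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  files <- character()
  jpath <- file.path(out_dir, paste0(prefix, ".json"))
  jsonlite::write_json(unclass(r), jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files <- c(files, jpath)

  if (inherits(r, "analysis_report")) {
    for (metric in names(r$rsn)) {
      p <- file.path(out_dir, sprintf("%s_rsn_%s.csv", prefix, metric))
      utils::write.csv(r$rsn[[metric]], p)
      files <- c(files, p)
    }
    bs <- do.call(rbind, lapply(names(r$block_summary), function(mt) {
      data.frame(metric = mt, as.data.frame(r$block_summary[[mt]][-1]))
    }))
    p <- file.path(out_dir, paste0(prefix, "_block_summary.csv"))
    utils::write.csv(bs, p, row.names = FALSE)
    files <- c(files, p)
    p <- file.path(out_dir, paste0(prefix, ".md"))
    writeLines(.global_markdown(r, prefix), p)
    files <- c(files, p)
  }
  if (inherits(r, "compare_report")) {
    p <- file.path(out_dir, paste0(prefix, "_regional_diff.csv"))
    utils::write.csv(r$regional, p, row.names = FALSE)
    files <- c(files, p)
    p <- file.path(out_dir, paste0(prefix, "_flags.json"))
    jsonlite::write_json(r$flags, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, p)
  }
  invisible(files)
}

.global_markdown <- function(r, prefix) {
  g <- r$global
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, digits = 4))
  rows <- c(
    c("ECM", "S_diag", fmt(g$s_diag)),
    c("WDCM", "assortativity", fmt(g$assortativity)),
    c("WDCM", "balance -log10(p)", fmt(g$balance_neg_log10_p)),
    c("WUCM", "strength (pair sum)", fmt(g$strength_pair_sum)),
    c("WUCM", "SWP", fmt(g$swp_mean)),
    c("WUCM", "dC", fmt(g$dC)),
    c("WUCM", "dL", fmt(g$dL)))
  rows <- matrix(rows, ncol = 3, byrow = TRUE)
  c(sprintf("# Global graph properties: %s", prefix),
    "",
    "| Matrix | Parameter | Value |",
    "|---|---|---|",
    apply(rows, 1, function(x) sprintf("| %s | %s | %s |",
                                       x[1], x[2], x[3])))
}

#' Recompute the published-style tables from deposited group matrices
#'
#' Given the deposited group-level matrices (two group ECMs and the
#' group-difference matrix) this runs the full pipeline and returns the
#' global two-group table, the RSN block summaries and the regional
#' screening table. The deposited files are not shipped with the package;
#' point \code{dir} at a local copy of the archive containing the three
#' matrices as labeled CSVs named \code{ecm_obesity.csv}, \code{ecm_t2dm.csv}
#' and \code{decm.csv} (or pass explicit paths).
#'
#' @param dir directory containing the three matrix files, or \code{NULL} if
#'   explicit paths are given.
#' @param ecm_a_path,ecm_b_path,decm_path explicit file paths overriding
#'   \code{dir}.
#' @param atlas a \code{region_atlas}.
#' @param n_null,seed SWP ensemble settings.
#' @param transpose passed to \code{\link{read_matrix}}.
#' @return List with \code{global} (two-column data frame of the 7 global
#'   metrics), \code{reports} (the two \code{analysis_report}s) and
#'   \code{regional} (the \code{compare_report}).
#' @export
reproduce_deposited <- function(dir = NULL, ecm_a_path = NULL,
                                ecm_b_path = NULL, decm_path = NULL,
                                atlas = load_region_atlas("raichle36"),
                                n_null = 1000L, seed = 1L, transpose = FALSE) {
  if (!is.null(dir)) {
    if (is.null(ecm_a_path)) ecm_a_path <- file.path(dir, "ecm_obesity.csv")
    if (is.null(ecm_b_path)) ecm_b_path <- file.path(dir, "ecm_t2dm.csv")
    if (is.null(decm_path)) decm_path <- file.path(dir, "decm.csv")
  }
  for (p in c(ecm_a_path, ecm_b_path, decm_path)) {
    if (!file.exists(p))
      stop("deposited matrix file not found: ", p,
           " (the deposited archive must be downloaded separately; see the ",
           "README section on reproducing the published tables)")
  }
  ra <- analyze(ecm_a_path, atlas, n_null = n_null, seed = seed,
                transpose = transpose)
  rb <- analyze(ecm_b_path, atlas, n_null = n_null, seed = seed,
                transpose = transpose)
  d <- read_matrix(decm_path, atlas, kind = "diff", transpose = transpose)
  cmp <- compare_groups(d = d, atlas = atlas)
  metric_names <- c("s_diag", "assortativity", "balance_neg_log10_p",
                    "strength_pair_sum", "swp_mean", "dC", "dL")
  global <- data.frame(
    parameter = metric_names,
    group_a = vapply(metric_names, function(k) {
      v <- ra$global[[k]]; if (is.null(v)) NA_real_ else v
    }, numeric(1)),
    group_b = vapply(metric_names, function(k) {
      v <- rb$global[[k]]; if (is.null(v)) NA_real_ else v
    }, numeric(1)))
  list(global = global, reports = list(a = ra, b = rb), regional = cmp)
}
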