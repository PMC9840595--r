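#' Connectivity matrix containers
#'
#' Four matrix classes carry the pipeline's data:
#' \describe{
#'   \item{\code{ecm}}{signed weighted directed effective connectivity matrix.
#'     Off-diagonal entries are coupling rates in Hz; entry (i, j) is the
#'     influence of region j (column, source) on region i (row, target).
#'     The diagonal holds dimensionless log-scaling self-inhibition
#'     parameters that scale a default inhibition of -0.5 Hz.}
#'   \item{\code{diff_matrix}}{signed element-wise group-difference matrix
#'     (Hz); not a connectivity matrix, so it is never converted to a WDCM.}
#'   \item{\code{wdcm}}{weighted directed connectivity matrix: absolute values
#'     of the ECM off-diagonals, zero diagonal.}
#'   \item{\code{wucm}}{weighted undirected connectivity matrix: symmetric,
#'     entry (i, j) = WDCM(i, j) + WDCM(j, i).}
#' }
#'
#' @param matrix square numeric matrix with finite entries.
#' @param labels character vector of region abbreviations in atlas order;
#'   defaults to existing dimnames or \code{R1..Rn}.
#' @param group_tag,tag free-text provenance tag (group name, sign
#'   convention).
#' @return An object of the corresponding class wrapping \code{matrix},
#'   \code{labels} and the tag.
#' @name conn_matrices
NULL

.new_conn <- function(matrix, labels, tag, class) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix))
    stop("matrix must be square, got ", nrow(matrix), "x", ncol(matrix))
  if (!is.numeric(matrix) || !all(is.finite(matrix)))
    stop("matrix must be numeric with all values finite")
  if (is.null(labels)) {
    labels <- rownames(matrix)
    if (is.null(labels)) labels <- paste0("R", seq_len(nrow(matrix)))
  }
  if (length(labels) != nrow(matrix))
    stop("labels length (", length(labels), ") != matrix dimension (",
         nrow(matrix), ")")
  dimnames(matrix) <- list(labels, labels)
  structure(list(matrix = matrix, labels = as.character(labels), tag = tag),
            class = c(class, "conn_matrix"))
}

#' @rdname conn_matrices
#' @export
ecm <- function(matrix, labels = NULL, group_tag = "") {
  .new_conn(matrix, labels, group_tag, "ecm")
}

#' @rdname conn_matrices
#' @export
diff_matrix <- function(matrix, labels = NULL,
                        tag = "positive = higher in group B") {
  .new_conn(matrix, labels, tag, "diff_matrix")
}

#' @rdname conn_matrices
#' @export
wdcm <- function(matrix, labels = NULL, tag = "") {
  m <- .new_conn(matrix, labels, tag, "wdcm")
  if (any(m$matrix < 0)) stop("WDCM entries must be nonnegative")
  if (any(diag(m$matrix) != 0)) stop("WDCM diagonal must be zero")
  m
}

#' @rdname conn_matrices
#' @export
wucm <- function(matrix, labels = NULL, tag = "") {
  m <- .new_conn(matrix, labels, tag, "wucm")
  if (any(m$matrix < 0)) stop("WUCM entries must be nonnegative")
  if (any(diag(m$matrix) != 0)) stop("WUCM diagonal must be zero")
  if (!isTRUE(all.equal(m$matrix, t(m$matrix), tolerance = 0)))
    stop("WUCM must be exactly symmetric")
  m
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<%s> %dx%d regions%s\n", class(x)[1], nrow(x$matrix),
              ncol(x$matrix),
              if (nzchar(x$tag)) paste0(" [", x$tag, "]") else ""))
  cat("  sum |off-diagonal| =",
      format(sum(abs(x$matrix)) - sum(abs(diag(x$matrix))), digits = 6), "\n")
  invisible(x)
}

#' @export
dim.conn_matrix <- function(x) dim(x$matrix)

#' Read a connectivity or difference matrix
#'
#' Reads a square numeric matrix from a delimited text file (comma, tab or
#' semicolon; sniffed automatically). If the file carries a header row and a
#' label column, the labels must be a permutation of the atlas abbreviations
#' and rows/columns are reordered to atlas order. Unlabeled files are assumed
#' to already be in atlas order, with a warning. Missing values are not
#' permitted: pruned parameters must be encoded as exact 0.
#'
#' @param path file path.
#' @param atlas a \code{region_atlas} defining the canonical order.
#' @param kind \code{"ecm"} or \code{"diff"}.
#' @param tag optional provenance tag stored on the result.
#' @param transpose logical; set \code{TRUE} for files stored with the
#'   opposite orientation (row = source) to convert them to the package's
#'   column-source convention.
#' @return An \code{ecm} or \code{diff_matrix} in atlas order.
#' @export
read_matrix <- function(path, atlas, kind = c("ecm", "diff"), tag = "",
                        transpose = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  sep <- .sniff_delim(path)
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", colClasses = "character")
  labeled <- is.na(suppressWarnings(as.numeric(raw[1, 2])))
  if (labeled) {
    col_labels <- as.character(raw[1, -1])
    row_labels <- as.character(raw[-1, 1])
    body <- raw[-1, -1, drop = FALSE]
  } else {
    col_labels <- row_labels <- NULL
    body <- raw
  }
  m <- suppressWarnings(matrix(as.numeric(as.matrix(body)),
                               nrow = nrow(body), ncol = ncol(body)))
  if (anyNA(m))
    stop("non-numeric or missing cell(s) in matrix body of ", path,
         " (pruned parameters must be written as exact 0)")
  if (nrow(m) != ncol(m))
    stop("matrix body must be square, got ", nrow(m), "x", ncol(m))
  if (nrow(m) != nrow(atlas))
    stop("matrix has ", nrow(m), " regions but atlas has ", nrow(atlas))
  if (labeled) {
    for (lb in list(row = row_labels, column = col_labels)) {
      if (!setequal(lb, atlas$abbrev) || length(lb) != nrow(atlas))
        stop("matrix labels are not a permutation of the atlas abbreviations")
    }
    m <- m[match(atlas$abbrev, row_labels), match(atlas$abbrev, col_labels)]
  } else {
    warning("matrix file ", basename(path),
            " has no labels; assuming rows/columns already in atlas order")
  }
  if (transpose) m <- t(m)
  if (kind == "ecm") ecm(m, atlas$abbrev, group_tag = tag)
  else diff_matrix(m, atlas$abbrev, tag = tag)
}

#' Write a matrix to CSV
#'
#' Writes a labeled CSV (first row and first column hold the region
#' abbreviations) at full double precision, so that
#' \code{read_matrix(write_matrix(m))} round-trips to at least 12 significant
#' digits.
#'
#' @param m a \code{conn_matrix} (or any of its subclasses).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "conn_matrix"))
  mat <- m$matrix
  body <- format(mat, digits = 17, scientific = TRUE, trim = TRUE)
  out <- rbind(c("", m$labels), cbind(m$labels, body))
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write matrix to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
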