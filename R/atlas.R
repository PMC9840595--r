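#' Resting-state network labels of the 36-region atlas
#'
#' Canonical ordering of the seven resting-state networks (RSNs) used
#' throughout the package: default mode (DMN), dorsal attention (DAN),
#' central executive (CEN), salience (SN), sensorimotor (SMN), visual (VN)
#' and auditory (AN) networks.
#'
#' @format Character vector of length 7.
#' @export
RSN_LEVELS <- c("DMN", "DAN", "CEN", "SN", "SMN", "VN", "AN")

.expected_rsn_sizes <- c(DMN = 9L, DAN = 8L, CEN = 5L, SN = 7L,
                         SMN = 3L, VN = 2L, AN = 2L)

#' Construct a region atlas
#'
#' A region atlas fixes the canonical node ordering used by every matrix in
#' the package: regions are listed network block by network block (DMN first,
#' AN last), and all connectivity matrices must carry their rows and columns
#' in exactly this order.
#'
#' @param abbrev character vector of unique short region labels.
#' @param name character vector of full region names.
#' @param network character vector of RSN memberships, each one of
#'   \code{RSN_LEVELS}.
#' @param x,y,z integer MNI152 coordinates in mm.
#' @param builtin logical; if \code{TRUE} the atlas is validated against the
#'   packaged 36-region layout (region count and per-network sizes).
#'
#' @return An object of class \code{region_atlas}: a data frame with columns
#'   \code{abbrev}, \code{name}, \code{network}, \code{x}, \code{y}, \code{z}.
#' @export
region_atlas <- function(abbrev, name, network, x, y, z, builtin = FALSE) {
  if (anyDuplicated(abbrev))
    stop("duplicate region abbreviation(s): ",
         paste(unique(abbrev[duplicated(abbrev)]), collapse = ", "))
  bad <- setdiff(unique(network), RSN_LEVELS)
  if (length(bad))
    stop("unknown network label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(RSN_LEVELS, collapse = ", "), ")")
  atlas <- data.frame(abbrev = as.character(abbrev),
                      name = as.character(name),
                      network = as.character(network),
                      x = as.integer(x), y = as.integer(y), z = as.integer(z),
                      stringsAsFactors = FALSE)
  if (builtin) {
    if (nrow(atlas) != 36L)
      stop("builtin atlas must have 36 regions, got ", nrow(atlas))
    sizes <- table(factor(atlas$network, levels = RSN_LEVELS))
    if (!all(sizes == .expected_rsn_sizes))
      stop("builtin atlas network sizes do not match the 36-region layout")
  }
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}

#' Load a region atlas from file or the builtin fixture
#'
#' @param path path to a TSV/CSV file with columns \code{abbrev}, \code{name},
#'   \code{network}, \code{x}, \code{y}, \code{z}, or the fixture id
#'   \code{"raichle36"} for the packaged 36-region / 7-RSN atlas.
#'
#' @return A \code{region_atlas}.
#' @examples
#' atlas <- load_region_atlas("raichle36")
#' nrow(atlas)            # 36
#' atlas[atlas$abbrev == "PCC", c("x", "y", "z")]
#' @export
load_region_atlas <- function(path = "raichle36") {
  builtin <- identical(path, "raichle36")
  if (builtin) {
    path <- system.file("extdata", "raichle36_atlas.tsv", package = "ecmgraph",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("atlas file not found: ", path)
  sep <- .sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  # tolerate 'abbreviation' as a synonym for 'abbrev'
  names(df)[names(df) == "abbreviation"] <- "abbrev"
  need <- c("abbrev", "name", "network", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("atlas file is missing column(s): ", paste(miss, collapse = ", "))
  region_atlas(df$abbrev, df$name, df$network, df$x, df$y, df$z,
               builtin = builtin)
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("Region atlas:", nrow(x), "regions in",
      length(unique(x$network)), "networks\n")
  sizes <- table(factor(x$network, levels = RSN_LEVELS))
  cat(paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  NextMethod()
  invisible(x)
}

# delimiter sniffing shared by atlas and matrix readers: pick the candidate
# that splits the first non-empty line into the most fields
.sniff_delim <- function(path) {
  line <- ""
  con <- file(path, "r")
  on.exit(close(con))
  while (!nzchar(trimws(line))) {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("file is empty: ", path)
  }
  counts <- vapply(c("," = ",", "\t" = "\t", ";" = ";"),
                   function(d) length(strsplit(line, d, fixed = TRUE)[[1]]),
                   integer(1))
  names(counts)[which.max(counts)]
}
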