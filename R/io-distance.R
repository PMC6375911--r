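# Square distance-matrix export in PHYLIP and NEXUS formats, for input to
# network/tree software (neighbor-net construction is out of scope here; we
# only provide the matrix).

#' Write a square distance matrix (PHYLIP or NEXUS)
#'
#' @param m square symmetric nonnegative numeric matrix.
#' @param ids taxon labels (defaults to `rownames(m)`).
#' @param path output file.
#' @param format `"phylip"` (square lower+upper) or `"nexus"` (a
#'   `DISTANCES` block).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, ids = rownames(m), path,
                                  format = c("phylip", "nexus")) {
  format <- match.arg(format)
  m <- as.matrix(m)
  n <- nrow(m)
  if (ncol(m) != n) stop("distance matrix must be square")
  if (anyNA(m) || any(!is.finite(m))) stop("distance matrix contains NA/NaN/Inf")
  if (any(m < 0)) stop("distance matrix must be nonnegative")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix must be symmetric")
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  ids <- gsub("\\s", "_", as.character(ids))
  rows <- vapply(seq_len(n), function(i)
    paste(formatC(ids[i], width = 12, flag = "-"),
          paste(sprintf("%.10g", m[i, ]), collapse = " ")), character(1))
  if (format == "phylip") {
    writeLines(c(sprintf("%5d", n), rows), path)
  } else {
    writeLines(c("#NEXUS", "BEGIN TAXA;",
                 sprintf("  DIMENSIONS NTAX=%d;", n),
                 paste0("  TAXLABELS ", paste(ids, collapse = " "), ";"),
                 "END;", "BEGIN DISTANCES;",
                 "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;", "  MATRIX",
                 paste0("    ", rows), "  ;", "END;"), path)
  }
  invisible(path)
}

#' Read a square distance matrix written by [write_distance_matrix()]
#'
#' The format is auto-detected (`#NEXUS` magic vs. PHYLIP count header).
#'
#' @param path input file.
#' @return numeric matrix with taxon labels as dimnames.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  if (grepl("^#NEXUS", lines[1], ignore.case = TRUE)) {
    start <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)[1]
    if (is.na(start)) stop("no MATRIX line in NEXUS distances block")
    end <- which(grepl("^\\s*;", lines) & seq_along(lines) > start)[1]
    body <- lines[(start + 1):(end - 1)]
  } else {
    n <- as.integer(trimws(lines[1]))
    body <- lines[2:(1 + n)]
  }
  parts <- strsplit(trimws(body), "\\s+")
  ids <- vapply(parts, `[[`, character(1), 1)
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(m) <- colnames(m) <- ids
  m
}
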