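# Haplotype alignments and population maps.

#' Construct a haplotype alignment with colony and group labels
#'
#' Container for an aligned set of mtDNA haplotype sequences with a
#' two-level sampling hierarchy: every sample belongs to a colony and every
#' colony to a group (colonies nest in groups).
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param sequences character vector of equal-length nucleotide strings over
#'   `A, C, G, T, N, -` (case-insensitive).
#' @param colony per-sample colony label.
#' @param group per-sample group label; each colony must map to exactly one
#'   group.
#' @return an object of class `hap_alignment`: a list with elements
#'   `ids`, `seq` (character matrix, one row per sample), `colony`, `group`.
#' @export
hap_alignment <- function(sample_ids, sequences, colony, group) {
  sample_ids <- as.character(sample_ids)
  sequences <- toupper(as.character(sequences))
  n <- length(sample_ids)
  if (n == 0) stop("empty alignment")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(sequences) != n || length(colony) != n || length(group) != n)
    stop("sample_ids, sequences, colony and group must have equal length")
  lens <- nchar(sequences)
  if (any(lens != lens[1])) {
    bad <- sample_ids[which(lens != lens[1])[1]]
    stop("ragged alignment: record '", bad, "' has length ", lens[lens != lens[1]][1],
         ", expected ", lens[1])
  }
  if (lens[1] < 1) stop("sequences must have length >= 1")
  m <- do.call(rbind, strsplit(sequences, ""))
  if (!all(m %in% c("A", "C", "G", "T", "N", "-")))
    stop("sequences may only contain A, C, G, T, N, -")
  rownames(m) <- sample_ids
  cg <- unique(data.frame(colony = as.character(colony), group = as.character(group)))
  if (anyDuplicated(cg$colony))
    stop("each colony must map to exactly one group")
  structure(list(ids = sample_ids, seq = m,
                 colony = as.character(colony), group = as.character(group)),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("<hap_alignment> ", length(x$ids), " samples x ", ncol(x$seq), " bp; ",
      length(unique(x$colony)), " colonies in ", length(unique(x$group)),
      " groups\n", sep = "")
  invisible(x)
}

#' Read a sample -> colony -> group population map
#'
#' Three-column whitespace/tab separated file (`sample`, `colony`, `group`);
#' lines starting with `#` are comments.
#'
#' @param path file path.
#' @return data.frame with columns `sample`, `colony`, `group`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "colony", "group"))
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample))
    stop("popmap lists sample '", df$sample[duplicated(df$sample)][1],
         "' more than once")
  cg <- unique(df[, c("colony", "group")])
  if (anyDuplicated(cg$colony))
    stop("popmap maps a colony to more than one group")
  df
}

#' Read a FASTA haplotype alignment together with its population map
#'
#' @param path FASTA file of aligned sequences.
#' @param popmap_path three-column popmap (see [read_popmap()]); must list
#'   every FASTA record (it may list additional, unsequenced samples).
#' @param trim if `TRUE`, drop every alignment column in which any sequence
#'   carries `N` or `-`, keeping only the region resolved in all samples.
#' @return a [hap_alignment()].
#' @export
read_fasta_alignment <- function(path, popmap_path, trim = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  lens <- Biostrings::width(ss)
  if (any(lens != lens[1])) {
    bad <- ids[which(lens != lens[1])[1]]
    stop("ragged alignment: record '", bad, "' has length ",
         lens[lens != lens[1]][1], ", expected ", lens[1])
  }
  pm <- read_popmap(popmap_path)
  missing <- setdiff(ids, pm$sample)
  if (length(missing) > 0)
    stop("samples present in FASTA but absent from popmap: ",
         paste(missing, collapse = ", "))
  idx <- match(ids, pm$sample)
  aln <- hap_alignment(ids, as.character(ss), pm$colony[idx], pm$group[idx])
  if (trim) {
    ambiguous <- apply(aln$seq == "N" | aln$seq == "-", 2, any)
    if (any(ambiguous)) {
      pp_log("trimming ", sum(ambiguous), " of ", ncol(aln$seq),
             " columns carrying N or - (columns [0,", ncol(aln$seq),
             ") 0-based half-open)")
      aln$seq <- aln$seq[, !ambiguous, drop = FALSE]
      if (ncol(aln$seq) == 0) stop("trimming removed every column")
    }
  }
  aln
}

#' Write a haplotype alignment as FASTA (and optionally its popmap)
#'
#' @param x a [hap_alignment()].
#' @param path output FASTA path.
#' @param popmap_path optional path for a matching 3-column popmap.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(x, path, popmap_path = NULL) {
  stopifnot(inherits(x, "hap_alignment"))
  seqs <- apply(x$seq, 1, paste0, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- x$ids
  Biostrings::writeXStringSet(ss, path, width = 80)
  if (!is.null(popmap_path)) {
    utils::write.table(data.frame(x$ids, x$colony, x$group), popmap_path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Subset an alignment to a set of colonies
#'
#' @param x a [hap_alignment()].
#' @param colonies colony labels to keep.
#' @return a [hap_alignment()] restricted to those samples.
#' @export
subset_colonies <- function(x, colonies) {
  stopifnot(inherits(x, "hap_alignment"))
  keep <- x$colony %in% colonies
  if (!any(keep)) stop("no samples in colonies: ", paste(colonies, collapse = ", "))
  hap_alignment(x$ids[keep],
                apply(x$seq[keep, , drop = FALSE], 1, paste0, collapse = ""),
                x$colony[keep], x$group[keep])
}
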