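# Diploid SNP genotype matrices from VCF or TSV.

#' Construct a diploid SNP genotype matrix
#'
#' Genotypes are coded 0/1/2 as the count of the globally minor allele
#' (ties broken toward the alternate allele, so that downstream folding is
#' stable); `NA` is missing. One column per SNP, one row per individual.
#'
#' @param individual_ids character vector of unique individual ids.
#' @param population per-individual population label.
#' @param geno integer matrix (individuals x SNPs) with values in
#'   `{0, 1, 2, NA}`.
#' @param locus_id per-SNP locus identifier (RAD locus of origin).
#' @param locus_length locus length in bases (default 95).
#' @param recode_minor if `TRUE` (default), recode columns so that 0/1/2
#'   counts the globally minor allele.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(individual_ids, population, geno, locus_id,
                            locus_length = 95, recode_minor = TRUE) {
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(individual_ids))
    stop("geno must have one row per individual")
  if (length(population) != length(individual_ids))
    stop("population must have one label per individual")
  if (length(locus_id) != ncol(geno))
    stop("locus_id must have one entry per SNP")
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  if (recode_minor && ncol(geno) > 0) {
    cnt <- colSums(geno, na.rm = TRUE)
    tot <- 2L * colSums(!is.na(geno))
    flip <- cnt > tot / 2           # strict: ties stay on the coded allele
    geno[, flip] <- 2L - geno[, flip]
  }
  rownames(geno) <- individual_ids
  structure(list(ids = individual_ids, population = as.character(population),
                 geno = geno, locus_id = as.character(locus_id),
                 locus_length = locus_length),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$ids), " individuals x ", ncol(x$geno),
      " SNPs on ", length(unique(x$locus_id)), " loci (", x$locus_length,
      " bp); populations: ",
      paste(sprintf("%s=%d", names(table(x$population)), table(x$population)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

parse_vcf_gt <- function(gt) {
  # accepts 0/0, 0|1, ., ./., half-missing ./1 treated as missing
  gt <- sub(":.*$", "", gt)
  a <- strsplit(gt, "[/|]")
  vapply(a, function(al) {
    if (length(al) != 2 || any(al == ".") || any(is.na(al))) return(NA_integer_)
    if (!all(al %in% c("0", "1"))) stop("unknown genotype token: ", paste(al, collapse = "/"))
    sum(al == "1")
  }, integer(1))
}

#' Read diploid SNP genotypes from VCF or a genotype TSV
#'
#' VCF rows that are multi-allelic or contain indels are dropped (with a
#' logged count), as are sites whose missing-call fraction exceeds
#' `max_missing_frac`. Genotype separators `/` and `|` are both accepted;
#' half-missing calls (`./1`) are treated as missing. The per-SNP locus id
#' is the VCF `CHROM` field (RAD loci are contigs of a reduced reference).
#'
#' The TSV alternative has header `locus  pos  <id1> <id2> ...` and cells
#' `0/1/2/NA`.
#'
#' @param path VCF (`*.vcf`) or TSV genotype matrix.
#' @param popmap_path popmap listing every individual with its population
#'   (column 3, the group, is carried along when present).
#' @param max_missing_frac drop sites with a larger missing fraction
#'   (default 0.25, i.e. sites genotyped in at least 75% of individuals are
#'   kept).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, popmap_path, max_missing_frac = 0.25) {
  first <- readLines(path, n = 1)
  is_vcf <- grepl("^##fileformat=VCF", first)
  if (is_vcf) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    biallelic <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
      ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    n_drop <- sum(!biallelic)
    if (n_drop > 0)
      pp_log("dropped ", n_drop, " multi-allelic or indel site(s); retained ",
             sum(biallelic))
    gt_raw <- v@gt[biallelic, -1, drop = FALSE]
    ids <- colnames(gt_raw)
    geno <- apply(gt_raw, 1, parse_vcf_gt)
    if (is.null(dim(geno))) geno <- matrix(geno, nrow = length(ids))
    locus <- fix[biallelic, "CHROM"]
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            na.strings = c("NA", "."))
    if (!all(c("locus", "pos") == names(df)[1:2]))
      stop("genotype TSV must start with columns 'locus' and 'pos'")
    ids <- names(df)[-(1:2)]
    geno <- t(as.matrix(df[, -(1:2), drop = FALSE]))
    storage.mode(geno) <- "integer"
    bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
    if (any(bad)) stop("unknown genotype token in TSV: ", geno[bad][1])
    locus <- as.character(df$locus)
  }
  miss <- colMeans(is.na(geno))
  keep <- miss <= max_missing_frac
  pp_log("missingness filter (> ", max_missing_frac, "): dropped ",
         sum(!keep), ", retained ", sum(keep), " site(s)")
  if (!any(keep)) stop("no sites survive the missingness filter")
  geno <- geno[, keep, drop = FALSE]
  locus <- locus[keep]
  pm <- read_popmap(popmap_path)
  missing <- setdiff(ids, pm$sample)
  if (length(missing) > 0)
    stop("individuals present in genotypes but absent from popmap: ",
         paste(missing, collapse = ", "))
  idx <- match(ids, pm$sample)
  gm <- genotype_matrix(ids, pm$colony[idx], geno, locus)
  attr(gm, "group") <- pm$group[idx]
  gm
}

#' Keep a single SNP per RAD locus
#'
#' Retains the first SNP (in input order) of every locus, mirroring the
#' one-SNP-per-locus thinning used to decorrelate RAD sites.
#'
#' @param gm a [genotype_matrix()].
#' @return a thinned [genotype_matrix()].
#' @export
one_snp_per_locus <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- !duplicated(gm$locus_id)
  pp_log("one-SNP-per-locus: retained ", sum(keep), " of ", length(keep), " SNPs")
  gm$geno <- gm$geno[, keep, drop = FALSE]
  gm$locus_id <- gm$locus_id[keep]
  gm
}

#' Apply the site missingness filter to an existing genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing_frac maximum tolerated missing fraction per site.
#' @return a filtered [genotype_matrix()].
#' @export
filter_missingness <- function(gm, max_missing_frac = 0.25) {
  stopifnot(inherits(gm, "genotype_matrix"))
  miss <- colMeans(is.na(gm$geno))
  keep <- miss <= max_missing_frac
  pp_log("missingness filter (> ", max_missing_frac, "): dropped ",
         sum(!keep), ", retained ", sum(keep), " site(s)")
  if (!any(keep)) stop("no sites survive the missingness filter")
  gm$geno <- gm$geno[, keep, drop = FALSE]
  gm$locus_id <- gm$locus_id[keep]
  gm
}

#' Write genotypes as a minimal plain-text VCF
#'
#' Emits an uncompressed VCFv4.2 with one contig per RAD locus and `GT`
#' fields only; the inverse of [read_genotypes()] for round-tripping.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param pos per-SNP position within its locus (default: SNP rank within
#'   locus).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path, pos = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_snp <- ncol(gm$geno)
  if (is.null(pos)) pos <- stats::ave(seq_len(n_snp), gm$locus_id, FUN = seq_along)
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=petrelpop",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$ids), collapse = "\t"))
  body <- vapply(seq_len(n_snp), function(s) {
    g <- gm$geno[, s]
    cells <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    paste(c(gm$locus_id[s], pos[s], ".", "A", "C", ".", "PASS", ".", "GT",
            cells), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write genotypes as the package's genotype TSV
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pos <- stats::ave(seq_along(gm$locus_id), gm$locus_id, FUN = seq_along)
  df <- data.frame(locus = gm$locus_id, pos = pos,
                   t(gm$geno), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
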