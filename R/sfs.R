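# Folded joint (2D) minor-allele frequency spectra: construction from
# genotypes with hypergeometric projection, locus block bootstrap, and a
# whitespace text format.

# fold an (n1+1) x (n2+1) joint spectrum on the pooled minor allele.
# tie cells (pooled count exactly half) get half weight on each mirror
# ("half") or all weight on the lexicographically smaller cell ("lower").
#' @noRd
fold_2d <- function(m, tie = c("half", "lower")) {
  tie <- match.arg(tie)
  n1 <- nrow(m) - 1L
  n2 <- ncol(m) - 1L
  half <- (n1 + n2) / 2
  out <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in 0:n1) {
    for (j in 0:n2) {
      v <- m[i + 1L, j + 1L]
      if (v == 0) next
      t <- i + j
      mi <- n1 - i; mj <- n2 - j
      if (t < half) {
        out[i + 1L, j + 1L] <- out[i + 1L, j + 1L] + v
      } else if (t > half) {
        out[mi + 1L, mj + 1L] <- out[mi + 1L, mj + 1L] + v
      } else if (i == mi && j == mj) {
        out[i + 1L, j + 1L] <- out[i + 1L, j + 1L] + v
      } else if (tie == "half") {
        out[i + 1L, j + 1L] <- out[i + 1L, j + 1L] + v / 2
        out[mi + 1L, mj + 1L] <- out[mi + 1L, mj + 1L] + v / 2
      } else {
        lower_first <- (i < mi) || (i == mi && j <= mj)
        if (lower_first) out[i + 1L, j + 1L] <- out[i + 1L, j + 1L] + v
        else out[mi + 1L, mj + 1L] <- out[mi + 1L, mj + 1L] + v
      }
    }
  }
  out
}

#' @noRd
fold_mask <- function(n1, n2) {
  t <- outer(0:n1, 0:n2, "+")
  t > (n1 + n2) / 2
}

#' @noRd
new_folded_2dsfs <- function(counts, n1, n2, n_snps_used, pops = c("pop1", "pop2")) {
  structure(list(counts = counts, n1 = as.integer(n1), n2 = as.integer(n2),
                 n_snps_used = n_snps_used,
                 mask = fold_mask(n1, n2), pops = pops),
            class = "folded_2dsfs")
}

#' @export
print.folded_2dsfs <- function(x, ...) {
  cat("<folded_2dsfs> ", x$n1, " x ", x$n2, " haploid samples (",
      nrow(x$counts), "x", ncol(x$counts), " cells), ",
      format(x$n_snps_used, digits = 6), " SNPs\n", sep = "")
  invisible(x)
}

#' Folded joint (2D) minor-allele frequency spectrum from genotypes
#'
#' Per SNP, the observed allele counts of each population are projected down
#' to haploid sizes `(n1, n2)` by the hypergeometric expectation over the
#' observed calls (absorbing missing data), the joint cell weights are
#' accumulated as real numbers, and the spectrum is folded on the pooled
#' minor allele; cells with pooled frequency above one half are masked
#' (zero), and exact ties are split half-weight between mirror cells by
#' default. SNPs with zero calls, or fewer called alleles than the
#' projection size, in either population are excluded with a logged count.
#' The monomorphic cell (0, 0) is retained but flagged; it is excluded from
#' composite likelihoods downstream.
#'
#' @param gm a [genotype_matrix()].
#' @param pop1,pop2 population labels (default: the two populations in
#'   order of appearance).
#' @param n1,n2 projection haploid sample sizes (>= 2). Default: the full
#'   haploid size when the population has no missing calls, otherwise 80%
#'   of it (rounded, made even).
#' @param tie tie-fold rule, `"half"` (default) or `"lower"`.
#' @return a `folded_2dsfs`: real-valued counts matrix of dimension
#'   `(n1+1) x (n2+1)`, fold mask, haploid sizes, and `n_snps_used`.
#' @export
folded_2dsfs <- function(gm, pop1 = NULL, pop2 = NULL, n1 = NULL, n2 = NULL,
                         tie = c("half", "lower")) {
  tie <- match.arg(tie)
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(gm$population)
  if (is.null(pop1)) pop1 <- pops[1]
  if (is.null(pop2)) pop2 <- pops[2]
  if (is.na(pop2)) stop("need two populations")
  g1 <- gm$geno[gm$population == pop1, , drop = FALSE]
  g2 <- gm$geno[gm$population == pop2, , drop = FALSE]
  if (nrow(g1) == 0 || nrow(g2) == 0) stop("empty population")
  default_proj <- function(g) {
    full <- 2L * nrow(g)
    if (!anyNA(g)) full else max(2L, 2L * floor(0.8 * full / 2))
  }
  if (is.null(n1)) n1 <- default_proj(g1)
  if (is.null(n2)) n2 <- default_proj(g2)
  if (n1 < 2 || n2 < 2) stop("projection sizes must be >= 2")
  if (n1 > 2 * nrow(g1) || n2 > 2 * nrow(g2))
    stop("projection size exceeds available haploid sample size")
  c1 <- 2L * colSums(!is.na(g1)); d1 <- colSums(g1, na.rm = TRUE)
  c2 <- 2L * colSums(!is.na(g2)); d2 <- colSums(g2, na.rm = TRUE)
  usable <- c1 >= n1 & c2 >= n2
  n_spp <- ncol(gm$geno)
  if (sum(!usable) > 0)
    pp_log("SFS: excluded ", sum(!usable), " of ", n_spp,
           " SNP(s) with too few calls for projection")
  acc <- matrix(0, n1 + 1L, n2 + 1L)
  for (s in which(usable)) {
    w1 <- stats::dhyper(0:n1, d1[s], c1[s] - d1[s], n1)
    w2 <- stats::dhyper(0:n2, d2[s], c2[s] - d2[s], n2)
    acc <- acc + outer(w1, w2)
  }
  counts <- fold_2d(acc, tie)
  new_folded_2dsfs(counts, n1, n2, sum(usable), pops = c(pop1, pop2))
}

#' Nonparametric locus block bootstrap of the folded 2D SFS
#'
#' RAD loci are resampled with replacement (each resampled locus carries all
#' of its SNPs), and each replicate spectrum is rebuilt with the same
#' projection as the original. Deterministic given `seed`.
#'
#' @param gm a [genotype_matrix()] with at least two loci.
#' @param n_replicates number of bootstrap replicates.
#' @param seed integer seed.
#' @inheritParams folded_2dsfs
#' @return list of `folded_2dsfs` objects (empty for `n_replicates = 0`).
#' @export
bootstrap_sfs <- function(gm, n_replicates, seed, pop1 = NULL, pop2 = NULL,
                          n1 = NULL, n2 = NULL, tie = c("half", "lower")) {
  tie <- match.arg(tie)
  stopifnot(inherits(gm, "genotype_matrix"))
  loci <- unique(gm$locus_id)
  if (length(loci) < 2) {
    if (n_replicates > 0)
      pp_log("single-locus input: every bootstrap replicate equals the original")
  }
  ref <- folded_2dsfs(gm, pop1, pop2, n1, n2, tie)
  set.seed(derive_seed(seed, 0L))
  snps_of_locus <- split(seq_along(gm$locus_id), gm$locus_id)
  lapply(seq_len(n_replicates), function(b) {
    pick <- sample(loci, length(loci), replace = TRUE)
    idx <- unlist(snps_of_locus[pick], use.names = FALSE)
    gb <- gm
    gb$geno <- gm$geno[, idx, drop = FALSE]
    gb$locus_id <- gm$locus_id[idx]
    folded_2dsfs(gb, ref$pops[1], ref$pops[2], ref$n1, ref$n2, tie)
  })
}

#' Write a folded 2D SFS as a whitespace matrix file
#'
#' Header line `n1 n2 folded`, then `n1 + 1` rows of `n2 + 1` cell values
#' (masked cells written as 0).
#'
#' @param x a `folded_2dsfs`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(x, path) {
  stopifnot(inherits(x, "folded_2dsfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(x$n1, x$n2, "folded"), con)
  utils::write.table(format(x$counts, digits = 12, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a folded 2D SFS written by [write_sfs()]
#'
#' @param path input path.
#' @return a `folded_2dsfs`.
#' @export
read_sfs <- function(path) {
  hdr <- strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]]
  n1 <- as.integer(hdr[1]); n2 <- as.integer(hdr[2])
  m <- as.matrix(utils::read.table(path, skip = 1))
  dimnames(m) <- NULL
  if (nrow(m) != n1 + 1 || ncol(m) != n2 + 1)
    stop("SFS dimensions do not match header")
  new_folded_2dsfs(m, n1, n2, sum(m))
}
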