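#' Regional genomic relationship matrix container
#'
#' @param M symmetric N x N relationship matrix.
#' @param ids individual ids (length N).
#' @param n_markers number of markers averaged over (S SNPs or H haplotype
#'   alleles).
#' @param kind one of `"snp"`, `"haplotype"`, `"whole_genome"`.
#' @param loadings optional N x m matrix Z with `M = Z %*% t(Z)`; kept when
#'   the GRM is built from standardized marker scores because the low-rank
#'   factor speeds up REML on large samples.
#' @return an object of class `RegionalGRM`.
#' @export
regional_grm <- function(M, ids, n_markers, kind, loadings = NULL) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == ncol(M), length(ids) == nrow(M))
  structure(list(M = M, ids = as.character(ids),
                 n_markers = n_markers, kind = kind, loadings = loadings),
            class = "RegionalGRM")
}

#' @export
print.RegionalGRM <- function(x, ...) {
  cat(sprintf("RegionalGRM (%s): %d individuals, %s markers\n",
              x$kind, nrow(x$M), x$n_markers))
  invisible(x)
}

#' Window-skipped sentinel
#'
#' Returned instead of a GRM when a window cannot be analyzed (no
#' polymorphic SNPs, or a single haplotype allele, for which the
#' denominators of the relationship estimators are undefined).
#'
#' @param reason character reason.
#' @return object of class `WindowSkip`.
#' @export
window_skip <- function(reason) structure(list(reason = reason),
                                          class = "WindowSkip")

#' @rdname window_skip
#' @param x object to test.
#' @export
is_window_skip <- function(x) inherits(x, "WindowSkip")

# standardized score matrix for dosage-like counts C (N x m) with counted
# frequencies p: (C - 2p) / sqrt(2 p (1-p) m); the GRM is tcrossprod of this
std_scores <- function(C, p, m) {
  sweep(sweep(C, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p) * m), "/")
}

#' Enumerate haplotype alleles in a window
#'
#' The haplotype alleles of a window are the distinct allele strings among
#' the 2N phased chromosomes restricted to the window's SNPs. Frequencies
#' are counts over the 2N chromosomes; the diplotype matrix Q counts, for
#' each individual, how many copies (0/1/2) of each haplotype allele they
#' carry. Alleles are ordered by decreasing frequency (ties by string) so
#' the enumeration is deterministic.
#'
#' @param panel a complete phased `HaplotypePanel`.
#' @param window one-row window (from a `BlockMap`), with `chrom`, `start`,
#'   `end`.
#' @return a `HaplotypeAlleles` object: list with `strings`, `freqs`,
#'   `counts`, `Q` (N x H), `ids`, `window`.
#' @export
enumerate_haplotypes <- function(panel, window) {
  stopifnot_complete(panel, "enumerate_haplotypes")
  rows <- window_snp_rows(panel, window)
  h1 <- panel$hap1[, rows, drop = FALSE]
  h2 <- panel$hap2[, rows, drop = FALSE]
  s1 <- apply(h1, 1L, paste, collapse = "")
  s2 <- apply(h2, 1L, paste, collapse = "")
  tab <- table(c(s1, s2))
  ord <- order(-as.integer(tab), names(tab))
  strings <- names(tab)[ord]
  counts <- as.integer(tab)[ord]
  H <- length(strings)
  n <- n_individuals(panel)
  Q <- matrix(0L, n, H, dimnames = list(panel$individual_ids, strings))
  i1 <- match(s1, strings); i2 <- match(s2, strings)
  Q[cbind(seq_len(n), i1)] <- Q[cbind(seq_len(n), i1)] + 1L
  Q[cbind(seq_len(n), i2)] <- Q[cbind(seq_len(n), i2)] + 1L
  structure(list(strings = strings, freqs = counts / (2 * n),
                 counts = counts, Q = Q, ids = panel$individual_ids,
                 window = window),
            class = "HaplotypeAlleles")
}

#' SNP-based regional genomic relationship matrix
#'
#' For a window of S polymorphic SNPs with dosages O (0/1/2) and counted
#' (ALT) allele frequencies P estimated from the analyzed individuals,
#'
#'   IBS_ij = (1/S) sum_k (O_ik - 2 P_k)(O_jk - 2 P_k) / (2 P_k (1 - P_k)).
#'
#' Monomorphic SNPs are dropped first (their denominator is undefined) and
#' S reduced accordingly.
#'
#' @param panel a complete phased `HaplotypePanel`.
#' @param window one-row window; `NULL` means all SNPs.
#' @param snp_rows alternative to `window`: explicit SNP row indices.
#' @return a `RegionalGRM` of kind `"snp"`, or a [window_skip()] when no
#'   polymorphic SNP remains.
#' @export
snp_regional_grm <- function(panel, window = NULL, snp_rows = NULL) {
  stopifnot_complete(panel, "snp_regional_grm")
  if (is.null(snp_rows))
    snp_rows <- if (is.null(window)) seq_len(n_snps(panel))
                else window_snp_rows(panel, window)
  O <- dosage_matrix(panel, snp_rows)
  p <- colMeans(O) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) return(window_skip("no polymorphic SNP in window"))
  O <- O[, poly, drop = FALSE]; p <- p[poly]
  Z <- std_scores(O, p, ncol(O))
  regional_grm(tcrossprod(Z), panel$individual_ids, ncol(O), "snp",
               loadings = Z)
}

#' Haplotype-based regional genomic relationship matrix
#'
#' For a window with H >= 2 haplotype alleles, diplotype counts Q and
#' haplotype frequencies P estimated from the 2N analyzed chromosomes,
#'
#'   HIBS_ij = (1/H) sum_k (Q_ik - 2 P_k)(Q_jk - 2 P_k) / (2 P_k (1 - P_k)),
#'
#' summing over all H haplotype alleles. Sharing a rare allele contributes
#' more to the estimated relationship than sharing a common one, which is
#' what gives the haplotype estimator its sensitivity to rare variants.
#'
#' @param alleles a `HaplotypeAlleles` from [enumerate_haplotypes()].
#' @return a `RegionalGRM` of kind `"haplotype"`, or a [window_skip()] when
#'   H = 1 (relationship undefined: zero denominator).
#' @export
haplotype_regional_grm <- function(alleles) {
  H <- length(alleles$freqs)
  if (H < 2) return(window_skip("single haplotype allele in window (H = 1)"))
  p <- alleles$freqs
  Z <- std_scores(alleles$Q, p, H)
  regional_grm(tcrossprod(Z), alleles$ids, H, "haplotype", loadings = Z)
}

#' Whole-genome relationship matrix
#'
#' The SNP estimator of [snp_regional_grm()] averaged over all retained
#' genome-wide SNPs. By default the tested region's SNPs are included (an
#' exclusion list is available).
#'
#' @param panel a complete phased `HaplotypePanel`.
#' @param exclude_snps optional integer vector of SNP rows to exclude
#'   (e.g. the tested window).
#' @return a `RegionalGRM` of kind `"whole_genome"`.
#' @export
whole_genome_grm <- function(panel, exclude_snps = NULL) {
  rows <- seq_len(n_snps(panel))
  if (!is.null(exclude_snps)) rows <- setdiff(rows, exclude_snps)
  if (length(rows) == 0) stop("empty SNP set for whole-genome GRM")
  g <- snp_regional_grm(panel, snp_rows = rows)
  if (is_window_skip(g)) stop("no polymorphic SNPs for whole-genome GRM")
  g$kind <- "whole_genome"
  g
}
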