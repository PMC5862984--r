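#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test for a biallelic SNP: the p-value is the total
#' probability, conditional on the observed allele counts, of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count. Computed with the standard recurrence over heterozygote
#' configurations, which is numerically robust at rare-variant frequencies
#' where the chi-square approximation breaks down.
#'
#' @param n_aa,n_ab,n_bb genotype counts (non-negative integers).
#' @return the exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_b <- 2 * n_bb + n_ab           # minor-or-not does not matter: symmetric
  n_rare <- min(n_b, 2 * n - n_b)
  het_obs <- n_ab
  # possible heterozygote counts share parity with n_rare
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  probs <- numeric(length(hets))
  # recurse from a mid-range het count in both directions:
  #   P(h+2)/P(h) = (nr - h)(nc - h) / ((h+1)(h+2))
  #   P(h-2)/P(h) = h(h-1) / ((nr - h + 2)(nc - h + 2))
  nc <- 2 * n - n_rare
  mid <- hets[which.max(hets * (n_rare - hets))]
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  if (i_mid > 1) for (i in seq(i_mid, 2)) {
    h <- hets[i]
    probs[i - 1] <- probs[i] * h * (h - 1) /
      ((n_rare - h + 2) * (nc - h + 2))
  }
  if (i_mid < length(hets)) for (i in seq(i_mid, length(hets) - 1)) {
    h <- hets[i]
    probs[i + 1] <- probs[i] * (n_rare - h) * (nc - h) /
      ((h + 1) * (h + 2))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(het_obs, hets)]
  if (is.na(p_obs)) stop("heterozygote count incompatible with allele count")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Quality-control filter for a haplotype panel
#'
#' Removes SNPs with minor allele frequency below `maf_min`, exact-test
#' Hardy-Weinberg p-value below `hwe_p_min`, or per-SNP call rate below
#' `snp_callrate_min`; and individuals with call rate below
#' `ind_callrate_min`. Because removing individuals changes per-SNP
#' frequencies (and vice versa), the filter is iterated to a fixed point,
#' which makes it idempotent.
#'
#' @param panel a `HaplotypePanel`, possibly with missing genotypes.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-8).
#' @param snp_callrate_min minimum per-SNP call rate (default 0.95).
#' @param ind_callrate_min minimum per-individual call rate (default 0.95).
#' @return the filtered `HaplotypePanel`.
#' @export
qc_filter <- function(panel, maf_min = 0.01, hwe_p_min = 1e-8,
                      snp_callrate_min = 0.95, ind_callrate_min = 0.95) {
  repeat {
    n0 <- n_individuals(panel); s0 <- n_snps(panel)
    O <- dosage_matrix(panel)
    call_snp <- colMeans(!is.na(O))
    keep_snp <- call_snp >= snp_callrate_min
    p <- colMeans(O, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    keep_snp <- keep_snp & !is.na(maf) & maf >= maf_min
    for (k in which(keep_snp)) {
      g <- O[, k]
      cnt <- c(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
               sum(g == 2L, na.rm = TRUE))
      if (hwe_exact_p(cnt[1], cnt[2], cnt[3]) < hwe_p_min)
        keep_snp[k] <- FALSE
    }
    if (!any(keep_snp)) stop("empty panel after QC")
    call_ind <- rowMeans(!is.na(O[, keep_snp, drop = FALSE]))
    keep_ind <- call_ind >= ind_callrate_min
    if (!any(keep_ind)) stop("empty panel after QC")
    panel <- subset_panel(panel, individuals = which(keep_ind),
                          snps = which(keep_snp))
    if (n_individuals(panel) == n0 && n_snps(panel) == s0) break
  }
  panel
}
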