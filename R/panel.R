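#' Construct a phased haplotype panel
#'
#' A `HaplotypePanel` holds phased biallelic genotypes for N individuals at S
#' SNPs as two N x S allele matrices (`hap1`, `hap2`), one per transmitted
#' chromosome, with allele codes 0 (reference) and 1 (counted/alternate).
#' Missing genotypes are allowed only in a pre-QC panel and are encoded as
#' `NA` in both allele matrices simultaneously.
#'
#' @param individual_ids character vector of N unique individual identifiers.
#' @param snp_table data.frame with one row per SNP and columns `id`,
#'   `chrom`, `pos_bp` (1-based physical position) and optionally `cM`
#'   (genetic position). Rows must be ordered by chromosome with strictly
#'   increasing positions within each chromosome.
#' @param hap1,hap2 integer N x S matrices of allele codes in \{0, 1, NA\}.
#'
#' @return an object of class `HaplotypePanel`.
#' @export
haplotype_panel <- function(individual_ids, snp_table, hap1, hap2) {
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids")
  snp_table <- as.data.frame(snp_table)
  req <- c("id", "chrom", "pos_bp")
  if (!all(req %in% names(snp_table)))
    stop("snp_table must have columns id, chrom, pos_bp")
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  n <- length(individual_ids); s <- nrow(snp_table)
  if (!all(dim(hap1) == c(n, s)) || !all(dim(hap2) == c(n, s)))
    stop("haplotype matrices must be N x S")
  ok1 <- hap1 %in% c(0L, 1L, NA); ok2 <- hap2 %in% c(0L, 1L, NA)
  if (!all(ok1) || !all(ok2))
    stop("allele codes must be 0, 1 or NA")
  if (!identical(is.na(hap1), is.na(hap2)))
    stop("missingness must affect both alleles of a genotype")
  for (ch in unique(snp_table$chrom)) {
    p <- snp_table$pos_bp[snp_table$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(individual_ids = individual_ids, snp_table = snp_table,
                 hap1 = hap1, hap2 = hap2),
            class = "HaplotypePanel")
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat(sprintf("HaplotypePanel: %d individuals, %d SNPs on %d chromosome(s)\n",
              n_individuals(x), n_snps(x),
              length(unique(x$snp_table$chrom))))
  if (anyNA(x$hap1))
    cat(sprintf("  contains missing genotypes (%.2f%%) - pre-QC panel\n",
                100 * mean(is.na(x$hap1))))
  invisible(x)
}

#' @rdname haplotype_panel
#' @param panel a `HaplotypePanel`.
#' @export
n_individuals <- function(panel) length(panel$individual_ids)

#' @rdname haplotype_panel
#' @export
n_snps <- function(panel) nrow(panel$snp_table)

#' Genotype dosage matrix
#'
#' Per-SNP count of the counted (ALT) allele: the sum of the two phased
#' alleles, giving the usual 0/1/2 genotype coding.
#'
#' @param panel a `HaplotypePanel`.
#' @param snp_rows optional integer vector of SNP (column) indices.
#' @return integer N x S matrix of dosages (NA where the genotype is missing).
#' @export
dosage_matrix <- function(panel, snp_rows = NULL) {
  if (is.null(snp_rows)) panel$hap1 + panel$hap2
  else panel$hap1[, snp_rows, drop = FALSE] + panel$hap2[, snp_rows, drop = FALSE]
}

#' Subset a panel by individuals and/or SNPs
#'
#' @param panel a `HaplotypePanel`.
#' @param individuals integer or logical index over individuals.
#' @param snps integer or logical index over SNPs (must preserve order).
#' @return a `HaplotypePanel`.
#' @export
subset_panel <- function(panel, individuals = NULL, snps = NULL) {
  if (is.null(individuals)) individuals <- seq_len(n_individuals(panel))
  if (is.null(snps)) snps <- seq_len(n_snps(panel))
  haplotype_panel(panel$individual_ids[individuals],
                  panel$snp_table[snps, , drop = FALSE],
                  panel$hap1[individuals, snps, drop = FALSE],
                  panel$hap2[individuals, snps, drop = FALSE])
}

stopifnot_complete <- function(panel, what = "this operation") {
  if (anyNA(panel$hap1))
    stop(what, " requires a complete (post-QC) panel without missing genotypes")
  invisible(TRUE)
}

# Global SNP row indices for a window (per-chromosome 0-based half-open
# indices -> rows of snp_table).
window_snp_rows <- function(panel, window) {
  chrom_rows <- which(panel$snp_table$chrom == window$chrom)
  s <- length(chrom_rows)
  if (window$start < 0 || window$end > s || window$end <= window$start)
    stop("window [", window$start, ",", window$end,
         ") out of range for chromosome ", window$chrom, " with ", s, " SNPs")
  chrom_rows[(window$start + 1L):window$end]
}

# Run `expr` under a locally-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Named independent sub-seeds derived from one master seed, so that e.g.
# effect draws can be replayed while mating randomness changes.
derive_seeds <- function(seed, names) {
  s <- with_seed(seed, sample.int(.Machine$integer.max, length(names)))
  stats::setNames(as.list(s), names)
}
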