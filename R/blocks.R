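#' Partition SNPs into haplotype-block analysis windows
#'
#' Haplotype blocks are runs of consecutive SNPs delimited by recombination
#' hotspots: a window boundary is placed in every inter-SNP interval whose
#' recombination rate reaches the threshold. The rate assigned to the
#' interval between two adjacent SNPs is the maximum map rate over the bp
#' span between them, so a hotspot lying strictly between two SNPs splits
#' them even though neither SNP sits on it. The comparison is inclusive
#' (rate >= threshold), matching the "at least 5 cM/Mb" rule; chromosome
#' ends are implicit boundaries. A map breakpoint located exactly on a SNP
#' position is assigned to the interval preceding that SNP.
#'
#' Window indices are 0-based half-open over the per-chromosome SNP order.
#'
#' @param panel a `HaplotypePanel`.
#' @param map a `GeneticMap` covering every SNP position.
#' @param threshold hotspot rate threshold in cM/Mb (> 0); default 5.
#' @return a `BlockMap`: data.frame with columns `chrom`, `start`, `end`,
#'   `n_snps`, `start_bp`, `end_bp` and attribute `threshold`.
#' @export
define_blocks <- function(panel, map, threshold = 5) {
  stopifnot(threshold > 0)
  map <- as.data.frame(map)
  out <- list()
  for (ch in unique(panel$snp_table$chrom)) {
    st <- panel$snp_table[panel$snp_table$chrom == ch, ]
    if (nrow(st) == 0) { message("chromosome ", ch, " has no SNPs, skipped"); next }
    m <- map[map$chrom == ch, ]
    if (nrow(m) == 0) stop("no map entries for chromosome ", ch)
    bp <- m$pos_bp; rate <- m$rate_cM_Mb
    pos <- st$pos_bp
    if (pos[1] < bp[1] || pos[length(pos)] > bp[length(bp)])
      stop("SNP ", st$id[if (pos[1] < bp[1]) 1 else length(pos)],
           " outside genetic-map span on chromosome ", ch)
    s <- nrow(st)
    boundary <- logical(max(s - 1, 0))
    if (s > 1) {
      lo <- findInterval(pos[-s], bp)
      hi <- findInterval(pos[-1], bp)
      for (i in seq_len(s - 1))
        boundary[i] <- max(rate[lo[i]:hi[i]]) >= threshold
    }
    starts <- c(0L, which(boundary))
    ends <- c(which(boundary), s)
    out[[length(out) + 1]] <- data.frame(
      chrom = ch, start = starts, end = as.integer(ends),
      n_snps = as.integer(ends) - starts,
      start_bp = pos[starts + 1L], end_bp = pos[ends])
  }
  if (length(out) == 0) stop("no chromosomes with SNPs")
  bm <- do.call(rbind, out)
  rownames(bm) <- NULL
  structure(bm, threshold = threshold, class = c("BlockMap", "data.frame"))
}

#' Locate the analysis window covering a SNP
#'
#' @param blocks a `BlockMap`.
#' @param chrom chromosome identifier.
#' @param snp_index 0-based SNP index in the per-chromosome order.
#' @return the single covering window as a one-row data.frame.
#' @export
window_for_region <- function(blocks, chrom, snp_index) {
  b <- blocks[blocks$chrom == chrom, , drop = FALSE]
  if (nrow(b) == 0) stop("no windows on chromosome ", chrom)
  hit <- b$start <= snp_index & snp_index < b$end
  if (!any(hit))
    stop("SNP index ", snp_index, " out of range [0, ", max(b$end),
         ") on chromosome ", chrom)
  b[which(hit), , drop = FALSE]
}

#' Export a BlockMap as a BED-like TSV
#'
#' Columns: chrom, start_bp (first SNP), end_bp (last SNP), start_index,
#' end_index (0-based half-open), n_snps.
#'
#' @param blocks a `BlockMap`.
#' @param path output path.
#' @export
write_blocks <- function(blocks, path) {
  df <- data.frame(chrom = blocks$chrom, start_bp = blocks$start_bp,
                   end_bp = blocks$end_bp, start_index = blocks$start,
                   end_index = blocks$end, n_snps = blocks$n_snps)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
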