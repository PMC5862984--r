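#' Read a phased VCF into a HaplotypePanel
#'
#' Parses a VCF 4.x file (via `VariantAnnotation::readVcf`) and extracts the
#' phased GT field of every biallelic SNP record. Alleles are oriented to the
#' VCF convention REF = 0, ALT = 1 (the ALT allele is the counted allele
#' throughout the package). Record order and 1-based positions are preserved.
#'
#' Multiallelic or non-SNP records are skipped with a message reporting the
#' count. Unphased ("/") or missing GT values are an error: QC and phasing
#' are upstream responsibilities.
#'
#' @param path path to an (optionally bgzipped) VCF file.
#' @return a [haplotype_panel()].
#' @export
read_vcf_phased <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  snv <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    alt1 %in% c("A", "C", "G", "T") & ref %in% c("A", "C", "G", "T")
  n_skip <- sum(!snv)
  if (n_skip > 0)
    message(n_skip, " multiallelic or non-SNP record(s) skipped")
  if (!any(snv)) stop("no biallelic SNP records in ", path)
  gt <- gt[snv, , drop = FALSE]
  ids <- rownames(gt)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))[snv]
  pos <- BiocGenerics::start(rr)[snv]

  bad <- matrix(!grepl("^[01]\\|[01]$", gt), nrow = nrow(gt))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("GT not phased or missing at record ", ids[w[1]],
         " (sample ", colnames(gt)[w[2]], "): '", gt[w[1], w[2]], "'")
  }
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  snp_table <- data.frame(id = ids, chrom = chrom, pos_bp = pos,
                          ref = ref[snv], alt = alt1[snv],
                          stringsAsFactors = FALSE)
  haplotype_panel(colnames(gt), snp_table, t(a1), t(a2))
}

#' Write a HaplotypePanel as a phased VCF
#'
#' Emits a minimal VCF 4.2 file with phased GT columns. Together with
#' [read_vcf_phased()] this round-trips GT columns byte-identically.
#'
#' @param panel a complete (no missing data) `HaplotypePanel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot_complete(panel, "write_vcf")
  st <- panel$snp_table
  ref <- if ("ref" %in% names(st)) st$ref else rep("A", nrow(st))
  alt <- if ("alt" %in% names(st)) st$alt else rep("G", nrow(st))
  gt <- matrix(paste0(t(panel$hap1), "|", t(panel$hap2)),
               nrow = nrow(st))
  header <- c("##fileformat=VCFv4.2",
              "##source=haplohm",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$individual_ids),
                    collapse = "\t"))
  body <- paste(st$chrom, st$pos_bp, st$id, ref, alt, ".", ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
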