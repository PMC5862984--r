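#' Read a HapMap-style genetic map
#'
#' Expects a tab- or whitespace-separated file with four columns:
#' chromosome, physical position (bp), recombination rate (cM/Mb) and
#' cumulative genetic position (cM). The rate on a row applies to the
#' interval from that row's position to the next row's position.
#'
#' @param path file path. A header line is detected and skipped.
#' @return a `GeneticMap`: data.frame with columns `chrom`, `pos_bp`,
#'   `rate_cM_Mb`, `cM`.
#' @export
read_genetic_map <- function(path) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) < 4) stop("genetic map must have 4 columns")
  dt <- dt[, 1:4]
  names(dt) <- c("chrom", "pos_bp", "rate_cM_Mb", "cM")
  genetic_map(dt)
}

#' @rdname read_genetic_map
#' @param map data.frame with columns `chrom`, `pos_bp`, `rate_cM_Mb`, `cM`.
#' @export
genetic_map <- function(map) {
  map <- as.data.frame(map)
  stopifnot(all(c("chrom", "pos_bp", "rate_cM_Mb", "cM") %in% names(map)))
  if (any(map$rate_cM_Mb < 0)) stop("negative recombination rate in map")
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (any(diff(sub$pos_bp) <= 0))
      stop("map positions not strictly increasing on chromosome ", ch)
    if (any(diff(sub$cM) < 0))
      stop("cumulative cM decreasing on chromosome ", ch)
  }
  structure(map, class = c("GeneticMap", "data.frame"))
}

#' @rdname read_genetic_map
#' @param path output path.
#' @export
write_genetic_map <- function(map, path) {
  data.table::fwrite(as.data.frame(map)[, c("chrom", "pos_bp", "rate_cM_Mb", "cM")],
                     path, sep = "\t")
  invisible(path)
}

#' Read / write a two-column phenotype file
#'
#' Header-less, tab-separated: individual id, phenotype value.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `value`.
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dt) != 2) stop("phenotype file must have exactly 2 columns")
  names(dt) <- c("id", "value")
  dt$id <- as.character(dt$id)
  if (anyDuplicated(dt$id))
    stop("duplicate phenotype id: ", dt$id[anyDuplicated(dt$id)])
  if (!is.numeric(dt$value) || any(!is.finite(dt$value)))
    stop("phenotype values must be finite numbers")
  dt
}

#' @rdname read_phenotypes
#' @param phenotypes data.frame with columns `id`, `value`, or a named
#'   numeric vector.
#' @export
write_phenotypes <- function(phenotypes, path) {
  if (is.numeric(phenotypes) && !is.null(names(phenotypes)))
    phenotypes <- data.frame(id = names(phenotypes), value = unname(phenotypes))
  data.table::fwrite(phenotypes[, c("id", "value")], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Write scan results as TSV
#'
#' One row per analysis window with a fixed header.
#'
#' @param table a `ScanResult` data.frame from [genome_scan()].
#' @param path output path.
#' @export
write_scan_results <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t", na = "NA")
  invisible(path)
}

#' GCTA-style GRM text files
#'
#' Writes/reads the lower triangle of a relationship matrix in the GCTA
#' `.grm.gz` convention: gzipped text with columns i, j, n_markers, value
#' (1-based indices, j <= i), plus a `.grm.id` file with one individual id
#' per line (family id column duplicated from the id).
#'
#' @param grm a [regional_grm()] object (or plain symmetric matrix with ids
#'   as dimnames).
#' @param prefix path prefix; files `<prefix>.grm.gz` and `<prefix>.grm.id`
#'   are produced.
#' @return `prefix` invisibly (`write_grm`); a `RegionalGRM` (`read_grm`).
#' @export
write_grm <- function(grm, prefix) {
  if (is.matrix(grm))
    grm <- regional_grm(grm, rownames(grm), n_markers = NA_integer_,
                        kind = "snp")
  M <- grm$M
  if (max(abs(M - t(M))) > 1e-8) stop("GRM must be symmetric")
  n <- nrow(M)
  idx <- which(lower.tri(M, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  con <- gzfile(paste0(prefix, ".grm.gz"), "wt")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("%d\t%d\t%d\t%.10g", idx[, 1], idx[, 2],
                     rep(as.integer(grm$n_markers), nrow(idx)),
                     M[idx]), con)
  writeLines(paste(grm$ids, grm$ids, sep = "\t"),
             paste0(prefix, ".grm.id"))
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  idf <- paste0(prefix, ".grm.id")
  gzf <- paste0(prefix, ".grm.gz")
  if (!file.exists(gzf)) gzf <- paste0(prefix, ".grm")
  ids <- utils::read.table(idf, header = FALSE,
                           colClasses = "character")[[2]]
  dat <- utils::read.table(gzfile(gzf), header = FALSE,
                           col.names = c("i", "j", "n", "value"))
  n <- length(ids)
  if (max(dat$i, dat$j) != n || nrow(dat) != n * (n + 1) / 2)
    stop("GRM id file and matrix size mismatch (", n, " ids, ",
         nrow(dat), " triangle entries)")
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  M[cbind(dat$i, dat$j)] <- dat$value
  M[cbind(dat$j, dat$i)] <- dat$value
  regional_grm(M, ids, n_markers = dat$n[1], kind = "snp")
}
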