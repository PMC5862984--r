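#' Configuration for the synthetic base panel generator
#'
#' The generator emulates a phased SNP panel with block-structured
#' haplotypes: each chromosome is a sequence of haplotype blocks separated
#' by recombination hotspots. Within a block, haplotype-allele frequencies
#' are drawn from a symmetric Dirichlet whose small concentration produces
#' the rare-allele-heavy spectrum typical of real haplotype data (most
#' alleles rare, many below frequency 0.02); each allele is a distinct
#' random binary SNP string, and the 2N chromosomes are sampled
#' independently across blocks.
#'
#' @param n_individuals number of individuals N.
#' @param n_chromosomes number of chromosomes.
#' @param n_blocks_per_chrom haplotype blocks per chromosome.
#' @param n_snps_range inclusive range of SNPs per block.
#' @param n_haplotypes_range inclusive range of haplotype alleles per block
#'   (capped at 2^n_snps).
#' @param dirichlet_concentration symmetric Dirichlet concentration for the
#'   haplotype-frequency spectrum (default 0.3; smaller = more rare alleles).
#' @param baseline_rate_cM_Mb recombination rate inside blocks (cM/Mb).
#' @param hotspot_rate_cM_Mb rate in inter-block hotspot intervals (cM/Mb);
#'   must reach the block-definition threshold.
#' @param snp_spacing_bp physical distance between adjacent SNPs in a block.
#' @param hotspot_width_bp physical width of each hotspot interval.
#' @param seed RNG seed.
#' @return a `PanelConfig` list.
#' @export
panel_config <- function(n_individuals = 1000,
                         n_chromosomes = 5,
                         n_blocks_per_chrom = 60,
                         n_snps_range = c(1, 12),
                         n_haplotypes_range = c(2, 12),
                         dirichlet_concentration = 0.3,
                         baseline_rate_cM_Mb = 1,
                         hotspot_rate_cM_Mb = 50,
                         snp_spacing_bp = 5000,
                         hotspot_width_bp = 20000,
                         seed = NULL) {
  stopifnot(n_individuals >= 1, n_chromosomes >= 1, n_blocks_per_chrom >= 1,
            all(n_snps_range >= 1), all(n_haplotypes_range >= 1),
            dirichlet_concentration > 0, hotspot_rate_cM_Mb > 0)
  structure(as.list(environment()), class = "PanelConfig")
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# sample() without the length-1 surprise
resample <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]

sample_range <- function(r) if (r[1] == r[2]) r[1] else resample(r[1]:r[2])

# distinct random binary strings of length s (as 0/1 matrix h x s)
random_binary_strings <- function(h, s) {
  if (h > 2^s) stop("haplotype count ", h, " exceeds 2^", s, " distinct strings")
  seen <- character(0)
  out <- matrix(0L, h, s)
  i <- 1L
  while (i <= h) {
    cand <- sample(0:1, s, replace = TRUE)
    key <- paste(cand, collapse = "")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[i, ] <- cand
      i <- i + 1L
    }
  }
  out
}

#' Generate a synthetic phased base panel
#'
#' Draws a block-structured phased panel per [panel_config()] and emits the
#' matching genetic map (hotspot-level rates between blocks, baseline rates
#' inside), so that [define_blocks()] at the hotspot threshold recovers the
#' generating blocks exactly.
#'
#' @param config a [panel_config()].
#' @return list with `panel` (`HaplotypePanel`), `map` (`GeneticMap`) and
#'   `blocks` (the generating `BlockMap`).
#' @export
synth_base_panel <- function(config) {
  stopifnot(inherits(config, "PanelConfig"))
  with_seed(config$seed, {
    n <- config$n_individuals
    snp_rows <- list(); map_rows <- list(); block_rows <- list()
    h1 <- list(); h2 <- list()
    for (ch in seq_len(config$n_chromosomes)) {
      chrom <- as.character(ch)
      pos <- 1L
      cum_cM <- 0
      snp_idx0 <- 0L
      for (b in seq_len(config$n_blocks_per_chrom)) {
        s <- sample_range(config$n_snps_range)
        hmax <- min(config$n_haplotypes_range[2], 2^s)
        if (config$n_haplotypes_range[1] > hmax)
          stop("haplotype count ", config$n_haplotypes_range[1],
               " exceeds 2^", s, " distinct strings for a ", s, "-SNP block")
        h <- sample_range(c(config$n_haplotypes_range[1], hmax))
        freqs <- rdirichlet1(h, config$dirichlet_concentration)
        strings <- random_binary_strings(h, s)
        draw <- sample.int(h, 2 * n, replace = TRUE, prob = freqs)
        a1 <- strings[draw[seq_len(n)], , drop = FALSE]
        a2 <- strings[draw[n + seq_len(n)], , drop = FALSE]
        bp <- pos + (seq_len(s) - 1L) * config$snp_spacing_bp
        snp_rows[[length(snp_rows) + 1]] <- data.frame(
          id = sprintf("c%db%ds%d", ch, b, seq_len(s)),
          chrom = chrom, pos_bp = bp)
        h1[[length(h1) + 1]] <- a1
        h2[[length(h2) + 1]] <- a2
        # map: baseline rate from block start; hotspot interval after block
        map_rows[[length(map_rows) + 1]] <- data.frame(
          chrom = chrom, pos_bp = bp[1],
          rate_cM_Mb = config$baseline_rate_cM_Mb, cM = cum_cM)
        cum_cM <- cum_cM +
          config$baseline_rate_cM_Mb * (bp[s] - bp[1]) / 1e6
        if (b < config$n_blocks_per_chrom) {
          hs_start <- bp[s] + config$snp_spacing_bp
          map_rows[[length(map_rows) + 1]] <- data.frame(
            chrom = chrom, pos_bp = hs_start,
            rate_cM_Mb = config$hotspot_rate_cM_Mb,
            cM = cum_cM + config$baseline_rate_cM_Mb *
              config$snp_spacing_bp / 1e6)
          cum_cM <- cum_cM + config$baseline_rate_cM_Mb *
            config$snp_spacing_bp / 1e6 +
            config$hotspot_rate_cM_Mb * config$hotspot_width_bp / 1e6
          pos <- hs_start + config$hotspot_width_bp
        } else if (bp[s] > bp[1]) {
          map_rows[[length(map_rows) + 1]] <- data.frame(
            chrom = chrom, pos_bp = bp[s], rate_cM_Mb = 0, cM = cum_cM)
        }
        block_rows[[length(block_rows) + 1]] <- data.frame(
          chrom = chrom, start = snp_idx0, end = snp_idx0 + s,
          n_snps = s, start_bp = bp[1], end_bp = bp[s])
        snp_idx0 <- snp_idx0 + s
      }
    }
    snp_table <- do.call(rbind, snp_rows)
    panel <- haplotype_panel(sprintf("ind%04d", seq_len(n)), snp_table,
                             do.call(cbind, h1), do.call(cbind, h2))
    map <- genetic_map(do.call(rbind, map_rows))
    blocks <- do.call(rbind, block_rows)
    rownames(blocks) <- NULL
    blocks <- structure(blocks, threshold = config$hotspot_rate_cM_Mb,
                        class = c("BlockMap", "data.frame"))
    list(panel = panel, map = map, blocks = blocks)
  })
}

# genetic position (cM) of every SNP, from the map's rate schedule
snp_cM <- function(panel, map) {
  map <- as.data.frame(map)
  out <- numeric(n_snps(panel))
  for (ch in unique(panel$snp_table$chrom)) {
    sel <- panel$snp_table$chrom == ch
    m <- map[map$chrom == ch, ]
    if (nrow(m) == 0) stop("no map entries for chromosome ", ch)
    pos <- panel$snp_table$pos_bp[sel]
    if (min(pos) < m$pos_bp[1] || max(pos) > m$pos_bp[nrow(m)])
      stop("SNP outside genetic-map span on chromosome ", ch)
    seg <- findInterval(pos, m$pos_bp)
    out[sel] <- m$cM[seg] + m$rate_cM_Mb[seg] * (pos - m$pos_bp[seg]) / 1e6
  }
  out
}

#' Forward-in-time random-mating simulation
#'
#' Simulates discrete generations of constant size N. Sexes are assigned
#' 1:1 at birth; each generation, N parent pairs are drawn uniformly with
#' replacement (one father, one mother per pair) and each pair produces one
#' offspring. Transmitted gametes are formed by sampling crossovers as a
#' Poisson process along genetic distance (no interference, no mutation):
#' the number of crossovers per chromosome is Poisson with mean the
#' chromosome's genetic length in Morgans, crossover positions are uniform
#' on the cM scale, and the starting parental chromosome is chosen at
#' random.
#'
#' @param panel a complete phased `HaplotypePanel` (the base generation).
#' @param map a `GeneticMap` covering all SNPs.
#' @param n_generations number of generations to simulate (0 returns the
#'   input panel unchanged).
#' @param seed RNG seed.
#' @return the generation-`n_generations` `HaplotypePanel`.
#' @export
forward_simulate <- function(panel, map, n_generations, seed = NULL) {
  if (n_generations < 0) stop("n_generations must be >= 0")
  stopifnot_complete(panel, "forward_simulate")
  if (n_generations == 0) return(panel)
  cm <- snp_cM(panel, map)
  chroms <- unique(panel$snp_table$chrom)
  chrom_cols <- lapply(chroms, function(ch) which(panel$snp_table$chrom == ch))
  n <- n_individuals(panel)
  with_seed(seed, {
    h1 <- panel$hap1; h2 <- panel$hap2
    sex <- sample(rep(c(1L, 2L), length.out = n))
    for (g in seq_len(n_generations)) {
      fathers <- resample(which(sex == 1L), n, replace = TRUE)
      mothers <- resample(which(sex == 2L), n, replace = TRUE)
      new1 <- matrix(0L, n, n_snps(panel))
      new2 <- matrix(0L, n, n_snps(panel))
      for (parent in 1:2) {
        par_idx <- if (parent == 1) fathers else mothers
        gam <- matrix(0L, n, n_snps(panel))
        for (ci in seq_along(chroms)) {
          cols <- chrom_cols[[ci]]
          cmc <- cm[cols]
          len_M <- (cmc[length(cmc)] - cmc[1]) / 100
          nx <- stats::rpois(n, len_M)
          start <- sample(0:1, n, replace = TRUE)
          pa <- h1[par_idx, cols, drop = FALSE]
          pb <- h2[par_idx, cols, drop = FALSE]
          # offspring allele source: start XOR (#crossovers below SNP) mod 2
          src <- matrix(start, n, length(cols))
          for (i in which(nx > 0)) {
            xpos <- sort(stats::runif(nx[i], cmc[1], cmc[length(cmc)]))
            src[i, ] <- (start[i] + findInterval(cmc, xpos)) %% 2L
          }
          gam[, cols] <- ifelse(src == 0L, pa, pb)
        }
        if (parent == 1) new1 <- gam else new2 <- gam
      }
      h1 <- new1; h2 <- new2
      sex <- sample(rep(c(1L, 2L), length.out = n))
    }
    haplotype_panel(panel$individual_ids, panel$snp_table, h1, h2)
  })
}

#' Simulation configuration for the phenotype generator
#'
#' @param architecture one of `"1SNP"`, `"AllSNP"`, `"1Hap"`, `"AllHap"`.
#' @param h2_region regional heritability (default 0.05).
#' @param h2_polygenic polygenic heritability (default 0.25).
#' @param causal_snp optional 0-based index (within the region) of the
#'   causal SNP for `1SNP`; default: random polymorphic SNP.
#' @param seed RNG seed.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(architecture = c("1SNP", "AllSNP", "1Hap", "AllHap"),
                       h2_region = 0.05, h2_polygenic = 0.25,
                       causal_snp = NULL, seed = NULL) {
  architecture <- match.arg(architecture)
  stopifnot(h2_region >= 0, h2_polygenic >= 0, h2_region <= 1,
            h2_polygenic <= 1, h2_region + h2_polygenic < 1)
  structure(list(architecture = architecture, h2_region = h2_region,
                 h2_polygenic = h2_polygenic, causal_snp = causal_snp,
                 seed = seed),
            class = "SimConfig")
}

# center v and remove its sample projection on the columns of basis
# (already centered); returns exactly orthogonal residual
orthogonalize <- function(v, basis = NULL) {
  v <- v - mean(v)
  if (!is.null(basis) && ncol(basis) > 0) {
    fit <- stats::lm.fit(cbind(1, basis), v)
    v <- fit$residuals
  }
  v
}

scale_to_var <- function(v, target) {
  s <- stats::var(v)
  if (s <= 0) stop("zero raw variance of simulated component")
  v * sqrt(target / s)
}

#' Simulate phenotypes under a regional genetic architecture
#'
#' Builds y = g_r + g_p + e with unit total variance: a regional genetic
#' value from one of four architectures, a polygenic value from small
#' effects at every SNP outside the region, and a normal residual.
#'
#' Architectures: `1SNP` puts an additive effect on one SNP's dosage;
#' `AllSNP` gives every regional SNP an effect proportional to
#' 1/sqrt(2 P (1-P)) with a random sign, so each SNP contributes equal
#' variance before scaling; `1Hap` selects one haplotype allele uniformly at
#' random among the window's distinct alleles (regardless of frequency) and
#' puts an effect on its diplotype count; `AllHap` draws one standard-normal
#' effect per haplotype allele and sums the two carried alleles' effects.
#'
#' Each component is centered, made empirically orthogonal to the preceding
#' components, and rescaled so the realized variances are exactly
#' `h2_region`, `h2_polygenic` and their complement; consequently
#' var(y) = 1 exactly.
#'
#' @param panel a complete phased `HaplotypePanel`.
#' @param region one-row window (from a `BlockMap`).
#' @param config a [sim_config()].
#' @return a `PhenotypeSet`: list with `y` (named), `g_r`, `g_p`, `e`,
#'   `causal` (record of the causal variant), `realized` (variance triple).
#' @export
simulate_phenotypes <- function(panel, region, config) {
  stopifnot(inherits(config, "SimConfig"))
  stopifnot_complete(panel, "simulate_phenotypes")
  rows <- window_snp_rows(panel, region)
  n <- n_individuals(panel)
  with_seed(config$seed, {
    O <- dosage_matrix(panel, rows)
    p <- colMeans(O) / 2
    poly <- p > 0 & p < 1
    causal <- list(architecture = config$architecture, region = region)
    g_raw <- switch(config$architecture,
      "1SNP" = {
        if (!any(poly)) stop("region monomorphic: no polymorphic SNP for 1SNP")
        k <- if (!is.null(config$causal_snp)) config$causal_snp + 1L
             else resample(which(poly))
        if (!poly[k]) stop("designated causal SNP is monomorphic")
        causal$snp_row <- rows[k]
        causal$snp_id <- panel$snp_table$id[rows[k]]
        causal$freq <- p[k]
        as.numeric(O[, k])
      },
      "AllSNP" = {
        if (!any(poly)) stop("region monomorphic: no polymorphic SNP")
        Op <- O[, poly, drop = FALSE]; pp <- p[poly]
        signs <- sample(c(-1, 1), length(pp), replace = TRUE)
        a <- signs / sqrt(2 * pp * (1 - pp))
        causal$effects <- data.frame(snp_row = rows[poly], effect = a,
                                     freq = pp)
        drop(Op %*% a)
      },
      "1Hap" = {
        al <- enumerate_haplotypes(panel, region)
        if (length(al$freqs) < 2)
          stop("region monomorphic under 1Hap: H = 1")
        k <- sample(length(al$freqs), 1)
        causal$haplotype <- al$strings[k]
        causal$freq <- al$freqs[k]
        as.numeric(al$Q[, k])
      },
      "AllHap" = {
        al <- enumerate_haplotypes(panel, region)
        if (length(al$freqs) < 2)
          stop("region monomorphic under AllHap: H = 1")
        b <- stats::rnorm(length(al$freqs))
        causal$effects <- data.frame(haplotype = al$strings, effect = b,
                                     freq = al$freqs)
        drop(al$Q %*% b)
      })
    if (stats::var(g_raw) <= 0)
      stop("zero raw variance of regional genetic value")
    g_r <- scale_to_var(orthogonalize(g_raw), config$h2_region)
    Og <- dosage_matrix(panel, setdiff(seq_len(n_snps(panel)), rows))
    pg <- colMeans(Og) / 2
    Og <- Og[, pg > 0 & pg < 1, drop = FALSE]
    if (ncol(Og) == 0) stop("no polymorphic SNPs outside the region")
    g_p_raw <- drop(Og %*% stats::rnorm(ncol(Og)))
    g_p <- scale_to_var(orthogonalize(g_p_raw, cbind(g_r)),
                        config$h2_polygenic)
    h2_e <- 1 - config$h2_region - config$h2_polygenic
    e <- scale_to_var(orthogonalize(stats::rnorm(n), cbind(g_r, g_p)), h2_e)
    y <- g_r + g_p + e
    names(y) <- panel$individual_ids
    structure(list(y = y, g_r = g_r, g_p = g_p, e = e, causal = causal,
                   realized = c(h2_region = stats::var(g_r),
                                h2_polygenic = stats::var(g_p),
                                h2_residual = stats::var(e))),
              class = "PhenotypeSet")
  })
}

#' Select analysis regions stratified by window size
#'
#' Uniform sample of windows without replacement, stratified over terciles
#' of the window-size (SNP-count) distribution so selected regions span the
#' observed size range.
#'
#' @param blocks a `BlockMap`.
#' @param n_regions number of windows to select.
#' @param seed RNG seed.
#' @return a `BlockMap` subset with `n_regions` rows.
#' @export
select_regions <- function(blocks, n_regions, seed = NULL) {
  nb <- nrow(blocks)
  if (n_regions > nb) stop("n_regions exceeds number of blocks")
  if (n_regions == nb) return(blocks)
  with_seed(seed, {
    terc <- cut(rank(blocks$n_snps, ties.method = "first"),
                breaks = 3, labels = FALSE)
    picks <- integer(0)
    # at least one window per non-empty tercile, remainder uniform
    base <- min(n_regions %/% 3, 1)
    if (n_regions >= 3)
      for (t in 1:3) picks <- c(picks, resample(which(terc == t), base))
    rest <- setdiff(seq_len(nb), picks)
    picks <- c(picks, resample(rest, n_regions - length(picks)))
    blocks[sort(picks), , drop = FALSE]
  })
}

#' Write a simulation truth file
#'
#' JSON record of the causal region, architecture, causal allele/effects and
#' realized variance components of a `PhenotypeSet`.
#'
#' @param pheno a `PhenotypeSet`.
#' @param path output path.
#' @export
write_truth <- function(pheno, path) {
  jsonlite::write_json(
    list(architecture = pheno$causal$architecture,
         region = as.list(pheno$causal$region),
         causal = pheno$causal[setdiff(names(pheno$causal),
                                       c("architecture", "region"))],
         realized = as.list(pheno$realized)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
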