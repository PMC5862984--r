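# Independent oracles and fixture builders. These deliberately avoid the
# package's own computational paths: brute-force double loops, log-factorial
# enumeration, determinant/solve-based likelihoods.

# --- fixtures ---------------------------------------------------------------

# panel from explicit per-individual chromosome strings, e.g.
# list(c("00","00"), c("00","01"), c("01","11"))
panel_from_strings <- function(chroms, chrom = "1", start_bp = 1000,
                               spacing = 100) {
  s <- nchar(chroms[[1]][1])
  n <- length(chroms)
  tobits <- function(x) as.integer(strsplit(x, "")[[1]])
  h1 <- matrix(unlist(lapply(chroms, function(z) tobits(z[1]))),
               nrow = n, ncol = s, byrow = TRUE)
  h2 <- matrix(unlist(lapply(chroms, function(z) tobits(z[2]))),
               nrow = n, ncol = s, byrow = TRUE)
  haplotype_panel(sprintf("i%02d", seq_len(n)),
                  data.frame(id = sprintf("s%d", seq_len(s)), chrom = chrom,
                             pos_bp = start_bp + (seq_len(s) - 1) * spacing),
                  h1, h2)
}

# random phased panel: independent SNPs with given allele frequencies
random_panel <- function(n, freqs, seed = 1, chrom = "1") {
  set.seed(seed)
  s <- length(freqs)
  h1 <- sapply(freqs, function(p) rbinom(n, 1, p))
  h2 <- sapply(freqs, function(p) rbinom(n, 1, p))
  haplotype_panel(sprintf("i%03d", seq_len(n)),
                  data.frame(id = sprintf("s%d", seq_len(s)), chrom = chrom,
                             pos_bp = 1000 + (seq_len(s) - 1) * 500),
                  h1, h2)
}

window_row <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end, n_snps = end - start)
}

# genetic map giving inter-SNP gap i exactly rate[i]: zero-rate rows at the
# SNP positions, rate rows at gap midpoints
gap_rate_map <- function(pos, rates, chrom = "1") {
  stopifnot(length(rates) == length(pos) - 1)
  rows <- data.frame(chrom = chrom, pos_bp = pos, rate_cM_Mb = 0)
  mids <- data.frame(chrom = chrom,
                     pos_bp = floor((pos[-1] + pos[-length(pos)]) / 2),
                     rate_cM_Mb = rates)
  m <- rbind(rows, mids)
  m <- m[order(m$pos_bp), ]
  # consistent cumulative cM from the rate schedule
  d <- diff(m$pos_bp) / 1e6
  m$cM <- c(0, cumsum(m$rate_cM_Mb[-nrow(m)] * d))
  genetic_map(m)
}

# --- GRM oracles (explicit double loops over pairs and markers) -------------

brute_grm <- function(C, p) {
  # C: n x m counts (dosages or diplotype counts), p: counted frequencies
  n <- nrow(C); m <- ncol(C)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (k in seq_len(m))
      acc <- acc + (C[i, k] - 2 * p[k]) * (C[j, k] - 2 * p[k]) /
        (2 * p[k] * (1 - p[k]))
    out[i, j] <- acc / m
  }
  out
}

# --- HWE exact-test oracle: direct multinomial enumeration ------------------

hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nb <- 2 * n_bb + n_ab
  nr <- min(nb, 2 * n - nb)
  hets <- seq(nr %% 2, nr, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (nr - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) + lfactorial(n) -
      (lfactorial(hom_r) + lfactorial(h) + lfactorial(hom_c))
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# --- restricted-likelihood oracle: direct determinant/solve evaluation ------

ll_direct <- function(theta, y, Ks, X = matrix(1, length(y), 1)) {
  n <- length(y); p <- ncol(X)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(Ks)) V <- V + theta[i] * Ks[[i]]
  Vi <- solve(V)
  B <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(B) %*% t(X) %*% Vi
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(B)$modulus) +
            drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi))
}

# multivariate normal draw with covariance Sigma (chol-based, test-only)
rmvn1 <- function(Sigma) {
  drop(t(chol(Sigma + 1e-10 * diag(nrow(Sigma)))) %*% rnorm(nrow(Sigma)))
}

# shared mid-size simulated dataset for scan/acceptance tests (built once)
.fixture_env <- new.env(parent = emptyenv())

fixture_panel <- function(name, config_fn) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- config_fn()
  .fixture_env[[name]]
}

# k-th window with at least min_snps SNPs and min_H realized haplotype
# alleles (drifted panels can fix whole blocks)
pick_region <- function(panel, blocks, min_snps = 2, min_H = 2, k = 1) {
  hit <- 0
  for (i in seq_len(nrow(blocks))) {
    w <- blocks[i, ]
    if (w$n_snps < min_snps) next
    if (length(enumerate_haplotypes(panel, w)$freqs) < min_H) next
    hit <- hit + 1
    if (hit == k) return(w)
  }
  stop("no qualifying window in fixture")
}

# 40-individual two-kernel fixture used by the varcomp and acceptance tests
varcomp_fixture <- function(n = 40, seed = 21) {
  set.seed(seed)
  pan <- random_panel(n, runif(12, 0.15, 0.85), seed = seed)
  Kr <- snp_regional_grm(pan, window_row("1", 0, 4))
  Kw <- snp_regional_grm(pan)
  y <- rmvn1(0.3 * Kr$M + 0.3 * Kw$M + 0.6 * diag(n))
  list(pan = pan, Kr = Kr, Kw = Kw, y = y)
}
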