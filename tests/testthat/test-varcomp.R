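test_that("an identity component matrix is rejected as non-identifiable", {
  n <- 30
  set.seed(1)
  y <- rnorm(n)
  expect_error(
    fit_reml(mixed_model_spec(y, K_w = diag(n)), components = "whole_genome"),
    "equals identity")
})

test_that("REML attains the grid-search oracle optimum on a 40-ind fixture", {
  fx <- varcomp_fixture()
  fit <- fit_reml(mixed_model_spec(fx$y, K_r = fx$Kr, K_w = fx$Kw))
  expect_true(fit$converged)
  Ks <- list(fx$Kr$M, fx$Kw$M)
  # independent check that the reported logLik is the restricted likelihood
  th <- pmax(fit$sigma2, 1e-8 * var(fx$y))
  expect_equal(fit$logLik, ll_direct(th, fx$y, Ks), tolerance = 1e-6)
  # coarse-to-fine dense grid search with the independent evaluator
  vp <- var(fx$y)
  grid1 <- as.matrix(expand.grid(r = seq(0.01, 1.2, length = 12) * vp,
                                 w = seq(0.01, 1.2, length = 12) * vp,
                                 e = seq(0.05, 1.2, length = 12) * vp))
  v1 <- apply(grid1, 1, ll_direct, y = fx$y, Ks = Ks)
  b <- grid1[which.max(v1), ]
  step <- 0.12 * vp
  grid2 <- as.matrix(expand.grid(
    r = seq(max(b[1] - step, 1e-4), b[1] + step, length = 11),
    w = seq(max(b[2] - step, 1e-4), b[2] + step, length = 11),
    e = seq(max(b[3] - step, 1e-4), b[3] + step, length = 11)))
  best <- max(v1, apply(grid2, 1, ll_direct, y = fx$y, Ks = Ks))
  expect_gte(fit$logLik, best - 1e-3)
})

test_that("estimates are equivariant to permutation and scaling", {
  fx <- varcomp_fixture(seed = 22)
  fit <- fit_reml(mixed_model_spec(fx$y, K_r = fx$Kr, K_w = fx$Kw))
  set.seed(5)
  pm <- sample(length(fx$y))
  Krp <- fx$Kr$M[pm, pm]; Kwp <- fx$Kw$M[pm, pm]
  fitp <- fit_reml(mixed_model_spec(fx$y[pm], K_r = Krp, K_w = Kwp))
  expect_equal(fitp$sigma2, fit$sigma2, tolerance = 1e-6)
  expect_equal(fitp$logLik, fit$logLik, tolerance = 1e-6)

  cc <- 3.7
  fits <- fit_reml(mixed_model_spec(cc * fx$y, K_r = fx$Kr, K_w = fx$Kw))
  expect_equal(fits$sigma2, fit$sigma2 * cc^2, tolerance = 1e-4)
  expect_equal(regional_heritability(fits), regional_heritability(fit),
               tolerance = 1e-6)
  null <- fit_reml(mixed_model_spec(fx$y, K_w = fx$Kw),
                   components = "whole_genome")
  nulls <- fit_reml(mixed_model_spec(cc * fx$y, K_w = fx$Kw),
                    components = "whole_genome")
  expect_equal(lrt(fits, nulls)$lrt, lrt(fit, null)$lrt, tolerance = 1e-4)
})

test_that("adding the regional component never lowers the restricted likelihood", {
  for (seed in 23:25) {
    fx <- varcomp_fixture(seed = seed)
    full <- fit_reml(mixed_model_spec(fx$y, K_r = fx$Kr, K_w = fx$Kw))
    null <- fit_reml(mixed_model_spec(fx$y, K_w = fx$Kw),
                     components = "whole_genome")
    expect_gte(full$logLik, null$logLik - 1e-6)
    expect_gte(lrt(full, null)$lrt, 0)
  }
})

test_that("lrt validates its inputs and floors at zero", {
  fx <- varcomp_fixture(seed = 26)
  full <- fit_reml(mixed_model_spec(fx$y, K_r = fx$Kr, K_w = fx$Kw))
  null <- fit_reml(mixed_model_spec(fx$y, K_w = fx$Kw),
                   components = "whole_genome")
  expect_error(lrt(null, full), "sub-model")
  other <- fit_reml(mixed_model_spec(rev(fx$y), K_w = fx$Kw),
                    components = "whole_genome")
  expect_error(lrt(full, other), NA)  # same checksum (reversal keeps sums)
  fx2 <- varcomp_fixture(seed = 27)
  other2 <- fit_reml(mixed_model_spec(fx2$y, K_w = fx2$Kw),
                     components = "whole_genome")
  expect_error(lrt(full, other2), "same data")
  fake_null <- null; fake_null$logLik <- full$logLik
  expect_equal(lrt(full, fake_null)$lrt, 0)
  fake_null$logLik <- full$logLik + 5
  expect_equal(lrt(full, fake_null)$lrt, 0)
  expect_true(lrt(full, null, threshold = -1)$significant)
})

test_that("regional heritability is the regional variance fraction", {
  mk <- function(s) haplohm:::new_varcomp_fit(
    c(regional = s[1], whole_genome = s[2], residual = s[3]),
    -1, 1, TRUE, rep(NA_real_, 3), 0, 10, c("regional", "whole_genome"),
    rep(0, 10))
  expect_equal(regional_heritability(mk(c(0.05, 0.25, 0.70))), 0.05)
  expect_equal(regional_heritability(mk(c(0, 0.25, 0.70))), 0)
  expect_equal(regional_heritability(mk(c(1, 1, 2))), 0.25)
  expect_error(regional_heritability(mk(c(0, 0, 0))), "zero total")
})

test_that("GRAMMAR residuals are centered BLUP residuals", {
  fx <- varcomp_fixture(n = 60, seed = 28)
  r <- grammar_residuals(mixed_model_spec(fx$y, K_w = fx$Kw))
  expect_lt(abs(mean(r)), 1e-10)
  # when the whole-genome variance is estimated at zero, residuals are OLS:
  # build y confined to the low-eigenvalue subspace of K_w
  eg <- eigen(fx$Kw$M, symmetric = TRUE)
  n <- length(fx$y)
  low <- eg$vectors[, (n - 20):(n - 1)]
  set.seed(6)
  y2 <- drop(low %*% rnorm(20))
  r2 <- grammar_residuals(mixed_model_spec(y2, K_w = fx$Kw))
  expect_equal(attr(r2, "null_fit")$sigma2[["whole_genome"]], 0)
  expect_lt(max(abs(r2 - (y2 - mean(y2)))), 1e-6)
})

test_that("regional-only scans on GRAMMAR residuals rank the causal window first", {
  set.seed(31)
  sp <- synth_base_panel(panel_config(n_individuals = 300, n_chromosomes = 1,
                                      n_blocks_per_chrom = 10,
                                      n_snps_range = c(3, 6), seed = 31))
  Kw <- grm_precompute_eigen(whole_genome_grm(sp$panel))
  grms <- lapply(seq_len(nrow(sp$blocks)), function(i)
    window_grm(sp$panel, sp$blocks[i, ], "hhm"))
  causal_w <- pick_region(sp$panel, sp$blocks, min_snps = 3, min_H = 4)
  causal <- which(sp$blocks$start == causal_w$start &
                    sp$blocks$chrom == causal_w$chrom)
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    ph <- simulate_phenotypes(sp$panel, causal_w,
                              sim_config("AllHap", h2_region = 0.10,
                                         seed = 500 + r))
    res <- grammar_residuals(mixed_model_spec(ph$y, K_w = Kw))
    lls <- vapply(grms, function(g) {
      if (is_window_skip(g)) return(-Inf)
      fit_reml(mixed_model_spec(res, K_r = g), components = "regional")$logLik
    }, numeric(1))
    if (which.max(lls) == causal) hits <- hits + 1
  }
  expect_gt(hits, n_rep / 2)
})

test_that("fast_scan_then_refit reduces to the full scan when all windows refit", {
  set.seed(33)
  sp <- synth_base_panel(panel_config(n_individuals = 150, n_chromosomes = 1,
                                      n_blocks_per_chrom = 6, seed = 33))
  Kw <- grm_precompute_eigen(whole_genome_grm(sp$panel))
  causal_w <- pick_region(sp$panel, sp$blocks, min_H = 3)
  causal <- which(sp$blocks$start == causal_w$start)
  ph <- simulate_phenotypes(sp$panel, causal_w,
                            sim_config("AllHap", seed = 34))
  grms <- lapply(seq_len(nrow(sp$blocks)), function(i)
    window_grm(sp$panel, sp$blocks[i, ], "hhm"))
  names(grms) <- paste0("w", seq_along(grms))
  fs <- fast_scan_then_refit(ph$y, NULL, Kw, grms, top_fraction = 1.0)
  expect_true(all(!fs$approximate, na.rm = TRUE))
  full <- genome_scan(sp$panel, sp$blocks, ph$y, method = "hhm",
                      mode = "full", K_w = Kw)
  expect_equal(fs$lrt, full$lrt, tolerance = 1e-6)
  expect_equal(fs$rh, full$rh, tolerance = 1e-6)
  # single window is always refitted
  f1 <- fast_scan_then_refit(ph$y, NULL, Kw, grms[causal],
                             top_fraction = 0.01)
  expect_false(f1$approximate[1])
  # causal window refit equals the full-model result at default fraction
  fs2 <- fast_scan_then_refit(ph$y, NULL, Kw, grms, top_fraction = 0.2)
  refit <- which(!fs2$approximate)
  expect_true(length(refit) >= 1)
  expect_equal(fs2$lrt[refit], full$lrt[refit], tolerance = 1e-6)
  expect_error(fast_scan_then_refit(ph$y, NULL, Kw, list()), "empty")
})

test_that("parameter recovery: mean estimates near truth on model draws", {
  set.seed(35)
  sp <- synth_base_panel(panel_config(n_individuals = 1000, n_chromosomes = 1,
                                      n_blocks_per_chrom = 30, seed = 35))
  Kw <- whole_genome_grm(sp$panel)
  w <- sp$blocks[which(sp$blocks$n_snps >= 4)[1], ]
  Kr <- window_grm(sp$panel, w, "hhm")
  truth <- c(0.05, 0.25, 0.70)
  Sig <- truth[1] * Kr$M + truth[2] * Kw$M + truth[3] * diag(1000)
  L <- t(chol(Sig))
  ests <- matrix(NA_real_, 20, 3)
  for (r in 1:20) {
    y <- drop(L %*% rnorm(1000))
    f <- fit_reml(mixed_model_spec(y, K_r = Kr, K_w = Kw))
    ests[r, ] <- f$sigma2
  }
  mc_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  for (j in 1:3)
    expect_lt(abs(mean(ests[, j]) - truth[j]), 2 * mc_se[j] + 0.005)
})
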