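#' Specify the two-variance-component mixed model
#'
#' The mapping model is y = X beta + g_r + g_w + e with
#' g_r ~ N(0, K_r sigma2_r), g_w ~ N(0, K_w sigma2_w), e ~ N(0, I sigma2_e):
#' one random effect for the tested region (regional GRM) and one for the
#' genome-wide polygenic background (whole-genome GRM).
#'
#' @param y numeric phenotype vector (length N, complete).
#' @param X fixed-effect design matrix; default a single intercept column.
#' @param K_r regional relationship matrix ([regional_grm()] or plain
#'   symmetric matrix).
#' @param K_w whole-genome relationship matrix.
#' @param ids optional individual ids; checked against GRM ids when both
#'   are available.
#' @return an object of class `MixedModelSpec`.
#' @export
mixed_model_spec <- function(y, X = NULL, K_r = NULL, K_w = NULL, ids = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) stop("phenotypes must be finite")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X must have one row per phenotype")
  if (n < ncol(X) + 3) stop("need at least ", ncol(X) + 3, " individuals")
  get_K <- function(K, what) {
    if (is.null(K)) return(NULL)
    if (inherits(K, "RegionalGRM")) {
      if (!is.null(ids) && !identical(as.character(ids), K$ids))
        stop(what, " ids do not match phenotype ids")
      if (nrow(K$M) != n) stop(what, " dimension does not match phenotypes")
      K
    } else {
      K <- as.matrix(K)
      if (nrow(K) != n || ncol(K) != n) stop(what, " must be N x N")
      regional_grm(K, if (is.null(ids)) seq_len(n) else ids,
                   NA_integer_, "snp")
    }
  }
  structure(list(y = y, X = X, K_r = get_K(K_r, "K_r"),
                 K_w = get_K(K_w, "K_w"), ids = ids),
            class = "MixedModelSpec")
}

new_varcomp_fit <- function(sigma2, logLik, iterations, converged, se, beta,
                            n, components, y) {
  structure(list(sigma2 = sigma2, logLik = logLik, iterations = iterations,
                 converged = converged, se = se, beta = beta, n = n,
                 components = components,
                 y_checksum = c(sum(y), sum(y^2))),
            class = "VarCompFit")
}

#' @export
print.VarCompFit <- function(x, ...) {
  cat("VarCompFit:", if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iteration(s)\n")
  est <- rbind(estimate = x$sigma2, se = x$se)
  print(round(est, 6))
  cat("restricted logLik:", format(x$logLik, digits = 10), "\n")
  invisible(x)
}

# ---- internal REML engines -------------------------------------------------

# Dense average-information REML for an arbitrary list of genetic kernels
# plus the residual identity kernel. EM fallback when the AI step does not
# improve the restricted likelihood; variances floored at
# floor_frac * var(y) during iteration.
reml_dense <- function(y, X, Klist, floor_frac = 1e-8, tol_ll = 1e-8,
                       tol_par = 1e-6, maxit = 200) {
  n <- length(y); p <- ncol(X); nc <- length(Klist)
  vp <- stats::var(y)
  fl <- floor_frac * vp
  theta <- c(rep(0.5 * vp / max(nc, 1), nc), 0.5 * vp)

  eval_theta <- function(theta) {
    V <- diag(theta[nc + 1], n)
    for (i in seq_len(nc)) V <- V + theta[i] * Klist[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VX <- Vinv %*% X
    B <- crossprod(X, VX)
    Bch <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(Bch)) return(NULL)
    Binv <- chol2inv(Bch)
    P <- Vinv - VX %*% tcrossprod(Binv, VX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(Bch))) +
                    sum(y * Py) + (n - p) * log(2 * pi))
    if (!is.finite(ll)) return(NULL)
    list(ll = ll, P = P, Py = Py, Vinv = Vinv, Binv = Binv)
  }

  st <- eval_theta(theta)
  if (is.null(st)) stop("non-finite restricted likelihood at starting values")
  converged <- FALSE; it <- 0; AI <- NULL
  while (it < maxit) {
    it <- it + 1
    trPK <- numeric(nc + 1)
    U <- matrix(0, n, nc + 1)
    for (i in seq_len(nc)) {
      trPK[i] <- sum(st$P * Klist[[i]])   # tr(P K), both symmetric
      U[, i] <- Klist[[i]] %*% st$Py
    }
    trPK[nc + 1] <- sum(diag(st$P))
    U[, nc + 1] <- st$Py
    yPKPy <- drop(crossprod(U, st$Py))
    score <- -0.5 * (trPK - yPKPy)
    AI <- 0.5 * crossprod(U, st$P %*% U)

    # active set: components pinned at the floor whose score pushes further
    # down stay fixed, so the AI step optimizes the free block properly
    free <- !(theta <= fl * (1 + 1e-9) & score < 0)
    if (!any(free)) free[nc + 1] <- TRUE
    stc <- NULL; cand <- theta
    delta <- rep(0, nc + 1)
    delta[free] <- tryCatch(
      solve(AI[free, free, drop = FALSE], score[free]),
      error = function(e) rep(NA_real_, sum(free)))
    if (all(is.finite(delta))) {
      step <- 1
      for (h in 1:6) {
        cand <- pmax(theta + step * delta, fl)
        stc <- eval_theta(cand)
        if (!is.null(stc) && stc$ll >= st$ll - 1e-10) break
        stc <- NULL
        step <- step / 2
      }
    }
    if (is.null(stc)) {  # EM fallback (monotone for this model)
      cand <- pmax(theta + theta^2 * (yPKPy - trPK) / n, fl)
      stc <- eval_theta(cand)
      if (is.null(stc))
        stop("non-finite restricted likelihood during REML iteration")
    }
    dll <- stc$ll - st$ll
    dpar <- max(abs(cand - theta))
    theta <- cand; st <- stc
    if (abs(dll) < tol_ll * (abs(st$ll) + 1) || dpar < tol_par * vp) {
      converged <- TRUE
      break
    }
  }
  beta <- drop(st$Binv %*% crossprod(X, st$Vinv %*% y))
  se <- tryCatch(sqrt(diag(solve(AI))),
                 error = function(e) rep(NA_real_, nc + 1))
  est <- ifelse(theta <= fl * (1 + 1e-9), 0, theta)
  list(theta = est, ll = st$ll, iterations = it, converged = converged,
       se = se, beta = beta, Py = st$Py)
}

# Eigen-basis blocks for a single-kernel model. K = U1 diag(d) U1' (U1 may
# span only rank m < N; the orthogonal complement enters through crossprod
# differences because V restricted there is sigma2_e I).
lowrank_pre <- function(y, X, U1, d) {
  y1 <- drop(crossprod(U1, y))
  X1 <- crossprod(U1, X)
  list(n = length(y), p = ncol(X), d = d, y1 = y1, X1 = X1,
       C_XX = crossprod(X) - crossprod(X1),
       C_Xy = drop(crossprod(X, y)) - drop(crossprod(X1, y1)),
       C_yy = sum(y^2) - sum(y1^2))
}

# Restricted log-likelihood at explicit (sigma2_g, sigma2_e) from low-rank
# blocks; also returns the pieces needed for beta and BLUP.
ll_lowrank <- function(th_g, th_e, pre) {
  dv <- th_g * pre$d + th_e
  if (any(dv <= 0) || th_e <= 0) return(list(ll = -Inf))
  w <- 1 / dv
  n0 <- pre$n - length(pre$d)
  B <- crossprod(pre$X1, w * pre$X1) + pre$C_XX / th_e
  XVy <- drop(crossprod(pre$X1, w * pre$y1)) + pre$C_Xy / th_e
  yVy <- sum(w * pre$y1^2) + pre$C_yy / th_e
  Bch <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(Bch)) return(list(ll = -Inf))
  beta <- backsolve(Bch, backsolve(Bch, XVy, transpose = TRUE))
  q <- yVy - sum(XVy * beta)
  ll <- -0.5 * (sum(log(dv)) + n0 * log(th_e) + 2 * sum(log(diag(Bch))) +
                  q + (pre$n - pre$p) * log(2 * pi))
  list(ll = ll, beta = beta, q = q)
}

# Single-kernel REML by profiling sigma2_e out of the likelihood and
# optimizing the variance ratio lambda = sigma2_g / sigma2_e in one
# dimension (coarse log-grid then Brent refinement). Deterministic and
# cheap: used for null (whole-genome only) and regional-only fits.
reml_1k <- function(y, X, U1, d, floor_frac = 1e-8) {
  pre <- lowrank_pre(y, X, U1, d)
  n <- pre$n; p <- pre$p
  prof <- function(lam) {
    w <- 1 / (lam * pre$d + 1)
    n0 <- n - length(pre$d)
    B <- crossprod(pre$X1, w * pre$X1) + pre$C_XX
    XVy <- drop(crossprod(pre$X1, w * pre$y1)) + pre$C_Xy
    yVy <- sum(w * pre$y1^2) + pre$C_yy
    Bch <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(Bch)) return(-Inf)
    q <- yVy - sum(XVy * backsolve(Bch, backsolve(Bch, XVy, transpose = TRUE)))
    s2e <- q / (n - p)
    if (s2e <= 0) return(-Inf)
    -0.5 * (sum(log(lam * pre$d + 1)) + 2 * sum(log(diag(Bch))) +
              (n - p) * (1 + log(s2e) + log(2 * pi)))
  }
  grid <- c(0, 10^seq(-6, 6, by = 0.5))
  vals <- vapply(grid, prof, numeric(1))
  k <- which.max(vals)
  lo <- if (k == 1) 0 else grid[k - 1]
  hi <- if (k == length(grid)) grid[k] * 10 else grid[k + 1]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
  lam <- if (opt$objective >= vals[k]) opt$maximum else grid[k]
  # recover sigma2_e at the chosen ratio
  w <- 1 / (lam * pre$d + 1)
  B <- crossprod(pre$X1, w * pre$X1) + pre$C_XX
  XVy <- drop(crossprod(pre$X1, w * pre$y1)) + pre$C_Xy
  yVy <- sum(w * pre$y1^2) + pre$C_yy
  q <- yVy - sum(XVy * solve(B, XVy))
  s2e <- q / (n - p)
  vp <- stats::var(y); fl <- floor_frac * vp
  th_g <- max(lam * s2e, 0)
  st <- ll_lowrank(max(th_g, fl), max(s2e, fl), pre)
  # numeric observed information for standard errors
  h <- 1e-4 * vp
  f <- function(a, b) ll_lowrank(max(a, fl), max(b, fl), pre)$ll
  H <- matrix(NA_real_, 2, 2)
  H[1, 1] <- (f(th_g + h, s2e) - 2 * st$ll + f(th_g - h, s2e)) / h^2
  H[2, 2] <- (f(th_g, s2e + h) - 2 * st$ll + f(th_g, s2e - h)) / h^2
  H[1, 2] <- H[2, 1] <- (f(th_g + h, s2e + h) - f(th_g + h, s2e - h) -
                           f(th_g - h, s2e + h) + f(th_g - h, s2e - h)) / (4 * h^2)
  se <- tryCatch(sqrt(diag(solve(-H))), error = function(e) c(NA_real_, NA_real_))
  list(theta = c(if (th_g <= fl * (1 + 1e-9)) 0 else th_g, s2e),
       ll = st$ll, iterations = length(grid), converged = TRUE,
       se = se, beta = st$beta, pre = pre, th_raw = c(max(th_g, fl), s2e))
}

# Residual-only REML (ordinary least squares).
reml_0k <- function(y, X) {
  n <- length(y); p <- ncol(X)
  fit <- stats::lm.fit(X, y)
  q <- sum(fit$residuals^2)
  s2e <- q / (n - p)
  ll <- -0.5 * (n * log(s2e) + 2 * sum(log(abs(diag(qr.R(qr(X)))))) -
                  p * log(s2e) + (n - p) + (n - p) * log(2 * pi))
  list(theta = s2e, ll = ll, iterations = 1, converged = TRUE,
       se = sqrt(2 * s2e^2 / (n - p)), beta = fit$coefficients)
}

# Eigendecomposition of a kernel, via SVD of the low-rank loadings when
# available (regional GRMs), else dense eigen. Cached inside the GRM object
# by fit helpers that reuse it.
kernel_eigen <- function(K) {
  if (inherits(K, "RegionalGRM")) {
    if (!is.null(K$eigen)) return(K$eigen)
    if (!is.null(K$loadings) && ncol(K$loadings) < nrow(K$M)) {
      sv <- svd(K$loadings, nu = min(dim(K$loadings)), nv = 0)
      keep <- sv$d^2 > max(sv$d^2, 0) * 1e-14
      return(list(U = sv$u[, keep, drop = FALSE], d = sv$d[keep]^2))
    }
    K <- K$M
  }
  e <- eigen(K, symmetric = TRUE)
  list(U = e$vectors, d = e$values)
}

#' Precompute the eigendecomposition of a whole-genome GRM
#'
#' Null-model (single-component) REML fits work in the eigenbasis of the
#' kernel, where each iteration is O(N). Decomposing once and attaching the
#' result makes repeated null fits against the same GRM cheap.
#'
#' @param grm a `RegionalGRM`.
#' @return the same GRM with an `eigen` element attached.
#' @export
grm_precompute_eigen <- function(grm) {
  stopifnot(inherits(grm, "RegionalGRM"))
  grm$eigen <- kernel_eigen(grm)
  grm
}

check_not_identity <- function(K, name) {
  M <- if (inherits(K, "RegionalGRM")) K$M else K
  n <- nrow(M)
  if (max(abs(M - diag(n))) < 1e-10)
    stop("component matrix equals identity (", name,
         "): variance not separable from the residual")
  invisible(TRUE)
}

#' Fit the variance-component model by REML
#'
#' Estimates the variance components of y = X beta + g_r + g_w + e for the
#' requested subset of genetic components. Two-component fits use dense
#' average-information REML with expectation-maximization fallback steps and
#' a variance floor of 1e-8 x var(y); single-component fits profile the
#' residual variance out and optimize the variance ratio in one dimension in
#' the kernel eigenbasis (numerically equivalent, much faster). Convergence
#' is declared when the relative restricted-log-likelihood change is below
#' 1e-8 or the largest parameter change is below 1e-6 x var(y), with at most
#' 200 iterations; non-convergence returns the fit with `converged = FALSE`
#' and a warning.
#'
#' @param spec a [mixed_model_spec()].
#' @param components character subset of `c("regional", "whole_genome")`.
#' @return a `VarCompFit` with elements `sigma2` (named vector
#'   regional/whole_genome/residual, `NA` for components not in the model),
#'   `logLik`, `iterations`, `converged`, `se`, `beta`.
#' @export
fit_reml <- function(spec, components = c("regional", "whole_genome")) {
  stopifnot(inherits(spec, "MixedModelSpec"))
  components <- match.arg(components, c("regional", "whole_genome"),
                          several.ok = TRUE)
  Ks <- list()
  if ("regional" %in% components) {
    if (is.null(spec$K_r)) stop("spec has no regional matrix K_r")
    Ks$regional <- spec$K_r
  }
  if ("whole_genome" %in% components) {
    if (is.null(spec$K_w)) stop("spec has no whole-genome matrix K_w")
    Ks$whole_genome <- spec$K_w
  }
  for (nm in names(Ks)) check_not_identity(Ks[[nm]], nm)
  y <- spec$y; X <- spec$X
  sig <- c(regional = NA_real_, whole_genome = NA_real_, residual = NA_real_)
  se <- sig
  if (length(Ks) == 2) {
    r <- reml_dense(y, X, lapply(Ks, function(k) k$M))
    if (!r$converged)
      warning("REML did not converge in ", r$iterations, " iterations")
    sig[c("regional", "whole_genome", "residual")] <- r$theta
    se[c("regional", "whole_genome", "residual")] <- r$se
  } else if (length(Ks) == 1) {
    eg <- kernel_eigen(Ks[[1]])
    r <- reml_1k(y, X, eg$U, eg$d)
    sig[c(names(Ks), "residual")] <- r$theta
    se[c(names(Ks), "residual")] <- r$se
  } else {
    r <- reml_0k(y, X)
    sig["residual"] <- r$theta
    se["residual"] <- r$se
  }
  new_varcomp_fit(sig, r$ll, r$iterations, r$converged, se, r$beta,
                  length(y), names(Ks), y)
}

#' Likelihood-ratio test for the regional variance component
#'
#' LRT = max(0, 2 (logL_full - logL_null)), floored at zero because the
#' regional variance is tested on the boundary of its parameter space (the
#' asymptotic null is the 50:50 mixture of a point mass at zero and a
#' 1-d.f. chi-square).
#'
#' @param full `VarCompFit` of the model including the regional component.
#' @param null `VarCompFit` of the same data without the regional component.
#' @param threshold optional significance threshold for the `significant`
#'   flag.
#' @return an `LrtResult`: list with `lrt` and `significant`.
#' @export
lrt <- function(full, null, threshold = NULL) {
  stopifnot(inherits(full, "VarCompFit"), inherits(null, "VarCompFit"))
  if (full$n != null$n ||
      max(abs(full$y_checksum - null$y_checksum)) > 1e-8 * (1 + abs(full$y_checksum[2])))
    stop("full and null fits are not from the same data")
  if (!all(null$components %in% full$components) ||
      length(null$components) >= length(full$components))
    stop("null model must be a strict sub-model of the full model")
  val <- max(0, 2 * (full$logLik - null$logLik))
  structure(list(lrt = val,
                 significant = if (is.null(threshold)) NA else val >= threshold),
            class = "LrtResult")
}

#' Regional heritability from a fitted model
#'
#' RH = sigma2_r / (sigma2_r + sigma2_w + sigma2_e): the proportion of the
#' phenotypic variance attributed to the tested region. Components absent
#' from the fit (approximate single-component scans) are omitted from the
#' denominator.
#'
#' @param fit a `VarCompFit` including the regional component.
#' @return regional heritability in [0, 1].
#' @export
regional_heritability <- function(fit) {
  stopifnot(inherits(fit, "VarCompFit"))
  if (is.na(fit$sigma2["regional"]))
    stop("fit has no regional component")
  tot <- sum(fit$sigma2, na.rm = TRUE)
  if (tot <= 0) stop("zero total variance")
  unname(fit$sigma2["regional"] / tot)
}

#' GRAMMAR-style residuals
#'
#' Fits the null model (whole-genome component only), computes the BLUP of
#' the polygenic effect g_w, and returns y - X beta - g_w. With an intercept
#' in X these residuals have exactly zero mean. They can be used as a
#' pre-adjusted phenotype for fast regional-only scans; note this is the
#' plain BLUP residual, without the deregression factor of GRAMMAR+.
#'
#' @param spec a [mixed_model_spec()] with `K_w`.
#' @return numeric residual vector with attributes `null_fit`.
#' @export
grammar_residuals <- function(spec) {
  stopifnot(inherits(spec, "MixedModelSpec"))
  if (is.null(spec$K_w)) stop("spec has no whole-genome matrix K_w")
  null <- fit_reml(spec, components = "whole_genome")
  if (!null$converged) stop("null model fit did not converge")
  s2w <- max(null$sigma2["whole_genome"], 0)
  s2e <- null$sigma2["residual"]
  y <- spec$y; X <- spec$X
  V <- s2w * spec$K_w$M + diag(s2e, length(y))
  Vinv_r <- solve(V, y - drop(X %*% null$beta))
  # identity: y - X beta - g_w = sigma2_e V^{-1} (y - X beta)
  res <- drop(s2e * Vinv_r)
  attr(res, "null_fit") <- null
  res
}

#' Fast scan: regional-only pass then full refit of top windows
#'
#' Pass 1 fits each window with the regional component only (omitting the
#' whole-genome component) and ranks windows by the pass-1 LRT against the
#' residual-only null. The top fraction is then refitted with the full
#' two-component model (LRT against the whole-genome-only null); the rest
#' keep their pass-1 results flagged `approximate`.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design matrix (`NULL` for intercept only).
#' @param K_w whole-genome `RegionalGRM`.
#' @param window_grms named list of regional GRMs (skips allowed).
#' @param top_fraction fraction of windows refitted with the full model.
#' @return data.frame with one row per window: variance estimates, `lrt`,
#'   `rh`, `approximate` flag; full fits attached as attribute `fits`.
#' @export
fast_scan_then_refit <- function(y, X = NULL, K_w, window_grms,
                                 top_fraction = 0.1) {
  if (length(window_grms) == 0) stop("empty window list")
  spec0 <- mixed_model_spec(y, X, K_w = K_w)
  null0 <- reml_0k(spec0$y, spec0$X)
  pass1 <- lapply(window_grms, function(g) {
    if (is_window_skip(g)) return(NULL)
    f <- fit_reml(mixed_model_spec(y, X, K_r = g), components = "regional")
    list(fit = f, lrt = max(0, 2 * (f$logLik - null0$ll)))
  })
  lrt1 <- vapply(pass1, function(z) if (is.null(z)) NA_real_ else z$lrt,
                 numeric(1))
  n_ok <- sum(!is.na(lrt1))
  n_top <- max(1L, min(n_ok, ceiling(top_fraction * n_ok)))
  refit_idx <- order(-lrt1, na.last = TRUE)[seq_len(n_top)]
  null_w <- fit_reml(spec0, components = "whole_genome")
  rows <- vector("list", length(window_grms))
  fits <- vector("list", length(window_grms))
  for (i in seq_along(window_grms)) {
    g <- window_grms[[i]]
    if (is_window_skip(g)) {
      rows[[i]] <- data.frame(window = names(window_grms)[i] %||% i,
                              sigma2_r = NA, sigma2_w = NA, sigma2_e = NA,
                              lrt = NA, rh = NA, approximate = NA,
                              skip_reason = g$reason)
      next
    }
    if (i %in% refit_idx) {
      f <- fit_reml(mixed_model_spec(y, X, K_r = g, K_w = K_w))
      l <- lrt(f, null_w)$lrt
      approx <- FALSE
    } else {
      f <- pass1[[i]]$fit
      l <- pass1[[i]]$lrt
      approx <- TRUE
    }
    fits[[i]] <- f
    rows[[i]] <- data.frame(window = names(window_grms)[i] %||% i,
                            sigma2_r = unname(f$sigma2["regional"]),
                            sigma2_w = unname(f$sigma2["whole_genome"]),
                            sigma2_e = unname(f$sigma2["residual"]),
                            lrt = l, rh = regional_heritability(f),
                            approximate = approx, skip_reason = NA_character_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
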