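## Gene-level burden testing from scratch: variance-component (SKAT) and
## weighted-count (burden) score tests and their optimal convex combination
## over a grid of mixing parameters rho (SKAT-O), with tail probabilities
## from the quadratic-form machinery in quadform.R.

#' Fit the logistic null model for burden testing
#'
#' Maximum-likelihood logistic regression of the binary phenotype on the
#' adjustment covariates (intercept added), giving the null fitted
#' probabilities `mu`, residuals `r = y - mu` and variance weights
#' `v = mu (1 - mu)` consumed by [skato_test()].
#'
#' @param y Binary 0/1 phenotype vector.
#' @param X Covariate matrix (without intercept) or `NULL` for an
#'   intercept-only null.
#' @return List of class `null_model` with elements `y`, `X` (with
#'   intercept column), `mu`, `resid`, `v`.
#' @export
fit_null_model <- function(y, X = NULL) {
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1))
  Xf <- cbind(Intercept = rep(1, length(y)), X)
  if (qr(Xf)$rank < ncol(Xf)) {
    stop("covariate matrix is rank deficient", call. = FALSE)
  }
  fit <- stats::glm.fit(Xf, y, family = stats::binomial())
  if (!isTRUE(fit$converged)) {
    stop("null logistic model did not converge", call. = FALSE)
  }
  mu <- fit$fitted.values
  structure(list(y = y, X = Xf, mu = mu, resid = y - mu, v = mu * (1 - mu)),
            class = "null_model")
}

#' Beta-density variant weights
#'
#' The conventional rare-variant up-weighting: the Beta(1, 25) density
#' evaluated at the pooled-sample minor allele frequency,
#' `w(maf) = 25 (1 - maf)^24` — finite as maf tends to 0 and decreasing on
#' (0, 0.5].
#'
#' @param maf Allele frequencies in (0, 1).
#' @param a,b Beta shape parameters.
#' @return Weight vector.
#' @export
beta_weights <- function(maf, a = 1, b = 25) {
  stats::dbeta(maf, a, b)
}

# standard rho grid for the SKAT-O search
default_rho_grid <- function() c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 0.5, 1)

#' SKAT-O gene-level association test
#'
#' Computes, for each mixing parameter rho in `rho_grid`, the statistic
#' `Q_rho = (1 - rho) Q_SKAT + rho Q_burden`, where
#' `Q_SKAT = sum_j (w_j g_j' r)^2` is the variance-component statistic and
#' `Q_burden = (sum_j w_j g_j' r)^2` the weighted-count statistic, with `r`
#' the null-model residuals. Each per-rho p-value comes from the
#' eigenvalue-weighted chi-square mixture of the covariate-projected
#' kernel; the SKAT-O p-value combines the minimum over the grid by
#' one-dimensional numerical integration over the shared burden-direction
#' chi-square component.
#'
#' Missing dosages are mean-imputed within variant for the kernel only
#' (kernel methods need rectangular input; everywhere else in the package
#' missing genotypes are excluded from denominators). Monomorphic variants
#' are dropped; if none remain the gene is skipped with a reason.
#'
#' @param G Dosage matrix (samples x variants) for the gene's variant set;
#'   rows must align with the null model's phenotype vector.
#' @param null_fit A [fit_null_model()] object.
#' @param weights Per-variant weights; default [beta_weights()] at the
#'   pooled-sample alternate-allele frequency.
#' @param rho_grid Mixing grid; must contain 0 (pure SKAT) and 1 (pure
#'   burden) to span both ends.
#' @param gene Optional gene label stored in the result.
#' @return List of class `skato_result`: `p_skato`, `rho_grid`, `p_per_rho`,
#'   `q_per_rho`, `weights`, `variant_keys`, `n_samples`, or a skipped
#'   result with `reason` when no polymorphic variant remains.
#' @export
skato_test <- function(G, null_fit, weights = NULL,
                       rho_grid = default_rho_grid(), gene = NA_character_) {
  stopifnot(inherits(null_fit, "null_model"))
  G <- as.matrix(unclass(G))
  if (nrow(G) != length(null_fit$y)) {
    stop("genotype rows do not match null-model samples", call. = FALSE)
  }
  stopifnot(all(rho_grid >= 0 & rho_grid <= 1))
  rho_grid <- sort(unique(rho_grid))

  # mean-impute missing dosages, then drop monomorphic columns
  G <- apply(G, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  if (is.null(dim(G))) G <- matrix(G, ncol = 1)
  poly <- apply(G, 2, function(g) stats::var(g) > 0)
  if (!any(poly)) {
    return(structure(list(gene = gene, p_skato = NA_real_,
                          reason = "all variants monomorphic"),
                     class = "skato_result"))
  }
  G <- G[, poly, drop = FALSE]
  if (is.null(colnames(G))) colnames(G) <- paste0("v", which(poly))
  m <- ncol(G)
  maf <- colMeans(G) / 2
  if (is.null(weights)) weights <- beta_weights(maf)
  if (length(weights) == ncol(G)) w <- weights else w <- weights[poly]

  r <- null_fit$resid
  v <- null_fit$v
  X <- null_fit$X
  Gw <- sweep(G, 2, w, `*`)

  S <- drop(crossprod(Gw, r))
  q_skat <- sum(S^2)
  q_burden <- sum(S)^2

  # covariance of the score vector under the null:
  # Sigma = Gw' V Gw - (Gw' V X)(X' V X)^{-1}(X' V Gw)
  sv <- sqrt(v)
  Sigma <- crossprod(Gw * sv)
  B <- crossprod(Gw * v, X)
  XtVX <- crossprod(X * sv)
  Sigma <- Sigma - B %*% solve(XtVX, t(B))

  q_rho <- (1 - rho_grid) * q_skat + rho_grid * q_burden
  lambdas <- lapply(rho_grid, function(rho) rho_kernel_eigenvalues(Sigma, rho))
  p_rho <- mapply(function(q, l) as.numeric(mixture_chisq_pvalue(q, l)),
                  q_rho, lambdas)
  min_p <- min(p_rho)

  p_skato <- if (length(rho_grid) == 1L) {
    min_p
  } else {
    skato_combine(min_p, Sigma, rho_grid, fallback = min(1, min_p * length(rho_grid)))
  }
  structure(list(gene = gene, variant_keys = colnames(G), weights = w,
                 rho_grid = rho_grid, q_per_rho = q_rho, p_per_rho = p_rho,
                 p_skato = p_skato, n_samples = nrow(G), maf = maf,
                 reason = NULL),
            class = "skato_result")
}

#' @export
print.skato_result <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat(sprintf("<skato_result %s> skipped: %s\n", x$gene, x$reason))
    return(invisible(x))
  }
  cat(sprintf("<skato_result %s> %d variants, %d samples, p_skato = %.3g\n",
              x$gene, length(x$variant_keys), x$n_samples, x$p_skato))
  cat("  per-rho p:", paste(sprintf("rho=%.2g:%.3g", x$rho_grid, x$p_per_rho),
                            collapse = "  "), "\n")
  invisible(x)
}

# eigenvalues of R_rho^{1/2} Sigma R_rho^{1/2} for R_rho = (1-rho)I + rho J;
# the matrix square root of aI + bJ is sqrt(a)I + ((sqrt(a + m b) - sqrt(a))/m)J
rho_kernel_eigenvalues <- function(Sigma, rho) {
  m <- nrow(Sigma)
  if (rho >= 1) return(sum(Sigma))
  a <- 1 - rho
  coef <- (sqrt(a + m * rho) - sqrt(a)) / m
  rs <- rowSums(Sigma)
  tot <- sum(rs)
  # R^{1/2} Sigma R^{1/2} expanded around the rank-one J term
  K <- a * Sigma +
    sqrt(a) * coef * (matrix(rs, m, m) + matrix(rs, m, m, byrow = TRUE)) +
    coef^2 * tot
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > 1e-10 * max(ev)]
}

# Combination of the minimum per-rho p-value over the grid. Exact under
# the Gaussian score model: conditional on the burden-direction chi-square
# x = (1'S)^2 / (1' Sigma 1), the SKAT statistic S'S is a noncentral
# chi-square mixture (plus a deterministic offset), so
# P(min_rho p_rho <= T) integrates its noncentral Imhof tail over
# x ~ chisq_1, with exact per-rho quantiles of the observed minimum.
skato_combine <- function(min_p, Sigma, rho_grid, fallback) {
  m <- nrow(Sigma)
  u <- drop(Sigma %*% rep(1, m))
  cc <- sum(u)
  if (cc <= 1e-12) return(fallback)
  q_rho <- vapply(rho_grid, function(rho) {
    lam <- rho_kernel_eigenvalues(Sigma, rho)
    mixture_chisq_quantile(min_p, lam)
  }, numeric(1))
  C <- Sigma - tcrossprod(u) / cc       # cov of S given the burden component
  es <- eigen(C, symmetric = TRUE)
  pos <- es$values > 1e-10 * max(abs(es$values), 1)
  if (!any(pos)) return(min_p)          # rank-one kernel: all rho agree
  lambda <- es$values[pos]
  vk2 <- drop(crossprod(es$vectors[, pos, drop = FALSE], u))^2
  resid2 <- max(sum(u^2) - sum(vk2), 0) # conditional-mean mass off the range
  lt1 <- rho_grid < 1
  q1 <- if (any(!lt1)) min(q_rho[!lt1]) else Inf
  g <- rho_grid[lt1]; qg <- q_rho[lt1]

  p_given_x <- function(x) {
    if (cc * x >= q1) return(1)         # the pure-burden end already rejects
    if (!length(g)) return(0)
    s <- min((qg - g * cc * x) / (1 - g))
    thr <- s - resid2 * x / cc
    if (thr <= 0) return(1)
    delta <- vk2 * x / (cc * lambda)
    v <- imhof_tail_nc(thr, lambda, delta)
    if (is.na(v)) v <- liu_tail(thr, lambda * (1 + delta))
    v
  }
  # integrate over s = sqrt(x) (half-normal scale) so the transition region
  # near x = 0 is resolved; p(x) is monotone increasing in x, so evaluation
  # stops once saturated and interpolates on the log scale in between
  ss <- seq(0, 8.5, length.out = 200L)
  ps <- numeric(length(ss))
  for (i in seq_along(ss)) {
    ps[i] <- p_given_x(ss[i]^2)
    if (ps[i] >= 1 - 1e-12) { ps[i:length(ss)] <- 1; break }
  }
  log_ps <- stats::approxfun(ss, log(pmax(ps, 1e-300)), rule = 2)
  p <- tryCatch(
    stats::integrate(function(s) exp(log_ps(s)) * 2 * stats::dnorm(s),
                     0, 8.5, subdivisions = 1000L,
                     rel.tol = 1e-6, abs.tol = 1e-12,
                     stop.on.error = FALSE)$value +
      2 * stats::pnorm(8.5, lower.tail = FALSE),
    error = function(e) NA_real_)
  if (is.na(p) || p <= 0) return(fallback)
  # the combined p can never beat the unadjusted minimum nor its Bonferroni
  # bound over the grid
  min(max(p, min_p), min_p * length(rho_grid), 1)
}
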