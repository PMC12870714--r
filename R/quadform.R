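## Tail probabilities of positive linear combinations of independent 1-df
## chi-square variables, Q = sum_i lambda_i * chisq_1. Primary route is
## numerical inversion of the characteristic function (Imhof's integral);
## when the integral fails or returns an out-of-range value the
## moment-matching approximation of Liu-Tang-Zhang is used and flagged.

# Truncation point for the Imhof integral: past U the integrand oscillates
# at frequency q/2 under the envelope exp(-lrho(u))/u, so the neglected
# tail is about envelope(U)/(q/2). Doubles U until that bound is small.
imhof_upper <- function(q, envelope, tol = 1e-9) {
  u <- 1
  bound <- function(u) envelope(u) / (0.5 * max(q, 1))
  while (bound(u) > tol && u < 1e7) u <- u * 1.8
  u
}

imhof_tail <- function(q, lambda, rel.tol = 1e-8) {
  # components below 1e-4 of the largest have negligible variance: absorb
  # them as their deterministic mean (keeps the integrand short-ranged)
  big <- lambda >= 1e-4 * max(lambda)
  if (!all(big)) {
    q <- q - sum(lambda[!big])
    lambda <- lambda[big]
  }
  if (q <= 0) return(1)
  if (length(lambda) == 1L) {          # exact single-component tail
    return(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE))
  }
  f <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    lrho <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
    out <- sin(theta) * exp(-lrho) / u
    out[u == 0] <- 0.5 * (sum(lambda) - q)
    out
  }
  U <- imhof_upper(q, function(u) {
    exp(-0.25 * sum(log1p(lambda^2 * u^2))) / u
  })
  int <- stats::integrate(f, 0, U, subdivisions = 5000L,
                          rel.tol = rel.tol, abs.tol = 1e-12,
                          stop.on.error = FALSE)
  if (!int$message %in% c("OK", "roundoff error was detected")) {
    return(NA_real_)
  }
  0.5 + int$value / pi
}

liu_tail <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  mu_x <- l + delta
  sigma_x <- sqrt(2 * (l + 2 * delta))
  tstar <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta,
                lower.tail = FALSE)
}

#' Tail probability of a mixture of one-degree chi-squares
#'
#' Computes `P(sum_i lambda_i chisq_1 > Q)` by numerical inversion of the
#' characteristic function (Imhof's method), falling back to the
#' Liu-Tang-Zhang moment-matching approximation when the integral fails;
#' the route taken is recorded in the `"method"` attribute.
#'
#' @param Q Observed quadratic-form value.
#' @param eigenvalues Non-negative mixture weights (a negative value beyond
#'   numerical tolerance is an error); zeros are dropped.
#' @return Tail probability in `[0, 1]`, attribute `"method"` set to
#'   `"imhof"` or `"liu"`.
#' @export
mixture_chisq_pvalue <- function(Q, eigenvalues) {
  tol <- 1e-8 * max(abs(eigenvalues), 1)
  if (any(eigenvalues < -tol)) {
    stop("negative eigenvalue beyond tolerance", call. = FALSE)
  }
  lambda <- eigenvalues[eigenvalues > tol]
  if (!length(lambda)) stop("all eigenvalues are zero", call. = FALSE)
  if (Q <= 0) return(structure(1, method = "exact"))
  p <- imhof_tail(Q, lambda)
  if (is.na(p) || p < -1e-8 || p > 1 + 1e-8 || p < 1e-12) {
    p <- liu_tail(Q, lambda)
    attr(p, "method") <- "liu"
  } else {
    p <- min(max(p, 0), 1)
    attr(p, "method") <- "imhof"
  }
  p
}

# Upper quantile: q with P(mixture > q) = p. Exact for a single component;
# otherwise a bracketed root search on the Imhof tail.
mixture_chisq_quantile <- function(p, lambda) {
  stopifnot(p > 0, p < 1)
  if (length(lambda) == 1L) {
    return(lambda * stats::qchisq(p, df = 1, lower.tail = FALSE))
  }
  tail_fun <- function(q) {
    v <- imhof_tail(q, lambda)
    if (is.na(v)) v <- liu_tail(q, lambda)
    v
  }
  hi <- sum(lambda) + 10 * sqrt(2 * sum(lambda^2))
  while (tail_fun(hi) > p) hi <- hi * 2
  stats::uniroot(function(q) tail_fun(q) - p, lower = 0, upper = hi,
                 tol = 1e-6 * max(hi, 1))$root
}

# Noncentral extension of the Imhof integral:
# P(sum_r lambda_r chisq_1(delta_r) > q).
imhof_tail_nc <- function(q, lambda, delta, rel.tol = 1e-6) {
  # absorb relatively tiny components as their deterministic mean
  # lambda * (1 + delta); tighter cutoff than the central case because a
  # large noncentrality inflates the variance of a dropped component
  big <- lambda >= 1e-5 * max(lambda)
  if (!all(big)) {
    q <- q - sum(lambda[!big] * (1 + delta[!big]))
    lambda <- lambda[big]
    delta <- delta[big]
  }
  if (q <= 0) return(1)
  if (length(lambda) == 1L) {
    return(stats::pchisq(q / lambda, df = 1, ncp = delta,
                         lower.tail = FALSE))
  }
  f <- function(u) {
    lu <- outer(lambda, u)
    lu2 <- lu^2
    theta <- 0.5 * colSums(atan(lu) + delta * lu / (1 + lu2)) - 0.5 * q * u
    lrho <- colSums(0.25 * log1p(lu2) + 0.5 * delta * lu2 / (1 + lu2))
    out <- sin(theta) * exp(-lrho) / u
    out[u == 0] <- 0.5 * (sum(lambda * (1 + delta)) - q)
    out
  }
  U <- imhof_upper(q, function(u) {
    lu2 <- lambda^2 * u^2
    exp(-sum(0.25 * log1p(lu2) + 0.5 * delta * lu2 / (1 + lu2))) / u
  })
  int <- stats::integrate(f, 0, U, subdivisions = 5000L,
                          rel.tol = rel.tol, abs.tol = 1e-12,
                          stop.on.error = FALSE)
  if (!int$message %in% c("OK", "roundoff error was detected")) {
    return(NA_real_)
  }
  min(max(0.5 + int$value / pi, 0), 1)
}

# Satterthwaite-style quantile of a mixture at upper tail probability p:
# chi-square moment match on (mean, variance, effective df). The standard
# grid-quantile approximation in the SKAT-O combination step.
moment_match_quantile <- function(p, lambda) {
  mu_q <- sum(lambda)
  var_q <- 2 * sum(lambda^2)
  df <- sum(lambda^2)^2 / sum(lambda^4)
  q0 <- stats::qchisq(p, df = df, lower.tail = FALSE)
  (q0 - df) / sqrt(2 * df) * sqrt(var_q) + mu_q
}
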