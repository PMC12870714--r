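## Single-causal-variant fine-mapping of a region from GWAS summary
## statistics via approximate Bayes factors, including a posterior for the
## no-association (null) model.

#' Wakefield approximate log Bayes factor
#'
#' For a variant with effect estimate `beta` and standard error `se`,
#' under a Normal(0, W^2) effect prior, the approximate Bayes factor for
#' association is
#' `log ABF = 0.5 log(V / (V + W^2)) + 0.5 z^2 W^2 / (V + W^2)`
#' with `V = se^2` and `z = beta / se`.
#'
#' @param beta Effect estimate(s) on the log-odds scale.
#' @param se Standard error(s), > 0.
#' @param W Prior standard deviation of the true effect (default 0.2, the
#'   conventional case-control scale).
#' @return Log approximate Bayes factor(s).
#' @export
wakefield_log_abf <- function(beta, se, W = 0.2) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || !is.finite(W)) {
    stop("beta, se and W must be finite", call. = FALSE)
  }
  stopifnot(all(se > 0), W >= 0)
  V <- se^2
  z <- beta / se
  0.5 * log(V / (V + W^2)) + 0.5 * z^2 * W^2 / (V + W^2)
}

#' Single-causal-variant fine-mapping of a region
#'
#' Assumes at most one causal variant. Each variant k receives prior
#' probability `p1` of being causal; the null (no association in the
#' region) takes the remaining mass. Posterior mass is proportional to
#' `p1 * ABF_k` per variant and to 1 for the null model, normalized so
#' `pp_null + sum(pp) = 1`. The decision is `"causal-candidate"` if the
#' best variant's posterior exceeds `pp_threshold`, `"null-favored"` if
#' the null's posterior does, otherwise `"inconclusive"`.
#'
#' @param stats Summary-statistics data frame (see [read_summary_stats()]).
#' @param p1 Per-variant prior probability of causality.
#' @param W Effect prior standard deviation, passed to
#'   [wakefield_log_abf()].
#' @param pp_threshold Posterior-probability decision threshold.
#' @return List of class `finemap_result`: per-variant `log_abf` and `pp`,
#'   `pp_null`, `lead_variant`, `lead_pp` and `decision`.
#' @export
finemap_region <- function(stats, p1 = 1e-4, W = 0.2, pp_threshold = 0.6) {
  stats <- validate_summary_stats(stats)
  if (nrow(stats) < 2) {
    stop("fine-mapping needs at least two variants", call. = FALSE)
  }
  stopifnot(p1 > 0, p1 < 1, pp_threshold > 0.5)
  labf <- wakefield_log_abf(stats$beta, stats$se, W)
  if (all(!is.finite(labf))) {
    stop("all approximate Bayes factors are non-finite", call. = FALSE)
  }
  # log posterior masses: variants at log(p1) + log ABF, null at 0
  lw <- c(log(p1) + labf, 0)
  mx <- max(lw)
  w <- exp(lw - mx)
  post <- w / sum(w)
  pp <- post[seq_len(nrow(stats))]
  pp_null <- post[length(post)]
  lead <- which.max(pp)
  decision <- if (pp[lead] > pp_threshold) "causal-candidate"
  else if (pp_null > pp_threshold) "null-favored"
  else "inconclusive"
  structure(list(
    variant_key = stats$variant_key, z = stats$beta / stats$se,
    log_abf = labf, pp = pp, pp_null = pp_null,
    lead_variant = stats$variant_key[lead], lead_pp = pp[lead],
    decision = decision, p1 = p1, W = W, pp_threshold = pp_threshold
  ), class = "finemap_result")
}

#' @export
print.finemap_result <- function(x, ...) {
  cat(sprintf("<finemap_result> %d variants, decision: %s\n",
              length(x$variant_key), x$decision))
  cat(sprintf("  lead %s pp = %.4f; pp_null = %.4f\n",
              x$lead_variant, x$lead_pp, x$pp_null))
  invisible(x)
}

#' @export
as.data.frame.finemap_result <- function(x, ...) {
  data.frame(variant_key = x$variant_key, z = x$z, log_abf = x$log_abf,
             pp = x$pp, stringsAsFactors = FALSE)
}
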