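## Covariate-adjusted single-variant association, Bonferroni scaling,
## one-sided Fisher carrier enrichment, and carrier demographic summaries.

#' Per-variant logistic association adjusted for sex, age and PC1-PC10
#'
#' Fits, for each variant, an additive-dosage logistic regression of
#' case/control status on dosage plus covariates (maximum likelihood,
#' complete-case rows only) and reports the Wald per-allele odds ratio,
#' 95\% confidence interval and p-value, together with the effect-allele
#' (alternate-allele) frequencies in affected (`f_a`) and unaffected
#' (`f_u`) individuals. Monomorphic variants are skipped with a reason.
#' Quasi-separated or non-converged fits are flagged (`converged = FALSE`,
#' triggered by non-convergence, |log OR| > 10 or a near-singular
#' information matrix) and the crude allelic odds ratio (Haldane-Anscombe
#' corrected) is reported as a fallback point estimate; Firth-type
#' penalization is deliberately not applied, so extreme Wald intervals are
#' reported as such.
#'
#' @param G A [genotype_matrix()].
#' @param samples Sample manifest (see [read_samples()]); phenotype
#'   `"control"` codes 0, anything else 1.
#' @param covariates Character vector of manifest columns to adjust for.
#'   `"sex"` is recoded M/F to 0/1.
#' @return Data frame of class `assoc_result`: one row per tested variant
#'   (`variant_key`, `effect_allele`, `or_point`, `ci_low`, `ci_high`, `p`,
#'   `f_a`, `f_u`, `converged`, `bonferroni_threshold`), with skipped
#'   variants and reasons in `attr(, "skipped")`.
#' @export
logistic_assoc <- function(G, samples,
                           covariates = c("sex", "age_years",
                                          paste0("PC", 1:10))) {
  samples <- samples[match(rownames(G), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) {
    stop("samples missing from manifest: ",
         paste(utils::head(setdiff(rownames(G), samples$sample_id)),
               collapse = ", "), call. = FALSE)
  }
  y <- as.integer(samples$phenotype != "control")
  if (length(unique(y)) < 2) {
    stop("phenotype must have two classes", call. = FALSE)
  }
  X <- covariate_matrix(samples, covariates)
  vk <- parse_variant_key(colnames(G))
  rows <- list(); skipped <- list()
  for (j in seq_len(ncol(G))) {
    g <- unclass(G)[, j]
    cc <- !is.na(g) & stats::complete.cases(X)
    gj <- g[cc]
    if (length(unique(gj)) < 2) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(variant_key = colnames(G)[j], reason = "monomorphic")
      next
    }
    Xfull <- cbind(Intercept = 1, dosage = gj, X[cc, , drop = FALSE])
    qq <- qr(Xfull)
    keep_col <- sort(qq$pivot[seq_len(qq$rank)])   # drop aliased covariates
    if (!all(1:2 %in% keep_col)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(variant_key = colnames(G)[j],
                   reason = "dosage aliased with covariates")
      next
    }
    Xfit <- Xfull[, keep_col, drop = FALSE]
    fit <- stats::glm.fit(Xfit, y[cc], family = stats::binomial())
    est <- fit$coefficients["dosage"]
    cov_un <- tryCatch(chol2inv(chol(crossprod(sqrt(fit$weights) * Xfit))),
                       error = function(e) NULL)
    se <- if (is.null(cov_un)) NA_real_ else
      sqrt(cov_un[which(colnames(Xfit) == "dosage"),
                  which(colnames(Xfit) == "dosage")])
    converged <- isTRUE(fit$converged) && !anyNA(fit$coefficients) &&
      is.finite(est) && abs(est) <= 10 && is.finite(se)
    f_a <- mean(gj[y[cc] == 1]) / 2
    f_u <- mean(gj[y[cc] == 0]) / 2
    if (converged) {
      or <- exp(est)
      ci <- exp(est + c(-1, 1) * stats::qnorm(0.975) * se)
      p <- 2 * stats::pnorm(-abs(est / se))
    } else {
      tab <- crude_allele_table(gj, y[cc])
      or <- (tab[1] + 0.5) * (tab[4] + 0.5) / ((tab[2] + 0.5) * (tab[3] + 0.5))
      ci <- c(NA_real_, NA_real_)
      p <- if (is.finite(est) && is.finite(se)) 2 * stats::pnorm(-abs(est / se)) else NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variant_key = colnames(G)[j], effect_allele = vk$alt[j],
      or_point = unname(or), ci_low = ci[1], ci_high = ci[2], p = unname(p),
      f_a = f_a, f_u = f_u, converged = converged,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_key = character(0))
  if (nrow(out)) out$bonferroni_threshold <- bonferroni_threshold(nrow(out))
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  class(out) <- c("assoc_result", class(out))
  out
}

# allele-count 2x2 table: alt/ref alleles in cases and controls
crude_allele_table <- function(g, y) {
  c(alt_case = sum(g[y == 1]), ref_case = sum(2 - g[y == 1]),
    alt_ctrl = sum(g[y == 0]), ref_ctrl = sum(2 - g[y == 0]))
}

# design matrix for the adjustment covariates; errors name all-missing ones
covariate_matrix <- function(samples, covariates) {
  cols <- lapply(covariates, function(v) {
    if (!v %in% names(samples)) {
      stop("covariate not in sample manifest: ", v, call. = FALSE)
    }
    x <- samples[[v]]
    if (v == "sex") x <- as.numeric(x == "F")
    x <- as.numeric(x)
    if (all(is.na(x))) stop("covariate all-missing: ", v, call. = FALSE)
    x
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  X
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %d variants tested, Bonferroni threshold %.3g\n",
              nrow(x), if (nrow(x)) x$bonferroni_threshold[1] else NA))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for `m` variants tested within a stratum.
#'
#' @param m Number of variants tested (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-variant threshold.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (length(m) != 1 || is.na(m) || m < 1) {
    stop("m must be a positive count", call. = FALSE)
  }
  alpha / m
}

#' One-sided Fisher exact test for carrier enrichment in cases
#'
#' Tests the 2x2 carrier table (carrier/non-carrier by case/control) for
#' enrichment of carriers among cases via the exact hypergeometric tail
#' (one-sided, greater in cases), reporting the conditional
#' maximum-likelihood odds ratio.
#'
#' @param k_case,n_case Carriers and total among cases.
#' @param k_ctrl,n_ctrl Carriers and total among controls.
#' @return List with `p`, `odds_ratio` and the underlying `table`.
#' @export
fisher_carrier_enrichment <- function(k_case, n_case, k_ctrl, n_ctrl) {
  if (n_case <= 0 || n_ctrl <= 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  stopifnot(k_case >= 0, k_case <= n_case, k_ctrl >= 0, k_ctrl <= n_ctrl)
  tab <- matrix(c(k_case, n_case - k_case, k_ctrl, n_ctrl - k_ctrl), 2,
                dimnames = list(c("carrier", "non_carrier"),
                                c("case", "control")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(p = unname(ft$p.value), odds_ratio = unname(ft$estimate), table = tab)
}

#' Demographic summary of variant carriers
#'
#' Family-history percentages are computed over all carriers; onset
#' percentages over carriers with an age at onset (AAO) available.
#' Late onset means AAO at or above the cutoff: conventionally 50 years
#' for PD and 65 years for AD/DLB.
#'
#' @param samples Sample manifest rows for the carriers.
#' @param aao_cutoff Late-onset AAO cutoff in years.
#' @return List of class `carrier_summary` with counts, one-decimal
#'   percentages, sex counts and age means.
#' @export
summarize_carriers <- function(samples, aao_cutoff = 50) {
  if (!nrow(samples)) stop("carrier set is empty", call. = FALSE)
  n <- nrow(samples)
  fh <- samples$family_history
  n_yes <- sum(fh == "yes"); n_no <- sum(fh == "no")
  n_unk <- sum(fh == "unknown")
  aao <- samples$aao_years
  with_aao <- sum(!is.na(aao))
  late <- sum(aao >= aao_cutoff, na.rm = TRUE)
  structure(list(
    n_carriers = n,
    n_family_history_yes = n_yes, n_family_history_no = n_no,
    n_family_history_unknown = n_unk,
    pct_family_history = round(100 * n_yes / n, 1),
    pct_no_family_history = round(100 * n_no / n, 1),
    n_with_aao = with_aao, n_late_onset = late,
    pct_late_onset = if (with_aao > 0) round(100 * late / with_aao, 1) else NA_real_,
    aao_cutoff = aao_cutoff,
    n_female = sum(samples$sex == "F"), n_male = sum(samples$sex == "M"),
    mean_age = mean(samples$age_years, na.rm = TRUE),
    mean_aao = mean(aao, na.rm = TRUE)
  ), class = "carrier_summary")
}

#' @export
print.carrier_summary <- function(x, ...) {
  cat(sprintf(
    "<carrier_summary> %d carriers; family history yes %d (%s%%), no %d (%s%%), unknown %d\n",
    x$n_carriers, x$n_family_history_yes, format_pct(x$pct_family_history),
    x$n_family_history_no, format_pct(x$pct_no_family_history),
    x$n_family_history_unknown))
  if (x$n_with_aao > 0) {
    cat(sprintf("  AAO available for %d; late-onset (AAO >= %g) %d (%s%%)\n",
                x$n_with_aao, x$aao_cutoff, x$n_late_onset,
                format_pct(x$pct_late_onset)))
  }
  invisible(x)
}
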