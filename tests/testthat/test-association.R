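test_that("Bonferroni threshold is alpha over the tested-variant count", {
  expect_equal(bonferroni_threshold(100), 5e-4)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(format_af(bonferroni_threshold(22)), "2.27E-03")
  expect_error(bonferroni_threshold(0), "positive")
})

test_that("one-sided Fisher enrichment matches hypergeometric enumeration", {
  got <- fisher_carrier_enrichment(4, 1793, 0, 346)
  want <- enum_fisher_greater(4, 1793, 0, 346)
  expect_equal(got$p, want, tolerance = 1e-12)
  expect_equal(round(want, 2), 0.49)

  expect_equal(fisher_carrier_enrichment(0, 100, 0, 100)$p, 1)
  expect_error(fisher_carrier_enrichment(1, 0, 0, 10), "non-empty")

  set.seed(21)
  for (i in 1:200) {
    n1 <- sample(1:40, 1); n2 <- sample(1:40, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(fisher_carrier_enrichment(k1, n1, k2, n2)$p,
                 enum_fisher_greater(k1, n1, k2, n2), tolerance = 1e-12)
  }
})

test_that("Fisher p is invariant to swapping groups with flipped tail", {
  # enrichment of carriers in cases == depletion of carriers in controls
  p1 <- fisher_carrier_enrichment(7, 40, 2, 35)$p
  tab <- matrix(c(2, 33, 7, 33), 2)
  p2 <- stats::fisher.test(tab, alternative = "less")$p.value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("carrier summaries compute the published percentage conventions", {
  ids <- paste0("C", 1:86)
  fh <- c(rep("yes", 25), rep("no", 45), rep("unknown", 16))
  aao <- c(rep(60, 35), rep(40, 17), rep(NA, 34))
  samples <- tiny_samples(ids, "PD", aao = NA, family_history = "unknown")
  samples$family_history <- fh
  samples$aao_years <- aao
  cs <- summarize_carriers(samples, aao_cutoff = 50)
  expect_equal(cs$n_carriers, 86)
  expect_equal(cs$pct_family_history, 29.1)
  expect_equal(cs$pct_no_family_history, 52.3)
  expect_equal(cs$n_with_aao, 52)
  expect_equal(cs$pct_late_onset, 67.3)
  # zero carriers with the attribute -> 0.0%
  none <- summarize_carriers(tiny_samples("X1", "PD",
                                          family_history = "no"), 50)
  expect_equal(none$pct_family_history, 0)
  expect_error(summarize_carriers(samples[0, ]), "empty")
})

test_that("monomorphic variants are skipped and separation is flagged", {
  set.seed(30)
  n <- 120
  ids <- paste0("S", 1:n)
  samples <- tiny_samples(ids, rep(c("PD", "control"), each = n / 2))
  samples$age_years <- rnorm(n, 65, 5)
  for (k in 1:10) samples[[paste0("PC", k)]] <- rnorm(n)
  dos <- cbind(mono = rep(1L, n),
               ok = rbinom(n, 2, 0.3),
               sep = as.integer(c(rbinom(n / 2, 1, 0.3), rep(0, n / 2))))
  rownames(dos) <- ids
  colnames(dos) <- sprintf("11:%d:A:G", 1:3)
  res <- logistic_assoc(genotype_matrix(dos), samples)
  expect_equal(attr(res, "skipped")$variant_key, "11:1:A:G")
  expect_equal(attr(res, "skipped")$reason, "monomorphic")
  expect_equal(nrow(res), 2)
  sep_row <- res[res$variant_key == "11:3:A:G", ]
  expect_false(sep_row$converged)
  expect_true(is.finite(sep_row$or_point))   # crude allelic OR fallback
  ok_row <- res[res$variant_key == "11:2:A:G", ]
  expect_true(ok_row$converged)
  expect_true(ok_row$ci_low <= ok_row$or_point &&
                ok_row$or_point <= ok_row$ci_high)
  expect_equal(res$bonferroni_threshold, rep(0.025, 2))
})

test_that("effect-allele frequencies agree with allele statistics", {
  cfg <- sim_config(seed = 31, n_cases = 150, n_controls = 150,
                    n_background_variants = 10, planted_caseonly = NULL)
  cc <- simulate_case_control(cfg)
  res <- logistic_assoc(cc$genotypes, cc$samples)
  cases <- cc$samples$sample_id[cc$samples$phenotype != "control"]
  ctrls <- cc$samples$sample_id[cc$samples$phenotype == "control"]
  st_ca <- compute_allele_stats(cc$genotypes, cases)
  st_co <- compute_allele_stats(cc$genotypes, ctrls)
  i <- match(res$variant_key, st_ca$variant_key)
  expect_equal(res$f_a, st_ca$af[i])
  expect_equal(res$f_u, st_co$af[match(res$variant_key, st_co$variant_key)])
})

test_that("zero-effect covariates reproduce the covariate-free fit", {
  set.seed(32)
  n <- 400
  ids <- paste0("S", 1:n)
  samples <- tiny_samples(ids, sample(c("PD", "control"), n, TRUE))
  # constant age and PCs = zero-information covariates aside from sex
  samples$sex <- "M"
  dos <- matrix(rbinom(n, 2, 0.25), n, 1,
                dimnames = list(ids, "11:5:A:G"))
  G <- genotype_matrix(dos)
  with_cov <- logistic_assoc(G, samples,
                             covariates = c("age_years", paste0("PC", 1:10)))
  y <- as.integer(samples$phenotype != "control")
  free <- stats::glm(y ~ dos[, 1], family = stats::binomial())
  expect_equal(log(with_cov$or_point), unname(coef(free)[2]),
               tolerance = 1e-6)
  # an all-missing covariate is a named error
  samples$age_years <- NA_real_
  expect_error(logistic_assoc(G, samples), "age_years")
})

test_that("carrier frequency is carriers over individuals", {
  expect_equal(carrier_frequency(4, 1793), 4 / 1793)
  expect_equal(format_af(carrier_frequency(25, 6781)), "3.69E-03")
  expect_error(carrier_frequency(5, 4), "k <= n")
})
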