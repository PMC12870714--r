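test_that("fixed seed gives identical output across all generators", {
  cfg <- sim_config(seed = 9, n_cases = 30, n_controls = 20,
                    n_background_variants = 10)
  a <- simulate_case_control(cfg); b <- simulate_case_control(cfg)
  expect_identical(a, b)
  fa <- simulate_families(cfg); fb <- simulate_families(cfg)
  expect_identical(fa, fb)
  ra <- simulate_summary_region(cfg); rb <- simulate_summary_region(cfg)
  expect_identical(ra, rb)
  # different seed differs
  expect_false(identical(
    simulate_case_control(sim_config(seed = 10, n_cases = 30,
                                     n_controls = 20,
                                     n_background_variants = 10)), a))
})

test_that("planted case-only variant reproduces the rare carrier pattern", {
  # 3 heterozygous carriers among 5,812 cases, absent from 4,411 controls
  cfg <- sim_config(seed = 2, n_background_variants = 0)
  cc <- simulate_case_control(cfg)
  key <- cc$truth$caseonly_keys
  cases <- cc$samples$sample_id[cc$samples$phenotype != "control"]
  ctrls <- cc$samples$sample_id[cc$samples$phenotype == "control"]
  st_ca <- compute_allele_stats(cc$genotypes, cases)
  st_co <- compute_allele_stats(cc$genotypes, ctrls)
  i <- match(key, st_ca$variant_key)
  expect_equal(st_ca$het_count[i], 3)
  expect_equal(st_ca$hom_count[i], 0)
  expect_equal(format_af(st_ca$af[i]), "2.58E-04")
  expect_equal(st_co$mac[match(key, st_co$variant_key)], 0)
  expect_equal(st_ca$zygosity[i], "het (3), hom (0)")
})

test_that("null association plant leaves case/control frequencies equal", {
  cfg <- sim_config(seed = 4, n_cases = 2000, n_controls = 2000,
                    n_background_variants = 0, planted_caseonly = NULL,
                    planted_assoc = data.frame(maf = 0.2, odds_ratio = 1.0))
  cc <- simulate_case_control(cfg)
  key <- cc$truth$assoc$variant_key
  g <- unclass(cc$genotypes)[, key]
  is_case <- cc$samples$phenotype != "control"
  f_a <- mean(g[is_case]) / 2
  f_u <- mean(g[!is_case]) / 2
  # binomial sampling error on the AF difference
  se <- sqrt(0.2 * 0.8 * (1 / (2 * 2000) + 1 / (2 * 2000)))
  expect_lt(abs(f_a - f_u), 4 * se)
})

test_that("planted odds ratio is recovered by Monte Carlo", {
  # 200 seeded replicates of a maf 0.1, OR 2 plant at 5,000/5,000: the
  # mean crude allelic OR estimate recovers the plant within 5%
  ors <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = 1000 + s, n_cases = 5000, n_controls = 5000,
                      n_background_variants = 0, planted_caseonly = NULL,
                      planted_assoc = data.frame(maf = 0.1, odds_ratio = 2))
    cc <- simulate_case_control(cfg)
    g <- unclass(cc$genotypes)[, 1]
    y <- cc$samples$phenotype != "control"
    (sum(g[y]) * sum(2 - g[!y])) / (sum(2 - g[y]) * sum(g[!y]))
  }, numeric(1))
  expect_lt(abs(mean(ors) - 2), 0.1)
})

test_that("planted family structure matches configuration", {
  cfg <- sim_config(seed = 6, planted_families = data.frame(
    n_members = c(2L, 3L), n_pd_cases = c(2L, 3L),
    segregating = c(TRUE, FALSE),
    extra_known_pd_variant = c(TRUE, FALSE)))
  fs <- simulate_families(cfg)
  # both members of the segregating duo are heterozygous carriers
  seg <- fs$truth$segregating_keys
  mem1 <- fs$truth$families[[1]]
  expect_equal(unname(unclass(fs$genotypes)[mem1, seg]), c(1L, 1L))
  # one kinship pair for a duo, all pairs above the second-degree cutoff
  p1 <- fs$pairs[fs$pairs$id1 %in% mem1 | fs$pairs$id2 %in% mem1, ]
  expect_equal(nrow(p1), 1)
  expect_true(all(fs$pairs$kinship > 0.0884))
  # non-segregating family: at least one PD member lacks the variant
  nonseg <- fs$truth$nonsegregating_keys
  mem2 <- fs$truth$families[[2]]
  expect_true(any(unclass(fs$genotypes)[mem2, nonseg] == 0))
  # co-planted known-PD-gene variant is carried by the affected duo
  known <- fs$truth$known_pd_keys
  expect_equal(unname(unclass(fs$genotypes)[mem1, known]), c(1L, 1L))
})

test_that("null summary region has standard-normal z and a causal plant does not", {
  cfg <- sim_config(seed = 8, region_spec = list(
    n_snps = 400L, causal_index = 1L, causal_beta = 0,
    n = 100000L, maf_range = c(0.05, 0.5)))
  reg <- simulate_summary_region(cfg)
  z <- reg$beta / reg$se
  ks <- stats::ks.test(z, "pnorm")
  expect_gt(ks$p.value, 0.01)
  expect_equal(reg$se, 1 / sqrt(2 * reg$n * reg$maf * (1 - reg$maf)))
})

test_that("planted het count beyond the case pool is rejected", {
  expect_error(sim_config(n_cases = 2, planted_caseonly = data.frame(
    consequence_class = "missense", cadd = 25, case_het_count = 3L)),
    "het count")
  expect_error(sim_config(planted_families = data.frame(
    n_members = 2L, n_pd_cases = 3L, segregating = TRUE,
    extra_known_pd_variant = FALSE)), "more PD cases")
  expect_error(sim_config(region_spec = list(n_snps = 10L, causal_index = 11L,
                                             causal_beta = 1, n = 100L,
                                             maf_range = c(0.1, 0.2))),
               "causal_index")
})

test_that("the autoregressive switch correlates adjacent background variants", {
  base <- sim_config(seed = 15, n_cases = 800, n_controls = 0,
                     n_background_variants = 30, planted_caseonly = NULL)
  ld <- sim_config(seed = 15, n_cases = 800, n_controls = 0,
                   n_background_variants = 30, planted_caseonly = NULL,
                   ld_rho = 0.9)
  G0 <- unclass(simulate_case_control(base)$genotypes)
  G1 <- unclass(simulate_case_control(ld)$genotypes)
  lag_cor <- function(G) {
    mean(vapply(seq_len(ncol(G) - 1), function(j) {
      suppressWarnings(cor(G[, j], G[, j + 1]))
    }, numeric(1)), na.rm = TRUE)
  }
  expect_gt(lag_cor(G1), 0.5)
  expect_lt(abs(lag_cor(G0)), 0.1)
  expect_error(sim_config(ld_rho = 1.2), "ld_rho")
})
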