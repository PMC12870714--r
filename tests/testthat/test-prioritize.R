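test_that("allele statistics ignore missing genotypes", {
  G <- tiny_genotypes()
  st <- compute_allele_stats(G)
  expect_equal(st$n_nonmissing, c(3L, 2L, 3L, 2L))
  expect_equal(st$mac, c(0L, 2L, 3L, 1L))
  expect_equal(st$af, c(0, 0.5, 0.5, 0.25))
  expect_equal(st$zygosity[1], "het (0), hom (0)")
  expect_equal(st$zygosity[3], "het (1), hom (1)")
  expect_error(compute_allele_stats(G, group = "nobody"), "empty")
})

test_that("allele statistics match an element-wise recount on random input", {
  set.seed(12)
  dos <- matrix(sample(c(0:2, NA), 120, replace = TRUE,
                       prob = c(.5, .25, .15, .1)), 20, 6)
  rownames(dos) <- paste0("S", 1:20)
  colnames(dos) <- sprintf("11:%d:A:G", 1:6)
  G <- genotype_matrix(dos)
  grp <- paste0("S", sample(20, 11))
  st <- compute_allele_stats(G, grp)
  for (j in 1:6) {
    col <- dos[grp, j]
    expect_equal(st$n_nonmissing[j], sum(!is.na(col)))
    expect_equal(st$het_count[j], sum(col == 1, na.rm = TRUE))
    expect_equal(st$hom_count[j], sum(col == 2, na.rm = TRUE))
    expect_equal(st$mac[j], st$het_count[j] + 2 * st$hom_count[j])
    expect_equal(st$af[j], st$mac[j] / (2 * st$n_nonmissing[j]))
  }
})

test_that("disease-causing cascade keeps the case-only damaging pattern", {
  keys <- sprintf("11:%d:A:G", 1:4)
  make_stats <- function(mac, n = 5812) {
    data.frame(variant_key = keys, stratum = "s", n_nonmissing = n,
               mac = mac, af = mac / (2 * n), het_count = mac, hom_count = 0,
               zygosity = sprintf("het (%d), hom (0)", mac),
               stringsAsFactors = FALSE)
  }
  ann <- tiny_annotations(keys)
  ann$cadd <- c(27.3, 27.3, 15, 27.3)
  ann$consequence_class <- c("missense", "missense", "missense", "synonymous")
  # variant 1: the retained pattern; 2: one control carrier; 3: low CADD;
  # 4: synonymous
  got <- filter_disease_causing(make_stats(c(3, 3, 3, 3)),
                                make_stats(c(0, 1, 0, 0), n = 4411), ann)
  expect_equal(got$variant_key, keys[1])
  expect_equal(got$case_maf, "2.58E-04")
  # case MAC below 2 removed
  got2 <- filter_disease_causing(make_stats(c(1, 3, 3, 3)),
                                 make_stats(c(0, 0, 0, 0), n = 4411), ann)
  expect_false(keys[1] %in% got2$variant_key)
  # un-annotated variants reported, not dropped silently
  got3 <- filter_disease_causing(make_stats(c(3, 3, 3, 3)),
                                 make_stats(c(0, 0, 0, 0), n = 4411),
                                 ann[-2, ])
  expect_equal(attr(got3, "skipped"), keys[2])
})

test_that("only planted case-only variants survive the cascade", {
  cfg <- sim_config(seed = 13, n_cases = 600, n_controls = 500,
                    n_background_variants = 500,
                    planted_caseonly = data.frame(
                      consequence_class = rep("missense", 5),
                      cadd = c(27.3, 22, 35, 25, 30),
                      case_het_count = c(3L, 2L, 2L, 4L, 2L)))
  cc <- simulate_case_control(cfg)
  cases <- cc$samples$sample_id[cc$samples$phenotype != "control"]
  ctrls <- cc$samples$sample_id[cc$samples$phenotype == "control"]
  got <- filter_disease_causing(
    compute_allele_stats(cc$genotypes, cases),
    compute_allele_stats(cc$genotypes, ctrls), cc$annotations)
  expect_setequal(got$variant_key, cc$truth$caseonly_keys)
})

test_that("cascade is monotone: adding criteria never enlarges the set", {
  cfg <- sim_config(seed = 14, n_cases = 300, n_controls = 200,
                    n_background_variants = 80)
  cc <- simulate_case_control(cfg)
  cases <- cc$samples$sample_id[cc$samples$phenotype != "control"]
  ctrls <- cc$samples$sample_id[cc$samples$phenotype == "control"]
  st_ca <- compute_allele_stats(cc$genotypes, cases)
  st_co <- compute_allele_stats(cc$genotypes, ctrls)
  loose <- filter_criteria(cadd_min = 1e-9, mac_min = 1,
                           allowed_classes = consequence_classes(),
                           case_only = FALSE)
  prev <- filter_disease_causing(st_ca, st_co, cc$annotations, loose)
  tighter <- list(
    filter_criteria(cadd_min = 1e-9, mac_min = 1,
                    allowed_classes = consequence_classes()),
    filter_criteria(mac_min = 1, allowed_classes = consequence_classes()),
    filter_criteria(allowed_classes = consequence_classes()),
    filter_criteria())
  for (crit in tighter) {
    cur <- filter_disease_causing(st_ca, st_co, cc$annotations, crit)
    expect_true(all(cur$variant_key %in% prev$variant_key))
    prev <- cur
  }
  # every survivor has case MAC >= 2
  final <- filter_disease_causing(st_ca, st_co, cc$annotations)
  expect_true(all(final$mac_case >= 2))
})

test_that("family-track filter keeps LOF and damaging missense below 1% AF", {
  keys <- sprintf("11:%d:C:T", 1:6)
  ann <- tiny_annotations(keys)
  ann$consequence_class <- c("missense", "missense", "synonymous",
                             "stopgain", "frameshift", "missense")
  ann$cadd <- c(28.6, 15, 25, 5, NA, 30)
  ann$af_EUR <- c(5e-4, 5e-4, 5e-4, 5e-4, NA, 0.05)
  got <- filter_family_damaging(ann, "EUR")
  # damaging missense kept; low-CADD missense and synonymous dropped;
  # LOF kept regardless of CADD; missing AF treated as 0 (kept);
  # common damaging missense dropped
  expect_setequal(got$variant_key, keys[c(1, 4, 5)])
  expect_error(filter_family_damaging(ann, "KLINGON"), "ancestry")
  ann2 <- ann[, setdiff(names(ann), "af_EUR")]
  expect_error(filter_family_damaging(ann2, "EUR"), "af_EUR")
})

test_that("novel/known labels follow exact key set membership", {
  keys <- c("11:121514282:A:G", "11:121625182:G:T", "11:121570255:G:A")
  known <- c("11:121514282:A:G", "11:121625182:G:T")
  expect_equal(flag_known(keys, known), c("known", "known", "novel"))
  # duplicates in the list behave as the deduplicated set
  expect_equal(flag_known(keys, rep(known, 3)), flag_known(keys, known))
  expect_equal(flag_known(keys, character(0)), rep("novel", 3))
})

test_that("frequencies render with three significant digits", {
  expect_equal(format_af(3 / (2 * 5812)), "2.58E-04")
  expect_equal(format_af(0), "0")
  expect_equal(format_af(c(0.05, 1)), c("5.00E-02", "1.00E+00"))
})
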