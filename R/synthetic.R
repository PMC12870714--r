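## Seeded synthetic-cohort generator. Emulates the statistical structure the
## downstream stages assume: case-control strata with planted case-only
## damaging variants and planted association odds ratios, small pedigrees
## with fully-segregating rare damaging variants, and a summary-statistic
## region with a single causal signal. One ancestry per simulated stratum;
## multi-ancestry runs are a loop over strata.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator, with defaults
#' mirroring the well-powered single-stratum setting used throughout the
#' package: a European-ancestry case-control stratum of 5,812 cases and
#' 4,411 controls, one planted case-only missense variant (CADD 27.3,
#' 3 heterozygous carriers, the classic rare case-only pattern), and small
#' families of which two fully segregate a rare damaging variant.
#'
#' @param seed Integer seed; fixed seed implies identical output.
#' @param ancestry Ancestry label for the stratum (see [ancestry_labels()]).
#' @param case_phenotype Phenotype label assigned to cases.
#' @param n_cases,n_controls Stratum sample sizes.
#' @param n_background_variants Number of background variants drawn
#'   binomially at their allele frequency, independent of phenotype; half
#'   common (MAF 0.05-0.4, any consequence), half rare and benign
#'   (CADD < 15).
#' @param planted_caseonly Data frame with columns `consequence_class`,
#'   `cadd`, `case_het_count`: variants heterozygous in exactly
#'   `case_het_count` cases and absent from controls.
#' @param planted_assoc Data frame with columns `maf`, `odds_ratio`:
#'   variants drawn retrospectively from a logistic disease model with the
#'   stated per-allele odds ratio (covariates have null effects).
#' @param ld_rho Autoregressive correlation (Gaussian copula, lag-1)
#'   between adjacent background variants; 0 (the default) gives
#'   independent Hardy-Weinberg draws. A stress-test switch for the burden
#'   machinery, not a realistic haplotype model.
#' @param planted_families Data frame with columns `n_members`,
#'   `n_pd_cases`, `segregating`, `extra_known_pd_variant`; each row is one
#'   family sharing kinship 0.25 among members.
#' @param n_family_background Common synonymous background variants typed in
#'   family members.
#' @param n_unrelated_cases,n_unrelated_controls Size of the unrelated
#'   case-control cohort genotyped alongside the families, used for carrier
#'   enrichment testing of prioritized variants (defaults mirror a small
#'   single-ancestry stratum: 1,793 cases, 346 controls).
#' @param unrelated_case_carriers,unrelated_control_carriers Heterozygous
#'   carriers of each segregating family variant planted in the unrelated
#'   cases / controls.
#' @param region_spec List with `n_snps`, `causal_index`, `causal_beta`,
#'   `n`, `maf_range` for the summary-statistic region generator.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       ancestry = "EUR",
                       case_phenotype = "AD",
                       n_cases = 5812L,
                       n_controls = 4411L,
                       n_background_variants = 200L,
                       planted_caseonly = data.frame(
                         consequence_class = "missense",
                         cadd = 27.3,
                         case_het_count = 3L),
                       planted_assoc = NULL,
                       ld_rho = 0,
                       planted_families = data.frame(
                         n_members = c(2L, 3L, 4L),
                         n_pd_cases = c(2L, 3L, 2L),
                         segregating = c(TRUE, TRUE, FALSE),
                         extra_known_pd_variant = c(TRUE, FALSE, FALSE)),
                       n_family_background = 20L,
                       n_unrelated_cases = 1793L,
                       n_unrelated_controls = 346L,
                       unrelated_case_carriers = 4L,
                       unrelated_control_carriers = 0L,
                       region_spec = list(n_snps = 200L, causal_index = 1L,
                                          causal_beta = 0.0195,
                                          n = 487511L,
                                          maf_range = c(0.05, 0.5))) {
  assert_ancestry(ancestry)
  assert_phenotype(case_phenotype)
  stopifnot(n_cases >= 0, n_controls >= 0, n_background_variants >= 0,
            n_family_background >= 0,
            unrelated_case_carriers <= n_unrelated_cases,
            unrelated_control_carriers <= n_unrelated_controls)
  if (!is.null(planted_caseonly) && nrow(planted_caseonly)) {
    assert_consequence(planted_caseonly$consequence_class)
    if (any(planted_caseonly$case_het_count > n_cases)) {
      stop("planted case-only het count exceeds n_cases", call. = FALSE)
    }
  }
  if (!is.null(planted_assoc) && nrow(planted_assoc)) {
    stopifnot(all(planted_assoc$odds_ratio > 0),
              all(planted_assoc$maf > 0 & planted_assoc$maf < 1))
  }
  if (!is.null(planted_families) && nrow(planted_families)) {
    if (any(planted_families$n_pd_cases > planted_families$n_members)) {
      stop("planted family has more PD cases than members", call. = FALSE)
    }
    if (any(planted_families$n_members < 1)) {
      stop("planted family must have at least one member", call. = FALSE)
    }
  }
  stopifnot(ld_rho >= 0, ld_rho < 1)
  rs <- region_spec
  if (!is.null(rs)) {
    stopifnot(rs$n_snps >= 2)
    if (rs$causal_index < 1 || rs$causal_index > rs$n_snps) {
      stop("region_spec: causal_index out of range", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), ancestry = ancestry,
                 case_phenotype = case_phenotype,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_background_variants = as.integer(n_background_variants),
                 planted_caseonly = planted_caseonly,
                 planted_assoc = planted_assoc,
                 ld_rho = ld_rho,
                 planted_families = planted_families,
                 n_family_background = as.integer(n_family_background),
                 n_unrelated_cases = as.integer(n_unrelated_cases),
                 n_unrelated_controls = as.integer(n_unrelated_controls),
                 unrelated_case_carriers = as.integer(unrelated_case_carriers),
                 unrelated_control_carriers = as.integer(unrelated_control_carriers),
                 region_spec = region_spec),
            class = "sim_config")
}

# Distinct ref/alt pair for position i, deterministic given the RNG stream.
random_alleles <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  list(ref = ref, alt = unname(alt))
}

# Covariate block shared by both genotype simulators: sex ~ Bernoulli(0.5),
# age ~ Normal(65, 10) truncated at 18 years, PCs ~ Normal(0, 1).
simulate_covariates <- function(ids, phenotype, ancestry) {
  n <- length(ids)
  age <- pmax(18, stats::rnorm(n, 65, 10))
  is_case <- phenotype != "control"
  aao <- ifelse(is_case, pmax(18, age - stats::rexp(n, 1 / 5)), NA_real_)
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  fh <- ifelse(is_case,
               sample(c("yes", "no", "unknown"), n, replace = TRUE,
                      prob = c(0.29, 0.52, 0.19)),
               sample(c("no", "unknown"), n, replace = TRUE,
                      prob = c(0.8, 0.2)))
  cbind(data.frame(sample_id = ids, ancestry = ancestry,
                   phenotype = phenotype,
                   sex = sample(c("M", "F"), n, replace = TRUE),
                   age_years = round(age, 1),
                   aao_years = round(aao, 1),
                   family_history = fh, stringsAsFactors = FALSE),
        as.data.frame(round(pcs, 4)))
}

#' Simulate a case-control stratum
#'
#' Background variants are drawn binomially (Hardy-Weinberg, no linkage
#' disequilibrium) at their allele frequency independent of phenotype.
#' Planted case-only variants receive exactly the configured heterozygote
#' count among cases and zero alternate alleles in controls. Planted
#' association variants are sampled retrospectively from a logistic disease
#' model with the configured per-allele odds ratio, so the case-control
#' conditional odds ratio equals the plant exactly; covariates are
#' independent of genotype (null effects).
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` ([genotype_matrix()]), `samples` (manifest
#'   data frame), `annotations` (annotation data frame) and `truth` (keys of
#'   planted variants and their parameters).
#' @export
simulate_case_control <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_ca <- config$n_cases
  n_co <- config$n_controls
  n <- n_ca + n_co
  ids <- sprintf("S%05d", seq_len(n))
  phen <- rep(c(config$case_phenotype, "control"), c(n_ca, n_co))
  samples <- simulate_covariates(ids, phen, config$ancestry)

  n_bg <- config$n_background_variants
  pc <- config$planted_caseonly
  pa <- config$planted_assoc
  n_pc <- if (is.null(pc)) 0L else nrow(pc)
  n_pa <- if (is.null(pa)) 0L else nrow(pa)
  m <- n_bg + n_pc + n_pa
  pos <- 121450000L + 50L * seq_len(m)
  al <- random_alleles(m)
  keys <- variant_key("11", pos, al$ref, al$alt)

  dos <- matrix(0L, n, m, dimnames = list(ids, keys))
  ann <- data.frame(
    variant_key = keys,
    rsid = sprintf("rs9%07d", seq_len(m)),
    gene = "GENE1",
    consequence_class = "other",
    protein_change = sprintf("p.X%d", seq_len(m)),
    cadd = 0, clinvar_class = "VUS", imputation_r2 = NA_real_,
    stringsAsFactors = FALSE)
  af_col <- paste0("af_", config$ancestry)
  ann[[af_col]] <- NA_real_
  truth_af <- numeric(m)

  j <- 0L
  # background: half common any-class, half rare benign
  if (n_bg > 0) {
    n_common <- ceiling(n_bg / 2)
    maf <- c(stats::runif(n_common, 0.05, 0.4),
             stats::runif(n_bg - n_common, 0.001, 0.01))
    cls <- c(sample(consequence_classes(), n_common, replace = TRUE),
             sample(c("synonymous", "other", "missense"), n_bg - n_common,
                    replace = TRUE))
    cadd <- c(stats::runif(n_common, 0, 30),
              stats::runif(n_bg - n_common, 0, 14))
    # a common variant with CADD > 20 can never be case-only at this sample
    # size; a rare background variant is kept benign so the cascade's
    # planted-truth property is deterministic
    cadd[seq_len(n_common)][cls[seq_len(n_common)] %in%
                              c("missense", "stopgain", "frameshift",
                                "splicing")] <-
      stats::runif(sum(cls[seq_len(n_common)] %in%
                         c("missense", "stopgain", "frameshift", "splicing")),
                   21, 35)
    # optional lag-1 Gaussian-copula correlation between adjacent
    # background variants (burden-test stress switch); planted variants
    # stay independent
    latent <- NULL
    if (config$ld_rho > 0) {
      latent <- matrix(0, n, n_bg)
      latent[, 1] <- stats::rnorm(n)
      for (k in seq_len(n_bg)[-1]) {
        latent[, k] <- config$ld_rho * latent[, k - 1] +
          sqrt(1 - config$ld_rho^2) * stats::rnorm(n)
      }
    }
    for (k in seq_len(n_bg)) {
      j <- j + 1L
      dos[, j] <- if (is.null(latent)) stats::rbinom(n, 2L, maf[k]) else
        stats::qbinom(stats::pnorm(latent[, k]), 2L, maf[k])
      ann$consequence_class[j] <- cls[k]
      ann$cadd[j] <- round(cadd[k], 1)
      ann[[af_col]][j] <- maf[k]
      truth_af[j] <- maf[k]
    }
  }
  # planted case-only damaging variants
  pc_keys <- character(0)
  if (n_pc > 0) {
    for (k in seq_len(n_pc)) {
      j <- j + 1L
      carriers <- sample(seq_len(n_ca), pc$case_het_count[k])
      dos[carriers, j] <- 1L
      ann$consequence_class[j] <- pc$consequence_class[k]
      ann$cadd[j] <- pc$cadd[k]
      ann[[af_col]][j] <- signif(stats::runif(1, 1e-6, 1e-4), 3)
      pc_keys <- c(pc_keys, keys[j])
    }
  }
  # planted association variants (retrospective sampling)
  pa_keys <- character(0)
  if (n_pa > 0) {
    for (k in seq_len(n_pa)) {
      j <- j + 1L
      b <- log(pa$odds_ratio[k])
      maf <- pa$maf[k]
      a <- -b * 2 * maf          # centres the logit; OR is invariant to a
      pg <- stats::dbinom(0:2, 2, maf)
      pr <- stats::plogis(a + b * (0:2))
      w_case <- pg * pr
      w_ctrl <- pg * (1 - pr)
      g <- integer(n)
      g[seq_len(n_ca)] <- sample(0:2, n_ca, replace = TRUE,
                                 prob = w_case / sum(w_case))
      g[n_ca + seq_len(n_co)] <- sample(0:2, n_co, replace = TRUE,
                                        prob = w_ctrl / sum(w_ctrl))
      dos[, j] <- g
      ann$consequence_class[j] <- "missense"
      ann$cadd[j] <- round(stats::runif(1, 0, 30), 1)
      ann[[af_col]][j] <- maf
      pa_keys <- c(pa_keys, keys[j])
    }
  }

  list(genotypes = genotype_matrix(dos),
       samples = samples,
       annotations = validate_annotations(ann),
       truth = list(caseonly_keys = pc_keys,
                    assoc = if (n_pa) cbind(data.frame(variant_key = pa_keys),
                                            pa) else NULL))
}

#' Simulate small pedigrees with planted segregating variants
#'
#' Each configured family shares pairwise kinship 0.25 (above the
#' second-degree cutoff 0.0884). A segregating family carries one private
#' rare damaging variant (missense, CADD > 20, reference allele frequency
#' < 1\%) heterozygous in every PD member and absent from family controls;
#' a non-segregating family has one PD member without the variant. An
#' optional known-PD-gene pathogenic variant (e.g. in *GBA1*) is co-planted
#' in the PD members, emulating co-carrier pedigrees. Common synonymous
#' background variants are typed in all members, independent of phenotype.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `samples`, `annotations`, `pairs`
#'   (kinship pair data frame) and `truth` (planted family memberships and
#'   segregating variant keys).
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  pf <- config$planted_families
  if (is.null(pf) || !nrow(pf)) {
    stop("config carries no planted families", call. = FALSE)
  }
  n_fam <- nrow(pf)
  ids <- list(); phen <- list()
  for (i in seq_len(n_fam)) {
    m <- pf$n_members[i]
    ids[[i]] <- sprintf("F%03d_%02d", i, seq_len(m))
    phen[[i]] <- rep(c("PD", "control"), c(pf$n_pd_cases[i],
                                           m - pf$n_pd_cases[i]))
  }
  n_uca <- config$n_unrelated_cases
  n_uco <- config$n_unrelated_controls
  unrel_ids <- sprintf("U%05d", seq_len(n_uca + n_uco))
  unrel_phen <- rep(c("PD", "control"), c(n_uca, n_uco))
  all_ids <- c(unlist(ids), unrel_ids)
  samples <- simulate_covariates(all_ids, c(unlist(phen), unrel_phen),
                                 config$ancestry)

  n_bg <- config$n_family_background
  m_var <- n_fam + sum(pf$extra_known_pd_variant) + n_bg
  pos <- 121640000L + 50L * seq_len(m_var)
  al <- random_alleles(m_var)
  keys <- variant_key("11", pos, al$ref, al$alt)
  dos <- matrix(0L, length(all_ids), m_var, dimnames = list(all_ids, keys))
  af_col <- paste0("af_", config$ancestry)
  ann <- data.frame(
    variant_key = keys, rsid = sprintf("rs8%07d", seq_len(m_var)),
    gene = "GENE1", consequence_class = "synonymous",
    protein_change = sprintf("p.F%d", seq_len(m_var)),
    cadd = 0, clinvar_class = "VUS", imputation_r2 = NA_real_,
    stringsAsFactors = FALSE)
  ann[[af_col]] <- NA_real_

  pairs <- list()
  seg_keys <- character(n_fam)
  known_keys <- character(0)
  j <- 0L
  for (i in seq_len(n_fam)) {
    mem <- ids[[i]]
    ph <- phen[[i]]
    if (length(mem) > 1) {
      cmb <- utils::combn(mem, 2)
      pairs[[i]] <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
                               kinship = 0.25, stringsAsFactors = FALSE)
    }
    # family-private rare damaging variant
    j <- j + 1L
    seg_keys[i] <- keys[j]
    ann$consequence_class[j] <- "missense"
    ann$cadd[j] <- round(stats::runif(1, 21, 35), 1)
    ann[[af_col]][j] <- signif(stats::runif(1, 1e-5, 5e-3), 3)
    carriers <- mem[ph == "PD"]
    if (!pf$segregating[i] && length(carriers) > 0) {
      carriers <- carriers[-1]   # one PD member misses the variant
    }
    dos[carriers, j] <- 1L
    # carriers of segregating variants in the unrelated cohort
    if (pf$segregating[i]) {
      uc <- config$unrelated_case_carriers
      ucc <- config$unrelated_control_carriers
      if (uc > 0) dos[sample(unrel_ids[seq_len(n_uca)], uc), j] <- 1L
      if (ucc > 0) dos[sample(unrel_ids[n_uca + seq_len(n_uco)], ucc), j] <- 1L
    }
    # optional co-planted pathogenic variant in a known PD gene
    if (isTRUE(pf$extra_known_pd_variant[i])) {
      j <- j + 1L
      known_keys <- c(known_keys, keys[j])
      ann$gene[j] <- "GBA1"
      ann$consequence_class[j] <- "missense"
      ann$cadd[j] <- round(stats::runif(1, 25, 35), 1)
      ann$clinvar_class[j] <- "pathogenic"
      ann[[af_col]][j] <- signif(stats::runif(1, 1e-5, 1e-3), 3)
      dos[mem[ph == "PD"], j] <- 1L
    }
  }
  if (n_bg > 0) {
    for (k in seq_len(n_bg)) {
      j <- j + 1L
      maf <- stats::runif(1, 0.05, 0.4)
      dos[, j] <- stats::rbinom(length(all_ids), 2L, maf)
      ann[[af_col]][j] <- maf
      ann$cadd[j] <- round(stats::runif(1, 0, 14), 1)
    }
  }
  list(genotypes = genotype_matrix(dos),
       samples = samples,
       annotations = validate_annotations(ann),
       pairs = do.call(rbind, pairs),
       truth = list(families = ids,
                    segregating_keys = seg_keys[pf$segregating],
                    nonsegregating_keys = seg_keys[!pf$segregating],
                    known_pd_keys = known_keys,
                    unrelated_case_ids = unrel_ids[seq_len(n_uca)],
                    unrelated_control_ids = unrel_ids[n_uca + seq_len(n_uco)]))
}

#' Simulate a GWAS summary-statistic region with one causal signal
#'
#' Non-causal SNPs have effects drawn from their null sampling distribution
#' (`beta ~ Normal(0, se)` with `se = 1/sqrt(2 n maf (1 - maf))`, the
#' standard error of a log-odds effect at a balanced binary trait); the
#' causal SNP has `beta = causal_beta` plus the same sampling noise.
#' P-values come from the two-sided Wald statistic.
#'
#' @param config A [sim_config()] (uses `region_spec`).
#' @return A summary-statistics data frame (see [read_summary_stats()])
#'   with attribute `"causal_key"` naming the planted SNP.
#' @export
simulate_summary_region <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rs <- config$region_spec
  if (is.null(rs)) stop("config carries no region_spec", call. = FALSE)
  set.seed(config$seed + 2L)
  m <- rs$n_snps
  maf <- stats::runif(m, rs$maf_range[1], rs$maf_range[2])
  se <- 1 / sqrt(2 * rs$n * maf * (1 - maf))
  beta <- stats::rnorm(m, 0, se)
  beta[rs$causal_index] <- rs$causal_beta + stats::rnorm(1, 0, se[rs$causal_index])
  p <- 2 * stats::pnorm(-abs(beta / se))
  pos <- 121450000L + 900L * seq_len(m)
  al <- random_alleles(m)
  out <- data.frame(
    variant_key = variant_key("11", pos, al$ref, al$alt),
    beta = beta, se = se, p = pmax(p, 1e-300), n = rs$n, maf = maf,
    stringsAsFactors = FALSE)
  attr(out, "causal_key") <- out$variant_key[rs$causal_index]
  validate_summary_stats(out)
}

#' Write a simulated cohort to disk in the pipeline's file formats
#'
#' @param sim Output of [simulate_case_control()] or [simulate_families()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of written paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    samples = file.path(dir, "samples.tsv"),
    annotations = file.path(dir, "annotations.tsv"))
  write_vcf(sim$genotypes, paths$vcf)
  write_samples(sim$samples, paths$samples)
  write_annotation_table(sim$annotations, paths$annotations)
  if (!is.null(sim$pairs)) {
    paths$related <- file.path(dir, "cohort.related")
    write_related_pairs(sim$pairs, paths$related)
  }
  invisible(paths)
}
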