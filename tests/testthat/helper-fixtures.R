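# Shared fixtures, built in code.

# small deterministic genotype matrix with known counts and missingness
tiny_genotypes <- function() {
  dos <- rbind(
    S1 = c(0L, 1L, 2L, NA),
    S2 = c(0L, 1L, 0L, 0L),
    S3 = c(0L, NA, 1L, 1L)
  )
  colnames(dos) <- c("11:100:A:G", "11:200:C:T", "11:300:G:A", "11:400:T:C")
  genotype_matrix(dos)
}

# minimal annotation table covering given keys
tiny_annotations <- function(keys,
                             consequence = "missense",
                             cadd = 25,
                             af_EUR = 1e-4) {
  n <- length(keys)
  data.frame(
    variant_key = keys,
    rsid = paste0("rs", seq_len(n)),
    gene = "GENE1",
    consequence_class = rep_len(consequence, n),
    protein_change = paste0("p.X", seq_len(n)),
    cadd = rep_len(cadd, n),
    clinvar_class = "VUS",
    imputation_r2 = NA_real_,
    af_EUR = rep_len(af_EUR, n),
    stringsAsFactors = FALSE
  )
}

# sample manifest for given ids/phenotypes with null covariates
tiny_samples <- function(ids, phenotype, ancestry = "EUR",
                         aao = NA_real_, family_history = "unknown") {
  n <- length(ids)
  out <- data.frame(
    sample_id = ids, ancestry = ancestry,
    phenotype = rep_len(phenotype, n),
    sex = rep_len(c("M", "F"), n),
    age_years = 65, aao_years = rep_len(aao, n),
    family_history = rep_len(family_history, n),
    stringsAsFactors = FALSE
  )
  for (k in 1:10) out[[paste0("PC", k)]] <- 0
  out
}

# one-sided hypergeometric enrichment p by explicit enumeration over all
# tables with the same margins (independent of fisher.test)
enum_fisher_greater <- function(k_case, n_case, k_ctrl, n_ctrl) {
  K <- k_case + k_ctrl
  n <- n_case + n_ctrl
  kk <- max(0, K - n_ctrl):min(K, n_case)
  probs <- choose(n_case, kk) * choose(n_ctrl, K - kk) / choose(n, K)
  sum(probs[kk >= k_case])
}
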