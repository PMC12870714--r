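## Per-stratum allele statistics and the two filter cascades: the
## case-control disease-causing-variant cascade (case-only, MAC >= 2,
## CADD > 20, protein-altering or splicing) and the family-track
## rare-damaging filter (LOF or missense CADD > 20, reference AF < 1%).

#' Filtering criteria for the disease-causing-variant cascade
#'
#' Defaults follow the conventional prioritization thresholds: CADD strictly
#' greater than 20 (about the top 1\% most deleterious), a minor allele
#' count of at least 2 in cases (conservative against artifacts),
#' protein-altering or splicing consequence, presence in cases only, and —
#' for the family track — ancestry-specific reference allele frequency
#' below 1\%.
#'
#' @param cadd_min CADD threshold (exclusive).
#' @param mac_min Minimum alternate-allele count in cases (inclusive).
#' @param allowed_classes Consequence classes retained by the case-control
#'   cascade.
#' @param case_only Require zero alternate alleles in controls.
#' @param ref_af_max Reference-AF ceiling for the family track (exclusive).
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(cadd_min = 20, mac_min = 2,
                            allowed_classes = c("missense", "stopgain",
                                                "frameshift", "splicing"),
                            case_only = TRUE, ref_af_max = 0.01) {
  stopifnot(cadd_min > 0, mac_min > 0, ref_af_max > 0)
  assert_consequence(allowed_classes)
  structure(list(cadd_min = cadd_min, mac_min = mac_min,
                 allowed_classes = allowed_classes, case_only = case_only,
                 ref_af_max = ref_af_max),
            class = "filter_criteria")
}

#' Per-variant allele statistics within a sample group
#'
#' Counts are computed over non-missing genotypes only. The allele
#' frequency is `mac / (2 * n_nonmissing)`; the zygosity string follows the
#' `"het (k), hom (k)"` convention of published carrier tables.
#'
#' @param G A [genotype_matrix()].
#' @param group Character vector of sample ids defining the group.
#' @param stratum Optional label stored with the result.
#' @return Data frame with one row per variant: `variant_key`, `stratum`,
#'   `n_nonmissing`, `mac`, `af`, `het_count`, `hom_count`, `zygosity`.
#' @export
compute_allele_stats <- function(G, group = rownames(G), stratum = NA_character_) {
  group <- intersect(group, rownames(G))
  if (!length(group)) {
    stop("empty intersection of group and genotype matrix", call. = FALSE)
  }
  sub <- unclass(G)[group, , drop = FALSE]
  n_nm <- colSums(!is.na(sub))
  het <- colSums(sub == 1L, na.rm = TRUE)
  hom <- colSums(sub == 2L, na.rm = TRUE)
  mac <- het + 2L * hom
  af <- ifelse(n_nm > 0, mac / (2 * n_nm), NA_real_)
  data.frame(variant_key = colnames(G), stratum = stratum,
             n_nonmissing = n_nm, mac = mac, af = af,
             het_count = het, hom_count = hom,
             zygosity = sprintf("het (%d), hom (%d)", het, hom),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Carrier frequency within a group
#'
#' The fraction of individuals carrying at least one alternate allele,
#' `k / n` (not an allele frequency).
#'
#' @param k Number of carriers.
#' @param n Group size.
#' @return `k / n`.
#' @export
carrier_frequency <- function(k, n) {
  stopifnot(all(n > 0), all(k >= 0), all(k <= n))
  k / n
}

#' Disease-causing-variant filter cascade (case-control track)
#'
#' Retains variants that are present only in cases (control allele count
#' zero), have a case minor allele count of at least `mac_min`, CADD
#' strictly above `cadd_min`, and a protein-altering or splicing
#' consequence. The criteria are conjunctive, so their order cannot change
#' the outcome. Variants with allele statistics but no annotation record
#' are reported in the `"skipped"` attribute rather than silently dropped.
#'
#' @param stats_cases,stats_controls Outputs of [compute_allele_stats()]
#'   for the case and control groups of the same stratum.
#' @param annotations Annotation data frame (see [read_annotation_table()]).
#' @param criteria A [filter_criteria()].
#' @return Data frame of retained variants carrying all evidence fields
#'   (case and control counts, CADD, consequence, formatted frequencies),
#'   with skipped un-annotated variant keys in `attr(, "skipped")`.
#' @export
filter_disease_causing <- function(stats_cases, stats_controls, annotations,
                                   criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  m <- merge(stats_cases, stats_controls, by = "variant_key",
             suffixes = c("_case", "_ctrl"))
  if (nrow(m) != nrow(stats_cases) || nrow(m) != nrow(stats_controls)) {
    stop("case and control statistics cover different variant sets",
         call. = FALSE)
  }
  skipped <- setdiff(m$variant_key, annotations$variant_key)
  m <- merge(m, annotations, by = "variant_key")
  keep <- (!criteria$case_only | m$mac_ctrl == 0) &
    m$mac_case >= criteria$mac_min &
    !is.na(m$cadd) & m$cadd > criteria$cadd_min &
    m$consequence_class %in% criteria$allowed_classes
  out <- m[keep, , drop = FALSE]
  out <- out[order(out$variant_key), , drop = FALSE]
  rownames(out) <- NULL
  out$case_maf <- format_af(out$af_case)
  attr(out, "skipped") <- skipped
  out
}

#' Family-track rare-damaging variant filter
#'
#' Retains loss-of-function variants (stopgain, frameshift, splicing)
#' regardless of CADD, plus missense variants with CADD strictly above 20,
#' provided the ancestry-specific reference allele frequency is below 1\%.
#' A missing reference frequency is treated as 0 (an unobserved allele).
#'
#' @param annotations Annotation data frame with an `af_<ancestry>` column.
#' @param ancestry Ancestry label (see [ancestry_labels()]).
#' @param criteria A [filter_criteria()] (`cadd_min`, `ref_af_max` used).
#' @return The retained annotation rows.
#' @export
filter_family_damaging <- function(annotations, ancestry,
                                   criteria = filter_criteria()) {
  assert_ancestry(ancestry)
  af_col <- paste0("af_", ancestry)
  if (!af_col %in% names(annotations)) {
    stop("annotation table has no reference AF column for ancestry ",
         ancestry, " (", af_col, ")", call. = FALSE)
  }
  ref_af <- annotations[[af_col]]
  ref_af[is.na(ref_af)] <- 0
  damaging <- annotations$consequence_class %in% lof_classes() |
    (annotations$consequence_class == "missense" &
       !is.na(annotations$cadd) & annotations$cadd > criteria$cadd_min)
  keep <- damaging & ref_af < criteria$ref_af_max
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label variants as novel or previously reported
#'
#' @param variant_keys Character vector of variant keys.
#' @param known_list Character vector of previously reported variant keys
#'   (duplicates are ignored; matching is by exact key).
#' @return Character vector `"known"`/`"novel"` parallel to `variant_keys`.
#' @export
flag_known <- function(variant_keys, known_list) {
  ifelse(variant_keys %in% unique(known_list), "known", "novel")
}
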