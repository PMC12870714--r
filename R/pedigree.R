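## Kinship-graph pedigree reconstruction, merging with core pedigrees,
## informative-family selection, segregation summaries and prioritization
## of fully-segregating variants.

#' Reconstruct families from kinship pairs
#'
#' Builds a graph whose edges are pairs with kinship strictly above the
#' threshold (0.0884, the conventional second-degree cutoff), after
#' removing individuals already present in core pedigrees, and defines each
#' connected component with at least two members as a family. Because
#' relationship direction cannot be inferred from kinship coefficients,
#' every member is represented as a founder.
#'
#' @param pairs Kinship pair data frame (`id1`, `id2`, `kinship`), one
#'   ancestry at a time.
#' @param threshold Kinship cutoff (exclusive).
#' @param exclude Sample ids to drop (core-pedigree members).
#' @param ancestry Optional ancestry label stored on each family.
#' @return List of `family` objects with source `"inferred"`.
#' @export
infer_families <- function(pairs, threshold = 0.0884, exclude = character(0),
                           ancestry = NA_character_) {
  if (is.null(pairs) || !nrow(pairs)) return(list())
  pairs <- dedup_kinship_pairs(pairs)
  keep <- pairs$kinship > threshold &
    !(pairs$id1 %in% exclude) & !(pairs$id2 %in% exclude)
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(list())
  g <- igraph::graph_from_data_frame(pairs[, c("id1", "id2")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- members[lengths(members) >= 2]
  out <- list()
  for (i in seq_along(members)) {
    out[[i]] <- new_family(sprintf("INF%03d", i), sort(members[[i]]),
                           source = "inferred", ancestry = ancestry)
  }
  out
}

#' Merge core and kinship-inferred family sets
#'
#' Union preserving source labels. Overlapping membership between the two
#' sets is an error (the exclusion rule in [infer_families()] guarantees
#' disjointness when used as intended); family-id collisions are resolved
#' by `core:`/`inf:` prefixes.
#'
#' @param core,inferred Lists of `family` objects.
#' @return Combined list of families.
#' @export
merge_pedigrees <- function(core, inferred) {
  overlap <- intersect(unlist(lapply(core, `[[`, "members")),
                       unlist(lapply(inferred, `[[`, "members")))
  if (length(overlap)) {
    stop("core and inferred families share members: ",
         paste(utils::head(overlap, 10), collapse = ", "), call. = FALSE)
  }
  ids_core <- vapply(core, `[[`, "", "family_id")
  ids_inf <- vapply(inferred, `[[`, "", "family_id")
  clash <- intersect(ids_core, ids_inf)
  if (length(clash)) {
    core <- lapply(core, function(f) {
      if (f$family_id %in% clash) f$family_id <- paste0("core:", f$family_id)
      f
    })
    inferred <- lapply(inferred, function(f) {
      if (f$family_id %in% clash) f$family_id <- paste0("inf:", f$family_id)
      f
    })
  }
  c(core, inferred)
}

#' Select informative families
#'
#' An informative family has at least one PD case and at least two
#' members.
#'
#' @param families List of `family` objects.
#' @param samples Sample manifest covering every member.
#' @return The informative subset of `families`.
#' @export
select_informative <- function(families, samples) {
  Filter(function(fam) {
    idx <- match(fam$members, samples$sample_id)
    if (anyNA(idx)) {
      stop("family ", fam$family_id, ": member(s) without sample record: ",
           paste(fam$members[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    length(fam$members) >= 2 && any(samples$phenotype[idx] == "PD")
  }, families)
}

#' Per-family segregation summary for candidate variants
#'
#' For each candidate variant and family, counts genotyped PD members and
#' carriers among them, genotyped family controls and carriers among
#' those, and attaches any co-occurring known-PD-gene variants carried by
#' family members. A member with a missing genotype at the candidate site
#' is excluded from the genotyped counts (it neither supports nor vetoes
#' segregation).
#'
#' @param family A `family` object.
#' @param G A [genotype_matrix()] covering the family members.
#' @param candidate_keys Candidate variant keys (typically the output of
#'   [filter_family_damaging()]).
#' @param samples Sample manifest (phenotypes of the members).
#' @param known_pd_keys Optional keys of pathogenic variants in known PD
#'   genes, screened for co-occurrence.
#' @return Data frame with one row per candidate variant: carrier and
#'   genotyped counts, zygosity pattern, `segregates` flag and
#'   co-occurring known-variant keys (comma-separated).
#' @export
segregation_summary <- function(family, G, candidate_keys, samples,
                                known_pd_keys = character(0)) {
  mem <- intersect(family$members, rownames(G))
  idx <- match(mem, samples$sample_id)
  is_pd <- samples$phenotype[idx] == "PD"
  pd <- mem[is_pd]; ctrl <- mem[!is_pd]
  co <- character(0)
  known_pd_keys <- intersect(known_pd_keys, colnames(G))
  if (length(known_pd_keys)) {
    carried <- vapply(known_pd_keys, function(k) {
      any(unclass(G)[mem, k] >= 1, na.rm = TRUE)
    }, logical(1))
    co <- known_pd_keys[carried]
  }
  rows <- lapply(candidate_keys, function(key) {
    gp <- unclass(G)[pd, key]
    gc <- if (length(ctrl)) unclass(G)[ctrl, key] else integer(0)
    n_gpd <- sum(!is.na(gp)); n_pdc <- sum(gp >= 1, na.rm = TRUE)
    n_gct <- sum(!is.na(gc)); n_ctc <- sum(gc >= 1, na.rm = TRUE)
    het <- sum(c(gp, gc) == 1, na.rm = TRUE)
    hom <- sum(c(gp, gc) == 2, na.rm = TRUE)
    data.frame(
      variant_key = key, family_id = family$family_id,
      n_genotyped_pd = n_gpd, n_pd_carriers = n_pdc,
      n_genotyped_controls = n_gct, n_control_carriers = n_ctc,
      zygosity = sprintf("het (%d), hom (%d)", het, hom),
      segregates = n_gpd > 0 && n_pdc == n_gpd && n_ctc == 0,
      co_occurring_known_pd_variants = paste(co, collapse = ","),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Prioritize variants that fully segregate in at least one family
#'
#' A variant is prioritized iff in one or more families every genotyped PD
#' member carries at least one alternate allele and no genotyped family
#' control carries it. The result is invariant to the order of families
#' and variants.
#'
#' @param summaries Row-bound output of [segregation_summary()] across
#'   families.
#' @return Sorted character vector of prioritized variant keys.
#' @export
prioritize_segregating <- function(summaries) {
  if (is.null(summaries) || !nrow(summaries)) return(character(0))
  sort(unique(summaries$variant_key[summaries$segregates]))
}
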