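## End-to-end orchestration: run every stage from a plain-text (YAML)
## configuration with a fixed seed, render publication-style tab-separated
## reports, and record a manifest of every threshold and count used.

#' Filter waterfall table
#'
#' Turns a monotone non-increasing sequence of per-stage variant counts
#' into a stage/count/removed table. An increasing count between stages is
#' an internal-consistency error.
#'
#' @param counts Named numeric vector of counts, in stage order.
#' @return Data frame with `stage`, `count`, `removed` (NA for the first
#'   stage).
#' @export
filter_waterfall <- function(counts) {
  if (!length(counts)) stop("no stages", call. = FALSE)
  if (is.null(names(counts))) names(counts) <- paste0("stage", seq_along(counts))
  if (any(diff(counts) > 0)) {
    stop("internal-consistency error: count increases between stages ",
         paste(names(counts)[which(diff(counts) > 0) + 1], collapse = ", "),
         call. = FALSE)
  }
  data.frame(stage = names(counts), count = as.numeric(counts),
             removed = c(NA, -diff(as.numeric(counts))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' All statistical thresholds live here, with the package's standard
#' values as defaults: CADD > 20, case MAC >= 2, kinship > 0.0884,
#' reference AF < 1\%, posterior-probability threshold 0.6, alpha 0.05.
#'
#' @param seed Integer seed propagated to every simulation stage.
#' @param outdir Output directory for reports and the manifest.
#' @param stages Character vector of stages to run, a subset of
#'   `c("prioritize", "assoc", "burden", "families", "finemap")`.
#' @param known_variants Character vector of previously reported variant
#'   keys for novel/known labelling.
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param criteria A [filter_criteria()].
#' @param gene Gene symbol under analysis; candidate variants for the
#'   segregation track are restricted to this gene (the known-PD-gene
#'   screen is not).
#' @param kinship_threshold Kinship cutoff for family inference.
#' @param aao_cutoff Late-onset cutoff in years for carrier summaries.
#' @param finemap_p1,finemap_W Fine-mapping prior parameters.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("varscreen_run_"),
                       stages = c("prioritize", "assoc", "burden",
                                  "families", "finemap"),
                       known_variants = character(0),
                       sim = sim_config(seed = seed),
                       criteria = filter_criteria(),
                       gene = "GENE1",
                       kinship_threshold = 0.0884,
                       aao_cutoff = 50,
                       finemap_p1 = 1e-4, finemap_W = 0.2) {
  stages <- match.arg(stages, c("prioritize", "assoc", "burden",
                                "families", "finemap"), several.ok = TRUE)
  structure(list(seed = as.integer(seed), outdir = outdir, stages = stages,
                 known_variants = known_variants, sim = sim,
                 criteria = criteria, gene = gene,
                 kinship_threshold = kinship_threshold,
                 aao_cutoff = aao_cutoff,
                 finemap_p1 = finemap_p1, finemap_W = finemap_W),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()], with `sim` and
#' `criteria` given as nested maps of [sim_config()] / [filter_criteria()]
#' arguments.
#'
#' @param path Path to a YAML configuration file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), c("seed", "outdir", "stages",
                                      "known_variants", "gene",
                                      "kinship_threshold",
                                      "aao_cutoff", "finemap_p1",
                                      "finemap_W"))]
  if (!is.null(raw$sim)) {
    if (is.null(raw$sim$seed) && !is.null(raw$seed)) raw$sim$seed <- raw$seed
    args$sim <- do.call(sim_config, raw$sim)
  } else if (!is.null(raw$seed)) {
    args$sim <- sim_config(seed = raw$seed)
  }
  if (!is.null(raw$criteria)) args$criteria <- do.call(filter_criteria, raw$criteria)
  do.call(run_config, args)
}

write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the full screening pipeline on synthetic inputs
#'
#' Executes the configured stages in order on a cohort generated by the
#' bundled simulator: case-control variant prioritization (carrier-table
#' report), covariate-adjusted association (association-table report),
#' SKAT-O burden per functional category, family reconstruction with
#' segregation prioritization and carrier enrichment (segregation-table
#' report), and summary-statistic fine-mapping. Identical configuration
#' and seed give byte-identical reports; a YAML manifest records the seed,
#' every threshold used, and the filter waterfall.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list with every stage's in-memory result, the
#'   waterfall, and the paths of written reports.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config, reports = list())
  waterfall <- NULL

  cc <- simulate_case_control(config$sim)
  cases <- cc$samples$sample_id[cc$samples$phenotype != "control"]
  ctrls <- cc$samples$sample_id[cc$samples$phenotype == "control"]

  if ("prioritize" %in% config$stages) {
    st_ca <- compute_allele_stats(cc$genotypes, cases, stratum = "cases")
    st_co <- compute_allele_stats(cc$genotypes, ctrls, stratum = "controls")
    hits <- filter_disease_causing(st_ca, st_co, cc$annotations,
                                   config$criteria)
    crit <- config$criteria
    m <- merge(merge(st_ca, st_co, by = "variant_key",
                     suffixes = c("_case", "_ctrl")),
               cc$annotations, by = "variant_key")
    n0 <- nrow(m)
    n1 <- sum(m$mac_ctrl == 0)
    n2 <- sum(m$mac_ctrl == 0 & m$mac_case >= crit$mac_min)
    n3 <- sum(m$mac_ctrl == 0 & m$mac_case >= crit$mac_min &
                m$cadd > crit$cadd_min)
    n4 <- nrow(hits)
    waterfall <- filter_waterfall(c(annotated = n0, case_only = n1,
                                    mac = n2, cadd = n3,
                                    consequence_class = n4))
    af_col <- paste0("af_", config$sim$ancestry)
    report1 <- data.frame(
      variant = hits$variant_key, rsID = hits$rsid,
      protein_change = hits$protein_change, CADD = hits$cadd,
      case_MAF = format_af(hits$af_case), zygosity = hits$zygosity_case,
      reference_AF = format_af(hits[[af_col]]),
      status = flag_known(hits$variant_key, config$known_variants),
      R2 = hits$imputation_r2, stringsAsFactors = FALSE)
    res$prioritized <- hits
    res$reports$carrier_table <-
      write_report(report1, file.path(config$outdir, "carrier_table.tsv"))
    res$reports$waterfall <-
      write_report(waterfall, file.path(config$outdir, "filter_waterfall.tsv"))
  }

  if ("assoc" %in% config$stages) {
    pooled <- compute_allele_stats(cc$genotypes, stratum = "all")
    exonic <- cc$annotations$consequence_class %in%
      c("missense", "stopgain", "frameshift", "synonymous", "splicing")
    testable <- intersect(
      pooled$variant_key[pooled$mac >= config$criteria$mac_min],
      cc$annotations$variant_key[exonic])
    assoc <- logistic_assoc(cc$genotypes[, testable, drop = FALSE],
                            cc$samples)
    ann_idx <- match(assoc$variant_key, cc$annotations$variant_key)
    report2 <- data.frame(
      variant = assoc$variant_key,
      rsID = cc$annotations$rsid[ann_idx],
      protein_change = cc$annotations$protein_change[ann_idx],
      ancestry = config$sim$ancestry,
      A1 = assoc$effect_allele, P = signif(assoc$p, 3),
      OR_L95_U95 = sprintf("%.2f (%.2f-%.2f)", assoc$or_point,
                           assoc$ci_low, assoc$ci_high),
      bonferroni_threshold = format_af(assoc$bonferroni_threshold),
      F_A = format_af(assoc$f_a), F_U = format_af(assoc$f_u),
      R2 = cc$annotations$imputation_r2[ann_idx], stringsAsFactors = FALSE)
    res$association <- assoc
    res$reports$association_table <-
      write_report(report2, file.path(config$outdir, "association_table.tsv"))
  }

  if ("burden" %in% config$stages) {
    y <- as.integer(cc$samples$phenotype != "control")
    X <- covariate_matrix(cc$samples, c("sex", "age_years", paste0("PC", 1:10)))
    null_fit <- fit_null_model(y, X)
    pooled <- compute_allele_stats(cc$genotypes, stratum = "all")
    categories <- list(
      all_exonic_splicing = c("missense", "stopgain", "frameshift",
                              "synonymous", "splicing"),
      protein_altering = c("missense", "stopgain", "frameshift"),
      missense = "missense", synonymous = "synonymous",
      lof = lof_classes())
    burden_rows <- lapply(names(categories), function(cat) {
      keys <- cc$annotations$variant_key[
        cc$annotations$consequence_class %in% categories[[cat]]]
      keys <- intersect(keys, pooled$variant_key[pooled$mac >= config$criteria$mac_min])
      if (length(keys) < 1) {
        return(data.frame(gene = "GENE1", category = cat, n_variants = 0L,
                          p_skato = NA_real_))
      }
      fit <- skato_test(cc$genotypes[, keys, drop = FALSE], null_fit,
                        gene = "GENE1")
      data.frame(gene = "GENE1", category = cat, n_variants = length(keys),
                 p_skato = fit$p_skato, stringsAsFactors = FALSE)
    })
    res$burden <- do.call(rbind, burden_rows)
    res$reports$burden_table <-
      write_report(res$burden, file.path(config$outdir, "burden_table.tsv"))
  }

  if ("families" %in% config$stages) {
    fs <- simulate_families(config$sim)
    inferred <- infer_families(fs$pairs, config$kinship_threshold,
                               ancestry = config$sim$ancestry)
    merged <- merge_pedigrees(list(), inferred)
    informative <- select_informative(merged, fs$samples)
    candidates <- filter_family_damaging(
      fs$annotations[fs$annotations$gene == config$gene, , drop = FALSE],
      config$sim$ancestry, config$criteria)
    known_keys <- fs$annotations$variant_key[
      fs$annotations$gene != config$gene &
        fs$annotations$clinvar_class %in% c("pathogenic", "likely_pathogenic")]
    summaries <- do.call(rbind, lapply(informative, function(fam) {
      segregation_summary(fam, fs$genotypes, candidates$variant_key,
                          fs$samples, known_keys)
    }))
    prioritized <- prioritize_segregating(summaries)
    fam_members <- unlist(lapply(merged, `[[`, "members"))
    unrel <- setdiff(fs$samples$sample_id, fam_members)
    unrel_pheno <- fs$samples$phenotype[match(unrel, fs$samples$sample_id)]
    u_case <- unrel[unrel_pheno == "PD"]
    u_ctrl <- unrel[unrel_pheno == "control"]
    enrich_rows <- lapply(prioritized, function(key) {
      g_case <- unclass(fs$genotypes)[u_case, key]
      g_ctrl <- unclass(fs$genotypes)[u_ctrl, key]
      k_case <- sum(g_case >= 1, na.rm = TRUE)
      k_ctrl <- sum(g_ctrl >= 1, na.rm = TRUE)
      n_case <- sum(!is.na(g_case)); n_ctrl <- sum(!is.na(g_ctrl))
      fe <- fisher_carrier_enrichment(k_case, n_case, k_ctrl, n_ctrl)
      seg <- summaries[summaries$variant_key == key & summaries$segregates, ,
                       drop = FALSE]
      ann_i <- match(key, fs$annotations$variant_key)
      data.frame(
        variant = key,
        protein_change = fs$annotations$protein_change[ann_i],
        CADD = fs$annotations$cadd[ann_i],
        families_with_carriers = nrow(seg),
        family_members = sum(seg$n_genotyped_pd + seg$n_genotyped_controls),
        pd_case_carriers = sum(seg$n_pd_carriers),
        reference_AF = format_af(
          fs$annotations[[paste0("af_", config$sim$ancestry)]][ann_i]),
        cc_pd = sprintf("%d/%d (%s)", k_case, n_case,
                        format_af(carrier_frequency(k_case, n_case))),
        cc_ctrl = sprintf("%d/%d (%s)", k_ctrl, n_ctrl,
                          format_af(carrier_frequency(k_ctrl, n_ctrl))),
        fisher_p = fe$p, stringsAsFactors = FALSE)
    })
    res$families <- merged
    res$informative <- informative
    res$segregation <- summaries
    res$prioritized_segregating <- prioritized
    res$enrichment <- if (length(enrich_rows)) do.call(rbind, enrich_rows) else NULL
    if (!is.null(res$enrichment)) {
      res$reports$segregation_table <-
        write_report(res$enrichment,
                     file.path(config$outdir, "segregation_table.tsv"))
    }
    write_ped(merged, file.path(config$outdir, "unified_families.ped"))
    res$reports$unified_ped <- file.path(config$outdir, "unified_families.ped")
  }

  if ("finemap" %in% config$stages) {
    region <- simulate_summary_region(config$sim)
    fm <- finemap_region(region, p1 = config$finemap_p1, W = config$finemap_W)
    tab <- as.data.frame(fm)
    tab <- tab[order(-tab$pp), , drop = FALSE]
    res$finemap <- fm
    res$reports$finemap_table <-
      write_report(tab, file.path(config$outdir, "finemap_table.tsv"))
  }

  manifest <- list(
    package = "varscreen",
    version = as.character(utils::packageVersion("varscreen")),
    seed = config$seed,
    stages = config$stages,
    thresholds = list(
      cadd_min = config$criteria$cadd_min,
      mac_min = config$criteria$mac_min,
      allowed_classes = config$criteria$allowed_classes,
      ref_af_max = config$criteria$ref_af_max,
      kinship_threshold = config$kinship_threshold,
      aao_cutoff = config$aao_cutoff,
      finemap_p1 = config$finemap_p1,
      finemap_W = config$finemap_W,
      alpha = 0.05),
    counts = if (!is.null(waterfall)) {
      stats::setNames(as.list(waterfall$count), waterfall$stage)
    } else NULL)
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  res$reports$manifest <- file.path(config$outdir, "manifest.yaml")
  res$waterfall <- waterfall
  invisible(res)
}
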