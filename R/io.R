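## Readers/writers for the external formats the pipeline touches. All
## tabular formats are tab-separated with fixed headers (documented in the
## README); genotypes travel as VCF v4.2 with a GT field; pedigrees as
## PLINK PED (sex/phenotype coded 1/2, -9/0 missing).

## VCF ----------------------------------------------------------------------

#' Read a VCF v4.2 file into a genotype matrix
#'
#' Parses GT fields into alternate-allele dosage counts. Multi-allelic
#' records are split into one variant key per alternate allele; any
#' genotype containing `"."` (e.g. `"./."`) is treated as missing. Variant
#' keys are normalized to `"chrom:pos:ref:alt"` without a `"chr"` prefix;
#' a `"-"` deletion allele is preserved verbatim.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A list with `genotypes` (a [genotype_matrix()]) and
#'   `annotations`, a stub annotation data frame carrying the variant key
#'   and rsID (from the VCF ID column) for later merging with a full
#'   annotation table.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCFv4")) {
    stop("VCF format error at line 1: missing ##fileformat=VCFv4.x header",
         call. = FALSE)
  }
  chrom_at <- which(startsWith(lines, "#CHROM"))
  if (length(chrom_at) != 1L) {
    stop("VCF format error at line ", length(lines),
         ": expected exactly one #CHROM header line", call. = FALSE)
  }
  header <- strsplit(lines[chrom_at], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10L || header[9] != "FORMAT") {
    stop("VCF format error at line ", chrom_at,
         ": #CHROM line must carry FORMAT and at least one sample",
         call. = FALSE)
  }
  sample_ids <- header[-(1:9)]

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  n_var <- nrow(fix)

  keys <- character(0)
  rsid <- character(0)
  cols <- list()
  for (i in seq_len(n_var)) {
    line_no <- chrom_at + i
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    bad <- !grepl("^([ACGT]+|-)$", c(ref, alts))
    if (any(bad)) {
      stop("VCF format error at line ", line_no, ": non-ACGT allele(s) ",
           paste(c(ref, alts)[bad], collapse = ", "), call. = FALSE)
    }
    g <- gt[i, ]
    alleles <- strsplit(g, "[/|]")
    missing <- vapply(alleles, function(a) any(a == "." | is.na(a)), logical(1)) |
      is.na(g)
    for (a in seq_along(alts)) {
      dos <- vapply(alleles, function(x) sum(x == as.character(a)), integer(1))
      dos[missing] <- NA_integer_
      keys <- c(keys, variant_key(fix[i, "CHROM"], fix[i, "POS"], ref, alts[a]))
      id <- fix[i, "ID"]
      rsid <- c(rsid, if (is.na(id) || id == ".") NA_character_ else id)
      cols[[length(cols) + 1L]] <- dos
    }
  }
  dosages <- do.call(cbind, cols)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- keys
  list(
    genotypes = genotype_matrix(dosages),
    annotations = data.frame(variant_key = keys, rsid = rsid,
                             stringsAsFactors = FALSE)
  )
}

#' Write a genotype matrix as VCF v4.2
#'
#' One record per variant key (multi-allelic sites are left split, the
#' inverse of [read_vcf()]'s convention). Dosages are written as unphased
#' GT calls (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @param rsids Optional character vector of rsIDs per variant (`NA` writes
#'   `"."`).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(G, path, rsids = NULL) {
  vk <- parse_variant_key(colnames(G))
  if (is.null(rsids)) rsids <- rep(NA_character_, ncol(G))
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=varscreen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    calls <- ifelse(is.na(g), "./.", gt_codes[as.character(g)])
    writeLines(paste(c(vk$chrom[j], vk$pos[j],
                       ifelse(is.na(rsids[j]), ".", rsids[j]),
                       vk$ref[j], vk$alt[j], ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}

## PLINK PED ----------------------------------------------------------------

#' Construct a family record
#'
#' The pedigree container used across the family track: identifier, member
#' list, source (`"core"` for curated pedigrees, `"inferred"` for
#' kinship-graph components), ancestry, and per-member parent/sex/phenotype
#' codes (PLINK conventions). Members with both parents `"0"` are founders.
#'
#' @param family_id Family identifier.
#' @param members Unique member sample ids.
#' @param source `"core"` or `"inferred"`.
#' @param ancestry Optional ancestry label.
#' @param father,mother Named character vectors of parent ids (`"0"` for
#'   founder), defaulting to all founders.
#' @param sex,phenotype Optional named vectors of PLINK codes.
#' @return An object of class `ped_family`.
#' @export
new_family <- function(family_id, members, source, ancestry = NA_character_,
                       father = NULL, mother = NULL, sex = NULL,
                       phenotype = NULL) {
  if (anyDuplicated(members)) {
    stop("duplicate member ids in family ", family_id, call. = FALSE)
  }
  zero <- stats::setNames(rep("0", length(members)), members)
  if (is.null(father)) father <- zero
  if (is.null(mother)) mother <- zero
  structure(list(
    family_id = as.character(family_id),
    members = as.character(members),
    source = match.arg(source, c("core", "inferred")),
    ancestry = ancestry,
    father = father, mother = mother,
    sex = sex, phenotype = phenotype,
    founder = father == "0" & mother == "0"
  ), class = "ped_family")
}

#' @export
print.ped_family <- function(x, ...) {
  cat(sprintf("<family %s> %d members (%d founders), source=%s\n",
              x$family_id, length(x$members), sum(x$founder), x$source))
  invisible(x)
}

#' Read a PLINK PED/FAM pedigree file
#'
#' Whitespace-delimited, six leading columns: family id, individual id,
#' father, mother, sex (1/2, other codes treated as missing), phenotype
#' (1 unaffected / 2 affected / -9 or 0 missing). A member is a founder iff
#' both parent ids are `"0"`. A non-zero parent id that is not itself
#' listed in the same family is a validation error.
#'
#' @param path Path to a PED/FAM file.
#' @return A list of `family` objects (source `"core"`), one per family id.
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 6L) {
    stop("PED file must have at least 6 columns", call. = FALSE)
  }
  names(tab)[1:6] <- c("fam", "id", "father", "mother", "sex", "phenotype")
  out <- list()
  for (f in unique(tab$fam)) {
    sub <- tab[tab$fam == f, , drop = FALSE]
    parents <- setdiff(c(sub$father, sub$mother), "0")
    absent <- setdiff(parents, sub$id)
    if (length(absent)) {
      stop("PED family ", f, ": parent id(s) referenced but absent: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    out[[f]] <- new_family(
      family_id = f, members = sub$id, source = "core",
      father = stats::setNames(sub$father, sub$id),
      mother = stats::setNames(sub$mother, sub$id),
      sex = stats::setNames(sub$sex, sub$id),
      phenotype = stats::setNames(sub$phenotype, sub$id)
    )
  }
  unname(out)
}

#' Write families as a PLINK PED file
#'
#' @param families List of `family` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(families, path) {
  rows <- lapply(families, function(fam) {
    sex <- if (is.null(fam$sex)) rep("0", length(fam$members)) else fam$sex[fam$members]
    phe <- if (is.null(fam$phenotype)) rep("-9", length(fam$members)) else fam$phenotype[fam$members]
    data.frame(fam = fam$family_id, id = fam$members,
               father = fam$father[fam$members],
               mother = fam$mother[fam$members],
               sex = sex, phenotype = phe, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Kinship pairs ------------------------------------------------------------

#' Read a ".related" kinship pair file
#'
#' Tab-separated with header columns `id1`, `id2`, `kinship`. Pairs are
#' unordered: duplicates (in either orientation) are collapsed keeping the
#' maximum kinship coefficient. Self-pairs and negative kinship values are
#' validation errors.
#'
#' @param path Path to the pair file.
#' @return Data frame with columns `id1`, `id2`, `kinship`, one row per
#'   unordered pair.
#' @export
read_related_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(id1 = "character", id2 = "character"))
  assert_columns(tab, c("id1", "id2", "kinship"), "kinship pair file")
  dedup_kinship_pairs(tab)
}

#' Collapse duplicate unordered kinship pairs
#'
#' @param pairs Data frame with `id1`, `id2`, `kinship`.
#' @return Deduplicated data frame, maximum kinship kept per unordered pair.
#' @export
dedup_kinship_pairs <- function(pairs) {
  assert_columns(pairs, c("id1", "id2", "kinship"), "kinship pairs")
  if (!nrow(pairs)) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      kinship = numeric(0)))
  }
  if (any(pairs$kinship < 0)) {
    stop("negative kinship coefficient", call. = FALSE)
  }
  if (any(pairs$id1 == pairs$id2)) {
    stop("self-pair in kinship file (id1 == id2)", call. = FALSE)
  }
  a <- pmin(pairs$id1, pairs$id2)
  b <- pmax(pairs$id1, pairs$id2)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(pairs$kinship, key, max)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(id1 = vapply(parts, `[`, "", 1),
                    id2 = vapply(parts, `[`, "", 2),
                    kinship = as.numeric(agg), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$id1, out$id2), , drop = FALSE]
}

#' Write kinship pairs
#' @param pairs Data frame with `id1`, `id2`, `kinship`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_related_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("id1", "id2", "kinship")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Sample manifest ----------------------------------------------------------

#' Read a sample manifest
#'
#' Tab-separated with columns `sample_id`, `ancestry`, `phenotype`, `sex`
#' (M/F), `age_years`, `aao_years` (age at onset, NA if unknown),
#' `family_history` (yes/no/unknown) and `PC1`..`PC10`. Ancestry and
#' phenotype labels must come from the closed sets [ancestry_labels()] and
#' [phenotype_labels()].
#'
#' @param path Path to the manifest.
#' @return Validated data frame of sample records.
#' @export
read_samples <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(sample_id = "character"))
  validate_samples(tab)
}

validate_samples <- function(tab) {
  pcs <- paste0("PC", 1:10)
  assert_columns(tab, c("sample_id", "ancestry", "phenotype", "sex",
                        "age_years", "aao_years", "family_history", pcs),
                 "sample manifest")
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id in sample manifest", call. = FALSE)
  }
  assert_ancestry(tab$ancestry)
  assert_phenotype(tab$phenotype)
  bad_fh <- setdiff(unique(tab$family_history), c("yes", "no", "unknown"))
  if (length(bad_fh)) {
    stop("family_history must be yes/no/unknown, got: ",
         paste(bad_fh, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Write a sample manifest
#' @param samples Sample data frame (see [read_samples()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Variant annotation table -------------------------------------------------

#' Read an ANNOVAR-style variant annotation table
#'
#' Tab-separated with columns `variant_key`, `rsid`, `gene`,
#' `consequence_class` (closed set, see [consequence_classes()]),
#' `protein_change`, `cadd` (phred-scaled, >= 0), `clinvar_class`,
#' `imputation_r2` (in \[0, 1\] or NA) and one `af_<ANCESTRY>` reference
#' allele-frequency column per available ancestry (values in \[0, 1\] or NA).
#'
#' @param path Path to the annotation table.
#' @return Validated annotation data frame.
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("cadd", "imputation_r2", grep("^af_", names(tab),
                                              value = TRUE))) {
    if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  }
  validate_annotations(tab)
}

validate_annotations <- function(tab) {
  assert_columns(tab, c("variant_key", "rsid", "gene", "consequence_class",
                        "protein_change", "cadd", "clinvar_class",
                        "imputation_r2"), "annotation table")
  if (anyDuplicated(tab$variant_key)) {
    stop("duplicate variant_key in annotation table", call. = FALSE)
  }
  assert_consequence(tab$consequence_class)
  if (any(tab$cadd < 0, na.rm = TRUE)) {
    stop("CADD scores must be >= 0", call. = FALSE)
  }
  r2 <- tab$imputation_r2
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) {
    stop("imputation_r2 must lie in [0, 1]", call. = FALSE)
  }
  for (col in grep("^af_", names(tab), value = TRUE)) {
    anc <- sub("^af_", "", col)
    if (!(anc %in% c(ancestry_labels(), "ALL"))) {
      stop("unknown ancestry in annotation AF column: ", col, call. = FALSE)
    }
    v <- tab[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("reference allele frequencies must lie in [0, 1] (", col, ")",
           call. = FALSE)
    }
  }
  tab
}

#' Write a variant annotation table
#' @param annotations Annotation data frame (see [read_annotation_table()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## GWAS summary statistics --------------------------------------------------

#' Read a GWAS summary-statistics table
#'
#' Tab-separated with columns `variant_key`, `beta` (log-odds scale), `se`
#' (> 0), `p` (in (0, 1\]), `n` (sample count) and `maf` (in (0, 0.5\]).
#' Rows violating these invariants are rejected with an error.
#'
#' @param path Path to the table.
#' @return Validated summary-statistics data frame.
#' @export
read_summary_stats <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_summary_stats(tab)
}

validate_summary_stats <- function(tab) {
  assert_columns(tab, c("variant_key", "beta", "se", "p", "n", "maf"),
                 "summary statistics")
  if (any(!is.finite(tab$se) | tab$se <= 0)) {
    stop("summary statistics: se must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(tab$beta))) {
    stop("summary statistics: beta must be finite", call. = FALSE)
  }
  if (any(tab$p <= 0 | tab$p > 1)) {
    stop("summary statistics: p must lie in (0, 1]", call. = FALSE)
  }
  if (any(tab$maf <= 0 | tab$maf > 0.5)) {
    stop("summary statistics: maf must lie in (0, 0.5]", call. = FALSE)
  }
  tab
}

#' Write a GWAS summary-statistics table
#' @param stats Summary-statistics data frame (see [read_summary_stats()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
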