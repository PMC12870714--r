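#' varscreen: gene-centric rare-variant screening
#'
#' Tools for multi-cohort, multi-ancestry screening of a candidate gene:
#' stratified allele statistics, disease-causing-variant filter cascades,
#' covariate-adjusted single-variant association, SKAT-O gene burden
#' testing, kinship-graph pedigree reconstruction with segregation
#' prioritization and carrier enrichment, and single-causal-variant
#' approximate-Bayes-factor fine-mapping, all exercised on a bundled
#' synthetic-cohort generator.
#'
#' @keywords internal
"_PACKAGE"

## Closed label sets shared across modules ---------------------------------

#' Recognized genetic-ancestry labels
#'
#' The eleven ancestry labels used for stratification: European (EUR),
#' African (AFR), American Admixed (AMR), African Admixed (AAC), Ashkenazi
#' Jewish (AJ), Central Asian (CAS), East Asian (EAS), South Asian (SAS),
#' Middle Eastern (MDE), Finnish (FIN) and Complex Admixture History (CAH).
#'
#' @return Character vector of ancestry codes.
#' @export
ancestry_labels <- function() {
  c("EUR", "AFR", "AMR", "AAC", "AJ", "CAS", "EAS", "SAS", "MDE", "FIN", "CAH")
}

#' Recognized phenotype labels
#'
#' Disease groups: Alzheimer's disease (AD), related dementias (RD),
#' Parkinson's disease (PD), dementia with Lewy bodies (DLB), and controls.
#'
#' @return Character vector of phenotype codes.
#' @export
phenotype_labels <- function() {
  c("AD", "RD", "PD", "DLB", "control")
}

#' Recognized variant consequence classes
#'
#' @return Character vector of consequence classes.
#' @export
consequence_classes <- function() {
  c("missense", "stopgain", "frameshift", "splicing", "synonymous", "other")
}

# Loss-of-function classes: damaging regardless of CADD in the family track.
lof_classes <- function() c("stopgain", "frameshift", "splicing")

## Variant keys -------------------------------------------------------------

#' Build and validate "chrom:pos:ref:alt" variant keys
#'
#' Keys use GRCh38 coordinates, 1-based positions, no "chr" prefix (e.g.
#' `"11:121514282:A:G"`). Deletion alleles written as `"-"` are accepted and
#' preserved verbatim.
#'
#' @param chrom Chromosome (character or integer, without "chr" prefix).
#' @param pos 1-based position (positive integer).
#' @param ref,alt Reference / alternate alleles (ACGT strings, or `"-"`).
#' @return Character vector of variant keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- sub("^chr", "", as.character(chrom))
  pos <- as.integer(pos)
  if (anyNA(pos) || any(pos <= 0)) {
    stop("variant positions must parse as positive integers", call. = FALSE)
  }
  ok <- grepl("^([ACGT]+|-)$", ref) & grepl("^([ACGT]+|-)$", alt)
  if (!all(ok)) {
    stop("alleles must be ACGT strings or '-': ",
         paste(unique(paste0(ref[!ok], "/", alt[!ok])), collapse = ", "),
         call. = FALSE)
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

parse_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed variant key: ", paste(key[bad], collapse = ", "),
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
             ref = m[, 3], alt = m[, 4], stringsAsFactors = FALSE)
}

## Formatting helpers -------------------------------------------------------

#' Format a frequency with three significant digits in scientific notation
#'
#' Matches the tabular convention used in published carrier tables, e.g.
#' `2.58E-04`.
#'
#' @param x Numeric vector of frequencies.
#' @return Character vector.
#' @export
format_af <- function(x) {
  out <- toupper(formatC(x, format = "e", digits = 2))
  out[!is.finite(x)] <- NA_character_
  out[is.finite(x) & x == 0] <- "0"
  out
}

# Percentage with one decimal, as "29.1".
format_pct <- function(x) formatC(round(x, 1), format = "f", digits = 1)

## Internal assertions ------------------------------------------------------

assert_ancestry <- function(x) {
  bad <- setdiff(unique(as.character(x)), ancestry_labels())
  if (length(bad)) {
    stop("unknown ancestry label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

assert_phenotype <- function(x) {
  bad <- setdiff(unique(as.character(x)), phenotype_labels())
  if (length(bad)) {
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

assert_consequence <- function(x) {
  bad <- setdiff(unique(as.character(x)), consequence_classes())
  if (length(bad)) {
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

# Columns that must be present in a data frame, error names the missing ones.
assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, ": missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
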