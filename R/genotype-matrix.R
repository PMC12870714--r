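#' Construct a genotype dosage matrix
#'
#' The central genotype container: an integer matrix of alternate-allele
#' dosages with samples in rows and variants in columns. Row names are
#' sample identifiers, column names are `"chrom:pos:ref:alt"` variant keys
#' (GRCh38, 1-based). Dosages are 0, 1, 2 or `NA` (missing). Missing
#' genotypes are excluded from all denominators downstream, never imputed
#' (the SKAT-O kernel, which needs rectangular input, is the one documented
#' exception).
#'
#' @param dosages Matrix-like of dosages in \{0, 1, 2, NA\}.
#' @param sample_ids Unique sample identifiers (defaults to rownames).
#' @param variant_keys Unique variant keys (defaults to colnames).
#' @return An integer matrix of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            variant_keys = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids) || is.null(variant_keys)) {
    stop("sample_ids and variant_keys are required", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyDuplicated(variant_keys)) {
    stop("duplicate variant keys", call. = FALSE)
  }
  if (length(sample_ids) != nrow(dosages) ||
      length(variant_keys) != ncol(dosages)) {
    stop("dimension mismatch between dosages and identifiers", call. = FALSE)
  }
  storage.mode(dosages) <- "integer"
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  parse_variant_key(variant_keys)  # validates key syntax
  dimnames(dosages) <- list(sample_ids, variant_keys)
  class(dosages) <- c("genotype_matrix", class(dosages))
  dosages
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("genotype_matrix", class(out))
  out
}
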