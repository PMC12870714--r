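Package: varscreen
Title: Gene-Centric Rare-Variant Prioritization, Burden, Segregation and
    Fine-Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A gene-centric toolkit for multi-cohort rare-variant analysis
    in case-control and family data. Provides strict readers and writers for
    VCF, PLINK PED, kinship pair files and tab-separated annotation, sample
    and GWAS summary-statistic tables; a seeded synthetic-cohort generator
    with planted case-only damaging variants, planted association odds
    ratios, segregating families and single-causal summary-statistic
    regions; stratified allele statistics and a disease-causing-variant
    filter cascade (CADD, allele count, consequence class, case-only);
    covariate-adjusted single-variant logistic association with Bonferroni
    scaling; a from-scratch SKAT-O gene burden test with quadratic-form
    tail probabilities; kinship-graph pedigree reconstruction with
    segregation prioritization and one-sided Fisher carrier enrichment; and
    single-causal-variant approximate-Bayes-factor fine-mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
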