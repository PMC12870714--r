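test_that("components above the kinship cutoff become families", {
  pairs <- data.frame(id1 = c("A", "B", "D"), id2 = c("B", "C", "E"),
                      kinship = c(0.25, 0.20, 0.30))
  fams <- infer_families(pairs)
  expect_length(fams, 2)
  members <- lapply(fams, `[[`, "members")
  expect_setequal(members, list(c("A", "B", "C"), c("D", "E")))
  expect_true(all(vapply(fams, function(f) all(f$founder), logical(1))))
  expect_equal(fams[[1]]$source, "inferred")

  # kinship at or below the threshold is not an edge
  low <- data.frame(id1 = "A", id2 = "B", kinship = 0.05)
  expect_length(infer_families(low), 0)
  at <- data.frame(id1 = "A", id2 = "B", kinship = 0.0884)
  expect_length(infer_families(at), 0)
  just <- data.frame(id1 = "A", id2 = "B", kinship = 0.0885)
  expect_length(infer_families(just), 1)

  # excluded core members drop out of the graph
  fams2 <- infer_families(pairs, exclude = "B")
  expect_length(fams2, 1)
  expect_setequal(fams2[[1]]$members, c("D", "E"))
})

test_that("components match a brute-force flood fill on random graphs", {
  flood_fill <- function(edges, nodes) {
    comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
    cur <- 0L
    for (start in nodes) {
      if (!is.na(comp[start])) next
      cur <- cur + 1L
      frontier <- start
      while (length(frontier)) {
        comp[frontier] <- cur
        nb <- unique(c(edges$id2[edges$id1 %in% frontier],
                       edges$id1[edges$id2 %in% frontier]))
        frontier <- nb[is.na(comp[nb])]
      }
    }
    split(names(comp), comp)
  }
  set.seed(50)
  for (rep in 1:5) {
    nodes <- sprintf("N%03d", 1:200)
    edges <- data.frame(id1 = sample(nodes, 220, TRUE),
                        id2 = sample(nodes, 220, TRUE),
                        kinship = runif(220, 0.09, 0.5))
    edges <- edges[edges$id1 != edges$id2, ]
    fams <- infer_families(edges)
    got <- lapply(fams, `[[`, "members")
    want <- flood_fill(dedup_kinship_pairs(edges),
                       unique(c(edges$id1, edges$id2)))
    want <- lapply(want[lengths(want) >= 2], sort)
    expect_setequal(got, unname(want))
    # partition: each node in exactly one family
    expect_false(anyDuplicated(unlist(got)) > 0)
    expect_setequal(unlist(got), unique(c(edges$id1, edges$id2)))
  }
})

test_that("merging preserves counts, sources, and disjointness", {
  mk <- function(id, members, source) new_family(id, members, source)
  core <- lapply(1:335, function(i) {
    mk(paste0("C", i), paste0("c", i, "_", 1:3), "core")
  })
  inferred <- lapply(1:134, function(i) {
    mk(paste0("I", i), paste0("i", i, "_", 1:2), "inferred")
  })
  merged <- merge_pedigrees(core, inferred)
  expect_length(merged, 469)
  expect_equal(sum(vapply(merged, `[[`, "", "source") == "core"), 335)

  # empty inferred set is the identity
  expect_identical(merge_pedigrees(core, list()), core)

  # split by source recovers the inputs
  expect_identical(Filter(function(f) f$source == "inferred", merged),
                   inferred)

  # overlapping membership is an error naming the samples
  clash <- mk("X", c("c1_1", "z"), "inferred")
  expect_error(merge_pedigrees(core, list(clash)), "c1_1")

  # family-id collisions get namespaced
  dup <- mk("C1", c("q1", "q2"), "inferred")
  fixed <- merge_pedigrees(core[1], list(dup))
  expect_setequal(vapply(fixed, `[[`, "", "family_id"),
                  c("core:C1", "inf:C1"))
})

test_that("informative families have >= 1 PD case and >= 2 members", {
  fams <- list(new_family("F1", c("a", "b", "c"), "core"),
               new_family("F2", c("d", "e"), "core"),
               new_family("F3", "f", "core"))
  samples <- tiny_samples(letters[1:6],
                          c("PD", "control", "control",
                            "control", "control", "PD"))
  kept <- select_informative(fams, samples)
  expect_equal(vapply(kept, `[[`, "", "family_id"), "F1")
  # random sets match an independent predicate filter
  set.seed(51)
  for (rep in 1:10) {
    n_f <- sample(3:8, 1)
    fams <- lapply(seq_len(n_f), function(i) {
      new_family(paste0("R", i),
                 sprintf("r%d_%d", i, seq_len(sample(1:5, 1))), "core")
    })
    ids <- unlist(lapply(fams, `[[`, "members"))
    samples <- tiny_samples(ids, sample(c("PD", "control"), length(ids),
                                        TRUE, prob = c(0.3, 0.7)))
    got <- select_informative(fams, samples)
    want <- Filter(function(f) {
      ph <- samples$phenotype[match(f$members, samples$sample_id)]
      length(f$members) >= 2 && sum(ph == "PD") >= 1
    }, fams)
    expect_identical(got, want)
  }
  expect_error(select_informative(list(new_family("F9", c("x", "y"), "core")),
                                  samples), "x")
})

test_that("segregation requires all genotyped PD carriers and clean controls", {
  ids <- c("p1", "p2", "p3", "u1")
  samples <- tiny_samples(ids, c("PD", "PD", "PD", "control"))
  fam <- new_family("F1", ids, "core")
  key <- "11:121545392:G:A"
  mk_G <- function(dos) {
    genotype_matrix(matrix(as.integer(dos), 4, 1,
                           dimnames = list(ids, key)))
  }
  # fully segregating duo pattern: all PD het, control clear
  s <- segregation_summary(fam, mk_G(c(1, 1, 1, 0)), key, samples)
  expect_true(s$segregates)
  expect_equal(s$n_pd_carriers, 3)
  expect_equal(s$zygosity, "het (3), hom (0)")
  expect_equal(prioritize_segregating(s), key)
  # one PD non-carrier vetoes
  s2 <- segregation_summary(fam, mk_G(c(1, 1, 0, 0)), key, samples)
  expect_false(s2$segregates)
  expect_length(prioritize_segregating(s2), 0)
  # a carrier family control vetoes
  s3 <- segregation_summary(fam, mk_G(c(1, 1, 1, 1)), key, samples)
  expect_false(s3$segregates)
  # a missing PD genotype neither vetoes nor counts
  s4 <- segregation_summary(fam, mk_G(c(1, 1, NA, 0)), key, samples)
  expect_true(s4$segregates)
  expect_equal(s4$n_genotyped_pd, 2)
})

test_that("planted segregating variants are recovered exactly in 50 families", {
  set.seed(52)
  pf <- data.frame(
    n_members = sample(2:5, 50, TRUE),
    n_pd_cases = NA_integer_,
    segregating = sample(c(TRUE, FALSE), 50, TRUE),
    extra_known_pd_variant = FALSE)
  pf$n_pd_cases <- pmax(1L, pf$n_members - sample(0:2, 50, TRUE))
  # a non-segregating plant needs a second PD member to miss the variant
  pf$n_pd_cases[!pf$segregating] <- pmax(2L, pf$n_pd_cases[!pf$segregating])
  pf$n_members <- pmax(pf$n_members, pf$n_pd_cases)
  cfg <- sim_config(seed = 52, planted_families = pf,
                    n_unrelated_cases = 50L, n_unrelated_controls = 20L)
  fs <- simulate_families(cfg)
  fams <- infer_families(fs$pairs, ancestry = "EUR")
  # kinship components recover the planted family partition
  expect_setequal(lapply(fams, `[[`, "members"),
                  lapply(fs$truth$families, sort))
  informative <- select_informative(fams, fs$samples)
  candidates <- filter_family_damaging(fs$annotations, "EUR")
  summaries <- do.call(rbind, lapply(informative, function(fam) {
    segregation_summary(fam, fs$genotypes, candidates$variant_key,
                        fs$samples)
  }))
  got <- prioritize_segregating(summaries)
  # sensitivity 1, no false positives
  expect_setequal(got, fs$truth$segregating_keys)
  # invariant to family and variant order
  perm <- summaries[sample(nrow(summaries)), ]
  expect_identical(prioritize_segregating(perm), got)
})

test_that("co-occurring known-PD-gene variants are attached to summaries", {
  cfg <- sim_config(seed = 53, planted_families = data.frame(
    n_members = 2L, n_pd_cases = 2L, segregating = TRUE,
    extra_known_pd_variant = TRUE),
    n_unrelated_cases = 10L, n_unrelated_controls = 5L)
  fs <- simulate_families(cfg)
  fam <- infer_families(fs$pairs, ancestry = "EUR")[[1]]
  s <- segregation_summary(fam, fs$genotypes, fs$truth$segregating_keys,
                           fs$samples,
                           known_pd_keys = fs$truth$known_pd_keys)
  expect_equal(s$co_occurring_known_pd_variants, fs$truth$known_pd_keys)
})
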