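test_that("the rare filter applies a strict threshold with pathogenic rescue", {
  recs <- make_records(5, pos = 1:5 * 100,
                       maf = c(9e-4, 1e-3, NA, 4e-3, 0.05))
  recs$prior <- list(character(), character(), character(),
                     "disease_associated", character())
  flt <- rare_filter(recs)
  expect_equal(flt$retained$pos, c(100L, 300L, 400L))
  expect_equal(flt$excluded$pos, c(200L, 500L))
  expect_equal(flt$retained$rescued, c(FALSE, FALSE, TRUE))
})

test_that("raising the threshold never shrinks the retained set", {
  set.seed(11)
  recs <- make_records(60, pos = 1:60 * 10,
                       maf = ifelse(runif(60) < 0.3, NA,
                                    10^runif(60, -5, -1)))
  recs$prior <- lapply(runif(60) < 0.1, function(x) {
    if (x) "pathogenic" else character()
  })
  thresholds <- c(1e-4, 1e-3, 1e-2, 1e-1)
  prev <- character(0)
  pathogenic_keys <- variant_key(recs$chrom, recs$pos, recs$ref, recs$alt)[
    vapply(recs$prior, function(p) "pathogenic" %in% p, TRUE)]
  for (th in thresholds) {
    flt <- rare_filter(recs, maf_threshold = th)
    keys <- variant_key(flt$retained$chrom, flt$retained$pos,
                        flt$retained$ref, flt$retained$alt)
    expect_true(all(prev %in% keys))
    prev <- keys
    # pathogenic variants survive every threshold (rescued or rare)
    expect_true(all(pathogenic_keys %in% keys))
    # the rescue set is invariant to the threshold
    rescued <- keys[flt$retained$rescued]
    expect_setequal(
      rescued,
      variant_key(recs$chrom, recs$pos, recs$ref, recs$alt)[
        !is.na(recs$maf) & recs$maf >= th &
          vapply(recs$prior, function(p) "pathogenic" %in% p, TRUE)])
  }
})

test_that("the rules engine assigns the five tiers with an auditable trace", {
  cases <- list(
    list(consequence = "silent", aa = c("A", "A"), prior = character(),
         category = 1L),
    list(consequence = "intronic_flank", aa = c(NA, NA),
         prior = character(), category = 1L),
    list(consequence = "missense", aa = c("L", "I"), prior = character(),
         category = 2L),   # conservative
    list(consequence = "missense", aa = c("L", "I"),
         prior = "disease_associated", category = 3L),
    list(consequence = "missense", aa = c("L", "I"),
         prior = "predicted_damaging", category = 3L),
    list(consequence = "missense", aa = c("D", "G"), prior = character(),
         category = 3L),   # non-conservative
    list(consequence = "nonsense", aa = c("Q", "*"), prior = character(),
         category = 3L),
    list(consequence = "frameshift", aa = c(NA, NA), prior = character(),
         category = 3L),
    list(consequence = "inframe_deletion", aa = c(NA, NA),
         prior = character(), category = 3L),
    list(consequence = "missense", aa = c("D", "G"),
         prior = "likely_pathogenic", category = 4L),
    # pathogenic for another disorder is demoted to likely pathogenic here
    list(consequence = "missense", aa = c("L", "I"),
         prior = "pathogenic_other_disorder", category = 4L),
    list(consequence = "missense", aa = c("D", "G"), prior = "pathogenic",
         category = 5L),
    # a prior can promote a silent variant above class 1
    list(consequence = "silent", aa = c("A", "A"), prior = "pathogenic",
         category = 5L)
  )
  recs <- make_records(length(cases), pos = seq_along(cases) * 10)
  recs$consequence <- vapply(cases, `[[`, "", "consequence")
  recs$aa_ref <- vapply(cases, function(x) as.character(x$aa[1]), "")
  recs$aa_alt <- vapply(cases, function(x) as.character(x$aa[2]), "")
  recs$prior <- lapply(cases, `[[`, "prior")
  out <- assign_category(recs)
  expect_equal(out$category, vapply(cases, `[[`, 0L, "category"))
  # every trace replays to the assigned class
  expect_equal(lynchburden:::replay_rule_trace(out$rule_trace),
               out$category)
  # assignment is order-independent
  perm <- sample(nrow(recs))
  out_perm <- assign_category(recs[perm, ])
  expect_equal(out_perm$category, out$category[perm])
})

test_that("classification requires consequence annotation", {
  recs <- make_records(1)
  recs$consequence <- NA_character_
  expect_error(assign_category(recs), class = "lynchburden_curation_error")
})

test_that("risk-variant selection keeps class >= 3 protein-altering changes only", {
  recs <- make_records(6, pos = 1:6 * 10)
  recs$consequence <- c("missense", "missense", "missense", "silent",
                        "nonsense", "missense")
  recs$aa_ref <- c("D", "L", "L", "A", "Q", "L")
  recs$aa_alt <- c("G", "I", "I", "A", "*", "I")
  recs$prior <- list(character(), character(), "disease_associated",
                     "pathogenic", character(), "likely_pathogenic")
  out <- assign_category(recs)
  sel <- select_risk_variants(out)
  # selected: non-conservative class 3 (pos 10), nonsense (pos 50),
  # class-4 conservative missense (pos 60; category dominates the proviso)
  expect_setequal(sel$pos, c(10L, 50L, 60L))
  # conservative class-3 missense and promoted silent are never selected
  expect_false(any(sel$consequence == "silent"))
  expect_true(all(sel$category >= 3))
})

test_that("co-segregation flags follow chromosome layout", {
  subjects <- make_subjects(c("S1", "S2"), mmr_gene = c("MSH6", "MSH6"))
  rv <- make_records(4, chrom = c("chr2", "chr7", "chr5", "chr5"),
                     pos = c(48010445L, 6035211L, 112179368L, 131915673L),
                     gene = c("MSH6", "PMS2", "APC", "RAD50"),
                     functional_group = c("mmr", "mmr", "tumor_suppressor",
                                          "tumor_suppressor"),
                     subject_id = c("S1", "S1", "S2", "S2"))
  rv$linkage_flag <- "independent"
  out <- linkage_check(rv, subjects)
  # MSH6 variant on chr2 with a familial MSH6 mutation: possible linkage
  expect_equal(out$linkage_flag[out$gene == "MSH6"],
               "possible_linkage_with_familial_mutation")
  # PMS2 on chr7 vs familial MSH6 on chr2: independent
  expect_equal(out$linkage_flag[out$gene == "PMS2"], "independent")
  # two non-MMR risk variants on chr5 in one subject: same-chromosome pair
  expect_equal(out$linkage_flag[out$gene %in% c("APC", "RAD50")],
               rep("same_chromosome_pair_within_subject", 2))

  rv$chrom[1] <- NA
  expect_error(linkage_check(rv, subjects),
               class = "lynchburden_curation_error")
})

test_that("burden counts independent non-MMR variants, with haplotype collapse", {
  subjects <- make_subjects(c("S1", "S2"), mmr_gene = "MSH6")
  rv <- make_records(4, chrom = c("chr1", "chr5", "chr5", "chr7"),
                     pos = c(100L, 200L, 300L, 400L),
                     gene = c("G1", "G2", "G3", "PMS2"),
                     functional_group = c("estrogen", "oncogene",
                                          "tumor_suppressor", "mmr"),
                     subject_id = "S1")
  rv$linkage_flag <- "independent"
  rv <- linkage_check(rv, subjects)

  prof <- burden(subjects, rv)
  expect_equal(prof$n_risk_variants_non_mmr, c(3L, 0L))
  expect_equal(prof$n_risk_variants_mmr_extra, c(1L, 0L))

  collapsed <- burden(subjects, rv, collapse_mode = "collapse_same_chromosome")
  expect_equal(collapsed$n_risk_variants_non_mmr, c(2L, 0L))
  expect_equal(collapsed$collapsed_haplotypes, c(1L, 0L))

  # collapse never increases any subject's burden
  set.seed(3)
  for (i in 1:20) {
    chroms <- paste0("chr", sample(1:8, 5, replace = TRUE))
    rv2 <- make_records(5, chrom = chroms, pos = 1:5 * 100,
                        gene = paste0("G", 1:5), subject_id = "S1",
                        functional_group = "estrogen")
    rv2$linkage_flag <- "independent"
    rv2 <- linkage_check(rv2, subjects)
    expect_lte(
      burden(subjects, rv2, "collapse_same_chromosome")$n_risk_variants_non_mmr[1],
      burden(subjects, rv2)$n_risk_variants_non_mmr[1])
  }

  # possibly linked MMR variants never count anywhere
  rv$linkage_flag[rv$gene == "PMS2"] <-
    "possible_linkage_with_familial_mutation"
  prof2 <- burden(subjects, rv)
  expect_equal(prof2$n_risk_variants_mmr_extra, c(0L, 0L))
})

test_that("evidence annotation respects the residue window and family sharing", {
  subjects <- make_subjects(c("S1", "S2", "S3"), mmr_gene = "MSH6")
  subjects$family_id <- c("FA", "FA", NA)
  rv <- make_records(3, pos = c(100L, 200L, 100L), aa_pos = 224L,
                     subject_id = c("S1", "S2", "S3"))
  rv$pos <- c(100L, 100L, 200L)  # S1 and S2 share the same variant
  rv$linkage_flag <- "independent"

  somatic <- tibble::tibble(gene = c("GENE1", "GENE1", "GENE1"),
                            aa_pos = c(226L, 230L, 221L),
                            nonsilent = c(TRUE, TRUE, FALSE))
  out <- annotate_evidence(rv, somatic_table = somatic, subjects = subjects)
  # 226 is within +/-3 of 224; 230 is outside; 221 is non-silent FALSE
  expect_true(all(out$somatic_proximity_hit))
  out2 <- annotate_evidence(rv, somatic_table = somatic[2:3, ],
                            subjects = subjects)
  expect_false(any(out2$somatic_proximity_hit))

  # same key in two same-family subjects -> shared; the singleton is not
  expect_equal(out$shared_among_relatives, c(TRUE, TRUE, FALSE))

  # absent tables leave evidence unavailable, never FALSE
  out3 <- annotate_evidence(rv)
  expect_true(all(is.na(out3$somatic_proximity_hit)))
  expect_true(all(is.na(out3$shared_among_relatives)))
  expect_true(all(is.na(out3$domain_conserved)))
})
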