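# Synthetic carrier cohorts: a toy gene panel with strand-aware transcripts,
# per-subject variant sets with a controlled rare-variant spectrum, and a
# planted burden -> phenotype effect, so every pipeline stage can be tested
# end to end without external data.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + offset
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the motivating study population: 35 carriers from 29
#' families, endometrial-cancer diagnosis ages distributed as 53.1 +/- 10.7
#' years truncated to 31-81, roughly half of the rare variants absent from
#' dbSNP, a mean planted burden of 1.7 risk-variants per subject, and a
#' logistic phenotype model
#' \eqn{P(poor) = expit(\beta_0 + \log(OR) \cdot 1[burden \ge k])}.
#'
#' @param seed Mandatory integer seed; the generator draws no implicit
#'   entropy.
#' @param n_subjects,n_families Cohort structure; extra subjects beyond one
#'   per family are assigned to random families.
#' @param age_mean,age_sd,age_min,age_max EC diagnosis age distribution
#'   (years; truncated normal, rounded to integers).
#' @param age_cutoff Young-onset cutoff (years, exclusive at the cutoff).
#' @param p_multi_given_poor Probability that a young-onset poor subject
#'   additionally develops a second tumor. Poor subjects without a
#'   below-cutoff diagnosis age always receive one (the phenotype must be
#'   realizable from the clinical record); ages are drawn unconditionally
#'   from the truncated normal so the cohort age marginal matches the
#'   configured distribution.
#' @param burden_lambda,burden_max Planted per-subject risk-variant count:
#'   Poisson(`burden_lambda`) capped at `burden_max`.
#' @param k Burden dichotomy threshold entering the phenotype model.
#' @param effect_or Odds ratio linking burden >= k to the poor phenotype.
#' @param baseline_poor_prob P(poor) for subjects below the threshold.
#' @param panel_genes Named counts of non-MMR toy genes per functional
#'   group; the four mismatch-repair genes are always added.
#' @param cds_codons Codons per toy transcript.
#' @param noise_rates Poisson rates per subject for `silent`,
#'   `conservative_missense`, `flank` and `common` (MAF >= 0.001,
#'   filter-excluded) variants.
#' @param risk_consequence_probs Mix of planted risk-variant consequences
#'   (`missense` = non-conservative, `nonsense`, `frameshift`, `inframe`).
#' @param p_nondbsnp Probability that a rare variant is absent from the
#'   frequency table (not deposited in dbSNP).
#' @param rescue_rate Per-subject probability of planting a common
#'   (MAF >= 0.001) variant carrying a disease-associated prior, exercising
#'   the rescue path without touching the burden.
#' @param prior_lp_rate,prior_pod_rate Probabilities that a planted risk
#'   variant additionally carries a likely-pathogenic /
#'   pathogenic-for-other-disorder prior (promoting it to class 4).
#' @param mmr_variant_rate Per-subject probability of an extra rare
#'   non-conservative variant in a mismatch-repair gene.
#' @param shared_family_rate Probability that a multi-member family shares
#'   one identical risk-variant among its members.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_subjects = 35,
                              n_families = 29,
                              age_mean = 53.1,
                              age_sd = 10.7,
                              age_min = 31,
                              age_max = 81,
                              age_cutoff = 50,
                              p_multi_given_poor = 13 / 23,
                              burden_lambda = 1.7,
                              burden_max = 5,
                              k = 2,
                              effect_or = 8,
                              baseline_poor_prob = 0.35,
                              panel_genes = c(estrogen = 6, oncogene = 5,
                                              tumor_suppressor = 6,
                                              other = 2),
                              cds_codons = 120,
                              noise_rates = c(silent = 0.6,
                                              conservative_missense = 0.6,
                                              flank = 0.2, common = 1.0),
                              risk_consequence_probs = c(missense = 0.8,
                                                         nonsense = 0.1,
                                                         frameshift = 0.05,
                                                         inframe = 0.05),
                              p_nondbsnp = 0.47,
                              rescue_rate = 0.05,
                              prior_lp_rate = 0.03,
                              prior_pod_rate = 0.02,
                              mmr_variant_rate = 0.1,
                              shared_family_rate = 0.3) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("simulation_config requires an explicit seed",
          class = "lynchburden_sim_error")
  }
  probs <- c(p_multi_given_poor, baseline_poor_prob,
             p_nondbsnp, rescue_rate, prior_lp_rate, prior_pod_rate,
             mmr_variant_rate, shared_family_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "lynchburden_sim_error")
  }
  if (effect_or <= 0) {
    abort("odds ratio must be positive", class = "lynchburden_sim_error")
  }
  if (n_families > n_subjects) {
    abort("more families than subjects", class = "lynchburden_sim_error")
  }
  structure(as.list(environment()), class = "simulation_config")
}

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# genomic positions of CDS indices 1..L, in coding order
cds_genomic_map <- function(exons, strand) {
  g <- unlist(mapply(seq, exons$start, exons$end, SIMPLIFY = FALSE))
  if (strand == "-") rev(g) else g
}

# Build one toy gene: region sequence (exons + intron + 30-nt flanks),
# two CDS exons, internal stop codons patched out, first codon forced ATG.
build_toy_gene <- function(symbol, chrom, functional_group, region_start,
                           cds_codons, strand) {
  cds_len <- 3L * cds_codons
  e1 <- (cds_len %/% 2L) - ((cds_len %/% 2L) %% 1L)
  e2 <- cds_len - e1
  intron <- 60L
  flank <- 30L
  region_len <- flank + e1 + intron + e2 + flank
  region <- random_seq(region_len)
  ex_start <- region_start + c(flank, flank + e1 + intron)
  ex_end <- ex_start + c(e1, e2) - 1L
  exons <- data.frame(start = ex_start, end = ex_end)
  gmap <- cds_genomic_map(exons, strand)

  region_chars <- strsplit(region, "")[[1]]
  get_cds <- function() {
    ch <- region_chars[gmap - region_start + 1L]
    if (strand == "-") ch <- comp_base(ch)
    paste(ch, collapse = "")
  }
  set_cds_base <- function(i, base) {
    b <- if (strand == "-") comp_base(base) else base
    region_chars[gmap[i] - region_start + 1L] <<- b
  }
  # force ATG start, then patch out stop codons (the toy CDS models an
  # internal coding segment, so no codon may translate to a stop)
  for (j in 1:3) set_cds_base(j, c("A", "T", "G")[j])
  repeat {
    cds <- get_cds()
    codons <- substring(cds, seq(1, cds_len - 2, 3), seq(3, cds_len, 3))
    bad <- which(codons %in% STOP_CODONS)
    if (length(bad) == 0) break
    for (b in bad) {
      for (j in 1:3) set_cds_base((b - 1L) * 3L + j, c("C", "T", "G")[j])
    }
  }
  region <- paste(region_chars, collapse = "")
  tx <- toy_transcript(symbol, chrom, strand, exons, get_cds(),
                       region_seq = region, region_start = region_start)
  list(symbol = symbol, chrom = chrom, functional_group = functional_group,
       tx = tx, region = region, region_start = region_start,
       region_end = region_start + region_len - 1L)
}

# Every possible coding SNV of a transcript with its consequence and
# (for missense) physicochemical conservativeness.
enumerate_snvs <- function(tx) {
  L <- nchar(tx$cds)
  s <- strsplit(tx$cds, "")[[1]]
  gmap <- cds_genomic_map(tx$exons, tx$strand)
  code <- Biostrings::GENETIC_CODE
  idx <- rep(seq_len(L), each = 3)
  alt <- unlist(lapply(s, function(b) setdiff(BASES, b)), use.names = FALSE)
  codon_start <- ((idx - 1L) %/% 3L) * 3L + 1L
  within <- idx - codon_start + 1L
  codon <- substring(tx$cds, codon_start, codon_start + 2L)
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt
  aa_ref <- unname(code[codon])
  aa_alt <- unname(code[alt_codon])
  consequence <- ifelse(aa_ref == aa_alt, "silent",
                        ifelse(aa_alt == "*", "nonsense", "missense"))
  ref_plus <- s[idx]
  alt_plus <- alt
  if (tx$strand == "-") {
    ref_plus <- comp_base(ref_plus)
    alt_plus <- comp_base(alt_plus)
  }
  out <- tibble(
    gene = tx$gene, chrom = tx$chrom, pos = gmap[idx],
    ref = ref_plus, alt = alt_plus,
    consequence = consequence,
    aa_ref = aa_ref, aa_pos = (codon_start - 1L) %/% 3L + 1L,
    aa_alt = aa_alt,
    conservative = NA
  )
  mis <- out$consequence == "missense"
  out$conservative[mis] <- conservativeness(out$aa_ref[mis],
                                            out$aa_alt[mis]) == "conservative"
  out
}

MMR_TOY <- data.frame(symbol = c("MLH1", "MSH2", "MSH6", "PMS2"),
                      chrom = c("chr3", "chr2", "chr2", "chr7"))

#' Build the toy gene panel used by the simulator
#'
#' Non-MMR genes are placed on distinct chromosomes (so planted
#' risk-variants are independent by construction), except the two genes of
#' the `other` group, which share a chromosome to exercise the
#' same-chromosome collapse path; the four mismatch-repair genes sit on
#' their real chromosomes (chr3, chr2, chr2, chr7).
#'
#' @param config A [simulation_config()].
#' @return A `toy_panel`: list with `panel` (a `panel_def`), `transcripts`
#'   and `candidates` (all possible coding SNVs with consequences).
#' @export
simulate_panel <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  counts <- config$panel_genes
  prefix <- c(estrogen = "EST", oncogene = "ONC",
              tumor_suppressor = "TSG", other = "OTH")
  symbols <- unlist(lapply(names(counts), function(g) {
    paste0(prefix[[g]], seq_len(counts[[g]]))
  }))
  groups <- rep(names(counts), counts)
  free_chroms <- paste0("chr", setdiff(1:22, c(2, 3, 7)))
  n_non_mmr <- length(symbols)
  chroms <- rep(free_chroms, length.out = n_non_mmr)
  # the "other" genes share one chromosome to exercise haplotype collapse
  oth <- which(groups == "other")
  if (length(oth) >= 2) chroms[oth] <- chroms[oth[1]]

  genes <- rbind(
    data.frame(symbol = symbols, chromosome = chroms,
               functional_group = groups),
    data.frame(symbol = MMR_TOY$symbol, chromosome = MMR_TOY$chrom,
               functional_group = "mmr")
  )
  # lay genes left to right on each chromosome with 10-kb spacing
  built <- vector("list", nrow(genes))
  offset <- setNames(rep(100000L, length(unique(genes$chromosome))),
                     unique(genes$chromosome))
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chromosome[i]
    strand <- if (i %% 2 == 0) "-" else "+"
    built[[i]] <- build_toy_gene(genes$symbol[i], ch,
                                 genes$functional_group[i],
                                 offset[[ch]], config$cds_codons, strand)
    offset[[ch]] <- built[[i]]$region_end + 10000L
  }
  transcripts <- setNames(lapply(built, `[[`, "tx"), genes$symbol)
  iv <- do.call(rbind, lapply(built, function(b) {
    data.frame(chrom = b$chrom, start = b$tx$exons$start - 10L,
               end = b$tx$exons$end + 10L, symbol = b$symbol)
  }))
  intervals <- GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(iv$start, iv$end), symbol = iv$symbol)
  panel <- structure(list(genes = tibble::as_tibble(genes),
                          intervals = GenomicRanges::sort(
                            intervals, ignore.strand = TRUE)),
                     class = "panel_def")
  candidates <- bind_rows(lapply(transcripts, enumerate_snvs))
  # precomputed index pools so per-replicate draws avoid rescanning
  mis_nc <- candidates$consequence == "missense" & !candidates$conservative
  pools <- list(
    mis_nc_by_gene = split(which(mis_nc), candidates$gene[mis_nc]),
    nonsense_by_gene = split(which(candidates$consequence == "nonsense"),
                             candidates$gene[candidates$consequence ==
                                               "nonsense"]),
    mis_nc = which(mis_nc),
    mis_nc_non_mmr = which(mis_nc & candidates$gene %in%
                             genes$symbol[genes$functional_group != "mmr"]),
    mis_c = which(candidates$consequence == "missense" &
                    candidates$conservative),
    silent = which(candidates$consequence == "silent")
  )
  structure(list(panel = panel, transcripts = transcripts,
                 candidates = candidates, pools = pools),
            class = "toy_panel")
}

pick1 <- function(pool) pool[sample.int(length(pool), 1L)]

draw_pool <- function(pool, counts, role, subject_id) {
  total <- sum(counts)
  if (total == 0) return(NULL)
  list(idx = pool[sample.int(length(pool), total, replace = TRUE)],
       sid = rep(subject_id, counts),
       role = rep(role, total))
}

TUMOR_SITES <- c("colorectum", "ovary", "breast", "urinary_tract")
TUMOR_SITE_PROBS <- c(0.5, 0.25, 0.15, 0.1)

build_tumor_lists <- function(age_ec, extra_n) {
  out <- vector("list", length(age_ec))
  for (i in seq_along(age_ec)) {
    if (extra_n[i] == 0L) {
      out[[i]] <- fast_tbl(site = "endometrium",
                           age_at_diagnosis = age_ec[i])
    } else {
      extra_age <- as.integer(pmin(pmax(
        age_ec[i] + sample(-10:15, extra_n[i], TRUE), 25L), 90L))
      out[[i]] <- fast_tbl(
        site = c("endometrium",
                 sample(TUMOR_SITES, extra_n[i], TRUE, TUMOR_SITE_PROBS)),
        age_at_diagnosis = c(age_ec[i], extra_age))
    }
  }
  out
}

sample_trunc_age <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n * 2 + 10, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  as.integer(out[seq_len(n)])
}

pick_rows <- function(df, cond, n = 1) {
  i <- which(cond)
  df[i[sample.int(length(i), n)], , drop = FALSE]
}

# construct a VCF-style indel inside an exon of tx (anchor base + ins/del)
make_indel <- function(tx, kind) {
  ex <- tx$exons[sample.int(nrow(tx$exons), 1), ]
  if (kind == "frameshift") {
    dlen <- sample(c(1L, 2L, 4L), 1)
  } else {
    dlen <- 3L
  }
  insert <- runif(1) < 0.5
  # anchor such that a deletion span stays inside the exon
  hi <- if (insert) ex$end else ex$end - dlen
  pos <- sample(seq(ex$start, hi - 1L), 1)
  at <- function(p) substr(tx$region_seq, p - tx$region_start + 1L,
                           p - tx$region_start + 1L)
  anchor <- at(pos)
  if (insert) {
    ref <- anchor
    alt <- paste0(anchor, random_seq(dlen))
  } else {
    ref <- paste0(anchor, paste(vapply(seq_len(dlen),
                                       function(j) at(pos + j), ""),
                                collapse = ""))
    alt <- anchor
  }
  fast_tbl(gene = tx$gene, chrom = tx$chrom, pos = pos, ref = ref,
           alt = alt,
           consequence = if (kind == "frameshift") "frameshift"
           else if (insert) "inframe_insertion" else "inframe_deletion",
           aa_ref = NA_character_, aa_pos = NA_integer_,
           aa_alt = NA_character_, conservative = NA)
}

# a flanking (non-coding) SNV within 3..10 nt of an exon boundary
make_flank_snv <- function(tx) {
  ex <- tx$exons[sample.int(nrow(tx$exons), 1), ]
  d <- sample(3:10, 1)
  pos <- if (runif(1) < 0.5) ex$start - d else ex$end + d
  ref <- substr(tx$region_seq, pos - tx$region_start + 1L,
                pos - tx$region_start + 1L)
  fast_tbl(gene = tx$gene, chrom = tx$chrom, pos = pos, ref = ref,
           alt = sample(setdiff(BASES, ref), 1),
           consequence = "intronic_flank", aa_ref = NA_character_,
           aa_pos = NA_integer_, aa_alt = NA_character_, conservative = NA)
}

#' Simulate a synthetic carrier cohort
#'
#' Deterministic for a fixed seed. Subjects receive a planted risk-variant
#' burden, a phenotype drawn from the logistic model, clinical records
#' realized to match the phenotype (diagnosis ages, additional tumors), and
#' variant sets covering every consequence class the annotator handles
#' (silent, conservative and non-conservative missense, nonsense,
#' frameshift, in-frame indels, exon flanks), plus common filter-excluded
#' variants, rescue variants, shared family variants and mismatch-repair
#' gene variants exercising the co-segregation check.
#'
#' @param config A [simulation_config()].
#' @param panel Optional prebuilt [simulate_panel()] output (reused across
#'   replicates; must come from a config with the same panel settings).
#' @return A `synthetic_cohort`: list with `subjects`, `variants`,
#'   `panel`, `transcripts`, `maf_table`, `annotations`, `somatic`,
#'   `truth` and `config`.
#' @export
simulate_cohort <- function(config, panel = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(panel)) panel <- simulate_panel(config)
  toy <- panel
  cand <- toy$candidates
  non_mmr_genes <- toy$panel$genes$symbol[
    toy$panel$genes$functional_group != "mmr"]
  if (config$burden_max > length(non_mmr_genes)) {
    abort("burden_max exceeds the number of non-MMR panel genes",
          class = "lynchburden_sim_error")
  }

  # ---- subjects ------------------------------------------------------
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_subjects
  fam_of <- c(seq_len(config$n_families),
              sample.int(config$n_families, n - config$n_families,
                         replace = TRUE))
  fam_of <- sort(fam_of)
  family_id <- sprintf("F%02d", fam_of)
  subject_id <- sprintf("S%03d", seq_len(n))
  mmr_gene_of_family <- sample(MMR_TOY$symbol, config$n_families,
                               replace = TRUE,
                               prob = c(0.08, 0.19, 0.65, 0.08))
  mmr_gene <- mmr_gene_of_family[fam_of]

  b <- pmin(rpois(n, config$burden_lambda), config$burden_max)
  p_poor <- stats::plogis(stats::qlogis(config$baseline_poor_prob) +
                            log(config$effect_or) * (b >= config$k))
  poor <- rbinom(n, 1, p_poor) == 1

  # Ages are drawn unconditionally from the truncated normal (so the
  # cohort age marginal matches the configured distribution) and the
  # below-cutoff ages are then assigned to poor subjects; a poor subject
  # with no young age is given a second tumor instead. Excess young ages
  # (more than there are poor subjects) are redrawn above the cutoff.
  ages_pool <- sample_trunc_age(n, config$age_mean, config$age_sd,
                                config$age_min, config$age_max)
  young_ages <- ages_pool[ages_pool < config$age_cutoff]
  old_ages <- ages_pool[ages_pool >= config$age_cutoff]
  poor_idx <- which(poor)
  n_young <- min(length(young_ages), length(poor_idx))
  young_sub <- if (n_young > 0) sample(poor_idx, n_young) else integer(0)
  age_ec <- integer(n)
  if (n_young > 0) {
    age_ec[young_sub] <- sample(young_ages)[seq_len(n_young)]
  }
  others <- setdiff(seq_len(n), young_sub)
  excess <- length(young_ages) - n_young
  old_pool <- c(old_ages,
                if (excess > 0) sample_trunc_age(excess, config$age_mean,
                                                 config$age_sd,
                                                 config$age_cutoff,
                                                 config$age_max))
  age_ec[others] <- sample(old_pool)[seq_along(others)]
  young <- age_ec < config$age_cutoff
  multi <- poor & (!young | runif(n) < config$p_multi_given_poor)
  extra_n <- ifelse(multi, 1L + (runif(n) < 0.1), 0L)
  tumors <- build_tumor_lists(age_ec, extra_n)
  subjects <- fast_tbl(
    subject_id = subject_id,
    family_id = family_id,
    age_ec = age_ec,
    ec_histology = rep("endometrioid", n),
    ec_grade = rep(NA_character_, n),
    ec_stage = rep(NA_character_, n),
    msi = rep(NA_character_, n),
    tumors = tumors,
    phenotype_override = rep(NA_character_, n),
    mmr_gene = mmr_gene,
    mmr_chromosome = unname(MMR_GENES[mmr_gene]),
    mmr_cdna = rep("c.100A>T", n),
    mmr_protein = rep("p.Lys34*", n),
    age_at_last_followup = as.integer(pmin(age_ec + sample(5:20, n, TRUE),
                                           95L)),
    ngs_ok = rep(TRUE, n)
  )

  # ---- variants ------------------------------------------------------
  set.seed(derive_seed(config$seed, 3L))
  pools <- toy$pools
  cand_df <- as.data.frame(cand)
  rcp <- config$risk_consequence_probs / sum(config$risk_consequence_probs)
  nr <- config$noise_rates

  idx <- integer(0)         # candidate-table row draws
  idx_sid <- character(0)
  idx_role <- character(0)
  extras <- list()          # constructed indel / flank rows

  # planted risk variants: b[i] distinct non-MMR genes per subject
  for (i in seq_len(n)) {
    if (b[i] == 0) next
    genes_i <- sample(non_mmr_genes, b[i])
    kinds <- sample(names(rcp), b[i], replace = TRUE, prob = rcp)
    for (j in seq_len(b[i])) {
      g <- genes_i[j]
      if (kinds[j] %in% c("frameshift", "inframe")) {
        row <- make_indel(toy$transcripts[[g]], kinds[j])
        row$role <- "risk"
        row$subject_id <- subject_id[i]
        extras[[length(extras) + 1L]] <- row
      } else {
        pool <- if (kinds[j] == "nonsense") pools$nonsense_by_gene[[g]]
        if (is.null(pool) || length(pool) == 0) pool <- pools$mis_nc_by_gene[[g]]
        idx <- c(idx, pick1(pool))
        idx_sid <- c(idx_sid, subject_id[i])
        idx_role <- c(idx_role, "risk")
      }
    }
  }

  # noise draws: pools disjoint from the risk pool (silent / conservative
  # missense only for "common"), so a key collision can never hand a
  # planted risk-variant a common allele frequency
  noise_draws <- list(
    draw_pool(pools$silent, rpois(n, nr[["silent"]]), "silent_noise",
              subject_id),
    draw_pool(pools$mis_c, rpois(n, nr[["conservative_missense"]]),
              "conservative_noise", subject_id),
    draw_pool(c(pools$silent, pools$mis_c), rpois(n, nr[["common"]]),
              "common", subject_id),
    draw_pool(pools$mis_c, as.integer(runif(n) < config$rescue_rate),
              "rescue", subject_id)
  )
  for (d in noise_draws) {
    if (is.null(d)) next
    idx <- c(idx, d$idx)
    idx_sid <- c(idx_sid, d$sid)
    idx_role <- c(idx_role, d$role)
  }

  # mismatch-repair gene variants; subject 1 deterministically receives one
  # in the familial MMR gene itself, guaranteeing the possible-linkage path
  mmr_pick <- runif(n) < config$mmr_variant_rate
  mmr_pick[1] <- TRUE
  for (i in which(mmr_pick)) {
    g <- if (i == 1L) mmr_gene[i] else sample(MMR_TOY$symbol, 1)
    idx <- c(idx, pick1(pools$mis_nc_by_gene[[g]]))
    idx_sid <- c(idx_sid, subject_id[i])
    idx_role <- c(idx_role, "mmr")
  }

  # exon-flank noise (constructed, not enumerated)
  n_fl <- rpois(n, nr[["flank"]])
  for (i in which(n_fl > 0)) {
    for (j in seq_len(n_fl[i])) {
      row <- make_flank_snv(toy$transcripts[[sample(non_mmr_genes, 1)]])
      row$role <- "flank_noise"
      row$subject_id <- subject_id[i]
      extras[[length(extras) + 1L]] <- row
    }
  }

  base_rows <- cand_df[idx, , drop = FALSE]
  base_rows$role <- idx_role
  base_rows$subject_id <- idx_sid
  variants <- bind_rows(c(list(tibble::as_tibble(base_rows)), extras))

  # shared family risk-variants: members of one multi-member family swap
  # their first planted risk-variant for a common one (burden unchanged)
  fam_sizes <- table(fam_of)
  multi_fams <- as.integer(names(fam_sizes)[fam_sizes >= 2])
  for (fm in multi_fams) {
    if (runif(1) >= config$shared_family_rate) next
    members <- which(fam_of == fm & b > 0)
    if (length(members) < 2) next
    shared <- cand_df[pick1(pools$mis_nc_non_mmr), , drop = FALSE]
    for (m in members) {
      rows_m <- which(variants$subject_id == subject_id[m])
      # skip if the member already carries a variant in that gene
      if (shared$gene %in% variants$gene[rows_m]) next
      ri <- rows_m[variants$role[rows_m] == "risk"][1]
      if (is.na(ri)) next
      variants[ri, names(shared)] <- shared
    }
  }
  variants <- distinct(variants, .data$subject_id, .data$chrom, .data$pos,
                       .data$ref, .data$alt, .keep_all = TRUE)
  variants$zygosity <- "het"
  variants$functional_group <- toy$panel$genes$functional_group[
    match(variants$gene, toy$panel$genes$symbol)]
  variants$off_target <- FALSE

  # ---- allele frequencies & annotation tables ------------------------
  set.seed(derive_seed(config$seed, 4L))
  uniq <- distinct(variants, .data$chrom, .data$pos, .data$ref, .data$alt,
                   .keep_all = TRUE)
  is_common <- uniq$role %in% c("common", "rescue")
  in_dbsnp <- is_common | runif(nrow(uniq)) >= config$p_nondbsnp
  maf <- ifelse(is_common, runif(nrow(uniq), 0.002, 0.2),
                runif(nrow(uniq), 1e-5, 9e-4))
  maf_table <- fast_tbl(
    chrom = uniq$chrom[in_dbsnp], pos = uniq$pos[in_dbsnp],
    ref = uniq$ref[in_dbsnp], alt = uniq$alt[in_dbsnp],
    dbsnp_id = sprintf("rs%08d", sample.int(99999999L, sum(in_dbsnp),
                                            replace = TRUE)),
    maf = maf[in_dbsnp]
  )

  ann <- list()
  resc <- uniq[uniq$role == "rescue", , drop = FALSE]
  if (nrow(resc) > 0) {
    ann$rescue <- fast_tbl(chrom = resc$chrom, pos = resc$pos,
                           ref = resc$ref, alt = resc$alt,
                           source = rep("synthetic_catalogue", nrow(resc)),
                           label = rep("disease_associated", nrow(resc)))
  }
  risky <- uniq[uniq$role == "risk", , drop = FALSE]
  if (nrow(risky) > 0) {
    lp <- runif(nrow(risky)) < config$prior_lp_rate
    pod <- !lp & runif(nrow(risky)) < config$prior_pod_rate
    if (any(lp)) {
      ann$lp <- fast_tbl(chrom = risky$chrom[lp], pos = risky$pos[lp],
                         ref = risky$ref[lp], alt = risky$alt[lp],
                         source = rep("synthetic_catalogue", sum(lp)),
                         label = rep("likely_pathogenic", sum(lp)))
    }
    if (any(pod)) {
      ann$pod <- fast_tbl(chrom = risky$chrom[pod], pos = risky$pos[pod],
                          ref = risky$ref[pod], alt = risky$alt[pod],
                          source = rep("synthetic_catalogue", sum(pod)),
                          label = rep("pathogenic_other_disorder",
                                      sum(pod)))
    }
  }
  annotations <- if (length(ann) > 0) bind_rows(ann) else
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character(), source = character(), label = character())

  somatic <- local({
    hits <- risky[!is.na(risky$aa_pos), , drop = FALSE]
    take <- runif(nrow(hits)) < 0.3
    bind_rows(
      if (any(take)) fast_tbl(gene = hits$gene[take],
                              aa_pos = hits$aa_pos[take] +
                                sample(-3:3, sum(take), TRUE),
                              nonsilent = rep(TRUE, sum(take))),
      fast_tbl(gene = sample(non_mmr_genes, 5, TRUE),
               aa_pos = sample(500:900, 5), nonsilent = rep(TRUE, 5))
    )
  })

  truth <- fast_tbl(
    subject_id = subject_id,
    true_burden = as.integer(table(factor(
      variants$subject_id[variants$role == "risk"], levels = subject_id))),
    phenotype = ifelse(poor, "poor", "neutral"),
    young_onset = young,
    multiple_cancers = multi
  )

  structure(list(subjects = subjects, variants = variants,
                 panel = toy$panel, transcripts = toy$transcripts,
                 maf_table = maf_table, annotations = annotations,
                 somatic = somatic, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic carrier cohort:", nrow(x$subjects), "subjects,",
      nrow(x$variants), "variant calls, seed", x$config$seed, "\n")
  invisible(x)
}
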