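# Shared fixtures: a tiny hand-built transcript pair and tibble builders.

# 40-codon CDS without stop codons, fixed and human-readable
test_cds <- function() {
  codons <- rep(c("ATG", "GCT", "GAA", "CTG", "AAA",
                  "TGC", "GGA", "TTC", "CCA", "GAT"), 4)
  paste(codons, collapse = "")
}

# plus-strand transcript: two 60-nt exons at chr1:101-160 and chr1:221-280
test_tx_plus <- function() {
  toy_transcript("TST1", "chr1", "+",
                 data.frame(start = c(101L, 221L), end = c(160L, 280L)),
                 test_cds())
}

# minus-strand transcript with the same coding sequence; the implied
# plus-strand genomic bases are its reverse complement
test_tx_minus <- function() {
  toy_transcript("TST2", "chr2", "-",
                 data.frame(start = c(101L, 221L), end = c(160L, 280L)),
                 test_cds())
}

# a variant-record tibble with all the columns the curation stage expects
make_records <- function(n = 1, chrom = "chr1", pos = seq(1000, by = 10,
                                                          length.out = n),
                         ref = "A", alt = "G", subject_id = "S1",
                         gene = "GENE1", functional_group = "estrogen",
                         consequence = "missense", aa_ref = "D",
                         aa_pos = 10L, aa_alt = "G", maf = NA_real_,
                         dbsnp_id = NA_character_,
                         prior = list(character())) {
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = rep_len(as.integer(pos), n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    subject_id = rep_len(subject_id, n), zygosity = "het",
    gene = rep_len(gene, n),
    functional_group = rep_len(functional_group, n),
    off_target = FALSE,
    consequence = rep_len(consequence, n),
    aa_ref = rep_len(aa_ref, n), aa_pos = rep_len(as.integer(aa_pos), n),
    aa_alt = rep_len(aa_alt, n),
    maf = rep_len(maf, n), dbsnp_id = rep_len(dbsnp_id, n),
    prior = rep_len(prior, n)
  )
}

# minimal cohort rows for linkage / burden tests
make_subjects <- function(ids = "S1", mmr_gene = "MSH6") {
  n <- length(ids)
  tibble::tibble(
    subject_id = ids,
    family_id = NA_character_,
    age_ec = 55L,
    tumors = rep(list(tibble::tibble(site = "endometrium",
                                     age_at_diagnosis = 55L)), n),
    mmr_gene = rep_len(mmr_gene, n),
    mmr_chromosome = unname(c(MLH1 = "chr3", MSH2 = "chr2", MSH6 = "chr2",
                              PMS2 = "chr7")[rep_len(mmr_gene, n)]),
    age_at_last_followup = NA_integer_,
    ngs_ok = TRUE
  )
}

# independent consequence oracle: rebuild the full mutant CDS, translate the
# whole protein with Biostrings, and diff against the reference protein
oracle_snv_consequence <- function(tx, pos, alt) {
  gmap <- lynchburden:::cds_genomic_map(tx$exons, tx$strand)
  i <- match(pos, gmap)
  s <- strsplit(tx$cds, "")[[1]]
  a <- if (tx$strand == "-") chartr("ACGT", "TGCA", alt) else alt
  s[i] <- a
  mut <- paste(s, collapse = "")
  p0 <- as.character(Biostrings::translate(Biostrings::DNAString(tx$cds),
                                           no.init.codon = TRUE))
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                           no.init.codon = TRUE))
  if (p0 == p1) "silent" else if (grepl("\\*", p1, fixed = FALSE)) "nonsense"
  else "missense"
}

# exact two-sided Fisher p by brute-force enumeration over all tables with
# the observed margins, using factorial ratios directly
oracle_fisher_p <- function(tab) {
  r <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  prob_of <- function(x) {
    choose(r[1], x) * choose(r[2], cs[1] - x) / choose(n, cs[1])
  }
  support <- max(0, cs[1] - r[2]):min(r[1], cs[1])
  probs <- vapply(support, prob_of, 0)
  p_obs <- prob_of(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}
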