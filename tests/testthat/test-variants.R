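write_test_vcf <- function(lines, samples = c("S1", "S2")) {
  tmp <- withr::local_tempfile(fileext = ".vcf",
                               .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines
  ), tmp)
  tmp
}

test_panel <- function() {
  bed <- withr::local_tempfile(fileext = ".bed",
                               .local_envir = parent.frame())
  genes <- withr::local_tempfile(fileext = ".tsv",
                                 .local_envir = parent.frame())
  # BED is 0-based half-open: covers chr2:47702100-47702300 (1-based)
  writeLines(c("chr2\t47702099\t47702300\tMSH2",
               "chr7\t6035100\t6035300\tPMS2"), bed)
  writeLines(c("symbol\tchromosome\tfunctional_group",
               "MSH2\tchr2\tmmr", "PMS2\tchr7\tmmr"), genes)
  read_panel(bed, genes)
}

test_that("VCF records are split per alternate allele and mapped to the panel", {
  panel <- test_panel()
  vcf <- write_test_vcf(c(
    "chr2\t47702191\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr7\t6035211\t.\tT\tC,A\t.\tPASS\t.\tGT\t1/2\t2/2",
    "chr9\t1000\t.\tG\tT\t.\tPASS\t.\tGT\t0/0\t0|1"
  ))
  recs <- read_vcf(vcf, panel)

  msh2 <- recs[recs$pos == 47702191, ]
  expect_equal(nrow(msh2), 1)
  expect_equal(msh2$gene, "MSH2")
  expect_equal(msh2$subject_id, "S1")
  expect_equal(msh2$zygosity, "het")

  # one line, two ALTs -> two records; genotype 1/2 carries both
  multi <- recs[recs$pos == 6035211, ]
  expect_equal(sort(unique(multi$alt)), c("A", "C"))
  expect_equal(nrow(multi), 3)  # S1 carries C and A, S2 carries A hom
  expect_equal(multi$zygosity[multi$subject_id == "S2"], "hom")

  # off-panel site retained and flagged
  off <- recs[recs$pos == 1000, ]
  expect_true(off$off_target)
  expect_true(is.na(off$gene))
  expect_equal(off$subject_id, "S2")
})

test_that("malformed VCF input fails with a parse error", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "at all"), tmp)
  expect_error(read_vcf(tmp), class = "lynchburden_vcf_error")
  expect_error(read_vcf("/nonexistent.vcf"), class = "lynchburden_io_error")
})

test_that("frequency annotation fills MAF and dbSNP id, leaving misses unknown", {
  recs <- make_records(3, pos = c(100, 200, 300))
  maf_table <- tibble::tibble(chrom = "chr1", pos = c(100L, 300L),
                              ref = "A", alt = "G",
                              dbsnp_id = c("rs1", "rs3"),
                              maf = c(4e-4, 0.12))
  out <- annotate_frequency(recs, maf_table)
  expect_equal(out$maf, c(4e-4, NA, 0.12))
  expect_equal(out$dbsnp_id, c("rs1", NA, "rs3"))
})

test_that("toy transcripts enforce their invariants", {
  expect_error(
    toy_transcript("BAD", "chr1", "+",
                   data.frame(start = 1, end = 10), "ACGTACGTAC"),
    class = "lynchburden_transcript_error")  # length 10, not divisible by 3
  expect_error(
    toy_transcript("BAD", "chr1", "+",
                   data.frame(start = 1, end = 9), "ATGTAAGCT"),
    class = "lynchburden_transcript_error")  # internal stop
  expect_error(
    toy_transcript("BAD", "chr1", "+",
                   data.frame(start = c(1, 5), end = c(6, 10)), "ATGGCTGAA"),
    class = "lynchburden_transcript_error")  # overlapping exons
})

test_that("codon-level consequences match known substitutions", {
  tx <- test_tx_plus()
  # codon 2 is GCT (Ala) at positions 104-106
  v <- tibble::tibble(chrom = "chr1", pos = 104L, ref = "G", alt = "A",
                      gene = "TST1")
  out <- annotate_consequence(v, list(TST1 = tx))
  expect_equal(out$consequence, "missense")
  expect_equal(out$aa_ref, "A")
  expect_equal(out$aa_alt, "T")
  expect_equal(out$aa_pos, 2L)

  # third-position synonymous change: GCT -> GCC
  v$pos <- 106L
  v$ref <- "T"
  v$alt <- "C"
  expect_equal(annotate_consequence(v, list(TST1 = tx))$consequence,
               "silent")

  # GAA -> TAA nonsense at codon 3
  v$pos <- 107L
  v$ref <- "G"
  v$alt <- "T"
  expect_equal(annotate_consequence(v, list(TST1 = tx))$consequence,
               "nonsense")
})

test_that("indels and flanking positions classify by length and distance", {
  tx <- test_tx_plus()
  txs <- list(TST1 = tx)
  # anchor base at chr1:110 is the "C" of codon 4 (CTG)
  v <- tibble::tibble(chrom = "chr1", pos = 110L, ref = "C",
                      alt = "CATTA", gene = "TST1")  # 4-nt duplication
  expect_equal(annotate_consequence(v, txs)$consequence, "frameshift")

  v$alt <- "CATT"  # 3-nt insertion
  expect_equal(annotate_consequence(v, txs)$consequence,
               "inframe_insertion")

  v2 <- tibble::tibble(chrom = "chr1", pos = 110L, ref = "CTGAA",
                       alt = "C", gene = "TST1")
  expect_equal(annotate_consequence(v2, txs)$consequence, "frameshift")

  # flank distances: 2 nt -> splice region, 5 nt -> intronic flank
  fl <- tibble::tibble(chrom = "chr1", pos = c(99L, 96L, 165L),
                       ref = "A", alt = "G", gene = "TST1")
  out <- annotate_consequence(fl, txs)
  expect_equal(out$consequence,
               c("splice_region", "intronic_flank", "intronic_flank"))

  # outside the 10-nt flank -> annotation error
  far <- tibble::tibble(chrom = "chr1", pos = 50L, ref = "A", alt = "G",
                        gene = "TST1")
  expect_error(annotate_consequence(far, txs),
               class = "lynchburden_annotation_error")

  # reference allele contradicting the transcript -> error
  bad <- tibble::tibble(chrom = "chr1", pos = 104L, ref = "T", alt = "A",
                        gene = "TST1")
  expect_error(annotate_consequence(bad, txs),
               class = "lynchburden_annotation_error")
})

test_that("strand-aware annotation agrees with the full-translation oracle", {
  set.seed(101)
  for (tx in list(test_tx_plus(), test_tx_minus())) {
    txs <- setNames(list(tx), tx$gene)
    gmap <- lynchburden:::cds_genomic_map(tx$exons, tx$strand)
    for (i in 1:150) {
      cds_i <- sample(nchar(tx$cds), 1)
      pos <- gmap[cds_i]
      ref_c <- substr(tx$cds, cds_i, cds_i)
      ref <- if (tx$strand == "-") chartr("ACGT", "TGCA", ref_c) else ref_c
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- tibble::tibble(chrom = tx$chrom, pos = pos, ref = ref,
                          alt = alt, gene = tx$gene)
      expect_equal(annotate_consequence(v, txs)$consequence,
                   oracle_snv_consequence(tx, pos, alt),
                   info = paste(tx$gene, pos, ref, alt))
    }
  }
})

test_that("transcript serialization round-trips through GFF3 + FASTA", {
  txs <- list(TST1 = test_tx_plus(), TST2 = test_tx_minus())
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_transcripts(txs, gff, fa)
  back <- read_transcripts(gff, fa)
  for (g in names(txs)) {
    expect_equal(back[[g]]$cds, txs[[g]]$cds)
    expect_equal(back[[g]]$strand, txs[[g]]$strand)
    expect_equal(back[[g]]$exons, txs[[g]]$exons)
  }
})
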