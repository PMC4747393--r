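# Serialization of a synthetic cohort to the pipeline's on-disk dialects
# (clinical TSV, multi-sample VCF, MAF/annotation/somatic TSVs, panel
# BED + metadata, transcript GFF3 + FASTA, truth JSON).

SITE_CODES <- c(colorectum = "C", ovary = "O", breast = "B",
                urinary_tract = "U", other = "X")

serialize_tumors <- function(tumors) {
  vapply(tumors, function(tt) {
    other <- tt[tt$site != "endometrium", , drop = FALSE]
    if (nrow(other) == 0) return("")
    age <- ifelse(is.na(other$age_at_diagnosis), "na",
                  as.character(other$age_at_diagnosis))
    paste(paste0(SITE_CODES[other$site], "-", age), collapse = ";")
  }, "")
}

write_clinical_table <- function(subjects, path) {
  out <- data.frame(
    subject_id = subjects$subject_id,
    family_id = subjects$family_id,
    age_ec = subjects$age_ec,
    ec_histology = subjects$ec_histology,
    ec_grade = subjects$ec_grade,
    ec_stage = subjects$ec_stage,
    msi = subjects$msi,
    other_tumors = serialize_tumors(subjects$tumors),
    phenotype_override = subjects$phenotype_override,
    mmr_gene = subjects$mmr_gene,
    mmr_cdna = subjects$mmr_cdna,
    mmr_protein = subjects$mmr_protein,
    age_at_last_followup = subjects$age_at_last_followup,
    ngs_ok = subjects$ngs_ok
  )
  write_tsv_plain(out, path)
}

write_vcf <- function(variants, sample_ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=lynchburden",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  ), con)
  if (nrow(variants) == 0) return(invisible(path))
  v <- order_variants(variants)
  site <- paste(v$chrom, v$pos, v$ref)
  sites <- unique(site)
  lines <- vapply(sites, function(s) {
    rows <- v[site == s, , drop = FALSE]
    alts <- unique(rows$alt)
    gts <- rep("0/0", length(sample_ids))
    names(gts) <- sample_ids
    for (j in seq_len(nrow(rows))) {
      kk <- match(rows$alt[j], alts)
      gts[rows$subject_id[j]] <-
        if (rows$zygosity[j] == "hom") paste0(kk, "/", kk) else paste0("0/", kk)
    }
    paste(c(rows$chrom[1], rows$pos[1], ".", rows$ref[1],
            paste(alts, collapse = ","), ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, "", USE.NAMES = FALSE)
  writeLines(lines, con)
  invisible(path)
}

#' Write a synthetic cohort to a fixture directory
#'
#' Emits the full file set consumed by the ingestion functions: clinical
#' TSV, multi-sample VCF (multi-allelic sites encoded on one line), MAF
#' table, panel BED plus gene metadata, transcript GFF3 plus FASTA, prior
#' annotation and somatic-catalogue TSVs, and the generator truth as JSON.
#' Reading the files back reproduces the in-memory cohort with no loss.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      abort(paste0("cannot create fixture directory: ", out_dir),
            class = "lynchburden_io_error")
    }
  }
  paths <- list(
    clinical = file.path(out_dir, "clinical.tsv"),
    vcf = file.path(out_dir, "variants.vcf"),
    maf = file.path(out_dir, "maf_table.tsv"),
    panel_bed = file.path(out_dir, "panel.bed"),
    panel_genes = file.path(out_dir, "panel_genes.tsv"),
    gff3 = file.path(out_dir, "transcripts.gff3"),
    fasta = file.path(out_dir, "transcripts.fasta"),
    annotations = file.path(out_dir, "annotations.tsv"),
    somatic = file.path(out_dir, "somatic.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_clinical_table(cohort$subjects, paths$clinical)
  write_vcf(cohort$variants, cohort$subjects$subject_id, paths$vcf)
  write_tsv_plain(cohort$maf_table, paths$maf)
  write_panel(cohort$panel, paths$panel_bed, paths$panel_genes)
  write_transcripts(cohort$transcripts, paths$gff3, paths$fasta)
  write_tsv_plain(cohort$annotations, paths$annotations)
  write_tsv_plain(cohort$somatic, paths$somatic)
  jsonlite::write_json(cohort$truth, paths$truth, dataframe = "rows",
                       na = "null", digits = NA)
  invisible(paths)
}
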