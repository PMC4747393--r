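# Pipeline orchestration: in-memory analysis of a cohort's variant calls,
# panel accounting, and the file-based runner emitting report bundles.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)),
          class = "lynchburden_pipeline_error")
  })
}

#' Panel accounting of retained rare variants
#'
#' Cross-tabulates the retained variant set by gene functional group, dbSNP
#' status (deposited with MAF below the threshold versus not deposited) and
#' consequence class (protein-altering = missense/nonsense/indel; silent;
#' intron-exon flank). Counts are of unique variants (carriers of the same
#' variant counted once); the grand total equals the retained unique
#' variant count.
#'
#' @param records Retained, consequence-annotated variant tibble.
#' @return Tibble with `functional_group`, `dbsnp_status`,
#'   `consequence_class` and `n`; total in attribute `grand_total`.
#' @export
summarize_panel <- function(records) {
  uniq <- distinct(records, .data$chrom, .data$pos, .data$ref, .data$alt,
                   .keep_all = TRUE)
  cls <- ifelse(uniq$consequence %in% PROTEIN_ALTERING, "protein_altering",
                ifelse(uniq$consequence == "silent", "silent", "intron_exon"))
  status <- ifelse(is.na(uniq$dbsnp_id), "non_dbsnp", "dbsnp_rare")
  groups <- c("estrogen", "oncogene", "tumor_suppressor", "other", "mmr")
  tab <- as.data.frame(table(
    functional_group = factor(uniq$functional_group, levels = groups),
    dbsnp_status = factor(status, levels = c("dbsnp_rare", "non_dbsnp")),
    consequence_class = factor(cls, levels = c("protein_altering", "silent",
                                               "intron_exon"))
  ), responseName = "n")
  out <- tibble::as_tibble(tab)
  attr(out, "grand_total") <- nrow(uniq)
  out
}

#' Run the burden-phenotype analysis on in-memory inputs
#'
#' The complete analysis chain: phenotype classification, frequency and
#' prior annotation, rare-variant filter with rescue, consequence
#' annotation, five-tier classification, risk-variant selection,
#' co-segregation check, per-subject burden, and the association
#' statistics (Fisher exact on the dichotomized table, Pearson chi-square
#' on the full burden distribution, optional survival comparison).
#' Subjects failing sequencing QC are excluded from the association.
#'
#' @param records Variant calls (long tibble from [read_vcf()] with panel
#'   columns).
#' @param subjects Cohort tibble from [read_clinical_table()].
#' @param transcripts Named list of [toy_transcript()] objects.
#' @param maf_table,annotations,somatic Optional lookup tables.
#' @param maf_threshold Strict MAF bound, default 0.001.
#' @param scheme Conservativeness scheme, see [conservativeness()].
#' @param k Burden dichotomy threshold, default 2.
#' @param collapse_mode See [burden()].
#' @param age_cutoff Young-onset cutoff, default 50.
#' @param compute_survival Build survival records and run Kaplan-Meier /
#'   log-rank (requires follow-up ages), default `TRUE`.
#' @param compute_panel_summary Include the panel accounting, default
#'   `TRUE`.
#' @return A list: `subjects` (classified), `retained`, `excluded`,
#'   `assignments`, `risk_variants`, `profiles`, `burden_distribution`,
#'   `dichotomized`, `fisher`, `chi_square`, `lifespan_t`, `km`,
#'   `log_rank`, `panel_summary`.
#' @export
analyze_cohort <- function(records, subjects, transcripts,
                           maf_table = NULL, annotations = NULL,
                           somatic = NULL, maf_threshold = 0.001,
                           scheme = "physicochemical", k = 2,
                           collapse_mode = "none", age_cutoff = 50,
                           compute_survival = TRUE,
                           compute_panel_summary = TRUE) {
  subjects <- stage("phenotype_classification",
                    classify_phenotype(subjects, age_cutoff = age_cutoff,
                                       on_indeterminate = "na"))
  analyzed <- subjects[subjects$ngs_ok, , drop = FALSE]
  recs <- records[records$subject_id %in% analyzed$subject_id, , drop = FALSE]
  recs <- recs[!is.na(recs$gene), , drop = FALSE]

  recs <- stage("frequency_annotation", {
    if (is.null(maf_table)) {
      abort("no allele-frequency table supplied")
    }
    annotate_frequency(recs, maf_table)
  })
  recs <- stage("prior_annotation", annotate_priors(recs, annotations))
  flt <- stage("rare_filter", rare_filter(recs, maf_threshold))
  retained <- stage("consequence_annotation",
                    annotate_consequence(flt$retained, transcripts))
  assignments <- stage("classification",
                       assign_category(retained, scheme = scheme))
  rv <- stage("risk_variant_selection", select_risk_variants(assignments))
  rv <- stage("linkage_check", linkage_check(rv, analyzed))
  rv <- stage("evidence_annotation",
              annotate_evidence(rv, somatic_table = somatic,
                                subjects = analyzed,
                                annotations = annotations))
  profiles <- stage("burden", burden(analyzed, rv, collapse_mode))

  classified <- analyzed[analyzed$phenotype %in% c("neutral", "poor"), ,
                         drop = FALSE]
  prof_cl <- profiles[profiles$subject_id %in% classified$subject_id, ,
                      drop = FALSE]
  tab <- stage("burden_table", burden_table(prof_cl, classified))
  dich <- stage("dichotomize", dichotomize(tab, k = k))
  fisher <- stage("fisher_test", fisher_exact_2x2(dich))
  chi <- stage("chi_square_test", {
    # all-zero burden rows carry no information and would zero a margin
    nonzero <- tab[rowSums(tab) > 0, , drop = FALSE]
    suppressWarnings(pearson_chi_square(nonzero))
  })

  lifespan_t <- NULL
  km <- NULL
  lr <- NULL
  if (compute_survival && any(!is.na(classified$age_at_last_followup))) {
    fu <- classified$age_at_last_followup
    neu <- fu[classified$phenotype == "neutral" & !is.na(fu)]
    poo <- fu[classified$phenotype == "poor" & !is.na(fu)]
    if (length(neu) >= 2 && length(poo) >= 2) {
      lifespan_t <- two_sample_t(neu, poo)
    }
    sr <- stage("survival_records",
                survival_records(classified, profiles, k = k,
                                 age_cutoff = age_cutoff))
    if (length(unique(sr$group)) == 2 && any(sr$event)) {
      km <- kaplan_meier(sr)
      lr <- log_rank(sr)
    }
  }

  panel_summary <- if (compute_panel_summary) {
    summarize_panel(left_join(
      retained,
      select(assignments, "chrom", "pos", "ref", "alt", "subject_id",
             "category"),
      by = c("chrom", "pos", "ref", "alt", "subject_id")
    ))
  } else NULL

  list(subjects = subjects, retained = retained, excluded = flt$excluded,
       assignments = assignments, risk_variants = rv, profiles = profiles,
       burden_distribution = tab, dichotomized = dich, fisher = fisher,
       chi_square = chi, lifespan_t = lifespan_t, km = km, log_rank = lr,
       panel_summary = panel_summary)
}

# One replicate of the simulation -> analysis chain; returns the Fisher p
# (used by the power / type-I-error studies).
simulate_and_test <- function(config, panel = NULL) {
  cohort <- simulate_cohort(config, panel = panel)
  res <- tryCatch(
    analyze_cohort(cohort$variants, cohort$subjects, cohort$transcripts,
                   maf_table = cohort$maf_table,
                   annotations = cohort$annotations,
                   k = config$k, age_cutoff = config$age_cutoff,
                   compute_survival = FALSE,
                   compute_panel_summary = FALSE),
    lynchburden_stats_error = function(e) NULL,
    lynchburden_pipeline_error = function(e) NULL
  )
  if (is.null(res)) NA_real_ else res$fisher$p_value
}

#' Run the pipeline on files and emit a report bundle
#'
#' Thin file-based wrapper over [analyze_cohort()]: reads the clinical
#' table, VCF, panel, transcripts and lookup tables, runs the analysis and
#' writes (1) a per-subject risk-variant matrix, (2) the panel accounting,
#' (3) the association report with every test result and its contingency
#' table, (4) Kaplan-Meier curves when survival input is available, and
#' (5) a run manifest (configuration, input MD5 hashes, package version).
#' Reports are deterministic: two runs on identical inputs are
#' byte-identical.
#'
#' @param clinical,vcf,maf,panel_bed,panel_genes,gff3,fasta Input paths
#'   (mandatory).
#' @param annotations,somatic Optional input paths.
#' @param out_dir Output directory.
#' @param maf_threshold,scheme,k,collapse_mode,age_cutoff Analysis
#'   parameters, see [analyze_cohort()].
#' @return Invisibly, the [analyze_cohort()] result list.
#' @export
run_pipeline <- function(clinical, vcf, maf, panel_bed, panel_genes,
                         gff3, fasta, annotations = NULL, somatic = NULL,
                         out_dir, maf_threshold = 0.001,
                         scheme = "physicochemical", k = 2,
                         collapse_mode = "none", age_cutoff = 50) {
  subjects <- stage("read_clinical", read_clinical_table(clinical))
  panel <- stage("read_panel", read_panel(panel_bed, panel_genes))
  records <- stage("read_vcf", read_vcf(vcf, panel))
  maf_table <- stage("frequency_annotation", {
    if (is.null(maf) || !file.exists(maf %||% "")) {
      abort("allele-frequency table missing")
    }
    read_maf_table(maf)
  })
  transcripts <- stage("read_transcripts", read_transcripts(gff3, fasta))
  ann <- if (!is.null(annotations)) {
    stage("read_annotations", read_annotation_table(annotations))
  } else NULL
  som <- if (!is.null(somatic)) {
    stage("read_somatic", read_somatic_table(somatic))
  } else NULL

  res <- analyze_cohort(records, subjects, transcripts,
                        maf_table = maf_table, annotations = ann,
                        somatic = som, maf_threshold = maf_threshold,
                        scheme = scheme, k = k,
                        collapse_mode = collapse_mode,
                        age_cutoff = age_cutoff)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  ph <- res$subjects
  prof <- res$profiles
  matrix_tbl <- tibble(
    subject_id = prof$subject_id,
    phenotype = ph$phenotype[match(prof$subject_id, ph$subject_id)],
    familial_mutation = paste0(
      ph$mmr_gene[match(prof$subject_id, ph$subject_id)], ":",
      ph$mmr_protein[match(prof$subject_id, ph$subject_id)]),
    mmr_extra = prof$n_risk_variants_mmr_extra,
    total = prof$n_risk_variants_non_mmr,
    risk_variants = vapply(prof$risk_variant_ids, paste, "",
                           collapse = ";")
  )
  write_tsv_plain(matrix_tbl, file.path(out_dir, "risk_variant_matrix.tsv"))
  write_tsv_plain(res$panel_summary, file.path(out_dir, "panel_summary.tsv"))

  as_named <- function(tr) {
    if (is.null(tr)) NULL else
      list(method = tr$method, statistic = tr$statistic, df = tr$df,
           p_value = tr$p_value)
  }
  report <- list(
    burden_distribution = as.data.frame(res$burden_distribution),
    dichotomized = as.data.frame(res$dichotomized),
    tests = Filter(Negate(is.null), list(
      fisher_exact = as_named(res$fisher),
      pearson_chi_square = as_named(res$chi_square),
      lifespan_t = as_named(res$lifespan_t),
      log_rank = as_named(res$log_rank)
    ))
  )
  jsonlite::write_json(report, file.path(out_dir, "association.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  if (!is.null(res$km)) {
    write_tsv_plain(res$km, file.path(out_dir, "km_curves.tsv"))
  }

  inputs <- c(clinical = clinical, vcf = vcf, maf = maf,
              panel_bed = panel_bed, panel_genes = panel_genes,
              gff3 = gff3, fasta = fasta, annotations = annotations,
              somatic = somatic)
  manifest <- list(
    package_version = as.character(utils::packageVersion("lynchburden")),
    parameters = list(maf_threshold = maf_threshold, scheme = scheme,
                      k = k, collapse_mode = collapse_mode,
                      age_cutoff = age_cutoff),
    inputs = lapply(inputs[!vapply(inputs, is.null, TRUE)], function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
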