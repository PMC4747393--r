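# Clinical data model: cohort table ingestion, phenotype classification and
# cohort summary statistics.

MMR_GENES <- c(MLH1 = "chr3", MSH2 = "chr2", MSH6 = "chr2", PMS2 = "chr7")

count_non_ec_tumors <- function(tt) sum(tt$site != "endometrium")

phenotype_reasons <- function(y, m) {
  c(if (y) "young_onset", if (m) "multiple_cancers")
}

TUMOR_SITE_CODES <- c(C = "colorectum", O = "ovary", B = "breast",
                      U = "urinary_tract", E = "endometrium")

CLINICAL_COLUMNS <- c("subject_id", "family_id", "age_ec", "ec_histology",
                      "ec_grade", "ec_stage", "msi", "other_tumors",
                      "phenotype_override", "mmr_gene", "mmr_cdna",
                      "mmr_protein", "ngs_ok")

# "C-29;C-43" -> tibble(site, age_at_diagnosis); "C-na" keeps the tumor with
# an unknown age (unknown ages never disqualify a tumor from counting).
parse_other_tumors <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(tibble(site = character(), age_at_diagnosis = integer()))
  }
  tokens <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  code <- toupper(sub("-.*$", "", tokens))
  age <- parse_age(sub("^[^-]*-", "", tokens))
  site <- unname(TUMOR_SITE_CODES[code])
  site[is.na(site)] <- "other"
  tibble(site = site, age_at_diagnosis = age)
}

#' Read a clinical cohort table
#'
#' Parses a tab-separated clinical table (one Lynch-syndrome mutation carrier
#' per row) into a cohort tibble. The `other_tumors` field uses the compact
#' `"C-59;U-81"` dialect (site code - age at diagnosis; codes `C` colorectum,
#' `O` ovary, `B` breast, `U` urinary tract). Unparseable ages are recorded
#' as unknown rather than dropped, and subjects failing sequencing QC
#' (`ngs_ok = FALSE`) are flagged but retained.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per subject: identifiers, EC diagnosis age,
#'   histology covariates (carried through, never used in any statistic), a
#'   `tumors` list-column (every subject's endometrial cancer plus any other
#'   primaries), and the familial mismatch-repair mutation
#'   (`mmr_gene`, `mmr_chromosome`, `mmr_cdna`, `mmr_protein`).
#' @export
#' @examples
#' cohort <- read_clinical_table(lynch_cohort_path())
#' nrow(cohort)
read_clinical_table <- function(path) {
  df <- read_tsv_strict(path, required = setdiff(CLINICAL_COLUMNS,
                                                 "phenotype_override"))
  if (!"phenotype_override" %in% names(df)) df$phenotype_override <- NA_character_
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate subject_id: ", paste(unique(dup), collapse = ", ")),
          class = "lynchburden_schema_error")
  }
  bad_gene <- setdiff(unique(df$mmr_gene), names(MMR_GENES))
  if (length(bad_gene) > 0) {
    abort(paste0("unknown mismatch-repair gene(s): ",
                 paste(bad_gene, collapse = ", ")),
          class = "lynchburden_schema_error")
  }
  age_ec <- parse_age(df$age_ec)
  tumors <- purrr::map2(df$other_tumors, age_ec, function(ot, age) {
    bind_rows(tibble(site = "endometrium", age_at_diagnosis = age),
              parse_other_tumors(ot))
  })
  tibble(
    subject_id = df$subject_id,
    family_id = df$family_id,
    age_ec = age_ec,
    ec_histology = df$ec_histology,
    ec_grade = df$ec_grade,
    ec_stage = df$ec_stage,
    msi = df$msi,
    tumors = tumors,
    phenotype_override = df$phenotype_override,
    mmr_gene = df$mmr_gene,
    mmr_chromosome = unname(MMR_GENES[df$mmr_gene]),
    mmr_cdna = df$mmr_cdna,
    mmr_protein = df$mmr_protein,
    age_at_last_followup = if ("age_at_last_followup" %in% names(df))
      parse_age(df$age_at_last_followup) else NA_integer_,
    ngs_ok = toupper(trimws(df$ngs_ok)) %in% c("TRUE", "YES", "1")
  )
}

#' Path to the packaged 37-subject carrier cohort
#'
#' The packaged fixture transcribes the clinical table of the motivating
#' study population: 37 Dutch Lynch-syndrome mutation carriers diagnosed
#' with endometrial cancer (ages 31-81), of whom two failed sequencing QC.
#'
#' @return Path to the TSV fixture.
#' @export
lynch_cohort_path <- function() {
  system.file("extdata", "lynch_cohort.tsv", package = "lynchburden",
              mustWork = TRUE)
}

#' Load the packaged carrier cohort
#'
#' @return Cohort tibble, see [read_clinical_table()].
#' @export
load_lynch_cohort <- function() {
  read_clinical_table(lynch_cohort_path())
}

#' Classify the clinical phenotype of each subject
#'
#' A subject has a *poor* clinical phenotype when she was diagnosed with
#' endometrial cancer before `age_cutoff` (49 or younger at the default
#' cutoff of 50), or when she was diagnosed with more than one cancer;
#' otherwise the phenotype is *neutral*. A second diagnosis at the same
#' site (e.g. colorectal cancer twice) counts as multiple cancers, and a
#' tumor with an unknown diagnosis age still counts. The `reasons` column
#' enumerates every triggered criterion.
#'
#' @param subjects Cohort tibble from [read_clinical_table()].
#' @param age_cutoff Exclusive age cutoff in years (default 50: poor iff
#'   diagnosed at 49 or younger).
#' @param on_indeterminate `"error"` (default) aborts when a subject has an
#'   unknown EC diagnosis age and no other tumor; `"na"` labels such
#'   subjects `"indeterminate"`.
#' @return `subjects` with added columns `phenotype`
#'   (`"poor"`/`"neutral"`/`"indeterminate"`) and `reasons` (list-column,
#'   subsets of `young_onset`, `multiple_cancers`).
#' @export
#' @examples
#' cohort <- classify_phenotype(load_lynch_cohort())
#' table(cohort$phenotype)
classify_phenotype <- function(subjects, age_cutoff = 50,
                               on_indeterminate = c("error", "na")) {
  on_indeterminate <- match.arg(on_indeterminate)
  n_other <- vapply(subjects$tumors, count_non_ec_tumors, 0L)
  young <- !is.na(subjects$age_ec) & subjects$age_ec < age_cutoff
  multi <- n_other >= 1L
  indet <- is.na(subjects$age_ec) & !multi
  if (any(indet) && on_indeterminate == "error") {
    abort(paste0("cannot classify phenotype (unknown EC age, no other ",
                 "tumor) for subject(s): ",
                 paste(subjects$subject_id[indet], collapse = ", ")),
          class = "lynchburden_phenotype_error")
  }
  reasons <- purrr::map2(young, multi, phenotype_reasons)
  label <- ifelse(indet, "indeterminate",
                  ifelse(young | multi, "poor", "neutral"))
  subjects$phenotype <- label
  subjects$reasons <- reasons
  subjects
}

#' Cohort summary statistics
#'
#' Mean and standard deviation (n-1 denominator) of the endometrial-cancer
#' diagnosis age over subjects with a known age, phenotype group sizes,
#' young-onset count, and the number of subjects with exactly one additional
#' Lynch-spectrum tumor (breast, intestine or ovary); subjects with several
#' additional tumors are tallied separately in `n_multi_event`.
#'
#' @param subjects Cohort tibble; phenotype columns are added via
#'   [classify_phenotype()] if absent.
#' @param age_cutoff Passed to [classify_phenotype()] when needed.
#' @return A one-row tibble with `n`, `n_poor`, `n_neutral`,
#'   `n_indeterminate`, `n_young_onset`, `n_second_lynch_tumor`,
#'   `n_multi_event`, `mean_age_ec`, `sd_age_ec`, `min_age`, `max_age`.
#' @export
#' @examples
#' cohort_summary(load_lynch_cohort())
cohort_summary <- function(subjects, age_cutoff = 50) {
  if (!"phenotype" %in% names(subjects)) {
    subjects <- classify_phenotype(subjects, age_cutoff = age_cutoff,
                                   on_indeterminate = "na")
  }
  ages <- subjects$age_ec[!is.na(subjects$age_ec)]
  if (length(ages) < 2) {
    abort("cohort summary requires at least two subjects with known EC age",
          class = "lynchburden_phenotype_error")
  }
  second <- vapply(subjects$tumors, function(tt) {
    other <- tt$site[tt$site != "endometrium"]
    length(other) == 1L && other %in% c("breast", "colorectum", "ovary")
  }, TRUE)
  multi_event <- vapply(subjects$tumors, function(tt) {
    sum(tt$site != "endometrium") >= 2L
  }, TRUE)
  tibble(
    n = nrow(subjects),
    n_poor = sum(subjects$phenotype == "poor"),
    n_neutral = sum(subjects$phenotype == "neutral"),
    n_indeterminate = sum(subjects$phenotype == "indeterminate"),
    n_young_onset = sum(!is.na(subjects$age_ec) &
                          subjects$age_ec < age_cutoff),
    n_second_lynch_tumor = sum(second),
    n_multi_event = sum(multi_event),
    mean_age_ec = mean(ages),
    sd_age_ec = stats::sd(ages),
    min_age = min(ages),
    max_age = max(ages)
  )
}
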