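# Risk-variant selection: rare-variant filter with pathogenic rescue,
# five-tier classification rules engine, evidence annotation, co-segregation
# flags and per-subject burden.

RESCUE_LABELS <- c("pathogenic", "pathogenic_other_disorder",
                   "disease_associated")
PROTEIN_ALTERING <- c("missense", "nonsense", "frameshift",
                      "inframe_insertion", "inframe_deletion")

has_prior <- function(prior, labels) {
  vapply(prior, function(p) any(p %in% labels), TRUE)
}

#' Rare-variant filter with pathogenic rescue
#'
#' Retains variants with a minor allele frequency strictly below the
#' threshold, variants with unknown frequency (not deposited in dbSNP), and
#' -- the rescue rule -- common variants previously reported as pathogenic
#' or disease-associated. Rescued records are flagged.
#'
#' @param records Variant tibble with `maf` and `prior` columns (see
#'   [annotate_frequency()], [annotate_priors()]).
#' @param maf_threshold Strict upper MAF bound, default 0.001.
#' @return List with `retained` and `excluded` tibbles; `retained` gains a
#'   logical `rescued` column.
#' @export
rare_filter <- function(records, maf_threshold = 0.001) {
  if (!"prior" %in% names(records)) records <- annotate_priors(records)
  rare <- is.na(records$maf) | records$maf < maf_threshold
  rescued <- !rare & has_prior(records$prior, RESCUE_LABELS)
  retained <- records[rare | rescued, , drop = FALSE]
  retained$rescued <- rescued[rare | rescued]
  list(retained = retained, excluded = records[!(rare | rescued), , drop = FALSE])
}

# Rules, in firing order; the highest-numbered applicable rule wins.
#  R1 silent / exon-flanking non-coding            -> class 1
#  R2 conservative missense                        -> class 2
#  R3 conservative missense + disease-associated
#     or predicted-damaging prior                  -> class 3
#  R4 non-conservative missense, in-frame indel,
#     nonsense or frameshift                       -> class 3
#  R5 prior likely-pathogenic                      -> class 4
#  R6 prior pathogenic for another disorder        -> class 4
#  R7 prior pathogenic for the study disease       -> class 5
RULE_CATEGORY <- c(R1 = 1L, R2 = 2L, R3 = 3L, R4 = 3L, R5 = 4L, R6 = 4L,
                   R7 = 5L)

#' Assign five-tier clinical-genetics classes
#'
#' Deterministic rules engine over (consequence, substitution
#' conservativeness, prior annotations), mirroring clinical-genetics
#' escalation: classes 1 and 2 = no effect, 3 = unknown significance,
#' 4 = likely pathogenic, 5 = pathogenic. When several rules fire, the
#' highest class wins; prior annotations can promote silent or flanking
#' variants above class 1. The fired rules are recorded in `rule_trace` so
#' every call is auditable.
#'
#' @param records Consequence-annotated variant tibble (see
#'   [annotate_consequence()]); a `prior` list-column is added if missing.
#' @param scheme Conservativeness scheme, see [conservativeness()].
#' @return `records` with added `conservativeness_call` (missense only),
#'   `category` (integer 1-5) and `rule_trace` (list-column of fired rule
#'   identifiers, in firing order).
#' @export
assign_category <- function(records, scheme = "physicochemical") {
  if (!"prior" %in% names(records)) records <- annotate_priors(records)
  if (!"consequence" %in% names(records) || anyNA(records$consequence)) {
    abort("assign_category requires consequence-annotated records",
          class = "lynchburden_curation_error")
  }
  n <- nrow(records)
  cons_call <- rep(NA_character_, n)
  mis <- records$consequence == "missense"
  if (any(mis)) {
    cons_call[mis] <- conservativeness(records$aa_ref[mis],
                                       records$aa_alt[mis], scheme = scheme)
  }
  noncoding <- records$consequence %in% c("silent", "intronic_flank",
                                          "splice_region")
  fired <- cbind(
    R1 = noncoding,
    R2 = mis & cons_call == "conservative",
    R3 = mis & cons_call == "conservative" &
      has_prior(records$prior, c("disease_associated", "predicted_damaging")),
    R4 = (mis & cons_call == "non_conservative") |
      records$consequence %in% c("inframe_insertion", "inframe_deletion",
                                 "nonsense", "frameshift"),
    R5 = has_prior(records$prior, "likely_pathogenic"),
    R6 = has_prior(records$prior, "pathogenic_other_disorder"),
    R7 = has_prior(records$prior, "pathogenic")
  )
  fired[is.na(fired)] <- FALSE
  if (any(rowSums(fired) == 0)) {
    abort("no classification rule applies to one or more records",
          class = "lynchburden_curation_error")
  }
  trace <- apply(fired, 1, fired_rule_ids, simplify = FALSE)
  records$conservativeness_call <- cons_call
  records$category <- replay_rule_trace(trace)
  records$rule_trace <- trace
  records
}

fired_rule_ids <- function(f) names(RULE_CATEGORY)[f]

max_rule_category <- function(tr) max(RULE_CATEGORY[tr])

# Re-derive the class from a recorded rule trace (audit replay).
replay_rule_trace <- function(trace) {
  vapply(trace, max_rule_category, 0L)
}

#' Select candidate risk-variants
#'
#' Keeps all class 4 and 5 variants, plus class 3 variants whose protein
#' change is protein-altering and non-conservative (nonsense, frameshift
#' and in-frame indels qualify; class 3 missense must be non-conservative).
#' Silent and flanking variants are never selected.
#'
#' @param assignments Tibble from [assign_category()].
#' @return The selected rows, with a `linkage_flag` column initialized to
#'   `"independent"` (see [linkage_check()]), sorted by genomic coordinate.
#' @export
select_risk_variants <- function(assignments) {
  alt_prot <- assignments$consequence %in% PROTEIN_ALTERING
  class3_ok <- assignments$category == 3L & alt_prot &
    (assignments$consequence != "missense" |
       assignments$conservativeness_call == "non_conservative")
  # silent / flanking variants are never candidate risk modifiers, even
  # when a prior annotation promoted them above class 1
  keep <- alt_prot & (assignments$category >= 4L | class3_ok)
  out <- assignments[keep, , drop = FALSE]
  out$linkage_flag <- rep("independent", nrow(out))
  order_variants(out)
}

#' Flag possible co-segregation with the familial mutation
#'
#' A risk-variant in a mismatch-repair gene lying on the same chromosome as
#' the carrier's familial MMR mutation cannot be excluded from
#' co-segregating with it and is flagged
#' `possible_linkage_with_familial_mutation` (excluded from the burden).
#' Within one subject, non-MMR risk-variants sharing a chromosome are
#' flagged `same_chromosome_pair_within_subject` (their burden contribution
#' is governed by the collapse mode). All others are `independent`.
#'
#' @param risk_variants Tibble from [select_risk_variants()] (long format,
#'   one row per variant x carrier).
#' @param subjects Cohort tibble with `subject_id` and `mmr_chromosome`.
#' @return `risk_variants` with `linkage_flag` set.
#' @export
linkage_check <- function(risk_variants, subjects) {
  if (nrow(risk_variants) == 0) return(risk_variants)
  if (anyNA(risk_variants$chrom)) {
    abort("risk-variant with unknown chromosome",
          class = "lynchburden_curation_error")
  }
  fam_chrom <- subjects$mmr_chromosome[
    match(risk_variants$subject_id, subjects$subject_id)]
  if (anyNA(fam_chrom)) {
    abort("familial mutation chromosome unknown for one or more carriers",
          class = "lynchburden_curation_error")
  }
  is_mmr <- !is.na(risk_variants$functional_group) &
    risk_variants$functional_group == "mmr"
  flag <- rep("independent", nrow(risk_variants))
  flag[is_mmr & risk_variants$chrom == fam_chrom] <-
    "possible_linkage_with_familial_mutation"
  # same-chromosome pairs among a subject's non-MMR risk-variants
  nm <- which(!is_mmr)
  if (length(nm) > 1) {
    key <- paste(risk_variants$subject_id[nm], risk_variants$chrom[nm])
    dupgrp <- key %in% key[duplicated(key)]
    flag[nm[dupgrp]] <- "same_chromosome_pair_within_subject"
  }
  risk_variants$linkage_flag <- flag
  risk_variants
}

#' Per-subject risk-variant burden
#'
#' Counts each subject's independent risk-variants outside the
#' mismatch-repair genes (the headline burden); MMR-gene risk-variants that
#' are not possibly linked to the familial mutation are reported separately
#' in `n_risk_variants_mmr_extra`. Under
#' `collapse_mode = "collapse_same_chromosome"`, a subject's risk-variants
#' sharing a chromosome are counted once (as one putative haplotype).
#'
#' @param subjects Cohort tibble (every subject gets a profile, including
#'   zero-burden subjects).
#' @param risk_variants Tibble after [linkage_check()].
#' @param collapse_mode `"none"` (default) or `"collapse_same_chromosome"`.
#' @return A tibble with one row per subject: `subject_id`,
#'   `n_risk_variants_non_mmr`, `n_risk_variants_mmr_extra`,
#'   `risk_variant_ids` (list-column), `collapsed_haplotypes`.
#' @export
burden <- function(subjects, risk_variants,
                   collapse_mode = c("none", "collapse_same_chromosome")) {
  collapse_mode <- match.arg(collapse_mode)
  rv <- order_variants(risk_variants)
  is_mmr <- !is.na(rv$functional_group) & rv$functional_group == "mmr"
  linked <- rv$linkage_flag == "possible_linkage_with_familial_mutation"
  non_mmr <- rv[!is_mmr & !linked, , drop = FALSE]
  mmr_extra <- rv[is_mmr & !linked, , drop = FALSE]
  lev <- subjects$subject_id
  f <- factor(non_mmr$subject_id, levels = lev)
  n_all <- as.integer(table(f))
  first_on_chrom <- !duplicated(paste(non_mmr$subject_id, non_mmr$chrom))
  n_chrom <- as.integer(table(f[first_on_chrom]))
  keys <- variant_key(non_mmr$chrom, non_mmr$pos, non_mmr$ref, non_mmr$alt)
  tibble(
    subject_id = lev,
    n_risk_variants_non_mmr =
      if (collapse_mode == "collapse_same_chromosome") n_chrom else n_all,
    n_risk_variants_mmr_extra =
      as.integer(table(factor(mmr_extra$subject_id, levels = lev))),
    risk_variant_ids = unname(split(keys, f)),
    collapsed_haplotypes = n_all - n_chrom
  )
}

#' Annotate supporting evidence for risk-variants
#'
#' Adds the evidence features used to characterize candidate risk
#' modifiers: proximity of non-silent cancer somatic mutations in the same
#' protein region (within `window_aa` residues), sharing of the identical
#' variant among relatives, and independence from the familial mutation
#' (from the linkage flag). Features whose supporting table was not
#' supplied are `NA` ("unavailable"), never defaulted to `FALSE`.
#'
#' @param risk_variants Tibble from [select_risk_variants()] (after
#'   [linkage_check()] if independence is to be reported).
#' @param somatic_table Optional tibble from [read_somatic_table()].
#' @param subjects Optional cohort tibble supplying `family_id` for the
#'   shared-among-relatives feature.
#' @param annotations Optional annotation table; its optional
#'   `domain_conserved`, `in_relevant_domain` and `note` columns populate
#'   the corresponding evidence fields.
#' @param window_aa Residue window for somatic proximity, default 3.
#' @return `risk_variants` with evidence columns `somatic_proximity_hit`,
#'   `shared_among_relatives`, `domain_conserved`, `in_relevant_domain`,
#'   `predicted_consequence_note`, `independent_of_familial_mutation`.
#' @export
annotate_evidence <- function(risk_variants, somatic_table = NULL,
                              subjects = NULL, annotations = NULL,
                              window_aa = 3) {
  n <- nrow(risk_variants)
  key <- variant_key(risk_variants$chrom, risk_variants$pos,
                     risk_variants$ref, risk_variants$alt)

  if (is.null(somatic_table)) {
    somatic <- rep(NA, n)
  } else {
    ns <- somatic_table[somatic_table$nonsilent, , drop = FALSE]
    somatic <- vapply(seq_len(n), function(i) {
      p <- risk_variants$aa_pos[i]
      g <- risk_variants$gene[i]
      if (is.na(p) || is.na(g)) return(FALSE)
      any(ns$gene == g & abs(ns$aa_pos - p) <= window_aa)
    }, TRUE)
  }

  if (is.null(subjects) || !"family_id" %in% names(subjects)) {
    shared <- rep(NA, n)
  } else {
    fam <- subjects$family_id[match(risk_variants$subject_id,
                                    subjects$subject_id)]
    fam_key <- ifelse(is.na(fam) | fam == "", NA_character_,
                      paste(key, fam))
    counts <- table(fam_key)
    shared <- !is.na(fam_key) & counts[fam_key] >= 2
    shared <- as.logical(shared)
  }

  dom_cons <- rep(NA, n)
  rel_dom <- rep(NA, n)
  note <- rep(NA_character_, n)
  if (!is.null(annotations)) {
    akey <- variant_key(annotations$chrom, annotations$pos,
                        annotations$ref, annotations$alt)
    m <- match(key, akey)
    if ("domain_conserved" %in% names(annotations)) {
      dom_cons <- toupper(annotations$domain_conserved[m]) %in%
        c("TRUE", "YES", "1")
      dom_cons[is.na(m)] <- NA
    }
    if ("in_relevant_domain" %in% names(annotations)) {
      rel_dom <- toupper(annotations$in_relevant_domain[m]) %in%
        c("TRUE", "YES", "1")
      rel_dom[is.na(m)] <- NA
    }
    if ("note" %in% names(annotations)) note <- annotations$note[m]
  }

  risk_variants$somatic_proximity_hit <- somatic
  risk_variants$shared_among_relatives <- shared
  risk_variants$domain_conserved <- dom_cons
  risk_variants$in_relevant_domain <- rel_dom
  risk_variants$predicted_consequence_note <- note
  risk_variants$independent_of_familial_mutation <-
    if ("linkage_flag" %in% names(risk_variants)) {
      risk_variants$linkage_flag != "possible_linkage_with_familial_mutation"
    } else rep(NA, n)
  risk_variants
}
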