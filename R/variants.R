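# Variant ingestion and annotation: VCF reading (multi-allelic splitting,
# per-carrier zygosity), panel mapping, and allele-frequency lookup.

empty_variant_tbl <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), subject_id = character(), zygosity = character(),
         gene = character(), functional_group = character(),
         off_target = logical())
}

#' Read germline variant calls from a VCF file
#'
#' Produces one row per (site, alternate allele, carrier): multi-allelic
#' sites are split, and carriers are read from the genotype fields
#' (`0/1`-style, phased or unphased; zygosity `het` or `hom`). When a panel
#' is supplied, each record is mapped to the panel gene whose captured
#' interval contains the position; records outside every interval are
#' retained with `gene = NA` and flagged `off_target`.
#'
#' @param path Path to a VCF 4.x file with genotypes.
#' @param panel Optional `panel_def` from [read_panel()].
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `subject_id`, `zygosity`, `gene`, `functional_group`, `off_target`,
#'   sorted by genomic coordinate.
#' @export
read_vcf <- function(path, panel = NULL) {
  if (!file.exists(path)) {
    abort(paste0("VCF not found: ", path), class = "lynchburden_io_error")
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      abort(paste0("malformed VCF ", path, ": ", conditionMessage(e)),
            class = "lynchburden_vcf_error")
    }
  )
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0) {
    out <- empty_variant_tbl()
    return(out)
  }
  if (ncol(vcf@gt) < 2) {
    abort(paste0("VCF ", path, " has no genotype columns"),
          class = "lynchburden_vcf_error")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gts <- gt[i, ]
    alleles <- strsplit(gts, "[/|]")
    purrr::map_dfr(seq_along(alts), function(k) {
      hit <- vapply(alleles, function(a) sum(a == as.character(k)), 0L)
      carriers <- which(!is.na(gts) & hit > 0)
      if (length(carriers) == 0) return(NULL)
      tibble(chrom = fix[i, "CHROM"],
             pos = as.integer(fix[i, "POS"]),
             ref = fix[i, "REF"],
             alt = alts[k],
             subject_id = samples[carriers],
             zygosity = unname(ifelse(hit[carriers] >= 2, "hom", "het")))
    })
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty_variant_tbl())
  if (!is.null(panel)) {
    out$gene <- panel_locate(panel, out$chrom, out$pos)
    out$functional_group <- panel$genes$functional_group[
      match(out$gene, panel$genes$symbol)]
    out$off_target <- is.na(out$gene)
  } else {
    out$gene <- NA_character_
    out$functional_group <- NA_character_
    out$off_target <- NA
  }
  order_variants(out)
}

#' Read an allele-frequency lookup table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `dbsnp_id`,
#'   `maf`.
#' @return Tibble keyed by variant, `maf` numeric in `[0, 1]`.
#' @export
read_maf_table <- function(path) {
  df <- read_tsv_strict(path, required = c("chrom", "pos", "ref", "alt",
                                           "dbsnp_id", "maf"))
  df$pos <- as.integer(df$pos)
  df$maf <- as.numeric(df$maf)
  if (any(!is.na(df$maf) & (df$maf < 0 | df$maf > 1))) {
    abort("MAF values must lie in [0, 1]", class = "lynchburden_schema_error")
  }
  df
}

#' Annotate variant records with population allele frequency
#'
#' Records absent from the lookup table get `maf = NA` and `dbsnp_id = NA`;
#' downstream they are treated as not deposited in dbSNP, hence rare.
#'
#' @param records Variant tibble from [read_vcf()].
#' @param maf_table Tibble from [read_maf_table()].
#' @return `records` with `maf` and `dbsnp_id` columns filled.
#' @export
annotate_frequency <- function(records, maf_table) {
  key <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  tkey <- variant_key(maf_table$chrom, maf_table$pos, maf_table$ref,
                      maf_table$alt)
  m <- match(key, tkey)
  records$maf <- maf_table$maf[m]
  records$dbsnp_id <- maf_table$dbsnp_id[m]
  records
}

#' Read a prior-evidence annotation table
#'
#' Each row attaches one curated label to one variant. Labels:
#' `disease_associated`, `predicted_damaging`, `likely_pathogenic`,
#' `pathogenic_other_disorder` (pathogenic, but for a disorder other than
#' the study disease) and `pathogenic` (for the study disease). Optional
#' columns `domain_conserved`, `in_relevant_domain`, `note` feed the
#' evidence bundle.
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `source`,
#'   `label`.
#' @return Tibble of annotations.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_strict(path, required = c("chrom", "pos", "ref", "alt",
                                           "source", "label"))
  df$pos <- as.integer(df$pos)
  bad <- setdiff(unique(df$label), PRIOR_LABELS)
  if (length(bad) > 0) {
    abort(paste0("unknown annotation label(s): ", paste(bad, collapse = ", ")),
          class = "lynchburden_schema_error")
  }
  df
}

PRIOR_LABELS <- c("disease_associated", "predicted_damaging",
                  "likely_pathogenic", "pathogenic_other_disorder",
                  "pathogenic")

#' Attach prior annotations to variant records
#'
#' @param records Variant tibble.
#' @param annotations Tibble from [read_annotation_table()], or `NULL`
#'   (every record gets an empty prior set).
#' @return `records` with a `prior` list-column of label character vectors.
#' @export
annotate_priors <- function(records, annotations = NULL) {
  key <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  if (is.null(annotations) || nrow(annotations) == 0) {
    records$prior <- rep(list(character()), nrow(records))
    return(records)
  }
  akey <- variant_key(annotations$chrom, annotations$pos, annotations$ref,
                      annotations$alt)
  by_key <- split(annotations$label, akey)
  m <- match(key, names(by_key))
  records$prior <- lapply(m, function(i) {
    if (is.na(i)) character() else unique(by_key[[i]])
  })
  records
}

#' Read a somatic-mutation catalogue
#'
#' @param path TSV with columns `gene`, `aa_pos`, `nonsilent`
#'   (TRUE/FALSE).
#' @return Tibble of somatic entries.
#' @export
read_somatic_table <- function(path) {
  df <- read_tsv_strict(path, required = c("gene", "aa_pos", "nonsilent"))
  df$aa_pos <- as.integer(df$aa_pos)
  df$nonsilent <- toupper(df$nonsilent) %in% c("TRUE", "YES", "1")
  df
}
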