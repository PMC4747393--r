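# Gene-panel definition: captured intervals (BED) plus gene metadata
# (functional group), and position-to-gene lookup.

FUNCTIONAL_GROUPS <- c("estrogen", "oncogene", "tumor_suppressor", "other", "mmr")

#' Read a gene-panel definition
#'
#' The capture panel is described by a BED file of captured intervals
#' (0-based half-open, `name` column = gene symbol) and a gene metadata TSV
#' with columns `symbol`, `chromosome`, `functional_group` (one of
#' `estrogen`, `oncogene`, `tumor_suppressor`, `other`, `mmr`).
#'
#' @param bed_path Path to the BED file of captured intervals.
#' @param genes_path Path to the gene metadata TSV.
#' @return An object of class `panel_def`: a list with `genes` (tibble) and
#'   `intervals` (a `GRanges`, 1-based closed, with a `symbol` column),
#'   intervals sorted and reduced per gene.
#' @export
read_panel <- function(bed_path, genes_path) {
  genes <- read_tsv_strict(genes_path,
                           required = c("symbol", "chromosome",
                                        "functional_group"))
  bad <- setdiff(unique(genes$functional_group), FUNCTIONAL_GROUPS)
  if (length(bad) > 0) {
    abort(paste0("unknown functional group(s): ", paste(bad, collapse = ", ")),
          class = "lynchburden_schema_error")
  }
  bed <- rtracklayer::import(bed_path, format = "BED")
  if (is.null(bed$name) || anyNA(bed$name)) {
    abort("panel BED requires a name column carrying the gene symbol",
          class = "lynchburden_schema_error")
  }
  missing <- setdiff(unique(bed$name), genes$symbol)
  if (length(missing) > 0) {
    abort(paste0("BED gene(s) absent from metadata: ",
                 paste(missing, collapse = ", ")),
          class = "lynchburden_schema_error")
  }
  # merge overlapping intervals within each gene, keep deterministic order
  per_gene <- S4Vectors::split(bed, bed$name)
  merged <- unlist(GenomicRanges::reduce(per_gene))
  intervals <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(merged),
    IRanges::ranges(merged),
    symbol = names(merged)
  )
  intervals <- GenomicRanges::sort(intervals, ignore.strand = TRUE)
  structure(list(genes = genes, intervals = intervals), class = "panel_def")
}

#' @export
print.panel_def <- function(x, ...) {
  cat("Gene panel:", nrow(x$genes), "genes,",
      length(x$intervals), "captured intervals\n")
  print(table(x$genes$functional_group))
  invisible(x)
}

# Map 1-based positions to the panel gene whose captured interval contains
# them; NA when off target.
panel_locate <- function(panel, chrom, pos) {
  stopifnot(inherits(panel, "panel_def"))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, panel$intervals, select = "first")
  ifelse(is.na(hits), NA_character_, panel$intervals$symbol[hits])
}

# Write a panel back to BED + metadata TSV (used by the cohort simulator).
write_panel <- function(panel, bed_path, genes_path) {
  iv <- panel$intervals
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(iv)),
    start = GenomicRanges::start(iv) - 1L,  # BED is 0-based half-open
    end = GenomicRanges::end(iv),
    name = iv$symbol
  )
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_tsv_plain(panel$genes, genes_path)
  invisible(c(bed_path, genes_path))
}
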