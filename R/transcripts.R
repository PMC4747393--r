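# Toy transcript models: minimal strand-aware gene models (CDS exons plus a
# reference coding sequence) that let the consequence annotator run without
# an external transcript database.

#' Construct a toy transcript
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with 1-based closed `start`, `end` columns
#'   (ascending, non-overlapping genomic coordinates of the CDS exons).
#' @param cds Reference coding sequence (character, coding-strand 5'->3');
#'   its length must equal the summed exon widths, be divisible by 3 and
#'   translate without an internal stop codon.
#' @param region_seq Optional plus-strand genomic sequence covering
#'   `region_start` .. (used by the simulator to supply reference context
#'   for intronic/flank positions).
#' @param region_start 1-based genomic start of `region_seq`.
#' @return Object of class `toy_transcript`.
#' @export
toy_transcript <- function(gene, chrom, strand, exons, cds,
                           region_seq = NULL, region_start = NA_integer_) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  widths <- exons$end - exons$start + 1L
  if (any(widths <= 0) ||
      (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))) {
    abort(paste0(gene, ": exons must be non-overlapping, positive-width"),
          class = "lynchburden_transcript_error")
  }
  if (sum(widths) != nchar(cds)) {
    abort(paste0(gene, ": CDS length (", nchar(cds),
                 ") does not match summed exon widths (", sum(widths), ")"),
          class = "lynchburden_transcript_error")
  }
  if (nchar(cds) %% 3 != 0) {
    abort(paste0(gene, ": CDS length not divisible by 3"),
          class = "lynchburden_transcript_error")
  }
  prot <- translate_cds(cds)
  if (grepl("\\*", substr(prot, 1, nchar(prot) - 1))) {
    abort(paste0(gene, ": CDS translates with an internal stop"),
          class = "lynchburden_transcript_error")
  }
  structure(list(gene = gene, chrom = chrom, strand = strand,
                 exons = exons, cds = toupper(cds),
                 region_seq = region_seq, region_start = region_start),
            class = "toy_transcript")
}

#' @export
print.toy_transcript <- function(x, ...) {
  cat("Toy transcript", x$gene, "(", x$chrom, x$strand, "):",
      nrow(x$exons), "exon(s),", nchar(x$cds), "nt CDS\n")
  invisible(x)
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Read toy transcript definitions from GFF3 + FASTA
#'
#' CDS features in the GFF3 (grouped and strand-annotated per gene via the
#' `ID`/`Parent`-free `gene_id` attribute written by [write_transcripts()])
#' are combined with the per-gene reference coding sequences in the FASTA.
#'
#' @param gff3_path GFF3 file with `CDS` features.
#' @param fasta_path FASTA of reference coding sequences named by gene.
#' @return Named list of [toy_transcript()] objects.
#' @export
read_transcripts <- function(gff3_path, fasta_path) {
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  gff <- gff[gff$type == "CDS"]
  ids <- if (!is.null(gff$gene_id)) gff$gene_id else gff$ID
  if (is.null(ids) || anyNA(ids)) {
    abort("GFF3 CDS features require a gene_id (or ID) attribute",
          class = "lynchburden_transcript_error")
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- lapply(unique(ids), function(g) {
    feats <- gff[ids == g]
    if (!g %in% names(seqs)) {
      abort(paste0("no FASTA sequence for transcript ", g),
            class = "lynchburden_transcript_error")
    }
    toy_transcript(
      gene = g,
      chrom = as.character(GenomicRanges::seqnames(feats))[1],
      strand = as.character(GenomicRanges::strand(feats))[1],
      exons = data.frame(start = GenomicRanges::start(feats),
                         end = GenomicRanges::end(feats)),
      cds = as.character(seqs[[g]])
    )
  })
  setNames(out, unique(ids))
}

#' Write toy transcripts to GFF3 + FASTA
#'
#' @param transcripts Named list of [toy_transcript()] objects.
#' @param gff3_path,fasta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcripts <- function(transcripts, gff3_path, fasta_path) {
  feats <- lapply(transcripts, function(tx) {
    w <- tx$exons$end - tx$exons$start + 1L
    coding_order <- if (tx$strand == "-") rev(seq_along(w)) else seq_along(w)
    preceding <- c(0L, cumsum(w[coding_order]))[seq_along(w)]
    phase <- integer(length(w))
    phase[coding_order] <- (3L - preceding %% 3L) %% 3L
    GenomicRanges::GRanges(tx$chrom,
                           IRanges::IRanges(tx$exons$start, tx$exons$end),
                           strand = tx$strand, type = "CDS",
                           phase = phase,
                           gene_id = tx$gene, source = "lynchburden")
  })
  gr <- suppressWarnings(do.call(c, unname(feats)))
  rtracklayer::export(gr, gff3_path, format = "gff3")
  seqs <- Biostrings::DNAStringSet(
    vapply(transcripts, function(tx) tx$cds, "")
  )
  names(seqs) <- vapply(transcripts, function(tx) tx$gene, "")
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(c(gff3_path, fasta_path))
}

# distance from each position to the nearest exon boundary (0 inside)
min_exon_distance <- function(p, starts, ends) {
  out <- numeric(length(p))
  for (j in seq_along(p)) out[j] <- min(pmax(starts - p[j], p[j] - ends))
  out
}

# cumulative CDS offsets preceding each exon (plus-strand orientation)
exon_offsets <- function(tx) {
  w <- tx$exons$end - tx$exons$start + 1L
  c(0L, cumsum(w))[seq_len(nrow(tx$exons))]
}

#' Annotate the coding consequence of variants on a toy transcript
#'
#' Single-nucleotide variants inside the CDS are classified as
#' `silent`/`missense`/`nonsense` by strand-aware codon translation;
#' length-changing indels as `frameshift` (length difference not divisible
#' by 3) or `inframe_insertion`/`inframe_deletion`; positions in the
#' non-coding sequence flanking an exon as `splice_region` (within 2 nt of
#' the exon boundary) or `intronic_flank` (3-10 nt). Positions outside the
#' CDS plus its 10-nt flanks are an error, as is a reference allele that
#' contradicts the transcript sequence.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` and a `gene`
#'   column naming the transcript; rows with genes absent from
#'   `transcripts` are passed through with `consequence = NA`.
#' @param transcripts Named list of [toy_transcript()] objects.
#' @return `variants` with added columns `consequence`, `aa_ref`, `aa_pos`,
#'   `aa_alt` (substitutions only; indels get the affected codon in
#'   `aa_pos`).
#' @export
annotate_consequence <- function(variants, transcripts) {
  n <- nrow(variants)
  consequence <- rep(NA_character_, n)
  aa_ref <- rep(NA_character_, n)
  aa_alt <- rep(NA_character_, n)
  aa_pos <- rep(NA_integer_, n)
  code <- Biostrings::GENETIC_CODE

  for (g in unique(variants$gene)) {
    if (is.na(g) || !g %in% names(transcripts)) next
    tx <- transcripts[[g]]
    idx <- which(variants$gene == g)
    pos <- variants$pos[idx]
    ref <- toupper(variants$ref[idx])
    alt <- toupper(variants$alt[idx])
    if (any(variants$chrom[idx] != tx$chrom)) {
      abort(paste0(g, ": variant chromosome does not match transcript"),
            class = "lynchburden_annotation_error")
    }
    starts <- tx$exons$start
    ends <- tx$exons$end
    offs <- exon_offsets(tx)
    L <- nchar(tx$cds)
    ex <- findInterval(pos, starts)
    in_exon <- ex >= 1L & pos <= ends[pmax(ex, 1L)]

    is_snv <- nchar(ref) == 1L & nchar(alt) == 1L
    is_indel <- nchar(ref) != nchar(alt)

    # --- flanking (non-exonic) positions -------------------------------
    out_i <- idx[!in_exon]
    if (length(out_i) > 0) {
      p <- variants$pos[out_i]
      dist <- min_exon_distance(p, starts, ends)
      bad <- dist > 10
      if (any(bad)) {
        abort(paste0(g, ": position(s) outside CDS and 10-nt flanks: ",
                     paste(p[bad], collapse = ", ")),
              class = "lynchburden_annotation_error")
      }
      consequence[out_i] <- ifelse(dist <= 2, "splice_region",
                                   "intronic_flank")
    }

    # --- in-CDS SNVs ---------------------------------------------------
    snv_i <- which(in_exon & is_snv)
    if (length(snv_i) > 0) {
      cds_plus <- offs[ex[snv_i]] + pos[snv_i] - starts[ex[snv_i]] + 1L
      minus <- tx$strand == "-"
      cds_i <- if (minus) L - cds_plus + 1L else cds_plus
      r <- ref[snv_i]
      a <- alt[snv_i]
      if (minus) {
        r <- chartr("ACGT", "TGCA", r)
        a <- chartr("ACGT", "TGCA", a)
      }
      have <- substr(rep(tx$cds, length(cds_i)), cds_i, cds_i)
      if (any(have != r)) {
        abort(paste0(g, ": reference allele mismatch at CDS position(s) ",
                     paste(cds_i[have != r], collapse = ", ")),
              class = "lynchburden_annotation_error")
      }
      codon_start <- ((cds_i - 1L) %/% 3L) * 3L + 1L
      within <- cds_i - codon_start + 1L
      codon <- substr(rep(tx$cds, length(cds_i)), codon_start,
                      codon_start + 2L)
      alt_codon <- codon
      substr(alt_codon, within, within) <- a
      p_ref <- unname(code[codon])
      p_alt <- unname(code[alt_codon])
      gi <- idx[snv_i]
      aa_ref[gi] <- p_ref
      aa_alt[gi] <- p_alt
      aa_pos[gi] <- (codon_start - 1L) %/% 3L + 1L
      consequence[gi] <- ifelse(p_ref == p_alt, "silent",
                                ifelse(p_alt == "*", "nonsense", "missense"))
    }

    # --- in-CDS indels -------------------------------------------------
    ind_i <- which(in_exon & is_indel)
    if (length(ind_i) > 0) {
      d <- nchar(ref[ind_i]) - nchar(alt[ind_i])
      cds_plus <- offs[ex[ind_i]] + pos[ind_i] - starts[ex[ind_i]] + 1L
      cds_i <- if (tx$strand == "-") L - cds_plus + 1L else cds_plus
      gi <- idx[ind_i]
      aa_pos[gi] <- (pmin(pmax(cds_i + 1L, 1L), L) - 1L) %/% 3L + 1L
      consequence[gi] <- ifelse(abs(d) %% 3L != 0L, "frameshift",
                                ifelse(d > 0, "inframe_deletion",
                                       "inframe_insertion"))
    }

    mnv_i <- which(in_exon & !is_snv & !is_indel)
    if (length(mnv_i) > 0) {
      abort(paste0(g, ": unsupported same-length multi-nucleotide variant"),
            class = "lynchburden_annotation_error")
    }
  }
  variants$consequence <- consequence
  variants$aa_ref <- aa_ref
  variants$aa_pos <- aa_pos
  variants$aa_alt <- aa_alt
  variants
}
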