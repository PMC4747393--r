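# Shared internal helpers: variant keys, chromosome ordering, TSV I/O.

#' Canonical string key for a genomic variant
#'
#' Builds the `chrom:pos:ref>alt` key used to match variant calls against
#' allele-frequency and annotation tables.
#'
#' @param chrom Chromosome name (e.g. `"chr7"`).
#' @param pos 1-based position (VCF convention).
#' @param ref,alt Reference and alternate alleles.
#' @return Character vector of keys.
#' @export
#' @examples
#' variant_key("chr7", 6035211, "T", "C")
variant_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

# Sort order for human-style chromosome names (chr1..chr22, chrX, chrY, chrM).
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", chrom)
  r <- suppressWarnings(as.numeric(x))
  r[x == "X"] <- 23
  r[x == "Y"] <- 24
  r[x %in% c("M", "MT")] <- 25
  r[is.na(r)] <- 26
  r
}

# Deterministic variant ordering used before any iteration that affects output.
order_variants <- function(df) {
  df[order(chrom_rank(df$chrom), df$pos, df$ref, df$alt), , drop = FALSE]
}

read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "lynchburden_io_error")
  }
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), check.names = FALSE,
                   colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s) in ", path, ": ",
                 paste(missing, collapse = ", ")),
          class = "lynchburden_schema_error")
  }
  tibble::as_tibble(df)
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  # list-columns are serialized as semicolon-joined strings
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(x) paste(x, collapse = ";"), "")
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

# light-weight tibble constructor for hot paths (no quosure machinery)
fast_tbl <- function(...) {
  l <- list(...)
  structure(l, class = c("tbl_df", "tbl", "data.frame"),
            row.names = c(NA_integer_, -length(l[[1]])))
}

# parse "53" -> 53L, "na"/""/NA -> NA_integer_
parse_age <- function(x) {
  out <- suppressWarnings(as.integer(x))
  out[!is.na(out) & (out < 0 | out > 120)] <- NA_integer_
  out
}
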