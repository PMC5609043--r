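# Gene-interval input for the Fst scan. BED (0-based half-open) and GFF3
# (1-based closed) are both normalized to the internal convention of 0-based
# half-open [start, end); variant positions stay 1-based. Conversions happen
# only here, at the I/O boundary.

#' Read gene intervals from BED or GFF3
#'
#' Records sharing a `gene_id` are merged into one interval spanning their
#' union, so the returned set has one row per gene.
#'
#' @param path file path.
#' @param format `"bed"` or `"gff3"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start` (0-based),
#'   `end` (exclusive), sorted by chromosome then start.
#' @export
read_gene_intervals <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  n_lines <- length(grep("^[^#[:space:]]", readLines(path)))
  if (n_lines == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  md <- as.data.frame(gr)
  id <- if (format == "bed") {
    md$name
  } else {
    md$gene_id %||% md$ID %||% md$Name
  }
  if (is.null(id) || all(is.na(id))) {
    stopf("no gene identifiers found in %s", path)
  }
  # GRanges is 1-based closed; convert to 0-based half-open
  ivs <- data.frame(gene_id = as.character(id),
                    chrom = as.character(md$seqnames),
                    start = md$start - 1L,
                    end = md$end,
                    stringsAsFactors = FALSE)
  ivs <- ivs[!is.na(ivs$gene_id), ]
  ivs <- gene_interval_set(ivs$gene_id, ivs$chrom, ivs$start, ivs$end)
  ivs
}

#' @rdname read_gene_intervals
#' @param gene_id,chrom,start,end interval fields; `start`/`end` 0-based
#'   half-open. Duplicated `gene_id` rows are unioned.
#' @export
gene_interval_set <- function(gene_id, chrom, start, end) {
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1]
    stopf("interval for gene %s has start >= end after normalization",
          df$gene_id[bad])
  }
  if (anyDuplicated(df$gene_id)) {
    chr_of <- tapply(df$chrom, df$gene_id, function(x) unique(x))
    if (any(lengths(chr_of) > 1)) {
      stopf("gene %s spans multiple chromosomes",
            names(chr_of)[lengths(chr_of) > 1][1])
    }
    df <- data.frame(
      gene_id = names(chr_of),
      chrom = unlist(chr_of),
      start = as.integer(tapply(df$start, df$gene_id, min)),
      end = as.integer(tapply(df$end, df$gene_id, max)),
      stringsAsFactors = FALSE
    )
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
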