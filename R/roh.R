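# Runs of homozygosity: two-stage SNP-count sliding-window scan in the style
# of PLINK's --homozyg, plus the F_ROH genome-fraction statistic.
#
# The scanning window is defined in SNPs (default 50) with per-window
# allowances for heterozygous and missing calls; a physical span guard
# (max_window_kb) additionally disqualifies windows stretched over sparse
# regions. Published SNP-array protocols often quote both a kb figure and a
# SNP count for "the window"; the SNP-count window carries the het/missing
# allowances here, with the kb figure acting as the span guard.

#' Detect runs of homozygosity
#'
#' Stage one slides a `window_snps`-SNP window along each chromosome of each
#' sample; a window is called homozygous when it contains at most `max_het`
#' heterozygous and at most `max_missing` missing calls (and spans at most
#' `max_window_kb`). Stage two scores every SNP by the fraction of
#' overlapping windows called homozygous; maximal runs of SNPs with score at
#' least `window_threshold` become segments, reported when they contain at
#' least `min_snps` SNPs and span at least `min_kb` kb.
#'
#' @param g genotype matrix.
#' @param vars matching variant table, positions sorted within chromosome.
#' @param window_snps SNPs per scanning window (default 50).
#' @param max_het maximum heterozygous calls per homozygous window (default 1).
#' @param max_missing maximum missing calls per window (default 5).
#' @param min_kb minimum reported segment span in kb (default 500).
#' @param min_snps minimum SNPs per reported segment (default 50).
#' @param window_threshold minimum fraction of homozygous overlapping windows
#'   for a SNP to be in the homozygous state (default 0.05).
#' @param max_window_kb span guard per window in kb (default 5000).
#' @return data.frame of segments: `sample_id`, `chrom`, `start`, `end` (bp,
#'   inclusive), `n_snps`, `length_bp`.
#' @export
detect_roh <- function(g, vars, window_snps = 50, max_het = 1, max_missing = 5,
                       min_kb = 500, min_snps = 50, window_threshold = 0.05,
                       max_window_kb = 5000) {
  validate_genotypes(g)
  stopifnot(ncol(g) == nrow(vars))
  if (any(tapply(vars$pos, vars$chrom, is.unsorted))) {
    stopf("variants must be sorted by position within chromosome")
  }
  out <- list()
  for (ch in unique(vars$chrom)) {
    cols <- which(vars$chrom == ch)
    M <- length(cols)
    if (M < window_snps) next
    pos <- vars$pos[cols]
    n_win <- M - window_snps + 1L
    span_ok <- (pos[seq_len(n_win) + window_snps - 1L] - pos[seq_len(n_win)]) <=
      max_window_kb * 1000
    for (i in seq_len(nrow(g))) {
      d <- g[i, cols]
      het <- cumsum(c(0L, as.integer(!is.na(d) & d == 1L)))
      mis <- cumsum(c(0L, as.integer(is.na(d))))
      w_het <- het[seq_len(n_win) + window_snps] - het[seq_len(n_win)]
      w_mis <- mis[seq_len(n_win) + window_snps] - mis[seq_len(n_win)]
      w_ok <- (w_het <= max_het) & (w_mis <= max_missing) & span_ok
      ok_cum <- cumsum(c(0L, as.integer(w_ok)))
      j <- seq_len(M)
      first_w <- pmax(1L, j - window_snps + 1L)
      last_w <- pmin(j, n_win)
      n_cover <- last_w - first_w + 1L
      score <- (ok_cum[last_w + 1L] - ok_cum[first_w]) / n_cover
      in_state <- n_cover > 0 & score >= window_threshold
      r <- rle(in_state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        ns <- r$lengths[k]
        bp <- pos[ends[k]] - pos[starts[k]] + 1L
        if (ns >= min_snps && bp >= min_kb * 1000) {
          out[[length(out) + 1L]] <- data.frame(
            sample_id = rownames(g)[i], chrom = ch,
            start = pos[starts[k]], end = pos[ends[k]],
            n_snps = ns, length_bp = bp, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), length_bp = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome fraction in runs of homozygosity
#'
#' F_ROH per individual is the summed ROH length divided by a genome
#' denominator: either the SNP-map span (sum over chromosomes of last minus
#' first SNP position; the default, self-contained choice) or a fixed
#' assembly length in bp supplied by the caller for cross-study
#' comparability.
#'
#' @param segments segment table from [detect_roh()].
#' @param vars variant table defining the map span.
#' @param sample_ids individuals to report (default: all samples appearing in
#'   `segments`); individuals without segments get `f_roh = 0`.
#' @param denominator `"map_span"` or `"fixed_bp"`.
#' @param fixed_bp genome length in bp when `denominator = "fixed_bp"`.
#' @return data.frame: `sample_id`, `n_segments`, `total_roh_bp`, `f_roh`.
#' @export
compute_froh <- function(segments, vars, sample_ids = NULL,
                         denominator = c("map_span", "fixed_bp"),
                         fixed_bp = NULL) {
  denominator <- match.arg(denominator)
  denom <- if (denominator == "map_span") {
    sum(tapply(vars$pos, vars$chrom, function(p) max(p) - min(p)))
  } else {
    fixed_bp %||% stopf("fixed_bp must be supplied for denominator='fixed_bp'")
  }
  if (is.na(denom) || denom <= 0) stopf("genome denominator must be positive")
  ids <- sample_ids %||% unique(segments$sample_id)
  tot <- vapply(ids, function(s) {
    sum(segments$length_bp[segments$sample_id == s])
  }, numeric(1))
  nseg <- vapply(ids, function(s) sum(segments$sample_id == s), numeric(1))
  data.frame(sample_id = ids, n_segments = as.integer(nseg),
             total_roh_bp = tot, f_roh = pmin(tot / denom, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
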