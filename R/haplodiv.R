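#' Construct and validate a phased haplotype matrix
#'
#' Haplotypes are a binary matrix with 2 rows per individual (rows 2i-1 and
#' 2i are the two haplotypes of sample i) and one column per variant. Entries
#' are 0/1 alleles with no missing values: statistical phasing is out of
#' scope, so input must already be phased and complete.
#'
#' @param h numeric 0/1 matrix with an even number of rows.
#' @param sample_ids identifiers, one per individual (half the row count).
#' @return validated integer matrix; row names `<id>_1` / `<id>_2`.
#' @export
haplotype_matrix <- function(h, sample_ids = NULL) {
  if (!is.matrix(h)) h <- as.matrix(h)
  storage.mode(h) <- "integer"
  if (nrow(h) %% 2 != 0) stopf("haplotype matrix must have an even row count")
  if (anyNA(h) || any(!(h %in% c(0L, 1L)))) {
    stopf("haplotypes must be complete 0/1 data; provide phased input")
  }
  n <- nrow(h) / 2
  sample_ids <- sample_ids %||% paste0("S", seq_len(n))
  stopifnot(length(sample_ids) == n)
  rownames(h) <- paste0(rep(sample_ids, each = 2), "_", c(1, 2))
  h
}

#' Windowed haplotype diversity per population
#'
#' For every population with at least `min_pop_n` individuals, exactly
#' `subsample_n` individuals (2x that many haplotypes) are drawn with the
#' given seed - never all of them, so that values are comparable across
#' populations of different sizes. Each chromosome is tiled with
#' non-overlapping windows of `w` SNPs (trailing remainder dropped) and the
#' statistic is the mean over windows of the number of distinct haplotype
#' strings, computed for each `w` in `window_sizes`.
#'
#' @param h haplotype matrix (see [haplotype_matrix()]).
#' @param populations population label per individual.
#' @param vars variant table giving the chromosome of each column.
#' @param window_sizes window lengths in SNPs (default 5, 10, 15).
#' @param subsample_n individuals drawn per population (default 10).
#' @param min_pop_n minimum population size; smaller populations are skipped
#'   with a warning (default 10).
#' @param seed RNG seed for the subsampling draw.
#' @return data.frame: `population`, `window_size`, `mean_haplotypes`,
#'   `n_windows`, `n_haplotypes`.
#' @export
haplotype_diversity <- function(h, populations, vars,
                                window_sizes = c(5, 10, 15),
                                subsample_n = 10, min_pop_n = 10,
                                seed = NULL) {
  if (anyNA(h) || any(!(h %in% c(0L, 1L)))) {
    stopf("haplotypes must be complete 0/1 data; provide phased input")
  }
  n <- nrow(h) / 2
  stopifnot(length(populations) == n, ncol(h) == nrow(vars))
  sizes <- table(populations)
  skipped <- names(sizes)[sizes < min_pop_n]
  if (length(skipped) > 0) {
    warnf("populations below %d individuals skipped: %s", min_pop_n,
          paste(skipped, collapse = ", "))
  }
  pops <- names(sizes)[sizes >= min_pop_n]
  chrom_cols <- split(seq_len(ncol(h)), vars$chrom)
  res <- list()
  for (pop in pops) {
    idx <- which(populations == pop)
    chosen <- with_seed(seed, sample(idx, subsample_n))
    hap_rows <- as.vector(rbind(2 * chosen - 1, 2 * chosen))
    sub <- h[hap_rows, , drop = FALSE]
    for (w in window_sizes) {
      counts <- integer(0)
      for (cols in chrom_cols) {
        n_win <- length(cols) %/% w
        if (n_win == 0) next
        for (b in seq_len(n_win)) {
          win <- cols[((b - 1) * w + 1):(b * w)]
          strs <- apply(sub[, win, drop = FALSE], 1, paste, collapse = "")
          counts <- c(counts, length(unique(strs)))
        }
      }
      res[[length(res) + 1L]] <- data.frame(
        population = pop, window_size = w,
        mean_haplotypes = if (length(counts)) mean(counts) else NA_real_,
        n_windows = length(counts), n_haplotypes = nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(population = character(), window_size = numeric(),
               mean_haplotypes = numeric(), n_windows = integer(),
               n_haplotypes = integer(), stringsAsFactors = FALSE)
  }
  attr(out, "seed") <- seed
  attr(out, "subsample_n") <- subsample_n
  out
}

#' Collapse haplotypes to genotype dosages
#'
#' @param h haplotype matrix.
#' @param sample_ids optional identifiers (defaults to haplotype row names
#'   with the `_1`/`_2` suffix removed).
#' @return genotype matrix of counted-allele dosages.
#' @export
haplotypes_to_genotypes <- function(h, sample_ids = NULL) {
  n <- nrow(h) / 2
  g <- h[seq(1, 2 * n, 2), , drop = FALSE] + h[seq(2, 2 * n, 2), , drop = FALSE]
  ids <- sample_ids %||% sub("_1$", "", rownames(h)[seq(1, 2 * n, 2)])
  genotype_matrix(g, ids, colnames(h))
}
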