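# Per-SNP Weir-Cockerham Fst between two groups (e.g. domestic vs wild),
# top-quantile outlier selection, candidate-gene proximity annotation, and
# the resampling null for outlier sets shared between two scans.

#' Select ancestry-pure individuals from an admixture fit
#'
#' Keeps samples whose largest ancestry fraction among `components` exceeds
#' `threshold`, the usual device for excluding recent hybrids before a
#' differentiation scan.
#'
#' @param fit `admixture_fit` object (or a bare Q matrix).
#' @param threshold purity threshold on the max ancestry fraction
#'   (exclusive, default 0.90).
#' @param components columns of Q considered (default all).
#' @return character vector of retained sample ids (or row indices when Q has
#'   no row names).
#' @export
select_pure_individuals <- function(fit, threshold = 0.90,
                                    components = NULL) {
  Q <- if (inherits(fit, "admixture_fit")) fit$Q else as.matrix(fit)
  components <- components %||% seq_len(ncol(Q))
  top <- apply(Q[, components, drop = FALSE], 1, max)
  keep <- which(top > threshold)
  if (length(keep) == 0) stopf("no individuals exceed the purity threshold")
  if (!is.null(rownames(Q))) rownames(Q)[keep] else keep
}

#' Per-variant Weir-Cockerham Fst
#'
#' The 1984 variance-components estimator theta = a / (a + b + c) for the
#' two-population biallelic case, computed per variant from sample sizes,
#' counted-allele frequencies and observed heterozygosity, with the standard
#' finite-sample corrections. Negative estimates are retained (not clipped):
#' they are informative about sampling noise and can never enter a
#' top-quantile outlier set. Variants with fewer than 2 called genotypes in
#' either group are returned as `NA`.
#'
#' @param g genotype matrix.
#' @param groups two-level factor/vector assigning each sample to a group.
#' @return data.frame: `variant_id`, `theta`, `rank` (1 = highest theta; `NA`
#'   thetas rank last), plus per-group called counts. The
#'   `"theta_multilocus"` attribute carries the multi-locus ratio-of-sums
#'   estimate (summed a over summed a+b+c components), the consistent
#'   genome-wide Fst; per-SNP thetas are for ranking and scanning.
#' @export
wc_fst <- function(g, groups) {
  validate_genotypes(g)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(g))
  lev <- sort(unique(groups))
  if (length(lev) != 2) stopf("exactly two groups required, found %d", length(lev))
  g1 <- g[groups == lev[1], , drop = FALSE]
  g2 <- g[groups == lev[2], , drop = FALSE]
  if (nrow(g1) == 0 || nrow(g2) == 0) stopf("one group is empty")

  comp <- function(gg) {
    n <- colSums(!is.na(gg))
    p <- colMeans(gg, na.rm = TRUE) / 2
    h <- colMeans(gg == 1L, na.rm = TRUE)
    list(n = n, p = p, h = h)
  }
  s1 <- comp(g1); s2 <- comp(g2)
  r <- 2
  n1 <- s1$n; n2 <- s2$n
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * s1$p + n2 * s2$p) / (r * nbar)
  s2v <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * s1$h + n2 * s2$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  usable <- n1 >= 2 & n2 >= 2
  theta[!usable] <- NA_real_
  theta[!is.finite(theta)] <- NA_real_     # e.g. monomorphic in both groups
  rk <- rank(-theta, ties.method = "first", na.last = "keep")
  rk[is.na(rk)] <- sum(!is.na(theta)) + seq_len(sum(is.na(theta)))
  out <- data.frame(variant_id = colnames(g), theta = theta,
                    rank = as.integer(rk),
                    n_called_1 = as.integer(n1), n_called_2 = as.integer(n2),
                    stringsAsFactors = FALSE, row.names = NULL)
  # the multi-locus estimator of Weir & Cockerham: ratio of summed variance
  # components, the consistent genome-wide Fst
  ok <- usable & is.finite(a) & is.finite(b) & is.finite(cc)
  attr(out, "theta_multilocus") <-
    sum(a[ok]) / sum(a[ok] + b[ok] + cc[ok])
  out
}

#' Top-quantile Fst outliers
#'
#' Selects the `round(q * M)` variants with the highest theta of an M-variant
#' scan. Ties at the cutoff (and `NA` thetas, which sort last) are broken by
#' genome order (chromosome, position), making the selection deterministic
#' and scale-free: any increasing transform of theta yields the same set.
#'
#' @param scan data.frame from [wc_fst()].
#' @param vars matching variant table (for the genome-order tie-break).
#' @param q outlier fraction in (0, 1), default 0.01.
#' @return the outlier subset of `scan`, ordered by decreasing theta, with an
#'   `outlier` column added.
#' @export
top_outliers <- function(scan, vars, q = 0.01) {
  stopifnot(q > 0, q < 1, nrow(scan) == nrow(vars))
  M <- nrow(scan)
  k <- round(q * M)
  ord <- order(-scan$theta, vars$chrom, vars$pos, na.last = TRUE)
  sel <- ord[seq_len(k)]
  out <- scan[sel, , drop = FALSE]
  out$chrom <- vars$chrom[sel]
  out$pos <- vars$pos[sel]
  out$outlier <- TRUE
  rownames(out) <- NULL
  out
}

#' Genes near outlier SNPs
#'
#' A gene is reported for an outlier SNP when the minimum distance between
#' the SNP position and the gene interval is at most `flank` bp (inclusive
#' boundary; distance 0 when the SNP lies inside the gene).
#'
#' @param outliers data.frame with `variant_id`, `chrom`, `pos`.
#' @param genes gene-interval set from [read_gene_intervals()].
#' @param flank flank size in bp (default 100000).
#' @return data.frame: `variant_id`, `chrom`, `pos`, `gene_id`, `distance`;
#'   zero rows for outliers with no gene within the flank.
#' @export
genes_near <- function(outliers, genes, flank = 100000) {
  if (nrow(genes) > 0) {
    unmatched <- setdiff(unique(outliers$chrom), unique(genes$chrom))
    if (length(unmatched) == length(unique(outliers$chrom)) &&
        nrow(outliers) > 0) {
      stopf("no shared chromosome names between outliers and genes (%s)",
            paste(unmatched, collapse = ", "))
    }
  }
  res <- list()
  for (i in seq_len(nrow(outliers))) {
    p <- outliers$pos[i]
    gsub <- genes[genes$chrom == outliers$chrom[i], , drop = FALSE]
    if (nrow(gsub) == 0) next
    # genes stored 0-based half-open; occupied 1-based positions are
    # (start+1)..end
    lo <- gsub$start + 1L
    hi <- gsub$end
    dist <- ifelse(p >= lo & p <= hi, 0L,
                   ifelse(p < lo, lo - p, p - hi))
    hit <- which(dist <= flank)
    if (length(hit)) {
      res[[length(res) + 1L]] <- data.frame(
        variant_id = outliers$variant_id[i], chrom = outliers$chrom[i],
        pos = p, gene_id = gsub$gene_id[hit], distance = dist[hit],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(variant_id = character(), chrom = character(),
               pos = integer(), gene_id = character(), distance = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Resampling null for outliers shared between two scans
#'
#' How many outliers would two scans share by chance? Draw `n_resamples`
#' pairs of random without-replacement variant sets of the observed sizes
#' from the common M-variant universe and count their overlap; the empirical
#' p-value is `(1 + #resamples >= observed) / (1 + n_resamples)`. The null
#' mean is the hypergeometric expectation |A||B|/M.
#'
#' @param set_a,set_b outlier identifier vectors (overlap = shared members).
#' @param universe_size number of variants M both scans drew from.
#' @param n_resamples resampling draws (default 10000).
#' @param seed RNG seed.
#' @return list: `observed_overlap`, `null_mean`, `null_sd`,
#'   `null_distribution`, `empirical_p`, `expected_overlap` (= |A||B|/M).
#' @export
shared_outlier_null <- function(set_a, set_b, universe_size,
                                n_resamples = 10000, seed = NULL) {
  ka <- length(unique(set_a)); kb <- length(unique(set_b))
  stopifnot(ka <= universe_size, kb <= universe_size)
  observed <- length(intersect(set_a, set_b))
  null <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      a <- sample.int(universe_size, ka)
      b <- sample.int(universe_size, kb)
      sum(!is.na(match(a, b)))
    }, numeric(1))
  })
  list(observed_overlap = observed,
       null_mean = mean(null), null_sd = stats::sd(null),
       null_distribution = null,
       empirical_p = (1 + sum(null >= observed)) / (1 + n_resamples),
       expected_overlap = ka * kb / universe_size,
       n_resamples = n_resamples)
}
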