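# Linkage disequilibrium and LD-decay effective population size. The link
# between LD and demography is the Sved relation E[r^2] = 1/(4*Ne*c + 1) for
# a pair of loci at genetic distance c Morgans; pairs at distance c carry
# information about Ne roughly T = 1/(2c) generations ago.

#' Assign genetic-map positions from a recombination-rate table
#'
#' Integrates a piecewise-constant recombination map (intervals in bp with a
#' rate in cM/Mb) into cumulative genetic positions in Morgans, writing the
#' `genetic_pos` column of the variant table. Positions outside every map
#' interval extrapolate with `fallback_cm_mb`.
#'
#' @param vars variant table.
#' @param rate_table data.frame with columns `chrom`, `start`, `end` (bp,
#'   0-based half-open) and `cm_per_mb`; `NULL` applies the constant
#'   fallback everywhere.
#' @param fallback_cm_mb rate used outside map intervals (default 1 cM/Mb).
#' @return the variant table with `genetic_pos` filled in (Morgans).
#' @export
add_genetic_positions <- function(vars, rate_table = NULL,
                                  fallback_cm_mb = 1) {
  morgans_to <- function(pos_bp, tab) {
    # cumulative Morgans from 0 to pos_bp under the piecewise map
    vapply(pos_bp, function(p) {
      total <- 0
      covered <- 0
      if (!is.null(tab) && nrow(tab) > 0) {
        for (k in seq_len(nrow(tab))) {
          lo <- tab$start[k]; hi <- min(tab$end[k], p)
          if (hi > lo) {
            total <- total + (hi - lo) * tab$cm_per_mb[k] * 1e-8
            covered <- covered + (hi - lo)
          }
        }
      }
      total + (p - covered) * fallback_cm_mb * 1e-8
    }, numeric(1))
  }
  for (ch in unique(vars$chrom)) {
    sel <- vars$chrom == ch
    tab <- if (is.null(rate_table)) NULL else {
      rate_table[rate_table$chrom == ch, , drop = FALSE]
    }
    vars$genetic_pos[sel] <- morgans_to(vars$pos[sel], tab)
  }
  vars
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact p-value conditioning on the observed allele counts
#' (Wigginton-style): the probabilities of all heterozygote counts compatible
#' with the allele counts are computed by recurrence and those no more
#' probable than the observed configuration are summed.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stopf("all genotype counts are zero")
  rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (rare == 0) return(1)                     # monomorphic: single configuration
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # anchor the recurrence at the modal het count (numerically stable for
  # large samples) and work outward with the ratio identities
  # P(h+2)/P(h) = 4*nr*nc / ((h+2)*(h+1)) and its inverse, where nr, nc are
  # the rare/common homozygote counts at h
  h0 <- round(rare * (2 * n - rare) / (2 * n))
  if (h0 %% 2 != rare %% 2) h0 <- h0 + 1
  h0 <- min(max(h0, hets[1]), hets[length(hets)])
  anchor <- which(hets == h0)
  probs[anchor] <- 1
  if (anchor < length(hets)) {
    for (k in (anchor + 1):length(hets)) {
      h <- hets[k - 1]
      nr <- (rare - h) / 2
      nc <- n - h - nr
      probs[k] <- probs[k - 1] * 4 * nr * nc / ((h + 2) * (h + 1))
    }
  }
  if (anchor > 1) {
    for (k in (anchor - 1):1) {
      h <- hets[k + 1]
      nr <- (rare - h) / 2
      nc <- n - h - nr
      probs[k] <- probs[k + 1] * h * (h - 1) / (4 * (nr + 1) * (nc + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- which(hets == n_Aa)
  sum(probs[probs <= probs[obs] * (1 + 1e-10)])
}

#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation of dosage vectors over co-called samples, for
#' adjacent retained SNPs (the classical within-population LD computation) or
#' for all pairs within a physical window (which populates long-range
#' distance bins far better for trajectory fitting). Variants are first
#' filtered on MAF (strictly greater than `maf_min`) and the HWE exact test
#' (p strictly greater than `hwe_min`). Genetic distance `c` in Morgans is
#' taken from the variant table's `genetic_pos` where present, otherwise from
#' the physical distance times a constant recombination rate.
#'
#' @param g genotype matrix; `vars` matching variant table.
#' @param mode `"adjacent"` or `"window"`.
#' @param max_bp maximum pair distance in bp for `mode = "window"`.
#' @param maf_min MAF filter (exclusive bound, default 0.05).
#' @param hwe_min HWE exact-test p-value filter (exclusive, default 1e-6).
#' @param rate_cm_mb fallback recombination rate in cM/Mb (default 1).
#' @param min_pair_n minimum co-called samples per pair (default 3); pairs
#'   below it are dropped and counted in the `n_dropped` attribute.
#' @return data.frame: `id_a`, `id_b`, `chrom`, `bp`, `c`, `r2`.
#' @export
pairwise_r2 <- function(g, vars, mode = c("adjacent", "window"),
                        max_bp = 10e6, maf_min = 0.05, hwe_min = 1e-6,
                        rate_cm_mb = 1, min_pair_n = 3) {
  mode <- match.arg(mode)
  validate_genotypes(g)
  stopifnot(ncol(g) == nrow(vars))
  mf <- maf(g)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    d <- g[, j]
    hwe_exact_test(sum(d == 2, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                   sum(d == 0, na.rm = TRUE))
  }, numeric(1))
  keep <- !is.na(mf) & mf > maf_min & hwe_p > hwe_min
  g <- g[, keep, drop = FALSE]
  vars <- vars[keep, , drop = FALSE]
  res <- list()
  n_dropped <- 0L
  for (ch in unique(vars$chrom)) {
    cols <- which(vars$chrom == ch)
    if (length(cols) < 2) next
    pos <- vars$pos[cols]
    gp <- vars$genetic_pos[cols]
    use_map <- !anyNA(gp)
    pairs <- if (mode == "adjacent") {
      cbind(seq_len(length(cols) - 1), seq_len(length(cols) - 1) + 1L)
    } else {
      idx <- which(outer(pos, pos, function(a, b) b - a) > 0 &
                     outer(pos, pos, function(a, b) abs(b - a)) <= max_bp,
                   arr.ind = TRUE)
      idx[idx[, 1] < idx[, 2], , drop = FALSE]
    }
    if (nrow(pairs) == 0) next
    cm <- suppressWarnings(
      stats::cor(g[, cols, drop = FALSE], use = "pairwise.complete.obs"))
    called <- (!is.na(g[, cols, drop = FALSE])) * 1
    ncoc <- crossprod(called)
    r2 <- cm[pairs]^2
    nn <- ncoc[pairs]
    ok <- !is.na(r2) & nn >= min_pair_n
    n_dropped <- n_dropped + sum(!ok)
    if (!any(ok)) next
    pairs <- pairs[ok, , drop = FALSE]
    bp <- pos[pairs[, 2]] - pos[pairs[, 1]]
    cc <- if (use_map) gp[pairs[, 2]] - gp[pairs[, 1]]
          else bp * rate_cm_mb * 1e-8
    res[[length(res) + 1L]] <- data.frame(
      id_a = vars$variant_id[cols][pairs[, 1]],
      id_b = vars$variant_id[cols][pairs[, 2]],
      chrom = ch, bp = bp, c = cc, r2 = r2[ok],
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(id_a = character(), id_b = character(), chrom = character(),
               bp = integer(), c = numeric(), r2 = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Effective-population-size trajectory from LD decay
#'
#' Pairs are grouped into genetic-distance bins; per bin, the Sved relation
#' is inverted at the bin means, `Ne = (1/mean(r2) - 1) / (4 * mean(c))`, and
#' the bin is labelled with generation `T = 1 / (2 * mean(c))`. No
#' sample-size correction is applied by default; `adjust_n` subtracts
#' 1/(2*adjust_n) from the mean r-squared first (a documented convention for
#' removing the finite-sample inflation of r-squared). A whole-range
#' nonlinear least-squares fit of a single Ne is also attempted.
#'
#' @param pairs data.frame from [pairwise_r2()] (`c`, `r2` columns used).
#' @param bins numeric vector of bin edges on `c` (Morgans); default 10
#'   equal-count bins.
#' @param n_bins number of default bins.
#' @param adjust_n optional sample count for the r-squared bias adjustment.
#' @return object of class `ne_trajectory`: data.frame `trajectory` with
#'   `T`, `Ne`, `n_pairs`, `c_mean`, `r2_mean`; plus `fit_ne`, `fit_residual`.
#' @export
fit_sved <- function(pairs, bins = NULL, n_bins = 10, adjust_n = NULL) {
  stopifnot(nrow(pairs) > 0, all(pairs$c >= 0))
  pairs <- pairs[pairs$c > 0, , drop = FALSE]
  if (nrow(pairs) == 0) stopf("no pairs with positive genetic distance")
  if (is.null(bins)) {
    bins <- unique(stats::quantile(pairs$c, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(bins) < 2) bins <- range(pairs$c) + c(-1e-12, 1e-12)
  }
  grp <- cut(pairs$c, bins, include.lowest = TRUE)
  rows <- list()
  for (lev in levels(grp)) {
    sel <- !is.na(grp) & grp == lev
    if (!any(sel)) next
    cbar <- mean(pairs$c[sel])
    r2bar <- mean(pairs$r2[sel])
    if (!is.null(adjust_n)) r2bar <- r2bar - 1 / (2 * adjust_n)
    if (!is.finite(r2bar) || r2bar <= 0 || r2bar >= 1) {
      warnf("bin %s skipped (mean r2 = %.4g outside (0,1))", lev, r2bar)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      T = 1 / (2 * cbar), Ne = (1 / r2bar - 1) / (4 * cbar),
      n_pairs = sum(sel), c_mean = cbar, r2_mean = r2bar)
  }
  traj <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(T = numeric(), Ne = numeric(), n_pairs = integer(),
               c_mean = numeric(), r2_mean = numeric())
  }
  traj <- traj[order(traj$T), , drop = FALSE]
  rownames(traj) <- NULL
  fit_ne <- NA_real_; fit_resid <- NA_real_
  if (nrow(traj) > 0) {
    start_ne <- stats::median(traj$Ne)
    fit <- tryCatch(
      stats::nls(r2 ~ 1 / (4 * Ne * c + 1), data = pairs,
                 start = list(Ne = max(start_ne, 1))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fit_ne <- unname(stats::coef(fit)[["Ne"]])
      fit_resid <- sqrt(mean(stats::residuals(fit)^2))
    }
  }
  out <- list(trajectory = traj, fit_ne = fit_ne, fit_residual = fit_resid,
              method = "sved_bin_inversion")
  class(out) <- "ne_trajectory"
  out
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("LD-decay Ne trajectory (Sved inversion per genetic-distance bin)\n")
  print(x$trajectory, row.names = FALSE)
  if (is.finite(x$fit_ne)) {
    cat(sprintf("Whole-range NLS fit: Ne = %.1f (rms residual %.4f)\n",
                x$fit_ne, x$fit_residual))
  }
  invisible(x)
}
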