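# Quality control: breed-size, relatedness and call-rate filters on samples;
# MAF and call-rate filters on variants; windowed LD pruning.

qc_report <- function(axis, n_in, removed) {
  removed <- unlist(removed)
  storage.mode(removed) <- "integer"
  rep <- list(axis = axis, n_in = as.integer(n_in),
              removed = as.list(removed),
              n_out = as.integer(n_in - sum(removed)))
  stopifnot(rep$n_out >= 0)
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report (%s): %d in, %d out\n", x$axis, x$n_in, x$n_out))
  for (nm in names(x$removed)) {
    cat(sprintf("  - removed by %s: %d\n", nm, x$removed[[nm]]))
  }
  invisible(x)
}

#' Sample-level quality control
#'
#' Reproduces the cohort-assembly cascade used for SNP-array diversity
#' panels: (1) breeds with fewer than `min_breed_n` individuals are dropped
#' entirely; (2) within each breed that entered with more than `cap`
#' individuals, one member of every highly related pair (IBS similarity
#' above `relatedness_ibs`) is removed at random (seeded), and the survivors
#' are then ranked by SNP call rate with only the top `cap` kept.
#'
#' @param g genotype matrix.
#' @param meta matching sample table.
#' @param min_breed_n minimum breed size (default 5).
#' @param relatedness_ibs IBS similarity above which a pair is treated as
#'   duplicates/close relatives (default 0.95).
#' @param cap maximum breed size after QC (default 20).
#' @param seed seed for the random member-of-pair removals.
#' @return list with filtered `genotypes`, `samples` and a `report`.
#' @export
filter_samples <- function(g, meta, min_breed_n = 5, relatedness_ibs = 0.95,
                           cap = 20, seed = NULL) {
  stopifnot(nrow(g) == nrow(meta))
  n_in <- nrow(g)
  sizes <- table(meta$population)
  small <- names(sizes)[sizes < min_breed_n]
  keep <- !(meta$population %in% small)
  n_small <- sum(!keep)

  cr <- if (all(is.na(meta$call_rate))) sample_call_rate(g) else meta$call_rate
  removed_rel <- 0L; removed_cap <- 0L
  drop <- rep(FALSE, n_in)
  drop[!keep] <- TRUE
  with_seed(seed, {
    for (pop in names(sizes)[sizes > cap & !(names(sizes) %in% small)]) {
      idx <- which(meta$population == pop & !drop)
      sim <- ibs_matrix(g[idx, , drop = FALSE], "similarity")
      alive <- rep(TRUE, length(idx))
      repeat {
        sub <- sim[alive, alive, drop = FALSE]
        sub[lower.tri(sub, diag = TRUE)] <- NA
        hot <- which(sub > relatedness_ibs, arr.ind = TRUE)
        if (nrow(hot) == 0) break
        pair <- hot[1, ]
        victim <- which(alive)[pair[sample(2, 1)]]
        alive[victim] <- FALSE
        removed_rel <- removed_rel + 1L
      }
      surv <- idx[alive]
      if (length(surv) > cap) {
        ranked <- surv[order(-cr[surv])]
        removed_cap <- removed_cap + length(surv) - cap
        drop[setdiff(surv, ranked[seq_len(cap)])] <- TRUE
      }
      drop[idx[!alive]] <- TRUE
    }
  })
  if (all(drop)) stopf("all samples removed by QC")
  rep <- qc_report("samples", n_in,
                   list(breed_too_small = n_small,
                        related_pair = removed_rel,
                        over_cap = removed_cap))
  list(genotypes = g[!drop, , drop = FALSE],
       samples = meta[!drop, , drop = FALSE],
       report = rep)
}

#' Variant- and sample-level call-rate/MAF filters
#'
#' Variants failing the MAF or call-rate threshold are removed first, then
#' samples failing the sample call-rate threshold, matching the published
#' filter order. MAF is recomputed on the sample set entering the call.
#'
#' @param g genotype matrix; `vars` matching variant table.
#' @param maf_min minimum minor-allele frequency (inclusive).
#' @param var_callrate_min minimum variant call rate (default 0.90).
#' @param sample_callrate_min minimum sample call rate (default 0.90).
#' @return list with filtered `genotypes`, `variants`, `sample_keep` (logical
#'   over input samples) and a `report`.
#' @export
filter_variants <- function(g, vars, maf_min = 0.01, var_callrate_min = 0.90,
                            sample_callrate_min = 0.90) {
  stopifnot(ncol(g) == nrow(vars), maf_min >= 0, maf_min <= 0.5)
  m_in <- ncol(g)
  mf <- maf(g)
  vcr <- variant_call_rate(g)
  fail_maf <- is.na(mf) | mf < maf_min
  fail_cr <- vcr < var_callrate_min
  vkeep <- !(fail_maf | fail_cr)
  g2 <- g[, vkeep, drop = FALSE]
  scr <- sample_call_rate(g2)
  skeep <- scr >= sample_callrate_min
  if (!any(vkeep) || !any(skeep)) warnf("QC output is empty")
  rep <- qc_report("variants", m_in,
                   list(low_maf = sum(fail_maf),
                        low_call_rate = sum(fail_cr & !fail_maf)))
  list(genotypes = g2[skeep, , drop = FALSE],
       variants = vars[vkeep, , drop = FALSE],
       sample_keep = skeep,
       report = rep)
}

#' Windowed LD pruning
#'
#' Greedy left-to-right pruning in sliding windows of `window` variants
#' advanced by `step`, dropping one variant of every retained pair whose
#' genotype r-squared exceeds `r2_max`. Within an offending pair the variant
#' with the lower MAF is dropped (tie: the later genomic position), a
#' deterministic rule close to common practice; bitwise concordance with any
#' particular external tool is not a goal.
#'
#' @param g genotype matrix; `vars` matching variant table sorted by
#'   (chromosome, position).
#' @param window window size in variants (default 50).
#' @param step window advance in variants (default 10).
#' @param r2_max maximum retained pairwise r-squared (default 0.2).
#' @return list with pruned `genotypes`, `variants` and a `report`.
#' @export
ld_prune <- function(g, vars, window = 50, step = 10, r2_max = 0.2) {
  stopifnot(ncol(g) == nrow(vars))
  if (any(tapply(vars$pos, vars$chrom, is.unsorted))) {
    stopf("variants must be sorted by position within chromosome")
  }
  m <- ncol(g)
  mf <- maf(g)
  keep <- rep(TRUE, m)
  for (ch in unique(vars$chrom)) {
    idx <- which(vars$chrom == ch)
    if (length(idx) < 2) next
    starts <- seq(1, max(1, length(idx) - 1), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(stats::cor(g[, win, drop = FALSE],
                                        use = "pairwise.complete.obs"))^2
      for (a in seq_len(length(win) - 1)) {
        if (!keep[win[a]]) next
        for (b in (a + 1):length(win)) {
          if (!keep[win[b]]) next
          if (!is.na(r2[a, b]) && r2[a, b] > r2_max) {
            va <- win[a]; vb <- win[b]
            victim <- if (mf[va] < mf[vb]) va
                      else if (mf[vb] < mf[va]) vb
                      else if (vars$pos[va] > vars$pos[vb]) va else vb
            keep[victim] <- FALSE
            if (victim == va) break
          }
        }
      }
    }
  }
  rep <- qc_report("variants", m, list(ld_pruned = sum(!keep)))
  list(genotypes = g[, keep, drop = FALSE],
       variants = vars[keep, , drop = FALSE],
       report = rep)
}
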