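# Independent oracles used by module and acceptance tests. These share no
# code with the package implementations they check.

# Literal transcription of the two-population Weir-Cockerham variance
# components, locus by locus from two dosage vectors.
wc_oracle <- function(d1, d2) {
  stats_of <- function(d) {
    d <- d[!is.na(d)]
    list(n = length(d), p = mean(d) / 2, h = mean(d == 1))
  }
  s1 <- stats_of(d1); s2 <- stats_of(d2)
  r <- 2
  nbar <- (s1$n + s2$n) / 2
  nc <- (s1$n + s2$n - (s1$n^2 + s2$n^2) / (s1$n + s2$n)) / (r - 1)
  pbar <- (s1$n * s1$p + s2$n * s2$p) / (s1$n + s2$n)
  ssq <- (s1$n * (s1$p - pbar)^2 + s2$n * (s2$p - pbar)^2) / nbar
  hbar <- (s1$n * s1$h + s2$n * s2$h) / (s1$n + s2$n)
  a <- nbar / nc * (ssq - (pbar * (1 - pbar) - ssq / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - ssq / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# Direct factorial-formula enumeration of the exact HWE test (conditional
# distribution of the heterozygote count given allele counts).
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2
    nbb <- n - naa - h
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[hets == n_Aa]
  sum(p[p <= obs * (1 + 1e-10)])
}
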