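# Shared fixture builders. All fixtures are generated in code; random ones
# take an explicit seed so failures reproduce.

# Random genotype matrix guaranteed polymorphic per column (both homozygotes
# observed), so PED round trips are unambiguous.
random_genotypes <- function(n = 8, m = 20, miss_rate = 0, seed = 1) {
  set.seed(seed)
  draw_col <- function() {
    repeat {
      x <- rbinom(n, 2, runif(1, 0.3, 0.7))
      if (miss_rate > 0) x[runif(n) < miss_rate] <- NA
      if (any(x == 0, na.rm = TRUE) && any(x == 2, na.rm = TRUE) &&
          !all(is.na(x))) {
        return(x)
      }
    }
  }
  genotype_matrix(vapply(seq_len(m), function(j) draw_col(), integer(n)))
}

# Matching metadata for a genotype matrix: one chromosome, 1-kb spacing.
fixture_tables <- function(g) {
  list(samples = sample_table(rownames(g), population = "popA",
                              call_rate = sample_call_rate(g)),
       variants = variant_table(colnames(g), "1",
                                pos = seq_len(ncol(g)) * 1000L))
}

# One-chromosome variant table at the given positions.
vars_at <- function(pos, chrom = "1", rate_cm_mb = 1) {
  variant_table(paste0("snp", seq_along(pos)), chrom, pos,
                genetic_pos = pos * rate_cm_mb * 1e-8)
}
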