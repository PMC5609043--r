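# HWE exact test, pairwise r2, Sved-equation Ne.

test_that("HWE exact test matches enumeration on canonical tables", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)             # monomorphic
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  expect_equal(hwe_exact_test(0, 20, 0), hwe_enum_oracle(0, 20, 0))
  p_eq <- hwe_exact_test(25, 50, 25)
  expect_equal(p_eq, hwe_enum_oracle(25, 50, 25))
  expect_gte(p_eq, 0.5)                                  # modal configuration
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("HWE exact test equals brute force on random tables", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    nA <- sample(0:(2 * n), 1)
    max_het <- min(nA, 2 * n - nA)
    het <- sample(seq(nA %% 2, max_het, by = 2), 1)
    n_AA <- (nA - het) / 2
    n_aa <- n - n_AA - het
    expect_equal(hwe_exact_test(n_AA, het, n_aa),
                 hwe_enum_oracle(n_AA, het, n_aa), tolerance = 1e-12)
  }
})

test_that("pairwise r2 hits its fixed points and coding invariances", {
  set.seed(23)
  a <- rbinom(300, 2, 0.5)
  g <- genotype_matrix(cbind(a, a, 2L - a))
  vars <- vars_at(c(1e4, 2e4, 3e4))
  pairs <- pairwise_r2(g, vars, mode = "window", max_bp = 1e6)
  expect_identical(nrow(pairs), 3L)
  expect_true(all(abs(pairs$r2 - 1) < 1e-12))    # duplicates and 2-d flip
  # c from constant-rate fallback: genetic_pos supplied by vars_at
  expect_equal(pairs$c[pairs$id_a == "snp1" & pairs$id_b == "snp2"], 1e4 * 1e-8)
})

test_that("independent variants have near-zero mean r2 (1/n bias scale)", {
  set.seed(29)
  n <- 10000
  g <- genotype_matrix(matrix(rbinom(n * 12, 2, 0.5), n, 12))
  pairs <- pairwise_r2(g, vars_at(seq_len(12) * 1e5), mode = "window",
                       max_bp = 1e9)
  expect_lt(mean(pairs$r2), 0.001)
})

test_that("MAF and HWE filters are applied before pairing", {
  set.seed(31)
  n <- 200
  ok <- rbinom(n, 2, 0.5)
  rare <- rbinom(n, 2, 0.02)                    # MAF ~ 0.02 < 0.05
  hwe_bad <- rep(c(0L, 2L), n / 2)              # no hets: HWE p tiny
  stopifnot(hwe_exact_test(sum(hwe_bad == 2), 0, sum(hwe_bad == 0)) < 1e-6)
  g <- genotype_matrix(cbind(ok, rare, hwe_bad, rbinom(n, 2, 0.4)))
  pairs <- pairwise_r2(g, vars_at(1:4 * 1e4), mode = "window", max_bp = 1e9)
  used <- unique(c(pairs$id_a, pairs$id_b))
  expect_setequal(used, c("snp1", "snp4"))
})

test_that("Sved inversion is exact on noise-free decay curves", {
  # property: generate r2 from the Sved curve for random Ne, recover Ne
  set.seed(37)
  for (i in 1:10) {
    ne <- runif(1, 10, 2000)
    cs <- seq(0.001, 0.05, length.out = 40)
    pairs <- data.frame(c = cs, r2 = 1 / (4 * ne * cs + 1))
    traj <- fit_sved(pairs, bins = c(0, cs))   # one pair per bin
    expect_equal(traj$trajectory$Ne, rep(ne, 40), tolerance = 1e-9)
    # trajectory is ordered by look-back time (largest c first)
    expect_equal(traj$trajectory$T, sort(1 / (2 * cs)), tolerance = 1e-9)
  }
  # generation labelling: c = 0.1 Morgan looks back T = 5 generations
  one <- fit_sved(data.frame(c = 0.1, r2 = 1 / (4 * 100 * 0.1 + 1)))
  expect_equal(one$trajectory$T, 5)
  expect_equal(one$trajectory$Ne, 100, tolerance = 1e-9)
})

test_that("estimated Ne tracks true population size across simulations", {
  meds <- vapply(c(25, 100), function(N) {
    est <- vapply(1:6, function(rep) {
      wf <- sim_wright_fisher(n_diploid = N, generations = 100, n_snps = 250,
                              chrom_length_bp = 10e6, seed = 1000 * N + rep)
      pr <- pairwise_r2(wf$genotypes, wf$variants, mode = "window",
                        max_bp = 10e6)
      # replicates that lost all variation to drift carry no LD information
      if (nrow(pr) == 0) return(NA_real_)
      traj <- fit_sved(pr, bins = c(0.02, 0.1))
      if (nrow(traj$trajectory) == 0) NA_real_ else traj$trajectory$Ne[1]
    }, numeric(1))
    median(est, na.rm = TRUE)
  }, numeric(1))
  expect_lt(meds[1], meds[2])            # monotone recovery
})

test_that("smaller samples bias Ne estimates downward on identical data", {
  wf <- sim_wright_fisher(n_diploid = 100, generations = 80, n_snps = 250,
                          chrom_length_bp = 10e6, seed = 71)
  sub_ne <- function(rows) {
    g <- genotype_matrix(wf$genotypes[rows, , drop = FALSE])
    pr <- pairwise_r2(g, wf$variants, mode = "window", max_bp = 10e6)
    fit_sved(pr, bins = c(0.05, 0.1))$trajectory$Ne[1]
  }
  full <- sub_ne(seq_len(100))
  small <- sub_ne(seq_len(12))
  expect_lt(small, full)
})

test_that("recombination-rate tables integrate into Morgan positions", {
  vars <- variant_table(paste0("s", 1:4), "1", c(1e6, 3e6, 5e6, 9e6))
  # 2 cM/Mb over [0, 4 Mb), fallback 1 cM/Mb elsewhere
  map <- data.frame(chrom = "1", start = 0, end = 4e6, cm_per_mb = 2)
  out <- add_genetic_positions(vars, map)
  # hand-integrated: 1 Mb @2 = 0.02 M; 3 Mb @2 = 0.06; 4 @2 + 1 @1 = 0.09;
  # 4 @2 + 5 @1 = 0.13
  expect_equal(out$genetic_pos, c(0.02, 0.06, 0.09, 0.13), tolerance = 1e-12)
  # constant fallback only
  flat <- add_genetic_positions(vars, NULL, fallback_cm_mb = 1)
  expect_equal(flat$genetic_pos, vars$pos * 1e-8)
  # the filled map feeds pairwise c directly
  set.seed(91)
  g <- genotype_matrix(matrix(rbinom(200 * 4, 2, 0.5), 200, 4))
  pr <- pairwise_r2(g, out, mode = "adjacent")
  expect_equal(pr$c, diff(out$genetic_pos))
})
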