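# Weir-Cockerham Fst scan, outlier machinery, gene proximity, overlap null.

test_that("theta is 1 at fixed differences and <= 0 without differentiation", {
  g <- genotype_matrix(rbind(matrix(2L, 5, 3), matrix(0L, 7, 3)))
  groups <- rep(c("dom", "wild"), c(5, 7))
  scan <- wc_fst(g, groups)
  expect_equal(scan$theta, rep(1, 3))

  # every sample identical: group frequencies and heterozygosity coincide
  g2 <- genotype_matrix(matrix(rep(c(0L, 1L, 2L, 1L), each = 4), 4, 4))
  scan2 <- wc_fst(g2, rep(c("a", "b"), each = 2))
  expect_true(all(scan2$theta <= 1e-12 | is.na(scan2$theta)))
})

test_that("theta matches an independent variance-components oracle", {
  set.seed(51)
  for (i in 1:100) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    d1 <- rbinom(n1, 2, runif(1, 0.1, 0.9))
    d2 <- rbinom(n2, 2, runif(1, 0.1, 0.9))
    if (sum(c(d1, d2)) %in% c(0, 2 * (n1 + n2))) next    # monomorphic overall
    g <- genotype_matrix(matrix(c(d1, d2), ncol = 1))
    th <- wc_fst(g, rep(c("g1", "g2"), c(n1, n2)))$theta
    expect_equal(th, wc_oracle(d1, d2), tolerance = 1e-12)
  }
})

test_that("theta is symmetric in group order and allele coding", {
  sim <- sim_balding_nichols(n_snps = 100, fst = 0.15, samples_per_pop = 15,
                             seed = 53)
  groups <- sim$samples$population
  t1 <- wc_fst(sim$genotypes, groups)$theta
  swapped <- ifelse(groups == "pop1", "zz", "aa")
  t2 <- wc_fst(sim$genotypes, swapped)$theta
  expect_equal(t1, t2, tolerance = 1e-12)
  t3 <- wc_fst(flip_alleles(sim$genotypes), groups)$theta
  expect_equal(t1, t3, tolerance = 1e-12)
})

test_that("purity selection keeps exactly the non-hybrids", {
  Q <- rbind(c(0.95, 0.05), c(0.89, 0.11), c(0.05, 0.95), c(0.50, 0.50))
  rownames(Q) <- paste0("s", 1:4)
  kept <- select_pure_individuals(Q, 0.90)
  expect_identical(kept, c("s1", "s3"))
  sim <- sim_balding_nichols(n_snps = 50, fst = 0.3, n_pops = 2,
                             samples_per_pop = 40, seed = 55)
  Qmix <- sim$Q_true
  hyb <- sample(nrow(Qmix), 8)
  Qmix[hyb, ] <- 0.5
  kept2 <- select_pure_individuals(Qmix, 0.90)
  expect_identical(sort(as.integer(kept2)), setdiff(seq_len(nrow(Qmix)), sort(hyb)))
})

test_that("top-quantile selection counts, tie-breaks and scale invariance", {
  set.seed(57)
  M <- 42808
  theta <- runif(M)
  vars <- variant_table(paste0("v", 1:M), chrom = rep("1", M), pos = 1:M)
  scan <- data.frame(variant_id = vars$variant_id, theta = theta,
                     rank = rank(-theta, ties.method = "first"))
  out <- top_outliers(scan, vars, q = 0.01)
  expect_identical(nrow(out), 428L)
  # scale-free: a monotone transform leaves the set unchanged
  scan2 <- scan; scan2$theta <- exp(5 * scan$theta)
  out2 <- top_outliers(scan2, vars, q = 0.01)
  expect_setequal(out$variant_id, out2$variant_id)
  # M = 100 -> a single outlier
  small <- scan[1:100, ]; vs <- vars[1:100, ]
  expect_identical(nrow(top_outliers(small, vs, 0.01)), 1L)
  # all-equal thetas: ties resolved in genome order
  flat <- data.frame(variant_id = vs$variant_id, theta = rep(0.5, 100),
                     rank = 1:100)
  got <- top_outliers(flat, vs, 0.05)
  expect_identical(got$variant_id, paste0("v", 1:5))
})

test_that("gene proximity respects the inclusive 100-kb boundary", {
  genes <- gene_interval_set(c("inside", "near", "far"), "1",
                             start = c(500000, 1700000, 1800001),
                             end = c(600000, 1750000, 1900000))
  outl <- data.frame(variant_id = "snp1", chrom = "1", pos = 550000L)
  hits <- genes_near(outl, genes, flank = 100000)
  expect_identical(hits$gene_id, "inside")
  expect_identical(hits$distance, 0L)

  # gene starting exactly 100,000 bp past the SNP is reported; one bp more
  # is not. SNP at 1.6 Mb: "near" starts (1-based) at 1700001 -> 100001 away
  outl2 <- data.frame(variant_id = "snp2", chrom = "1", pos = 1600000L)
  hits2 <- genes_near(outl2, genes, flank = 100000)
  expect_identical(hits2$gene_id, character(0))
  outl3 <- data.frame(variant_id = "snp3", chrom = "1", pos = 1600001L)
  hits3 <- genes_near(outl3, genes, flank = 100000)
  expect_identical(hits3$gene_id, "near")
  expect_identical(hits3$distance, 100000L)

  expect_error(genes_near(data.frame(variant_id = "x", chrom = "7",
                                     pos = 1L), genes),
               "chromosome")
})

test_that("overlap null has hypergeometric behavior and sane p-values", {
  # identical sets: maximal overlap, minimal p
  res <- shared_outlier_null(1:50, 1:50, universe_size = 5000,
                             n_resamples = 500, seed = 2)
  expect_identical(res$observed_overlap, 50L)
  expect_equal(res$empirical_p, 1 / 501)
  # empty sets: overlap 0, p = 1
  res0 <- shared_outlier_null(integer(0), integer(0), 100,
                              n_resamples = 100, seed = 3)
  expect_identical(res0$observed_overlap, 0L)
  expect_equal(res0$empirical_p, 1)
  # null mean/variance match the hypergeometric expectation
  res2 <- shared_outlier_null(1:40, 2000 + 1:60, universe_size = 4000,
                              n_resamples = 4000, seed = 5)
  expect_equal(res2$null_mean, 40 * 60 / 4000, tolerance = 0.15)
  hyper_var <- {
    k1 <- 40; k2 <- 60; M <- 4000
    k2 * (k1 / M) * (1 - k1 / M) * (M - k2) / (M - 1)
  }
  expect_equal(res2$null_sd^2, hyper_var, tolerance = 0.15)
})
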