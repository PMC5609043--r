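# IBS distances, classical MDS, NJ trees, geographic correlation.

test_that("IBS similarity matches hand-computed values", {
  g <- genotype_matrix(rbind(c(2L, 0L, 1L), c(2L, 0L, 1L)))
  s <- ibs_matrix(g, "similarity")
  expect_equal(s[1, 2], 1)                        # identical vectors
  expect_equal(ibs_matrix(g, "distance")[1, 2], 0)

  g2 <- genotype_matrix(rbind(c(2L, 2L), c(0L, 0L)))
  expect_equal(ibs_matrix(g2, "similarity")[1, 2], 0)  # opposite homozygotes

  g3 <- genotype_matrix(rbind(2L, 1L))                 # AA vs Aa: one step
  expect_equal(ibs_matrix(g3, "similarity")[1, 2], 0.5)
})

test_that("IBS is invariant to allele flips and variant order, NA-safe", {
  g <- random_genotypes(8, 40, miss_rate = 0.15, seed = 13)
  s <- ibs_matrix(g, "similarity")
  expect_equal(ibs_matrix(flip_alleles(g), "similarity"), s)
  perm <- sample(ncol(g))
  expect_equal(ibs_matrix(g[, perm], "similarity"), s)
  # brute-force pairwise oracle
  oracle <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    mean((2 - abs(a[ok] - b[ok])) / 2)
  }
  for (i in 1:3) for (j in 4:6) {
    expect_equal(s[i, j], oracle(g[i, ], g[j, ]))
  }
  # a pair with no co-called variants is NA with a warning
  g2 <- g
  g2[1, 1:20] <- NA; g2[2, 21:40] <- NA
  expect_warning(s2 <- ibs_matrix(g2, "similarity"), "no co-called")
  expect_true(is.na(s2[1, 2]))
})

test_that("classical MDS reproduces Euclidean configurations", {
  # equilateral triangle
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  fit <- classical_mds(d3, 2)
  expect_equal(as.matrix(dist(fit$coordinates)), unname(d3) + 0,
               ignore_attr = TRUE, tolerance = 1e-9)
  # known 2-D configuration: compare via distance matrices (coordinates are
  # only defined up to rotation/reflection)
  set.seed(8)
  xy <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(xy))
  dimnames(d) <- list(paste0("p", 1:10), paste0("p", 1:10))
  fit2 <- classical_mds(d, 2)
  expect_equal(as.matrix(dist(fit2$coordinates)), d, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_true(all(diff(fit2$eigenvalues) <= 1e-9))
  expect_lt(max(abs(colMeans(fit2$coordinates))), 1e-9)
  # Torgerson identity: eigenvalue mass equals centered squared-distance mass
  n <- nrow(d)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% d^2 %*% J
  expect_equal(sum(fit2$all_eigenvalues), sum(diag(B)), tolerance = 1e-9)
})

test_that("axis 1 separates a two-ancestry cohort with no misassignments", {
  sim <- sim_balding_nichols(n_snps = 800, fst = 0.2, n_pops = 2,
                             samples_per_pop = 30, seed = 101)
  d <- ibs_matrix(sim$genotypes, "distance")
  fit <- classical_mds(d, 2)
  ax1 <- fit$coordinates[, 1]
  pop <- sim$samples$population
  side <- ax1 > 0
  mis <- min(sum(side != (pop == "pop1")), sum(side != (pop == "pop2")))
  expect_identical(mis, 0L)
})

test_that("NJ recovers a 4-taxon additive tree exactly", {
  # additive matrix from ((A:1,B:2):1,(C:3,D:1)); internal branch 1
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- 3
  dm["A", "C"] <- 1 + 1 + 3; dm["A", "D"] <- 1 + 1 + 1
  dm["B", "C"] <- 2 + 1 + 3; dm["B", "D"] <- 2 + 1 + 1
  dm["C", "D"] <- 4
  dm <- dm + t(dm)
  # oracle: brute force over the 3 unrooted 4-taxon topologies, least-squares
  # branch lengths per topology (design matrix of path indicators)
  topos <- list(c("A", "B"), c("A", "C"), c("A", "D"))  # A's cherry partner
  fits <- lapply(topos, function(partner) {
    cherry1 <- c("A", partner[partner != "A"])
    cherry1 <- c("A", setdiff(partner, "A"))
    others <- setdiff(LETTERS[1:4], cherry1)
    taxa <- c(cherry1, others)
    # branches: e1..e4 leaf branches (order taxa), e5 internal
    pairs <- t(combn(4, 2))
    X <- matrix(0, nrow(pairs), 5)
    y <- numeric(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      X[r, i] <- 1; X[r, j] <- 1
      same_cherry <- (i <= 2 && j <= 2) || (i >= 3 && j >= 3)
      if (!same_cherry) X[r, 5] <- 1
      y[r] <- dm[taxa[i], taxa[j]]
    }
    beta <- qr.solve(X, y)
    list(rss = sum((X %*% beta - y)^2), partner = setdiff(cherry1, "A"),
         lengths = beta, taxa = taxa)
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  expect_equal(best$partner, "B")                 # oracle topology
  expect_equal(best$rss, 0, tolerance = 1e-20)
  expect_equal(unname(best$lengths), c(1, 2, 3, 1, 1))

  tree <- nj_tree(dm)
  # same sister pair as the oracle
  pair_AB <- ape::getMRCA(ape::root(tree, "C"), c("A", "B"))
  expect_identical(sort(ape::extract.clade(ape::root(tree, "C"),
                                           pair_AB)$tip.label), c("A", "B"))
  # branch lengths recovered: pairwise tree distances equal the input
  expect_equal(ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]],
               dm, tolerance = 1e-9)
})

test_that("3-taxon and star-like matrices behave as the closed form predicts", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d3)
  # closed form: bx = (3+4-5)/2 = 1, by = (3+5-4)/2 = 2, bz = (4+5-3)/2 = 3
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co[rownames(d3), colnames(d3)], d3, tolerance = 1e-12)

  star <- matrix(2, 4, 4); diag(star) <- 0
  dimnames(star) <- list(LETTERS[1:4], LETTERS[1:4])
  st <- nj_tree(star)
  internal <- st$edge[, 2] > length(st$tip.label)
  expect_true(all(abs(st$edge.length[internal]) < 1e-12))
  expect_error(nj_tree(star[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive topologies (consistency property)", {
  set.seed(55)
  for (rep in 1:10) {
    ntip <- sample(6:10, 1)
    true <- ape::rtree(ntip, br = function(n) runif(n, 0.1, 1))
    dm <- ape::cophenetic.phylo(ape::unroot(true))
    est <- nj_tree(dm)
    expect_equal(unname(ape::dist.topo(ape::unroot(true), est)[1]), 0,
                     label = paste("replicate", rep))
  }
})

test_that("subsampled trees keep at most 6 leaves per population, seeded", {
  g <- random_genotypes(30, 60, seed = 17)
  d <- ibs_matrix(g, "distance")
  pops <- rep(c("P1", "P2", "P3"), each = 10)
  t1 <- nj_tree(d, populations = pops, per_pop_subsample = 6, seed = 9)
  t2 <- nj_tree(d, populations = pops, per_pop_subsample = 6, seed = 9)
  expect_identical(sort(t1$tip.label), sort(t2$tip.label))
  expect_identical(length(t1$tip.label), 18L)
  # Newick round trip preserves topology
  dir <- withr::local_tempdir()
  ape::write.tree(t1, file.path(dir, "t.nwk"))
  back <- ape::read.tree(file.path(dir, "t.nwk"))
  expect_equal(unname(ape::dist.topo(t1, back)[1]), 0)
})

test_that("great-circle distances match analytic values", {
  meta <- sample_table(c("a", "b", "c", "d"),
                       population = c("P0", "Panti", "P90", "Psame"),
                       lat = c(0, 0, 0, 0), lon = c(0, 180, 90, 0))
  d <- geo_distance(meta)
  expect_equal(d["P0", "Psame"], 0)
  expect_equal(d["P0", "Panti"], pi * 6371.0088, tolerance = 1e-6)
  expect_equal(d["P0", "P90"], pi * 6371.0088 / 2, tolerance = 1e-6)
})

test_that("genetic-geographic correlation behaves across null and IBD regimes", {
  # identical matrices: r = 1
  set.seed(2)
  m <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(m) <- list(paste0("P", 1:6), paste0("P", 1:6))
  same <- geo_genetic_correlation(m, m)
  expect_equal(same$r, 1)
  expect_identical(same$n_pairs, 15L)

  # stepping-stone demes: isolation by distance forces r > 0
  sim <- sim_stepping_stone(n_demes = 10, samples_per_deme = 8, n_snps = 400,
                            m = 0.01, generations = 100, seed = 71)
  gd <- breed_genetic_distance(sim$genotypes, sim$samples$population)
  geo <- geo_distance(sim$samples)
  res <- geo_genetic_correlation(gd, geo)
  expect_gt(res$r, 0.3)
  expect_lt(res$p_value, 0.01)

  # shuffled labels: permutation p behaves as a null (not significant here)
  set.seed(4)
  perm <- sample(nrow(gd))
  shuf <- gd[perm, perm]
  dimnames(shuf) <- dimnames(gd)
  null_res <- geo_genetic_correlation(shuf, geo, n_perm = 199, seed = 5)
  expect_gt(null_res$p_perm, 0.05)
})

test_that("removing introgressed demes strengthens isolation by distance", {
  # admixed stepping stones: demes 1-8 form a line; demes 9-10 receive heavy
  # ancestry from a distant unrelated source, masking the geographic signal
  sim <- sim_stepping_stone(n_demes = 10, samples_per_deme = 8, n_snps = 400,
                            m = 0.02, generations = 80, seed = 81)
  far <- sim_balding_nichols(n_snps = 400, fst = 0.4, n_pops = 1,
                             samples_per_pop = 16, seed = 82)
  g <- sim$genotypes
  intro <- sim$samples$population %in% c("deme9", "deme10")
  g[intro, ] <- far$genotypes[seq_len(sum(intro)), ]
  gd_all <- breed_genetic_distance(g, sim$samples$population)
  geo <- geo_distance(sim$samples)
  r_all <- geo_genetic_correlation(gd_all, geo)$r
  keep <- !(rownames(gd_all) %in% c("deme9", "deme10"))
  r_pure <- geo_genetic_correlation(gd_all[keep, keep], geo[keep, keep])$r
  expect_gt(r_pure, r_all)
})
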