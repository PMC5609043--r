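# Synthetic genotype/haplotype generators with known truth, one per study
# condition the pipeline is validated against: Balding-Nichols admixed
# cohorts (structure, admixture, Fst truth), stepping-stone demes
# (isolation-by-distance truth), forward Wright-Fisher populations with
# recombination (LD/Ne and haplotype-diversity truth), and gene-dropped
# pedigrees (ROH/inbreeding truth). Every generator is exactly reproducible
# from its arguments plus `seed`; truth objects are returned alongside the
# data and are meant for tests only, never as pipeline inputs.

evenly_spaced_variants <- function(n_snps, n_chrom = 1, spacing_bp = 50000,
                                   rate_cm_mb = 1) {
  per <- rep(n_snps %/% n_chrom, n_chrom)
  if (n_snps %% n_chrom > 0) {
    per[seq_len(n_snps %% n_chrom)] <- per[seq_len(n_snps %% n_chrom)] + 1L
  }
  chrom <- rep(as.character(seq_len(n_chrom)), per)
  pos <- unlist(lapply(per, function(k) seq_len(k) * spacing_bp))
  variant_table(paste0("snp", seq_len(n_snps)), chrom, pos,
                genetic_pos = pos * rate_cm_mb * 1e-8)
}

#' Balding-Nichols cohort with optional admixture
#'
#' Ancestral counted-allele frequencies are drawn Uniform(0.05, 0.95); each
#' of K populations drifts them through a Beta(p(1-F)/F, (1-p)(1-F)/F) draw
#' (F = 0 leaves populations identical). Individual ancestry vectors are
#' either pure (block design, one population each) or Dirichlet(`admix_alpha`)
#' admixed; dosages are Binomial(2, sum_k q_k p_kj). The drift parameter F
#' maps directly onto the expected Fst between populations, which is what
#' makes this the natural truth source for differentiation estimators.
#'
#' @param n_snps number of variants.
#' @param fst drift parameter F per population (scalar or length-K).
#' @param n_pops number of ancestral populations K.
#' @param samples_per_pop individuals per population (block design), or total
#'   individuals when `admix_alpha` is given.
#' @param admix_alpha optional Dirichlet concentration (length K) for admixed
#'   individuals; `NULL` gives the pure block design.
#' @param Q optional explicit n x K ancestry matrix overriding both designs.
#' @param seed RNG seed.
#' @return list: `genotypes`, `samples`, `variants`, `Q_true`, `P_true`
#'   (K x m population frequencies), `p_ancestral`.
#' @export
sim_balding_nichols <- function(n_snps = 1000, fst = 0.2, n_pops = 2,
                                samples_per_pop = 50, admix_alpha = NULL,
                                Q = NULL, seed = NULL) {
  K <- n_pops
  fst <- rep_len(fst, K)
  stopifnot(all(fst >= 0), all(fst < 1))
  with_seed(seed, {
    p <- stats::runif(n_snps, 0.05, 0.95)
    P <- matrix(NA_real_, K, n_snps)
    for (k in seq_len(K)) {
      P[k, ] <- if (fst[k] == 0) p else {
        stats::rbeta(n_snps, p * (1 - fst[k]) / fst[k],
                     (1 - p) * (1 - fst[k]) / fst[k])
      }
    }
    if (is.null(Q)) {
      if (is.null(admix_alpha)) {
        n <- samples_per_pop * K
        Q <- matrix(0, n, K)
        pop_of <- rep(seq_len(K), each = samples_per_pop)
        Q[cbind(seq_len(n), pop_of)] <- 1
        labels <- paste0("pop", pop_of)
      } else {
        stopifnot(length(admix_alpha) == K)
        n <- samples_per_pop
        qa <- matrix(stats::rgamma(n * K, shape = rep(admix_alpha, each = n)),
                     n, K)
        Q <- qa / rowSums(qa)
        labels <- rep("admixed", n)
      }
    } else {
      Q <- as.matrix(Q)
      stopifnot(ncol(Q) == K)
      n <- nrow(Q)
      labels <- paste0("pop", max.col(Q))
    }
    pi <- Q %*% P
    calls <- matrix(stats::rbinom(length(pi), 2, pi), nrow(pi), ncol(pi))
    ids <- sprintf("ind%03d", seq_len(nrow(Q)))
    g <- genotype_matrix(calls, ids, paste0("snp", seq_len(n_snps)))
    list(genotypes = g,
         samples = sample_table(ids, labels, call_rate = 1),
         variants = evenly_spaced_variants(n_snps),
         Q_true = Q, P_true = P, p_ancestral = p)
  })
}

#' Stepping-stone demes with drift and neighbor migration
#'
#' Demes sit on a line with assigned coordinates; shared initial allele
#' frequencies evolve for `generations` rounds of symmetric nearest-neighbor
#' migration at rate `m` followed by binomial drift in demes of `deme_size`
#' diploids. Gene flow decaying with distance forces isolation by distance,
#' i.e. a positive correlation between genetic and geographic distance.
#'
#' @param n_demes number of demes (>= 2).
#' @param samples_per_deme individuals genotyped per deme.
#' @param n_snps number of variants.
#' @param m total migration rate per deme per generation (must be <= 0.5).
#' @param generations rounds of migration + drift.
#' @param deme_size diploid deme size governing drift.
#' @param deme_spacing_deg longitude spacing between demes in degrees.
#' @param seed RNG seed.
#' @return list: `genotypes`, `samples` (with lat/lon), `variants`,
#'   `freq_true` (deme x variant final frequencies).
#' @export
sim_stepping_stone <- function(n_demes = 10, samples_per_deme = 10,
                               n_snps = 500, m = 0.01, generations = 100,
                               deme_size = 100, deme_spacing_deg = 2,
                               seed = NULL) {
  if (n_demes < 2) stopf("need at least 2 demes")
  if (m > 0.5) stopf("migration rate m must be <= 0.5")
  with_seed(seed, {
    freq <- matrix(stats::runif(n_snps, 0.1, 0.9), n_demes, n_snps,
                   byrow = TRUE)
    for (gen in seq_len(generations)) {
      nb <- freq
      for (d in seq_len(n_demes)) {
        neigh <- c(if (d > 1) d - 1, if (d < n_demes) d + 1)
        nb[d, ] <- (1 - m) * freq[d, ] +
          m * colMeans(freq[neigh, , drop = FALSE])
      }
      freq <- matrix(stats::rbinom(length(nb), 2 * deme_size, nb),
                     n_demes, n_snps) / (2 * deme_size)
    }
    n <- n_demes * samples_per_deme
    deme_of <- rep(seq_len(n_demes), each = samples_per_deme)
    pi <- freq[deme_of, , drop = FALSE]
    calls <- matrix(stats::rbinom(length(pi), 2, pi), n, n_snps)
    ids <- sprintf("ind%03d", seq_len(n))
    g <- genotype_matrix(calls, ids, paste0("snp", seq_len(n_snps)))
    meta <- sample_table(ids, paste0("deme", deme_of),
                         lat = 0, lon = (deme_of - 1) * deme_spacing_deg,
                         call_rate = 1)
    list(genotypes = g, samples = meta,
         variants = evenly_spaced_variants(n_snps), freq_true = freq)
  })
}

# One meiosis: recombine a parent's two chromosomes (rows of a 2 x S matrix,
# any payload) into a gamete, with crossover counts Poisson in the map length
# and breakpoints uniform on the map. `gpos` is the cumulative genetic
# position (Morgans) of each column; `chrom` delimits linkage groups.
meiosis <- function(pair, gpos, chrom) {
  out <- pair[1, ]
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)
    gp <- gpos[cols]
    len <- gp[length(gp)] - gp[1]
    k <- stats::rpois(1, len)
    phase0 <- sample(2L, 1)
    if (k == 0) {
      out[cols] <- pair[phase0, cols]
    } else {
      brk <- sort(stats::runif(k, gp[1], gp[length(gp)]))
      seg <- findInterval(gp, brk)
      phase <- (phase0 + seg - 1) %% 2 + 1
      out[cols] <- pair[cbind(phase, cols)]
    }
  }
  out
}

#' Forward Wright-Fisher population with recombination
#'
#' `n_diploid` individuals evolve for `generations` discrete generations on a
#' single chromosome of `chrom_length_bp` at a uniform recombination rate.
#' Standing variation is initialized from per-site frequencies drawn Uniform
#' over `init_freq_range`; each offspring haplotype is a recombinant gamete
#' (crossovers Poisson in the map length) of a uniformly chosen parent. The
#' final generation's phased haplotypes and map are returned, making the
#' realized Ne of the run equal to `n_diploid` by construction.
#'
#' @param n_diploid population size N.
#' @param generations number of generations (0 returns the initialization).
#' @param n_snps variant count at initialization.
#' @param chrom_length_bp chromosome length in bp (default 10 Mb).
#' @param rate_cm_mb recombination rate (default 1 cM/Mb).
#' @param init_freq_range range of initial allele frequencies.
#' @param seed RNG seed.
#' @return list: `haplotypes` (2N x m, see [haplotype_matrix()]),
#'   `genotypes`, `variants`, `n_diploid`.
#' @export
sim_wright_fisher <- function(n_diploid = 50, generations = 200,
                              n_snps = 400, chrom_length_bp = 10e6,
                              rate_cm_mb = 1, init_freq_range = c(0.05, 0.95),
                              seed = NULL) {
  with_seed(seed, {
    pos <- sort(sample.int(chrom_length_bp, n_snps))
    gpos <- pos * rate_cm_mb * 1e-8
    map_len <- gpos[n_snps] - gpos[1]
    p0 <- stats::runif(n_snps, init_freq_range[1], init_freq_range[2])
    H <- matrix(stats::rbinom(2 * n_diploid * n_snps, 1,
                              rep(p0, each = 2 * n_diploid)),
                2 * n_diploid, n_snps)
    for (gen in seq_len(generations)) {
      parent <- sample.int(n_diploid, 2 * n_diploid, replace = TRUE)
      k <- stats::rpois(2 * n_diploid, map_len)
      phase <- sample.int(2L, 2 * n_diploid, replace = TRUE)
      Hn <- H
      plain <- k == 0
      Hn[plain, ] <- H[2 * (parent[plain] - 1) + phase[plain], , drop = FALSE]
      for (i in which(!plain)) {
        brk <- sort(stats::runif(k[i], gpos[1], gpos[n_snps]))
        seg <- findInterval(gpos, brk)
        ph <- (phase[i] + seg - 1) %% 2 + 1
        Hn[i, ] <- H[cbind(2 * (parent[i] - 1) + ph, seq_len(n_snps))]
      }
      H <- Hn
    }
    ids <- sprintf("ind%03d", seq_len(n_diploid))
    h <- haplotype_matrix(H, ids)
    vars <- variant_table(paste0("snp", seq_len(n_snps)), "1", pos,
                          genetic_pos = gpos)
    list(haplotypes = h, genotypes = haplotypes_to_genotypes(h),
         variants = vars, n_diploid = n_diploid)
  })
}

#' Gene-dropped pedigrees with known inbreeding
#'
#' Founder haplotypes carry unique labels; meioses with recombination drop
#' them through one of four pedigree designs, so autozygosity (both labels
#' identical at a site) is known by construction:
#' `"outbred"` (child of two unrelated founders, expected F = 0),
#' `"full_sib"` (child of a full-sib mating, expected F = 0.25),
#' `"selfing_n"` (n rounds of selfing, expected F = 1 - 2^-n), and
#' `"f1_cross_of_inbred_lines"` (cross of two fully divergent fixed lines:
#' heterozygous at every site, so no runs of homozygosity at all).
#' Founder alleles are Bernoulli draws at per-site frequencies Uniform over
#' `founder_maf_range`, except for the F1 design where the two lines are
#' fixed for opposite alleles.
#'
#' @param design pedigree design (see above).
#' @param n_offspring number of independently dropped offspring.
#' @param n_chrom,chrom_length_bp,snp_spacing_bp genome layout (defaults:
#'   5 chromosomes x 120 Mb, one SNP per 40 kb, array-like density).
#' @param rate_cm_mb uniform recombination rate (default 1 cM/Mb).
#' @param founder_maf_range allele-frequency range for founder haplotypes.
#' @param selfing_generations rounds of selfing for `"selfing_n"`.
#' @param seed RNG seed.
#' @return list: `genotypes` (offspring only), `variants`, `f_expected`,
#'   `f_realized` (per offspring: fraction of sites identical by descent).
#' @export
sim_pedigree_inbreeding <- function(design = c("outbred", "full_sib",
                                               "selfing_n",
                                               "f1_cross_of_inbred_lines"),
                                    n_offspring = 1, n_chrom = 5,
                                    chrom_length_bp = 120e6,
                                    snp_spacing_bp = 40e3, rate_cm_mb = 1,
                                    founder_maf_range = c(0.2, 0.8),
                                    selfing_generations = 3, seed = NULL) {
  design <- match.arg(design)
  snps_per_chrom <- chrom_length_bp %/% snp_spacing_bp
  n_snps <- n_chrom * snps_per_chrom
  chrom <- rep(as.character(seq_len(n_chrom)), each = snps_per_chrom)
  pos <- rep(seq_len(snps_per_chrom) * snp_spacing_bp, n_chrom)
  gpos <- pos * rate_cm_mb * 1e-8
  vars <- variant_table(paste0("snp", seq_len(n_snps)), chrom, pos,
                        genetic_pos = gpos)
  with_seed(seed, {
    freq <- stats::runif(n_snps, founder_maf_range[1], founder_maf_range[2])
    founder_alleles <- if (design == "f1_cross_of_inbred_lines") {
      rbind(rep(0L, n_snps), rep(0L, n_snps),
            rep(1L, n_snps), rep(1L, n_snps))
    } else {
      matrix(stats::rbinom(4 * n_snps, 1, rep(freq, each = 4)), 4, n_snps)
    }
    drop_one <- function() {
      # founder label haplotypes: founder 1 carries labels 1,2; founder 2
      # carries 3,4 (the F1 design uses 1,1 and 2,2: fixed inbred lines)
      if (design == "f1_cross_of_inbred_lines") {
        A <- rbind(rep(1L, n_snps), rep(2L, n_snps))   # one hap from each line
        return(A)
      }
      f1 <- rbind(rep(1L, n_snps), rep(2L, n_snps))
      f2 <- rbind(rep(3L, n_snps), rep(4L, n_snps))
      switch(design,
        outbred = rbind(meiosis(f1, gpos, chrom), meiosis(f2, gpos, chrom)),
        full_sib = {
          sib1 <- rbind(meiosis(f1, gpos, chrom), meiosis(f2, gpos, chrom))
          sib2 <- rbind(meiosis(f1, gpos, chrom), meiosis(f2, gpos, chrom))
          rbind(meiosis(sib1, gpos, chrom), meiosis(sib2, gpos, chrom))
        },
        selfing_n = {
          x <- rbind(meiosis(f1, gpos, chrom), meiosis(f2, gpos, chrom))
          for (t in seq_len(selfing_generations)) {
            x <- rbind(meiosis(x, gpos, chrom), meiosis(x, gpos, chrom))
          }
          x
        })
    }
    calls <- matrix(NA_integer_, n_offspring, n_snps)
    f_real <- numeric(n_offspring)
    for (i in seq_len(n_offspring)) {
      labs <- drop_one()
      if (design == "f1_cross_of_inbred_lines") {
        a1 <- founder_alleles[1, ]
        a2 <- founder_alleles[3, ]
        f_real[i] <- 0
      } else {
        a1 <- founder_alleles[cbind(labs[1, ], seq_len(n_snps))]
        a2 <- founder_alleles[cbind(labs[2, ], seq_len(n_snps))]
        f_real[i] <- mean(labs[1, ] == labs[2, ])
      }
      calls[i, ] <- a1 + a2
    }
    f_exp <- switch(design,
                    outbred = 0,
                    full_sib = 0.25,
                    selfing_n = 1 - 0.5^selfing_generations,
                    f1_cross_of_inbred_lines = 0)
    ids <- sprintf("off%03d", seq_len(n_offspring))
    list(genotypes = genotype_matrix(calls, ids, vars$variant_id),
         variants = vars, f_expected = f_exp, f_realized = f_real)
  })
}
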