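# Population structure: identity-by-state distances, classical MDS,
# neighbor-joining trees, and isolation-by-distance correlation.

#' Pairwise identity-by-state matrix
#'
#' IBS similarity between two individuals is the mean over co-called variants
#' of (2 - |d_i - d_j|) / 2, where d are counted-allele dosages; the distance
#' is 1 - similarity. The computation is exact and fully vectorized via
#' indicator cross-products. Pairs with no co-called variant are returned as
#' `NA` with a warning, never silently as 0.
#'
#' @param g genotype matrix (samples x variants).
#' @param what return `"distance"` (1 - IBS, default) or `"similarity"`.
#' @return square labelled matrix (see [distance_matrix()] for the contract).
#' @export
ibs_matrix <- function(g, what = c("distance", "similarity")) {
  what <- match.arg(what)
  validate_genotypes(g)
  n <- nrow(g)
  if (n < 2) stopf("need at least 2 samples")
  C <- (!is.na(g)) * 1
  D0 <- g; D0[is.na(D0)] <- 0L
  storage.mode(D0) <- "double"
  H <- (g == 1L) * 1; H[is.na(H)] <- 0
  Sab <- tcrossprod(D0)
  S2 <- tcrossprod(D0^2, C)
  A2 <- S2 + t(S2) - 2 * Sab              # sum over co-called of (d_i - d_j)^2
  Hterm <- tcrossprod(H, C) + tcrossprod(C, H) - 2 * tcrossprod(H)
  sumabs <- (A2 + Hterm) / 2              # |d_i-d_j| = ((d_i-d_j)^2 + het term)/2
  ncoc <- tcrossprod(C)
  sim <- 1 - sumabs / (2 * ncoc)
  if (any(ncoc == 0)) {
    warnf("%d sample pairs share no co-called variants; set to NA",
          (sum(ncoc == 0) - sum(diag(ncoc) == 0)) / 2)
    sim[ncoc == 0] <- NA_real_
  }
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(g), rownames(g))
  out <- if (what == "similarity") sim else 1 - sim
  if (what == "distance") diag(out) <- 0
  out
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centered eigendecomposition of the squared-distance matrix via
#' [stats::cmdscale()]. Axes are ordered by decreasing eigenvalue and
#' coordinates are column-centered. When the input is Euclidean-embeddable in
#' `k` dimensions the configuration reproduces the distances exactly.
#'
#' @param d distance matrix.
#' @param k number of axes.
#' @return list with `coordinates` (n x k), `eigenvalues` (first k, descending)
#'   and `all_eigenvalues`; negative eigenvalues beyond 1e-8 of the largest
#'   trigger a warning (non-Euclidean input) and are clipped from the axes.
#' @export
classical_mds <- function(d, k = 2) {
  d <- distance_matrix(d)
  n <- nrow(d)
  if (k > n - 1) stopf("k must be <= n - 1")
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warnf("distance matrix is not Euclidean (negative eigenvalues clipped)")
  }
  pts <- fit$points
  if (ncol(pts) < k) {                    # axes lost to non-positive eigenvalues
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  colnames(pts) <- paste0("axis", seq_len(k))
  list(coordinates = pts, eigenvalues = eig[seq_len(k)], all_eigenvalues = eig)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on an optionally subsampled
#' distance matrix: when `populations` is given, at most `per_pop_subsample`
#' individuals per population are drawn (seeded) before tree building, the
#' usual device for keeping trees legible in large cohorts. Negative branch
#' lengths are set to zero with the deficit transferred to the adjacent
#' branch, the convention popularized by PHYLIP.
#'
#' @param d distance matrix over individuals.
#' @param populations optional vector of population labels aligned with the
#'   rows of `d` (or named by its labels).
#' @param per_pop_subsample individuals retained per population (default 6).
#' @param seed RNG seed for the subsampling draw.
#' @return an [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(d, populations = NULL, per_pop_subsample = 6, seed = NULL) {
  d <- distance_matrix(d)
  keep <- rownames(d)
  if (!is.null(populations)) {
    pops <- if (!is.null(names(populations))) {
      populations[rownames(d)]
    } else {
      stopifnot(length(populations) == nrow(d))
      populations
    }
    keep <- with_seed(seed, {
      unlist(lapply(split(rownames(d), pops), function(ids) {
        if (length(ids) > per_pop_subsample) {
          sample(ids, per_pop_subsample)
        } else ids
      }), use.names = FALSE)
    })
    keep <- rownames(d)[rownames(d) %in% keep]   # preserve matrix order
  }
  if (length(keep) < 3) stopf("need at least 3 leaves for a tree")
  tree <- ape::nj(stats::as.dist(d[keep, keep]))
  clamp_negative_branches(tree)
}

# Zero out negative branch lengths, transferring each deficit to the adjacent
# branch so paths through the node keep their total length where possible.
clamp_negative_branches <- function(tree) {
  el <- tree$edge.length
  if (is.null(el) || all(el >= 0)) return(tree)
  edge <- tree$edge
  for (e in order(el)) {
    if (el[e] >= 0) next
    v <- edge[e, 2]
    adj <- which(edge[, 1] == v)          # edges below the child node
    if (length(adj) == 0) {               # leaf branch: use the sibling
      adj <- setdiff(which(edge[, 1] == edge[e, 1]), e)
    }
    if (length(adj) > 0) el[adj] <- el[adj] + el[e] / length(adj)
    el[e] <- 0
  }
  tree$edge.length <- pmax(el, 0)
  tree
}

#' Great-circle distances between populations
#'
#' Population coordinates are the mean of the member samples' sampling
#' coordinates; distances are haversine great-circle distances on a sphere of
#' mean Earth radius 6371.0088 km. Populations without coordinates are
#' excluded with a warning.
#'
#' @param meta sample table with `population`, `lat`, `lon`.
#' @return population x population distance matrix in kilometres.
#' @export
geo_distance <- function(meta) {
  has <- !is.na(meta$lat) & !is.na(meta$lon)
  dropped <- setdiff(unique(meta$population), unique(meta$population[has]))
  if (length(dropped) > 0) {
    warnf("populations without coordinates excluded: %s",
          paste(dropped, collapse = ", "))
  }
  meta <- meta[has, , drop = FALSE]
  if (nrow(meta) == 0) stopf("no populations with coordinates")
  lat <- tapply(meta$lat, meta$population, mean)
  lon <- tapply(meta$lon, meta$population, mean)
  pops <- names(lat)
  n <- length(pops)
  x <- cbind(lon, lat)
  km <- geosphere::distHaversine(x[rep(seq_len(n), each = n), , drop = FALSE],
                                 x[rep(seq_len(n), times = n), , drop = FALSE],
                                 r = 6371008.8) / 1000
  m <- matrix(km, n, n, byrow = TRUE, dimnames = list(pops, pops))
  distance_matrix((m + t(m)) / 2)         # symmetrize away float jitter
}

#' Population-level genetic distance
#'
#' The default summarizes individual-level 1 - IBS as the mean over all
#' between-population sample pairs. The `"centroid"` alternative is the
#' Euclidean distance between population mean dosage vectors divided by the
#' number of variants (a frequency-space distance).
#'
#' @param g genotype matrix.
#' @param populations population label per sample (aligned with rows of `g`).
#' @param method `"mean_pairwise"` (default) or `"centroid"`.
#' @return population x population distance matrix.
#' @export
breed_genetic_distance <- function(g, populations,
                                   method = c("mean_pairwise", "centroid")) {
  method <- match.arg(method)
  stopifnot(length(populations) == nrow(g))
  pops <- sort(unique(populations))
  n <- length(pops)
  out <- matrix(0, n, n, dimnames = list(pops, pops))
  if (method == "mean_pairwise") {
    d <- ibs_matrix(g, "distance")
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        block <- d[populations == pops[i], populations == pops[j], drop = FALSE]
        out[i, j] <- out[j, i] <- mean(block, na.rm = TRUE)
      }
    }
  } else {
    freq <- apply(g, 2, function(col) tapply(col, populations, mean, na.rm = TRUE)) / 2
    freq <- freq[pops, , drop = FALSE]
    out <- as.matrix(stats::dist(freq)) / sqrt(ncol(g))
  }
  distance_matrix(out)
}

#' Correlation between genetic and geographic distance
#'
#' Pearson correlation over the upper-triangle population pairs, with the
#' p-value from the usual t reference distribution (pairs treated as
#' independent). An optional permutation test (shuffling population labels of
#' one matrix) gives a null-respecting alternative.
#'
#' @param gd genetic distance matrix (population level).
#' @param geo geographic distance matrix with the same label set.
#' @param n_perm permutations for the optional empirical p (0 = skip).
#' @param seed RNG seed for permutations.
#' @return list with `r`, `p_value`, `n_pairs`, and `p_perm` when requested.
#' @export
geo_genetic_correlation <- function(gd, geo, n_perm = 0, seed = NULL) {
  gd <- distance_matrix(gd); geo <- distance_matrix(geo)
  common <- intersect(rownames(gd), rownames(geo))
  if (length(common) < 3) stopf("need at least 3 shared populations")
  gd <- gd[common, common]; geo <- geo[common, common]
  ut <- upper.tri(gd)
  x <- gd[ut]; y <- geo[ut]
  ok <- is.finite(x) & is.finite(y)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  out <- list(r = unname(ct$estimate), p_value = ct$p.value,
              n_pairs = sum(ok))
  if (n_perm > 0) {
    obs <- abs(out$r)
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        perm <- sample(length(common))
        gp <- gd[perm, perm]
        abs(stats::cor(gp[ut][ok], y[ok])) >= obs
      }, logical(1)))
    })
    out$p_perm <- (1 + hits) / (1 + n_perm)
  }
  out
}
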