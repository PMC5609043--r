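# Maximum-likelihood admixture model: each individual's genome is a mixture
# of K ancestral populations with proportions Q (rows on the simplex);
# genotype dosages are Binomial(2, pi_ij) draws with pi = Q %*% P, where P
# holds ancestral counted-allele frequencies. Estimation is by plain EM with
# the standard expected-ancestry-count updates: simpler than block-relaxation
# quasi-Newton schemes, and provably monotone in the log-likelihood, which is
# adequate at the scales this package targets.

EPS_PI <- 1e-9

#' Admixture-model log-likelihood
#'
#' Binomial log-likelihood of the dosage matrix under mixing proportions `Q`
#' and ancestral frequencies `P`, up to the genotype-independent binomial
#' coefficient. Missing calls contribute nothing; the success probability is
#' clamped to \[1e-9, 1 - 1e-9\].
#'
#' @param g genotype matrix (n x m dosages).
#' @param Q n x K mixing proportions; each row must sum to 1 within 1e-6.
#' @param P K x m ancestral counted-allele frequencies in \[0, 1\].
#' @return scalar log-likelihood.
#' @export
admixture_loglik <- function(g, Q, P) {
  Q <- as.matrix(Q); P <- as.matrix(P)
  stopifnot(nrow(Q) == nrow(g), ncol(Q) == nrow(P), ncol(P) == ncol(g))
  if (any(Q < -1e-9 | Q > 1 + 1e-9) || any(abs(rowSums(Q) - 1) > 1e-6)) {
    stopf("Q rows must lie on the probability simplex")
  }
  if (any(P < -1e-9 | P > 1 + 1e-9)) stopf("P entries must lie in [0, 1]")
  pi <- clamp(Q %*% P, EPS_PI, 1 - EPS_PI)
  d <- g
  ll <- d * log(pi) + (2 - d) * log1p(-pi)
  sum(ll, na.rm = TRUE)
}

#' Fit the admixture model by EM
#'
#' Runs `n_restarts` independent EM fits from Dirichlet-random initial `Q`
#' (and jittered observed-frequency `P`), keeping the best final
#' log-likelihood. Iteration stops when the log-likelihood improves by less
#' than `tol`, or at `max_iter`. Missing genotypes are skipped entry-wise in
#' both the E and M steps. Component order carries no meaning (label
#' switching); compare fits after permutation matching.
#'
#' @param g genotype matrix.
#' @param K number of ancestral components (>= 1).
#' @param seed RNG seed; restart r uses `seed + r - 1`.
#' @param tol convergence threshold on the log-likelihood improvement.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts independent initializations (default 3).
#' @return object of class `admixture_fit`: `Q`, `P`, `K`, `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, and `restart_logliks`.
#' @export
fit_admixture <- function(g, K, seed = NULL, tol = 1e-4, max_iter = 2000,
                          n_restarts = 3) {
  validate_genotypes(g)
  n <- nrow(g); m <- ncol(g)
  if (K < 1) stopf("K must be >= 1")
  if (K > n) stopf("K (%d) exceeds the number of samples (%d)", K, n)

  if (K == 1) {                       # analytic fixed point
    P <- matrix(allele_freq(g), 1, m)
    Q <- matrix(1, n, 1)
    ll <- admixture_loglik(g, Q, P)
    fit <- list(K = 1L, Q = Q, P = P, loglik = ll, loglik_trace = ll,
                n_iter = 1L, converged = TRUE, restart_logliks = ll)
    class(fit) <- "admixture_fit"
    return(fit)
  }

  D0 <- g; D0[is.na(D0)] <- 0L; storage.mode(D0) <- "double"
  U0 <- 2 - g; U0[is.na(U0)] <- 0; storage.mode(U0) <- "double"
  m_called <- rowSums(!is.na(g))
  if (any(m_called == 0)) stopf("samples with no called genotypes present")
  phat <- allele_freq(g)

  run_once <- function(run_seed) {
    init <- with_seed(run_seed, {
      qa <- matrix(stats::rgamma(n * K, shape = 1), n, K)
      list(Q = qa / rowSums(qa),
           P = clamp(matrix(rep(phat, each = K), K, m) +
                       matrix(stats::runif(K * m, -0.1, 0.1), K, m),
                     0.05, 0.95))
    })
    Q <- init$Q; P <- init$P
    trace <- numeric(0)
    ll_old <- -Inf; converged <- FALSE; it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      pi <- clamp(Q %*% P, EPS_PI, 1 - EPS_PI)
      R1 <- D0 / pi
      R0 <- U0 / (1 - pi)
      N1 <- P * t(crossprod(R1, Q))          # K x m expected '1' alleles
      N0 <- (1 - P) * t(crossprod(R0, Q))    # K x m expected '0' alleles
      Qn <- Q * (R1 %*% t(P) + R0 %*% t(1 - P)) / (2 * m_called)
      Pn <- N1 / (N1 + N0)
      Pn[!is.finite(Pn)] <- P[!is.finite(Pn)]
      Q <- Qn / rowSums(Qn)                  # renormalize away float drift
      P <- clamp(Pn, EPS_PI, 1 - EPS_PI)
      ll <- admixture_loglik(g, Q, P)
      if (!is.finite(ll)) stopf("non-finite log-likelihood at iteration %d", it)
      trace <- c(trace, ll)
      if (ll - ll_old < tol && it > 1) { converged <- TRUE; break }
      ll_old <- ll
    }
    list(Q = Q, P = P, loglik = trace[length(trace)], loglik_trace = trace,
         n_iter = it, converged = converged)
  }

  seeds <- if (is.null(seed)) {
    sample.int(.Machine$integer.max, n_restarts)
  } else {
    seed + seq_len(n_restarts) - 1
  }
  runs <- lapply(seeds, run_once)
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best <- runs[[which.max(lls)]]
  fit <- c(best[c("Q", "P", "loglik", "loglik_trace", "n_iter", "converged")],
           list(K = as.integer(K), restart_logliks = lls))
  rownames(fit$Q) <- rownames(g)
  colnames(fit$P) <- colnames(g)
  class(fit) <- "admixture_fit"
  fit
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("Admixture model fit: K = %d, %d samples, %d variants\n",
              x$K, nrow(x$Q), ncol(x$P)))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
summary.admixture_fit <- function(object, ...) {
  print(object)
  cat("Mean ancestry fractions:\n")
  print(round(colMeans(object$Q), 3))
  invisible(object)
}

#' @export
coef.admixture_fit <- function(object, ...) object$Q

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$Q) + length(object$P),
            class = "logLik")
}

#' Match component labels between two Q matrices
#'
#' EM component order is arbitrary; this searches all column permutations of
#' `Q_est` (feasible for the K used here) for the one minimizing RMSE against
#' `Q_ref`.
#'
#' @param Q_est,Q_ref n x K ancestry matrices.
#' @return list with the permuted `Q`, the `permutation` and the `rmse`.
#' @export
match_ancestry_columns <- function(Q_est, Q_ref) {
  K <- ncol(Q_est)
  stopifnot(ncol(Q_ref) == K, nrow(Q_est) == nrow(Q_ref))
  perms <- permutations_of(K)
  best <- NULL
  for (p in perms) {
    r <- sqrt(mean((Q_est[, p, drop = FALSE] - Q_ref)^2))
    if (is.null(best) || r < best$rmse) {
      best <- list(Q = Q_est[, p, drop = FALSE], permutation = p, rmse = r)
    }
  }
  best
}

permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (rest in permutations_of(K - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(K), i)[rest])
    }
  }
  out
}
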