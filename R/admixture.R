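#' Maximum-likelihood admixture estimation by EM
#'
#' Fits the standard admixture model for unlinked biallelic SNPs: dosage
#' `g_il ~ Binomial(2, p_il)` with `p_il = sum_k q_ik f_kl`, where `Q`
#' (samples x K) holds ancestry coefficients and `F` (K x sites) ancestral
#' allele frequencies. Parameters are estimated by multiplicative EM updates
#' from a seeded random start (Q from a symmetric Dirichlet, F from jittered
#' observed frequencies); missing calls are skipped. The log-likelihood is
#' checked to be non-decreasing at every iteration. `F` is clipped to
#' `[1e-6, 1 - 1e-6]` each iteration.
#'
#' At `K = 1` the fit equals the closed form: `Q` all ones, `F` the observed
#' allele frequencies, and the log-likelihood the binomial log-likelihood at
#' those frequencies.
#'
#' @param G dosage matrix (samples x sites, 0/1/2/`NA`).
#' @param K number of ancestral populations (1 <= K <= n samples).
#' @param seed integer seed for the random initialisation.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change for convergence.
#' @return an `admixture_fit`: list with `Q`, `F`, `loglik`, `trajectory`
#'   (per-iteration log-likelihoods), `K`, `seed`, `n_iter`, `converged`.
#' @export
em_admixture <- function(G, K, seed = 1, max_iter = 500, tol = 1e-6) {
  n <- nrow(G)
  L <- ncol(G)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of samples (", n, ")")
  m_i <- rowSums(!is.na(G))
  if (any(m_i == 0)) {
    ids <- rownames(G)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    stop("sample(s) with all calls missing: ",
         paste(ids[m_i == 0], collapse = ", "))
  }

  set.seed(seed)
  M <- (!is.na(G)) * 1
  Gm <- G
  Gm[is.na(Gm)] <- 0
  storage.mode(Gm) <- "double"
  Tm <- 2 * M

  obs_f <- colSums(Gm) / pmax(colSums(Tm), 1)
  Fm <- matrix(rep(obs_f, each = K), K, L) +
    matrix(stats::runif(K * L, -0.05, 0.05), K, L)
  Fm <- pmin(pmax(Fm, 1e-6), 1 - 1e-6)
  if (K == 1L) {
    Q <- matrix(1, n, 1)
  } else {
    Qa <- matrix(stats::rgamma(n * K, shape = 1), n, K)
    Q <- Qa / rowSums(Qa)
  }

  ll_prev <- -Inf
  traj <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    P <- Q %*% Fm
    P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
    R1 <- Gm / P
    R0 <- (Tm - Gm) / (1 - P)
    # multiplicative updates; responsibilities never materialised per k
    Fnum <- Fm * crossprod(Q, R1)
    Fden <- Fnum + (1 - Fm) * crossprod(Q, R0)
    Qnew <- Q * (R1 %*% t(Fm) + R0 %*% t(1 - Fm))
    Q <- Qnew / (2 * m_i)
    Q <- Q / rowSums(Q)
    Fm <- Fnum / pmax(Fden, 1e-12)
    Fm <- pmin(pmax(Fm, 1e-6), 1 - 1e-6)

    P <- pmin(pmax(Q %*% Fm, 1e-9), 1 - 1e-9)
    ll <- sum(Gm * log(P) + (Tm - Gm) * log1p(-P))
    traj <- c(traj, ll)
    if (is.finite(ll_prev) && ll < ll_prev - 1e-6 * abs(ll_prev) - 1e-8) {
      stop("EM log-likelihood decreased (", ll_prev, " -> ", ll, ")")
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  rownames(Q) <- rownames(G)
  colnames(Fm) <- colnames(G)
  structure(list(Q = Q, F = Fm, loglik = traj[length(traj)],
                 trajectory = traj, K = K, seed = seed, n_iter = it,
                 converged = converged),
            class = "admixture_fit")
}

#' @exportS3Method base::print
print.admixture_fit <- function(x, ...) {
  cat("admixture fit: K =", x$K, ", n =", nrow(x$Q),
      ", loglik =", format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Multi-start, multi-K admixture scan
#'
#' Runs [em_admixture()] with `restarts` random starts for every K in a
#' contiguous range, keeps the best fit per K, and computes the Evanno
#' delta-K table from the per-run final log-likelihoods.
#'
#' @param G dosage matrix.
#' @param k_range contiguous integer range of K values (default 1:10).
#' @param restarts random restarts per K (default 5).
#' @param seed integer seed; per-run seeds are derived reproducibly.
#' @param ... passed to [em_admixture()] (`max_iter`, `tol`).
#' @return an `admixture_scan`: list with `fits` (best fit per K, named by
#'   K), `logliks` (matrix K x restart), `delta_k` (see [evanno_delta_k()]),
#'   and `best_k` (argmax of delta-K over the Ks where it is defined, `NA`
#'   if nowhere defined).
#' @export
admixture_scan <- function(G, k_range = 1:10, restarts = 5, seed = 1, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 1L) stop("empty K range")
  if (restarts < 2L) stop("need at least 2 restarts per K for delta-K")
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(k_range) * restarts),
                      nrow = length(k_range))
  fits <- vector("list", length(k_range))
  names(fits) <- as.character(k_range)
  logliks <- matrix(NA_real_, length(k_range), restarts,
                    dimnames = list(as.character(k_range), NULL))
  for (i in seq_along(k_range)) {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- em_admixture(G, k_range[i], seed = run_seeds[i, r], ...)
      logliks[i, r] <- fit$loglik
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    fits[[i]] <- best
  }
  dk <- if (length(k_range) >= 3L && all(diff(k_range) == 1L)) {
    evanno_delta_k(lapply(seq_along(k_range), function(i) logliks[i, ]),
                   k = k_range)
  } else {
    NULL
  }
  best_k <- if (!is.null(dk) && any(dk$defined)) {
    dk$K[which.max(ifelse(dk$defined, dk$delta_k, -Inf))]
  } else {
    NA_integer_
  }
  structure(list(fits = fits, logliks = logliks, delta_k = dk,
                 best_k = best_k, k_range = k_range, seed = seed),
            class = "admixture_scan")
}

#' Evanno delta-K from per-K log-likelihood collections
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`, with
#' the sample standard deviation across runs at K. Delta-K is undefined at
#' the endpoints of the range and wherever the between-run standard
#' deviation is zero (flagged via the `defined` column, not reported as
#' infinite).
#'
#' @param logliks list of numeric vectors of final log-likelihoods, one per
#'   K in ascending contiguous order; inner Ks need at least 2 runs.
#' @param k optional integer vector of the K values (defaults to positions
#'   of `logliks`, or its names when all are integers).
#' @return data.frame with columns `K`, `n_runs`, `mean_loglik`,
#'   `sd_loglik`, `delta_k`, `defined`.
#' @export
evanno_delta_k <- function(logliks, k = NULL) {
  if (is.null(k)) {
    k <- suppressWarnings(as.integer(names(logliks)))
    if (length(k) == 0L || anyNA(k)) k <- seq_along(logliks)
  }
  if (length(logliks) < 3L) stop("need a contiguous K range of length >= 3")
  if (any(diff(k) != 1L)) stop("K range must be contiguous")
  m <- vapply(logliks, mean, numeric(1))
  s <- vapply(logliks, function(x) if (length(x) >= 2) stats::sd(x) else NA_real_,
              numeric(1))
  nr <- vapply(logliks, length, integer(1))
  inner <- seq(2L, length(k) - 1L)
  if (any(nr[inner] < 2L)) {
    stop("inner K values need at least 2 runs for the delta-K denominator")
  }
  delta <- rep(NA_real_, length(k))
  for (i in inner) {
    second_diff <- abs(m[i + 1] - 2 * m[i] + m[i - 1])
    if (!is.na(s[i]) && s[i] > 0) delta[i] <- second_diff / s[i]
  }
  if (any(s[inner] == 0, na.rm = TRUE)) {
    warning("zero between-run sd at some K; delta-K undefined there")
  }
  data.frame(K = k, n_runs = nr, mean_loglik = m, sd_loglik = s,
             delta_k = delta, defined = !is.na(delta))
}

#' Classify cluster membership from ancestry coefficients
#'
#' A sample is assigned to its majority cluster when the maximum ancestry
#' coefficient strictly exceeds the threshold, and called `admixed`
#' otherwise (so a sample at exactly the threshold is admixed).
#'
#' @param Q ancestry matrix (samples x K), rows summing to 1.
#' @param threshold membership threshold (default 0.80).
#' @return character vector of labels `"cluster<k>"` or `"admixed"`.
#' @export
classify_membership <- function(Q, threshold = 0.80) {
  Q <- as.matrix(Q)
  apply(Q, 1, function(q) {
    j <- which.max(q)
    if (q[j] > threshold) paste0("cluster", j) else "admixed"
  })
}

#' Classify two-pool hybrids from ancestry coefficients
#'
#' With K = 2, samples whose ancestry toward pool 1 is within `tol` of 0.5
#' are F1-like; within `tol` of 0.25 or 0.75, BC1-like (first-generation
#' backcross); anything else is `other`. F1 takes precedence (the classes
#' cannot overlap for `tol <= 0.125`).
#'
#' @param Q ancestry matrix with 2 columns, or a numeric vector of
#'   pool-1 ancestry fractions.
#' @param tol half-width of the acceptance window (default 0.02).
#' @return character vector of `"F1-like"`, `"BC1-like"`, `"other"`.
#' @export
classify_hybrid_class <- function(Q, tol = 0.02) {
  if (is.matrix(Q)) {
    if (ncol(Q) != 2L) stop("hybrid classification requires K = 2")
    q1 <- Q[, 1]
  } else {
    q1 <- as.numeric(Q)
  }
  out <- rep("other", length(q1))
  out[abs(q1 - 0.25) <= tol | abs(q1 - 0.75) <= tol] <- "BC1-like"
  out[abs(q1 - 0.5) <= tol] <- "F1-like"
  names(out) <- names(q1)
  out
}

#' Align cluster labels between two ancestry matrices
#'
#' EM cluster labels are arbitrary (label switching). This greedily matches
#' columns of `Q` to columns of `reference` by correlation, the convention
#' used when collating multi-run results.
#'
#' @param Q ancestry matrix to relabel.
#' @param reference ancestry matrix with the same dimensions.
#' @return `Q` with columns permuted to best match `reference`; the
#'   permutation is attached as attribute `"perm"`.
#' @export
match_cluster_labels <- function(Q, reference) {
  Q <- as.matrix(Q)
  reference <- as.matrix(reference)
  if (!all(dim(Q) == dim(reference))) stop("dimension mismatch")
  K <- ncol(Q)
  cm <- suppressWarnings(stats::cor(reference, Q))
  cm[!is.finite(cm)] <- 0
  perm <- integer(K)
  used <- rep(FALSE, K)
  for (step in seq_len(K)) {
    best <- which(cm == max(cm[!is.na(cm)]), arr.ind = TRUE)[1, ]
    perm[best[1]] <- best[2]
    cm[best[1], ] <- -Inf
    cm[, best[2]] <- -Inf
  }
  out <- Q[, perm, drop = FALSE]
  attr(out, "perm") <- perm
  out
}
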