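#' Simulate divergent gene-pool allele frequencies
#'
#' Balding-Nichols style divergence: an ancestral frequency per site is
#' drawn uniform on \[0.05, 0.95\] (bounded away from 0/1 so MAF filtering
#' does not degenerate), and each pool's frequency is drawn from
#' `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)` when `fst > 0`, or
#' equals the ancestral frequency when `fst = 0`. Emulates a crop with two
#' (or more) genetically divergent gene pools.
#'
#' @param K_pools number of pools (>= 1).
#' @param L number of sites (>= 1).
#' @param fst divergence parameter in \[0, 1).
#' @param seed integer seed.
#' @return object of class `pool_frequencies`: list with `freqs`
#'   (K_pools x L matrix, entries strictly inside (0, 1)), `fst`, `seed`.
#' @export
simulate_pools <- function(K_pools, L, fst, seed = 1) {
  if (K_pools < 1) stop("K_pools must be >= 1")
  if (L < 1) stop("L must be >= 1")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  set.seed(seed)
  p <- stats::runif(L, 0.05, 0.95)
  if (fst == 0) {
    freqs <- matrix(rep(p, each = K_pools), K_pools, L)
  } else {
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    freqs <- matrix(NA_real_, K_pools, L)
    for (k in seq_len(K_pools)) {
      freqs[k, ] <- stats::rbeta(L, a, b)
    }
    freqs <- pmin(pmax(freqs, 1e-6), 1 - 1e-6)
  }
  structure(list(freqs = freqs, fst = fst, seed = seed),
            class = "pool_frequencies")
}

#' Specify a synthetic cohort
#'
#' Describes pure founders per pool, hybrid founders (for two pools),
#' clone groups duplicating a founder, and the genotyping noise applied
#' after cloning. Noise defaults are generator-level placeholders in the
#' absence of measured per-platform error rates: 5% heterozygote miscall,
#' 0.5% allele error, 5% missingness.
#'
#' @param n_per_pool integer vector: pure founders per pool.
#' @param hybrid_spec list of `c(ancestry_toward_pool1, count)` pairs, e.g.
#'   `list(c(0.5, 5), c(0.25, 8))`; requires exactly 2 pools.
#' @param clone_groups list of `c(founder_index, copies)` pairs; `copies`
#'   is the total group size including the founder, in 2..9 to mirror the
#'   clone-group sizes germplasm surveys report.
#' @param L number of sites (must match the pool frequencies).
#' @param het_miscall,allele_error,missing noise rates in \[0, 1\] (see
#'   [corrupt_genotypes()]).
#' @param mislabel_fraction fraction of clone copies renamed to another
#'   founder's cultivar name (creates deliberate homonyms).
#' @param unknown_fraction fraction of samples stripped of their cultivar
#'   name (flagged UNKNOWN).
#' @param seed integer seed for the cohort draw.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_pool, hybrid_spec = list(), clone_groups = list(),
                        L, het_miscall = 0.05, allele_error = 0.005,
                        missing = 0.05, mislabel_fraction = 0,
                        unknown_fraction = 0, seed = 1) {
  if (any(n_per_pool < 0)) stop("founder counts must be non-negative")
  for (h in hybrid_spec) {
    if (h[1] < 0 || h[1] > 1) stop("hybrid ancestry fraction must be in [0, 1]")
    if (h[2] < 0) stop("hybrid counts must be non-negative")
  }
  for (cg in clone_groups) {
    if (cg[2] < 2) stop("clone group copies must be >= 2")
  }
  rates <- c(het_miscall, allele_error, missing, mislabel_fraction,
             unknown_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates and fractions must be in [0, 1]")
  structure(list(n_per_pool = as.integer(n_per_pool),
                 hybrid_spec = hybrid_spec, clone_groups = clone_groups,
                 L = as.integer(L), het_miscall = het_miscall,
                 allele_error = allele_error, missing = missing,
                 mislabel_fraction = mislabel_fraction,
                 unknown_fraction = unknown_fraction, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Synthetic site table: sites spread over chromosomes with irregular spacing.
synthetic_sites <- function(L, n_chrom = 10) {
  n_chrom <- min(n_chrom, L)
  chrom_of <- sort(rep_len(seq_len(n_chrom), L))
  pos <- unlist(lapply(split(seq_len(L), chrom_of), function(idx) {
    cumsum(sample(200:2000, length(idx), replace = TRUE))
  }))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  sites <- data.frame(chrom = paste0("Chr", chrom_of), pos = as.integer(pos),
                      ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  sites$site_id <- paste(sites$chrom, sites$pos, sep = "_")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Simulate a genotyped cohort with known truth
#'
#' Founder genotypes are drawn `Binomial(2, p_il)` with
#' `p_il = sum_k q_ik f_kl`; clone-group members are exact copies of their
#' founder before noise; genotyping noise is then applied with
#' [corrupt_genotypes()]. Clone groups share their founder's cultivar name
#' by default, so the synonymy stage can anchor seed groups on them;
#' `mislabel_fraction` and `unknown_fraction` deliberately create homonyms
#' and unnamed samples. The returned truth record holds the true ancestry
#' matrix and the true clone partition.
#'
#' @param spec a [cohort_spec()].
#' @param pools a [simulate_pools()] result with matching `L` and pool
#'   count.
#' @return list with `genotypes` (dosage matrix), `sites` (synthetic site
#'   table), `meta` (sample table), and `truth` (list: `true_Q`,
#'   `clone_partition` with `groups`/`singletons`, `founder_genotypes`).
#' @export
simulate_cohort <- function(spec, pools) {
  K <- nrow(pools$freqs)
  if (spec$L != ncol(pools$freqs)) {
    stop("spec L (", spec$L, ") does not match pool frequencies (",
         ncol(pools$freqs), ")")
  }
  if (length(spec$n_per_pool) != K) {
    stop("n_per_pool length must equal the number of pools")
  }
  if (length(spec$hybrid_spec) && K != 2L) {
    stop("hybrid founders require exactly 2 pools")
  }
  set.seed(spec$seed)

  Qrows <- list()
  for (k in seq_len(K)) {
    if (spec$n_per_pool[k] > 0) {
      qk <- rep(0, K)
      qk[k] <- 1
      Qrows <- c(Qrows, rep(list(qk), spec$n_per_pool[k]))
    }
  }
  for (h in spec$hybrid_spec) {
    if (h[2] > 0) {
      Qrows <- c(Qrows, rep(list(c(h[1], 1 - h[1])), h[2]))
    }
  }
  n_f <- length(Qrows)
  for (cg in spec$clone_groups) {
    if (cg[1] < 1 || cg[1] > n_f) {
      stop("clone founder index ", cg[1], " out of range (1..", n_f, ")")
    }
  }

  empty <- function() {
    G0 <- matrix(integer(0), 0, spec$L)
    list(genotypes = G0, sites = synthetic_sites(spec$L),
         meta = as_sample_table(data.frame(sample_id = character(0),
                                           cultivar_name = character(0))),
         truth = list(true_Q = matrix(numeric(0), 0, K),
                      clone_partition = list(groups = list(),
                                             singletons = character(0)),
                      founder_genotypes = G0))
  }
  if (n_f == 0L) return(empty())

  Qf <- do.call(rbind, Qrows)
  P <- Qf %*% pools$freqs
  Gf <- matrix(stats::rbinom(n_f * spec$L, 2, as.vector(P)), n_f, spec$L)

  founder_of <- seq_len(n_f) # row i of output came from founder founder_of[i]
  for (cg in spec$clone_groups) {
    founder_of <- c(founder_of, rep(cg[1], cg[2] - 1L))
  }
  n <- length(founder_of)
  G <- Gf[founder_of, , drop = FALSE]
  Q <- Qf[founder_of, , drop = FALSE]
  storage.mode(G) <- "integer"

  ids <- sprintf("S%03d", seq_len(n))
  rownames(G) <- ids
  rownames(Q) <- ids
  names_of_founder <- sprintf("CV%03d", seq_len(n_f))
  cultivar <- names_of_founder[founder_of]

  is_copy <- seq_len(n) > n_f
  if (spec$mislabel_fraction > 0 && any(is_copy) && n_f > 1) {
    idx <- which(is_copy)
    k <- round(spec$mislabel_fraction * length(idx))
    if (k > 0) {
      chosen <- sample(idx, k)
      for (i in chosen) {
        cultivar[i] <- sample(setdiff(names_of_founder, cultivar[i]), 1)
      }
    }
  }
  if (spec$unknown_fraction > 0) {
    k <- round(spec$unknown_fraction * n)
    if (k > 0) cultivar[sample(seq_len(n), k)] <- "UNKNOWN"
  }

  part <- split(ids, founder_of)
  sizes <- vapply(part, length, integer(1))
  truth <- list(
    true_Q = Q,
    clone_partition = list(groups = unname(part[sizes >= 2L]),
                           singletons = unlist(unname(part[sizes == 1L]),
                                               use.names = FALSE)),
    founder_genotypes = Gf
  )

  sites <- synthetic_sites(spec$L)
  colnames(G) <- sites$site_id
  G <- corrupt_genotypes(G, spec$het_miscall, spec$allele_error,
                         spec$missing, seed = spec$seed + 1L)
  meta <- as_sample_table(data.frame(sample_id = ids, cultivar_name = cultivar,
                                     stringsAsFactors = FALSE))
  list(genotypes = G, sites = sites, meta = meta, truth = truth)
}

#' Apply genotyping noise to a dosage matrix
#'
#' Emulates the error sources of reduced-representation genotyping, in a
#' fixed order for testability: (1) each heterozygous call independently
#' becomes a random homozygote with probability `het_miscall_rate`; (2) each
#' remaining call is perturbed by one dosage unit (direction equiprobable,
#' clipped to \[0, 2\]) with probability `allele_error_rate`; (3) each call
#' is set missing with probability `missing_rate`.
#'
#' @param G dosage matrix.
#' @param het_miscall_rate,allele_error_rate,missing_rate rates in \[0, 1\].
#' @param seed integer seed.
#' @return corrupted dosage matrix (same shape and dimnames).
#' @export
corrupt_genotypes <- function(G, het_miscall_rate = 0, allele_error_rate = 0,
                              missing_rate = 0, seed = 1) {
  rates <- c(het_miscall_rate, allele_error_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  set.seed(seed)
  out <- G
  hets <- which(!is.na(out) & out == 1L)
  if (length(hets)) {
    flip <- hets[stats::runif(length(hets)) < het_miscall_rate]
    if (length(flip)) {
      out[flip] <- sample(c(0L, 2L), length(flip), replace = TRUE)
    }
  }
  obs <- which(!is.na(out))
  if (length(obs)) {
    err <- obs[stats::runif(length(obs)) < allele_error_rate]
    if (length(err)) {
      delta <- sample(c(-1L, 1L), length(err), replace = TRUE)
      out[err] <- pmin(pmax(out[err] + delta, 0L), 2L)
    }
  }
  obs <- which(!is.na(out))
  if (length(obs)) {
    drop <- obs[stats::runif(length(obs)) < missing_rate]
    if (length(drop)) out[drop] <- NA_integer_
  }
  out
}
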