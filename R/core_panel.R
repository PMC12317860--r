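#' Per-site minor allele frequency
#'
#' Alternate-allele frequency is computed over non-missing alleles and
#' folded: `MAF = min(p, 1 - p)`. Sites with no non-missing call get `NA`.
#'
#' @param G dosage matrix (samples x sites).
#' @return numeric vector of MAF per site (named by site when `G` has
#'   colnames).
#' @export
site_maf <- function(G) {
  M <- !is.na(G)
  alt <- colSums(G, na.rm = TRUE)
  tot <- 2 * colSums(M)
  p <- ifelse(tot > 0, alt / tot, NA_real_)
  maf <- pmin(p, 1 - p)
  names(maf) <- colnames(G)
  maf
}

#' Polymorphic information content (Botstein)
#'
#' `PIC = 1 - sum_i p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`. For a biallelic
#' marker with frequencies (p, q) this is `1 - p^2 - q^2 - 2 p^2 q^2`,
#' maximal at 0.375 when p = 0.5. A single frequency is interpreted as one
#' allele of a biallelic marker; a vector must sum to 1.
#'
#' @param freqs allele frequency (scalar, biallelic) or vector of allele
#'   frequencies summing to 1.
#' @return the PIC value.
#' @export
pic <- function(freqs) {
  freqs <- as.numeric(freqs)
  if (length(freqs) == 1L) freqs <- c(freqs, 1 - freqs)
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1 (got ", sum(freqs), ")")
  }
  s2 <- sum(freqs^2)
  p2 <- freqs^2
  cross <- (sum(p2)^2 - sum(p2^2)) # 2 * sum_{i<j} p_i^2 p_j^2
  1 - s2 - cross
}

#' Per-site PIC for a genotype matrix
#'
#' @inheritParams site_maf
#' @return numeric vector of PIC per site (`NA` for all-missing sites).
#' @export
site_pic <- function(G) {
  maf <- site_maf(G)
  vapply(maf, function(p) if (is.na(p)) NA_real_ else pic(p), numeric(1))
}

pair_index <- function(ids) {
  n <- length(ids)
  p1 <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  p2 <- unlist(lapply(seq_len(n - 1L), function(i) seq(i + 1L, n)))
  list(p1 = p1, p2 = p2)
}

#' Greedy minimal discriminating SNP panel
#'
#' Iteratively selects the site that distinguishes the largest number of
#' currently indistinguishable target pairs; a pair is distinguished at a
#' site iff both calls are non-missing and the dosages differ (a panel must
#' not rely on missingness patterns). Ties are broken by genomic order (the
#' column order of `G`, which follows (chrom, pos) for matrices read from
#' VCF). Selection stops when no pair remains or no site adds coverage;
#' pairs left over are genuinely indistinguishable using all sites and are
#' reported as residual, not as an error.
#'
#' @param G dosage matrix (samples x sites).
#' @param targets sample ids to discriminate (default: all samples; at
#'   least 2).
#' @return object of class `panel_result`: list with `site_ids` (in
#'   selection order), `site_index`, `residual_pairs` (data.frame
#'   `sample1`/`sample2`), `targets`.
#' @export
greedy_min_panel <- function(G, targets = NULL) {
  if (is.null(targets)) targets <- rownames(G)
  if (length(targets) < 2L) stop("need at least 2 target samples")
  Gt <- G[targets, , drop = FALSE]
  L <- ncol(Gt)
  px <- pair_index(targets)
  remaining <- seq_along(px$p1)
  chosen <- integer(0)
  while (length(remaining)) {
    a <- px$p1[remaining]
    b <- px$p2[remaining]
    counts <- vapply(seq_len(L), function(l) {
      g1 <- Gt[, l][a]
      g2 <- Gt[, l][b]
      sum(!is.na(g1) & !is.na(g2) & g1 != g2)
    }, numeric(1))
    best <- max(counts)
    if (best == 0) break
    pick <- which(counts == best)[1L]
    chosen <- c(chosen, pick)
    g1 <- Gt[, pick][a]
    g2 <- Gt[, pick][b]
    solved <- !is.na(g1) & !is.na(g2) & g1 != g2
    remaining <- remaining[!solved]
  }
  residual <- data.frame(sample1 = targets[px$p1[remaining]],
                         sample2 = targets[px$p2[remaining]],
                         stringsAsFactors = FALSE)
  structure(list(site_ids = colnames(Gt)[chosen], site_index = chosen,
                 residual_pairs = residual, targets = targets),
            class = "panel_result")
}

#' @exportS3Method base::print
print.panel_result <- function(x, ...) {
  cat("SNP panel of", length(x$site_index), "marker(s) over",
      length(x$targets), "samples;",
      nrow(x$residual_pairs), "indistinguishable pair(s)\n")
  if (length(x$site_ids)) cat(" ", paste(x$site_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive minimum discriminating panel (small instances)
#'
#' Finds a smallest-cardinality site subset covering every distinguishable
#' target pair, by increasing-size subset enumeration (lexicographic
#' tie-break). Intended as an oracle for small instances; refuses site
#' counts above `max_sites`.
#'
#' @inheritParams greedy_min_panel
#' @param max_sites enumeration bound (default 20).
#' @return integer vector of selected site indices (possibly empty).
#' @export
exhaustive_min_panel <- function(G, targets = NULL, max_sites = 20) {
  if (is.null(targets)) targets <- rownames(G)
  if (length(targets) < 2L) stop("need at least 2 target samples")
  Gt <- G[targets, , drop = FALSE]
  L <- ncol(Gt)
  if (L > max_sites) {
    stop("site count ", L, " exceeds the enumeration bound (", max_sites,
         "); use greedy_min_panel()")
  }
  px <- pair_index(targets)
  disc <- vapply(seq_len(L), function(l) {
    g1 <- Gt[, l][px$p1]
    g2 <- Gt[, l][px$p2]
    !is.na(g1) & !is.na(g2) & g1 != g2
  }, logical(length(px$p1)))
  disc <- matrix(disc, nrow = length(px$p1))
  coverable <- which(rowSums(disc) > 0)
  if (!length(coverable)) return(integer(0))
  for (s in seq_len(L)) {
    combos <- utils::combn(L, s)
    for (ci in seq_len(ncol(combos))) {
      sub <- disc[coverable, combos[, ci], drop = FALSE]
      if (all(rowSums(sub) > 0)) return(combos[, ci])
    }
  }
  integer(0)
}

#' Panel report table with per-marker MAF and PIC
#'
#' @param G dosage matrix the panel was selected from.
#' @param sites site table (columns `site_id`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param panel a `panel_result` or character vector of site ids.
#' @return data.frame with columns `SNP_ID`, `CHROM`, `POSITION`, `MAF`
#'   (4 decimals), `PIC` (3 decimals), `Reference_allele`,
#'   `Alternate_allele`, one row per panel marker in panel order.
#' @export
panel_report <- function(G, sites, panel) {
  ids <- if (inherits(panel, "panel_result")) panel$site_ids else as.character(panel)
  if (!all(ids %in% sites$site_id)) {
    stop("panel sites absent from site table: ",
         paste(setdiff(ids, sites$site_id), collapse = ", "))
  }
  idx <- match(ids, sites$site_id)
  gidx <- match(ids, colnames(G))
  maf <- site_maf(G[, gidx, drop = FALSE])
  data.frame(
    SNP_ID = ids,
    CHROM = sites$chrom[idx],
    POSITION = sites$pos[idx],
    MAF = round(unname(maf), 4),
    PIC = round(vapply(unname(maf), pic, numeric(1)), 3),
    Reference_allele = sites$ref[idx],
    Alternate_allele = sites$alt[idx],
    stringsAsFactors = FALSE
  )
}
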