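#' Site-filter configuration
#'
#' Bundles the three site filters applied, in fixed order, by
#' [apply_filters()]: per-site missingness, minor allele frequency, and
#' physical distance thinning. The missingness threshold can be an absolute
#' sample count (`mode = "count"`, site kept iff missing calls are strictly
#' fewer than the threshold) or a fraction of samples (`mode = "fraction"`,
#' site kept iff missing fraction is at most the threshold). Count mode is
#' the default.
#'
#' @param max_missing missingness threshold (count or fraction, per
#'   `missing_mode`).
#' @param missing_mode `"count"` or `"fraction"`.
#' @param min_maf minimum minor allele frequency; sites with MAF strictly
#'   below it (and monomorphic sites) are removed. Must be in \[0, 0.5\].
#' @param thin_bp minimum distance in bp between kept sites on a chromosome.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(max_missing = 10, missing_mode = c("count", "fraction"),
                          min_maf = 0.05, thin_bp = 10000) {
  missing_mode <- match.arg(missing_mode)
  if (missing_mode == "fraction" && (max_missing < 0 || max_missing > 1)) {
    stop("fractional max_missing must be in [0, 1]")
  }
  if (missing_mode == "count" && max_missing < 0) {
    stop("max_missing count must be non-negative")
  }
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must be in [0, 0.5]")
  if (thin_bp < 1) stop("thin_bp must be >= 1")
  structure(list(max_missing = max_missing, missing_mode = missing_mode,
                 min_maf = min_maf, thin_bp = thin_bp),
            class = "filter_config")
}

#' Missingness site filter
#'
#' @param G dosage matrix (samples x sites).
#' @param max_missing threshold; in count mode a site passes iff the number
#'   of missing calls is strictly less than `max_missing`; in fraction mode
#'   iff `n_missing <= max_missing * n_samples`.
#' @param mode `"count"` or `"fraction"`.
#' @return logical site mask.
#' @export
filter_missingness <- function(G, max_missing, mode = c("count", "fraction")) {
  mode <- match.arg(mode)
  n_missing <- colSums(is.na(G))
  if (mode == "count") {
    n_missing < max_missing
  } else {
    if (max_missing > 1) stop("fractional max_missing must be in [0, 1]")
    n_missing <= max_missing * nrow(G)
  }
}

#' Minor-allele-frequency site filter
#'
#' MAF is computed over non-missing alleles. A site is kept iff its MAF is at
#' least `min_maf` (a site at exactly the threshold is kept). Monomorphic and
#' all-missing sites are always removed.
#'
#' @inheritParams filter_missingness
#' @param min_maf minimum minor allele frequency in \[0, 0.5\].
#' @return logical site mask.
#' @export
filter_maf <- function(G, min_maf = 0.05) {
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must be in [0, 0.5]")
  maf <- site_maf(G)
  !is.na(maf) & maf >= min_maf & maf > 0
}

#' Physical-distance thinning
#'
#' Greedy left-to-right scan per chromosome: the first site is kept, and each
#' subsequent site is kept only if its position is at least `thin_bp` beyond
#' the last kept site. No two kept sites on a chromosome are closer than
#' `thin_bp`. Sites must be sorted by (chrom, pos).
#'
#' @param sites site table (columns `chrom`, `pos`).
#' @param thin_bp minimum spacing in bp.
#' @return logical site mask in the order of `sites`.
#' @export
thin_by_distance <- function(sites, thin_bp) {
  if (thin_bp < 1) stop("thin_bp must be >= 1")
  if (is.unsorted(order(sites$chrom, sites$pos))) {
    # order() of a sorted table is 1..n; anything else means unsorted input
    stop("site table must be sorted by (chrom, pos)")
  }
  keep <- logical(nrow(sites))
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    last <- -Inf
    for (i in idx) {
      if (sites$pos[i] - last >= thin_bp || !is.finite(last)) {
        keep[i] <- TRUE
        last <- sites$pos[i]
      }
    }
  }
  keep
}

#' Apply the site filters in fixed order
#'
#' Order is missingness, then MAF, then thinning; the order matters because
#' the thinning scan depends on which sites remain. The returned report
#' records the surviving site count after each stage.
#'
#' @param G dosage matrix (samples x sites).
#' @param sites site table matching the columns of `G`.
#' @param config a [filter_config()].
#' @return list with `genotypes`, `sites` (both filtered) and `report`
#'   (data.frame of stage and n_sites).
#' @export
apply_filters <- function(G, sites, config = filter_config()) {
  if (ncol(G) != nrow(sites)) stop("genotypes and site table disagree on site count")
  report <- data.frame(stage = "input", n_sites = ncol(G),
                       stringsAsFactors = FALSE)

  m1 <- filter_missingness(G, config$max_missing, config$missing_mode)
  G <- G[, m1, drop = FALSE]
  sites <- sites[m1, , drop = FALSE]
  report <- rbind(report, data.frame(stage = "missingness", n_sites = ncol(G)))

  m2 <- filter_maf(G, config$min_maf)
  G <- G[, m2, drop = FALSE]
  sites <- sites[m2, , drop = FALSE]
  report <- rbind(report, data.frame(stage = "maf", n_sites = ncol(G)))

  m3 <- thin_by_distance(sites, config$thin_bp)
  G <- G[, m3, drop = FALSE]
  sites <- sites[m3, , drop = FALSE]
  report <- rbind(report, data.frame(stage = "thin", n_sites = ncol(G)))

  if (ncol(G) == 0L) stop("no sites survive filtering")
  rownames(sites) <- NULL
  list(genotypes = G, sites = sites, report = report)
}
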