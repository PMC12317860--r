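#' Classify maturity-group genotype from the two-primer indel assay
#'
#' The assay scores presence/absence of amplification for two primer pairs
#' flanking the insertion (haplotype B) and deletion (haplotype C) alleles
#' of the indel near the COL307 flowering-time gene. Amplification with only
#' the insertion pair means a B homozygote (late-maturing type), only the
#' deletion pair a C homozygote (extremely-early type), both pairs a
#' heterozygote (early-maturing hybrid type), and neither a failed assay.
#'
#' @param amp_B logical: insertion-haplotype primer pair amplified.
#' @param amp_C logical: deletion-haplotype primer pair amplified.
#' @return factor with levels `B_homozygote`, `C_homozygote`,
#'   `heterozygote`, `failed` (vectorised over the inputs).
#' @export
classify_maturity <- function(amp_B, amp_C) {
  amp_B <- as.logical(amp_B)
  amp_C <- as.logical(amp_C)
  if (length(amp_B) != length(amp_C)) stop("amp_B and amp_C differ in length")
  out <- ifelse(amp_B & amp_C, "heterozygote",
                ifelse(amp_B, "B_homozygote",
                       ifelse(amp_C, "C_homozygote", "failed")))
  factor(out, levels = c("B_homozygote", "C_homozygote", "heterozygote",
                         "failed"))
}

#' Read a maturity assay table
#'
#' TSV with columns `sample_id`, `amp_B`, `amp_C` (logical or 0/1).
#'
#' @param path path to the TSV.
#' @return data.frame with `sample_id` and logical `amp_B`, `amp_C`.
#' @export
read_assay <- function(path) {
  if (!file.exists(path)) stop("assay file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "amp_B", "amp_C")
  if (!all(req %in% names(df))) {
    stop("assay table must have columns: ", paste(req, collapse = ", "))
  }
  to_logical <- function(x) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(x != 0)
    x <- trimws(toupper(as.character(x)))
    yes <- c("TRUE", "T", "1", "YES", "Y")
    no <- c("FALSE", "F", "0", "NO", "N")
    out <- x %in% yes
    out[!x %in% c(yes, no)] <- NA
    out
  }
  df$amp_B <- to_logical(df$amp_B)
  df$amp_C <- to_logical(df$amp_C)
  df[, req]
}

#' Tabulate maturity assay calls
#'
#' Counts samples per maturity class; optionally cross-tabulates the calls
#' against admixture membership labels.
#'
#' @param assay data.frame with `sample_id`, `amp_B`, `amp_C` (see
#'   [read_assay()]).
#' @param membership optional named character vector of cluster/admixed
#'   labels (names are sample ids), e.g. from [classify_membership()].
#' @return list with `calls` (per-sample factor), `counts` (named integer
#'   vector over the four classes) and `cross` (contingency table or
#'   `NULL`).
#' @export
tabulate_assay <- function(assay, membership = NULL) {
  if (anyDuplicated(assay$sample_id)) {
    stop("duplicate sample rows in assay: ",
         paste(unique(assay$sample_id[duplicated(assay$sample_id)]),
               collapse = ", "))
  }
  calls <- classify_maturity(assay$amp_B, assay$amp_C)
  names(calls) <- assay$sample_id
  counts <- table(calls)
  cross <- NULL
  if (!is.null(membership)) {
    memb <- membership[assay$sample_id]
    cross <- table(call = calls, membership = memb)
  }
  list(calls = calls, counts = counts, cross = cross)
}
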