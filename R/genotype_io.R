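#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses the GT field of a VCF into a samples-by-sites integer dosage matrix
#' (count of alternate alleles, 0/1/2, `NA` for missing). Only biallelic SNP
#' records (single-base REF and ALT) are used; multi-allelic and indel records
#' are skipped with a warning and counted. Phased (`|`) and unphased (`/`)
#' genotypes are treated identically; `./.` becomes `NA`.
#'
#' @param path Path to a VCF file (plain text or gzip).
#' @return A list with components:
#'   \describe{
#'     \item{genotypes}{integer matrix, samples in rows (rownames = sample
#'       ids), sites in columns (colnames = site ids `chrom_pos`).}
#'     \item{sites}{data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'       `alt`, `site_id`, sorted by (chrom, pos).}
#'     \item{n_skipped}{number of non-SNP / multi-allelic records skipped.}
#'   }
#' @seealso [write_vcf()], [read_sample_metadata()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {
    # single-record VCFs come back as a bare named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0L) {
    stop("no variant records in VCF: ", path)
  }
  bases <- c("A", "C", "G", "T")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(ref) & !is.na(alt) & ref %in% bases & alt %in% bases
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(n_skipped, " multi-allelic or non-SNP record(s) skipped")
  }
  if (!any(keep)) stop("no biallelic SNP records in VCF: ", path)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  miss <- is.na(gt) | a1 == "." | a2 == "."
  dos <- (a1 == "1") + (a2 == "1")
  dos[miss] <- NA_integer_

  sites <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep],
    alt = alt[keep],
    stringsAsFactors = FALSE
  )
  sites$site_id <- paste(sites$chrom, sites$pos, sep = "_")
  if (anyDuplicated(sites[, c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) records in VCF: ", path)
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL

  G <- t(dos)[, ord, drop = FALSE]
  storage.mode(G) <- "integer"
  colnames(G) <- sites$site_id
  list(genotypes = G, sites = sites, n_skipped = n_skipped)
}

#' Write a dosage genotype matrix as VCF 4.2
#'
#' Emits a minimal GT-only VCF: dosage 0 becomes `0/0`, 1 becomes `0/1`,
#' 2 becomes `1/1`, `NA` becomes `./.`.
#'
#' @param G integer dosage matrix (samples x sites, values 0/1/2/`NA`).
#' @param sites site table as returned by [read_vcf()] (columns `chrom`,
#'   `pos`, `ref`, `alt`, `site_id`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, sites, path) {
  if (ncol(G) != nrow(sites)) {
    stop("genotype matrix has ", ncol(G), " sites but site table has ",
         nrow(sites))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=germclone",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  if (nrow(sites) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  gt <- matrix(c("0/0", "0/1", "1/1")[G + 1L], nrow = nrow(G))
  gt[is.na(G)] <- "./."
  cols <- c(
    list(sites$chrom, sites$pos, sites$site_id, sites$ref, sites$alt,
         ".", "PASS", ".", "GT"),
    if (nrow(G) > 0L) as.data.frame(t(gt), stringsAsFactors = FALSE),
    list(sep = "\t")
  )
  writeLines(c(header, do.call(paste, cols)), path)
  invisible(path)
}

#' Construct a validated sample-metadata table
#'
#' Normalises cultivar names for matching (trim + case-fold, kept in
#' `name_key`) while preserving the original spelling. Samples named
#' `UNKNOWN` (any case) or with an empty name are flagged unknown and get no
#' `name_key`, so they never match a named cultivar. An optional
#' `synonym_group` column declares cultivar names known from prior work to be
#' synonymous: samples sharing a group key are treated as same-named by the
#' synonymy stage.
#'
#' @param df data.frame with columns `sample_id`, `cultivar_name` and
#'   optionally `synonym_group`.
#' @return data.frame with columns `sample_id`, `cultivar_name`,
#'   `is_unknown`, `name_key`, `synonym_group`.
#' @export
as_sample_table <- function(df) {
  req <- c("sample_id", "cultivar_name")
  if (!all(req %in% names(df))) {
    stop("sample metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  name <- trimws(as.character(df$cultivar_name))
  unk <- is.na(name) | name == "" | toupper(name) == "UNKNOWN"
  key <- tolower(name)
  key[unk] <- NA_character_
  syn <- if ("synonym_group" %in% names(df)) {
    s <- trimws(as.character(df$synonym_group))
    s[is.na(s) | s == ""] <- NA_character_
    s
  } else {
    rep(NA_character_, nrow(df))
  }
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    cultivar_name = name,
    is_unknown = unk,
    name_key = key,
    synonym_group = syn,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read sample metadata from a tab-separated file
#'
#' Expects a header with `sample_id`, `cultivar_name` and optionally
#' `synonym_group` (see [as_sample_table()] for the normalisation rules).
#' When a genotype matrix is supplied, every genotyped sample must appear in
#' the table.
#'
#' @param path path to the TSV file.
#' @param genotypes optional dosage matrix whose rownames are checked against
#'   the table.
#' @return a sample table (see [as_sample_table()]).
#' @export
read_sample_metadata <- function(path, genotypes = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  tab <- as_sample_table(df)
  if (!is.null(genotypes)) {
    missing <- setdiff(rownames(genotypes), tab$sample_id)
    if (length(missing)) {
      stop("samples in genotypes absent from metadata: ",
           paste(missing, collapse = ", "))
    }
  }
  tab
}

# Effective name key used for same-name matching: a shared synonym_group
# overrides the cultivar name, so known-synonym pairs compare equal.
# Unknowns stay NA and never match anything.
effective_name_key <- function(meta) {
  key <- meta$name_key
  has_syn <- !is.na(meta$synonym_group)
  key[has_syn] <- paste0("synonym_group:", meta$synonym_group[has_syn])
  names(key) <- meta$sample_id
  key
}
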