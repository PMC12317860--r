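#' Pipeline configuration
#'
#' Collects every stage's inputs and tuning parameters for
#' [run_pipeline()]. Defaults follow the analysis conventions for germplasm
#' SNP surveys: 1000 bootstrap replicates, K from 1 to 10 with 5 EM restarts
#' per K, membership threshold 0.80, and at most 2 extra samples in a
#' synonymy seed clade.
#'
#' @param vcf path to the genotype VCF.
#' @param metadata path to the sample metadata TSV.
#' @param outdir output directory (created if needed).
#' @param assay optional path to a maturity assay TSV.
#' @param filter a [filter_config()].
#' @param boot bootstrap replicate count.
#' @param k_range contiguous K range for the admixture scan.
#' @param restarts EM restarts per K.
#' @param seed integer master seed (bootstrap and admixture streams are
#'   derived from it and recorded in the manifest).
#' @param max_extra seed-clade interloper bound.
#' @param cutoff manual clone-distance cutoff overriding the derived one
#'   (`NULL` = derive from seed groups).
#' @param membership_threshold cluster membership threshold.
#' @param panel_targets sample ids the SNP panel must discriminate
#'   (`NULL` = all samples).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, metadata, outdir, assay = NULL,
                            filter = filter_config(), boot = 1000,
                            k_range = 1:10, restarts = 5, seed = 1,
                            max_extra = 2, cutoff = NULL,
                            membership_threshold = 0.80,
                            panel_targets = NULL) {
  structure(list(vcf = vcf, metadata = metadata, outdir = outdir,
                 assay = assay, filter = filter, boot = boot,
                 k_range = k_range, restarts = restarts, seed = seed,
                 max_extra = max_extra, cutoff = cutoff,
                 membership_threshold = membership_threshold,
                 panel_targets = panel_targets),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full characterisation pipeline
#'
#' Executes filter, distance, tree + bootstrap, admixture + delta-K,
#' synonymy, panel and (optionally) maturity tabulation, writing TSV /
#' newick artifacts and a JSON run manifest (seeds, per-stage counts) to the
#' output directory. Any stage error halts the run with the stage name and
#' dumps the partial manifest.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every stage's in-memory result plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  for (p in c(config$vcf, config$metadata, config$assay)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("germclone")),
                   seed = config$seed, timestamp = format(Sys.time()),
                   stages = list())
  res <- list()

  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest,
                           file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    out
  }

  # --- input + filter ---------------------------------------------------
  res$input <- stage("read", {
    vc <- read_vcf(config$vcf)
    meta <- read_sample_metadata(config$metadata, vc$genotypes)
    c(vc, list(meta = meta))
  })
  manifest$stages$read <- list(n_samples = nrow(res$input$genotypes),
                               n_sites = ncol(res$input$genotypes),
                               n_skipped = res$input$n_skipped)

  res$filtered <- stage("filter", {
    apply_filters(res$input$genotypes, res$input$sites, config$filter)
  })
  write_tsv(res$filtered$report, file.path(config$outdir, "filter_report.tsv"))
  manifest$stages$filter <- as.list(stats::setNames(
    res$filtered$report$n_sites, res$filtered$report$stage))

  G <- res$filtered$genotypes

  # --- distance + tree --------------------------------------------------
  res$distance <- stage("distance", p_distance_matrix(G))
  write_phylip(res$distance, file.path(config$outdir, "distances.phy"))
  manifest$stages$distance <- list(
    n_pairs = nrow(as.matrix(res$distance)) * (nrow(as.matrix(res$distance)) - 1) / 2,
    max_distance = max(as.matrix(res$distance)))

  res$tree <- stage("tree", {
    main <- nj_tree(res$distance)
    reps <- bootstrap_distance_matrices(G, B = config$boot,
                                        seed = config$seed + 1L)
    rep_trees <- lapply(reps, nj_tree)
    bootstrap_support(main, rep_trees)
  })
  write_newick(res$tree, file.path(config$outdir, "tree.nwk"))
  manifest$stages$tree <- list(n_tips = length(res$tree$tip.label),
                               boot = config$boot)

  # --- admixture --------------------------------------------------------
  res$admixture <- stage("admixture", {
    admixture_scan(G, k_range = config$k_range, restarts = config$restarts,
                   seed = config$seed + 2L)
  })
  scan <- res$admixture
  if (!is.null(scan$delta_k)) {
    write_tsv(scan$delta_k, file.path(config$outdir, "delta_k.tsv"))
  }
  report_k <- if (!is.na(scan$best_k)) scan$best_k else max(scan$k_range)
  best_fit <- scan$fits[[as.character(report_k)]]
  qdf <- data.frame(sample_id = rownames(best_fit$Q),
                    round(best_fit$Q, 5), check.names = FALSE)
  names(qdf)[-1] <- paste0("Q", seq_len(best_fit$K))
  # bar-plot-ready ordering mirrors tip order on the tree
  tip_order <- res$tree$tip.label
  qdf <- qdf[match(tip_order, qdf$sample_id), , drop = FALSE]
  write_tsv(qdf, file.path(config$outdir, "qmatrix.tsv"))
  membership <- classify_membership(best_fit$Q, config$membership_threshold)
  memb_df <- data.frame(sample_id = rownames(best_fit$Q),
                        membership = membership, stringsAsFactors = FALSE)
  if (best_fit$K == 2L) {
    memb_df$hybrid_class <- classify_hybrid_class(best_fit$Q)
  }
  write_tsv(memb_df, file.path(config$outdir, "membership.tsv"))
  manifest$stages$admixture <- list(best_k = scan$best_k,
                                    report_k = report_k,
                                    membership = as.list(table(membership)))

  # --- synonymy ---------------------------------------------------------
  res$synonymy <- stage("synonymy", {
    seeds <- find_seed_groups(res$tree, res$input$meta, res$distance,
                              max_extra = config$max_extra)
    cutoff <- if (is.null(config$cutoff)) derive_cutoff(seeds) else config$cutoff
    grouping <- clone_groups(res$distance, cutoff)
    report <- classify_nomenclature(grouping, res$input$meta)
    list(seed_groups = seeds, cutoff = cutoff, grouping = grouping,
         report = report)
  })
  sg <- res$synonymy$seed_groups
  write_tsv(data.frame(
    anchor = vapply(sg, function(g) g$anchor, character(1)),
    size = vapply(sg, function(g) length(g$members), integer(1)),
    max_distance = vapply(sg, function(g) g$max_distance, numeric(1)),
    members = vapply(sg, function(g) paste(g$members, collapse = ","),
                     character(1))
  ), file.path(config$outdir, "seed_groups.tsv"))
  grouping <- res$synonymy$grouping
  write_tsv(data.frame(
    group = rep(seq_along(grouping$groups),
                vapply(grouping$groups, length, 1L)),
    sample_id = unlist(grouping$groups)
  ), file.path(config$outdir, "clone_groups.tsv"))
  write_tsv(res$synonymy$report$unknown_suggestions,
            file.path(config$outdir, "unknown_suggestions.tsv"))
  write_tsv(res$synonymy$report$synonym_sets,
            file.path(config$outdir, "synonym_sets.tsv"))
  write_tsv(res$synonymy$report$homonyms,
            file.path(config$outdir, "homonyms.tsv"))
  gsum <- summary(grouping)
  manifest$stages$synonymy <- list(cutoff = res$synonymy$cutoff,
                                   n_seed_groups = length(sg),
                                   n_groups = gsum$n_groups,
                                   n_clonal = gsum$n_clonal,
                                   n_distinct = gsum$n_distinct)

  # --- core panel -------------------------------------------------------
  res$panel <- stage("panel", {
    pr <- greedy_min_panel(G, targets = config$panel_targets)
    list(panel = pr, report = panel_report(G, res$filtered$sites, pr))
  })
  write_tsv(res$panel$report, file.path(config$outdir, "panel.tsv"))
  manifest$stages$panel <- list(
    n_markers = length(res$panel$panel$site_index),
    n_residual_pairs = nrow(res$panel$panel$residual_pairs))

  # --- maturity (optional) ---------------------------------------------
  if (!is.null(config$assay)) {
    res$maturity <- stage("maturity", {
      tabulate_assay(read_assay(config$assay),
                     membership = stats::setNames(membership,
                                                  rownames(best_fit$Q)))
    })
    write_tsv(data.frame(call = names(res$maturity$counts),
                         n = as.integer(res$maturity$counts)),
              file.path(config$outdir, "maturity_counts.tsv"))
    manifest$stages$maturity <- as.list(res$maturity$counts)
  }

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}
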