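#' Same-named sister pairs in a tree
#'
#' Finds all cherries (two-tip clades) whose tips carry the same cultivar
#' name or share a known-synonym group. These pairs anchor the
#' clone-distance cutoff.
#'
#' @param tree `phylo` tree whose tips are sample ids.
#' @param meta sample table (see [as_sample_table()]).
#' @return data.frame with columns `sample1`, `sample2`, `name_key` (one row
#'   per qualifying cherry; zero rows when none qualify).
#' @export
find_same_name_sister_pairs <- function(tree, meta) {
  missing <- setdiff(tree$tip.label, meta$sample_id)
  if (length(missing)) {
    stop("tree tips absent from metadata: ", paste(missing, collapse = ", "))
  }
  key <- effective_name_key(meta)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- data.frame(sample1 = character(0), sample2 = character(0),
                    name_key = character(0), stringsAsFactors = FALSE)
  for (node in names(kids)) {
    ch <- kids[[node]]
    if (length(ch) == 2L && all(ch <= ntip)) {
      t1 <- tree$tip.label[ch[1]]
      t2 <- tree$tip.label[ch[2]]
      k1 <- key[[t1]]
      k2 <- key[[t2]]
      if (!is.na(k1) && !is.na(k2) && k1 == k2) {
        out <- rbind(out, data.frame(sample1 = min(t1, t2),
                                     sample2 = max(t1, t2),
                                     name_key = k1, stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$sample1, out$sample2), , drop = FALSE]
}

#' Seed groups for the clone-distance cutoff
#'
#' For every cultivar name (or known-synonym group) represented by at least
#' two tips, finds the clades of the midpoint-rooted tree that contain at
#' least two matching tips and at most `max_extra` non-matching tips. By
#' default the largest qualifying clade per name is kept (`expand =
#' "maximal"`), the expanded-group construction that reports whole
#' near-identical clusters with one or two interlopers; `expand = "minimal"`
#' instead keeps the smallest clusters in which two same-named samples meet.
#' Same-named sister pairs are always included as size-2 seed groups.
#'
#' Each group's `max_distance` — the quantity [derive_cutoff()] consumes —
#' is the maximum pairwise distance among the *same-named* members only.
#' Interlopers are candidate clones whose status the cutoff will decide, so
#' letting their distances feed the cutoff would be circular, and a lone
#' distant relative absorbed by a qualifying clade would inflate it
#' arbitrarily. The all-member diameter is still reported as
#' `max_distance_all`.
#'
#' @param tree `phylo` tree over the sample ids.
#' @param meta sample table.
#' @param D `p_distance` object or distance matrix over the same samples.
#' @param max_extra maximum number of non-matching tips in a seed clade
#'   (default 2).
#' @param expand keep `"maximal"` (default) or `"minimal"` qualifying
#'   clades.
#' @return object of class `seed_groups`: list of lists with `members`,
#'   `anchor` (name key), `n_matching`, `max_distance` (same-named members),
#'   `max_distance_all` (all members).
#' @export
find_seed_groups <- function(tree, meta, D, max_extra = 2,
                             expand = c("maximal", "minimal")) {
  expand <- match.arg(expand)
  key <- effective_name_key(meta)
  Dm <- as.matrix(D)
  clades <- tight_clades(tree)
  pairs <- find_same_name_sister_pairs(tree, meta)
  cherries <- lapply(seq_len(nrow(pairs)), function(i) {
    list(members = c(pairs$sample1[i], pairs$sample2[i]),
         anchor = pairs$name_key[i])
  })

  tip_keys <- key[tree$tip.label]
  anchors <- unique(tip_keys[!is.na(tip_keys) & duplicated(tip_keys)])
  groups <- list()
  for (a in anchors) {
    qual <- Filter(function(cl) {
      n_match <- sum(!is.na(key[cl]) & key[cl] == a)
      n_match >= 2L && (length(cl) - n_match) <= max_extra
    }, clades)
    if (!length(qual)) next
    # qualifying clades for one name are nested or disjoint
    keep <- if (expand == "maximal") {
      qual[!vapply(qual, function(cl) {
        any(vapply(qual, function(other) {
          length(other) > length(cl) && all(cl %in% other)
        }, logical(1)))
      }, logical(1))]
    } else {
      qual[!vapply(qual, function(cl) {
        any(vapply(qual, function(other) {
          length(other) < length(cl) && all(other %in% cl)
        }, logical(1)))
      }, logical(1))]
    }
    groups <- c(groups, lapply(keep, function(cl) {
      list(members = cl, anchor = a)
    }))
  }
  groups <- c(groups, cherries)
  if (!length(groups)) {
    stop("no seed groups found: no clade holds >= 2 same-named samples; ",
         "supply a manual cutoff instead")
  }
  # deduplicate identical member sets
  sig <- vapply(groups, function(g) paste(sort(g$members), collapse = "|"),
                character(1))
  groups <- groups[!duplicated(sig)]
  groups <- lapply(groups, function(g) {
    anch <- g$members[!is.na(key[g$members]) & key[g$members] == g$anchor]
    g$n_matching <- length(anch)
    g$max_distance <- max(Dm[anch, anch, drop = FALSE])
    g$max_distance_all <- max(Dm[g$members, g$members, drop = FALSE])
    g
  })
  ord <- order(vapply(groups, function(g) g$members[1], character(1)))
  structure(groups[ord], class = "seed_groups")
}

#' @exportS3Method base::print
print.seed_groups <- function(x, ...) {
  cat(length(x), "seed group(s):\n")
  for (g in x) {
    cat(sprintf("  [%s] n=%d max_dist=%.4f: %s\n", g$anchor,
                length(g$members), g$max_distance,
                paste(g$members, collapse = ", ")))
  }
  invisible(x)
}

#' Derive the clone-distance cutoff from seed groups
#'
#' The cutoff is the maximum over seed groups of the maximum pairwise
#' distance inside each group. Accepts either a `seed_groups` object or a
#' numeric vector of per-group distance maxima.
#'
#' @param x `seed_groups` object or numeric vector of group maxima.
#' @return the cutoff distance (scalar).
#' @export
derive_cutoff <- function(x) {
  vals <- if (inherits(x, "seed_groups")) {
    vapply(x, function(g) g$max_distance, numeric(1))
  } else {
    as.numeric(x)
  }
  if (!length(vals)) stop("cannot derive a cutoff from zero seed groups")
  max(vals)
}

#' Clone groups by single-linkage at a distance cutoff
#'
#' Groups are the connected components of the graph with an edge wherever
#' `d(i, j) <= cutoff` (union-find). Components of size >= 2 are clone
#' groups; the rest are singletons.
#'
#' @param D `p_distance` object or distance matrix.
#' @param cutoff non-negative distance threshold.
#' @return object of class `clone_grouping` (see [clone_grouping()]).
#' @export
clone_groups <- function(D, cutoff) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  Dm <- as.matrix(D)
  n <- nrow(Dm)
  labels <- rownames(Dm)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (Dm[i, j] <= cutoff) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(labels, roots)
  comp <- comp[order(vapply(split(seq_len(n), roots), min, integer(1)))]
  sizes <- vapply(comp, length, integer(1))
  clone_grouping(groups = unname(comp[sizes >= 2L]),
                 singletons = unlist(unname(comp[sizes == 1L])),
                 cutoff = cutoff)
}

#' Construct a clone grouping (partition into clone groups and singletons)
#'
#' @param groups list of character vectors (each of size >= 2).
#' @param singletons character vector of singleton sample ids.
#' @param cutoff the distance cutoff used (or `NA` for transcribed
#'   groupings).
#' @return object of class `clone_grouping`.
#' @export
clone_grouping <- function(groups, singletons = character(0), cutoff = NA_real_) {
  groups <- lapply(groups, as.character)
  singletons <- as.character(singletons)
  if (length(groups) && any(vapply(groups, length, 1L) < 2L)) {
    stop("clone groups must have >= 2 members")
  }
  all_ids <- c(unlist(groups), singletons)
  if (anyDuplicated(all_ids)) {
    stop("groups and singletons must partition the samples (duplicate ids)")
  }
  structure(list(groups = groups, singletons = singletons, cutoff = cutoff),
            class = "clone_grouping")
}

#' @export
summary.clone_grouping <- function(object, ...) {
  sizes <- vapply(object$groups, length, integer(1))
  out <- list(
    n_samples = sum(sizes) + length(object$singletons),
    n_groups = length(object$groups),
    n_clonal = sum(sizes),
    n_singletons = length(object$singletons),
    n_distinct = length(object$groups) + length(object$singletons),
    group_sizes = sizes,
    cutoff = object$cutoff
  )
  class(out) <- "summary.clone_grouping"
  out
}

#' @exportS3Method base::print
print.summary.clone_grouping <- function(x, ...) {
  cat(sprintf(
    "%d samples: %d clone group(s) holding %d clonal individuals, %d singleton(s)\n",
    x$n_samples, x$n_groups, x$n_clonal, x$n_singletons))
  cat(sprintf("distinct genotypes: %d; group sizes: %s; cutoff: %s\n",
              x$n_distinct, paste(sort(x$group_sizes, decreasing = TRUE),
                                  collapse = ","),
              format(x$cutoff, digits = 4)))
  invisible(x)
}

#' @exportS3Method base::print
print.clone_grouping <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Classify synonyms, homonyms and unknown-name suggestions
#'
#' Applies the nomenclature rules to a clone grouping: a clone group whose
#' members carry two or more distinct cultivar names is a synonym set; a
#' cultivar name whose samples fall in two or more different groups or
#' singleton positions is a homonym; an unnamed (unknown) sample in a group
#' with exactly one distinct cultivar name is suggested to be that cultivar,
#' with two or more names `ambiguous`, and alone `none`.
#'
#' @param grouping a `clone_grouping`.
#' @param meta sample table covering all grouped samples.
#' @return object of class `synonymy_report`: list with data.frames
#'   `synonym_sets` (group, names), `homonyms` (name, n_units) and
#'   `unknown_suggestions` (sample_id, suggestion).
#' @export
classify_nomenclature <- function(grouping, meta) {
  ids <- c(unlist(grouping$groups), grouping$singletons)
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing)) {
    stop("grouped samples absent from metadata: ",
         paste(missing, collapse = ", "))
  }
  meta <- meta[match(ids, meta$sample_id), ]
  unit <- c(
    rep(paste0("group", seq_along(grouping$groups)),
        vapply(grouping$groups, length, 1L)),
    if (length(grouping$singletons)) {
      paste0("singleton:", grouping$singletons)
    }
  )
  names(unit) <- ids

  lookup <- function(id, col) meta[[col]][match(id, meta$sample_id)]

  synonym_sets <- data.frame(group = character(0), names = character(0),
                             stringsAsFactors = FALSE)
  for (gi in seq_along(grouping$groups)) {
    members <- grouping$groups[[gi]]
    keys <- unique(stats::na.omit(lookup(members, "name_key")))
    if (length(keys) >= 2L) {
      nm <- sort(unique(lookup(members, "cultivar_name")[
        !lookup(members, "is_unknown")]))
      synonym_sets <- rbind(synonym_sets, data.frame(
        group = paste0("group", gi),
        names = paste(nm, collapse = " / "),
        stringsAsFactors = FALSE))
    }
  }

  homonyms <- data.frame(name = character(0), n_units = integer(0),
                         stringsAsFactors = FALSE)
  for (k in unique(stats::na.omit(meta$name_key))) {
    members <- meta$sample_id[!is.na(meta$name_key) & meta$name_key == k]
    if (length(members) < 2L) next
    units <- unique(unit[members])
    if (length(units) >= 2L) {
      homonyms <- rbind(homonyms, data.frame(
        name = meta$cultivar_name[match(k, meta$name_key)],
        n_units = length(units), stringsAsFactors = FALSE))
    }
  }

  unknown_ids <- meta$sample_id[meta$is_unknown]
  unknown_suggestions <- data.frame(sample_id = character(0),
                                    suggestion = character(0),
                                    stringsAsFactors = FALSE)
  for (u in unknown_ids) {
    g <- NULL
    for (gi in seq_along(grouping$groups)) {
      if (u %in% grouping$groups[[gi]]) {
        g <- grouping$groups[[gi]]
        break
      }
    }
    sug <- if (is.null(g)) {
      "none"
    } else {
      keys <- unique(stats::na.omit(lookup(g, "name_key")))
      if (length(keys) == 1L) {
        lookup(g[which(!is.na(lookup(g, "name_key")) &
                         lookup(g, "name_key") == keys)[1]], "cultivar_name")
      } else if (length(keys) >= 2L) {
        "ambiguous"
      } else {
        "none"
      }
    }
    unknown_suggestions <- rbind(unknown_suggestions, data.frame(
      sample_id = u, suggestion = sug, stringsAsFactors = FALSE))
  }

  structure(list(synonym_sets = synonym_sets, homonyms = homonyms,
                 unknown_suggestions = unknown_suggestions),
            class = "synonymy_report")
}

#' @exportS3Method base::print
print.synonymy_report <- function(x, ...) {
  cat("synonym sets:", nrow(x$synonym_sets),
      "| homonymous names:", nrow(x$homonyms),
      "| unknowns with a suggestion:",
      sum(!x$unknown_suggestions$suggestion %in% c("none", "ambiguous")), "\n")
  invisible(x)
}
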