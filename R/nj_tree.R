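#' Neighbour-joining tree from a p-distance matrix
#'
#' Saitou-Nei agglomeration (Studier-Keppler Q-criterion, as implemented in
#' \pkg{ape}). On additive input the returned metric reproduces the input
#' distances exactly. Negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to zero with a message.
#'
#' @param D a `p_distance` object or symmetric distance matrix with at least
#'   3 labelled samples.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  m <- as.matrix(D)
  if (nrow(m) < 3L) stop("neighbour joining needs at least 3 samples")
  if (!all(is.finite(m))) stop("distance matrix contains non-finite values")
  tr <- ape::nj(m)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative branch length(s) clamped to zero")
    tr$edge.length[neg] <- 0
  }
  tr
}

# Canonical keys for the non-trivial bipartitions (internal edges) of an
# unrooted tree. Membership is encoded over the sorted tip set and
# complemented so the first tip is always on the FALSE side.
split_keys <- function(tree, include_nodes = FALSE) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  nodes <- integer(0)
  keys <- character(0)
  for (i in seq_along(pp)) {
    memb <- tips %in% labs[pp[[i]]]
    if (sum(memb) < 2L || sum(!memb) < 2L) next # trivial or root split
    if (memb[1L]) memb <- !memb
    keys <- c(keys, paste(as.integer(memb), collapse = ""))
    nodes <- c(nodes, ntip + i)
  }
  if (include_nodes) list(keys = keys, nodes = nodes, tree = tree) else keys
}

#' Map bootstrap bipartition support onto a tree
#'
#' Each internal edge of the main tree is annotated with the percentage of
#' replicate trees containing the same bipartition (rounded to integer).
#' Supports are stored as internal node labels of the returned (unrooted)
#' tree; the root and tip-adjacent edges carry no support.
#'
#' @param main `phylo` tree to annotate.
#' @param replicates list of `phylo` trees over the identical tip set.
#' @return the main tree with `node.label` set to supports in \[0, 100\].
#' @export
bootstrap_support <- function(main, replicates) {
  tips <- sort(main$tip.label)
  for (r in replicates) {
    if (!identical(sort(r$tip.label), tips)) {
      stop("replicate tree tip set differs from the main tree")
    }
  }
  B <- length(replicates)
  if (B < 1L) stop("need at least one replicate tree")
  counts <- table(unlist(lapply(replicates, split_keys)))
  st <- split_keys(main, include_nodes = TRUE)
  tree <- st$tree
  lab <- rep("", tree$Nnode)
  for (i in seq_along(st$keys)) {
    hit <- counts[st$keys[i]]
    pct <- if (is.na(hit)) 0 else round(100 * as.integer(hit) / B)
    lab[st$nodes[i] - length(tree$tip.label)] <- as.character(pct)
  }
  tree$node.label <- lab
  tree
}

#' Serialise a tree to newick
#'
#' Branch lengths are written with 6 significant digits; internal node labels
#' (e.g. bootstrap supports) are preserved, giving the dialect tree viewers
#' accept.
#'
#' @param tree a `phylo` object.
#' @param path optional file path; when `NULL` the string is returned only.
#' @param digits significant digits for branch lengths.
#' @return the newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Parse a newick string (or file) into a tree
#'
#' @param x newick string, or path to a file containing one.
#' @return a `phylo` object.
#' @export
parse_newick <- function(x) {
  if (length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x)) {
    x <- paste(readLines(x), collapse = "")
  }
  s <- paste(x, collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(s))) {
    ch <- substr(s, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parenthesis at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parenthesis at position ", nchar(s))
  tr <- tryCatch(ape::read.tree(text = s), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick string")
  tr
}

#' Enumerate the clades of a midpoint-rooted tree
#'
#' The tree is midpoint rooted (a display convention only; NJ trees are
#' unrooted) and every internal node's tip set is returned. Used by the
#' synonymy stage to search for tight seed groups.
#'
#' @param tree a `phylo` object with at least 3 tips.
#' @return list of character vectors (sorted tip labels), ordered by clade
#'   size then first tip; the trivial all-tips clade is excluded.
#' @export
tight_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("need at least 3 tips")
  rt <- phangorn::midpoint(tree)
  pp <- ape::prop.part(rt)
  labs <- attr(pp, "labels")
  clades <- lapply(pp, function(idx) sort(labs[idx]))
  clades <- clades[vapply(clades, length, 1L) < ntip]
  ord <- order(vapply(clades, length, 1L),
               vapply(clades, `[`, character(1), 1L))
  clades[ord]
}
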