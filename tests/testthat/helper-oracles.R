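# Independent oracles and fixture builders shared across the suite.
# Each oracle is deliberately a different algorithm from the implementation
# it checks (loops instead of cross products, enumeration instead of
# recursion, closure instead of union-find).

# Collection-scale synthetic cohort: two pools, 13 clone groups of sizes 2..9
# (55 clonal of 91), 23 singleton founders, 5 F1 and 8 BC1 hybrids.
make_reference_cohort <- function(seed, L = 5000, fst = 0.3) {
  pools <- simulate_pools(2, L, fst = fst, seed = seed * 1000L)
  sizes <- c(2, 2, 9, 3, 5, 7, 2, 6, 3, 2, 2, 4, 8)
  group_founders <- c(1:8, 25:29)
  spec <- cohort_spec(
    n_per_pool = c(24, 12),
    hybrid_spec = list(c(0.5, 5), c(0.25, 8)),
    clone_groups = Map(c, group_founders, sizes),
    L = L, seed = seed
  )
  simulate_cohort(spec, pools)
}

canon_partition <- function(groups) {
  sort(vapply(groups, function(g) paste(sort(g), collapse = "|"), character(1)))
}

# per-pair loop using the scalar pair function (vs the cross-product path)
oracle_distance_loop <- function(G) {
  n <- nrow(G)
  D <- matrix(0, n, n, dimnames = list(rownames(G), rownames(G)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      D[i, j] <- D[j, i] <- p_distance_pair(G[i, ], G[j, ])$distance
    }
  }
  D
}

# transitive closure of the <=cutoff adjacency by boolean matrix powering
oracle_reachability_groups <- function(Dm, cutoff) {
  n <- nrow(Dm)
  adj <- Dm <= cutoff
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach > 0)) break
    reach <- nxt
  }
  comp_id <- apply(reach, 1, function(r) min(which(r)))
  split(rownames(Dm), comp_id)
}

# bipartitions of an unrooted tree by cutting each internal edge and
# flood-filling tip sets over the remaining edges (no ape clade machinery)
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  internal <- which(edges[, 2] > ntip)
  all_tips <- sort(tree$tip.label)
  keys <- character(0)
  for (e in internal) {
    keep <- edges[-e, , drop = FALSE]
    # tips connected to the child endpoint of the cut edge
    frontier <- edges[e, 2]
    seen <- frontier
    repeat {
      nbr <- c(keep[keep[, 1] %in% frontier, 2],
               keep[keep[, 2] %in% frontier, 1])
      nbr <- setdiff(nbr, seen)
      if (!length(nbr)) break
      seen <- c(seen, nbr)
      frontier <- nbr
    }
    side <- sort(tree$tip.label[seen[seen <= ntip]])
    if (length(side) < 2 || length(side) > ntip - 2) next
    memb <- all_tips %in% side
    if (memb[1]) memb <- !memb
    keys <- c(keys, paste(as.integer(memb), collapse = ""))
  }
  sort(keys)
}

random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 1)
  tr
}

random_genotypes <- function(n, L, seed, miss = 0.1) {
  set.seed(seed)
  G <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  G[stats::runif(n * L) < miss] <- NA
  rownames(G) <- sprintf("S%02d", seq_len(n))
  colnames(G) <- sprintf("site%03d", seq_len(L))
  storage.mode(G) <- "integer"
  G
}

# Per-site outcome enumeration for the corruption model: distribution of a
# single corrupted copy given the founder dosage, then the expected
# contribution E|X - Y|/2 for two independent copies (conditional on both
# being observed; missingness is independent of the value).
oracle_corruption_expected_distance <- function(founder_dosages, het_miscall,
                                                allele_error) {
  copy_dist <- function(g) {
    # after het miscall
    p <- c(`0` = 0, `1` = 0, `2` = 0)
    if (g == 1) {
      p["1"] <- 1 - het_miscall
      p["0"] <- het_miscall / 2
      p["2"] <- het_miscall / 2
    } else {
      p[as.character(g)] <- 1
    }
    # after +/-1 allele error with clipping
    q <- c(`0` = 0, `1` = 0, `2` = 0)
    for (v in 0:2) {
      pv <- p[as.character(v)]
      if (pv == 0) next
      q[as.character(v)] <- q[as.character(v)] + pv * (1 - allele_error)
      down <- max(v - 1, 0)
      up <- min(v + 1, 2)
      q[as.character(down)] <- q[as.character(down)] + pv * allele_error / 2
      q[as.character(up)] <- q[as.character(up)] + pv * allele_error / 2
    }
    q
  }
  per_site <- vapply(founder_dosages, function(g) {
    q <- copy_dist(g)
    e <- 0
    for (x in 0:2) for (y in 0:2) {
      e <- e + q[as.character(x)] * q[as.character(y)] * abs(x - y) / 2
    }
    e
  }, numeric(1))
  mean(per_site)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
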