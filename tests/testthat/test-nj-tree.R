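test_that("NJ resolves the worked additive example exactly", {
  # unrooted tree with tip edges A:1 B:2 C:3 D:4 and internal edge 1
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  keys <- germclone:::split_keys(tr)
  expect_length(keys, 1L)              # single internal edge: AB | CD
  expect_identical(keys, "0011")       # tips sorted A,B,C,D; A side complemented
  ntip <- 4L
  internal <- tr$edge[, 2] > ntip
  expect_equal(unname(tr$edge.length[internal]), 1, tolerance = 1e-9)
  expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("three taxa resolve by the closed-form star formulas", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  ce <- cophenetic(tr)[rownames(D), colnames(D)]
  expect_equal(ce, D, tolerance = 1e-12)
  lens <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(sort(lens), sort(c((0.3 + 0.5 - 0.6) / 2,
                                  (0.3 + 0.6 - 0.5) / 2,
                                  (0.5 + 0.6 - 0.3) / 2)), tolerance = 1e-12)
})

test_that("NJ recovers random additive trees and tolerates label permutation", {
  for (s in 1:10) {
    tr0 <- random_additive_tree(sample(5:10, 1), seed = 100 + s)
    D <- cophenetic(tr0)
    tr <- nj_tree(D)
    expect_equal(ape::dist.topo(tr0, tr), 0, ignore_attr = TRUE)
    expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
    perm <- sample(nrow(D))
    tr_p <- nj_tree(D[perm, perm])
    expect_equal(ape::dist.topo(tr, tr_p), 0, ignore_attr = TRUE)
  }
})

test_that("degenerate distance inputs are rejected", {
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
  D <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D), "non-finite")
})

test_that("bootstrap support counts bipartitions as percentages", {
  tr <- random_additive_tree(6, seed = 5)
  full <- bootstrap_support(tr, rep(list(tr), 10))
  sup <- suppressWarnings(as.numeric(full$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  # replicates that share no internal edge with a caterpillar tree
  main <- parse_newick("((((a:1,b:1):1,c:1):1,d:1):1,(e:1,f:1):1);")
  other <- parse_newick("((((a:1,f:1):1,c:1):1,e:1):1,(d:1,b:1):1);")
  res <- bootstrap_support(main, rep(list(other), 4))
  sup <- suppressWarnings(as.numeric(res$node.label))
  expect_true(all(sup[!is.na(sup)] == 0))

  expect_error(bootstrap_support(main, list(parse_newick("(a:1,b:1,c:1);"))),
               "tip set")
})

test_that("support matches a brute-force edge-cut enumeration", {
  set.seed(9)
  main <- random_additive_tree(6, seed = 31)
  reps <- lapply(1:20, function(i) random_additive_tree(6, seed = 200 + i))
  annotated <- bootstrap_support(main, reps)
  rep_keys <- unlist(lapply(reps, oracle_bipartitions))
  st <- germclone:::split_keys(annotated, include_nodes = TRUE)
  for (i in seq_along(st$keys)) {
    expected <- round(100 * sum(rep_keys == st$keys[i]) / length(reps))
    lab <- annotated$node.label[st$nodes[i] - 6L]
    expect_identical(as.integer(lab), as.integer(expected))
  }
})

test_that("newick serialisation round-trips topology, lengths and support", {
  for (s in 1:3) {
    tr <- random_additive_tree(20, seed = 300 + s)
    back <- parse_newick(write_newick(tr))
    expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
    expect_equal(cophenetic(back)[tr$tip.label, tr$tip.label],
                 cophenetic(tr), tolerance = 1e-4)
  }
  two <- parse_newick("(A:1,B:1);")
  expect_identical(sort(two$tip.label), c("A", "B"))
  expect_error(parse_newick("((A:1,B:1);"), "unbalanced")
  expect_error(parse_newick("(A:1,B:1)):1;"), "unbalanced")

  tr <- bootstrap_support(random_additive_tree(6, seed = 77),
                          lapply(1:4, function(i)
                            random_additive_tree(6, seed = 400 + i)))
  back <- parse_newick(write_newick(tr))
  expect_identical(sort(back$node.label), sort(tr$node.label))
})

test_that("clade enumeration matches the brute-force cut oracle", {
  tr <- random_additive_tree(4, seed = 55)
  clades <- tight_clades(tr)
  sizes <- vapply(clades, length, integer(1))
  expect_true(all(sizes < 4))
  # a 4-taxon unrooted binary tree has exactly one non-trivial bipartition
  expect_length(germclone:::split_keys(tr), 1L)
  expect_identical(sort(germclone:::split_keys(tr)), oracle_bipartitions(tr))

  tr8 <- random_additive_tree(8, seed = 56)
  expect_identical(sort(germclone:::split_keys(tr8)), oracle_bipartitions(tr8))
  # every non-trivial split side appears among the midpoint-rooted clades
  clades8 <- tight_clades(tr8)
  tips <- sort(tr8$tip.label)
  keys_from_clades <- vapply(clades8, function(cl) {
    memb <- tips %in% cl
    if (memb[1]) memb <- !memb
    paste(as.integer(memb), collapse = "")
  }, character(1))
  expect_true(all(germclone:::split_keys(tr8) %in% keys_from_clades))
})
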