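make_meta <- function(ids, names, syn = NULL) {
  df <- data.frame(sample_id = ids, cultivar_name = names,
                   stringsAsFactors = FALSE)
  if (!is.null(syn)) df$synonym_group <- syn
  as_sample_table(df)
}

test_that("same-named and known-synonym cherries are found, others not", {
  tree <- parse_newick(
    "(((KM_a:0.01,KM_b:0.01):0.2,(OH:0.01,HKP7:0.01):0.2):0.1,(KM_c:0.2,WC:0.2):0.1);")
  meta <- make_meta(
    c("KM_a", "KM_b", "OH", "HKP7", "KM_c", "WC"),
    c("Kwai Mi", "Kwai Mi", "O-Hia", "Hak Ip", "Kwai Mi", "Wai Chee"),
    c(NA, NA, "syn1", "syn1", NA, NA))
  pairs <- find_same_name_sister_pairs(tree, meta)
  expect_identical(nrow(pairs), 2L)
  expect_true(any(pairs$sample1 == "KM_a" & pairs$sample2 == "KM_b"))
  expect_true(any(pairs$sample1 == "HKP7" & pairs$sample2 == "OH"))
  # KM_c shares a name with KM_a/KM_b but is not their sister
  expect_false("KM_c" %in% c(pairs$sample1, pairs$sample2))
  expect_error(find_same_name_sister_pairs(tree, meta[-1, ]), "absent")
})

test_that("seed groups admit interlopers up to max_extra, cutoff uses anchors", {
  # clade ((A1,A2),X) : two same-named plus one interloper
  tree <- parse_newick(
    "(((A1:0.01,A2:0.01):0.01,X:0.02):0.3,((B1:0.01,B2:0.012):0.01,(Y:0.02,(Z1:0.02,Z2:0.02):0.01):0.01):0.3);")
  ids <- c("A1", "A2", "X", "B1", "B2", "Y", "Z1", "Z2")
  meta <- make_meta(ids, c("Alpha", "Alpha", "Xi", "Beta", "Beta", "Ypsilon",
                           "Zeta", "Zeta"))
  D <- cophenetic(tree)[ids, ids]
  sg <- find_seed_groups(tree, meta, D, max_extra = 2)
  anchors <- vapply(sg, function(g) g$anchor, character(1))
  expect_true("alpha" %in% anchors)
  alpha <- sg[[which(anchors == "alpha")[1]]]
  expect_setequal(alpha$members, c("A1", "A2", "X"))
  # cutoff input comes from the same-named members only
  expect_equal(alpha$max_distance, D["A1", "A2"], tolerance = 1e-9)
  expect_true(alpha$max_distance_all >= D["A1", "X"] - 1e-12)

  # with max_extra = 0 the Beta clade (B1,B2) still qualifies, Alpha shrinks
  sg0 <- find_seed_groups(tree, meta, D, max_extra = 0)
  for (g in sg0) expect_identical(g$n_matching, length(g$members))

  # Beta + Y + Z1 + Z2 would need 3 extras: no such seed group
  beta_groups <- Filter(function(g) g$anchor == "beta", sg)
  for (g in beta_groups) expect_true(length(setdiff(g$members,
                                                    c("B1", "B2"))) <= 2)

  meta_distinct <- make_meta(ids, paste0("cv", seq_along(ids)))
  expect_error(find_seed_groups(tree, meta_distinct, D), "manual cutoff")
})

test_that("minimal expansion keeps the smallest qualifying clusters", {
  tree <- parse_newick(
    "(((A1:0.01,A2:0.01):0.01,A3:0.02):0.3,(B:0.1,C:0.1):0.3);")
  ids <- c("A1", "A2", "A3", "B", "C")
  meta <- make_meta(ids, c("Alpha", "Alpha", "Alpha", "Bee", "Cee"))
  D <- cophenetic(tree)[ids, ids]
  mini <- find_seed_groups(tree, meta, D, expand = "minimal")
  expect_true(any(vapply(mini, function(g)
    setequal(g$members, c("A1", "A2")), logical(1))))
  maxi <- find_seed_groups(tree, meta, D, expand = "maximal")
  expect_true(any(vapply(maxi, function(g)
    setequal(g$members, c("A1", "A2", "A3")), logical(1))))
})

test_that("the cutoff is the maximum over seed-group maxima", {
  expect_equal(derive_cutoff(c(0.0651, 0.0442, 0.0413, 0.0564, 0.0482,
                               0.0482)), 0.0651)
  expect_equal(derive_cutoff(0.042), 0.042)
  expect_equal(derive_cutoff(c(0, 0, 0)), 0)
  expect_error(derive_cutoff(numeric(0)), "zero seed groups")
})

test_that("single linkage chains through the worked example", {
  D <- matrix(c(0, 0.03, 0.09,
                0.03, 0, 0.05,
                0.09, 0.05, 0), 3, 3,
              dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  cg <- clone_groups(D, 0.0651)
  expect_length(cg$groups, 1L)
  expect_setequal(cg$groups[[1]], c("s1", "s2", "s3"))
  all_single <- clone_groups(D, 0.01)
  expect_length(all_single$groups, 0L)
  expect_setequal(all_single$singletons, c("s1", "s2", "s3"))
})

test_that("single linkage equals brute-force reachability, order-invariantly", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(8:20, 1)
    Dm <- matrix(stats::runif(n * n, 0, 0.3), n, n)
    Dm <- (Dm + t(Dm)) / 2
    diag(Dm) <- 0
    dimnames(Dm) <- list(sprintf("x%02d", 1:n), sprintf("x%02d", 1:n))
    cutoff <- sample(Dm[upper.tri(Dm)], 1)  # exercise boundary ties too
    cg <- clone_groups(Dm, cutoff)
    comp <- oracle_reachability_groups(Dm, cutoff)
    got <- canon_partition(c(cg$groups, as.list(cg$singletons)))
    want <- canon_partition(unname(comp))
    expect_identical(got, want)

    perm <- sample(n)
    cg_p <- clone_groups(Dm[perm, perm], cutoff)
    expect_identical(canon_partition(cg_p$groups), canon_partition(cg$groups))
  }
})

test_that("raising the cutoff never splits a group", {
  set.seed(11)
  n <- 15
  Dm <- matrix(stats::runif(n * n, 0, 0.3), n, n)
  Dm <- (Dm + t(Dm)) / 2
  diag(Dm) <- 0
  dimnames(Dm) <- list(letters[1:n], letters[1:n])
  cuts <- sort(stats::runif(6, 0, 0.3))
  prev <- NULL
  for (ct in cuts) {
    cg <- clone_groups(Dm, ct)
    unit_of <- integer(n)
    names(unit_of) <- letters[1:n]
    for (i in seq_along(cg$groups)) unit_of[cg$groups[[i]]] <- i
    unit_of[cg$singletons] <- seq_along(cg$singletons) + length(cg$groups) + 100L
    if (!is.null(prev)) {
      # refinement: samples together at the smaller cutoff stay together
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (prev[i] == prev[j]) expect_true(unit_of[i] == unit_of[j])
      }
    }
    prev <- unit_of
  }
})

test_that("nomenclature report flags synonyms, homonyms and unknowns", {
  grouping <- clone_grouping(
    groups = list(c("UNK9", "ITO"),            # unknown resolves to Ito
                  c("NMT1", "UNK1", "UNK2"),   # unknowns resolve to one name
                  c("SAL1", "SAL2", "WC"),     # two names: synonym set
                  c("KM1", "HL")),             # KM split across units: homonym
    singletons = c("KM2", "UNK5", "HKP2"))
  meta <- make_meta(
    c("UNK9", "ITO", "NMT1", "UNK1", "UNK2", "SAL1", "SAL2", "WC", "KM1",
      "HL", "KM2", "UNK5", "HKP2"),
    c("UNKNOWN", "Ito", "No Mai Tsze", "UNKNOWN", "UNKNOWN", "Salathiel",
      "Salathiel", "Wai Chee", "Kwai Mi", "Hwai Lai", "Kwai Mi", "UNKNOWN",
      "Hak Ip"))
  rep <- classify_nomenclature(grouping, meta)

  sug <- rep$unknown_suggestions
  expect_identical(sug$suggestion[sug$sample_id == "UNK9"], "Ito")
  expect_identical(sug$suggestion[sug$sample_id == "UNK1"], "No Mai Tsze")
  expect_identical(sug$suggestion[sug$sample_id == "UNK5"], "none")

  expect_true(any(grepl("Salathiel", rep$synonym_sets$names) &
                    grepl("Wai Chee", rep$synonym_sets$names)))
  expect_true("Kwai Mi" %in% rep$homonyms$name)
  expect_false("Salathiel" %in% rep$homonyms$name)
  # a group with a single cultivar name is not a synonym set
  expect_false(any(grepl("Ito", rep$synonym_sets$names)))
})

test_that("ambiguous unknowns are labelled, and partitions are validated", {
  grouping <- clone_grouping(groups = list(c("UNKa", "X1", "Y1")),
                             singletons = "Z")
  meta <- make_meta(c("UNKa", "X1", "Y1", "Z"),
                    c("UNKNOWN", "Ex", "Why", "Zed"))
  rep <- classify_nomenclature(grouping, meta)
  expect_identical(rep$unknown_suggestions$suggestion, "ambiguous")

  expect_error(clone_grouping(groups = list("solo")), ">= 2")
  expect_error(clone_grouping(groups = list(c("a", "b")), singletons = "a"),
               "partition")
})
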