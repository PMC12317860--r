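test_that("pool simulation is seeded, bounded and degenerate at fst = 0", {
  p0 <- simulate_pools(2, 100, fst = 0, seed = 1)
  expect_identical(p0$freqs[1, ], p0$freqs[2, ])
  expect_true(all(p0$freqs > 0 & p0$freqs < 1))

  pa <- simulate_pools(1, 10, fst = 0.3, seed = 3)
  pb <- simulate_pools(1, 10, fst = 0.3, seed = 3)
  expect_identical(pa, pb)

  expect_error(simulate_pools(2, 10, fst = 1), "fst")
  expect_error(simulate_pools(2, 10, fst = -0.1), "fst")
})

test_that("between-pool divergence increases with fst", {
  wins <- vapply(1:10, function(s) {
    hi <- simulate_pools(2, 2000, fst = 0.5, seed = s)
    lo <- simulate_pools(2, 2000, fst = 0.05, seed = s)
    mean(abs(hi$freqs[1, ] - hi$freqs[2, ])) >
      mean(abs(lo$freqs[1, ] - lo$freqs[2, ]))
  }, logical(1))
  expect_true(all(wins))
})

test_that("cohort simulation is deterministic and truth-consistent", {
  pools <- simulate_pools(2, 300, fst = 0.3, seed = 5)
  spec <- cohort_spec(n_per_pool = c(3, 3), hybrid_spec = list(c(0.5, 2)),
                      clone_groups = list(c(1, 3)), L = 300, seed = 9)
  a <- simulate_cohort(spec, pools)
  b <- simulate_cohort(spec, pools)
  expect_identical(a, b)

  n <- nrow(a$genotypes)
  part_ids <- c(unlist(a$truth$clone_partition$groups),
                a$truth$clone_partition$singletons)
  expect_setequal(part_ids, rownames(a$genotypes))
  expect_false(anyDuplicated(part_ids) > 0)
  expect_equal(unname(rowSums(a$truth$true_Q)), rep(1, n))
  expect_setequal(a$meta$sample_id, rownames(a$genotypes))
  expect_identical(colnames(a$genotypes), a$sites$site_id)
})

test_that("clone copies are exact before noise and cohort errors are caught", {
  pools <- simulate_pools(2, 400, fst = 0.3, seed = 2)
  spec <- cohort_spec(n_per_pool = c(2, 2), clone_groups = list(c(1, 3)),
                      L = 400, het_miscall = 0, allele_error = 0, missing = 0,
                      seed = 4)
  sim <- simulate_cohort(spec, pools)
  grp <- sim$truth$clone_partition$groups[[1]]
  D <- as.matrix(p_distance_matrix(sim$genotypes))
  expect_equal(max(D[grp, grp]), 0)

  bad <- cohort_spec(n_per_pool = c(2, 2), clone_groups = list(c(99, 2)),
                     L = 400, seed = 1)
  expect_error(simulate_cohort(bad, pools), "out of range")
  expect_error(cohort_spec(n_per_pool = c(2, 2), clone_groups = list(c(1, 1)),
                           L = 10), "copies")

  none <- cohort_spec(n_per_pool = c(0, 0), L = 400, seed = 1)
  empty <- simulate_cohort(none, pools)
  expect_identical(nrow(empty$genotypes), 0L)
  expect_length(empty$truth$clone_partition$groups, 0)
})

test_that("corruption respects its rate definitions", {
  G <- matrix(1L, 5, 40, dimnames = list(paste0("S", 1:5), NULL))
  expect_identical(corrupt_genotypes(G, 0, 0, 0, seed = 1), G)
  allhom <- corrupt_genotypes(G, het_miscall_rate = 1, seed = 2)
  expect_false(any(allhom == 1L, na.rm = TRUE))
  gone <- corrupt_genotypes(G, missing_rate = 1, seed = 3)
  expect_true(all(is.na(gone)))
  expect_error(corrupt_genotypes(G, het_miscall_rate = 1.5), "rates")
})

test_that("within-clone distance matches the per-site enumeration oracle", {
  set.seed(77)
  L <- 10000
  founder <- sample(0:2, L, replace = TRUE, prob = c(0.35, 0.3, 0.35))
  G <- rbind(founder, founder, founder)
  rownames(G) <- c("a", "b", "c")
  storage.mode(G) <- "integer"
  noisy <- corrupt_genotypes(G, het_miscall_rate = 0.05,
                             allele_error_rate = 0.005, seed = 101)
  D <- as.matrix(p_distance_matrix(noisy))
  obs <- D[upper.tri(D)]
  expected <- oracle_corruption_expected_distance(founder, 0.05, 0.005)
  # per-site contribution is bounded by 1; 3 pairs x L sites
  se <- stats::sd(obs) / sqrt(length(obs)) + sqrt(expected / L)
  expect_true(abs(mean(obs) - expected) < 3 * se)
})

test_that("noise strictly increases expected within-clone distance", {
  pools <- simulate_pools(2, 2000, fst = 0.3, seed = 8)
  dist_at <- function(het, s) {
    spec <- cohort_spec(n_per_pool = c(1, 0), clone_groups = list(c(1, 3)),
                        L = 2000, het_miscall = het, allele_error = 0,
                        missing = 0, seed = s)
    sim <- simulate_cohort(spec, pools)
    mean(as.matrix(p_distance_matrix(sim$genotypes))[upper.tri(diag(3))])
  }
  deltas <- vapply(1:6, function(s) dist_at(0.1, s) - dist_at(0.02, s),
                   numeric(1))
  expect_true(mean(deltas > 0) >= 5 / 6)
})

test_that("mislabelling and unknown fractions reshape the name table", {
  pools <- simulate_pools(2, 200, fst = 0.3, seed = 3)
  spec <- cohort_spec(n_per_pool = c(4, 4),
                      clone_groups = list(c(1, 4), c(2, 3)), L = 200,
                      mislabel_fraction = 1, unknown_fraction = 0, seed = 6)
  sim <- simulate_cohort(spec, pools)
  copies <- setdiff(unlist(sim$truth$clone_partition$groups),
                    sprintf("S%03d", 1:8))
  founder_names <- sim$meta$cultivar_name[match(sprintf("S%03d", 1:8),
                                                sim$meta$sample_id)]
  copy_names <- sim$meta$cultivar_name[match(copies, sim$meta$sample_id)]
  # every copy renamed away from its founder's cultivar
  for (i in seq_along(copies)) {
    f <- sim$truth$clone_partition$groups[[
      which(vapply(sim$truth$clone_partition$groups,
                   function(g) copies[i] %in% g, logical(1)))]][1]
    expect_false(copy_names[i] == founder_names[match(f, sprintf("S%03d", 1:8))])
  }

  spec2 <- cohort_spec(n_per_pool = c(4, 4), L = 200, unknown_fraction = 0.5,
                       seed = 6)
  sim2 <- simulate_cohort(spec2, pools)
  expect_equal(sum(sim2$meta$is_unknown), 4)
})
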