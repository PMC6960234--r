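test_that("the prior series is geometric with exact endpoints", {
  pr <- prior_series(abgd_params())
  expect_length(pr, 10)
  expect_identical(pr[1], 0.001)
  expect_identical(pr[10], 0.1)
  expect_true(all(diff(pr) > 0))
  expect_equal(pr[2], 0.001 * 100^(1 / 9), tolerance = 1e-12)
  expect_equal(pr[2], 0.001668101, tolerance = 1e-6)
  expect_equal(prior_series(abgd_params(steps = 2)), c(0.001, 0.1))
  expect_error(abgd_params(p_min = 0.2, p_max = 0.1), "p_min")
  expect_error(abgd_params(x = 0.9), "x must")
})

test_that("find_gap matches the hand-traced rule on the worked list", {
  d <- c(0.01, 0.02, 0.03, 0.15, 0.16)
  g <- find_gap(d, prior = 0.05, x = 1.5)
  expect_true(g$found)
  expect_equal(g$lower_edge, 0.03)
  expect_equal(g$upper_edge, 0.15)
  expect_equal(g$threshold, 0.09)
  expect_equal(g$rank_index, 3L)
  # no candidate gap ends beyond a prior of 0.20
  expect_false(find_gap(d, prior = 0.20, x = 1.5)$found)
  # uniform distances carry no gap
  expect_false(find_gap(c(0.1, 0.1, 0.1), prior = 0.05, x = 1.5)$found)
  expect_error(find_gap(c(0.2, 0.1), prior = 0.05, x = 1.5), "sorted")
})

test_that("single linkage equals the brute-force transitive closure", {
  for (rep in 1:25) {
    set.seed(rep)
    n <- sample(3:10, 1)
    D <- random_dist(n)
    thr <- stats::runif(1)
    p <- single_linkage(D, thr)
    expect_identical(part_sig(p), part_sig(closure_oracle(D, thr)),
                     label = sprintf("rep %d", rep))
  }
  D <- random_dist(6)
  expect_equal(length(unique(single_linkage(D, 0))), 6)
  expect_equal(length(unique(single_linkage(D, max(D) + 1))), 1)
})

test_that("group ids are the smallest member specimen id", {
  D <- dist_fixture(c("S3", "S1", "S2"), c(0.01, 0.5, 0.5))
  p <- single_linkage(D, 0.1)
  expect_identical(unname(p[c("S1", "S3")]), c("S1", "S1"))
  expect_identical(unname(p[["S2"]]), "S2")
})

test_that("recursion refines a two-level structure that the initial split misses", {
  # cluster A: four specimens with a broad, even intra spread (no gap);
  # cluster B: two tight subclusters separated by a secondary gap that only
  # stands out once A's distances are out of the picture
  labs <- c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4")
  D <- matrix(0.4, 8, 8, dimnames = list(labs, labs))
  A <- c(0.004, 0.02, 0.04, 0.055, 0.07, 0.085)
  D["a1", "a2"] <- A[1]; D["a1", "a3"] <- A[2]; D["a2", "a3"] <- A[3]
  D["a1", "a4"] <- A[4]; D["a2", "a4"] <- A[5]; D["a3", "a4"] <- A[6]
  D["b1", "b2"] <- 0.004; D["b3", "b4"] <- 0.004
  for (i in c("b1", "b2")) for (j in c("b3", "b4")) D[i, j] <- 0.095
  D["b1", "b3"] <- 0.09; D["b2", "b4"] <- 0.105; D["b1", "b4"] <- 0.1
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  params <- abgd_params(p_max = 0.3, x = 1.125)

  # without recursion: only the primary gap (0.105 -> 0.4) splits A from B
  d_all <- sort(D[upper.tri(D)])
  gap <- find_gap(d_all, prior = 0.02, x = params$x)
  expect_equal(gap$lower_edge, 0.105)
  init <- single_linkage(D, gap$threshold)
  expect_equal(length(unique(init)), 2)

  # with recursion, B's subclusters separate as well
  part <- recursive_partition(D, params, prior = 0.02)
  expect_equal(length(unique(part)), 3)
  expect_identical(unname(part[c("b1", "b2")]), c("b1", "b1"))
  expect_identical(unname(part[c("b3", "b4")]), c("b3", "b3"))
  # refinement: every recursive group is a subset of an initial group
  for (g in split(names(part), unname(part))) {
    expect_equal(length(unique(init[g])), 1)
  }
})

test_that("a clear-gap dataset is recovered and the true partition selected", {
  ds <- generate_dataset(sim_config(n_species = 12, seqs_per_species = 4,
                                    seed = 77))
  coi <- ds$records[ds$records$marker == "COI", ]
  D <- build_matrix(coi, "JC69")
  sc <- scan_priors(D, abgd_params())
  expect_identical(part_sig(sc$selected), part_sig(truth_partition(ds$truth)))
  # a mid-range prior alone also recovers the truth
  p01 <- recursive_partition(D, abgd_params(), prior = 0.01)
  expect_identical(part_sig(p01), part_sig(truth_partition(ds$truth)))
  # single species: no gap, one group
  one <- generate_dataset(sim_config(n_species = 2, seqs_per_species = 5,
                                     seed = 3))
  coi1 <- one$records[one$records$marker == "COI" &
                        one$truth$species_index[
                          match(one$records$specimen_id,
                                one$truth$specimen_id)] == 1, ]
  D1 <- build_matrix(coi1, "JC69")
  expect_equal(length(unique(recursive_partition(D1, abgd_params(),
                                                 prior = 0.01))), 1)
})

test_that("initial-split group counts never increase with the prior", {
  for (rep in 1:10) {
    set.seed(100 + rep)
    n <- 9
    D <- random_dist(n) * 0.3
    counts <- vapply(prior_series(abgd_params(p_max = 0.25)), function(pr) {
      d <- sort(D[upper.tri(D)])
      gap <- find_gap(d, pr, 1.125)
      if (!gap$found) return(1L)
      length(unique(single_linkage(D, gap$threshold)))
    }, integer(1))
    expect_true(all(diff(counts) <= 0), label = sprintf("rep %d", rep))
  }
})

test_that("the prior scan reports histogram and per-prior group counts", {
  ds <- generate_dataset(sim_config(n_species = 5, seqs_per_species = 3,
                                    seed = 14))
  D <- build_matrix(ds$records[ds$records$marker == "COI", ], "JC69")
  sc <- scan_priors(D, abgd_params())
  expect_equal(nrow(sc$group_counts), 10)
  expect_equal(sum(sc$histogram$count), sum(upper.tri(D)))
  expect_equal(sc$histogram$bin_mid[2] - sc$histogram$bin_mid[1], 0.005)
  expect_s3_class(sc$selected, "otu_partition")
})
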