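part <- function(...) {
  x <- c(...)
  structure(x, class = "otu_partition")
}

test_that("identical partitions produce no conflict blocks", {
  p <- part(a = "g1", b = "g1", c = "g2", d = "g2")
  blocks <- align_partitions(p, p)
  expect_true(all(!vapply(blocks, `[[`, TRUE, "conflict")))
  expect_equal(length(blocks), 2)
})

test_that("a lump/split disagreement forms one conflict block", {
  p_coi <- part(a = "x", b = "x", c = "y", d = "y")
  p_16s <- part(a = "z", b = "z", c = "z", d = "z")
  blocks <- align_partitions(p_coi, p_16s)
  expect_equal(length(blocks), 1)
  expect_true(blocks[[1]]$conflict)
  expect_setequal(blocks[[1]]$members, c("a", "b", "c", "d"))
})

test_that("disjoint specimen sets give single-marker blocks without conflict", {
  p_coi <- part(a = "x", b = "x")
  p_16s <- part(c = "z", d = "w")
  blocks <- align_partitions(p_coi, p_16s)
  expect_equal(length(blocks), 3)
  expect_true(all(!vapply(blocks, `[[`, TRUE, "conflict")))
})

make_conflict_block <- function() {
  p_coi <- part(a = "x", b = "x", c = "y", d = "y")
  p_16s <- part(a = "z", b = "z", c = "z", d = "z")
  align_partitions(p_coi, p_16s)[[1]]
}

test_that("the finer option wins when its groups diverge enough in either marker", {
  block <- make_conflict_block()
  D_low <- dist_fixture(c("a", "b", "c", "d"),
                        c(0.01, 0.08, 0.08, 0.08, 0.08, 0.01))
  res <- resolve_conflict(block, D_coi = D_low, D_16s = NULL,
                          consensus_thresholds())
  expect_equal(res$outcome, "accepted_by_coi")
  expect_equal(length(unique(res$grouping)), 2)

  # minimum COI divergence 0.04 and 16S 0.02: both below -> fewer OTUs
  D_coi <- dist_fixture(c("a", "b", "c", "d"),
                        c(0.01, 0.04, 0.04, 0.04, 0.04, 0.01))
  D_16s <- dist_fixture(c("a", "b", "c", "d"),
                        c(0.005, 0.02, 0.02, 0.02, 0.02, 0.005))
  res <- resolve_conflict(block, D_coi, D_16s, consensus_thresholds())
  expect_equal(res$outcome, "fewer_otus")
  expect_equal(length(unique(res$grouping)), 1)

  # 16S alone can rescue the split
  D_16s_hi <- dist_fixture(c("a", "b", "c", "d"),
                           c(0.005, 0.03, 0.03, 0.03, 0.03, 0.005))
  res <- resolve_conflict(block, D_coi, D_16s_hi, consensus_thresholds())
  expect_equal(res$outcome, "accepted_by_16s")
  expect_equal(length(unique(res$grouping)), 2)
})

test_that("divergence exactly at a threshold counts (inclusive bounds)", {
  block <- make_conflict_block()
  D_exact <- dist_fixture(c("a", "b", "c", "d"),
                          c(0.01, 0.05, 0.05, 0.05, 0.05, 0.01))
  res <- resolve_conflict(block, D_exact, NULL, consensus_thresholds())
  expect_equal(res$outcome, "accepted_by_coi")
  just_below <- dist_fixture(c("a", "b", "c", "d"),
                             c(0.01, 0.049999, 0.049999, 0.049999,
                               0.049999, 0.01))
  expect_equal(resolve_conflict(block, just_below, NULL,
                                consensus_thresholds())$outcome, "fewer_otus")
})

test_that("zero thresholds always accept the finer option; huge ones never do", {
  block <- make_conflict_block()
  D <- dist_fixture(c("a", "b", "c", "d"),
                    c(0.01, 0.02, 0.02, 0.02, 0.02, 0.01))
  fine <- resolve_conflict(block, D, D, consensus_thresholds(1e-9, 1e-9))
  expect_equal(length(unique(fine$grouping)), 2)
  coarse <- resolve_conflict(block, D, D, consensus_thresholds(10, 10))
  expect_equal(length(unique(coarse$grouping)), 1)
})

test_that("missing distances on both markers leave the conflict unresolved (coarser)", {
  block <- make_conflict_block()
  res <- resolve_conflict(block, NULL, NULL, consensus_thresholds())
  expect_equal(res$outcome, "unresolved")
  expect_equal(length(unique(res$grouping)), 1)
})

test_that("consensus covers all specimens and stays between the marker counts", {
  set.seed(20)
  for (rep in 1:5) {
    ds <- generate_dataset(sim_config(n_species = 6, seqs_per_species = 3,
                                      seed = 200 + rep))
    D_coi <- build_matrix(ds$records[ds$records$marker == "COI", ], "JC69")
    D_16s <- build_matrix(ds$records[ds$records$marker == "16S", ], "JC69")
    p_coi <- scan_priors(D_coi, abgd_params())$selected
    p_16s <- scan_priors(D_16s, abgd_params(p_max = 0.05, x = 1.5))$selected
    cons <- consensus_otus(p_coi, p_16s, D_coi, D_16s)
    n <- length(unique(cons$partition))
    expect_setequal(names(cons$partition),
                    union(names(p_coi), names(p_16s)))
    expect_gte(n, min(length(unique(p_coi)), length(unique(p_16s))))
    expect_lte(n, max(length(unique(p_coi)), length(unique(p_16s))))
  }
})

test_that("specimens sequenced for one marker inherit that marker's group", {
  p_coi <- part(a = "x", b = "x", c = "y")
  p_16s <- part(a = "z", b = "z", c = "w", d = "w")  # d has 16S only
  cons <- consensus_otus(p_coi, p_16s)
  expect_equal(unname(cons$partition[["d"]]), unname(cons$partition[["c"]]))
})

test_that("conflict resolution is invariant to specimen input order", {
  p_coi <- part(a = "x", b = "x", c = "y", d = "y", e = "q")
  p_16s <- part(d = "z", c = "z", b = "z", a = "z", e = "r")
  D <- dist_fixture(c("a", "b", "c", "d", "e"),
                    c(0.01, 0.08, 0.08, 0.3,
                      0.08, 0.08, 0.3, 0.01, 0.3, 0.3))
  c1 <- consensus_otus(p_coi, p_16s, D, NULL)
  ord <- c("e", "c", "a", "d", "b")
  c2 <- consensus_otus(p_coi[ord[ord %in% names(p_coi)]],
                       p_16s[rev(names(p_16s))], D, NULL)
  expect_identical(c1$partition[sort(names(c1$partition))],
                   c2$partition[sort(names(c2$partition))])
})

test_that("concordance counting matches constructed lump and split cases", {
  final <- part(s1 = "o1", s2 = "o1", s3 = "o2", s4 = "o3", s5 = "o3")
  labels <- c(s1 = "Alpheus formosus", s2 = "Alpheus formosus",
              s3 = "Tozeuma carolinense", s4 = "Tozeuma carolinense",
              s5 = "Synalpheus brevicarpus")
  rep <- concordance_report(final, labels)
  expect_equal(rep$n_otus, 3)
  expect_equal(rep$n_single_name, 2)
  expect_equal(rep$n_multi_name, 1)        # o3 lumps two names
  expect_equal(rep$n_split_morphospecies, 1)  # T. carolinense spans o2 and o3
  expect_error(concordance_report(final, labels[-1]), "without morphospecies")
})
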