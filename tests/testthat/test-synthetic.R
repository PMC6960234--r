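test_that("dataset dimensions, truth coverage and marker pairing are exact", {
  ds <- generate_dataset(sim_config(n_species = 20, seqs_per_species = 5,
                                    seed = 11))
  expect_equal(nrow(ds$truth), 100)
  expect_equal(nrow(ds$records), 200)
  expect_setequal(unique(ds$records$marker), c("COI", "16S"))
  # every specimen has exactly one record per marker and one truth row
  per <- table(ds$records$specimen_id, ds$records$marker)
  expect_true(all(per == 1))
  expect_equal(sort(unique(ds$records$specimen_id)), sort(ds$truth$specimen_id))
  # truth species count equals distinct species indices among records
  expect_equal(length(unique(ds$truth$species_index)), 20)
})

test_that("no pseudogenes are emitted when pseudo_fraction is zero", {
  ds <- generate_dataset(sim_config(n_species = 4, seqs_per_species = 3,
                                    seed = 2))
  expect_false(any(ds$truth$is_pseudogene))
  coi <- ds$records[ds$records$marker == "COI", ]
  expect_true(all(vapply(coi$residues, function(s) count_stops(s, 1L),
                         integer(1)) == 0L))
})

test_that("configs without a barcode gap are rejected", {
  expect_error(sim_config(intra_div = 0.05, inter_div = 0.05), "barcode gap")
  expect_error(sim_config(intra_div = 0.10, inter_div = 0.05), "barcode gap")
  expect_error(sim_config(coi_length = 0), "lengths")
  expect_error(sim_config(pseudo_fraction = 1.5), "pseudo_fraction")
})

test_that("every within-species p-distance is below every between-species one", {
  # exhaustive pairwise scan at the default divergences, both markers
  ds <- generate_dataset(sim_config(n_species = 8, seqs_per_species = 4,
                                    intra_div = 0.01, inter_div = 0.08,
                                    seed = 31))
  sp <- stats::setNames(ds$truth$species_index, ds$truth$specimen_id)
  for (mk in c("COI", "16S")) {
    sub <- ds$records[ds$records$marker == mk, ]
    D <- build_matrix(sub, model = "p")
    same <- outer(sp[rownames(D)], sp[colnames(D)], "==")
    ut <- upper.tri(D)
    expect_lt(max(D[ut & same]), min(D[ut & !same]))
    if (mk == "COI")  # gap-free marker: the inter_div floor is exact
      expect_gte(min(D[ut & !same]), 0.08)
  }
})

test_that("generation is byte-deterministic in the config", {
  cfg <- sim_config(n_species = 4, seqs_per_species = 3,
                    pseudo_fraction = 0.25, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("pseudogene injection produces exactly the advertised defects", {
  ds <- generate_dataset(sim_config(n_species = 3, seqs_per_species = 2,
                                    seed = 5))
  rec <- ds$records[ds$records$marker == "COI", ][1, , drop = FALSE]
  L <- nchar(rec$residues)

  st <- inject_pseudogene(rec, "stop", seed = 7)
  expect_gte(count_stops(st$residues, 1L), 1L)
  expect_equal(nchar(gsub("-", "", st$residues)), L)

  fs <- inject_pseudogene(rec, "frameshift", seed = 7)
  expect_equal(nchar(gsub("-", "", fs$residues)), L - 1L)
  expect_true(detect_frameshift(fs$residues, L))

  gx <- inject_pseudogene(rec, "gc_shift", seed = 7, gc_delta = 0.10)
  gc0 <- sum(strsplit(rec$residues, "")[[1]] %in% c("G", "C")) / L
  gc1 <- sum(strsplit(gx$residues, "")[[1]] %in% c("G", "C")) / L
  expect_lt(abs(gc1 - (gc0 + 0.10)), 0.02)
  # silent changes only: the translation is unchanged
  expect_equal(count_stops(gx$residues, 1L), 0L)

  r16 <- ds$records[ds$records$marker == "16S", ][1, , drop = FALSE]
  expect_error(inject_pseudogene(r16, "stop"), "coding")
})

test_that("simulated quality strings have the configured profile", {
  ds <- generate_dataset(sim_config(n_species = 2, seqs_per_species = 2,
                                    seed = 3))
  rec <- ds$records[1, , drop = FALSE]

  hi <- simulate_qualities(rec, mean_q = 40, bad_tail_fraction = 0, seed = 1)
  q <- utf8ToInt(hi$qualities) - 33L
  expect_equal(length(q), nchar(gsub("-", "", rec$residues)))
  expect_gte(mean(q >= 30), 0.99)

  lo <- simulate_qualities(rec, mean_q = 40, bad_tail_fraction = 0.2,
                           tail_mean_q = 10, seed = 1)
  q <- utf8ToInt(lo$qualities) - 33L
  n_tail <- floor(0.2 * length(q))
  expect_lt(mean(q[(length(q) - n_tail + 1):length(q)]), 20)

  empty <- rec
  empty$residues <- ""
  expect_identical(simulate_qualities(empty, 40, 0, seed = 1)$qualities, "")
})

test_that("a wide gap separates intra and inter distance clouds", {
  # inter_div >= 4x intra_div: the largest consecutive gap in the sorted
  # distance list must lie between the clouds and dwarf the intra gaps
  ds <- generate_dataset(sim_config(n_species = 5, seqs_per_species = 4,
                                    intra_div = 0.01, inter_div = 0.05,
                                    seed = 17))
  coi <- ds$records[ds$records$marker == "COI", ]
  D <- build_matrix(coi, model = "p")
  d <- sort(D[upper.tri(D)])
  g <- diff(d)
  sp <- stats::setNames(ds$truth$species_index, ds$truth$specimen_id)
  same <- outer(sp[rownames(D)], sp[colnames(D)], "==")
  max_intra <- max(D[upper.tri(D) & same])
  intra_gaps <- g[d[-1] <= max_intra]
  expect_gt(max(g), max(intra_gaps))
  expect_gte(d[which.max(g) + 1], min(D[upper.tri(D) & !same]))
})
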