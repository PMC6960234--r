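#' Configuration for the two-marker synthetic barcode generator
#'
#' Describes a dataset of `n_species` species with `seqs_per_species`
#' specimens each, every specimen carrying one COI-like protein-coding
#' record (translation table 5, stop-free unless pseudogenised) and one
#' 16S-like rRNA record that may contain alignment gaps (indels).
#'
#' Divergences are proportions of differing sites (p-distances): specimens
#' within a species differ by about `intra_div`, while any two specimens of
#' different species differ by at least `inter_div`, giving a controllable
#' barcode gap.  `pseudo_fraction` of the COI records are replaced by
#' pseudogene copies carrying frameshift, stop-codon or GC-shift defects.
#'
#' @param n_species number of species.
#' @param seqs_per_species specimens per species.
#' @param coi_length COI-like marker length in bases (default 658).
#' @param rrna_length 16S-like marker length in bases (default 550).
#' @param intra_div expected intraspecific p-distance (default 0.01).
#' @param inter_div minimum interspecific p-distance (default 0.08).
#' @param pseudo_fraction fraction of COI records replaced by pseudogenes.
#' @param indel_rate_16S per-site deletion probability for the 16S-like
#'   marker (default 0.005).
#' @param gc_target ancestral GC fraction (default 0.38, a typical decapod
#'   mitochondrial value).
#' @param seed master integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 20L, seqs_per_species = 5L,
                       coi_length = 658L, rrna_length = 550L,
                       intra_div = 0.01, inter_div = 0.08,
                       pseudo_fraction = 0, indel_rate_16S = 0.005,
                       gc_target = 0.38, seed = 1L) {
  if (coi_length <= 0 || rrna_length <= 0) stop("lengths must be > 0")
  if (intra_div < 0 || inter_div > 0.75 || intra_div >= inter_div)
    stop("require 0 <= intra_div < inter_div <= 0.75 (no barcode gap otherwise)")
  if (pseudo_fraction < 0 || pseudo_fraction > 1)
    stop("pseudo_fraction must be in [0, 1]")
  structure(list(n_species = as.integer(n_species),
                 seqs_per_species = as.integer(seqs_per_species),
                 coi_length = as.integer(coi_length),
                 rrna_length = as.integer(rrna_length),
                 intra_div = intra_div, inter_div = inter_div,
                 pseudo_fraction = pseudo_fraction,
                 indel_rate_16S = indel_rate_16S,
                 gc_target = gc_target, seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# invertebrate mitochondrial genetic code, memoised
code5 <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::getGeneticCode("5")
    tab
  }
})

# does changing chars[pos] to `base` create an in-frame (frame 1) stop?
creates_stop <- function(chars, pos, base) {
  cod <- (pos - 1L) %/% 3L
  a <- cod * 3L + 1L
  if (a + 2L > length(chars)) return(FALSE)  # trailing partial codon
  codon <- chars[a:(a + 2L)]
  codon[pos - a + 1L] <- base
  paste(codon, collapse = "") %in% c("TAA", "TAG")
}

# mutate chars[pos] to a different base; in coding mode reject bases that
# would create an in-frame stop (some alternative is always safe)
mutate_site <- function(chars, pos, coding) {
  alts <- sample(setdiff(BASES, chars[pos]))
  for (b in alts) {
    if (!coding || !creates_stop(chars, pos, b)) {
      chars[pos] <- b
      return(chars)
    }
  }
  chars
}

# random ancestor with the target GC fraction; coding ancestors are scrubbed
# of in-frame stops (TAA/TAG -> TAC, a tyrosine codon)
make_ancestor <- function(len, gc_target, coding) {
  p <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2, (1 - gc_target) / 2)
  chars <- sample(BASES, len, replace = TRUE, prob = p)
  if (coding) {
    for (a in seq(1L, len - len %% 3L - 2L, by = 3L)) {
      if (paste(chars[a:(a + 2L)], collapse = "") %in% c("TAA", "TAG"))
        chars[a + 2L] <- "C"
    }
  }
  chars
}

#' Generate a two-marker synthetic barcode dataset with known truth
#'
#' Species ancestors are built star-wise from a single random base ancestor:
#' each species receives its own disjoint set of `ceiling(inter_div * L / 2)`
#' diagnostic sites, mutated away from the ancestral state, so any two
#' specimens of different species differ at no fewer than `inter_div * L`
#' sites.  Specimens then accumulate intraspecific mutations (per-site rate
#' `intra_div / 2`, confined to non-diagnostic sites so the interspecific
#' floor is exact).  COI-like records stay stop-free in frame 1 under
#' translation table 5 unless pseudogenised; 16S-like records may carry
#' deletions emitted as alignment gaps.  Per-base Phred qualities are
#' attached via [simulate_qualities].  Output is byte-deterministic in the
#' config (including the seed): every record draws from a private RNG
#' substream keyed by its specimen id.
#'
#' @param cfg a [sim_config].
#' @return A list: `records` (a [barcode_records] table, two rows per
#'   specimen), `truth` (data frame `specimen_id`, `species_index`,
#'   `is_pseudogene`), `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_spec <- cfg$n_species * cfg$seqs_per_species
  ids <- sprintf("SP%04d", seq_len(n_spec))
  species_of <- rep(seq_len(cfg$n_species), each = cfg$seqs_per_species)
  morpho <- sprintf("Synthetica simulata%02d", species_of)

  markers <- list(COI = list(len = cfg$coi_length, coding = TRUE),
                  `16S` = list(len = cfg$rrna_length, coding = FALSE))
  rec_list <- list()
  for (mk in names(markers)) {
    len <- markers[[mk]]$len
    coding <- markers[[mk]]$coding
    k <- max(1L, as.integer(ceiling(cfg$inter_div * len / 2)))
    if (cfg$n_species * k > len)
      stop("inter_div unattainable: ", cfg$n_species, " species need ",
           cfg$n_species * k, " disjoint diagnostic sites but the ", mk,
           " marker has only ", len)
    anc <- list()
    diag_sites <- list()
    with_seed(substream_seed(cfg$seed, paste0("ancestor:", mk)), {
      base <- make_ancestor(len, cfg$gc_target, coding)
      all_sites <- sample.int(len, cfg$n_species * k)
      for (sp in seq_len(cfg$n_species)) {
        sites <- all_sites[((sp - 1L) * k + 1L):(sp * k)]
        diag_sites[[sp]] <- sites
        chars <- base
        for (s in sites) chars <- mutate_site(chars, s, coding)
        anc[[sp]] <- chars
      }
    })
    free_sites <- setdiff(seq_len(len), unlist(diag_sites))
    seqs <- character(n_spec)
    for (i in seq_len(n_spec)) {
      with_seed(substream_seed(cfg$seed, paste0(ids[i], ":", mk)), {
        chars <- anc[[species_of[i]]]
        n_mut <- stats::rbinom(1L, len, cfg$intra_div / 2)
        n_mut <- min(n_mut, length(free_sites))
        if (n_mut > 0L) {
          for (s in sample(free_sites, n_mut)) chars <- mutate_site(chars, s, coding)
        }
        if (!coding && cfg$indel_rate_16S > 0) {
          n_del <- stats::rbinom(1L, len, cfg$indel_rate_16S)
          n_del <- min(n_del, length(free_sites))
          if (n_del > 0L) chars[sample(free_sites, n_del)] <- "-"
        }
        seqs[i] <- paste(chars, collapse = "")
      })
    }
    rec_list[[mk]] <- barcode_records(
      specimen_id = ids, marker = mk, residues = seqs,
      morphospecies = morpho, expected_length = len)
  }

  truth <- data.frame(specimen_id = ids, species_index = species_of,
                      is_pseudogene = FALSE, stringsAsFactors = FALSE)

  n_pseudo <- round(cfg$pseudo_fraction * n_spec)
  if (n_pseudo > 0L) {
    pick <- with_seed(substream_seed(cfg$seed, "pseudo"),
                      sample(ids, n_pseudo))
    modes <- rep(c("frameshift", "stop", "gc_shift"), length.out = n_pseudo)
    coi <- rec_list[["COI"]]
    for (j in seq_len(n_pseudo)) {
      i <- match(pick[j], coi$specimen_id)
      coi[i, ] <- inject_pseudogene(coi[i, , drop = FALSE], modes[j],
                                    seed = substream_seed(cfg$seed,
                                                          paste0(pick[j], ":pg")))
      truth$is_pseudogene[truth$specimen_id == pick[j]] <- TRUE
    }
    rec_list[["COI"]] <- coi
  }

  records <- rbind(rec_list[["COI"]], rec_list[["16S"]])
  class(records) <- c("barcode_records", "data.frame")
  for (i in seq_len(nrow(records))) {
    records[i, ] <- simulate_qualities(
      records[i, , drop = FALSE], mean_q = 40, bad_tail_fraction = 0,
      seed = substream_seed(cfg$seed,
                            paste0(records$specimen_id[i], ":",
                                   records$marker[i], ":qual")))
  }
  rownames(records) <- NULL
  list(records = records, truth = truth, config = cfg)
}

#' Inject a pseudogene defect into a coding-marker record
#'
#' Creates exactly the defect classes the pseudogene screen detects:
#' `frameshift` deletes one base at a random internal position (emitted as
#' an alignment gap so the row stays aligned), `stop` rewrites a random
#' internal in-frame codon to TAA or TAG, and `gc_shift` resamples silent
#' third-codon positions (synonymous under translation table 5) until the
#' GC fraction has moved by `gc_delta`.
#'
#' @param record a single-row [barcode_records] table with `marker == "COI"`.
#' @param mode one of `"frameshift"`, `"stop"`, `"gc_shift"`.
#' @param seed integer seed for the defect placement.
#' @param gc_delta signed GC-fraction shift for `gc_shift` mode
#'   (default +0.12).
#' @return The modified single-row record.
#' @export
inject_pseudogene <- function(record, mode = c("frameshift", "stop", "gc_shift"),
                              seed = 1L, gc_delta = 0.12) {
  mode <- match.arg(mode)
  if (nrow(record) != 1L) stop("record must be a single row")
  if (record$marker != "COI") stop("pseudogene injection requires a coding (COI) record")
  aligned <- seq_chars(record$residues)
  base_idx <- which(aligned != "-")   # ungapped position -> aligned column
  chars <- aligned[base_idx]
  L <- length(chars)
  del_pos <- NA_integer_
  with_seed(seed, {
    if (mode == "frameshift") {
      del_pos <- sample(2:(L - 1L), 1L)
      aligned[base_idx[del_pos]] <- "-"
    } else if (mode == "stop") {
      ncod <- L %/% 3L
      cod <- sample(2:(ncod - 1L), 1L)
      stop_codon <- seq_chars(sample(c("TAA", "TAG"), 1L))
      aligned[base_idx[(cod * 3L - 2L):(cod * 3L)]] <- stop_codon
    } else {
      aligned[base_idx] <- shift_gc_silent(chars, gc_delta)
    }
  })
  record$residues <- paste(aligned, collapse = "")
  if (!is.na(record$qualities) && nzchar(record$qualities) &&
      mode == "frameshift") {
    q <- decode_phred(record$qualities)
    record$qualities <- encode_phred(q[-del_pos])
  }
  record
}

# synonymous third-position resampling toward a GC shift of `delta`
shift_gc_silent <- function(chars, delta) {
  gc5 <- code5()
  L <- length(chars)
  target <- round(abs(delta) * L)
  from <- if (delta > 0) c("A", "T") else c("G", "C")
  to <- if (delta > 0) c("G", "C") else c("A", "T")
  ncod <- L %/% 3L
  done <- 0L
  for (cod in sample.int(ncod)) {
    if (done >= target) break
    a <- cod * 3L - 2L
    third <- a + 2L
    if (!(chars[third] %in% from)) next
    old <- paste(chars[a:third], collapse = "")
    for (b in sample(to)) {
      new <- paste(c(chars[a:(a + 1L)], b), collapse = "")
      if (identical(gc5[[new]], gc5[[old]]) && gc5[[new]] != "*") {
        chars[third] <- b
        done <- done + 1L
        break
      }
    }
  }
  if (done < target)
    warning("gc_shift: only ", done, " of ", target, " silent changes available")
  chars
}

#' Simulate per-base Phred qualities for a record
#'
#' Draws per-base scores from a normal distribution (sd 3) around `mean_q`,
#' with the trailing `bad_tail_fraction` of bases drawn around `tail_mean_q`
#' instead (emulating 3' quality decay in Sanger traces), clamps to
#' `[2, 41]` and stores them as a Sanger offset-33 string.
#'
#' @param record a single-row [barcode_records] table.
#' @param mean_q mean Phred score of the good portion, in `[2, 60]`.
#' @param bad_tail_fraction fraction of 3' bases drawn from the low-quality
#'   distribution.
#' @param tail_mean_q mean Phred score of the bad tail (default 10).
#' @param seed integer seed.
#' @return The record with its `qualities` field set.
#' @export
simulate_qualities <- function(record, mean_q = 40, bad_tail_fraction = 0,
                               tail_mean_q = 10, seed = 1L) {
  if (mean_q < 2 || mean_q > 60) stop("mean_q must be in [2, 60]")
  L <- nchar(ungap(record$residues))
  if (L == 0L) {
    record$qualities <- ""
    return(record)
  }
  with_seed(seed, {
    q <- stats::rnorm(L, mean_q, 3)
    n_tail <- floor(bad_tail_fraction * L)
    if (n_tail > 0L)
      q[(L - n_tail + 1L):L] <- stats::rnorm(n_tail, tail_mean_q, 3)
    record$qualities <- encode_phred(pmin(pmax(q, 2), 41))
  })
  record
}

#' Write a synthetic dataset to disk
#'
#' Emits, per marker, an aligned FASTA and an (ungapped) FASTQ with Sanger
#' offset-33 qualities, plus a metadata TSV (`specimen_id`, `marker`,
#' `morphospecies`, `expected_length`) and the truth TSV.
#'
#' @param dataset result of [generate_dataset].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  rec <- dataset$records
  for (mk in unique(rec$marker)) {
    sub <- rec[rec$marker == mk, ]
    tag <- tolower(sub("16S", "r16s", mk))
    fa <- file.path(dir, paste0(tag, ".fasta"))
    writeLines(paste0(">", sub$specimen_id, "\n", sub$residues), fa)
    fq <- file.path(dir, paste0(tag, ".fastq"))
    writeLines(paste0("@", sub$specimen_id, "\n", ungap(sub$residues),
                      "\n+\n", sub$qualities), fq)
    paths[paste0(tag, "_fasta")] <- fa
    paths[paste0(tag, "_fastq")] <- fq
  }
  meta <- file.path(dir, "metadata.tsv")
  write_tsv(rec[, c("specimen_id", "marker", "morphospecies",
                    "expected_length")], meta)
  truth <- file.path(dir, "truth.tsv")
  write_tsv(dataset$truth, truth)
  c(paths, metadata = meta, truth = truth)
}
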