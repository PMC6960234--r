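#' Pipeline configuration
#'
#' Bundles all stage parameters and input paths.  Marker-specific ABGD
#' settings default to the standard two-marker survey values (COI:
#' p_min 0.001, p_max 0.1, x 1.125, 10 steps; 16S: p_max 0.05, x 1.5).
#'
#' @param coi_fasta,r16s_fasta aligned FASTA per marker (optional if
#'   `records` passed to [run_pipeline]).
#' @param coi_fastq,r16s_fastq optional FASTQ files supplying per-base
#'   qualities for the same specimens.
#' @param metadata metadata TSV path or data frame (`specimen_id`,
#'   `marker`, `morphospecies`, `expected_length`).
#' @param reference_library optional reference FASTA path or data frame
#'   ([read_reference_library] format).
#' @param out_dir output directory.
#' @param qc a [qc_params].
#' @param abgd_coi,abgd_16s [abgd_params] per marker.
#' @param consensus a [consensus_thresholds].
#' @param novelty a [novelty_thresholds].
#' @param dist_model distance model for ABGD and trees (default `"JC69"`).
#' @param z_cut pseudogene GC standard-score cutoff.
#' @param n_boot bootstrap replicates for tree support (default 100).
#' @param seed integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(coi_fasta = NULL, coi_fastq = NULL,
                            r16s_fasta = NULL, r16s_fastq = NULL,
                            metadata = NULL, reference_library = NULL,
                            out_dir = tempfile("barcodekit_run_"),
                            qc = qc_params(),
                            abgd_coi = abgd_params(),
                            abgd_16s = abgd_params(p_max = 0.05, x = 1.5),
                            consensus = consensus_thresholds(),
                            novelty = novelty_thresholds(),
                            dist_model = "JC69",
                            z_cut = 3.0, n_boot = 100L, seed = 1L) {
  structure(list(coi_fasta = coi_fasta, coi_fastq = coi_fastq,
                 r16s_fasta = r16s_fasta, r16s_fastq = r16s_fastq,
                 metadata = metadata, reference_library = reference_library,
                 out_dir = out_dir, qc = qc,
                 abgd_coi = abgd_coi, abgd_16s = abgd_16s,
                 consensus = consensus, novelty = novelty,
                 dist_model = dist_model, z_cut = z_cut,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "pipeline_config")
}

# attach FASTQ qualities to FASTA-derived records of the same specimens
attach_qualities <- function(records, fastq_path, metadata, marker) {
  fq <- read_sequences(fastq_path, "fastq", metadata, marker)
  hit <- match(records$specimen_id, fq$specimen_id)
  ok <- !is.na(hit)
  mism <- ok & ungap(records$residues) != fq$residues[hit]
  if (any(mism))
    stop("FASTQ/FASTA residue mismatch for: ",
         paste(records$specimen_id[mism], collapse = ", "))
  records$qualities[ok] <- fq$qualities[hit[ok]]
  records
}

load_pipeline_records <- function(config) {
  md <- config$metadata
  if (is.character(md)) md <- read_tsv(md)
  if (is.null(md)) stop("metadata is required")
  recs <- list()
  if (!is.null(config$coi_fasta)) {
    r <- read_sequences(config$coi_fasta, "fasta", md, "COI")
    if (!is.null(config$coi_fastq))
      r <- attach_qualities(r, config$coi_fastq, md, "COI")
    recs[["COI"]] <- r
  }
  if (!is.null(config$r16s_fasta)) {
    r <- read_sequences(config$r16s_fasta, "fasta", md, "16S")
    if (!is.null(config$r16s_fastq))
      r <- attach_qualities(r, config$r16s_fastq, md, "16S")
    recs[["16S"]] <- r
  }
  if (!length(recs)) stop("no sequence inputs configured")
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("barcode_records", "data.frame")
  out
}

#' Run the whole barcoding pipeline
#'
#' QC screen -> contamination screen -> per-marker distance matrices ->
#' BIONJ trees with bootstrap support -> ABGD prior scan and partition
#' selection per marker -> cross-marker consensus -> reference matching and
#' novelty -> pseudogene screen -> OTU summary.  All outputs are written
#' under `config$out_dir` and returned invisibly; reruns with identical
#' inputs, config and seed are byte-identical.
#'
#' @param config a [pipeline_config].
#' @param records optional in-memory [barcode_records] table (bypasses the
#'   file-reading stage).
#' @return (Invisibly) a list with every stage result; see the fields
#'   written in the run manifest.
#' @export
run_pipeline <- function(config, records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$out_dir, f)
  if (is.null(records)) records <- load_pipeline_records(config)

  # --- QC ---
  qc_res <- filter_dataset(records, config$qc)
  write_tsv(qc_res$dropped[, c("specimen_id", "marker", "reason")],
            out_path("qc_drop_log.tsv"))
  kept <- qc_res$kept

  # --- contamination ---
  library_df <- config$reference_library
  if (is.character(library_df)) library_df <- read_reference_library(library_df)
  contam <- data.frame(specimen_id = character(0), marker = character(0),
                       best_ref = character(0), identity = numeric(0))
  if (!is.null(library_df) &&
      any(library_df$status == "nontarget") && nrow(kept) > 0L) {
    nt <- library_df[library_df$status == "nontarget", ]
    nt_seqs <- stats::setNames(nt$residues, nt$ref_id)
    hits <- lapply(seq_len(nrow(kept)), function(i)
      screen_contamination(ungap(kept$residues[i]), nt_seqs,
                           config$novelty$contaminant_identity))
    flagged <- vapply(hits, `[[`, TRUE, "flagged")
    if (any(flagged)) {
      contam <- data.frame(
        specimen_id = kept$specimen_id[flagged],
        marker = kept$marker[flagged],
        best_ref = vapply(hits[flagged], `[[`, "", "best_ref"),
        identity = vapply(hits[flagged], `[[`, 0, "best_identity"))
      kept <- kept[!flagged, , drop = FALSE]
      class(kept) <- c("barcode_records", "data.frame")
    }
  }
  write_tsv(contam, out_path("contaminants.tsv"))

  markers <- intersect(c("COI", "16S"), unique(kept$marker))
  dists <- list(); trees <- list(); scans <- list(); selected <- list()
  for (mk in markers) {
    sub <- marker_records(kept, mk)
    if (nrow(sub) < 3L) next
    tag <- if (mk == "COI") "coi" else "r16s"
    D <- build_matrix(sub, model = config$dist_model)
    dists[[mk]] <- D
    write_phylip(D, out_path(paste0(tag, "_dist.phy")))
    bs <- bootstrap_support(records_alignment(sub), model = config$dist_model,
                            n_reps = config$n_boot,
                            seed = substream_seed(config$seed, paste0("boot:", mk)))
    trees[[mk]] <- bs
    ape::write.tree(bs$tree, out_path(paste0(tag, "_tree.nwk")))
    params <- if (mk == "COI") config$abgd_coi else config$abgd_16s
    sc <- scan_priors(D, params)
    scans[[mk]] <- sc
    selected[[mk]] <- sc$selected
    write_partition(sc$selected, out_path(paste0(tag, "_partition.tsv")))
    write_tsv(sc$group_counts, out_path(paste0(tag, "_group_counts.tsv")))
    write_tsv(sc$histogram, out_path(paste0(tag, "_dist_histogram.tsv")))
  }
  if (!length(selected)) stop("stage abgd: no marker had >= 3 post-QC records")

  # --- consensus ---
  p_coi <- selected[["COI"]] %||% structure(character(0), class = "otu_partition")
  p_16s <- selected[["16S"]] %||% structure(character(0), class = "otu_partition")
  cons <- consensus_otus(p_coi, p_16s, dists[["COI"]], dists[["16S"]],
                         config$consensus)
  write_partition(cons$partition, out_path("consensus_partition.tsv"))
  write_tsv(cons$conflicts, out_path("conflict_log.tsv"))

  # --- reference match / novelty ---
  matches <- NULL
  if (!is.null(library_df)) {
    matches <- match_references(kept, library_df, config$novelty)
    write_tsv(matches, out_path("reference_matches.tsv"))
  }

  # --- pseudogene screen ---
  pseudo <- NULL
  if (sum(kept$marker == "COI") >= 2L) {
    pseudo <- pseudogene_screen(kept, z_cut = config$z_cut)
    write_tsv(pseudo$per_sequence, out_path("pseudogene_report.tsv"))
  }

  # --- OTU summary ---
  morpho <- stats::setNames(kept$morphospecies, kept$specimen_id)
  morpho <- morpho[!duplicated(names(morpho))]
  morpho[is.na(morpho)] <- "unknown"
  conc <- concordance_report(cons$partition, morpho)
  summary_df <- otu_summary(cons$partition, morpho, matches, markers)
  write_tsv(summary_df, out_path("otu_summary.tsv"))

  result <- list(records = records, kept = kept, dropped = qc_res$dropped,
                 contaminants = contam, distances = dists, trees = trees,
                 abgd = scans, selected = selected, consensus = cons,
                 matches = matches, pseudogene = pseudo,
                 concordance = conc, otu_summary = summary_df,
                 config = config)
  result$counts <- summarize_counts(result)
  manifest <- list(
    package = "barcodekit",
    seed = config$seed,
    dist_model = config$dist_model,
    n_boot = config$n_boot,
    qc = unclass(config$qc),
    abgd_coi = unclass(config$abgd_coi),
    abgd_16s = unclass(config$abgd_16s),
    consensus = unclass(config$consensus),
    novelty = unclass(config$novelty),
    z_cut = config$z_cut,
    outputs = setdiff(sort(list.files(config$out_dir)), "manifest.json"),
    counts = result$counts)
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}

# Table-1-style per-OTU rows: members, morphospecies names, per-marker
# novelty flags (an OTU is "new" for a marker when none of its sequenced
# members is a known match)
otu_summary <- function(partition, morpho, matches, markers) {
  otus <- split(names(partition), unname(partition))
  rows <- lapply(names(otus), function(o) {
    mem <- otus[[o]]
    nm <- sort(unique(morpho[mem]))
    flag <- function(mk) {
      if (is.null(matches)) return(NA)
      m <- matches[matches$marker == mk & matches$specimen_id %in% mem, ]
      if (nrow(m) == 0L) return(NA)
      !any(m$class == "known")
    }
    data.frame(otu_id = o,
               morphospecies = paste(nm, collapse = "|"),
               n_individuals = length(mem),
               coi_new = flag("COI"), r16s_new = flag("16S"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Headline counts of a pipeline run
#'
#' @param result the list returned by [run_pipeline].
#' @return Named list: per-marker OTU counts, consensus OTU count, new /
#'   known OTU counts per marker, OTUs with multiple morphospecies names,
#'   morphospecies split across OTUs, conflicts resolved.
#' @export
summarize_counts <- function(result) {
  s <- result$otu_summary
  cnt <- function(mk) {
    p <- result$selected[[mk]]
    if (is.null(p)) NA_integer_ else length(unique(p))
  }
  list(n_otus_coi = cnt("COI"),
       n_otus_16s = cnt("16S"),
       n_otus_consensus = result$concordance$n_otus,
       n_new_coi = if (all(is.na(s$coi_new))) NA_integer_ else
         sum(s$coi_new, na.rm = TRUE),
       n_new_16s = if (all(is.na(s$r16s_new))) NA_integer_ else
         sum(s$r16s_new, na.rm = TRUE),
       n_multi_name_otus = result$concordance$n_multi_name,
       n_single_name_otus = result$concordance$n_single_name,
       n_split_morphospecies = result$concordance$n_split_morphospecies,
       n_conflicts = nrow(result$consensus$conflicts),
       n_dropped_qc = nrow(result$dropped),
       n_contaminants = nrow(result$contaminants))
}
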