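#' Count in-frame stop codons under the invertebrate mitochondrial code
#'
#' In translation table 5 only TAA and TAG are stops (AGA/AGG encode serine
#' and TGA tryptophan).  The trailing partial codon is ignored.
#'
#' @param seq ungapped DNA string.
#' @param frame reading frame, 1, 2 or 3.
#' @return Integer stop count.
#' @export
count_stops <- function(seq, frame = 1L) {
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3")
  ch <- seq_chars(ungap(seq))
  n <- length(ch)
  if (n - frame + 1L < 3L) return(0L)
  starts <- seq(frame, n - 2L, by = 3L)
  codons <- paste0(ch[starts], ch[starts + 1L], ch[starts + 2L])
  sum(codons %in% c("TAA", "TAG"))
}

#' Best reading frame of a coding sequence
#'
#' The frame minimising the stop count; ties go to the lowest frame index.
#'
#' @param seq ungapped DNA string, length >= 6.
#' @return A list: `frame`, `n_stops`.
#' @export
best_reading_frame <- function(seq) {
  if (nchar(ungap(seq)) < 6L) stop("sequence too short to frame")
  stops <- vapply(1:3, function(f) count_stops(seq, f), integer(1))
  f <- which.min(stops)
  list(frame = f, n_stops = stops[f])
}

#' Detect a frame-disrupting indel
#'
#' Alignment-free mode compares the ungapped length modulo 3 with the
#' expectation; aligned mode additionally flags any internal gap run whose
#' length is not a multiple of 3 (an in-frame 3n-base indel is not a
#' frameshift).
#'
#' @param seq DNA string, possibly with alignment gaps.
#' @param reference_length the expected ungapped length (its value mod 3 is
#'   the expectation).
#' @param aligned if `TRUE`, also inspect internal gap runs.
#' @return Logical flag.
#' @export
detect_frameshift <- function(seq, reference_length, aligned = FALSE) {
  flag <- (nchar(ungap(seq)) %% 3L) != (as.integer(reference_length) %% 3L)
  if (aligned && grepl("-", seq, fixed = TRUE)) {
    internal <- sub("^-+", "", sub("-+$", "", seq))
    runs <- regmatches(internal, gregexpr("-+", internal))[[1L]]
    if (any(nchar(runs) %% 3L != 0L)) flag <- TRUE
  }
  flag
}

#' GC-content statistics for a marker cohort
#'
#' GC% is `100 * (G+C) / (A+C+G+T)` over ungapped unambiguous bases.
#' Cohort mean and standard deviation give per-sequence standard scores;
#' sequences with `|z| > z_cut` are flagged as GC outliers (mitochondrial
#' coding sequences and their nuclear pseudogene copies tend to differ in
#' AT bias).  Sequences with no unambiguous base are excluded and reported.
#'
#' @param seqs named character vector of DNA sequences (one marker).
#' @param z_cut standard-score cutoff (default 3).
#' @return A list: `per_sequence` (data frame `id`, `gc_pct`, `gc_z`,
#'   `gc_outlier`), `gc_min`, `gc_max`, `excluded` (ids).
#' @export
gc_stats <- function(seqs, z_cut = 3.0) {
  gc <- vapply(seqs, gc_fraction, numeric(1)) * 100
  excluded <- names(seqs)[is.na(gc)]
  ok <- !is.na(gc)
  if (sum(ok) < 2L) stop("need >= 2 sequences with unambiguous bases")
  mu <- mean(gc[ok])
  sdv <- stats::sd(gc[ok])
  z <- (gc - mu) / sdv
  per <- data.frame(id = names(seqs)[ok], gc_pct = gc[ok], gc_z = z[ok],
                    gc_outlier = abs(z[ok]) > z_cut,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(per_sequence = per, gc_min = min(gc[ok]), gc_max = max(gc[ok]),
       excluded = excluded)
}

#' Cross-marker GC correlation
#'
#' Pearson correlation of per-specimen (GC% COI, GC% 16S) pairs over
#' specimens sequenced for both markers; if the two markers share the
#' mitochondrial AT bias the correlation is expected to be positive, and
#' specimens far off the trend are pseudogene suspects.
#'
#' @param gc_coi,gc_16s named numeric vectors of GC% per specimen.
#' @return A list: `pearson_r` (`NA` when undefined), `n_shared`,
#'   `defined` (logical; `FALSE` when a marker has zero variance).
#' @export
gc_correlation <- function(gc_coi, gc_16s) {
  shared <- intersect(names(gc_coi), names(gc_16s))
  if (length(shared) < 3L) stop("need >= 3 specimens with both markers")
  x <- gc_coi[shared]
  y <- gc_16s[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pearson_r = NA_real_, n_shared = length(shared),
                defined = FALSE))
  list(pearson_r = stats::cor(x, y), n_shared = length(shared),
       defined = TRUE)
}

# amino-acid p-distance of each translated sequence to the cohort's modal
# (per-position most frequent) translated sequence
aa_divergence <- function(seqs) {
  gc5 <- code5()
  translate1 <- function(s) {
    ch <- seq_chars(ungap(s))
    n <- length(ch) - length(ch) %% 3L
    if (n < 3L) return(character(0))
    starts <- seq(1L, n - 2L, by = 3L)
    codons <- paste0(ch[starts], ch[starts + 1L], ch[starts + 2L])
    aa <- gc5[codons]
    aa[is.na(aa)] <- "X"
    unname(aa)
  }
  aas <- lapply(seqs, translate1)
  len <- min(lengths(aas))
  if (len == 0L) return(stats::setNames(rep(NA_real_, length(seqs)), names(seqs)))
  M <- do.call(rbind, lapply(aas, `[`, seq_len(len)))
  modal <- apply(M, 2L, function(col) names(which.max(table(col))))
  stats::setNames(rowMeans(sweep(M, 2L, modal, `!=`)), names(seqs))
}

#' Screen a dataset for pseudogene signatures
#'
#' The three-step screen for obvious pseudogenes in a protein-coding marker:
#' (1) in-frame stop codons and frame-disrupting indels, (2) unusually
#' divergent amino-acid sequences (p-distance to the cohort's modal
#' translation above `aa_cut`), (3) deviant GC content (`|z| > z_cut`
#' within the marker cohort).  Steps 1-2 apply to the coding marker only;
#' GC statistics and the cross-marker GC correlation cover both markers.
#'
#' @param records a [barcode_records] table with COI (and optionally 16S)
#'   rows.
#' @param z_cut GC standard-score cutoff (default 3).
#' @param aa_cut amino-acid divergence cutoff (default 0.20).
#' @return A list of class `pseudogene_report`: `per_sequence` (data frame
#'   `specimen_id`, `best_frame`, `n_stops`, `frameshift`, `aa_div`,
#'   `gc_pct`, `gc_z`, `flags`), `gc_min`, `gc_max` (cohort, both markers
#'   pooled), `pearson_r`, `n_flagged`.
#' @export
pseudogene_screen <- function(records, z_cut = 3.0, aa_cut = 0.20) {
  coi <- records[records$marker == "COI", , drop = FALSE]
  if (nrow(coi) < 2L) stop("need >= 2 COI records")
  seqs <- stats::setNames(coi$residues, coi$specimen_id)
  frames <- lapply(seqs, best_reading_frame)
  fs <- vapply(seq_len(nrow(coi)), function(i)
    detect_frameshift(coi$residues[i], coi$expected_length[i],
                      aligned = grepl("-", coi$residues[i], fixed = TRUE)),
    logical(1))
  aa <- aa_divergence(seqs)
  gcs <- gc_stats(seqs, z_cut = z_cut)
  gc_i <- match(coi$specimen_id, gcs$per_sequence$id)
  per <- data.frame(
    specimen_id = coi$specimen_id,
    best_frame = vapply(frames, `[[`, 0L, "frame"),
    n_stops = vapply(frames, `[[`, 0L, "n_stops"),
    frameshift = fs,
    aa_div = unname(aa),
    gc_pct = gcs$per_sequence$gc_pct[gc_i],
    gc_z = gcs$per_sequence$gc_z[gc_i],
    stringsAsFactors = FALSE, row.names = NULL)
  per$flags <- apply(per, 1L, function(r) {
    f <- c(if (as.integer(r[["n_stops"]]) > 0L) "stop",
           if (as.logical(r[["frameshift"]])) "indel",
           if (!is.na(r[["aa_div"]]) && as.numeric(r[["aa_div"]]) > aa_cut)
             "aa_divergent",
           if (!is.na(r[["gc_z"]]) && abs(as.numeric(r[["gc_z"]])) > z_cut)
             "gc_outlier")
    paste(f, collapse = ",")
  })
  gc_all <- c(gcs$per_sequence$gc_pct)
  r16 <- records[records$marker == "16S", , drop = FALSE]
  pearson_r <- NA_real_
  if (nrow(r16) >= 3L) {
    gcs16 <- gc_stats(stats::setNames(r16$residues, r16$specimen_id),
                      z_cut = z_cut)
    gc_all <- c(gc_all, gcs16$per_sequence$gc_pct)
    cc <- tryCatch(gc_correlation(
      stats::setNames(gcs$per_sequence$gc_pct, gcs$per_sequence$id),
      stats::setNames(gcs16$per_sequence$gc_pct, gcs16$per_sequence$id)),
      error = function(e) NULL)
    if (!is.null(cc)) pearson_r <- cc$pearson_r
  }
  structure(list(per_sequence = per,
                 gc_min = min(gc_all), gc_max = max(gc_all),
                 pearson_r = pearson_r,
                 n_flagged = sum(nzchar(per$flags))),
            class = "pseudogene_report")
}

#' @export
print.pseudogene_report <- function(x, ...) {
  cat(sprintf(paste0("pseudogene_report: %d sequences screened, %d flagged; ",
                     "GC%% range %.2f-%.2f; COI~16S GC r = %s\n"),
              nrow(x$per_sequence), x$n_flagged, x$gc_min, x$gc_max,
              format(x$pearson_r, digits = 3)))
  invisible(x)
}
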