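#' Quality-screening parameters
#'
#' A sequence passes only if its ungapped length exceeds `min_len_frac` of
#' the expected amplicon length and (when per-base qualities are present)
#' more than `min_frac_above` of its bases reach Phred `min_phred`.  The
#' defaults are the standard barcoding screen: >90% of the expected length
#' with Phred >= 30 for more than 85% of the bases; both rules are strict
#' inequalities.
#'
#' @param min_len_frac minimum length fraction, in (0, 1].
#' @param min_phred minimum per-base Phred score.
#' @param min_frac_above minimum fraction of bases at or above `min_phred`.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_len_frac = 0.90, min_phred = 30L,
                      min_frac_above = 0.85) {
  if (min_len_frac <= 0 || min_len_frac > 1 ||
      min_frac_above <= 0 || min_frac_above > 1)
    stop("fractions must be in (0, 1]")
  if (min_phred < 0) stop("min_phred must be >= 0")
  structure(list(min_len_frac = min_len_frac,
                 min_phred = as.integer(min_phred),
                 min_frac_above = min_frac_above),
            class = "qc_params")
}

#' Read sequences and join them to specimen metadata
#'
#' Reads FASTA (gap characters preserved) or FASTQ (Sanger offset-33
#' qualities decoded) and joins every record to its metadata row by
#' `(specimen_id, marker)`.  A record absent from the metadata, or a
#' duplicated `(specimen, marker)` pair, is a hard error.
#'
#' @param path sequence file.
#' @param format `"fasta"` or `"fastq"`.
#' @param metadata data frame with columns `specimen_id`, `marker`,
#'   `morphospecies`, `expected_length`.
#' @param marker marker name of the file (`"COI"` or `"16S"`).
#' @return A [barcode_records] table.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq"), metadata,
                           marker) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)  # BString keeps gap characters
    seqs <- toupper(as.character(x))
    quals <- rep(NA_character_, length(x))
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    seqs <- toupper(as.character(x))
    quals <- as.character(methods::slot(x, "elementMetadata")$qualities)
  }
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  md <- metadata[metadata$marker == marker, , drop = FALSE]
  hit <- match(ids, md$specimen_id)
  if (anyNA(hit))
    stop("record id(s) absent from metadata for marker ", marker, ": ",
         paste(ids[is.na(hit)], collapse = ", "))
  barcode_records(specimen_id = ids, marker = marker, residues = seqs,
                  qualities = quals,
                  morphospecies = md$morphospecies[hit],
                  expected_length = md$expected_length[hit])
}

#' Does a record pass the quality screen?
#'
#' Length rule: ungapped length strictly greater than
#' `min_len_frac * expected_length`.  Quality rule (only when qualities are
#' present — archival FASTA skips it): the fraction of bases with Phred
#' `>= min_phred` strictly greater than `min_frac_above`.
#'
#' @param record a single-row [barcode_records] table.
#' @param params a [qc_params].
#' @return A list: `pass` (logical) and `reason` (string, `""` on pass).
#' @export
passes_qc <- function(record, params = qc_params()) {
  len <- nchar(ungap(record$residues))
  exp_len <- record$expected_length
  if (is.na(exp_len)) stop("record has no expected_length")
  if (!(len > params$min_len_frac * exp_len)) {
    return(list(pass = FALSE,
                reason = sprintf("length %d <= %.0f%% of expected %d",
                                 len, 100 * params$min_len_frac, exp_len)))
  }
  q <- decode_phred(record$qualities)
  if (length(q) > 0L) {
    frac <- mean(q >= params$min_phred)
    if (!(frac > params$min_frac_above)) {
      return(list(pass = FALSE,
                  reason = sprintf("only %.1f%% of bases >= Q%d (need > %.0f%%)",
                                   100 * frac, params$min_phred,
                                   100 * params$min_frac_above)))
    }
  }
  list(pass = TRUE, reason = "")
}

#' Split a record set into QC passes and failures
#'
#' @param records a [barcode_records] table.
#' @param params a [qc_params].
#' @return A list: `kept` (records passing), `dropped` (records failing,
#'   with an extra `reason` column).  Input order is preserved and every
#'   record appears in exactly one of the two.
#' @export
filter_dataset <- function(records, params = qc_params()) {
  if (nrow(records) == 0L) {
    dropped <- cbind(records, reason = character(0))
    return(list(kept = records, dropped = dropped))
  }
  res <- lapply(seq_len(nrow(records)), function(i)
    passes_qc(records[i, , drop = FALSE], params))
  pass <- vapply(res, `[[`, TRUE, "pass")
  kept <- records[pass, , drop = FALSE]
  dropped <- records[!pass, , drop = FALSE]
  dropped$reason <- vapply(res[!pass], `[[`, "", "reason")
  rownames(kept) <- rownames(dropped) <- NULL
  class(kept) <- c("barcode_records", "data.frame")
  list(kept = kept, dropped = dropped)
}
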