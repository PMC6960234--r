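#' Barcode sequence records
#'
#' A `barcode_records` object is a data frame with one row per marker sequence
#' of a specimen: columns `specimen_id`, `marker` (`"COI"` or `"16S"`),
#' `residues` (IUPAC DNA, may contain `-` alignment gaps), `qualities`
#' (Sanger offset-33 Phred string, or `NA` when absent), `morphospecies`
#' (taxonomic name, or `NA`) and `expected_length` (nominal ungapped amplicon
#' length in bases).
#'
#' When qualities are present their length must equal the ungapped residue
#' length: gap characters are alignment artefacts, not called bases.
#'
#' @param specimen_id character vector of specimen identifiers.
#' @param marker character vector, each `"COI"` or `"16S"`.
#' @param residues character vector of uppercase IUPAC DNA strings.
#' @param qualities optional character vector of Phred strings (offset 33).
#' @param morphospecies optional character vector of names.
#' @param expected_length optional integer vector of expected amplicon lengths.
#' @return A data frame of class `barcode_records`.
#' @export
barcode_records <- function(specimen_id, marker, residues,
                            qualities = NA_character_,
                            morphospecies = NA_character_,
                            expected_length = NA_integer_) {
  df <- data.frame(
    specimen_id = as.character(specimen_id),
    marker = as.character(marker),
    residues = toupper(as.character(residues)),
    qualities = as.character(qualities),
    morphospecies = as.character(morphospecies),
    expected_length = as.integer(expected_length),
    stringsAsFactors = FALSE
  )
  validate_records(df)
  class(df) <- c("barcode_records", "data.frame")
  df
}

validate_records <- function(df) {
  bad_marker <- setdiff(unique(df$marker), c("COI", "16S"))
  if (length(bad_marker))
    stop("unknown marker(s): ", paste(bad_marker, collapse = ", "))
  dup <- duplicated(df[, c("specimen_id", "marker")])
  if (any(dup))
    stop("duplicate (specimen, marker) records: ",
         paste(unique(df$specimen_id[dup]), collapse = ", "))
  has_q <- !is.na(df$qualities) & nzchar(df$qualities)
  if (any(has_q)) {
    qlen <- nchar(df$qualities[has_q])
    slen <- nchar(ungap(df$residues[has_q]))
    if (any(qlen != slen))
      stop("quality string length differs from ungapped residue length for: ",
           paste(df$specimen_id[has_q][qlen != slen], collapse = ", "))
  }
  invisible(df)
}

#' @export
print.barcode_records <- function(x, ...) {
  cat(sprintf("barcode_records: %d records, %d specimens, markers: %s\n",
              nrow(x), length(unique(x$specimen_id)),
              paste(sort(unique(x$marker)), collapse = ", ")))
  NextMethod()
}

# subset records for one marker, preserving class
marker_records <- function(records, marker) {
  out <- records[records$marker == marker, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("barcode_records", "data.frame")
  out
}

# named aligned-residue vector for one marker (rows must share length)
records_alignment <- function(records, marker = NULL) {
  if (!is.null(marker)) records <- records[records$marker == marker, ]
  aln <- stats::setNames(records$residues, records$specimen_id)
  if (length(unique(nchar(aln))) > 1L)
    stop("records are not aligned: unequal residue lengths")
  aln
}
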