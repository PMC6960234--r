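#' Novelty / contamination thresholds
#'
#' A COI query is "known" when its best reference identity exceeds
#' `coi_known_identity` percent (default 95), a 16S query when it exceeds
#' `rrna_known_identity` (default 97); both bounds are strict, so boundary
#' values classify as new.  A query is a contaminant when its identity to a
#' non-target reference exceeds `contaminant_identity` (default 95).
#'
#' @param coi_known_identity,rrna_known_identity,contaminant_identity
#'   percentages in (0, 100].
#' @return A list of class `novelty_thresholds`.
#' @export
novelty_thresholds <- function(coi_known_identity = 95,
                               rrna_known_identity = 97,
                               contaminant_identity = 95) {
  v <- c(coi_known_identity, rrna_known_identity, contaminant_identity)
  if (any(v <= 0 | v > 100)) stop("identities must be in (0, 100]")
  structure(list(coi_known_identity = coi_known_identity,
                 rrna_known_identity = rrna_known_identity,
                 contaminant_identity = contaminant_identity),
            class = "novelty_thresholds")
}

#' Percent identity from a global ends-free alignment
#'
#' Aligns two ungapped sequences globally with free terminal gaps
#' (match +1, mismatch -1, gap open -5, gap extend -2) and reports
#' `100 * matches / aligned columns`, terminal-gap columns excluded — a
#' deterministic stand-in for BLAST identity on same-locus amplicons.
#'
#' A gap of length `k` costs `5 + 2k`; terminal gaps are free.
#'
#' @param query,reference ungapped DNA strings.
#' @return Percent identity in `[0, 100]`, with the optimal alignment score
#'   attached as attribute `"score"`.
#' @export
pairwise_identity <- function(query, reference) {
  if (!nzchar(query) || !nzchar(reference)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(query)),
    Biostrings::DNAString(toupper(reference)),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 5, gapExtension = 2)
  p <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  s <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  if (length(p) == 0L) return(structure(0, score = Biostrings::score(al)))
  structure(100 * sum(p == s & p != "-") / length(p),
            score = Biostrings::score(al))
}

#' Classify a query as known or new
#'
#' @param best_identity best percent identity against the target reference
#'   library.
#' @param marker `"COI"` or `"16S"`.
#' @param thresholds a [novelty_thresholds].
#' @return `"known"` or `"new"`.
#' @export
classify_novelty <- function(best_identity, marker,
                             thresholds = novelty_thresholds()) {
  cut <- switch(marker, COI = thresholds$coi_known_identity,
                `16S` = thresholds$rrna_known_identity,
                stop("unknown marker: ", marker))
  if (best_identity > cut) "known" else "new"
}

#' Flag contamination against non-target references
#'
#' @param query ungapped DNA string.
#' @param nontarget_refs named character vector of non-target reference
#'   sequences (may be empty).
#' @param threshold percent identity above which the query is flagged.
#' @return A list: `flagged`, `best_identity`, `best_ref`.
#' @export
screen_contamination <- function(query, nontarget_refs, threshold = 95) {
  if (length(nontarget_refs) == 0L)
    return(list(flagged = FALSE, best_identity = NA_real_,
                best_ref = NA_character_))
  ids <- vapply(nontarget_refs, function(r) pairwise_identity(query, r),
                numeric(1))
  ord <- order(-ids, names(nontarget_refs))
  best <- ord[1L]
  list(flagged = ids[best] > threshold,
       best_identity = unname(ids[best]),
       best_ref = names(nontarget_refs)[best])
}

# strip open-nomenclature qualifiers (cf., aff., nr.) and parse a binomial
parse_binomial <- function(name) {
  name <- trimws(gsub("\\b(cf|aff|nr)\\.?\\s+", "", name))
  parts <- strsplit(name, "\\s+")[[1L]]
  if (length(parts) < 1L || !grepl("^[A-Z][A-Za-z-]*$", parts[1L])) return(NULL)
  epithet <- if (length(parts) >= 2L) parts[2L] else NA_character_
  if (!is.na(epithet) && grepl("^sp\\.?$", epithet, ignore.case = TRUE))
    epithet <- NA_character_
  list(genus = parts[1L], epithet = epithet)
}

#' Compare a query name with a reference name
#'
#' `concordant` when genus and epithet agree; `better_resolution` when the
#' reference lacks an epithet (or is "sp.") but the query has one in the
#' same genus; `discordant_species` when the genus agrees and the epithets
#' differ; `discordant_higher` otherwise.  Qualifiers (cf./aff./nr.) are
#' stripped first; unparsable names give `"n/a"`.
#'
#' @param query_name,reference_name taxon names.
#' @return One of `"concordant"`, `"better_resolution"`,
#'   `"discordant_species"`, `"discordant_higher"`, `"n/a"`.
#' @export
name_concordance <- function(query_name, reference_name) {
  q <- parse_binomial(query_name)
  r <- parse_binomial(reference_name)
  if (is.null(q) || is.null(r)) return("n/a")
  if (q$genus != r$genus) return("discordant_higher")
  if (is.na(r$epithet)) {
    if (!is.na(q$epithet)) return("better_resolution")
    return("concordant")
  }
  if (is.na(q$epithet)) return("discordant_species")
  if (q$epithet == r$epithet) "concordant" else "discordant_species"
}

#' Read a local reference library FASTA
#'
#' Header convention: `refID|taxon_name|target` or
#' `refID|taxon_name|nontarget`.
#'
#' @param path FASTA file.
#' @return Data frame `ref_id`, `taxon`, `status`, `residues`.
#' @export
read_reference_library <- function(path) {
  x <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed reference header(s): ",
         paste(names(x)[bad], collapse = ", "))
  data.frame(ref_id = vapply(parts, `[[`, "", 1L),
             taxon = vapply(parts, `[[`, "", 2L),
             status = vapply(parts, `[[`, "", 3L),
             residues = toupper(as.character(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Match queries against a reference library
#'
#' For each query the best target-library hit (maximum identity, ties to
#' the lexicographically smallest reference id) determines the novelty
#' class and name concordance.
#'
#' @param records a [barcode_records] table (one marker at a time is
#'   typical; the marker column selects the novelty threshold per row).
#' @param library data frame as returned by [read_reference_library];
#'   only `status == "target"` rows are used here.
#' @param thresholds a [novelty_thresholds].
#' @return Data frame: `specimen_id`, `marker`, `best_ref`, `best_taxon`,
#'   `identity`, `class`, `name_concordance`.
#' @export
match_references <- function(records, library,
                             thresholds = novelty_thresholds()) {
  targets <- library[library$status == "target", , drop = FALSE]
  out <- lapply(seq_len(nrow(records)), function(i) {
    q <- ungap(records$residues[i])
    if (nrow(targets) == 0L) {
      return(data.frame(specimen_id = records$specimen_id[i],
                        marker = records$marker[i],
                        best_ref = NA_character_, best_taxon = NA_character_,
                        identity = 0, class = "new",
                        name_concordance = "n/a", stringsAsFactors = FALSE))
    }
    ids <- vapply(targets$residues, function(r) pairwise_identity(q, r),
                  numeric(1), USE.NAMES = FALSE)
    best <- order(-ids, targets$ref_id)[1L]
    cls <- classify_novelty(ids[best], records$marker[i], thresholds)
    conc <- if (cls == "known" && !is.na(records$morphospecies[i]))
      name_concordance(records$morphospecies[i], targets$taxon[best])
    else "n/a"
    data.frame(specimen_id = records$specimen_id[i],
               marker = records$marker[i],
               best_ref = targets$ref_id[best],
               best_taxon = targets$taxon[best],
               identity = ids[best], class = cls,
               name_concordance = conc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
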