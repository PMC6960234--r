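# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so library code does not
#' disturb user-level random streams.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

#' Stable per-key RNG substream seed
#'
#' Polynomial rolling hash of `key` folded with the master seed, mod 2^31-1.
#' Insertion order of records therefore never changes their private streams.
#' @noRd
substream_seed <- function(master, key) {
  h <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# strip alignment gaps
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# split a sequence string into single characters
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# fraction of G+C over unambiguous bases, in [0,1]; NA if no unambiguous base
gc_fraction <- function(seq) {
  ch <- seq_chars(ungap(seq))
  n_gc <- sum(ch %in% c("G", "C"))
  n_at <- sum(ch %in% c("A", "T"))
  if (n_gc + n_at == 0L) return(NA_real_)
  n_gc / (n_gc + n_at)
}

# decode a Sanger (offset 33) quality string to integer Phred scores
decode_phred <- function(qstring) {
  if (is.na(qstring) || !nzchar(qstring)) return(integer(0))
  utf8ToInt(qstring) - 33L
}

# encode integer Phred scores as a Sanger quality string
encode_phred <- function(q) {
  if (length(q) == 0L) return("")
  intToUtf8(pmin(pmax(as.integer(round(q)), 0L), 93L) + 33L)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}
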