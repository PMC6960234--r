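#' Pairwise site counts under pairwise deletion
#'
#' Compares two equal-length aligned rows and counts comparable sites,
#' differences, transitions and transversions.  A site is comparable only if
#' both rows carry an unambiguous base (`A`, `C`, `G`, `T`): gaps and IUPAC
#' ambiguity codes are excluded for this pair only (pairwise deletion).
#' Transitions are the purine (A<->G) and pyrimidine (C<->T) exchanges; every
#' other mismatch is a transversion.
#'
#' @param row_i,row_j aligned DNA strings (or character vectors) of equal
#'   length.
#' @return Named integer vector with elements `comparable_sites`,
#'   `differences`, `transitions`, `transversions`.
#' @examples
#' pairwise_counts("ATGC", "ATGA")  # one transversion
#' @export
pairwise_counts <- function(row_i, row_j) {
  a <- encode_dna(row_i)
  b <- encode_dna(row_j)
  if (length(a) != length(b)) stop("rows have unequal aligned lengths")
  counts_from_encoded(a, b)
}

# A=1 C=2 G=3 T=4; anything else (gaps, ambiguities) NA
encode_dna <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- seq_chars(x)
  m <- match(toupper(x), c("A", "C", "G", "T"))
  m
}

counts_from_encoded <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  ai <- a[ok]
  bi <- b[ok]
  diff <- ai != bi
  purine <- c(TRUE, FALSE, TRUE, FALSE)
  ts <- sum(diff & (purine[ai] == purine[bi]))
  nd <- sum(diff)
  c(comparable_sites = sum(ok), differences = nd,
    transitions = ts, transversions = nd - ts)
}

#' Jukes-Cantor (JC69) distance
#'
#' `d = -(3/4) ln(1 - (4/3) p)` for a proportion `p` of differing sites.
#' Saturated inputs (`p >= 0.75`) have no finite JC69 distance and raise an
#' error.
#'
#' @param p proportion(s) of differing sites, in `[0, 0.75)`.
#' @return Numeric distance(s), substitutions per site.
#' @export
jc69 <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75))
    stop("JC69 saturation: p >= 0.75 for ",
         paste(format(p[p >= 0.75]), collapse = ", "))
  -0.75 * log(1 - 4 * p / 3)
}

#' Kimura two-parameter (K2P) distance
#'
#' `d = -(1/2) ln(1 - 2P - Q) - (1/4) ln(1 - 2Q)` with `P` the transition and
#' `Q` the transversion proportion.  Requires `1 - 2P - Q > 0` and
#' `1 - 2Q > 0`; violations are saturation errors.
#'
#' @param P transition proportion(s).
#' @param Q transversion proportion(s).
#' @return Numeric distance(s), substitutions per site.
#' @export
k2p <- function(P, Q) {
  if (any(P < 0) || any(Q < 0)) stop("P and Q must be non-negative")
  if (any(1 - 2 * P - Q <= 0) || any(1 - 2 * Q <= 0))
    stop("K2P saturation: require 1-2P-Q > 0 and 1-2Q > 0")
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' Build a pairwise distance matrix from an alignment
#'
#' Computes all pairwise distances under the chosen model with pairwise
#' deletion.  The result is a symmetric matrix of class `barcode_dist`
#' carrying the model name and the per-pair comparable-site counts as
#' attributes.
#'
#' @param aln a named character vector of equal-length aligned sequences, a
#'   `Biostrings::DNAStringSet`, or a [barcode_records] table restricted to
#'   one marker.
#' @param model `"JC69"` (default), `"p"` or `"K2P"`.
#' @param on_saturation `"error"` (default) stops and lists saturated pairs;
#'   `"cap"` replaces a saturated distance with the model value just inside
#'   its domain boundary.
#' @return A symmetric numeric matrix (class `barcode_dist`) with zero
#'   diagonal; attributes `model` and `sites` (comparable-site counts).
#' @export
build_matrix <- function(aln, model = c("JC69", "p", "K2P"),
                         on_saturation = c("error", "cap")) {
  model <- match.arg(model)
  on_saturation <- match.arg(on_saturation)
  aln <- as_alignment(aln)
  n <- length(aln)
  if (n < 2L) stop("need at least 2 sequences")
  if (anyDuplicated(names(aln))) stop("duplicate sequence labels")
  enc <- lapply(aln, encode_dna)
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  S <- matrix(0L, n, n, dimnames = dimnames(D))
  incomparable <- character(0)
  saturated <- character(0)
  p_cap <- 0.75 - 1e-9
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ct <- counts_from_encoded(enc[[i]], enc[[j]])
      S[i, j] <- S[j, i] <- ct[["comparable_sites"]]
      pair <- paste(names(aln)[i], names(aln)[j], sep = "/")
      if (ct[["comparable_sites"]] == 0L) {
        incomparable <- c(incomparable, pair)
        next
      }
      ns <- ct[["comparable_sites"]]
      p <- ct[["differences"]] / ns
      d <- switch(model,
        p = p,
        JC69 = {
          if (p >= 0.75) {
            saturated <- c(saturated, pair)
            if (on_saturation == "cap") jc69(p_cap) else NA_real_
          } else jc69(p)
        },
        K2P = {
          P <- ct[["transitions"]] / ns
          Q <- ct[["transversions"]] / ns
          if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
            saturated <- c(saturated, pair)
            if (on_saturation == "cap") {
              -0.5 * log(max(1 - 2 * P - Q, 1e-9)) -
                0.25 * log(max(1 - 2 * Q, 1e-9))
            } else NA_real_
          } else k2p(P, Q)
        })
      D[i, j] <- D[j, i] <- d
    }
  }
  if (length(incomparable))
    stop("incomparable pairs (no shared unambiguous sites): ",
         paste(incomparable, collapse = ", "))
  if (length(saturated) && on_saturation == "error")
    stop("saturated pairs under ", model, ": ",
         paste(saturated, collapse = ", "))
  structure(D, model = model, sites = S,
            class = c("barcode_dist", "matrix", "array"))
}

as_alignment <- function(aln) {
  if (inherits(aln, "barcode_records")) return(records_alignment(aln))
  if (methods::is(aln, "XStringSet")) {
    out <- toupper(as.character(aln))
    names(out) <- names(aln)
    aln <- out
  }
  if (!is.character(aln)) stop("unsupported alignment input")
  if (is.null(names(aln)) || any(!nzchar(names(aln))))
    stop("alignment rows must be named")
  if (length(unique(nchar(aln))) > 1L)
    stop("alignment rows have unequal lengths")
  toupper(aln)
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat(sprintf("barcode_dist: %d taxa, model %s\n", nrow(x), attr(x, "model")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' Write / read a square PHYLIP distance matrix
#'
#' @param D a `barcode_dist` (or plain symmetric matrix with dimnames).
#' @param path file path.
#' @return `read_phylip` returns a symmetric matrix with dimnames.
#' @export
write_phylip <- function(D, path) {
  n <- nrow(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.9f", D[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  parts <- strsplit(trimws(lines[1L + seq_len(n)]), "\\s+")
  labs <- vapply(parts, `[[`, "", 1L)
  D <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(n)))
  dimnames(D) <- list(labs, labs)
  D
}
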