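# Independent oracles and small fixture builders shared across tests.

# canonical label-free signature of a specimen->group mapping
part_sig <- function(p) {
  ids <- sort(names(p))
  paste(match(unname(p[ids]), unique(unname(p[ids]))), collapse = ",")
}

truth_partition <- function(truth) {
  stats::setNames(as.character(truth$species_index), truth$specimen_id)
}

# brute-force transitive closure: repeatedly merge any two groups joined by
# an edge d < threshold, until a fixed point — deliberately naive
closure_oracle <- function(D, threshold) {
  ids <- rownames(D)
  grp <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i != j && D[i, j] < threshold && grp[i] != grp[j]) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  grp
}

# random symmetric distance matrix with zero diagonal
random_dist <- function(n) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2)
  D <- D + t(D)
  dimnames(D) <- list(sprintf("t%02d", seq_len(n)), sprintf("t%02d", seq_len(n)))
  D
}

# Needleman-Wunsch with affine gaps (open 5 + extend 2 per base) and free
# terminal gaps, match +1 / mismatch -1: returns the optimal score.
# Three-state DP, independent of the alignment engine under test.
nw_overlap_score <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  gap <- function(k) 5 + 2 * k
  M <- matrix(NEG, n + 1, m + 1)   # a[i] aligned to b[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (a[i] unmatched)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  X[cbind(2:(n + 1), 1)] <- 0      # free leading gaps
  Y[cbind(1, 2:(m + 1))] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) 1 else -1
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap(1), X[i - 1, j] - 2)
      Y[i, j] <- max(M[i, j - 1] - gap(1), Y[i, j - 1] - 2)
    }
  }
  # free trailing gaps: end anywhere on the last row or column, any state
  best <- NEG
  for (i in 1:(n + 1)) best <- max(best, M[i, m + 1], X[i, m + 1], Y[i, m + 1])
  for (j in 1:(m + 1)) best <- max(best, M[n + 1, j], X[n + 1, j], Y[n + 1, j])
  best
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# mutate a sequence at k random positions
mutate_dna <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  for (p in sample(length(ch), k)) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                           ch[p]), 1)
  paste(ch, collapse = "")
}

# single-row record builder for unit tests
one_record <- function(residues, qualities = NA_character_, marker = "COI",
                       id = "S1", expected_length = nchar(gsub("-", "", residues)),
                       morphospecies = NA_character_) {
  barcode_records(specimen_id = id, marker = marker, residues = residues,
                  qualities = qualities, morphospecies = morphospecies,
                  expected_length = expected_length)
}

# distance matrix from explicit upper-triangle values (column-wise: AB, AC,
# BC, AD, ...) and labels
dist_fixture <- function(labels, upper) {
  n <- length(labels)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  D[upper.tri(D)] <- upper
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}
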