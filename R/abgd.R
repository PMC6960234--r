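#' ABGD parameters
#'
#' Parameters of the Automatic Barcode Gap Discovery scan: a geometric series
#' of `steps` priors on the maximal intraspecific divergence between `p_min`
#' and `p_max`, and the relative gap width `x` a candidate gap must exceed
#' (relative to the local mean gap) to count as the barcode gap.  Defaults
#' are the COI settings used throughout the package (`p_min` 0.001, `p_max`
#' 0.1, `x` 1.125, 10 steps); the matching 16S settings are `p_max = 0.05`,
#' `x = 1.5`.
#'
#' @param p_min,p_max prior bounds, `0 < p_min < p_max < 1`.
#' @param x relative gap width, `> 1`.
#' @param steps number of priors in the geometric series, `>= 2`.
#' @param min_gap_context minimum number of preceding gaps required for the
#'   local mean-gap estimate (default 2); below it the median of all gaps is
#'   used instead.
#' @return A list of class `abgd_params`.
#' @export
abgd_params <- function(p_min = 0.001, p_max = 0.1, x = 1.125, steps = 10L,
                        min_gap_context = 2L) {
  if (!(p_min > 0 && p_min < p_max && p_max < 1))
    stop("require 0 < p_min < p_max < 1")
  if (x <= 1) stop("x must be > 1")
  if (steps < 2L) stop("steps must be >= 2")
  structure(list(p_min = p_min, p_max = p_max, x = x,
                 steps = as.integer(steps),
                 min_gap_context = as.integer(min_gap_context)),
            class = "abgd_params")
}

#' Geometric series of priors
#'
#' `P_k = p_min * (p_max/p_min)^(k/(steps-1))`, `k = 0..steps-1`; strictly
#' increasing with exact endpoints.
#'
#' @param params an [abgd_params] object.
#' @return Numeric vector of priors.
#' @export
prior_series <- function(params) {
  k <- seq(0L, params$steps - 1L)
  pr <- params$p_min * (params$p_max / params$p_min)^(k / (params$steps - 1L))
  pr[1L] <- params$p_min
  pr[length(pr)] <- params$p_max
  pr
}

#' Locate the barcode gap in a ranked distance list
#'
#' Scans consecutive gaps `g_i = d[i+1] - d[i]` of the ascending distance
#' list.  A gap is a candidate if its far edge exceeds the prior maximal
#' intraspecific divergence (`d[i+1] > prior`); it is significant if it is
#' more than `x` times the local gap scale — the larger of the mean of the
#' preceding consecutive gaps (or the median of all gaps when fewer than
#' `min_gap_context` precede) and the prior itself.  Scaling by the prior
#' keeps the sampling noise of a dense intraspecific distance cloud, whose
#' consecutive gaps shrink toward zero, from masquerading as a barcode gap:
#' under a prior maximal intraspecific divergence `p`, a believable gap must
#' be wide on the scale of `p`, not merely wide relative to its tied
#' neighbours.  The first significant candidate in rank order is returned,
#' with the partition threshold at the gap midpoint.
#'
#' @param sorted_distances ascending numeric vector, length >= 2.
#' @param prior prior maximal intraspecific divergence.
#' @param x relative gap width.
#' @param min_gap_context see [abgd_params].
#' @return A list: `found`, `lower_edge`, `upper_edge`, `threshold`,
#'   `rank_index`.
#' @export
find_gap <- function(sorted_distances, prior, x, min_gap_context = 2L) {
  d <- sorted_distances
  n <- length(d)
  none <- list(found = FALSE, lower_edge = NA_real_, upper_edge = NA_real_,
               threshold = NA_real_, rank_index = NA_integer_)
  if (n < 2L) return(none)
  if (is.unsorted(d)) stop("distances must be sorted ascending")
  g <- diff(d)
  med_all <- stats::median(g)
  for (i in seq_len(n - 1L)) {
    if (d[i + 1L] <= prior) next
    s_i <- if (i - 1L >= min_gap_context) mean(g[seq_len(i - 1L)]) else med_all
    if (g[i] > x * max(s_i, prior)) {
      return(list(found = TRUE, lower_edge = d[i], upper_edge = d[i + 1L],
                  threshold = (d[i] + d[i + 1L]) / 2, rank_index = i))
    }
  }
  none
}

#' Single-linkage grouping below a distance threshold
#'
#' Connected components of the graph whose edges join specimens with
#' `d(i, j) < threshold` (strictly below: the gap itself is never bridged).
#'
#' @param D symmetric distance matrix with specimen dimnames.
#' @param threshold non-negative distance.
#' @return An `otu_partition`: named character vector mapping specimen to
#'   group id, where each group id is the smallest specimen id it contains.
#' @export
single_linkage <- function(D, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  D <- as.matrix(D)
  ids <- rownames(D)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (D[i, j] < threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as_partition(stats::setNames(roots, ids))
}

# normalise a specimen->integer grouping into an otu_partition whose group
# ids are the smallest member specimen_id (deterministic, order-independent)
as_partition <- function(mapping, marker = NA_character_, prior = NA_real_,
                         provenance = "initial") {
  ids <- names(mapping)
  grp <- split(ids, mapping[ids])
  lab <- vapply(grp, function(m) min(m), "")
  out <- stats::setNames(rep(lab, lengths(grp)), unlist(grp, use.names = FALSE))
  out <- out[sort(ids)]
  structure(out, marker = marker, prior = prior, provenance = provenance,
            class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  cat(sprintf("otu_partition: %d specimens in %d groups (marker %s, prior %s)\n",
              length(x), length(unique(x)), attr(x, "marker"),
              format(attr(x, "prior"))))
  invisible(x)
}

# canonical signature for partition identity (label-free)
partition_signature <- function(p) {
  ids <- sort(names(p))
  paste(ids, unname(p[ids]), sep = "=", collapse = ";")
}

#' Recursive ABGD partition at one prior
#'
#' Applies [find_gap] to all pairwise distances; when a gap is found the
#' specimens are split by [single_linkage] at the gap midpoint and the
#' procedure recurses independently inside each group using only intra-group
#' distances.  Recursion stops when no significant gap is found, a split
#' yields a single group, or a group has fewer than 3 members (with fewer
#' than 3 specimens there is at most one internal distance and no gap is
#' definable).
#'
#' @param D symmetric distance matrix with specimen dimnames.
#' @param params an [abgd_params] object.
#' @param prior the prior maximal intraspecific divergence to use.
#' @return An `otu_partition`.
#' @export
recursive_partition <- function(D, params, prior) {
  D <- as.matrix(D)
  ids <- rownames(D)
  groups <- list()
  recurse <- function(members) {
    if (length(members) < 3L) {
      groups[[length(groups) + 1L]] <<- members
      return(invisible())
    }
    sub <- D[members, members, drop = FALSE]
    d <- sort(sub[upper.tri(sub)])
    gap <- find_gap(d, prior, params$x, params$min_gap_context)
    if (!gap$found) {
      groups[[length(groups) + 1L]] <<- members
      return(invisible())
    }
    part <- single_linkage(sub, gap$threshold)
    sub_groups <- split(names(part), unname(part))
    if (length(sub_groups) == 1L) {
      groups[[length(groups) + 1L]] <<- members
      return(invisible())
    }
    for (sg in sub_groups) recurse(sg)
  }
  recurse(ids)
  mapping <- stats::setNames(rep(seq_along(groups), lengths(groups)),
                             unlist(groups, use.names = FALSE))
  as_partition(mapping, prior = prior,
               provenance = if (length(groups) > 1L) "recursive" else "initial")
}

#' Scan the prior series and select the modal partition
#'
#' Runs [recursive_partition] at every prior of the geometric series and
#' selects the modal partition — the grouping produced by the largest number
#' of priors (ties resolved in favour of the smaller prior).  Also returns
#' the pairwise-distance histogram (bin width 0.005) used as a prior
#' diagnostic, and the per-prior group counts.
#'
#' @param D symmetric distance matrix with specimen dimnames.
#' @param params an [abgd_params] object.
#' @return A list: `priors`, `partitions` (one per prior), `selected`
#'   (`otu_partition`), `selected_prior`, `group_counts` (data frame),
#'   `histogram` (data frame of bin mids and counts).
#' @export
scan_priors <- function(D, params) {
  priors <- prior_series(params)
  parts <- lapply(priors, function(pr) recursive_partition(D, params, pr))
  sigs <- vapply(parts, partition_signature, "")
  tab <- table(factor(sigs, levels = unique(sigs)))  # unique() keeps prior order
  modal_sig <- names(tab)[which.max(tab)]            # ties -> earliest = smallest prior
  sel_idx <- which(sigs == modal_sig)[1L]
  Dm <- as.matrix(D)
  dvals <- Dm[upper.tri(Dm)]
  breaks <- seq(0, max(dvals) + 0.005, by = 0.005)
  counts <- as.integer(table(cut(dvals, breaks, include.lowest = TRUE)))
  h <- list(mids = (breaks[-1L] + breaks[-length(breaks)]) / 2, counts = counts)
  list(priors = priors,
       partitions = parts,
       selected = parts[[sel_idx]],
       selected_prior = priors[sel_idx],
       group_counts = data.frame(prior = priors,
                                 n_groups = vapply(parts, function(p)
                                   length(unique(p)), integer(1))),
       histogram = data.frame(bin_mid = h$mids, count = h$counts))
}

#' Write a partition as TSV
#'
#' @param partition an `otu_partition`.
#' @param path file path.
#' @export
write_partition <- function(partition, path) {
  write_tsv(data.frame(specimen_id = names(partition),
                       otu_id = unname(partition),
                       prior = attr(partition, "prior") %||% NA_real_),
            path)
  invisible(path)
}
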