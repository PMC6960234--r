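#' Thresholds for cross-marker conflict resolution
#'
#' When the COI and 16S partitions disagree about a set of specimens, the
#' finer grouping is accepted only if each extra group diverges from every
#' other specimen of the conflict block by at least `min_div_coi`
#' substitutions per site in COI or `min_div_16s` in 16S ("at least" is an
#' inclusive bound); otherwise the option producing fewer OTUs wins.
#'
#' @param min_div_coi minimum COI divergence (default 0.05).
#' @param min_div_16s minimum 16S divergence (default 0.03).
#' @return A list of class `consensus_thresholds`.
#' @export
consensus_thresholds <- function(min_div_coi = 0.05, min_div_16s = 0.03) {
  if (min_div_coi <= 0 || min_div_16s <= 0) stop("thresholds must be > 0")
  structure(list(min_div_coi = min_div_coi, min_div_16s = min_div_16s),
            class = "consensus_thresholds")
}

# grouping implied by marker `m` on the specimens of one block:
# members carrying the marker take its groups; members lacking it inherit
# the group of the co-grouped (other-marker) specimen with the smallest id
# that does carry it, or form their own group per other-marker OTU
implied_grouping <- function(members, p_have, p_other) {
  grp <- stats::setNames(rep(NA_character_, length(members)), members)
  has <- members[members %in% names(p_have)]
  grp[has] <- p_have[has]
  missing <- members[is.na(grp)]
  for (m in missing) {
    if (!is.null(p_other) && m %in% names(p_other)) {
      mates <- names(p_other)[p_other == p_other[[m]]]
      mates <- sort(intersect(mates, has))
      if (length(mates)) {
        grp[m] <- grp[mates[1L]]
        next
      }
      grp[m] <- paste0("only:", p_other[[m]])
    } else {
      grp[m] <- paste0("self:", m)
    }
  }
  grp
}

#' Align two marker partitions into conflict blocks
#'
#' Specimens are linked whenever either marker co-groups them; the connected
#' components of that join graph are the blocks within which the two markers
#' can be compared.  Specimens sequenced for a single marker belong to the
#' block their available marker implies.
#'
#' @param p_coi,p_16s `otu_partition`s (named specimen -> group vectors);
#'   their specimen sets may differ.
#' @return A list of blocks; each block is a list with `members`,
#'   `grouping_coi`, `grouping_16s` (groupings implied on the block by each
#'   marker) and `conflict` (logical).
#' @export
align_partitions <- function(p_coi, p_16s) {
  ids <- sort(union(names(p_coi), names(p_16s)))
  idx <- stats::setNames(seq_along(ids), ids)
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link_groups <- function(p) {
    for (g in split(names(p), unname(p))) {
      if (length(g) > 1L) {
        r1 <- find(idx[[g[1L]]])
        for (m in g[-1L]) {
          r2 <- find(idx[[m]])
          if (r1 != r2) parent[r2] <<- r1
        }
      }
    }
  }
  link_groups(p_coi)
  link_groups(p_16s)
  roots <- vapply(seq_along(ids), find, integer(1))
  canon <- function(g) {
    g <- g[sort(names(g))]
    paste(match(g, unique(g)), collapse = ",")
  }
  blocks <- lapply(split(ids, roots), function(members) {
    g_coi <- implied_grouping(members, p_coi, p_16s)
    g_16s <- implied_grouping(members, p_16s, p_coi)
    list(members = members, grouping_coi = g_coi, grouping_16s = g_16s,
         conflict = canon(g_coi) != canon(g_16s))
  })
  names(blocks) <- NULL
  blocks
}

# minimum distance between two specimen sets in matrix D (NA if no pair has
# a distance, e.g. specimens unsequenced for that marker)
min_between <- function(D, set_a, set_b) {
  if (is.null(D)) return(NA_real_)
  a <- intersect(set_a, rownames(D))
  b <- intersect(set_b, rownames(D))
  if (!length(a) || !length(b)) return(NA_real_)
  min(D[a, b, drop = FALSE])
}

#' Resolve one cross-marker conflict block
#'
#' Of the two candidate groupings the finer option `F` (more groups) is
#' accepted only if each of its groups diverges from every other specimen of
#' the block by at least `min_div_coi` in COI or `min_div_16s` in 16S;
#' otherwise the coarser option `C` (fewer OTUs) is used.  When the two
#' marker groupings cross (neither refines the other) the finer candidate is
#' their common refinement and the coarser is the marker grouping with fewer
#' groups.
#'
#' @param block one block from [align_partitions].
#' @param D_coi,D_16s distance matrices (either may be `NULL`).
#' @param thresholds a [consensus_thresholds].
#' @return A list: `grouping` (named specimen -> group), `outcome` (one of
#'   `accepted_by_coi`, `accepted_by_16s`, `fewer_otus`, `no_conflict`,
#'   `unresolved`).
#' @export
resolve_conflict <- function(block, D_coi, D_16s,
                             thresholds = consensus_thresholds()) {
  g_coi <- block$grouping_coi
  g_16s <- block$grouping_16s
  if (!block$conflict)
    return(list(grouping = g_coi, outcome = "no_conflict"))
  # common refinement (meet); equals the finer grouping when one refines the
  # other, and resolves crossing partitions finest-first otherwise
  meet <- paste(g_coi, g_16s, sep = "&")
  names(meet) <- block$members
  n_coi <- length(unique(g_coi))
  n_16s <- length(unique(g_16s))
  coarse <- if (n_coi <= n_16s) g_coi else g_16s
  fine <- meet
  if (length(unique(fine)) == length(unique(coarse)))
    return(list(grouping = coarse, outcome = "fewer_otus"))
  by_coi <- TRUE
  by_16s <- FALSE
  all_pass <- TRUE
  any_dist <- FALSE
  for (g in split(block$members, fine[block$members])) {
    others <- setdiff(block$members, g)
    if (!length(others)) next
    d_c <- min_between(D_coi, g, others)
    d_r <- min_between(D_16s, g, others)
    if (is.na(d_c) && is.na(d_r)) next  # no evidence either way for this group
    any_dist <- TRUE
    ok_c <- !is.na(d_c) && d_c >= thresholds$min_div_coi
    ok_r <- !is.na(d_r) && d_r >= thresholds$min_div_16s
    if (!ok_c) by_coi <- FALSE
    if (ok_r) by_16s <- TRUE
    if (!ok_c && !ok_r) {
      all_pass <- FALSE
      break
    }
  }
  if (!any_dist)
    return(list(grouping = coarse, outcome = "unresolved"))
  if (all_pass) {
    list(grouping = fine,
         outcome = if (by_coi) "accepted_by_coi" else "accepted_by_16s")
  } else {
    list(grouping = coarse, outcome = "fewer_otus")
  }
}

#' Consensus OTUs across two markers
#'
#' Reconciles the per-marker partitions block by block with
#' [resolve_conflict] and returns the final consensus partition over every
#' specimen carrying at least one marker, plus a per-conflict log.
#'
#' @param p_coi,p_16s per-marker `otu_partition`s.
#' @param D_coi,D_16s per-marker distance matrices (substitutions per site).
#' @param thresholds a [consensus_thresholds].
#' @return A list: `partition` (consensus `otu_partition`), `conflicts`
#'   (data frame: block members, group counts of both markers, outcome).
#' @export
consensus_otus <- function(p_coi, p_16s, D_coi = NULL, D_16s = NULL,
                           thresholds = consensus_thresholds()) {
  blocks <- align_partitions(p_coi, p_16s)
  mapping <- character(0)
  log <- list()
  for (b in blocks) {
    res <- resolve_conflict(b, D_coi, D_16s, thresholds)
    g <- res$grouping[b$members]
    local_ids <- paste0(b$members[1L], "#", match(g, unique(g)))
    mapping <- c(mapping, stats::setNames(local_ids, b$members))
    if (b$conflict) {
      log[[length(log) + 1L]] <- data.frame(
        members = paste(b$members, collapse = ","),
        n_groups_coi = length(unique(b$grouping_coi)),
        n_groups_16s = length(unique(b$grouping_16s)),
        outcome = res$outcome, stringsAsFactors = FALSE)
    }
  }
  conflicts <- if (length(log)) do.call(rbind, log) else
    data.frame(members = character(0), n_groups_coi = integer(0),
               n_groups_16s = integer(0), outcome = character(0))
  part <- as_partition(stats::setNames(match(mapping, unique(mapping)),
                                       names(mapping)),
                       provenance = "consensus")
  list(partition = part, conflicts = conflicts)
}

#' OTU / morphospecies concordance report
#'
#' Compares a final partition with the morphological identifications:
#' counts OTUs associated with exactly one morphospecies name, OTUs lumping
#' several names, and morphospecies split across several OTUs.
#'
#' @param final an `otu_partition`.
#' @param morphospecies named character vector (specimen -> name).
#' @return A list: `per_otu` (data frame `otu_id`, `n_members`, `n_names`,
#'   `names`), `n_otus`, `n_single_name`, `n_multi_name`,
#'   `n_split_morphospecies`.
#' @export
concordance_report <- function(final, morphospecies) {
  miss <- setdiff(names(final), names(morphospecies))
  if (length(miss))
    stop("specimens without morphospecies label: ", paste(miss, collapse = ", "))
  otus <- split(names(final), unname(final))
  per_otu <- do.call(rbind, lapply(names(otus), function(o) {
    nm <- sort(unique(morphospecies[otus[[o]]]))
    data.frame(otu_id = o, n_members = length(otus[[o]]),
               n_names = length(nm), names = paste(nm, collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  by_name <- split(unname(final[names(morphospecies)[names(morphospecies) %in%
                                                       names(final)]]),
                   morphospecies[names(morphospecies) %in% names(final)])
  n_split <- sum(vapply(by_name, function(g) length(unique(g)), integer(1)) > 1L)
  list(per_otu = per_otu,
       n_otus = length(otus),
       n_single_name = sum(per_otu$n_names == 1L),
       n_multi_name = sum(per_otu$n_names > 1L),
       n_split_morphospecies = n_split)
}
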