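#' Cluster PWMs of one TF family by similarity
#'
#' Builds the graph whose edges join pairs of PWMs with PCC >= `threshold`
#' and returns its connected components (single linkage: a chain a~b, b~c
#' puts a, b and c in one cluster even if a and c are dissimilar). Clusters
#' are ordered by decreasing size, then by the lexicographically smallest
#' member id.
#'
#' @param pwms list of `pwm` objects sharing one family label.
#' @param threshold PCC threshold (default 0.80).
#' @param min_overlap passed to [pwm_similarity()].
#' @return list of clusters; each is a list with `family`, `members` and
#'   `core` (filled by [align_and_consensus()], `NULL` here).
#' @export
cluster_by_similarity <- function(pwms, threshold = 0.80, min_overlap = NULL) {
  if (!length(pwms)) return(list())
  n <- length(pwms)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      sim <- tryCatch(pwm_similarity(pwms[[i]], pwms[[j]], min_overlap = min_overlap),
                      error = function(e) NULL)
      if (!is.null(sim) && sim$pcc >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  clusters <- lapply(comp, function(idx) {
    members <- pwms[idx]
    ids <- vapply(members, function(p) p$motif_id, character(1))
    members <- members[order(ids)]
    list(family = members[[1L]]$family, members = members, core = NULL)
  })
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  firsts <- vapply(clusters, function(cl) cl$members[[1L]]$motif_id, character(1))
  clusters <- clusters[order(-sizes, firsts)]
  names(clusters) <- NULL
  clusters
}

#' Consensus (core) motif of a motif cluster
#'
#' The member with the highest information content anchors an ungapped
#' alignment: every other member is placed at its best [pwm_similarity()]
#' offset and strand relative to the anchor, columns are averaged
#' (unweighted, or weighted by peak support) over the members covering each
#' position, positions covered by fewer than `min_coverage` members are
#' trimmed from the ends, and the result is renormalised.
#'
#' @param cluster a cluster from [cluster_by_similarity()], or a plain list
#'   of `pwm` objects.
#' @param min_members smallest cluster for which a core motif is built
#'   (default 3).
#' @param min_coverage minimum number of members covering a retained column
#'   (default 2).
#' @param weight_by_support average columns weighted by `support_peaks`
#'   instead of uniformly.
#' @param min_overlap passed to [pwm_similarity()].
#' @return consensus `pwm` whose `motif_id` is `core_<family>`.
#' @export
align_and_consensus <- function(cluster, min_members = 3L, min_coverage = 2L,
                                weight_by_support = FALSE, min_overlap = NULL) {
  members <- if (!is.null(cluster$members)) cluster$members else cluster
  if (length(members) < min_members)
    stop("a core motif requires at least ", min_members,
         " member PWMs; got ", length(members))
  ics <- vapply(members, information_content, numeric(1))
  anchor_i <- which.max(ics)
  anchor <- members[[anchor_i]]
  placed <- list()
  for (i in seq_along(members)) {
    if (i == anchor_i) {
      placed[[i]] <- list(mat = members[[i]]$matrix, offset = 0L)
    } else {
      sim <- pwm_similarity(anchor, members[[i]], min_overlap = min_overlap)
      m <- if (sim$strand == "+") members[[i]]$matrix else reverse_complement(members[[i]])$matrix
      placed[[i]] <- list(mat = m, offset = sim$offset)
    }
  }
  offs <- vapply(placed, function(p) p$offset, integer(1))
  lo <- min(1L + offs)
  hi <- max(vapply(placed, function(p) ncol(p$mat), integer(1)) + offs)
  width <- hi - lo + 1L
  acc <- matrix(0, 4L, width)
  cov <- numeric(width)
  wts <- if (weight_by_support) {
    w <- vapply(members, function(p) p$support_peaks, numeric(1))
    ifelse(is.na(w) | w <= 0, 1, w)
  } else rep(1, length(members))
  for (i in seq_along(placed)) {
    cols <- seq_len(ncol(placed[[i]]$mat)) + placed[[i]]$offset - lo + 1L
    acc[, cols] <- acc[, cols] + wts[i] * placed[[i]]$mat
    cov[cols] <- cov[cols] + wts[i] * 1
  }
  ncov <- integer(width)
  for (i in seq_along(placed)) {
    cols <- seq_len(ncol(placed[[i]]$mat)) + placed[[i]]$offset - lo + 1L
    ncov[cols] <- ncov[cols] + 1L
  }
  keep <- which(ncov >= min_coverage)
  if (!length(keep)) stop("no column covered by >= ", min_coverage, " members")
  keep <- min(keep):max(keep)
  mat <- sweep(acc[, keep, drop = FALSE], 2L, cov[keep], "/")
  mat <- sweep(mat, 2L, colSums(mat), "/")
  fam <- members[[1L]]$family
  new_pwm(mat, motif_id = paste0("core_", ifelse(is.na(fam), "family", fam)),
          tf_name = paste0("core_", ifelse(is.na(fam), "family", fam)),
          family = fam, source = "inferred")
}

#' Core motifs of a TF family
#'
#' Clusters the family's canonical PWMs by similarity and builds a
#' consensus core motif for every cluster with at least `min_members`
#' members; a family may yield several core motifs or none.
#'
#' @inheritParams cluster_by_similarity
#' @inheritParams align_and_consensus
#' @return the cluster list with `core` filled for qualifying clusters.
#' @export
family_core_motifs <- function(pwms, threshold = 0.80, min_members = 3L,
                               min_overlap = NULL, weight_by_support = FALSE) {
  clusters <- cluster_by_similarity(pwms, threshold, min_overlap)
  for (i in seq_along(clusters)) {
    if (length(clusters[[i]]$members) >= min_members) {
      clusters[[i]]$core <- align_and_consensus(
        clusters[[i]], min_members = min_members,
        weight_by_support = weight_by_support, min_overlap = min_overlap)
      clusters[[i]]$core$motif_id <- paste0(clusters[[i]]$core$motif_id, "_", i)
    }
  }
  clusters
}
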