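#' Per-peak motif composition of a TF (X / Y / Z counts)
#'
#' For every peak the presence (not multiplicity) of canonical and
#' non-canonical (co-occurring) motif hits is recorded and the peaks are
#' tallied as: X = peaks containing only the canonical motif, Y = peaks
#' containing at least one non-canonical motif but no canonical motif
#' (tethered binding), Z = peaks containing both (co-binding). Peaks with
#' neither motif contribute to `n_peaks` only.
#'
#' @param peaks `GRanges` of peaks with unique `peak_id`s.
#' @param canonical_hits,noncanonical_hits `GRanges` of motif hits already
#'   restricted to peaks (see [filter_hits_by_peaks()]).
#' @param tf_name TF label carried into the result.
#' @param canonical_source where the canonical PWM came from:
#'   `"inferred"`, `"db_fallback"` or `"unknown"`.
#' @return an object of class `binding_mode_counts` with fields `tf_name`,
#'   `X`, `Y`, `Z`, `n_peaks`, `group` and `canonical_source`.
#' @export
count_peak_motifs <- function(peaks, canonical_hits, noncanonical_hits,
                              tf_name = NA_character_,
                              canonical_source = "inferred") {
  ids <- S4Vectors::mcols(peaks)$peak_id
  if (anyDuplicated(ids))
    stop("duplicate peak ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  has_can <- IRanges::overlapsAny(peaks, canonical_hits, ignore.strand = TRUE)
  has_non <- IRanges::overlapsAny(peaks, noncanonical_hits, ignore.strand = TRUE)
  X <- sum(has_can & !has_non)
  Y <- sum(!has_can & has_non)
  Z <- sum(has_can & has_non)
  grp <- if (X + Y + Z > 0) classify_binding_group(X, Y, Z) else NA_integer_
  structure(list(tf_name = tf_name, X = X, Y = Y, Z = Z,
                 n_peaks = length(peaks), group = grp,
                 canonical_source = canonical_source),
            class = "binding_mode_counts")
}

#' @export
print.binding_mode_counts <- function(x, ...) {
  cat(sprintf("%s: X=%d Y=%d Z=%d of %d peaks -> group %s (%s canonical)\n",
              x$tf_name, x$X, x$Y, x$Z, x$n_peaks,
              ifelse(is.na(x$group), "unclassified", x$group),
              x$canonical_source))
  invisible(x)
}

#' Five-group binding-mode classification from X / Y / Z counts
#'
#' Group 1: `X > 0, Y = Z = 0` (canonical binding only); group 2:
#' `X > Y > Z`; group 3: `X > Z > Y`; group 4: `Y > X` and `Y > Z`
#' (tethered binding most frequent); group 5: `Z > X` and `Z > Y`
#' (co-binding most frequent). Configurations satisfying none of the strict
#' rules (ties such as `X = Y > Z`) are returned as `NA` with attribute
#' `reason = "tie"`.
#'
#' @param X,Y,Z non-negative integer peak counts, not all zero.
#' @return integer group in 1..5, or `NA` for tied configurations.
#' @export
classify_binding_group <- function(X, Y, Z) {
  if (any(c(X, Y, Z) < 0)) stop("X, Y, Z must be non-negative")
  if (X == 0 && Y == 0 && Z == 0) stop("no motif evidence: X = Y = Z = 0")
  if (X > 0 && Y == 0 && Z == 0) return(1L)
  if (X > Y && Y > Z) return(2L)
  if (X > Z && Z > Y) return(3L)
  if (Y > X && Y > Z) return(4L)
  if (Z > X && Z > Y) return(5L)
  structure(NA_integer_, reason = "tie")
}

#' Database-fallback canonical PWM for a TF
#'
#' When no canonical motif could be inferred from the ChIP-seq data, the
#' TF's canonical PWM is looked up in the reference databases; if several
#' entries exist, the one with the highest information content wins (ties
#' broken by the lexicographically smaller motif id).
#'
#' @param tf_name TF whose canonical motif is sought.
#' @param dbs a `motif_db` or list of `motif_db` objects.
#' @return the selected `pwm`, or `NULL` when no database has an entry.
#' @export
fallback_canonical <- function(tf_name, dbs) {
  if (is(dbs, "motif_db")) dbs <- list(dbs)
  cands <- list()
  for (db in dbs)
    cands <- c(cands, Filter(function(p) identical(p$tf_name, tf_name), db$entries))
  if (!length(cands)) return(NULL)
  ics <- vapply(cands, information_content, numeric(1))
  ids <- vapply(cands, function(p) p$motif_id, character(1))
  cands[[order(-ics, ids)[1L]]]
}

#' End-to-head distance between two motif hits in the same peak
#'
#' The gap in bp from the end of the upstream-most motif to the start of
#' the downstream motif, in coordinate order and irrespective of strand.
#' Overlapping motifs give a negative gap, which is reported as-is.
#'
#' @param hit_a,hit_b single-interval `GRanges` hits carrying a `peak_id`
#'   metadata column.
#' @return integer gap in bp.
#' @export
pair_distance <- function(hit_a, hit_b) {
  pa <- S4Vectors::mcols(hit_a)$peak_id
  pb <- S4Vectors::mcols(hit_b)$peak_id
  if (!is.null(pa) && !is.null(pb) && !identical(as.character(pa), as.character(pb)))
    stop("hits are in different peaks: ", pa, " vs ", pb)
  a <- c(GenomicRanges::start(hit_a), GenomicRanges::end(hit_a))
  b <- c(GenomicRanges::start(hit_b), GenomicRanges::end(hit_b))
  if (a[1L] <= b[1L]) b[1L] - a[2L] - 1L else a[1L] - b[2L] - 1L
}

#' Type a co-occurring TF pair through the protein-interaction network
#'
#' A pair of TFs whose motifs co-occur in peaks is typed by the shortest
#' path between them in an undirected protein-protein interaction network:
#' the same TF twice is `G3` (one TF binding two nearby motifs); a direct
#' edge is `G1`; a path through exactly one co-factor is `G2_N1`; a longer
#' path is `G2_Ngt1`. Pairs with no path, or with a TF absent from the
#' network, are `untyped`.
#'
#' @param tf1,tf2 TF names.
#' @param ppi an `igraph` graph or a two-column edge data frame / matrix.
#' @return list with `type` (`"G1"`, `"G2_N1"`, `"G2_Ngt1"`, `"G3"` or
#'   `"untyped"`) and `path_len` (edge count; 0 for `G3`, `NA` when
#'   untyped).
#' @export
classify_cooccurrence <- function(tf1, tf2, ppi) {
  g <- as_ppi_graph(ppi)
  if (identical(tf1, tf2)) return(list(type = "G3", path_len = 0L))
  if (!(tf1 %in% igraph::V(g)$name) || !(tf2 %in% igraph::V(g)$name))
    return(list(type = "untyped", path_len = NA_integer_))
  d <- igraph::distances(g, v = tf1, to = tf2)[1L, 1L]
  if (!is.finite(d)) return(list(type = "untyped", path_len = NA_integer_))
  d <- as.integer(d)
  type <- if (d == 1L) "G1" else if (d == 2L) "G2_N1" else "G2_Ngt1"
  list(type = type, path_len = d)
}

as_ppi_graph <- function(ppi) {
  if (is(ppi, "igraph")) return(ppi)
  el <- as.matrix(ppi)[, 1:2, drop = FALSE]
  igraph::graph_from_edgelist(apply(el, 2L, as.character), directed = FALSE)
}

#' Read a protein-interaction edge list
#'
#' @param path two-column TSV of interacting protein names (header
#'   optional, detected from the first line).
#' @return an undirected `igraph` graph.
#' @export
read_ppi <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("node|protein|tf", tolower(first))
  tab <- read.delim(path, header = header, stringsAsFactors = FALSE)
  as_ppi_graph(tab)
}

#' Summarise binding-mode groups over TFs
#'
#' @param modes a list of `binding_mode_counts`, a data frame with columns
#'   `group` and `canonical_source`, or a named/ordered numeric vector of
#'   per-group TF counts (groups 1..5).
#' @return list with `summary` (data frame: group, count, percent --
#'   percentages of classified TFs, rounded to whole percent), `n_classified`,
#'   `n_tied` and `unknown_canonical` (TF names with no known canonical
#'   motif, when available).
#' @export
summarize_modes <- function(modes) {
  unknown <- character(0)
  tied <- 0L
  if (is.numeric(modes)) {
    counts <- as.integer(modes)
    if (length(counts) != 5L) stop("expected 5 group counts")
  } else {
    if (is.list(modes) && !is.data.frame(modes)) {
      modes <- do.call(rbind, lapply(modes, function(m)
        data.frame(tf_name = m$tf_name, group = as.integer(m$group),
                   canonical_source = m$canonical_source)))
    }
    unknown <- modes$tf_name[modes$canonical_source == "unknown"]
    tied <- sum(is.na(modes$group))
    counts <- vapply(1:5, function(g) sum(modes$group == g, na.rm = TRUE), integer(1))
  }
  n <- sum(counts)
  pct <- if (n > 0) round(100 * counts / n) else rep(NA_real_, 5L)
  list(summary = data.frame(group = 1:5, count = counts, percent = pct),
       n_classified = n, n_tied = tied, unknown_canonical = unknown)
}

#' Overlap-share percentage
#'
#' Convenience for reporting what percentage of a set of TFs falls in an
#' overlap category (e.g. the share of co-factor-mediated co-binding TFs
#' that also bind multiple own sites).
#'
#' @param n count in the category.
#' @param total category denominator.
#' @return `100 * n / total`.
#' @export
percent_share <- function(n, total) {
  if (total <= 0) stop("total must be positive")
  100 * sum(n) / total
}

#' Extrapolate the promoter TFBS load to the full TF repertoire
#'
#' Given the mean number of binding sites per promoter observed for a
#' studied subset of TFs, estimates the mean for the complete TF repertoire
#' by linear scaling: `mean_sites * n_total / n_studied`. The estimate is
#' an upper bound since related TFs can share sites.
#'
#' @param mean_sites observed mean TFBSs per promoter.
#' @param n_total size of the full TF repertoire.
#' @param n_studied number of TFs contributing to `mean_sites`.
#' @return extrapolated mean TFBSs per promoter.
#' @export
extrapolate_promoter_load <- function(mean_sites, n_total, n_studied) {
  if (n_studied <= 0) stop("n_studied must be positive")
  mean_sites * n_total / n_studied
}
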