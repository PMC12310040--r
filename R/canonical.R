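#' Best database match for a PWM
#'
#' Finds the database motif with the highest PCC to the query among entries
#' passing the family filter, provided that PCC reaches `threshold`. Ties
#' on PCC are broken towards the database motif with the higher information
#' content, then the lexicographically smaller motif id.
#'
#' @param pwm query `pwm`; its `family` field drives the filter.
#' @param db a `motif_db`.
#' @param family_filter `"same"` (same family as the query), `"other"`
#'   (any different family) or `"any"`.
#' @param threshold minimum PCC to call a match (default 0.80).
#' @param min_overlap passed to [pwm_similarity()].
#' @return `NULL` when nothing matches, otherwise a list with elements
#'   `db_pwm` and `similarity`.
#' @export
best_db_match <- function(pwm, db, family_filter = c("same", "other", "any"),
                          threshold = 0.80, min_overlap = NULL) {
  family_filter <- match.arg(family_filter)
  stopifnot(is(db, "motif_db"))
  fams <- db_families(db)
  keep <- switch(family_filter,
                 same = !is.na(fams) & fams == pwm$family,
                 other = is.na(fams) | fams != pwm$family,
                 any = rep(TRUE, length(fams)))
  entries <- db$entries[keep]
  best <- NULL
  for (e in entries) {
    sim <- tryCatch(pwm_similarity(pwm, e, min_overlap = min_overlap),
                    error = function(err) NULL)
    if (is.null(sim) || sim$pcc < threshold) next
    if (is.null(best) ||
        sim$pcc > best$similarity$pcc + 1e-12 ||
        (abs(sim$pcc - best$similarity$pcc) <= 1e-12 &&
         (information_content(e) > information_content(best$db_pwm) ||
          (information_content(e) == information_content(best$db_pwm) &&
           e$motif_id < best$db_pwm$motif_id)))) {
      best <- list(db_pwm = e, similarity = sim)
    }
  }
  best
}

#' Does a PWM contain a known motif as a sub-motif plus extra sequence?
#'
#' A long inferred PWM sometimes embeds a window that is highly similar to a
#' canonical motif while carrying an additional, informative flanking
#' signal; such a PWM is not itself canonical. The test requires that (i)
#' some window of the query at the canonical's width reaches PCC >=
#' `threshold` with the canonical, (ii) the full-length correlation -- all
#' query columns against the canonical padded with uniform background --
#' stays below `threshold` (informative extra sequence dilutes it,
#' uninformative flanks do not), and (iii) the non-matching flank has at
#' least `flank_min_cols` columns with information content >=
#' `flank_min_ic` bits.
#'
#' @param pwm query `pwm`, wider than `canonical`.
#' @param canonical reference canonical `pwm`.
#' @param threshold PCC similarity threshold (default 0.80).
#' @param flank_min_cols minimum number of informative flank columns.
#' @param flank_min_ic per-column IC (bits) for a flank column to count as
#'   informative.
#' @return `TRUE` when the query looks like canonical-plus-extra-sequence.
#' @export
contains_submotif <- function(pwm, canonical, threshold = 0.80,
                              flank_min_cols = 3L, flank_min_ic = 0.5) {
  wq <- pwm_width(pwm); wc <- pwm_width(canonical)
  if (wq <= wc) return(FALSE)
  # full-length view: correlate ALL query columns against the canonical
  # padded with uniform background outside its span, over every placement
  # and both strands. Informative extra sequence dilutes this correlation;
  # uninformative (near-uniform) flanks do not.
  full_pcc <- -1
  for (cm in list(canonical$matrix, reverse_complement(canonical)$matrix)) {
    for (s in seq_len(wq - wc + 1L)) {
      padded <- matrix(0.25, 4L, wq)
      padded[, s:(s + wc - 1L)] <- cm
      r <- if (sd(padded) == 0 || sd(pwm$matrix) == 0) 0 else
        cor(as.vector(pwm$matrix), as.vector(padded))
      if (r > full_pcc) full_pcc <- r
    }
  }
  if (full_pcc >= threshold) return(FALSE)
  ic <- information_content(pwm, per_column = TRUE)
  for (s in seq_len(wq - wc + 1L)) {
    win <- new_pwm(pwm$matrix[, s:(s + wc - 1L), drop = FALSE],
                   motif_id = paste0(pwm$motif_id, "_win"))
    sim <- pwm_similarity(win, canonical, min_overlap = wc)
    if (sim$pcc < threshold) next
    flank_ic <- ic[setdiff(seq_len(wq), s:(s + wc - 1L))]
    if (sum(flank_ic >= flank_min_ic) >= flank_min_cols) return(TRUE)
  }
  FALSE
}

#' Classify the inferred motifs of a TF as canonical / candidate / none
#'
#' Implements the canonical-PWM decision procedure. PWMs supported by fewer
#' than `min_support` peaks are dropped first. Then:
#'
#' 1. Every remaining PWM that is similar (PCC >= `threshold`) to a
#'    database canonical of the TF's own family -- and that is not merely a
#'    wider motif containing it as a sub-motif -- is canonical; the one most
#'    similar to the database is the representative.
#' 2. Otherwise, if the top-ranked PWM is similar to no database motif in
#'    any family, it becomes the "candidate canonical" PWM (it may match a
#'    motif not yet characterised).
#' 3. Otherwise the PWMs are walked in rank order: each one matching another
#'    family's canonical is recorded as a co-occurring motif. If no PWM of
#'    the TF's own family is ever found the verdict is `none`.
#'
#' Co-occurring motifs (matches to other families) are recorded in every
#' case.
#'
#' @param tf_name TF name.
#' @param family the TF's family label.
#' @param inferred list of `pwm` objects, sorted by rank (1 = top).
#' @param db a `motif_db` of known canonical motifs with family labels.
#' @param threshold PCC similarity threshold (default 0.80).
#' @param min_support minimum peak support for an inferred PWM to be
#'   considered (default 100).
#' @param min_overlap passed to [pwm_similarity()].
#' @return an object of class `canonical_call` with fields `tf_name`,
#'   `family`, `status` (`"canonical"`, `"candidate_canonical"` or
#'   `"none"`), `representative`, `canonical_set` and `co_occurring` (a
#'   data frame with one row per other-family match).
#' @export
classify_tf_motifs <- function(tf_name, family, inferred, db,
                               threshold = 0.80, min_support = 100L,
                               min_overlap = NULL) {
  stopifnot(is(db, "motif_db"))
  inferred <- Filter(function(p) is.na(p$support_peaks) ||
                       p$support_peaks >= min_support, inferred)
  co <- data.frame(motif_id = character(0), matched_db_motif_id = character(0),
                   matched_family = character(0), pcc = numeric(0))
  call_obj <- function(status, representative, canonical_set) {
    structure(list(tf_name = tf_name, family = family, status = status,
                   representative = representative,
                   canonical_set = canonical_set, co_occurring = co),
              class = "canonical_call")
  }
  if (!length(inferred)) return(call_obj("none", NULL, list()))
  for (i in seq_along(inferred)) inferred[[i]]$family <- family

  same <- lapply(inferred, best_db_match, db = db, family_filter = "same",
                 threshold = threshold, min_overlap = min_overlap)
  other <- lapply(inferred, best_db_match, db = db, family_filter = "other",
                  threshold = threshold, min_overlap = min_overlap)
  for (i in seq_along(inferred)) {
    if (!is.null(other[[i]])) {
      co <- rbind(co, data.frame(motif_id = inferred[[i]]$motif_id,
                                 matched_db_motif_id = other[[i]]$db_pwm$motif_id,
                                 matched_family = other[[i]]$db_pwm$family,
                                 pcc = other[[i]]$similarity$pcc))
    }
  }

  is_same <- !vapply(same, is.null, logical(1))
  if (any(is_same)) {
    idx <- which(is_same)
    # reject wider PWMs that merely contain the best-matching canonical
    best_i <- idx[which.max(vapply(same[idx], function(m) m$similarity$pcc, numeric(1)))]
    ref_db <- same[[best_i]]$db_pwm
    ok <- vapply(idx, function(i) !contains_submotif(inferred[[i]], ref_db,
                                                     threshold = threshold),
                 logical(1))
    idx <- idx[ok]
    if (length(idx)) {
      pccs <- vapply(same[idx], function(m) m$similarity$pcc, numeric(1))
      ranks <- vapply(inferred[idx], function(p) ifelse(is.na(p$rank), .Machine$integer.max, p$rank), numeric(1))
      ids <- vapply(inferred[idx], function(p) p$motif_id, character(1))
      rep_i <- idx[order(-pccs, ranks, ids)][1L]
      return(call_obj("canonical", inferred[[rep_i]], inferred[idx]))
    }
  }

  top <- inferred[[1L]]
  top_any <- best_db_match(top, db, "any", threshold, min_overlap)
  if (is.null(top_any))
    return(call_obj("candidate_canonical", top, list(top)))
  call_obj("none", NULL, list())
}

#' @export
print.canonical_call <- function(x, ...) {
  cat("TF ", x$tf_name, " (", x$family, "): ", x$status, sep = "")
  if (!is.null(x$representative))
    cat(", representative ", x$representative$motif_id, sep = "")
  cat("; ", nrow(x$co_occurring), " co-occurring motif(s)\n", sep = "")
  invisible(x)
}

#' Merge a motif that was inferred as two split halves
#'
#' When a single long binding motif is recovered as two separate PWMs,
#' their hits co-occur in most shared peaks at a short, nearly constant
#' end-to-head gap. If a modal gap `g` with `0 <= g <= max_gap` accounts for
#' more than half of the observed co-occurrences, the two PWMs are
#' concatenated with `g` uniform spacer columns at that gap.
#'
#' @param pwm_a,pwm_b the two `pwm` halves, in genomic order (a upstream).
#' @param gaps integer vector of observed end-to-head gaps (bp) between the
#'   two motifs' hits across shared peaks, same strand.
#' @param max_gap largest allowed modal gap (default 4 bp).
#' @param min_frac fraction of co-occurrences the modal gap must reach
#'   (default 0.5, exclusive).
#' @return merged `pwm`; provenance of both parents is kept in a
#'   `parents` attribute.
#' @export
merge_split_motifs <- function(pwm_a, pwm_b, gaps, max_gap = 4L, min_frac = 0.5) {
  stopifnot(is_pwm(pwm_a), is_pwm(pwm_b))
  if (!length(gaps)) stop("no co-occurring hit pairs supplied")
  tab <- table(gaps)
  modal <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) <= min_frac * length(gaps) || modal < 0L || modal > max_gap)
    stop("no consistent modal gap: the most frequent gap (", modal,
         " bp, ", max(tab), "/", length(gaps),
         " pairs) does not support a merge")
  spacer <- matrix(0.25, nrow = 4L, ncol = modal)
  merged <- new_pwm(cbind(pwm_a$matrix, spacer, pwm_b$matrix),
                    motif_id = paste0(pwm_a$motif_id, "+", pwm_b$motif_id),
                    tf_name = pwm_a$tf_name, family = pwm_a$family,
                    support_peaks = min(pwm_a$support_peaks, pwm_b$support_peaks),
                    rank = min(pwm_a$rank, pwm_b$rank),
                    source = pwm_a$source)
  attr(merged, "parents") <- c(pwm_a$motif_id, pwm_b$motif_id)
  attr(merged, "gap") <- modal
  merged
}
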