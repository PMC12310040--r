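#' Pearson-correlation similarity between two PWMs
#'
#' Slides motif `b` (and its reverse complement) along motif `a` over every
#' ungapped offset whose overlap is at least `min_overlap` columns, computes
#' the Pearson correlation between the two flattened 4 x L overlapping
#' sub-matrices, and returns the best alignment. Two motifs are conventionally
#' called similar when the returned PCC is at least 0.80.
#'
#' Ties on PCC are broken by larger overlap, then by the + strand, then by
#' the smaller absolute offset. An alignment in which either overlapping
#' sub-matrix is constant (zero variance) gets PCC 0.
#'
#' @param a,b `pwm` objects.
#' @param min_overlap minimum number of overlapping columns; default
#'   `min(width(a), width(b), 5)`.
#' @return a list of class `pwm_similarity` with elements `pcc`, `offset`
#'   (columns of `b`, as oriented, shifted right relative to `a`), `strand`
#'   (`"+"` if `b` aligned as given, `"-"` if reverse-complemented) and
#'   `overlap_len`.
#' @export
pwm_similarity <- function(a, b, min_overlap = NULL) {
  stopifnot(is_pwm(a), is_pwm(b))
  wa <- pwm_width(a); wb <- pwm_width(b)
  if (is.null(min_overlap)) min_overlap <- min(wa, wb, 5L)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (min_overlap > min(wa, wb))
    stop("overlap of ", min_overlap, " columns impossible for widths ",
         wa, " and ", wb)
  best <- NULL
  for (strand in c("+", "-")) {
    mb <- if (strand == "+") b$matrix else reverse_complement(b)$matrix
    for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
      lo <- max(1L, 1L + off); hi <- min(wa, wb + off)
      L <- hi - lo + 1L
      if (L < min_overlap) next
      va <- as.vector(a$matrix[, lo:hi, drop = FALSE])
      vb <- as.vector(mb[, (lo - off):(hi - off), drop = FALSE])
      pcc <- if (sd(va) == 0 || sd(vb) == 0) 0 else cor(va, vb)
      cand <- list(pcc = pcc, offset = off, strand = strand, overlap_len = L)
      if (is.null(best) || better_alignment(cand, best)) best <- cand
    }
  }
  class(best) <- "pwm_similarity"
  best
}

better_alignment <- function(x, y, eps = 1e-12) {
  if (x$pcc > y$pcc + eps) return(TRUE)
  if (x$pcc < y$pcc - eps) return(FALSE)
  if (x$overlap_len != y$overlap_len) return(x$overlap_len > y$overlap_len)
  if (x$strand != y$strand) return(x$strand == "+")
  abs(x$offset) < abs(y$offset)
}

#' @export
print.pwm_similarity <- function(x, ...) {
  cat(sprintf("PCC %.4f at offset %+d, strand %s, %d overlapping columns\n",
              x$pcc, x$offset, x$strand, x$overlap_len))
  invisible(x)
}
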