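#' @importFrom methods is
#' @importFrom stats cor density quantile rnorm runif rbinom prcomp sd setNames
#' @importFrom utils head modifyList read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix (PWM) object
#'
#' A PWM describes the per-position nucleotide preference of a transcription
#' factor binding site as a column-stochastic 4 x w probability matrix with
#' rows ordered A, C, G, T.
#'
#' @param matrix numeric 4 x w matrix of probabilities; rows A, C, G, T.
#'   Columns are renormalised to sum exactly to 1 provided each column sum is
#'   already within `tol` of 1.
#' @param motif_id unique motif identifier.
#' @param tf_name transcription factor name (defaults to `motif_id`).
#' @param family TF family label (e.g. "bZIP", "C2H2-ZF") or `NA`.
#' @param support_peaks number of ChIP-seq peaks supporting the motif
#'   (`NA` when unknown, e.g. for database motifs).
#' @param rank rank of the motif within its experiment (1 = top motif).
#' @param source provenance: `"inferred"`, `"database_selex"` (CIS-BP-like
#'   in vitro data) or `"database_curated"` (JASPAR-like curation).
#' @param tol maximum tolerated deviation of a column sum from 1.
#'
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(matrix, motif_id, tf_name = motif_id, family = NA_character_,
                    support_peaks = NA_integer_, rank = NA_integer_,
                    source = "inferred", tol = 0.01) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L)
    stop("PWM matrix must have 4 rows (A, C, G, T); got ", nrow(matrix))
  w <- ncol(matrix)
  if (w < 4L || w > 50L)
    stop("PWM width must be between 4 and 50 columns; motif '", motif_id,
         "' has width ", w)
  if (any(matrix < 0))
    stop("PWM matrix for '", motif_id, "' contains negative entries")
  csums <- colSums(matrix)
  bad <- which(abs(csums - 1) > tol)
  if (length(bad))
    stop("PWM '", motif_id, "' has column(s) ", paste(bad, collapse = ", "),
         " with probabilities summing to ",
         paste(signif(csums[bad], 4), collapse = ", "), " (outside 1 ± ", tol, ")")
  matrix <- sweep(matrix, 2L, csums, "/")
  dimnames(matrix) <- list(DNA_BASES, NULL)
  structure(list(motif_id = as.character(motif_id),
                 tf_name = as.character(tf_name),
                 family = as.character(family),
                 matrix = matrix,
                 support_peaks = if (is.na(support_peaks)) NA_integer_ else as.integer(support_peaks),
                 rank = if (is.na(rank)) NA_integer_ else as.integer(rank),
                 source = source),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM ", x$motif_id, " (", x$tf_name,
      if (!is.na(x$family)) paste0(", ", x$family), "), width ",
      pwm_width(x), ", IC ", round(information_content(x), 1), " bits",
      if (!is.na(x$support_peaks)) paste0(", support ", x$support_peaks, " peaks"),
      "\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Width of a PWM in columns
#' @param pwm a `pwm` object.
#' @return integer number of columns.
#' @export
pwm_width <- function(pwm) ncol(pwm$matrix)

is_pwm <- function(x) inherits(x, "pwm")

#' Reverse complement of a PWM
#'
#' Reverses the column order and swaps A with T and C with G within each
#' column, giving the binding preference read from the opposite strand.
#'
#' @param pwm a `pwm` object.
#' @return a `pwm` object with the same metadata and `motif_id`.
#' @export
reverse_complement <- function(pwm) {
  stopifnot(is_pwm(pwm))
  m <- pwm$matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$matrix))), drop = FALSE]
  rownames(m) <- DNA_BASES
  out <- pwm
  out$matrix <- m
  out
}

#' Information content of a PWM
#'
#' Per column the information content relative to a uniform background is
#' `2 + sum_b p_b log2 p_b` bits, with `0 * log2(0)` taken as 0; the motif IC
#' is the sum over columns.
#'
#' @param pwm a `pwm` object.
#' @param per_column if `TRUE` return the per-column IC vector instead of the
#'   total.
#' @return total IC in bits, or a vector of per-column ICs.
#' @export
information_content <- function(pwm, per_column = FALSE) {
  m <- pwm$matrix
  plogp <- ifelse(m > 0, m * log2(m), 0)
  ic <- 2 + colSums(plogp)
  if (per_column) ic else sum(ic)
}

#' Consensus sequence of a PWM
#'
#' The most probable base at each position (ties broken by alphabet order).
#'
#' @param pwm a `pwm` object.
#' @return a character string over A, C, G, T.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$matrix, 2L, which.max)], collapse = "")
}

#' Motif database
#'
#' A named collection of PWMs with unique motif ids, standing in for a
#' reference motif resource (a SELEX-derived collection in the CIS-BP role or
#' a curated collection in the JASPAR role).
#'
#' @param pwms list of `pwm` objects.
#' @param name database name.
#' @return an object of class `motif_db`.
#' @export
motif_db <- function(pwms, name = "db") {
  stopifnot(all(vapply(pwms, is_pwm, logical(1))))
  ids <- vapply(pwms, function(p) p$motif_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate motif_id in database: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(pwms) <- ids
  structure(list(entries = pwms, name = name), class = "motif_db")
}

#' @export
print.motif_db <- function(x, ...) {
  fams <- vapply(x$entries, function(p) p$family, character(1))
  cat("motif_db '", x$name, "': ", length(x$entries), " motifs, ",
      length(unique(fams[!is.na(fams)])), " families\n", sep = "")
  invisible(x)
}

#' @export
length.motif_db <- function(x) length(x$entries)

db_families <- function(db) vapply(db$entries, function(p) p$family, character(1))
db_tf_names <- function(db) vapply(db$entries, function(p) p$tf_name, character(1))
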