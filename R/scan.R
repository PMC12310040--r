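#' Log-odds score matrix for a PWM
#'
#' Per cell the score in bits is `log2((p + eps * b) / ((1 + eps) * b))`,
#' mixing the motif probability `p` with the background probability `b`
#' through the pseudocount fraction `eps`; any positive `eps` keeps all
#' entries finite.
#'
#' @param pwm a `pwm` object.
#' @param background background nucleotide probabilities (A, C, G, T),
#'   summing to 1; all entries must be positive.
#' @param pseudocount pseudocount fraction `eps` (default 0.01).
#' @return 4 x w numeric matrix of scores in bits.
#' @export
log_odds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.01) {
  stopifnot(is_pwm(pwm))
  if (any(background <= 0)) stop("background probabilities must all be positive")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  log2(sweep(pwm$matrix, 1L, pseudocount * background, "+") /
         ((1 + pseudocount) * background))
}

#' Exact p-values for PWM scores by dynamic programming
#'
#' Discretises the log-odds column scores to `1/granularity` bits and
#' convolves the per-column score distributions under an i.i.d. background
#' model, yielding the exact null distribution of the score of a random
#' w-mer. The resulting table maps any attainable score to
#' `P(score >= s)` and is monotone non-increasing in `s`.
#'
#' @inheritParams log_odds
#' @param granularity number of score bins per bit (>= 1000); the
#'   discretisation error of a word score is bounded by `w / granularity`
#'   bits.
#' @return an object of class `score_pvalue_table`.
#' @export
score_pvalue_table <- function(pwm, background = rep(0.25, 4),
                               pseudocount = 0.01, granularity = 1000L) {
  if (granularity < 1000L) stop("granularity must be >= 1000")
  S <- log_odds(pwm, background, pseudocount)
  ints <- round(S * granularity)
  col_min <- apply(ints, 2L, min)
  dp <- 1
  for (j in seq_len(ncol(ints))) {
    shifted <- ints[, j] - col_min[j]
    new <- numeric(length(dp) + max(shifted))
    for (b in 1:4) {
      k <- shifted[b]
      idx <- seq_along(dp) + k
      new[idx] <- new[idx] + dp * background[b]
    }
    dp <- new
  }
  pvals <- rev(cumsum(rev(dp)))
  pvals <- pmin(pvals, 1)
  structure(list(int_scores = ints, min_int = sum(col_min), pvals = pvals,
                 granularity = granularity, background = background,
                 motif_id = pwm$motif_id, width = ncol(ints)),
            class = "score_pvalue_table")
}

#' Look up the p-value of a score
#'
#' @param table a `score_pvalue_table`.
#' @param score score(s) in bits, or integer bin scores when
#'   `integer_scale = TRUE`.
#' @param integer_scale whether `score` is already on the table's integer
#'   bin scale.
#' @return p-value(s) `P(score >= s)` under the background model.
#' @export
score_pvalue <- function(table, score, integer_scale = FALSE) {
  int <- if (integer_scale) score else round(score * table$granularity)
  idx <- int - table$min_int + 1L
  idx <- pmax(1L, idx)
  p <- rep(0, length(idx))
  inside <- idx <= length(table$pvals)
  p[inside] <- table$pvals[idx[inside]]
  p
}

encode_dna <- function(sequence) {
  if (is(sequence, "DNAString") || is(sequence, "DNAStringSet"))
    sequence <- as.character(sequence)
  chars <- strsplit(toupper(sequence), "")[[1]]
  match(chars, DNA_BASES)  # N and anything else -> NA
}

#' Scan a DNA sequence with a PWM
#'
#' FIMO-style scanning: both strands of the sequence are scored with the
#' PWM's log-odds matrix and every window whose exact p-value is at or below
#' `p_threshold` is reported. Windows containing `N` (or any non-ACGT
#' letter) are skipped. Minus-strand windows are scored with the reverse
#' complement of the PWM and reported on the forward coordinate system.
#'
#' @param sequence character scalar, `DNAString`, or `DNAStringSet` of
#'   length 1.
#' @param pwm a `pwm` object.
#' @param p_threshold report hits with `p <= p_threshold` (default 1e-4).
#' @param chrom optional chromosome/sequence name attached to the hits.
#' @param table optional precomputed `score_pvalue_table` for `pwm` (must
#'   match `background`/`pseudocount`).
#' @inheritParams score_pvalue_table
#' @return data frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive), `strand`, `motif_id`, `score` (bits) and `p_value`,
#'   ordered by `start`.
#' @export
scan <- function(sequence, pwm, p_threshold = 1e-4, chrom = NA_character_,
                 background = rep(0.25, 4), pseudocount = 0.01,
                 granularity = 1000L, table = NULL) {
  stopifnot(is_pwm(pwm))
  if (is.null(table))
    table <- score_pvalue_table(pwm, background, pseudocount, granularity)
  code <- encode_dna(sequence)
  w <- table$width
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), motif_id = character(0),
                      score = numeric(0), p_value = numeric(0))
  n <- length(code)
  if (n < w) return(empty)
  nw <- n - w + 1L
  ints_fwd <- table$int_scores
  ints_rev <- ints_fwd[4:1, w:1, drop = FALSE]  # reverse complement scores
  res <- list()
  for (strand in c("+", "-")) {
    ints <- if (strand == "+") ints_fwd else ints_rev
    sc <- numeric(nw)
    for (j in seq_len(w)) sc <- sc + ints[cbind(code[j:(j + nw - 1L)], j)]
    valid <- which(!is.na(sc))
    if (!length(valid)) next
    p <- score_pvalue(table, sc[valid], integer_scale = TRUE)
    keep <- p <= p_threshold
    if (!any(keep)) next
    pos <- valid[keep]
    res[[strand]] <- data.frame(chrom = chrom, start = pos, end = pos + w - 1L,
                                strand = strand, motif_id = pwm$motif_id,
                                score = sc[pos] / table$granularity,
                                p_value = p[keep])
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a genome with one or more PWMs
#'
#' Runs [scan()] over every sequence of a genome and returns the hits as a
#' `GRanges` with metadata columns `motif_id`, `score` and `p_value`.
#'
#' @param genome a named `DNAStringSet` (or named character vector of
#'   sequences).
#' @param pwms a `pwm`, a list of `pwm` objects, or a `motif_db`.
#' @inheritParams scan
#' @return a `GRanges` of motif hits.
#' @export
scan_genome <- function(genome, pwms, p_threshold = 1e-4,
                        background = rep(0.25, 4), pseudocount = 0.01,
                        granularity = 1000L) {
  if (is_pwm(pwms)) pwms <- list(pwms)
  if (is(pwms, "motif_db")) pwms <- pwms$entries
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  parts <- list()
  for (p in pwms) {
    tab <- score_pvalue_table(p, background, pseudocount, granularity)
    for (chr in names(genome)) {
      h <- scan(genome[[chr]], p, p_threshold, chrom = chr, table = tab)
      if (nrow(h)) parts[[length(parts) + 1L]] <- h
    }
  }
  if (!length(parts)) {
    return(GenomicRanges::GRanges(seqlengths = seqlens,
                                  motif_id = character(0), score = numeric(0),
                                  p_value = numeric(0)))
  }
  df <- do.call(rbind, parts)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$end),
                         strand = df$strand,
                         motif_id = df$motif_id, score = df$score,
                         p_value = df$p_value, seqlengths = seqlens)
}

#' Build summit-centred peaks
#'
#' Each ChIP-seq binding event is represented by the 200-bp interval
#' obtained by extending 100 bp on either side of its summit (in BED
#' coordinates `[summit - 100, summit + 100)`), clipped at chromosome
#' bounds when sequence lengths are supplied.
#'
#' @param chrom chromosome names.
#' @param summit 1-based summit positions.
#' @param signal peak signal values (e.g. fold enrichment), >= 0.
#' @param experiment_id experiment label(s).
#' @param peak_id unique peak identifiers; generated when `NULL`.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return a `GRanges` with metadata columns `summit`, `signal`,
#'   `experiment_id` and `peak_id`.
#' @export
make_peaks <- function(chrom, summit, signal, experiment_id = "exp1",
                       peak_id = NULL, seqlengths = NULL) {
  start <- pmax(1L, as.integer(summit) - 100L)
  end <- as.integer(summit) + 99L
  if (!is.null(seqlengths)) end <- pmin(end, seqlengths[chrom])
  if (is.null(peak_id)) peak_id <- sprintf("peak_%05d", seq_along(summit))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               summit = as.integer(summit), signal = signal,
                               experiment_id = experiment_id, peak_id = peak_id)
  if (!is.null(seqlengths)) GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Keep motif hits that overlap ChIP-seq peaks
#'
#' A hit is retained iff it overlaps at least one peak by at least 1 bp;
#' the id of the (first) overlapping peak is attached as `peak_id`. The
#' operation is idempotent and its output is always a subset of its input.
#'
#' @param hits `GRanges` of motif hits.
#' @param peaks `GRanges` of peaks with a `peak_id` metadata column.
#' @return the retained hits with a `peak_id` column.
#' @export
filter_hits_by_peaks <- function(hits, peaks) {
  ov <- GenomicRanges::findOverlaps(hits, peaks, minoverlap = 1L,
                                    ignore.strand = TRUE, select = "first")
  keep <- !is.na(ov)
  out <- hits[keep]
  S4Vectors::mcols(out)$peak_id <- S4Vectors::mcols(peaks)$peak_id[ov[keep]]
  out
}

#' Select the top peaks across experiments
#'
#' Peaks overlapping the blacklist are removed first. With a single
#' experiment the `k` highest-signal peaks are returned (default k = 500).
#' With two or more experiments, peaks are ranked by signal within each
#' experiment and merged by best rank (ties broken by signal), taking the
#' top `k` overall (default k = 1000); this rank merge stands in for
#' cross-experiment peak prioritisation schemes used upstream of motif
#' discovery.
#'
#' @param experiments a `GRanges` of peaks (single experiment) or a list of
#'   `GRanges`, one per experiment; each needs `signal` metadata.
#' @param k number of peaks to keep; defaults to 500 for one experiment and
#'   1000 for several.
#' @param blacklist optional `GRanges` of regions whose peaks are excluded.
#' @return a `GRanges` of at most `k` peaks, best first.
#' @export
select_top_peaks <- function(experiments, k = NULL, blacklist = NULL) {
  if (is(experiments, "GRanges")) experiments <- list(experiments)
  if (is.null(k)) k <- if (length(experiments) == 1L) 500L else 1000L
  if (k <= 0) stop("k must be positive")
  drop_bl <- function(gr) {
    if (is.null(blacklist)) return(gr)
    gr[!IRanges::overlapsAny(gr, blacklist, ignore.strand = TRUE)]
  }
  experiments <- lapply(experiments, drop_bl)
  if (length(experiments) == 1L) {
    gr <- experiments[[1L]]
    ord <- order(-S4Vectors::mcols(gr)$signal)
    return(gr[head(ord, k)])
  }
  ranked <- lapply(experiments, function(gr) {
    gr[order(-S4Vectors::mcols(gr)$signal)]
  })
  all <- suppressWarnings(do.call(c, lapply(ranked, function(gr) {
    S4Vectors::mcols(gr)$exp_rank <- seq_along(gr)
    gr
  })))
  ord <- order(S4Vectors::mcols(all)$exp_rank, -S4Vectors::mcols(all)$signal)
  out <- all[head(ord, k)]
  S4Vectors::mcols(out)$exp_rank <- NULL
  out
}
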