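#' Parse motifs from MEME minimal format
#'
#' Reads a MEME minimal-format motif file (version line, optional alphabet,
#' strands and background lines, then `MOTIF` blocks with
#' `letter-probability matrix:` sections). The `nsites=` field, when present,
#' is mapped to `support_peaks`.
#'
#' @param text character scalar (file contents) or vector of lines; use
#'   [read_meme()] to read from a path.
#' @param source provenance label attached to each parsed PWM.
#' @return list of `pwm` objects.
#' @export
parse_meme <- function(text, source = "inferred") {
  lines <- if (length(text) == 1L && grepl("\n", text)) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  motif_starts <- grep("^MOTIF\\b", lines)
  pwms <- vector("list", length(motif_starts))
  bounds <- c(motif_starts, length(lines) + 1L)
  for (k in seq_along(motif_starts)) {
    block <- lines[motif_starts[k]:(bounds[k + 1L] - 1L)]
    header <- strsplit(trimws(block[1L]), "\\s+")[[1]]
    if (length(header) < 2L) stop("MOTIF line without an identifier: '", block[1L], "'")
    motif_id <- header[2L]
    alt_name <- if (length(header) >= 3L) header[3L] else motif_id
    lp <- grep("^letter-probability matrix:", block)
    if (!length(lp)) stop("motif '", motif_id, "': no letter-probability matrix section")
    lp <- lp[1L]
    hdr <- block[lp]
    getfield <- function(name) {
      m <- regmatches(hdr, regexec(paste0(name, "=\\s*([0-9.eE+-]+)"), hdr))[[1]]
      if (length(m) == 2L) as.numeric(m[2L]) else NA_real_
    }
    w <- getfield("w")
    nsites <- getfield("nsites")
    rows <- character(0)
    i <- lp + 1L
    while (i <= length(block)) {
      ln <- trimws(block[i])
      if (ln == "" || grepl("^(URL|MOTIF)", ln)) break
      if (grepl("^[0-9.eE+-]", ln)) rows <- c(rows, ln) else break
      i <- i + 1L
    }
    if (!is.na(w) && length(rows) < w)
      stop("motif '", motif_id, "': expected ", w, " matrix rows, found ", length(rows))
    if (!is.na(w)) rows <- rows[seq_len(w)]
    vals <- lapply(rows, function(r) {
      x <- suppressWarnings(as.numeric(strsplit(r, "\\s+")[[1]]))
      if (length(x) != 4L || anyNA(x))
        stop("motif '", motif_id, "': malformed matrix row '", r,
             "' (expected 4 numeric fields)")
      x
    })
    mat <- t(do.call(rbind, vals))  # rows become columns: 4 x w, A C G T
    pwms[[k]] <- new_pwm(mat, motif_id = motif_id, tf_name = alt_name,
                         support_peaks = if (is.na(nsites)) NA_integer_ else as.integer(nsites),
                         rank = k, source = source)
  }
  pwms
}

#' @rdname parse_meme
#' @param path path to a MEME minimal file.
#' @export
read_meme <- function(path, source = "inferred") parse_meme(readLines(path), source = source)

#' Write motifs in MEME minimal format
#'
#' @param pwms list of `pwm` objects (may be empty: a valid header-only file
#'   is produced).
#' @param path optional path; when `NULL` the text is returned invisibly.
#' @param background background letter frequencies, length 4 (A, C, G, T).
#' @return character vector of lines, invisibly when written to `path`.
#' @export
write_meme <- function(pwms, path = NULL, background = rep(0.25, 4)) {
  out <- c("MEME version 4", "",
           "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           paste(sprintf("%s %.5f", DNA_BASES, background), collapse = " "), "")
  for (p in pwms) {
    stopifnot(is_pwm(p))
    hdr <- sprintf("letter-probability matrix: alength= 4 w= %d", pwm_width(p))
    if (!is.na(p$support_peaks)) hdr <- paste0(hdr, sprintf(" nsites= %d", p$support_peaks))
    rows <- apply(p$matrix, 2L, function(col) paste(sprintf("%.6f", col), collapse = "  "))
    out <- c(out, paste("MOTIF", p$motif_id, p$tf_name), hdr, rows, "")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    invisible(out)
  } else out
}

#' Parse a JASPAR position frequency matrix
#'
#' Reads one motif in JASPAR PFM format: a `>` header line followed by four
#' count rows ordered A, C, G, T, with or without the `A [ ... ]` bracket
#' style. Counts are converted to probabilities with an additive pseudocount
#' per cell: `(c + eps) / (sum(c) + 4 eps)`.
#'
#' @param text character scalar or vector of lines.
#' @param pseudocount per-cell additive pseudocount `eps` (default 0.25).
#' @param source provenance label.
#' @return a `pwm` object.
#' @export
parse_jaspar_pfm <- function(text, pseudocount = 0.25, source = "database_curated") {
  lines <- if (length(text) == 1L && grepl("\n", text)) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[lines != ""]
  motif_id <- "jaspar_motif"; tf_name <- motif_id
  if (grepl("^>", lines[1L])) {
    hdr <- strsplit(sub("^>\\s*", "", lines[1L]), "\\s+")[[1]]
    motif_id <- hdr[1L]
    tf_name <- if (length(hdr) >= 2L) hdr[2L] else motif_id
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop("JASPAR PFM '", motif_id, "': expected 4 count rows")
  counts <- lapply(lines[1:4], function(r) {
    r <- gsub("^[ACGTacgt]\\s*", "", r)
    r <- gsub("[][]", " ", r)
    x <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
    if (anyNA(x)) stop("JASPAR PFM '", motif_id, "': non-numeric count row")
    x
  })
  lens <- lengths(counts)
  if (length(unique(lens)) != 1L)
    stop("JASPAR PFM '", motif_id, "': unequal row lengths (",
         paste(lens, collapse = ", "), ")")
  cmat <- do.call(rbind, counts)  # 4 x w
  tot <- colSums(cmat)
  prob <- sweep(cmat + pseudocount, 2L, tot + 4 * pseudocount, "/")
  new_pwm(prob, motif_id = motif_id, tf_name = tf_name,
          support_peaks = NA_integer_, source = source)
}

#' Read a TF family sidecar table
#'
#' A tab-separated table with columns `motif_id` (or `tf_name`), `family`
#' and optionally `dbd_label`, used to attach family labels to motifs read
#' from MEME files.
#'
#' @param path path to the TSV file.
#' @param pwms list of `pwm` objects to label (matched on `motif_id`, then
#'   `tf_name`).
#' @return the input list with `family` fields filled in.
#' @export
apply_family_table <- function(path, pwms) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    j <- if ("motif_id" %in% names(tab)) match(p$motif_id, tab$motif_id) else NA
    if (is.na(j) && "tf_name" %in% names(tab)) j <- match(p$tf_name, tab$tf_name)
    if (!is.na(j)) pwms[[i]]$family <- tab$family[j]
  }
  pwms
}
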