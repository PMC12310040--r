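#' @name synthetic
#' @title Synthetic study generator
#' @description
#' Generators that emulate the inputs of a TF ChIP-seq motif study with a
#' planted, fully known ground truth: a small genome with genes and
#' cis-regulatory feature annotations, a reference motif database with
#' family labels, summit-centred peaks carrying planted canonical /
#' tethered / co-binding motif instances, a conservation track elevated at
#' planted sites, and a protein-interaction network with planted direct
#' edges and co-factor bridges. All randomness flows from one master seed
#' through named substreams, so each component is reproducible on its own.
NULL

substream_seed <- function(seed, name) {
  idx <- match(name, c("genome", "motifs", "tfs", "peaks", "track", "ppi", "misc"))
  if (is.na(idx)) stop("unknown substream '", name, "'")
  as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.41) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic genome with genes and feature annotations
#'
#' Sequences are i.i.d. with configurable GC content. Non-overlapping
#' genes with exon/intron structure are placed on both strands; PLS
#' features sit on promoters, pELS within 2 kb upstream, dELS in distal
#' intergenic space, and CTCF-bound intervals are scattered with a
#' configurable fraction near promoters.
#'
#' @param seed integer seed (substreamed internally).
#' @param lengths chromosome lengths in bp (each >= 50 kb).
#' @param n_genes number of genes to place.
#' @param gc GC content of the background sequence.
#' @param exon_range,intron_range per-element length ranges in bp.
#' @param n_exon_range range of exons per gene.
#' @param utr5_len,utr3_len UTR lengths carved from the terminal exons.
#' @param n_ctcf number of CTCF-bound intervals.
#' @param ctcf_near_promoter_frac fraction of CTCF intervals placed within
#'   500 bp of a promoter.
#' @param n_dels number of distal enhancer-like intervals.
#' @return list of class `synthetic_genome`: `genome` (`DNAStringSet`),
#'   `genes`, `exons`, `utr5`, `utr3`, `features`, `seqlengths` and
#'   `annotation` (a [genome_annotation()]).
#' @export
generate_genome <- function(seed, lengths = c(chr1 = 300000L, chr2 = 150000L),
                            n_genes = 40L, gc = 0.41,
                            exon_range = c(100L, 300L),
                            intron_range = c(200L, 1200L),
                            n_exon_range = c(2L, 6L),
                            utr5_len = 80L, utr3_len = 120L,
                            n_ctcf = 60L, ctcf_near_promoter_frac = 0.3,
                            n_dels = 40L) {
  if (any(lengths < 50000L)) stop("chromosome lengths must be >= 50 kb")
  if (is.null(names(lengths))) names(lengths) <- paste0("chr", seq_along(lengths))
  with_seed(substream_seed(seed, "genome"), {
    genome <- Biostrings::DNAStringSet(vapply(lengths, random_dna, character(1), gc = gc))
    names(genome) <- names(lengths)

    buffer <- 1500L
    occupied <- lapply(lengths, function(l) IRanges::IRanges())
    genes <- list(); exons <- list(); utr5 <- list(); utr3 <- list()
    placed <- 0L; attempts <- 0L
    while (placed < n_genes && attempts < n_genes * 200L) {
      attempts <- attempts + 1L
      n_ex <- sample(n_exon_range[1L]:n_exon_range[2L], 1L)
      ex_len <- sample(exon_range[1L]:exon_range[2L], n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(intron_range[1L]:intron_range[2L], n_ex - 1L, replace = TRUE) else integer(0)
      span <- sum(ex_len) + sum(in_len)
      chr <- sample(names(lengths), 1L, prob = lengths / sum(lengths))
      max_start <- lengths[[chr]] - span - buffer
      if (max_start < buffer + 1L) next
      gstart <- sample(seq.int(buffer + 1L, max_start), 1L)
      cand <- IRanges::IRanges(gstart - buffer, gstart + span + buffer)
      if (length(IRanges::findOverlaps(cand, occupied[[chr]]))) next
      occupied[[chr]] <- c(occupied[[chr]], cand)
      placed <- placed + 1L
      strand <- sample(c("+", "-"), 1L)
      gname <- sprintf("gene%03d", placed)
      biotype <- sample(c("coding", "ncRNA"), 1L, prob = c(0.75, 0.25))
      ex_st <- gstart + cumsum(c(0L, head(ex_len, -1L) + in_len))
      ex_en <- ex_st + ex_len - 1L
      gend <- max(ex_en)
      tss <- if (strand == "+") gstart else gend
      tts <- if (strand == "+") gend else gstart
      genes[[placed]] <- data.frame(gene = gname, chrom = chr, strand = strand,
                                    tss = tss, tts = tts, biotype = biotype)
      exons[[placed]] <- GenomicRanges::GRanges(chr, IRanges::IRanges(ex_st, ex_en), gene = gname)
      first <- if (strand == "+") 1L else n_ex
      last <- if (strand == "+") n_ex else 1L
      u5 <- if (strand == "+")
        IRanges::IRanges(ex_st[first], min(ex_en[first], ex_st[first] + utr5_len - 1L))
      else IRanges::IRanges(max(ex_st[first], ex_en[first] - utr5_len + 1L), ex_en[first])
      u3 <- if (strand == "+")
        IRanges::IRanges(max(ex_st[last], ex_en[last] - utr3_len + 1L), ex_en[last])
      else IRanges::IRanges(ex_st[last], min(ex_en[last], ex_st[last] + utr3_len - 1L))
      utr5[[placed]] <- GenomicRanges::GRanges(chr, u5, gene = gname)
      utr3[[placed]] <- GenomicRanges::GRanges(chr, u3, gene = gname)
    }
    if (placed < n_genes)
      stop("could only place ", placed, " of ", n_genes, " genes; ",
           "reduce n_genes or enlarge the genome")
    genes <- do.call(rbind, genes)
    exons <- suppressWarnings(unname(do.call(c, exons)))
    utr5 <- suppressWarnings(unname(do.call(c, utr5)))
    utr3 <- suppressWarnings(unname(do.call(c, utr3)))

    plus <- genes$strand == "+"
    pls <- GenomicRanges::GRanges(genes$chrom,
      IRanges::IRanges(ifelse(plus, genes$tss - 200L, genes$tss - 100L),
                       ifelse(plus, genes$tss + 100L, genes$tss + 200L)))
    pels_off <- sample(300:1900, nrow(genes), replace = TRUE)
    pels <- GenomicRanges::GRanges(genes$chrom,
      IRanges::IRanges(ifelse(plus, genes$tss - pels_off - 150L, genes$tss + pels_off - 150L),
                       width = 300L))
    rand_intervals <- function(n, width) {
      chr <- sample(names(lengths), n, replace = TRUE, prob = lengths / sum(lengths))
      st <- vapply(chr, function(cc) sample.int(lengths[[cc]] - width, 1L), integer(1))
      GenomicRanges::GRanges(chr, IRanges::IRanges(st, width = width))
    }
    dels <- rand_intervals(n_dels, 300L)
    dels <- dels[!suppressWarnings(IRanges::overlapsAny(dels, pls, maxgap = 2000L))]
    n_near <- round(n_ctcf * ctcf_near_promoter_frac)
    near_idx <- sample(nrow(genes), n_near, replace = TRUE)
    ctcf_near <- GenomicRanges::GRanges(genes$chrom[near_idx],
      IRanges::IRanges(genes$tss[near_idx] + sample(-500:500, n_near, replace = TRUE),
                       width = 150L))
    ctcf <- suppressWarnings(c(ctcf_near, rand_intervals(n_ctcf - n_near, 150L)))
    features <- lapply(list(PLS = pls, pELS = pels, dELS = dels, CTCF_bound = ctcf),
                       function(g) {
                         GenomeInfoDb::seqlevels(g) <- names(lengths)
                         GenomeInfoDb::seqlengths(g) <- unname(lengths)
                         g
                       })
    ann <- genome_annotation(genes, exons, utr5, utr3, features,
                             seqlengths = lengths)
    structure(list(genome = genome, genes = genes, exons = exons,
                   utr5 = utr5, utr3 = utr3, features = features,
                   seqlengths = lengths, annotation = ann),
              class = "synthetic_genome")
  })
}

ic_to_prob <- function(ic) {
  # column (p, q, q, q): solve 2 + p log2 p + (1-p) log2((1-p)/3) = ic
  f <- function(p) {
    q <- (1 - p) / 3
    2 + p * log2(p) + ifelse(q > 0, 3 * q * log2(q), 0) - ic
  }
  if (ic <= 0) return(0.25)
  if (ic >= 2) return(1)
  stats::uniroot(f, c(0.2500001, 0.9999999))$root
}

sample_pwm_matrix <- function(w, target_ic) {
  target_ic <- min(target_ic, 1.9 * w)
  col_ic <- pmax(0, pmin(2, rnorm(w, target_ic / w, 0.15)))
  col_ic <- col_ic * target_ic / max(sum(col_ic), 1e-9)
  mat <- vapply(col_ic, function(ic) {
    p <- ic_to_prob(min(ic, 1.99))
    col <- rep((1 - p) / 3, 4)
    col[sample.int(4L, 1L)] <- p
    col
  }, numeric(4))
  mat
}

#' Perturb a PWM by mixing with Dirichlet noise
#'
#' Each column is replaced by `(1 - noise) * p + noise * d` with `d` a
#' symmetric Dirichlet draw; small `noise` keeps the PCC to the parent
#' high.
#'
#' @param pwm parent `pwm`.
#' @param noise mixing weight in `[0, 1]`.
#' @param motif_id id for the perturbed copy.
#' @return a `pwm`.
#' @export
jitter_pwm <- function(pwm, noise = 0.1, motif_id = paste0(pwm$motif_id, "_j")) {
  m <- pwm$matrix
  d <- matrix(stats::rgamma(length(m), shape = 1), nrow = 4L)
  d <- sweep(d, 2L, colSums(d), "/")
  new <- (1 - noise) * m + noise * d
  new_pwm(sweep(new, 2L, colSums(new), "/"), motif_id = motif_id,
          tf_name = pwm$tf_name, family = pwm$family,
          support_peaks = pwm$support_peaks, source = "inferred")
}

#' Generate a synthetic reference motif database
#'
#' Draws one PWM per (family, member) with widths and information contents
#' in the requested ranges; optionally part of each family is generated as
#' a correlated cluster (jittered copies of a family seed motif), which
#' exercises within-family clustering and core-motif construction.
#'
#' @param seed integer seed.
#' @param families family names.
#' @param motifs_per_family motifs per family (recycled).
#' @param w_range motif width range in columns.
#' @param ic_range motif information content range in bits.
#' @param clustered_frac fraction of each family generated as a tight
#'   similarity cluster.
#' @param name database name.
#' @return a `motif_db`; each entry's `tf_name` is `<family>_TF<i>`.
#' @export
generate_motif_db <- function(seed, families = c("bZIP", "C2H2-ZF", "homeodomain", "Ets"),
                              motifs_per_family = 5L, w_range = c(12L, 16L),
                              ic_range = c(20, 26), clustered_frac = 0,
                              name = "synthetic_db") {
  motifs_per_family <- rep_len(motifs_per_family, length(families))
  with_seed(substream_seed(seed, "motifs"), {
    pwms <- list()
    for (fi in seq_along(families)) {
      fam <- families[fi]
      n <- motifs_per_family[fi]
      n_clust <- round(n * clustered_frac)
      seed_pwm <- NULL
      for (k in seq_len(n)) {
        id <- sprintf("%s_M%02d", gsub("[^A-Za-z0-9]", "", fam), k)
        tf <- sprintf("%s_TF%02d", gsub("[^A-Za-z0-9]", "", fam), k)
        if (k <= n_clust && !is.null(seed_pwm)) {
          p <- jitter_pwm(seed_pwm, noise = 0.08, motif_id = id)
          p$tf_name <- tf
        } else {
          w <- sample(w_range[1L]:w_range[2L], 1L)
          ic <- runif(1, ic_range[1L], ic_range[2L])
          p <- new_pwm(sample_pwm_matrix(w, ic), motif_id = id, tf_name = tf,
                       family = fam, source = "database_selex")
          if (k == 1L) seed_pwm <- p
        }
        p$family <- fam
        pwms[[id]] <- p
      }
    }
    motif_db(pwms, name = name)
  })
}

max_db_pcc <- function(pwm, db, family_filter = "any") {
  fams <- db_families(db)
  keep <- switch(family_filter,
                 any = rep(TRUE, length(fams)),
                 same = fams == pwm$family,
                 other = fams != pwm$family)
  best <- -1
  for (e in db$entries[keep]) {
    s <- tryCatch(pwm_similarity(pwm, e)$pcc, error = function(x) -1)
    if (s > best) best <- s
  }
  best
}

#' Plant per-TF inferred motif sets with known canonical status
#'
#' For each synthetic TF a ranked list of "inferred" PWMs is generated so
#' that the canonical-inference procedure has a known right answer:
#' `canonical` TFs get a close copy (PCC >= 0.9) of a same-family database
#' motif; `candidate` TFs get a novel motif dissimilar (PCC < 0.7) to every
#' database entry; `none` TFs get only close copies of other-family
#' database motifs. Rejection sampling at generation time enforces the
#' similarity constraints.
#'
#' @param seed integer seed.
#' @param db a `motif_db` with at least two families.
#' @param n_tfs number of synthetic TFs.
#' @param status_mix proportions of planted statuses
#'   (canonical, candidate, none).
#' @param support_range peak-support range assigned to inferred PWMs.
#' @return list with `tfs` (data frame: tf_name, family, status_planted,
#'   canonical_db_id) and `inferred` (per-TF list of ranked `pwm`s).
#' @export
plant_tf_motifs <- function(seed, db, n_tfs = 60L,
                            status_mix = c(canonical = 0.5, candidate = 0.3, none = 0.2),
                            support_range = c(150L, 600L)) {
  fams <- unique(db_families(db))
  if (length(fams) < 2L) stop("need at least two families in the database")
  with_seed(substream_seed(seed, "tfs"), {
    statuses <- sample(names(status_mix), n_tfs, replace = TRUE, prob = status_mix)
    tfs <- data.frame(tf_name = sprintf("synTF%03d", seq_len(n_tfs)),
                      family = sample(fams, n_tfs, replace = TRUE),
                      status_planted = statuses,
                      canonical_db_id = NA_character_)
    inferred <- vector("list", n_tfs)
    rsupport <- function() sample(support_range[1L]:support_range[2L], 1L)
    close_copy <- function(entry, id) {
      for (try in 1:50) {
        p <- jitter_pwm(entry, noise = 0.05, motif_id = id)
        if (pwm_similarity(p, entry)$pcc >= 0.9) return(p)
      }
      stop("could not generate a close copy of ", entry$motif_id)
    }
    novel_motif <- function(id, fam) {
      for (try in 1:100) {
        w <- sample(8:14, 1L)
        p <- new_pwm(sample_pwm_matrix(w, runif(1, 10, 16)), motif_id = id,
                     tf_name = id, family = fam)
        if (max_db_pcc(p, db) < 0.7) return(p)
      }
      stop("could not generate a novel motif dissimilar to the database")
    }
    for (i in seq_len(n_tfs)) {
      fam <- tfs$family[i]
      own <- db$entries[db_families(db) == fam]
      others <- db$entries[db_families(db) != fam]
      id <- function(k) sprintf("%s_inf%d", tfs$tf_name[i], k)
      pw <- list()
      if (statuses[i] == "canonical") {
        src <- own[[sample(length(own), 1L)]]
        tfs$canonical_db_id[i] <- src$motif_id
        pw[[1L]] <- close_copy(src, id(1))
        if (runif(1) < 0.3) pw[[2L]] <- close_copy(others[[sample(length(others), 1L)]], id(2))
      } else if (statuses[i] == "candidate") {
        pw[[1L]] <- novel_motif(id(1), fam)
        if (runif(1) < 0.3) pw[[2L]] <- novel_motif(id(2), fam)
      } else {
        n_co <- sample(1:3, 1L)
        for (k in seq_len(n_co))
          pw[[k]] <- close_copy(others[[sample(length(others), 1L)]], id(k))
      }
      for (k in seq_along(pw)) {
        pw[[k]]$tf_name <- tfs$tf_name[i]
        pw[[k]]$family <- fam
        pw[[k]]$rank <- k
        pw[[k]]$support_peaks <- rsupport()
      }
      inferred[[i]] <- pw
    }
    list(tfs = tfs, inferred = inferred)
  })
}

sample_motif_instance <- function(pwm) {
  paste(apply(pwm$matrix, 2L, function(col) sample(DNA_BASES, 1L, prob = col)),
        collapse = "")
}

revcomp_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

replace_at <- function(seqs, chr, start, instance) {
  s <- seqs[[chr]]
  Biostrings::subseq(s, start, start + nchar(instance) - 1L) <- Biostrings::DNAString(instance)
  seqs[[chr]] <- s
  seqs
}

#' Plant motif-bearing ChIP-seq peaks with a controlled binding-mode mixture
#'
#' For each configured TF, peaks are placed at non-overlapping random
#' positions and populated according to the TF's binding-mode mixture:
#' canonical-only peaks embed a sampled instance of the TF's canonical
#' motif; tethered peaks embed only the partner TF's motif; co-binding
#' peaks embed both, separated by an end-to-head gap drawn from
#' `Normal(gap_mean, gap_sd)` (truncated at 0). Motif instances are
#' sampled from the PWM column distributions, the peak summit sits at the
#' centre of the (first) planted motif, and signal decreases with peak
#' rank.
#'
#' @param seed integer seed.
#' @param tf_config data frame with columns `tf_name`, `canonical_id`,
#'   `partner_id` (db motif ids), `n_peaks`, `f_canonical`, `f_tethered`,
#'   `f_cobind`, and optionally `gap_mean` (default 40) and `gap_sd`
#'   (default 8).
#' @param genome a `synthetic_genome` (its sequences are modified to carry
#'   the planted instances).
#' @param db the `motif_db` holding the referenced motifs.
#' @return list with `genome` (modified `DNAStringSet`), `peaks`
#'   (`GRanges` with `summit`, `signal`, `experiment_id`, `peak_id`,
#'   `tf_name`), `sites` (`GRanges` of planted motif instances with
#'   `tf_name`, `motif_id`, `role`), and `truth` (per-peak data frame with
#'   the planted mode and gap).
#' @export
plant_peaks <- function(seed, tf_config, genome, db) {
  stopifnot(is(genome, "synthetic_genome"))
  seqs <- genome$genome
  lengths <- genome$seqlengths
  with_seed(substream_seed(seed, "peaks"), {
    occupied <- lapply(lengths, function(l) IRanges::IRanges())
    peak_rows <- list(); site_rows <- list(); truth_rows <- list()
    pid <- 0L
    for (r in seq_len(nrow(tf_config))) {
      cfg <- tf_config[r, ]
      gap_mean <- if ("gap_mean" %in% names(cfg) && !is.na(cfg$gap_mean)) cfg$gap_mean else 40
      gap_sd <- if ("gap_sd" %in% names(cfg) && !is.na(cfg$gap_sd)) cfg$gap_sd else 8
      can <- db$entries[[cfg$canonical_id]]
      par <- if (!is.na(cfg$partner_id)) db$entries[[cfg$partner_id]] else NULL
      mix <- c(cfg$f_canonical, cfg$f_tethered, cfg$f_cobind)
      if (abs(sum(mix) - 1) > 1e-6) stop("mixture for ", cfg$tf_name, " must sum to 1")
      modes <- sample(c("canonical", "tethered", "cobind"), cfg$n_peaks,
                      replace = TRUE, prob = mix)
      for (k in seq_len(cfg$n_peaks)) {
        placed <- FALSE
        for (try in 1:200) {
          chr <- sample(names(lengths), 1L, prob = lengths / sum(lengths))
          summit <- sample(seq.int(300L, lengths[[chr]] - 300L), 1L)
          cand <- IRanges::IRanges(summit - 120L, summit + 120L)
          if (length(IRanges::findOverlaps(cand, occupied[[chr]]))) next
          occupied[[chr]] <- c(occupied[[chr]], cand)
          placed <- TRUE
          break
        }
        if (!placed) stop("could not place peak ", k, " for ", cfg$tf_name,
                          " after 200 attempts")
        pid <- pid + 1L
        mode <- modes[k]
        gap <- NA_integer_
        plant_one <- function(p, start, strand = "+") {
          inst <- sample_motif_instance(p)
          if (strand == "-") inst <- revcomp_string(inst)
          seqs <<- replace_at(seqs, chr, start, inst)
          site_rows[[length(site_rows) + 1L]] <<- data.frame(
            chrom = chr, start = start, end = start + pwm_width(p) - 1L,
            strand = strand, tf_name = cfg$tf_name, motif_id = p$motif_id,
            role = if (identical(p$motif_id, cfg$canonical_id)) "canonical" else "partner",
            peak_id = sprintf("pk%05d", pid))
        }
        if (mode == "canonical") {
          w <- pwm_width(can)
          plant_one(can, summit - floor(w / 2), sample(c("+", "-"), 1L))
        } else if (mode == "tethered") {
          w <- pwm_width(par)
          plant_one(par, summit - floor(w / 2), sample(c("+", "-"), 1L))
        } else {
          gap <- max(0L, round(rnorm(1, gap_mean, gap_sd)))
          w1 <- pwm_width(can)
          start1 <- summit - floor(w1 / 2)
          plant_one(can, start1, "+")
          plant_one(par, start1 + w1 + gap, "+")
        }
        peak_rows[[pid]] <- data.frame(
          chrom = chr, summit = summit,
          signal = round(100 * exp(-k / (cfg$n_peaks + 1)) + runif(1), 3),
          experiment_id = paste0(cfg$tf_name, "_exp1"),
          peak_id = sprintf("pk%05d", pid), tf_name = cfg$tf_name)
        truth_rows[[pid]] <- data.frame(peak_id = sprintf("pk%05d", pid),
                                        tf_name = cfg$tf_name, mode = mode,
                                        gap = gap)
      }
    }
    pk <- do.call(rbind, peak_rows)
    peaks <- make_peaks(pk$chrom, pk$summit, pk$signal, pk$experiment_id,
                        pk$peak_id, seqlengths = lengths)
    S4Vectors::mcols(peaks)$tf_name <- pk$tf_name
    sd <- do.call(rbind, site_rows)
    sites <- GenomicRanges::GRanges(sd$chrom, IRanges::IRanges(sd$start, sd$end),
                                    strand = sd$strand, tf_name = sd$tf_name,
                                    motif_id = sd$motif_id, role = sd$role,
                                    peak_id = sd$peak_id, seqlengths = lengths)
    list(genome = seqs, peaks = peaks, sites = sites,
         truth = do.call(rbind, truth_rows))
  })
}

#' Generate a conservation track elevated at planted sites
#'
#' The background is tiled with low scores plus noise; each planted site
#' interval is set to a high score with probability `q_site` (the site is
#' then "conserved") and a low score otherwise.
#'
#' @param seed integer seed.
#' @param sites `GRanges` of planted sites.
#' @param seqlengths named chromosome lengths.
#' @param q_site probability that a planted site is conserved.
#' @param high,low scores for conserved sites and background.
#' @param noise half-range of uniform background noise.
#' @param bin background tile width in bp.
#' @return list with `track` (`GRanges` with `score`) and `conserved`
#'   (logical vector parallel to `sites`).
#' @export
generate_conservation_track <- function(seed, sites, seqlengths, q_site = 0.8,
                                        high = 0.9, low = 0.1, noise = 0.05,
                                        bin = 200L) {
  with_seed(substream_seed(seed, "track"), {
    bg <- list()
    for (chr in names(seqlengths)) {
      st <- seq.int(1L, seqlengths[[chr]], by = bin)
      en <- pmin(st + bin - 1L, seqlengths[[chr]])
      bg[[chr]] <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, en),
                                          score = pmax(0, low + runif(length(st), -noise, noise)))
    }
    conserved <- runif(length(sites)) < q_site
    site_scores <- ifelse(conserved, high, low)
    site_gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(sites),
                                      IRanges::IRanges(GenomicRanges::start(sites),
                                                       GenomicRanges::end(sites)),
                                      score = site_scores)
    # carve planted intervals out of the background so scores do not stack
    bg <- suppressWarnings(do.call(c, unname(bg)))
    site_gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(site_gr),
                                      IRanges::ranges(site_gr),
                                      score = S4Vectors::mcols(site_gr)$score)
    GenomeInfoDb::seqlevels(site_gr) <- names(seqlengths)
    keep <- suppressWarnings(BiocGenerics::setdiff(bg, site_gr))
    ov <- GenomicRanges::findOverlaps(keep, bg, select = "first")
    S4Vectors::mcols(keep)$score <- S4Vectors::mcols(bg)$score[ov]
    track <- sort(suppressWarnings(c(keep, site_gr)), ignore.strand = TRUE)
    list(track = track, conserved = conserved)
  })
}

#' Generate a protein-interaction network with planted path lengths
#'
#' Direct pairs get an edge; `one_cofactor` pairs are bridged by a single
#' co-factor node; `multi_cofactor` pairs by a chain of two co-factors
#' (shortest path of 3 edges). Distractor nodes are attached as leaves so
#' that planted shortest paths cannot shrink; the planted distances are
#' verified by BFS before returning.
#'
#' @param seed integer seed.
#' @param relations data frame with columns `tf1`, `tf2`, `relation`
#'   (`"direct"`, `"one_cofactor"` or `"multi_cofactor"`).
#' @param n_distractors number of distractor leaf nodes.
#' @return an undirected `igraph` graph.
#' @export
generate_ppi <- function(seed, relations, n_distractors = 30L) {
  with_seed(substream_seed(seed, "ppi"), {
    edges <- character(0)
    cof <- 0L
    for (r in seq_len(nrow(relations))) {
      t1 <- relations$tf1[r]; t2 <- relations$tf2[r]
      rel <- relations$relation[r]
      if (rel == "direct") {
        edges <- c(edges, t1, t2)
      } else if (rel == "one_cofactor") {
        cof <- cof + 1L
        cn <- sprintf("COF%03d", cof)
        edges <- c(edges, t1, cn, cn, t2)
      } else if (rel == "multi_cofactor") {
        cn1 <- sprintf("COF%03d", cof + 1L); cn2 <- sprintf("COF%03d", cof + 2L)
        cof <- cof + 2L
        edges <- c(edges, t1, cn1, cn1, cn2, cn2, t2)
      } else stop("unknown relation '", rel, "'")
    }
    g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                                     directed = FALSE)
    g <- igraph::simplify(g)
    anchors <- igraph::V(g)$name
    for (d in seq_len(n_distractors)) {
      leaf <- sprintf("DIST%03d", d)
      g <- igraph::add_vertices(g, 1L, name = leaf)
      g <- igraph::add_edges(g, c(leaf, sample(anchors, 1L)))
    }
    expected <- c(direct = 1L, one_cofactor = 2L, multi_cofactor = 3L)
    d <- igraph::distances(g, v = unique(relations$tf1), to = unique(relations$tf2))
    got <- d[cbind(match(relations$tf1, rownames(d)),
                   match(relations$tf2, colnames(d)))]
    if (!all(got == expected[relations$relation]))
      stop("planted PPI path lengths were perturbed; regenerate with another seed")
    g
  })
}

#' Simulate a complete synthetic binding study
#'
#' Convenience wrapper chaining [generate_genome()], [generate_motif_db()],
#' [plant_peaks()], [generate_conservation_track()] and [generate_ppi()]
#' under one master seed. The defaults follow the emulated study design:
#' a binding-mode mixture of 60% canonical-only, 30% tethered and 10%
#' co-binding peaks per TF, 500 peaks per TF, co-occurring motif gaps of
#' Normal(40, 8) bp, and planted sites conserved with probability 0.8.
#'
#' @param seed master seed.
#' @param n_tfs number of TFs with planted peaks.
#' @param peaks_per_tf peaks per TF.
#' @param mixture length-3 binding-mode mixture
#'   (canonical, tethered, co-binding).
#' @param gap_mean,gap_sd co-occurring motif spacing parameters in bp.
#' @param q_conserved probability a planted site is conserved.
#' @param genome_args,db_args argument lists forwarded to
#'   [generate_genome()] / [generate_motif_db()].
#' @return list with components `genome_obj`, `db`, `tf_config`, `genome`
#'   (mutated sequences), `peaks`, `sites`, `truth`, `track`, `conserved`
#'   and `ppi`.
#' @export
simulate_study <- function(seed, n_tfs = 6L, peaks_per_tf = 500L,
                           mixture = c(0.6, 0.3, 0.1), gap_mean = 40,
                           gap_sd = 8, q_conserved = 0.8,
                           genome_args = list(), db_args = list()) {
  gen <- do.call(generate_genome, c(list(seed = seed), genome_args))
  db <- do.call(generate_motif_db, c(list(seed = seed), db_args))
  fams <- db_families(db)
  ids <- names(db$entries)
  cfg <- with_seed(substream_seed(seed, "misc"), {
    can <- sample(ids, n_tfs, replace = n_tfs > length(ids))
    partner <- vapply(can, function(cid) {
      pool <- ids[fams != fams[match(cid, ids)]]
      sample(pool, 1L)
    }, character(1))
    data.frame(tf_name = vapply(can, function(cid) db$entries[[cid]]$tf_name, character(1)),
               canonical_id = can, partner_id = partner,
               n_peaks = peaks_per_tf, f_canonical = mixture[1L],
               f_tethered = mixture[2L], f_cobind = mixture[3L],
               gap_mean = gap_mean, gap_sd = gap_sd)
  })
  planted <- plant_peaks(seed, cfg, gen, db)
  cons <- generate_conservation_track(seed, planted$sites, gen$seqlengths,
                                      q_site = q_conserved)
  rel <- with_seed(substream_seed(seed, "misc") + 1L, data.frame(
    tf1 = cfg$tf_name,
    tf2 = vapply(cfg$partner_id, function(p) db$entries[[p]]$tf_name, character(1)),
    relation = sample(c("direct", "one_cofactor", "multi_cofactor"),
                      nrow(cfg), replace = TRUE)))
  ppi <- generate_ppi(seed, rel)
  list(genome_obj = gen, db = db, tf_config = cfg, genome = planted$genome,
       peaks = planted$peaks, sites = planted$sites, truth = planted$truth,
       track = cons$track, conserved = cons$conserved, relations = rel,
       ppi = ppi)
}
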