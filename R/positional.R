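#' Genome annotation object
#'
#' Bundles the gene model and labelled feature sets used by the positional
#' analyses. The promoter of a gene is the strand-aware interval from
#' `promoter_upstream` bp upstream to `promoter_downstream` bp downstream
#' of its TSS (default -1000..+100, an 1100-bp window); the TTS region
#' extends `tts_flank` bp downstream of the TTS.
#'
#' @param genes data frame with columns `gene`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tss`, `tts` (1-based positions) and `biotype`
#'   (`"coding"` or `"ncRNA"`).
#' @param exons `GRanges` of exons with a `gene` metadata column (and
#'   optionally `rank`, counted 5' to 3' in gene orientation; computed when
#'   absent).
#' @param utr5,utr3 optional `GRanges` of untranslated regions.
#' @param features named list of `GRanges` feature sets, typically `PLS`,
#'   `pELS`, `dELS` and `CTCF_bound`.
#' @param seqlengths named vector of chromosome lengths.
#' @param promoter_upstream,promoter_downstream promoter bounds around the
#'   TSS in bp.
#' @param tts_flank downstream extent of the TTS region in bp.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, exons, utr5 = NULL, utr3 = NULL,
                              features = list(), seqlengths = NULL,
                              promoter_upstream = 1000L,
                              promoter_downstream = 100L, tts_flank = 100L) {
  stopifnot(all(c("gene", "chrom", "strand", "tss", "tts") %in% names(genes)))
  if (!"biotype" %in% names(genes)) genes$biotype <- "coding"
  plus <- genes$strand == "+"
  prom <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(ifelse(plus, genes$tss - promoter_upstream,
                            genes$tss - promoter_downstream),
                     ifelse(plus, genes$tss + promoter_downstream,
                            genes$tss + promoter_upstream)),
    gene = genes$gene)
  tts <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(ifelse(plus, genes$tts, genes$tts - tts_flank),
                     ifelse(plus, genes$tts + tts_flank, genes$tts)),
    gene = genes$gene)
  if (is.null(S4Vectors::mcols(exons)$rank))
    exons <- add_exon_ranks(exons, genes)
  introns <- gene_introns(exons, genes)
  structure(list(genes = genes, exons = exons, introns = introns,
                 utr5 = utr5, utr3 = utr3, promoters = prom,
                 tts_regions = tts, features = features,
                 seqlengths = seqlengths,
                 promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream),
            class = "genome_annotation")
}

add_exon_ranks <- function(exons, genes) {
  rk <- integer(length(exons))
  for (g in unique(S4Vectors::mcols(exons)$gene)) {
    i <- which(S4Vectors::mcols(exons)$gene == g)
    minus <- genes$strand[match(g, genes$gene)] == "-"
    ord <- order(GenomicRanges::start(exons[i]), decreasing = minus)
    rk[i[ord]] <- seq_along(i)
  }
  S4Vectors::mcols(exons)$rank <- rk
  exons
}

gene_introns <- function(exons, genes) {
  out <- list()
  for (g in unique(S4Vectors::mcols(exons)$gene)) {
    ex <- exons[S4Vectors::mcols(exons)$gene == g]
    if (length(ex) < 2L) next
    ex <- ex[order(GenomicRanges::start(ex))]
    st <- GenomicRanges::end(ex)[-length(ex)] + 1L
    en <- GenomicRanges::start(ex)[-1L] - 1L
    keep <- st <= en
    if (!any(keep)) next
    gr <- GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(ex))[1L],
                                 IRanges::IRanges(st[keep], en[keep]),
                                 gene = g)
    minus <- genes$strand[match(g, genes$gene)] == "-"
    rk <- seq_len(length(gr))
    if (minus) rk <- rev(rk)
    S4Vectors::mcols(gr)$rank <- rk
    out[[g]] <- gr
  }
  if (!length(out)) {
    return(GenomicRanges::GRanges(gene = character(0), rank = integer(0)))
  }
  suppressWarnings(do.call(c, unname(out)))
}

site_centers <- function(sites) {
  GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(sites),
    IRanges::IRanges(floor((GenomicRanges::start(sites) + GenomicRanges::end(sites)) / 2),
                     width = 1L))
}

#' Filter motif sites by evolutionary conservation
#'
#' The conservation score of a site is the aggregate (mean by default) of
#' the per-base track scores over its interval; bases missing from the
#' track score 0. A site is retained iff its score is strictly greater
#' than `threshold`.
#'
#' @param sites `GRanges` of candidate binding sites.
#' @param track `GRanges` with a numeric `score` column (as read from a
#'   bedGraph/wig file).
#' @param threshold retention threshold (default 0.5, strict).
#' @param aggregate `"mean"` or `"max"` per-base aggregation.
#' @return the retained sites, with a `conservation` metadata column.
#' @export
conservation_filter <- function(sites, track, threshold = 0.5,
                                aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  cov <- GenomicRanges::coverage(track, weight = S4Vectors::mcols(track)$score)
  score <- numeric(length(sites))
  chroms <- as.character(GenomeInfoDb::seqnames(sites))
  for (chr in unique(chroms)) {
    i <- which(chroms == chr)
    rle <- if (chr %in% names(cov)) cov[[chr]] else S4Vectors::Rle(0, 0)
    need <- max(GenomicRanges::end(sites[i]))
    if (length(rle) < need) rle <- c(rle, S4Vectors::Rle(0, need - length(rle)))
    v <- IRanges::Views(rle, IRanges::IRanges(GenomicRanges::start(sites[i]),
                                              GenomicRanges::end(sites[i])))
    score[i] <- if (aggregate == "mean") IRanges::viewMeans(v) else IRanges::viewMaxs(v)
  }
  out <- sites[score > threshold]
  S4Vectors::mcols(out)$conservation <- score[score > threshold]
  out
}

#' Merge highly overlapping binding sites
#'
#' Two sites are combined into one when their overlap is at least
#' `overlap_frac` of the shorter site (or of both, in reciprocal mode);
#' merging is repeated to a fixpoint, so the result is idempotent and
#' order-independent. TF name annotations are unioned.
#'
#' @param sites `GRanges` with a `tf_name` (or comma-separated `tf_names`)
#'   metadata column.
#' @param overlap_frac required overlap fraction (default 0.9).
#' @param reciprocal require the fraction of both intervals rather than of
#'   the shorter one.
#' @return merged `GRanges` with a `tf_names` column (comma-separated,
#'   sorted, unique).
#' @export
merge_tfbs <- function(sites, overlap_frac = 0.9, reciprocal = FALSE) {
  if (!length(sites)) return(sites)
  tfs <- S4Vectors::mcols(sites)$tf_names
  if (is.null(tfs)) tfs <- S4Vectors::mcols(sites)$tf_name
  if (is.null(tfs)) tfs <- rep(NA_character_, length(sites))
  chrom <- as.character(GenomeInfoDb::seqnames(sites))
  st <- GenomicRanges::start(sites); en <- GenomicRanges::end(sites)
  repeat {
    n <- length(st)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en))
    ov <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    keep <- qi < si
    qi <- qi[keep]; si <- si[keep]
    if (length(qi)) {
      ow <- pmin(en[qi], en[si]) - pmax(st[qi], st[si]) + 1L
      w1 <- en[qi] - st[qi] + 1L; w2 <- en[si] - st[si] + 1L
      ref <- if (reciprocal) pmax(w1, w2) else pmin(w1, w2)
      sel <- ow >= overlap_frac * ref - 1e-9
      qi <- qi[sel]; si <- si[sel]
    }
    if (!length(qi)) break
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_along(qi)) {
      a <- find(qi[k]); b <- find(si[k])
      if (a != b) parent[b] <- a
    }
    roots <- vapply(seq_len(n), find, integer(1))
    comp <- split(seq_len(n), roots)
    st <- vapply(comp, function(i) min(st[i]), integer(1))
    en2 <- vapply(comp, function(i) max(en[i]), integer(1))
    chrom <- vapply(comp, function(i) chrom[i[1L]], character(1))
    tfs <- vapply(comp, function(i) {
      paste(sort(unique(unlist(strsplit(tfs[i][!is.na(tfs[i])], ",")))), collapse = ",")
    }, character(1))
    en <- en2
  }
  ord <- order(chrom, st)
  GenomicRanges::GRanges(unname(chrom[ord]),
                         IRanges::IRanges(unname(st[ord]), unname(en[ord])),
                         tf_names = unname(tfs[ord]))
}

#' Signed distance from binding sites to the closest TSS
#'
#' Uses the centre position of each site and the closest TSS over all
#' genes (each TSS of a multi-TSS gene counts). The sign is strand-aware:
#' negative means upstream of the gene in its own orientation. Ties on
#' absolute distance are broken by gene name.
#'
#' @param sites `GRanges` of binding sites.
#' @param genes gene table as in [genome_annotation()] (or a
#'   `genome_annotation`).
#' @return data frame with columns `distance` (signed bp) and `gene`.
#' @export
distance_to_tss <- function(sites, genes) {
  if (is(genes, "genome_annotation")) genes <- genes$genes
  if (!nrow(genes)) stop("no genes supplied")
  centers <- GenomicRanges::start(site_centers(sites))
  chroms <- as.character(GenomeInfoDb::seqnames(sites))
  dist <- rep(NA_integer_, length(sites))
  gene <- rep(NA_character_, length(sites))
  for (chr in unique(chroms)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    i <- which(chroms == chr)
    if (!nrow(g)) next
    ord <- order(g$tss, g$gene)
    g <- g[ord, , drop = FALSE]
    for (k in i) {
      d <- abs(centers[k] - g$tss)
      best <- which(d == min(d))
      best <- best[order(g$gene[best])][1L]
      sgn <- if (g$strand[best] == "+") centers[k] - g$tss[best] else g$tss[best] - centers[k]
      dist[k] <- sgn
      gene[k] <- g$gene[best]
    }
  }
  data.frame(distance = dist, gene = gene)
}

#' Positional density of TFBS-to-TSS distances
#'
#' Histogram of distances within `+/- window` bp of the TSS, normalised so
#' the bin probabilities sum to one, plus a Gaussian kernel density
#' estimate.
#'
#' @param distances signed distances in bp.
#' @param window half-width of the reporting window (default 10000).
#' @param binwidth histogram bin width in bp (default 100).
#' @param bw KDE bandwidth; default Scott's rule via [stats::bw.nrd()].
#' @return list with `mids`, `prob` (summing to 1), and `kde` (a
#'   `density` object), plus `n_in_window`.
#' @export
positional_density <- function(distances, window = 10000L, binwidth = 100L,
                               bw = NULL) {
  d <- distances[abs(distances) <= window]
  if (length(d) < 10L) stop("need at least 10 distances within the window")
  breaks <- seq(-window, window + binwidth, by = binwidth) - binwidth / 2
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  prob <- h$counts / sum(h$counts)
  if (is.null(bw)) bw <- if (stats::sd(d) > 0) stats::bw.nrd(d) else binwidth
  kde <- stats::density(d, bw = bw, from = -window, to = window)
  list(mids = h$mids, prob = prob, kde = kde, n_in_window = length(d))
}

#' Annotate binding sites with genomic regions
#'
#' Assigns each site (by its centre) one label among `promoter`, `utr5`,
#' `utr3`, `exon`, `intron`, `tts` and `intergenic`, with precedence in
#' that order when the centre falls in several classes. Exon and intron
#' labels carry the ordinal of the element counted 5' to 3' in gene
#' orientation, binned 1..10 and `">10"`.
#'
#' @param sites `GRanges` of binding sites.
#' @param annotation a `genome_annotation`.
#' @return data frame with columns `region` and `ordinal` (bin label or
#'   `NA`).
#' @export
annotate_region <- function(sites, annotation) {
  stopifnot(is(annotation, "genome_annotation"))
  ctr <- site_centers(sites)
  n <- length(sites)
  region <- rep("intergenic", n)
  ordinal <- rep(NA_character_, n)
  hit_first <- function(gr) {
    if (is.null(gr) || !length(gr)) return(rep(NA_integer_, n))
    GenomicRanges::findOverlaps(ctr, gr, select = "first", ignore.strand = TRUE)
  }
  unset <- function() region == "intergenic"
  assign_class <- function(gr, label, with_rank = FALSE) {
    ov <- hit_first(gr)
    sel <- unset() & !is.na(ov)
    region[sel] <<- label
    if (with_rank) {
      rk <- S4Vectors::mcols(gr)$rank[ov[sel]]
      ordinal[sel] <<- ifelse(rk > 10L, ">10", as.character(rk))
    }
  }
  assign_class(annotation$promoters, "promoter")
  assign_class(annotation$utr5, "utr5")
  assign_class(annotation$utr3, "utr3")
  assign_class(annotation$exons, "exon", with_rank = TRUE)
  assign_class(annotation$introns, "intron", with_rank = TRUE)
  assign_class(annotation$tts_regions, "tts")
  data.frame(region = region, ordinal = ordinal)
}

#' Enrichment fold-change of sites in regions
#'
#' For each region set the observed number of sites (by centre position)
#' is compared with the count expected if sites fell uniformly on the
#' genome: `N_expected = n_sites * region_length / genome_length`, with
#' region length taken over the merged (reduced) region intervals. The
#' fold change is `log2(N / N_expected)`; an empty region count gives
#' `-Inf`.
#'
#' @param sites `GRanges` of sites.
#' @param regions named list of `GRanges` region sets.
#' @param genome_len total genome length in bp.
#' @return data frame with columns `region`, `n`, `expected` and `fc`.
#' @export
enrichment_fc <- function(sites, regions, genome_len) {
  ctr <- site_centers(sites)
  res <- lapply(names(regions), function(nm) {
    red <- GenomicRanges::reduce(regions[[nm]], ignore.strand = TRUE)
    len <- sum(GenomicRanges::width(red))
    if (len == 0) stop("region '", nm, "' has zero length")
    nobs <- sum(IRanges::overlapsAny(ctr, red, ignore.strand = TRUE))
    nexp <- length(ctr) * len / genome_len
    data.frame(region = nm, n = nobs, expected = nexp,
               fc = ifelse(nobs == 0, -Inf, log2(nobs / nexp)))
  })
  do.call(rbind, res)
}

#' Per-TF enrichment profiles over feature regions
#'
#' Computes [enrichment_fc()] separately for the sites of each TF,
#' keeping only TFs with at least `min_sites` sites in at least one region.
#'
#' @param sites `GRanges` with `tf_names` (comma-separated) or `tf_name`.
#' @param regions named list of `GRanges` region sets (typically PLS,
#'   pELS, dELS, CTCF_bound).
#' @param genome_len genome length in bp.
#' @param min_sites per-region site count a TF must reach in at least one
#'   region (default 10).
#' @return matrix of log2 fold changes, TFs in rows, regions in columns.
#' @export
enrichment_profiles <- function(sites, regions, genome_len, min_sites = 10L) {
  tfs <- S4Vectors::mcols(sites)$tf_names
  if (is.null(tfs)) tfs <- S4Vectors::mcols(sites)$tf_name
  lst <- strsplit(as.character(tfs), ",")
  idx <- rep(seq_along(lst), lengths(lst))
  tf <- unlist(lst)
  mats <- list()
  for (t in sort(unique(tf))) {
    s <- sites[unique(idx[tf == t])]
    fc <- enrichment_fc(s, regions, genome_len)
    if (max(fc$n) < min_sites) next
    mats[[t]] <- stats::setNames(fc$fc, fc$region)
  }
  if (!length(mats)) stop("no TF reaches ", min_sites, " sites in any region")
  do.call(rbind, mats)
}

#' TFBS proximity to CTCF-bound sites
#'
#' A binding site is "near" a CTCF site when it lies within `window` bp of
#' one. The percent abundance of a TF is 100 x (number of its TFBSs near a
#' CTCF site) / (number of CTCF sites that have any nearby TFBS); two TFs
#' can flank the same CTCF site, so the abundances do not sum to 100.
#'
#' @param sites `GRanges` with `tf_names`/`tf_name` metadata.
#' @param ctcf_sites `GRanges` of CTCF-bound intervals.
#' @param window proximity window in bp (default 200).
#' @return list with `per_tf` (data frame: tf, n_near, abundance_pct),
#'   `pct_ctcf_with_tfbs`, `n_ctcf_with_tfbs` and `distances` (bp from
#'   each TFBS to its nearest CTCF site, for null comparisons).
#' @export
ctcf_proximity <- function(sites, ctcf_sites, window = 200L) {
  near_ctcf <- IRanges::overlapsAny(ctcf_sites, sites, maxgap = window,
                                    ignore.strand = TRUE)
  n_ctcf_near <- sum(near_ctcf)
  hits <- GenomicRanges::distanceToNearest(sites, ctcf_sites, ignore.strand = TRUE)
  dist <- rep(NA_integer_, length(sites))
  dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  site_near <- !is.na(dist) & dist <= window
  tfs <- S4Vectors::mcols(sites)$tf_names
  if (is.null(tfs)) tfs <- S4Vectors::mcols(sites)$tf_name
  lst <- strsplit(as.character(tfs), ",")
  idx <- rep(seq_along(lst), lengths(lst))
  tf <- unlist(lst)
  per_tf <- do.call(rbind, lapply(sort(unique(tf)), function(t) {
    s <- unique(idx[tf == t])
    n_near <- sum(site_near[s])
    data.frame(tf = t, n_near = n_near,
               abundance_pct = if (n_ctcf_near > 0) 100 * n_near / n_ctcf_near else NA_real_)
  }))
  list(per_tf = per_tf[order(-per_tf$abundance_pct), ],
       pct_ctcf_with_tfbs = 100 * n_ctcf_near / length(ctcf_sites),
       n_ctcf_with_tfbs = n_ctcf_near,
       distances = dist)
}

#' Uniform random genomic intervals
#'
#' Places `n` intervals of length `l` uniformly on the genome, choosing
#' each chromosome with probability proportional to its length (the
#' `bedtools random` model). Reproducible under a fixed seed.
#'
#' @param n number of intervals.
#' @param l interval length in bp.
#' @param seqlengths named vector of chromosome lengths.
#' @param seed optional integer seed applied locally.
#' @return `GRanges` of `n` intervals.
#' @export
random_sites <- function(n, l, seqlengths, seed = NULL) {
  if (l > min(seqlengths))
    stop("interval length ", l, " exceeds the shortest chromosome (",
         min(seqlengths), " bp)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  chrom <- sample(names(seqlengths), n, replace = TRUE,
                  prob = seqlengths / sum(seqlengths))
  start <- floor(runif(n, min = 1, max = seqlengths[chrom] - l + 1))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(as.integer(start), width = l))
}

#' Rescale site positions by gene length
#'
#' Maps the position of a site relative to a gene's TSS, in gene
#' orientation, onto units of the gene length `L = |TTS - TSS|`: the TSS
#' maps to 0, the TTS to 1, and upstream positions are negative.
#'
#' @param sites `GRanges` of sites (centres are used).
#' @param gene a single-row slice of the gene table (with `tss`, `tts`,
#'   `strand`).
#' @return numeric vector of scaled coordinates.
#' @export
rescale_by_gene_length <- function(sites, gene) {
  L <- abs(gene$tts - gene$tss)
  if (L == 0) stop("gene '", gene$gene, "' has zero length (TSS == TTS)")
  ctr <- GenomicRanges::start(site_centers(sites))
  x <- if (gene$strand == "+") ctr - gene$tss else gene$tss - ctr
  x / L
}

#' Per-family positional quantiles of TFBS-to-TSS distances
#'
#' Restricts distances to the reporting window (default -2000..+200 bp of
#' the TSS) and returns the empirical 10/50/90% quantile positions per TF
#' family. Families with `min_tfs` or fewer TFs are pooled into
#' `"others"`.
#'
#' @param distances signed distances in bp.
#' @param family family label per distance.
#' @param tf per-distance TF name, used to count distinct TFs per family
#'   for pooling; when `NULL` no pooling is done.
#' @param window two-element reporting window (default `c(-2000, 200)`).
#' @param probs quantile probabilities.
#' @param min_n minimum number of in-window distances per reported family.
#' @param min_tfs families with at most this many distinct TFs are pooled.
#' @return data frame with one row per family and one column per quantile.
#' @export
family_quantiles <- function(distances, family, tf = NULL,
                             window = c(-2000, 200),
                             probs = c(0.1, 0.5, 0.9), min_n = 20L,
                             min_tfs = 10L) {
  if (!is.null(tf)) {
    sizes <- tapply(tf, family, function(x) length(unique(x)))
    small <- names(sizes)[sizes <= min_tfs]
    family[family %in% small] <- "others"
  }
  keep <- distances >= window[1L] & distances <= window[2L]
  distances <- distances[keep]; family <- family[keep]
  rows <- lapply(sort(unique(family)), function(f) {
    d <- distances[family == f]
    if (length(d) < min_n) return(NULL)
    q <- quantile(d, probs = probs, type = 1, names = FALSE)
    cbind(data.frame(family = f, n = length(d)),
          stats::setNames(as.data.frame(t(q)), paste0("q", probs * 100)))
  })
  do.call(rbind, rows)
}

#' PCA grouping of TFs by region enrichment profiles
#'
#' Maps TFs onto principal components of their log2 fold-change profiles
#' over the feature regions and cuts the first component at five
#' cut-points into six ordered groups G1..G6. `-Inf` sentinels (regions
#' with no sites) are imputed to one less than the column's smallest
#' finite value; columns are centred and PC1 is oriented so that the PLS
#' loading is positive.
#'
#' @param fc matrix of log2 fold changes, TFs in rows, regions in columns
#'   (a `PLS` column fixes the orientation; otherwise the first column is
#'   used).
#' @param cutpoints five increasing PC1 cut values; default the five
#'   equal-count sextile boundaries of PC1.
#' @param scale. also scale columns to unit variance before PCA.
#' @return list with `scores` (data frame: tf, pc1, pc2, group),
#'   `loadings`, `explained` (variance fractions), `cutpoints` and
#'   `group_means` (mean FC per group and region).
#' @export
pca_group <- function(fc, cutpoints = NULL, scale. = FALSE) {
  fc <- as.matrix(fc)
  if (nrow(fc) < 6L) stop("PCA grouping needs at least 6 TFs; got ", nrow(fc))
  imputed <- fc
  for (j in seq_len(ncol(fc))) {
    col <- fc[, j]
    if (any(!is.finite(col))) {
      lo <- min(col[is.finite(col)]) - 1
      imputed[!is.finite(col), j] <- lo
    }
  }
  pc <- prcomp(imputed, center = TRUE, scale. = scale.)
  orient_col <- if ("PLS" %in% colnames(fc)) "PLS" else colnames(fc)[1L]
  if (pc$rotation[orient_col, 1L] < 0) {
    pc$rotation[, 1L] <- -pc$rotation[, 1L]
    pc$x[, 1L] <- -pc$x[, 1L]
  }
  pc1 <- pc$x[, 1L]; pc2 <- pc$x[, 2L]
  if (is.null(cutpoints))
    cutpoints <- unname(quantile(pc1, probs = (1:5) / 6))
  if (length(cutpoints) != 5L || is.unsorted(cutpoints, strictly = FALSE) ||
      any(diff(cutpoints) < 0))
    stop("cutpoints must be 5 non-decreasing PC1 values")
  grp <- findInterval(pc1, cutpoints) + 1L
  group <- factor(paste0("G", grp), levels = paste0("G", 1:6))
  gm <- do.call(rbind, lapply(levels(group), function(g) {
    sel <- group == g
    if (!any(sel)) return(NULL)
    cbind(data.frame(group = g, n = sum(sel)),
          as.data.frame(t(colMeans(imputed[sel, , drop = FALSE]))))
  }))
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = data.frame(tf = rownames(fc), pc1 = pc1, pc2 = pc2,
                           group = group, row.names = NULL),
       loadings = pc$rotation, explained = explained,
       cutpoints = cutpoints, group_means = gm)
}
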