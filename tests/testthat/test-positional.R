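mk_sites <- function(start, width = 10L, chrom = "chr1", tf = "TF1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = width),
                         tf_name = tf)
}

simple_annotation <- function() {
  # plus-strand gene at 10000..13000 (3 exons), minus-strand gene at 20000..23000
  genes <- data.frame(gene = c("gplus", "gminus"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(10000L, 23000L),
                      tts = c(13000L, 20000L),
                      biotype = c("coding", "ncRNA"))
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(10000L, 11000L, 12500L, 20000L, 21000L, 22500L),
    c(10400L, 11400L, 13000L, 20400L, 21400L, 23000L)),
    gene = rep(c("gplus", "gminus"), each = 3L))
  genome_annotation(genes, exons, seqlengths = c(chr1 = 50000L))
}

test_that("conservation filter keeps strictly-above-threshold mean scores", {
  sites <- mk_sites(c(100L, 300L, 500L))
  track <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100L, 300L), c(109L, 309L)), score = c(1.0, 0.5))
  kept <- conservation_filter(sites, track)
  expect_length(kept, 1L)                     # 0.5 is dropped (strict >)
  expect_equal(GenomicRanges::start(kept), 100L)
  expect_equal(S4Vectors::mcols(kept)$conservation, 1.0)
  # bases absent from the track score 0: half-covered site at 1.0 scores 0.5
  half <- GenomicRanges::GRanges("chr1", IRanges::IRanges(700L, 709L))
  track2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(700L, 704L), score = 1)
  expect_length(conservation_filter(half, track2), 0L)
  expect_length(conservation_filter(half, track2, aggregate = "max"), 1L)
})

test_that("site merging unions TF names and respects the 90% threshold", {
  two <- c(mk_sites(100L, tf = "A"), mk_sites(100L, tf = "B"))
  m <- merge_tfbs(two)
  expect_length(m, 1L)
  expect_equal(S4Vectors::mcols(m)$tf_names, "A,B")
  # 8 bp overlap of 10-bp sites (80%) is below the default 90%
  apart <- c(mk_sites(100L), mk_sites(102L))
  expect_length(merge_tfbs(apart), 2L)
  # 9 bp overlap (90%) merges
  near <- c(mk_sites(100L), mk_sites(101L))
  expect_length(merge_tfbs(near), 1L)
})

test_that("site merging reaches the same fixpoint as the O(n^2) oracle", {
  withr::with_seed(61, {
    for (rep in 1:5) {
      st <- sample(1:3000, 60)
      w <- sample(8:20, 60, TRUE)
      sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, width = w),
                                      tf_name = "T")
      got <- merge_tfbs(sites)
      orc <- oracle_merge(st, st + w - 1L)
      expect_equal(GenomicRanges::start(got), orc$start)
      expect_equal(GenomicRanges::end(got), orc$end)
      # idempotent
      again <- merge_tfbs(got)
      expect_equal(GenomicRanges::start(again), GenomicRanges::start(got))
    }
  })
})

test_that("TSS distances are signed in gene orientation with nearest-TSS choice", {
  ann <- simple_annotation()
  # centre exactly on the plus-strand TSS
  expect_equal(distance_to_tss(mk_sites(9996L, 9L), ann)$distance, 0L)
  # 50 bp 5' (upstream) of the minus-strand TSS = coordinate tss + 50
  d <- distance_to_tss(mk_sites(23046L, 9L), ann)
  expect_equal(d$distance, -50L)
  expect_equal(d$gene, "gminus")
  expect_error(distance_to_tss(mk_sites(1L), data.frame()), "no genes")
})

test_that("TSS distances match a brute-force nearest-TSS oracle", {
  withr::with_seed(62, {
    genes <- data.frame(gene = sprintf("g%02d", 1:15), chrom = "chr1",
                        strand = sample(c("+", "-"), 15, TRUE),
                        tss = sample(1000:90000, 15), tts = 0L)
    genes$tts <- genes$tss + 2000L
    sites <- mk_sites(sample(1000:90000, 40), width = 11L)
    got <- distance_to_tss(sites, genes)
    ctr <- GenomicRanges::start(sites) + 5L
    for (i in seq_along(sites)) {
      dd <- abs(ctr[i] - genes$tss)
      j <- which(dd == min(dd))[1L]
      sgn <- if (genes$strand[j] == "+") ctr[i] - genes$tss[j] else genes$tss[j] - ctr[i]
      expect_equal(got$distance[i], sgn)
    }
  })
})

test_that("positional density normalises to one", {
  d <- rep(0L, 25)
  out <- positional_density(d, window = 1000L)
  expect_equal(sum(out$prob), 1)
  expect_equal(max(out$prob), 1)  # all mass in one bin
  withr::with_seed(63, {
    d2 <- round(rnorm(400, 0, 800))
    out2 <- positional_density(d2, window = 5000L)
    expect_equal(sum(out2$prob), 1, tolerance = 1e-9)
    # symmetric input gives a near-symmetric histogram
    expect_lt(abs(sum(out2$prob[out2$mids < 0]) - 0.5), 0.1)
  })
  expect_error(positional_density(1:5), "at least 10")
})

test_that("region annotation applies the precedence and gene-oriented ordinals", {
  ann <- simple_annotation()
  # 500 bp upstream of the plus-strand TSS: promoter
  expect_equal(annotate_region(mk_sites(9496L, 9L), ann)$region, "promoter")
  # centre in the 2nd intron of the minus-strand gene (introns ranked 5'->3')
  # gminus introns: 20401..20999 (rank 2), 21401..22499 (rank 1)
  r <- annotate_region(mk_sites(20696L, 9L), ann)
  expect_equal(r$region, "intron")
  expect_equal(r$ordinal, "2")
  r1 <- annotate_region(mk_sites(21896L, 9L), ann)
  expect_equal(r1$ordinal, "1")
  # far from all genes: intergenic
  expect_equal(annotate_region(mk_sites(40000L, 9L), ann)$region, "intergenic")
  # promoter beats exon at the TSS itself
  expect_equal(annotate_region(mk_sites(10001L, 9L), ann)$region, "promoter")
})

test_that("enrichment fold-changes follow log2(N / N_expected)", {
  genome_len <- 80000L
  regions <- list(R = GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 10000L)))
  sites <- mk_sites(seq(100L, 9000L, by = 300L))  # all inside R (1/8 of genome)
  fc <- enrichment_fc(sites, regions, genome_len)
  expect_equal(fc$fc, 3)
  empty <- enrichment_fc(mk_sites(70000L), regions, genome_len)
  expect_equal(empty$fc, -Inf)
  expect_error(enrichment_fc(sites, list(Z = GenomicRanges::GRanges()), genome_len),
               "zero length")
})

test_that("uniform random sites show no enrichment in large regions", {
  withr::with_seed(64, {
    seqlens <- c(chr1 = 300000L, chr2 = 100000L)
    sites <- random_sites(10000L, 10L, seqlens)
    regions <- list(half = GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 150000L)),
                    tenth = GenomicRanges::GRanges("chr2", IRanges::IRanges(1L, 40000L)))
    fc <- enrichment_fc(sites, regions, sum(seqlens))
    expect_true(all(abs(fc$fc) < 0.2))
  })
})

test_that("random sites follow chromosome lengths and the seed", {
  seqlens <- c(chr1 = 90000L, chr2 = 30000L)  # 3:1
  s1 <- random_sites(1000L, 20L, seqlens, seed = 7)
  s2 <- random_sites(1000L, 20L, seqlens, seed = 7)
  expect_identical(as.character(GenomeInfoDb::seqnames(s1)),
                   as.character(GenomeInfoDb::seqnames(s2)))
  expect_identical(GenomicRanges::start(s1), GenomicRanges::start(s2))
  n1 <- sum(GenomeInfoDb::seqnames(s1) == "chr1")
  expect_lt(abs(n1 - 750), 3 * sqrt(1000 * 0.75 * 0.25))
  expect_true(all(GenomicRanges::end(s1) <= seqlens[as.character(GenomeInfoDb::seqnames(s1))]))
  expect_true(all(GenomicRanges::start(s1) >= 1L))
  expect_error(random_sites(10L, 40000L, seqlens), "shortest")
})

test_that("CTCF proximity percent abundance follows its definition", {
  ctcf <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(1000L, 10000L, 1000L),
                                                          width = 100L))
  # one TF whose every site is 50 bp from a distinct CTCF site
  sites <- mk_sites(GenomicRanges::start(ctcf) - 60L, width = 10L, tf = "T1")
  prox <- ctcf_proximity(sites, ctcf)
  expect_equal(prox$per_tf$abundance_pct, 100)
  expect_equal(prox$pct_ctcf_with_tfbs, 100)
  # two TFs near the same CTCF sites: abundances sum over 100%
  both <- c(sites, mk_sites(GenomicRanges::start(ctcf) + 150L, width = 10L, tf = "T2"))
  prox2 <- ctcf_proximity(both, ctcf)
  expect_gt(sum(prox2$per_tf$abundance_pct), 100)
})

test_that("gene-length rescaling maps TSS to 0 and TTS to 1", {
  gene_plus <- data.frame(gene = "g", strand = "+", tss = 1000L, tts = 3000L)
  expect_equal(rescale_by_gene_length(mk_sites(2996L, 9L), gene_plus), 1)
  expect_equal(rescale_by_gene_length(mk_sites(996L, 9L), gene_plus), 0)
  expect_equal(rescale_by_gene_length(mk_sites(-1004L, 9L), gene_plus), -1)
  gene_minus <- data.frame(gene = "g", strand = "-", tss = 3000L, tts = 1000L)
  expect_equal(rescale_by_gene_length(mk_sites(996L, 9L), gene_minus), 1)
  expect_error(rescale_by_gene_length(mk_sites(1L),
                                      data.frame(gene = "g", strand = "+",
                                                 tss = 5L, tts = 5L)), "zero length")
})

test_that("family quantiles equal sorted-array indexing and pool small families", {
  withr::with_seed(65, {
    d <- round(rnorm(200, -50, 300))
    q <- family_quantiles(d, rep("famA", 200), window = c(-2000, 200))
    inwin <- sort(d[d >= -2000 & d <= 200])
    n <- length(inwin)
    expect_equal(unlist(q[, c("q10", "q50", "q90")], use.names = FALSE),
                 inwin[ceiling(c(0.1, 0.5, 0.9) * n)])
    expect_true(q$q10 <= q$q50 && q$q50 <= q$q90)
    # symmetric distances: median at the centre
    sym <- c(-100:-1, 1:100) - 50
    qs <- family_quantiles(sym, rep("f", 200))
    expect_lt(abs(qs$q50 - (-50)), 2)
    # pooling: a family carried by few TFs is reported as "others"
    fam <- rep(c("big", "small"), c(150, 50))
    tf <- c(sprintf("t%02d", sample(1:20, 150, TRUE)), rep(c("u1", "u2"), 25))
    qp <- family_quantiles(d, fam, tf = tf)
    expect_setequal(qp$family, c("big", "others"))
  })
})

test_that("PCA grouping orients PC1 by PLS, cuts into six groups, matches eigen", {
  withr::with_seed(66, {
    n <- 30L
    fc <- cbind(PLS = c(rnorm(15, 3), rnorm(15, -3)),
                pELS = rnorm(n), dELS = rnorm(n), CTCF_bound = rnorm(n, 0, 0.5))
    rownames(fc) <- sprintf("tf%02d", 1:n)
    res <- pca_group(fc)
    expect_gte(res$explained[1L], res$explained[2L])
    # the two planted clusters separate on PC1
    expect_true(all(res$scores$pc1[1:15] > 0) && all(res$scores$pc1[16:30] < 0))
    expect_equal(levels(res$scores$group), paste0("G", 1:6))
    # scores match an eigen-decomposition oracle up to the fixed orientation
    cc <- scale(fc, center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(cc) / (n - 1))
    o1 <- cc %*% ev$vectors[, 1L]
    if (ev$vectors["PLS" == colnames(fc), 1L] < 0) o1 <- -o1
    expect_equal(unname(res$scores$pc1), unname(o1[, 1L]), tolerance = 1e-8)
    # -Inf sentinels are imputed, not propagated
    fc2 <- fc; fc2[1, "dELS"] <- -Inf
    expect_true(all(is.finite(pca_group(fc2)$scores$pc1)))
    expect_error(pca_group(fc[1:4, ]), "at least 6")
    expect_error(pca_group(fc, cutpoints = c(3, 2, 1, 0, -1)), "non-decreasing")
  })
})
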