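mk_hits <- function(chrom, start, width = 10L, peak_id = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = width),
                               strand = "+")
  if (!is.null(peak_id)) S4Vectors::mcols(gr)$peak_id <- peak_id
  gr
}

test_that("X/Y/Z counting uses per-peak presence, not hit multiplicity", {
  peaks <- make_peaks("chr1", summit = c(1000L, 3000L, 5000L), signal = 1,
                      peak_id = c("p1", "p2", "p3"))
  can <- mk_hits("chr1", c(950, 4950, 4970))   # p1 and p3 (twice)
  non <- mk_hits("chr1", c(2950, 5000))        # p2 and p3
  m <- count_peak_motifs(peaks, can, non, "TFX")
  expect_equal(c(m$X, m$Y, m$Z), c(1L, 1L, 1L))
  expect_equal(m$n_peaks, 3L)
  # two canonical hits in one peak, nothing else -> one X
  m2 <- count_peak_motifs(peaks[1], mk_hits("chr1", c(950, 970)),
                          GenomicRanges::GRanges(), "TFY")
  expect_equal(c(m2$X, m2$Y, m2$Z), c(1L, 0L, 0L))
  # peaks with neither motif count only towards n_peaks
  m3 <- count_peak_motifs(peaks, mk_hits("chr1", 950), GenomicRanges::GRanges(), "TFZ")
  expect_equal(m3$n_peaks, 3L)
  expect_equal(m3$X + m3$Y + m3$Z, 1L)
  dup <- peaks; S4Vectors::mcols(dup)$peak_id <- c("p1", "p1", "p3")
  expect_error(count_peak_motifs(dup, can, non), "duplicate")
})

test_that("five-group classification follows the strict rule table", {
  expect_equal(classify_binding_group(5, 0, 0), 1L)
  expect_equal(classify_binding_group(10, 4, 6), 3L)
  expect_equal(classify_binding_group(2, 9, 1), 4L)
  expect_equal(classify_binding_group(1, 2, 5), 5L)
  tie <- classify_binding_group(7, 3, 3)
  expect_true(is.na(tie))
  expect_equal(attr(tie, "reason"), "tie")
  expect_error(classify_binding_group(0, 0, 0), "no motif evidence")
  expect_error(classify_binding_group(-1, 0, 0), "non-negative")
})

test_that("classification agrees with the rule table over all (X,Y,Z) in [0,6]^3", {
  for (X in 0:6) for (Y in 0:6) for (Z in 0:6) {
    if (X + Y + Z == 0) next
    got <- classify_binding_group(X, Y, Z)
    want <- if (X > 0 && Y == 0 && Z == 0) 1L
      else if (X > Y && Y > Z) 2L
      else if (X > Z && Z > Y) 3L
      else if (Y > X && Y > Z) 4L
      else if (Z > X && Z > Y) 5L
      else NA_integer_
    expect_identical(as.integer(got), want,
                     label = sprintf("(%d,%d,%d)", X, Y, Z))
  }
})

test_that("database fallback picks the highest-IC canonical with deterministic ties", {
  withr::with_seed(51, {
    strong <- sharp_pwm(10L, 0.97, motif_id = "strong", tf_name = "TFQ")
    weak <- sharp_pwm(10L, 0.80, motif_id = "weak", tf_name = "TFQ")
    db <- motif_db(list(weak, strong, sharp_pwm(8L, 0.9, motif_id = "other",
                                                tf_name = "TFO")))
    expect_equal(fallback_canonical("TFQ", db)$motif_id, "strong")
    expect_null(fallback_canonical("TFMISSING", db))
    # IC tie: lexicographically smaller motif id
    a <- sharp_pwm(10L, 0.9, motif_id = "aa", tf_name = "T2")
    b <- a; b$motif_id <- "bb"
    expect_equal(fallback_canonical("T2", motif_db(list(b, a)))$motif_id, "aa")
  })
})

test_that("pair distances are end-to-head gaps in coordinate order", {
  # BED-style [100,110) and [150,158): 1-based 101..110 and 151..158, gap 40
  a <- mk_hits("chr1", 101, width = 10L, peak_id = "p")
  b <- mk_hits("chr1", 151, width = 8L, peak_id = "p")
  expect_equal(pair_distance(a, b), 40L)
  expect_equal(pair_distance(b, a), 40L)
  # abutting motifs
  expect_equal(pair_distance(mk_hits("chr1", 101, 10, "p"),
                             mk_hits("chr1", 111, 8, "p")), 0L)
  # overlapping motifs give a negative gap, reported as-is
  expect_lt(pair_distance(mk_hits("chr1", 101, 10, "p"),
                          mk_hits("chr1", 105, 10, "p")), 0L)
  expect_error(pair_distance(mk_hits("chr1", 101, 10, "p1"),
                             mk_hits("chr1", 151, 8, "p2")), "different peaks")
})

test_that("co-occurrence typing follows PPI shortest paths", {
  edges <- rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E"))
  expect_equal(classify_cooccurrence("A", "B", edges),
               list(type = "G1", path_len = 1L))
  expect_equal(classify_cooccurrence("A", "C", edges),
               list(type = "G2_N1", path_len = 2L))
  expect_equal(classify_cooccurrence("A", "E", edges),
               list(type = "G2_Ngt1", path_len = 4L))
  expect_equal(classify_cooccurrence("A", "A", edges),
               list(type = "G3", path_len = 0L))
  expect_equal(classify_cooccurrence("A", "ZZ", edges)$type, "untyped")
})

test_that("path typing matches a hand-written BFS oracle on a random graph", {
  withr::with_seed(52, {
    n <- 60L
    nodes <- sprintf("n%02d", 1:n)
    edges <- cbind(sample(nodes, 120, TRUE), sample(nodes, 120, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], ]
    for (k in 1:100) {
      pair <- sample(nodes, 2)
      want <- oracle_bfs(edges, pair[1], pair[2])
      got <- classify_cooccurrence(pair[1], pair[2], edges)$path_len
      expect_identical(got, want, label = paste(pair, collapse = "-"))
    }
  })
})

test_that("five-group summaries reproduce whole-percent shares", {
  s <- summarize_modes(c(274, 53, 17, 153, 20))
  expect_equal(s$summary$percent, c(53, 10, 3, 30, 4))
  expect_equal(s$n_classified, 517L)
  expect_lte(abs(sum(s$summary$percent) - 100), 1)  # rounding
  one <- summarize_modes(data.frame(tf_name = "t", group = 1L,
                                    canonical_source = "inferred"))
  expect_equal(one$summary$percent, c(100, 0, 0, 0, 0))
  unk <- summarize_modes(data.frame(tf_name = c("a", "b"), group = c(1L, NA),
                                    canonical_source = c("inferred", "unknown")))
  expect_equal(unk$unknown_canonical, "b")
  expect_equal(unk$n_tied, 1L)
})

test_that("X/Y/Z fractions recover a planted mixture within binomial error", {
  withr::with_seed(53, {
    n <- 500L
    mix <- c(0.6, 0.3, 0.1)
    modes <- sample(c("can", "teth", "co"), n, TRUE, prob = mix)
    peaks <- make_peaks("chr1", summit = seq(1000L, by = 500L, length.out = n),
                        signal = 1, peak_id = sprintf("p%03d", 1:n))
    can_idx <- which(modes != "teth")
    non_idx <- which(modes != "can")
    can <- mk_hits("chr1", GenomicRanges::start(peaks)[can_idx] + 50L)
    non <- mk_hits("chr1", GenomicRanges::start(peaks)[non_idx] + 120L)
    m <- count_peak_motifs(peaks, can, non, "TFS")
    for (k in 1:3) {
      frac <- c(m$X, m$Y, m$Z)[k] / n
      expect_lt(abs(frac - mix[k]), 3 * sqrt(mix[k] * (1 - mix[k]) / n))
    }
  })
})
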