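# Scenario fixtures mirror the archetypal canonical-inference cases: a single
# inferred motif matching its own family; a top motif matching another family
# with the true motif ranked second; novel motifs matching nothing; and
# inferred motifs that all belong to other families.

make_inferred <- function(db_entry, id, rank = 1L, support = 300L, noise = 0.04) {
  p <- jitter_pwm(db_entry, noise = noise, motif_id = id)
  p$rank <- rank
  p$support_peaks <- support
  p
}

novel_pwm <- function(db, id, seed) {
  withr::with_seed(seed, {
    repeat {
      p <- sharp_pwm(9L, 0.9, motif_id = id)
      best <- max(vapply(db$entries, function(e) pwm_similarity(p, e)$pcc, numeric(1)))
      if (best < 0.7) return(p)
    }
  })
}

test_that("best_db_match honours the family filter and the PCC threshold", {
  db <- tiny_db()
  q <- db$entries[["db_bzip1"]]
  q$motif_id <- "query"
  hit <- best_db_match(q, db, "same")
  expect_equal(hit$db_pwm$motif_id, "db_bzip1")
  expect_equal(hit$similarity$pcc, 1.0)
  # a query similar only to another family's entry is absent under filter=same
  q2 <- db$entries[["db_ets1"]]
  q2$motif_id <- "query2"; q2$family <- "bZIP"
  expect_null(best_db_match(q2, db, "same"))
  expect_equal(best_db_match(q2, db, "other")$db_pwm$motif_id, "db_ets1")
})

test_that("best_db_match equals a brute-force maximum over the database", {
  withr::with_seed(8, {
    db <- motif_db(lapply(1:10, function(i)
      sharp_pwm(10L, 0.92, motif_id = paste0("d", i), family = "fam")), "ten")
    q <- jitter_pwm(db$entries[[4]], noise = 0.15, motif_id = "q")
    q$family <- "fam"
    pccs <- vapply(db$entries, function(e) pwm_similarity(q, e)$pcc, numeric(1))
    hit <- best_db_match(q, db, "any", threshold = 0)
    expect_equal(hit$similarity$pcc, max(pccs))
    expect_equal(hit$db_pwm$motif_id, names(db$entries)[which.max(pccs)])
  })
})

test_that("contains_submotif detects canonical-plus-extra-sequence motifs", {
  withr::with_seed(9, {
    canonical <- sharp_pwm(8L, 0.97, motif_id = "can")
    unrelated <- sharp_pwm(6L, 0.97, motif_id = "extra")
    # canonical concatenated with an unrelated informative motif
    compound <- new_pwm(cbind(canonical$matrix, unrelated$matrix), "compound")
    expect_true(contains_submotif(compound, canonical))
    # canonical embedded in uninformative uniform flanks
    flank <- matrix(0.25, 4, 4)
    padded <- new_pwm(cbind(flank, canonical$matrix, flank), "padded")
    expect_false(contains_submotif(padded, canonical))
    # identical motif: precondition (wider) fails
    expect_false(contains_submotif(canonical, canonical))
  })
})

test_that("the four canonical-inference scenarios yield the right verdicts", {
  db <- tiny_db()
  # (a) single inferred PWM highly similar to its own family's db motif
  inf_a <- list(make_inferred(db$entries[["db_bzip1"]], "a1"))
  call_a <- classify_tf_motifs("TFA", "bZIP", inf_a, db)
  expect_equal(call_a$status, "canonical")
  expect_equal(call_a$representative$motif_id, "a1")

  # (b) top PWM matches another family; the second matches the TF's own family
  inf_b <- list(make_inferred(db$entries[["db_ets1"]], "b1", rank = 1L),
                make_inferred(db$entries[["db_hd1"]], "b2", rank = 2L))
  call_b <- classify_tf_motifs("TFB", "homeodomain", inf_b, db)
  expect_equal(call_b$status, "canonical")
  expect_equal(call_b$representative$motif_id, "b2")
  expect_true("b1" %in% call_b$co_occurring$motif_id)
  expect_equal(call_b$co_occurring$matched_family[call_b$co_occurring$motif_id == "b1"],
               "Ets")

  # (c) no inferred PWM matches anything: top becomes the candidate canonical
  inf_c <- list(novel_pwm(db, "c1", 21), novel_pwm(db, "c2", 22))
  for (k in 1:2) { inf_c[[k]]$rank <- k; inf_c[[k]]$support_peaks <- 200L }
  call_c <- classify_tf_motifs("TFC", "C2H2-ZF", inf_c, db)
  expect_equal(call_c$status, "candidate_canonical")
  expect_equal(call_c$representative$motif_id, "c1")

  # (d) every inferred PWM matches another family: no canonical motif
  inf_d <- list(make_inferred(db$entries[["db_bzip1"]], "d1", rank = 1L),
                make_inferred(db$entries[["db_ets2"]], "d2", rank = 2L),
                make_inferred(db$entries[["db_bzip2"]], "d3", rank = 3L))
  call_d <- classify_tf_motifs("TFD", "homeodomain", inf_d, db)
  expect_equal(call_d$status, "none")
  expect_null(call_d$representative)
  expect_equal(nrow(call_d$co_occurring), 3L)
})

test_that("multiple same-family matches all become canonical with the best as representative", {
  db <- tiny_db()
  inf <- list(make_inferred(db$entries[["db_bzip1"]], "r1", rank = 1L, noise = 0.10),
              make_inferred(db$entries[["db_bzip1"]], "r2", rank = 2L, noise = 0.01))
  call <- classify_tf_motifs("TFR", "bZIP", inf, db)
  expect_equal(call$status, "canonical")
  expect_length(call$canonical_set, 2L)
  # representative is the member most similar to the database
  pccs <- vapply(inf, function(p) pwm_similarity(p, db$entries[["db_bzip1"]])$pcc,
                 numeric(1))
  expect_equal(call$representative$motif_id, c("r1", "r2")[which.max(pccs)])
})

test_that("PWMs supported by fewer than 100 peaks are dropped before classification", {
  db <- tiny_db()
  weak <- make_inferred(db$entries[["db_bzip1"]], "w1", support = 50L)
  expect_equal(classify_tf_motifs("TFW", "bZIP", list(weak), db)$status, "none")
  strong <- make_inferred(db$entries[["db_bzip1"]], "w2", support = 100L)
  expect_equal(classify_tf_motifs("TFW", "bZIP", list(strong), db)$status, "canonical")
  expect_equal(classify_tf_motifs("TFW", "bZIP", list(), db)$status, "none")
})

test_that("split motifs merge at the modal gap with uniform spacers", {
  withr::with_seed(23, {
    long <- sharp_pwm(12L, 0.97, motif_id = "long")
    left <- new_pwm(long$matrix[, 1:6], "left")
    right <- new_pwm(long$matrix[, 7:12], "right")
    merged <- merge_split_motifs(left, right, gaps = rep(0L, 20))
    expect_equal(pwm_width(merged), 12L)
    expect_gte(pwm_similarity(merged, long)$pcc, 0.95)
    # gap 2 produces two uniform spacer columns
    m2 <- merge_split_motifs(left, right, gaps = c(rep(2L, 15), 0L, 1L))
    expect_equal(pwm_width(m2), 14L)
    expect_equal(unname(m2$matrix[, 7:8]), matrix(0.25, 4, 2))
    # no modal gap: random spacing refuses to merge
    expect_error(merge_split_motifs(left, right, gaps = c(0L, 1L, 2L, 3L, 7L, 9L)),
                 "modal gap")
    expect_error(merge_split_motifs(left, right, gaps = rep(9L, 10)), "modal gap")
  })
})

test_that("planted canonical status is recovered on synthetic TFs", {
  db <- generate_motif_db(31, motifs_per_family = 4L)
  planted <- plant_tf_motifs(31, db, n_tfs = 12L)
  status_map <- c(canonical = "canonical", candidate = "candidate_canonical",
                  none = "none")
  called <- vapply(seq_len(12L), function(i)
    classify_tf_motifs(planted$tfs$tf_name[i], planted$tfs$family[i],
                       planted$inferred[[i]], db)$status, character(1))
  expect_equal(called, unname(status_map[planted$tfs$status_planted]))
})
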