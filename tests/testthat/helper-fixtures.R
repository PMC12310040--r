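# Fixture builders and independent brute-force oracles used across tests.

rand_pwm <- function(w = 8L, motif_id = "rnd", alpha = 0.5, ...) {
  m <- matrix(rgamma(4L * w, shape = alpha), nrow = 4L)
  m <- sweep(m, 2L, colSums(m), "/")
  new_pwm(m, motif_id = motif_id, ...)
}

sharp_pwm <- function(w = 10L, p = 0.97, motif_id = "sharp", ...) {
  m <- matrix((1 - p) / 3, 4L, w)
  for (j in seq_len(w)) m[sample(4L, 1L), j] <- p
  new_pwm(m, motif_id = motif_id, ...)
}

random_sequence <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# exhaustive alignment search, written independently of pwm_similarity
oracle_best_pcc <- function(a, b, min_overlap = min(ncol(a$matrix), ncol(b$matrix), 5L)) {
  best <- -Inf
  wa <- ncol(a$matrix); wb <- ncol(b$matrix)
  for (mb in list(b$matrix, reverse_complement(b)$matrix)) {
    for (sa in 1:wa) for (sb in 1:wb) {
      if (sa > 1L && sb > 1L) next  # full overlaps only: one motif starts the window
      L <- min(wa - sa, wb - sb) + 1L
      if (L < min_overlap) next
      x <- as.vector(a$matrix[, sa:(sa + L - 1L)])
      y <- as.vector(mb[, sb:(sb + L - 1L)])
      r <- suppressWarnings(cor(x, y))
      if (is.na(r)) r <- 0
      if (r > best) best <- r
    }
  }
  best
}

# exact p-value by enumerating all 4^w words (w small)
oracle_pvalues <- function(pwm, background = rep(0.25, 4), pseudocount = 0.01) {
  S <- log_odds(pwm, background, pseudocount)
  w <- ncol(S)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(words))
  weights <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    idx <- cbind(words[i, ], seq_len(w))
    scores[i] <- sum(S[idx])
    weights[i] <- prod(background[words[i, ]])
  }
  list(scores = scores, weights = weights,
       p_at = function(s) sum(weights[scores >= s]))
}

# plain BFS shortest path, no igraph
oracle_bfs <- function(edges, from, to) {
  nodes <- unique(c(edges[, 1], edges[, 2]))
  if (!(from %in% nodes) || !(to %in% nodes)) return(NA_integer_)
  if (from == to) return(0L)
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  dist <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) for (u in adj[[v]]) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        nxt <- c(nxt, u)
      }
    }
    if (!is.na(dist[to])) return(unname(dist[to]))
    frontier <- nxt
  }
  NA_integer_
}

# O(n^2) repeated pairwise merge of intervals to a fixpoint
oracle_merge <- function(st, en, frac = 0.9) {
  repeat {
    n <- length(st)
    merged <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ov <- min(en[i], en[j]) - max(st[i], st[j]) + 1L
        shorter <- min(en[i] - st[i], en[j] - st[j]) + 1L
        if (ov >= frac * shorter - 1e-9) {
          st[i] <- min(st[i], st[j]); en[i] <- max(en[i], en[j])
          st <- st[-j]; en <- en[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  ord <- order(st)
  list(start = st[ord], end = en[ord])
}

tiny_db <- function(seed = 101) {
  withr::with_seed(seed, {
    mk <- function(id, tf, fam) sharp_pwm(10L, 0.95, motif_id = id, tf_name = tf,
                                          family = fam, source = "database_selex")
    motif_db(list(mk("db_bzip1", "BZ1", "bZIP"), mk("db_bzip2", "BZ2", "bZIP"),
                  mk("db_ets1", "ET1", "Ets"), mk("db_ets2", "ET2", "Ets"),
                  mk("db_hd1", "HD1", "homeodomain")),
             name = "tiny")
  })
}
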