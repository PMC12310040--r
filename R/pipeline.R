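#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with the
#' analysis constants at their standard values: PCC similarity threshold
#' 0.80, scan p-value 1e-4, conservation threshold 0.5, site-merge overlap
#' 0.9, minimum motif support 100 peaks, CTCF proximity window 200 bp and
#' promoter bounds -1000..+100 bp of the TSS.
#'
#' @param seed master seed.
#' @param outdir results directory.
#' @param ... named overrides, merged recursively.
#' @return a named list.
#' @export
default_config <- function(seed = 1L, outdir = "motifscape_results", ...) {
  cfg <- list(
    seed = seed,
    outdir = outdir,
    stages = list(simulate = TRUE, canonical = TRUE, core = TRUE,
                  modes = TRUE, positions = TRUE),
    thresholds = list(pcc = 0.80, p_value = 1e-4, conservation = 0.5,
                      overlap = 0.9, support = 100L, ctcf_window = 200L,
                      promoter_upstream = 1000L, promoter_downstream = 100L),
    simulate = list(n_tfs = 6L, peaks_per_tf = 120L,
                    mixture = c(0.6, 0.3, 0.1), gap_mean = 40, gap_sd = 8,
                    q_conserved = 0.8, n_status_tfs = 24L,
                    db_clustered_frac = 0.6))
  overrides <- list(...)
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields are filled from [default_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(default_config(), cfg)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

granges_to_bed_df <- function(gr, extra = character(0)) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # BED is 0-based
                   end = GenomicRanges::end(gr))
  for (col in extra) df[[col]] <- S4Vectors::mcols(gr)[[col]]
  df
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated study:
#' `simulate` (genome, motif database, planted peaks, conservation track,
#' PPI network), `canonical` (canonical-status classification of planted
#' inferred motif sets), `core` (family core motifs), `modes` (scanning,
#' X/Y/Z counting, five-group classification, co-occurrence spacing and
#' PPI typing) and `positions` (conservation filtering, TFBS merging,
#' TSS distances, region annotation, enrichment and PCA grouping, CTCF
#' proximity). Every stage writes TSV outputs plus a log to the results
#' directory; reruns with the same config are identical.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   to a YAML file.
#' @return (invisibly) a list with the in-memory results of each stage and
#'   `outdir`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "pipeline.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con))
  log_line(con, "motifscape pipeline; seed=", config$seed)
  log_line(con, "thresholds: ", paste(names(config$thresholds),
                                      unlist(config$thresholds),
                                      sep = "=", collapse = " "))
  th <- config$thresholds
  res <- list(outdir = outdir)

  if (!isTRUE(config$stages$simulate))
    stop("stage 'simulate' is required: no external inputs are configured")
  sim_cfg <- config$simulate
  log_line(con, "stage simulate: n_tfs=", sim_cfg$n_tfs,
           " peaks_per_tf=", sim_cfg$peaks_per_tf)
  sim <- simulate_study(config$seed, n_tfs = sim_cfg$n_tfs,
                        peaks_per_tf = sim_cfg$peaks_per_tf,
                        mixture = sim_cfg$mixture,
                        gap_mean = sim_cfg$gap_mean, gap_sd = sim_cfg$gap_sd,
                        q_conserved = sim_cfg$q_conserved,
                        genome_args = if (is.null(sim_cfg$genome_args)) list() else sim_cfg$genome_args,
                        db_args = list(clustered_frac = sim_cfg$db_clustered_frac))
  res$sim <- sim
  Biostrings::writeXStringSet(sim$genome, file.path(outdir, "genome.fa"))
  write_meme(sim$db$entries, file.path(outdir, "motif_db.meme"))
  write_tsv(data.frame(motif_id = names(sim$db$entries),
                       tf_name = db_tf_names(sim$db),
                       family = db_families(sim$db)),
            file.path(outdir, "motif_db_families.tsv"))
  write_tsv(granges_to_bed_df(sim$peaks, c("peak_id", "summit", "signal",
                                           "experiment_id", "tf_name")),
            file.path(outdir, "peaks.tsv"))
  write_tsv(granges_to_bed_df(sim$track, "score"),
            file.path(outdir, "conservation_track.tsv"))
  write_tsv(as.data.frame(igraph::as_edgelist(sim$ppi)),
            file.path(outdir, "ppi_edges.tsv"))

  if (isTRUE(config$stages$canonical)) {
    log_line(con, "stage canonical: ", sim_cfg$n_status_tfs, " TFs")
    planted <- plant_tf_motifs(config$seed, sim$db, n_tfs = sim_cfg$n_status_tfs)
    status_map <- c(canonical = "canonical", candidate = "candidate_canonical",
                    none = "none")
    calls <- lapply(seq_len(nrow(planted$tfs)), function(i) {
      classify_tf_motifs(planted$tfs$tf_name[i], planted$tfs$family[i],
                         planted$inferred[[i]], sim$db,
                         threshold = th$pcc, min_support = th$support)
    })
    call_df <- data.frame(
      tf_name = planted$tfs$tf_name, family = planted$tfs$family,
      status_planted = status_map[planted$tfs$status_planted],
      status_called = vapply(calls, function(x) x$status, character(1)),
      representative = vapply(calls, function(x)
        if (is.null(x$representative)) NA_character_ else x$representative$motif_id,
        character(1)),
      n_co_occurring = vapply(calls, function(x) nrow(x$co_occurring), integer(1)))
    call_df$recovered <- call_df$status_planted == call_df$status_called
    write_tsv(call_df, file.path(outdir, "canonical_calls.tsv"))
    res$canonical <- list(calls = calls, table = call_df,
                          recovery = mean(call_df$recovered))
    log_line(con, "canonical status recovery: ",
             round(100 * res$canonical$recovery, 1), "%")
  }

  if (isTRUE(config$stages$core)) {
    fams <- db_families(sim$db)
    clusters <- list()
    for (fam in unique(fams)) {
      cl <- family_core_motifs(unname(sim$db$entries[fams == fam]),
                               threshold = th$pcc)
      clusters[[fam]] <- cl
    }
    cores <- unlist(lapply(clusters, function(cl)
      Filter(Negate(is.null), lapply(cl, `[[`, "core"))), recursive = FALSE)
    log_line(con, "stage core: ", length(cores), " core motif(s) across ",
             length(clusters), " families")
    if (length(cores)) write_meme(cores, file.path(outdir, "core_motifs.meme"))
    memb <- do.call(rbind, lapply(names(clusters), function(fam) {
      do.call(rbind, lapply(seq_along(clusters[[fam]]), function(i) {
        data.frame(family = fam, cluster = i,
                   motif_id = vapply(clusters[[fam]][[i]]$members,
                                     function(p) p$motif_id, character(1)),
                   has_core = !is.null(clusters[[fam]][[i]]$core))
      }))
    }))
    write_tsv(memb, file.path(outdir, "core_motif_clusters.tsv"))
    res$core <- clusters
  }

  if (isTRUE(config$stages$modes)) {
    log_line(con, "stage modes: scanning ", nrow(sim$tf_config), " TFs")
    modes <- list(); gaps <- list(); canon_hits_all <- list()
    for (r in seq_len(nrow(sim$tf_config))) {
      cfg_r <- sim$tf_config[r, ]
      tf_peaks <- sim$peaks[S4Vectors::mcols(sim$peaks)$tf_name == cfg_r$tf_name]
      can_hits <- scan_genome(sim$genome, sim$db$entries[[cfg_r$canonical_id]],
                              p_threshold = th$p_value)
      par_hits <- scan_genome(sim$genome, sim$db$entries[[cfg_r$partner_id]],
                              p_threshold = th$p_value)
      can_in <- filter_hits_by_peaks(can_hits, tf_peaks)
      par_in <- filter_hits_by_peaks(par_hits, tf_peaks)
      S4Vectors::mcols(can_in)$tf_name <- cfg_r$tf_name
      canon_hits_all[[r]] <- can_in
      modes[[r]] <- count_peak_motifs(tf_peaks, can_in, par_in,
                                      tf_name = cfg_r$tf_name)
      shared <- intersect(S4Vectors::mcols(can_in)$peak_id,
                          S4Vectors::mcols(par_in)$peak_id)
      if (length(shared)) {
        best_in_peak <- function(hits, pk) {
          h <- hits[S4Vectors::mcols(hits)$peak_id == pk]
          h[which.max(S4Vectors::mcols(h)$score)]
        }
        g <- vapply(shared, function(pk) {
          pair_distance(best_in_peak(can_in, pk), best_in_peak(par_in, pk))
        }, integer(1))
        gaps[[r]] <- data.frame(tf1 = cfg_r$tf_name,
                                tf2 = sim$db$entries[[cfg_r$partner_id]]$tf_name,
                                peak_id = shared, gap = g)
      }
    }
    mode_df <- do.call(rbind, lapply(modes, function(m)
      data.frame(tf_name = m$tf_name, X = m$X, Y = m$Y, Z = m$Z,
                 n_peaks = m$n_peaks, group = as.integer(m$group),
                 canonical_source = m$canonical_source)))
    write_tsv(mode_df, file.path(outdir, "binding_modes.tsv"))
    summ <- summarize_modes(modes)
    write_tsv(summ$summary, file.path(outdir, "binding_mode_summary.tsv"))
    gap_df <- if (length(gaps)) do.call(rbind, gaps) else NULL
    if (!is.null(gap_df)) {
      typing <- t(vapply(seq_len(nrow(gap_df)), function(i) {
        ty <- classify_cooccurrence(gap_df$tf1[i], gap_df$tf2[i], sim$ppi)
        c(ty$type, as.character(ty$path_len))
      }, character(2)))
      gap_df$type <- typing[, 1L]
      gap_df$path_len <- suppressWarnings(as.integer(typing[, 2L]))
      write_tsv(gap_df, file.path(outdir, "cooccurrence_pairs.tsv"))
    }
    res$modes <- list(per_tf = mode_df, summary = summ, pairs = gap_df,
                      canonical_hits = canon_hits_all)
    log_line(con, "modes: mean co-occurrence gap ",
             if (is.null(gap_df)) "NA" else round(mean(gap_df$gap), 1), " bp")
  }

  if (isTRUE(config$stages$positions)) {
    if (is.null(res$modes)) stop("stage 'positions' requires stage 'modes'")
    hits <- suppressWarnings(unname(do.call(c, res$modes$canonical_hits)))
    log_line(con, "stage positions: ", length(hits), " peak-filtered hits")
    conserved <- conservation_filter(hits, sim$track,
                                     threshold = th$conservation)
    merged <- merge_tfbs(conserved, overlap_frac = th$overlap)
    ann <- sim$genome_obj$annotation
    dist <- distance_to_tss(merged, ann)
    reg <- annotate_region(merged, ann)
    genome_len <- sum(sim$genome_obj$seqlengths)
    fc <- enrichment_fc(merged, sim$genome_obj$features, genome_len)
    prox <- ctcf_proximity(merged, sim$genome_obj$features$CTCF_bound,
                           window = th$ctcf_window)
    site_df <- cbind(granges_to_bed_df(merged, "tf_names"),
                     distance_to_tss = dist$distance, nearest_gene = dist$gene,
                     region = reg$region, ordinal = reg$ordinal)
    write_tsv(site_df, file.path(outdir, "conserved_tfbs.tsv"))
    write_tsv(fc, file.path(outdir, "region_enrichment.tsv"))
    write_tsv(prox$per_tf, file.path(outdir, "ctcf_proximity.tsv"))
    pca <- tryCatch({
      prof <- enrichment_profiles(merged, sim$genome_obj$features, genome_len,
                                  min_sites = 10L)
      pca_group(prof)
    }, error = function(e) {
      log_line(con, "positions: PCA grouping skipped (", conditionMessage(e), ")")
      NULL
    })
    if (!is.null(pca)) write_tsv(pca$scores, file.path(outdir, "pca_groups.tsv"))
    res$positions <- list(conserved = conserved, merged = merged,
                          distances = dist, regions = reg, enrichment = fc,
                          ctcf = prox, pca = pca)
    log_line(con, "positions: ", length(merged), " merged conserved TFBSs")
  }

  log_line(con, "pipeline complete: ", outdir)
  invisible(res)
}
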