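# End-to-end orchestration of the two tracks: the sequence track
# (filter MSAs -> strand windows -> profile HMMs -> calibrated search ->
# shuffle/EVD confirmation -> network and metamorphism statistics) and
# the structure track (motif TM-search -> conserved-water geometry).

#' Configuration for a pipeline run
#'
#' All defaults follow the protocol's stated values: MSA coverage 90%
#' and identity 30%, four-strand windows, E-value cutoff 1e-3 with
#' X-group 6 excluded, 1000 shuffles, TM threshold 0.5, short
#' hydrogen-bond cutoff 3.0 Angstrom.
#'
#' @param evalue_max E-value inclusion cutoff (strict `<`), default 1e-3.
#' @param exclude_xgroup Target X-group excluded from the search
#'   (default 6, the query lineage itself).
#' @param k Strands per window, default 4.
#' @param min_strand_len Minimum strand length, default 2.
#' @param coverage_min,identity_min MSA filter cutoffs (0.90 / 0.30).
#' @param occupancy_min,pseudocount_alpha Profile build parameters.
#' @param n_random Calibration sample size per profile, default 200.
#' @param n_shuffles Shuffle count for the EVD p-value, default 1000.
#' @param shuffle_p_max Confirmation p-value cutoff, default 0.05.
#' @param tm_min TM-score acceptance threshold, default 0.5.
#' @param short_hbond,max_hbond Water hydrogen-bond cutoffs (3.0 / 3.5 A).
#' @param seed Base seed for calibration and shuffling.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(evalue_max = 1e-3, exclude_xgroup = 6L, k = 4L,
                       min_strand_len = 2L, coverage_min = 0.90,
                       identity_min = 0.30, occupancy_min = 0.5,
                       pseudocount_alpha = 0.5, n_random = 200L,
                       n_shuffles = 1000L, shuffle_p_max = 0.05,
                       tm_min = 0.5, short_hbond = 3.0, max_hbond = 3.5,
                       seed = 1L) {
  stopifnot(evalue_max > 0, k >= 1L, n_random >= 50L, n_shuffles >= 30L,
            tm_min >= 0, short_hbond <= max_hbond)
  structure(as.list(environment()), class = "run_config")
}

#' Run the bridging-theme sequence pipeline
#'
#' For each master MSA: filter rows, cut four-strand windows using the
#' master's secondary structure, build and calibrate a profile HMM per
#' window, search the domain set, and attach shuffle/EVD p-values to
#' the hits (realigning the master window sequence against each hit
#' target). When CA coordinates are supplied for both domains of a
#' hit, the aligned-segment RMSD is attached as well.
#'
#' @param msas Named list of `msa` objects (one per master domain).
#' @param ss_table Named character vector: H/E/C string per master id.
#' @param domains Data frame `domain_id`, `sequence`, `group` (the
#'   search database).
#' @param config A [run_config()].
#' @param coords Optional named list of CA coordinate matrices per
#'   domain id (for segment RMSDs).
#' @param classification Optional classification for [build_network()];
#'   defaults to the masters' own groups joined with `domains`.
#' @param master_groups Named character vector: group label per master
#'   id (required for the network stage).
#' @return List: `hits` (list of `theme_hit`), `hit_table` (data
#'   frame), `network`, `theme_counts`, `metamorphism`, `profiles`.
#' @export
run_theme_pipeline <- function(msas, ss_table, domains, config = run_config(),
                               coords = NULL, master_groups = NULL,
                               classification = NULL) {
  stopifnot(inherits(config, "run_config"))
  db_size <- nrow(domains)
  random_len <- as.integer(stats::median(nchar(domains$sequence)))
  all_hits <- list()
  profiles <- list()
  for (mi in seq_along(msas)) {
    msa <- msas[[mi]]
    master_id <- msa$master_id
    ss <- ss_table[[master_id]]
    if (is.null(ss) || is.na(ss)) {
      warning("no secondary structure for master ", master_id,
              "; skipped")
      next
    }
    msa_f <- filter_msa(msa, config$coverage_min, config$identity_min)
    windows <- fragment_windows(msa_f, ss, k = config$k,
                                min_strand_len = config$min_strand_len)
    for (w in windows) {
      profile_id <- paste0(master_id, "_w", w$strand_span[[1]])
      hmm <- build_hmm(w$msa,
                       pseudocount_alpha = config$pseudocount_alpha,
                       occupancy_min = config$occupancy_min,
                       profile_id = profile_id,
                       strand_span = w$strand_span,
                       residue_range = w$residue_range)
      hmm <- calibrate_evalue(hmm, n_random = config$n_random,
                              random_len = random_len,
                              seed = config$seed + 1000L * mi +
                                w$strand_span[[1]],
                              db_size = db_size)
      profiles[[profile_id]] <- hmm
      hits <- search_domains(hmm, domains,
                             evalue_max = config$evalue_max,
                             exclude_xgroup = config$exclude_xgroup)
      # shuffle/EVD confirmation: master window sequence vs target
      master_seq <- gsub("-", "", msa_master_seq(w$msa), fixed = TRUE)
      for (h in seq_along(hits)) {
        tgt <- domains$sequence[[match(hits[[h]]$target_domain,
                                       domains$domain_id)]]
        sp <- shuffle_pvalue(master_seq, tgt,
                             n_shuffles = config$n_shuffles,
                             seed = config$seed + 7L * h +
                               1000L * mi)
        hits[[h]]$shuffle_pvalue <- sp$p_value
        if (!is.null(coords)) {
          ca_q <- coords[[hits[[h]]$master_domain]]
          ca_t <- coords[[hits[[h]]$target_domain]]
          if (!is.null(ca_q) && !is.null(ca_t)) {
            hits[[h]]$segment_rmsd <- theme_rmsd(hits[[h]]$alignment,
                                                 ca_q, ca_t)
          }
        }
      }
      all_hits <- c(all_hits, hits)
    }
  }
  hit_table <- hits_to_table(all_hits)
  network <- NULL
  if (!is.null(master_groups) && nrow(hit_table) > 0L) {
    classification <- classification %||% rbind(
      data.frame(domain_id = names(master_groups),
                 group = unname(master_groups)),
      domains[, c("domain_id", "group")])
    network <- build_network(hit_table, classification)
  }
  list(hits = all_hits, hit_table = hit_table, network = network,
       theme_counts = count_unique_themes(hit_table),
       metamorphism = metamorphism_stats(hit_table),
       profiles = profiles)
}

#' Run the structural motif pipeline
#'
#' Searches each target structure for the motif with the
#' motif-length-normalized TM-score; for hits at or above `tm_min`,
#' characterizes the conserved-water geometry on the mapped residues
#' (reports, hydrophobic clamp, dry detection).
#'
#' @param motif A motif from [extract_motif()], with optional
#'   `donor_motif_idx` attribute for dry detection.
#' @param targets Named list of `protein_structure` objects (each with
#'   `ss`, or assignable via [assign_ss()]).
#' @param config A [run_config()].
#' @param donor_motif_idx Motif-frame indices of the water-binding
#'   backbone donor positions (for [detect_dry_motif()]).
#' @return Data frame sorted by TM descending: `target`, `tm_score`,
#'   `rmsd`, `n_mapped`, `n_waters`, `n_short_hbonds`, `clamp`, `dry`,
#'   with the per-target hits and water reports as attributes `hits`
#'   and `water_reports`.
#' @export
run_motif_pipeline <- function(motif, targets, config = run_config(),
                               donor_motif_idx = NULL) {
  stopifnot(inherits(config, "run_config"))
  rows <- NULL
  hits <- list()
  reports <- list()
  for (nm in names(targets)) {
    st <- targets[[nm]]
    if (is.null(st$ss)) st$ss <- assign_ss(st)
    hit <- motif_search(motif, st$atoms$CA)
    hits[[nm]] <- hit
    n_wat <- 0L; n_short <- NA_integer_; clamp <- NA; dry <- NA
    if (hit$tm_score >= config$tm_min && nrow(hit$mapping) > 0L) {
      wr <- find_water_motif(st, motif_residues = hit$mapping[, "target_idx"],
                             short_cutoff = config$short_hbond,
                             max_cutoff = config$max_hbond)
      reports[[nm]] <- wr
      n_wat <- length(wr)
      if (n_wat > 0L) {
        r1 <- wr[[1]]
        n_short <- r1$n_short_hbonds
        strand_partners <- unique(
          r1$partners$residue[r1$partner_context == "strand"])
        if (length(strand_partners) >= 2L) {
          clamp <- hydrophobic_clamp(st, strand_partners[1:2])
        }
        dry <- FALSE
      } else if (!is.null(donor_motif_idx)) {
        dry <- detect_dry_motif(st, hit, donor_motif_idx,
                                short_cutoff = config$short_hbond,
                                max_cutoff = config$max_hbond)
      }
    }
    rows <- rbind(rows, data.frame(
      target = nm, tm_score = hit$tm_score, rmsd = hit$rmsd,
      n_mapped = nrow(hit$mapping), n_waters = n_wat,
      n_short_hbonds = n_short, clamp = clamp, dry = dry))
  }
  out <- rows[order(-rows$tm_score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hits") <- hits
  attr(out, "water_reports") <- reports
  out
}

#' Write pipeline outputs with a content manifest
#'
#' Writes the hit table, network node/edge tables, theme counts and
#' metamorphism statistics as TSVs, a run log recording the
#' configuration defaults in force, and a `manifest.tsv` with an MD5
#' content hash per output so that reruns can be verified
#' byte-for-byte.
#'
#' @param results Value of [run_theme_pipeline()].
#' @param dir Output directory (created if needed).
#' @param config The [run_config()] used (recorded in the log).
#' @return Invisibly, the manifest data frame.
#' @export
write_run_outputs <- function(results, dir, config = run_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hit_table(results$hit_table, file.path(dir, "hits.tsv"))
  utils::write.table(results$theme_counts,
                     file.path(dir, "theme_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(results$network)) {
    write_network(results$network, file.path(dir, "network_nodes.tsv"),
                  file.path(dir, "network_edges.tsv"))
  }
  meta <- results$metamorphism
  utils::write.table(
    data.frame(median_rmsd = meta$median_rmsd,
               fraction_below = meta$fraction_below,
               n_defined = meta$n_defined, n_missing = meta$n_missing),
    file.path(dir, "metamorphism.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  log_lines <- c(
    paste0("seed\t", config$seed),
    paste0("evalue_max\t", config$evalue_max),
    paste0("exclude_xgroup\t", config$exclude_xgroup),
    paste0("n_shuffles\t", config$n_shuffles),
    paste0("tm_min\t", config$tm_min),
    paste0("coverage_min\t", config$coverage_min),
    paste0("identity_min\t", config$identity_min))
  writeLines(log_lines, file.path(dir, "run_log.tsv"))
  outputs <- setdiff(list.files(dir), "manifest.tsv")
  manifest <- data.frame(
    file = outputs,
    md5 = unname(tools::md5sum(file.path(dir, outputs))))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Verify a run directory against its manifest
#' @param dir Directory written by [write_run_outputs()].
#' @return TRUE if every listed file matches its recorded hash.
#' @export
verify_run_outputs <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  current <- unname(tools::md5sum(file.path(dir, manifest$file)))
  all(current == manifest$md5)
}
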