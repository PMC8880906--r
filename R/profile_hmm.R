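# Profile hidden Markov models over fragment-window MSAs: build,
# local forward scoring in bits, Viterbi alignment, simulation-based
# Gumbel E-value calibration, and database search. This replaces the
# hmmbuild/hmmsearch step of the bridging-theme protocol with a
# self-contained engine (single background-proportional pseudocount,
# Henikoff position-based weights, per-sequence E-values).

TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

# Henikoff & Henikoff position-based sequence weights, normalized to
# sum to one so that duplicated rows collapse to a single observation.
henikoff_weights <- function(rows) {
  n <- length(rows)
  chars <- lapply(rows, seq_to_chars)
  L <- length(chars[[1]])
  w <- numeric(n)
  for (j in seq_len(L)) {
    col <- vapply(chars, `[[`, "", j)
    res <- col[col != "-"]
    if (length(res) == 0L) next
    counts <- table(res)
    r <- length(counts)
    for (i in seq_len(n)) {
      if (col[[i]] != "-") w[[i]] <- w[[i]] + 1 / (r * counts[[col[[i]]]])
    }
  }
  if (sum(w) == 0) w <- rep(1, n)
  w / sum(w)
}

#' Build a profile HMM from an MSA
#'
#' Match columns are those with non-gap fraction at least
#' `occupancy_min`. Emissions are background-proportional pseudocount
#' estimates, `(weighted counts + alpha * background) / (total + alpha)`,
#' with Henikoff position-based sequence weights; insert states emit the
#' background. Transitions are estimated from the observed per-row state
#' paths with Laplace smoothing `alpha` on the counts.
#'
#' @param msa An `msa`.
#' @param pseudocount_alpha Pseudocount weight, default 0.5.
#' @param occupancy_min Match-column occupancy threshold, default 0.5.
#' @param background Background frequencies (default Robinson--Robinson).
#' @param profile_id Optional identifier stored in provenance.
#' @param strand_span Optional strand window `(i, j)` for provenance.
#' @param residue_range Optional master residue range `(start, end)`;
#'   used to report alignment coordinates on the master domain.
#' @return Object of class `profile_hmm` with fields `M`,
#'   `match_emissions` (M x 20), `insert_emissions` ((M+1) x 20),
#'   `transitions` (M x 7: MM MI MD IM II DM DD), `background`,
#'   `provenance`, `calibration` (NULL until [calibrate_evalue()]).
#' @export
build_hmm <- function(msa, pseudocount_alpha = 0.5, occupancy_min = 0.5,
                      background = background_frequencies(),
                      profile_id = NULL, strand_span = NULL,
                      residue_range = NULL) {
  alpha <- pseudocount_alpha
  rows <- msa$seqs
  n <- length(rows)
  if (n == 0L) stop("empty MSA")
  chars <- lapply(rows, seq_to_chars)
  L <- length(chars[[1]])
  occ <- vapply(seq_len(L), function(j) {
    mean(vapply(chars, `[[`, "", j) != "-")
  }, 0)
  match_cols <- which(occ >= occupancy_min)
  M <- length(match_cols)
  if (M == 0L) stop("MSA has zero match columns at occupancy ",
                    occupancy_min)
  w <- henikoff_weights(rows)

  # emissions
  match_em <- matrix(0, M, 20, dimnames = list(NULL, AA_ALPHABET))
  for (m in seq_len(M)) {
    j <- match_cols[[m]]
    counts <- stats::setNames(numeric(20), AA_ALPHABET)
    for (i in seq_len(n)) {
      a <- chars[[i]][[j]]
      if (a %in% AA_ALPHABET) counts[[a]] <- counts[[a]] + w[[i]]
    }
    match_em[m, ] <- (counts + alpha * background) / (sum(counts) + alpha)
  }
  insert_em <- matrix(rep(background, each = M + 1L), M + 1L, 20,
                      dimnames = list(NULL, AA_ALPHABET))

  # transitions from observed state paths: node of column j is the number
  # of match columns at or before j; state M/D at match columns, I at
  # occupied insert columns.
  node_of <- cumsum(seq_len(L) %in% match_cols)
  counts <- matrix(0, M + 1L, 7, dimnames = list(NULL, TRANS_NAMES))
  for (i in seq_len(n)) {
    prev_state <- "M"; prev_node <- 0L  # begin state acts as M_0
    for (j in seq_len(L)) {
      is_match <- j %in% match_cols
      a <- chars[[i]][[j]]
      if (is_match) {
        state <- if (a == "-") "D" else "M"
      } else {
        if (a == "-") next
        state <- "I"
      }
      tr <- paste0(prev_state, state)
      # D->I and I->D do not exist in the architecture; such observed
      # steps (gap next to an occupied insert column) are not counted.
      if (tr %in% TRANS_NAMES) {
        counts[prev_node + 1L, tr] <- counts[prev_node + 1L, tr] + w[[i]]
      }
      prev_state <- state
      prev_node <- node_of[[j]]
    }
    # closing transition into the (virtual) end node, counted as ->M
    tr <- paste0(prev_state, "M")
    counts[prev_node + 1L, tr] <- counts[prev_node + 1L, tr] + w[[i]]
  }
  trans <- matrix(0, M, 7, dimnames = list(NULL, TRANS_NAMES))
  for (k in seq_len(M)) {
    cm <- counts[k + 1L, c("MM", "MI", "MD")] + alpha
    ci <- counts[k + 1L, c("IM", "II")] + alpha
    cd <- counts[k + 1L, c("DM", "DD")] + alpha
    trans[k, c("MM", "MI", "MD")] <- cm / sum(cm)
    trans[k, c("IM", "II")] <- ci / sum(ci)
    trans[k, c("DM", "DD")] <- cd / sum(cd)
  }
  match_positions <- if (!is.null(residue_range)) {
    # column index within the restricted MSA equals master offset
    residue_range[[1]] + match_cols - 1L
  } else {
    match_cols
  }
  structure(list(
    M = M, match_emissions = match_em, insert_emissions = insert_em,
    transitions = trans, background = background,
    provenance = list(profile_id = profile_id %||% msa$master_id,
                      master_id = msa$master_id,
                      strand_span = strand_span,
                      residue_range = residue_range,
                      match_positions = match_positions,
                      pseudocount_alpha = alpha,
                      occupancy_min = occupancy_min,
                      n_rows = n),
    calibration = NULL), class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm: ", x$M, " match states (", x$provenance$profile_id,
      ")", if (!is.null(x$calibration)) " [calibrated]", "\n", sep = "")
  invisible(x)
}

# log-odds tables and residue indexing shared by forward/Viterbi
hmm_scoring_tables <- function(hmm) {
  lodM <- log(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  lodI <- log(sweep(hmm$insert_emissions[-1L, , drop = FALSE], 2,
                    hmm$background, "/"))
  list(lodM = lodM, lodI = lodI, ltr = log(hmm$transitions))
}

encode_sequence <- function(sequence, warn = TRUE) {
  idx <- aa_index(seq_to_chars(toupper(sequence)))
  n_bad <- sum(is.na(idx))
  if (n_bad > 0L && warn) {
    message("forward_score: ", n_bad,
            " non-canonical residue(s) scored as background (X)")
  }
  idx[is.na(idx)] <- 0L
  idx
}

#' Local forward bit score of a sequence against a profile HMM
#'
#' Log-odds forward score over the local path ensemble, in bits:
#' `log2 P(seq | hmm, local) / P(seq | background)`. A local path enters
#' at any match state at any sequence position (probability `1/(M*L)`,
#' uniform over both) and exits after any match state (`1/M`); flanking
#' residues are scored by the background. The ensemble is a probability
#' subdensity, so background sequences score at or below zero on
#' average.
#' Computed in log space with exact log-sum-exp; finite for all inputs.
#' Non-canonical residues are treated as X (background emission).
#'
#' @param hmm A `profile_hmm`.
#' @param sequence Amino-acid string, length >= 1.
#' @return Bit score (numeric scalar).
#' @export
forward_score <- function(hmm, sequence) {
  stopifnot(nchar(sequence) >= 1L)
  tb <- hmm_scoring_tables(hmm)
  phmm_forward(tb$lodM, tb$lodI, tb$ltr, encode_sequence(sequence))
}

#' Viterbi alignment of a sequence to a profile HMM
#'
#' Maximum-scoring local path under the same entry/exit model as
#' [forward_score()]. Ties in the traceback prefer match over insert
#' over delete, making the path deterministic.
#'
#' @inheritParams forward_score
#' @return List with `score` (bits, always <= the forward score) and
#'   `alignment`, a data frame of matched `(node, master_pos, target_pos)`
#'   pairs, strictly increasing in both coordinates; `master_pos` is in
#'   master-domain residue numbering when the profile was built from a
#'   restricted window MSA.
#' @export
viterbi_align <- function(hmm, sequence) {
  stopifnot(nchar(sequence) >= 1L)
  tb <- hmm_scoring_tables(hmm)
  v <- phmm_viterbi(tb$lodM, tb$lodI, tb$ltr, encode_sequence(sequence))
  mp <- hmm$provenance$match_positions
  aln <- data.frame(node = v$node,
                    master_pos = mp[v$node],
                    target_pos = v$pos)
  list(score = v$score, alignment = aln)
}

#' Calibrate Gumbel E-values for a profile HMM by simulation
#'
#' Scores `n_random` i.i.d. background sequences with [forward_score()],
#' fits a Gumbel distribution by the method of moments
#' ([fit_gumbel()]), and stores the calibration on the profile. The
#' E-value of a score s is then
#' `db_size * (1 - exp(-exp(-lambda * (s - mu))))`.
#'
#' @param hmm A `profile_hmm`.
#' @param n_random Number of random sequences (>= 50), default 200.
#' @param random_len Length of the random sequences; a sensible choice
#'   is the median domain length of the search database.
#' @param seed Integer seed for the random sequences.
#' @param db_size Number of targets the E-value refers to.
#' @return The profile with `$calibration` set (list: `mu`, `lam`,
#'   `n_samples`, `random_len`, `db_size`).
#' @export
calibrate_evalue <- function(hmm, n_random = 200L, random_len, seed,
                             db_size) {
  stopifnot(n_random >= 50L, random_len >= 1L, db_size >= 1)
  scores <- withr_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      forward_score(hmm, random_aa_sequence(random_len, hmm$background))
    }, 0)
  })
  if (stats::sd(scores) == 0) {
    stop("calibration error: zero-variance null scores")
  }
  fit <- fit_gumbel(scores)
  hmm$calibration <- list(mu = fit$mu, lam = fit$lam,
                          n_samples = n_random, random_len = random_len,
                          db_size = db_size, seed = seed)
  hmm
}

# evaluate seeded code without disturbing the caller's RNG stream
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' E-value of a bit score under a profile's calibration
#' @param hmm Calibrated `profile_hmm`.
#' @param score Bit score(s).
#' @return E-value(s): expected number of false hits at or above `score`
#'   in a database of the calibrated size.
#' @export
evalue_score <- function(hmm, score) {
  cal <- hmm$calibration
  if (is.null(cal)) stop("profile is not calibrated; run calibrate_evalue()")
  cal$db_size * (1 - exp(-exp(-cal$lam * (score - cal$mu))))
}

#' Search a domain set with a calibrated profile HMM
#'
#' Scores every domain, converts scores to E-values under the profile's
#' calibration, drops targets in the excluded X-group (the master's own
#' lineage), and returns hits with E-value below `evalue_max`, sorted by
#' E-value, each carrying its Viterbi alignment.
#'
#' @param hmm Calibrated `profile_hmm`.
#' @param domains Data frame with columns `domain_id`, `sequence`,
#'   `group` (dotted X.T.F label).
#' @param evalue_max Inclusion threshold, default 1e-3 (strict `<`).
#' @param exclude_xgroup X-group to omit from targets (default 6, the
#'   beta-trefoils themselves); NULL to keep all.
#' @return List of `theme_hit` objects: `profile_id`, `master_domain`,
#'   `target_domain`, `target_group`, `bit_score`, `evalue`,
#'   `alignment`, plus `shuffle_pvalue`/`segment_rmsd` slots (NA until
#'   filled by later stages).
#' @export
search_domains <- function(hmm, domains, evalue_max = 1e-3,
                           exclude_xgroup = 6L) {
  if (is.null(hmm$calibration)) {
    stop("profile is not calibrated; run calibrate_evalue()")
  }
  hits <- list()
  for (i in seq_len(nrow(domains))) {
    grp <- domains$group[[i]]
    if (!is.null(exclude_xgroup) && parse_group(grp)$x == exclude_xgroup) {
      next
    }
    s <- forward_score(hmm, domains$sequence[[i]])
    ev <- evalue_score(hmm, s)
    if (ev < evalue_max) {
      v <- viterbi_align(hmm, domains$sequence[[i]])
      hits[[length(hits) + 1L]] <- structure(list(
        profile_id = hmm$provenance$profile_id,
        master_domain = hmm$provenance$master_id,
        window_strands = paste(hmm$provenance$strand_span %||% NA,
                               collapse = "-"),
        target_domain = domains$domain_id[[i]],
        target_group = grp,
        bit_score = s, evalue = ev,
        alignment = v$alignment,
        shuffle_pvalue = NA_real_,
        segment_rmsd = NA_real_), class = "theme_hit")
    }
  }
  hits[order(vapply(hits, `[[`, 0, "evalue"))]
}

#' Flatten theme hits into the fixed hit-table data frame
#' @param hits List of `theme_hit` objects.
#' @return Data frame with the documented hit-table columns.
#' @export
hits_to_table <- function(hits) {
  if (length(hits) == 0L) {
    out <- as.data.frame(stats::setNames(
      replicate(length(HIT_TABLE_COLS), character(0), simplify = FALSE),
      HIT_TABLE_COLS))
    return(out)
  }
  rng <- function(x) if (length(x)) paste0(min(x), "-", max(x)) else ""
  do.call(rbind, lapply(hits, function(h) {
    data.frame(profile_id = h$profile_id,
               master_domain = h$master_domain,
               window_strands = h$window_strands,
               target_domain = h$target_domain,
               target_group = h$target_group,
               bit_score = h$bit_score, evalue = h$evalue,
               shuffle_pvalue = h$shuffle_pvalue,
               aln_master_range = rng(h$alignment$master_pos),
               aln_target_range = rng(h$alignment$target_pos),
               segment_rmsd = h$segment_rmsd)
  }))
}

# ---------------------------------------------------------------------------
# Plain-text serialization (documented key-value format, not HMMER3)

#' Write a profile HMM to a plain-text file
#' @param hmm A `profile_hmm`.
#' @param path Output path.
#' @export
write_hmm <- function(hmm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(formatC(x, format = "g", digits = 17),
                           collapse = " ")
  writeLines(c(
    "format trefoilthemes-hmm 1",
    paste("profile_id", hmm$provenance$profile_id),
    paste("master_id", hmm$provenance$master_id),
    paste("M", hmm$M),
    paste("alphabet", paste(AA_ALPHABET, collapse = "")),
    paste("background", num(hmm$background))), con)
  writeLines(vapply(seq_len(hmm$M), function(k) {
    paste("match", k, num(hmm$match_emissions[k, ]))
  }, ""), con)
  writeLines(vapply(seq_len(hmm$M + 1L), function(k) {
    paste("insert", k - 1L, num(hmm$insert_emissions[k, ]))
  }, ""), con)
  writeLines(vapply(seq_len(hmm$M), function(k) {
    paste("trans", k, num(hmm$transitions[k, ]))
  }, ""), con)
  if (!is.null(hmm$calibration)) {
    cal <- hmm$calibration
    writeLines(paste("calibration", num(c(cal$mu, cal$lam, cal$n_samples,
                                          cal$random_len, cal$db_size))),
               con)
  }
  invisible(path)
}

#' Read a profile HMM written by [write_hmm()]
#' @param path Path to the file.
#' @return A `profile_hmm`.
#' @export
read_hmm <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[[1]], "format trefoilthemes-hmm")) {
    stop("not a trefoilthemes HMM file: ", path)
  }
  fields <- strsplit(lines, " +")
  key <- vapply(fields, `[[`, "", 1)
  get1 <- function(k) fields[[match(k, key)]][[2]]
  M <- as.integer(get1("M"))
  nums <- function(v, from) as.numeric(v[from:length(v)])
  bg <- stats::setNames(nums(fields[[match("background", key)]], 2),
                        AA_ALPHABET)
  grab <- function(kind, nrow, offset = 0L) {
    m <- matrix(0, nrow, length(fields[[match(kind, key)]]) - 2L)
    for (f in fields[key == kind]) {
      m[as.integer(f[[2]]) + offset, ] <- nums(f, 3)
    }
    m
  }
  match_em <- grab("match", M); colnames(match_em) <- AA_ALPHABET
  insert_em <- grab("insert", M + 1L, offset = 1L)
  colnames(insert_em) <- AA_ALPHABET
  trans <- grab("trans", M); colnames(trans) <- TRANS_NAMES
  hmm <- structure(list(
    M = M, match_emissions = match_em, insert_emissions = insert_em,
    transitions = trans, background = bg,
    provenance = list(profile_id = get1("profile_id"),
                      master_id = get1("master_id"),
                      strand_span = NULL, residue_range = NULL,
                      match_positions = seq_len(M)),
    calibration = NULL), class = "profile_hmm")
  if ("calibration" %in% key) {
    v <- nums(fields[[match("calibration", key)]], 2)
    hmm$calibration <- list(mu = v[[1]], lam = v[[2]], n_samples = v[[3]],
                            random_len = v[[4]], db_size = v[[5]])
  }
  hmm
}
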