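# Secondary-structure assignment and the four-strand sliding windows that
# define candidate theme fragments on a master domain.

vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) v / vnorm(v)

# Backbone amide H position, DSSP convention: 1.0 A from N opposite the
# previous residue's carbonyl (H_i = N_i + unit(C_{i-1} - O_{i-1})).
backbone_h_positions <- function(structure) {
  n <- n_residues(structure)
  N <- structure$atoms$N; C <- structure$atoms$C; O <- structure$atoms$O
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (anyNA(c(N[i, ], C[i - 1, ], O[i - 1, ]))) next
    H[i, ] <- N[i, ] + unit(C[i - 1, ] - O[i - 1, ])
  }
  H
}

# Kabsch--Sander electrostatic hydrogen-bond energies.
# hb[i, j] is TRUE when the amide N-H of residue i donates to the
# carbonyl C=O of residue j with E < -0.5 kcal/mol,
# E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN).
backbone_hbonds <- function(structure, energy_cutoff = -0.5) {
  n <- n_residues(structure)
  N <- structure$atoms$N; C <- structure$atoms$C; O <- structure$atoms$O
  H <- backbone_h_positions(structure)
  hb <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  for (i in seq_len(n)) {
    if (anyNA(N[i, ]) || anyNA(H[i, ])) next  # proline-like / chain start
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L) next
      if (anyNA(C[j, ]) || anyNA(O[j, ])) next
      rON <- vnorm(O[j, ] - N[i, ])
      if (rON > 5.2) next  # beyond plausible H-bond range
      rCH <- vnorm(C[j, ] - H[i, ])
      rOH <- vnorm(O[j, ] - H[i, ])
      rCN <- vnorm(C[j, ] - N[i, ])
      e <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[i, j] <- e < energy_cutoff
    }
  }
  hb
}

#' Assign secondary structure from backbone coordinates
#'
#' A reduced DSSP-style assignment based on the Kabsch--Sander
#' electrostatic hydrogen-bond criterion: a residue is helix (`H`) when
#' it lies inside a run of at least two consecutive i -> i+4 backbone
#' hydrogen bonds, strand (`E`) when it participates in at least one
#' parallel or antiparallel bridge hydrogen-bond pair, and coil (`C`)
#' otherwise. Residues with incomplete backbone are coil.
#'
#' @param structure A `protein_structure` with N/CA/C/O coordinates.
#' @return A string over `{H,E,C}`, one letter per residue.
#' @export
assign_ss <- function(structure) {
  n <- n_residues(structure)
  if (n < 3L) return(strrep("C", n))
  hb <- backbone_hbonds(structure)
  ss <- rep("C", n)

  # helix: turn(i) = H-bond N-H(i+4) -> C=O(i); two consecutive turns
  # mark residues i+1 .. i+4 as helix (DSSP 4-turn rule).
  turn <- rep(FALSE, n)
  for (i in seq_len(n - 4L)) turn[i] <- hb[i + 4L, i]
  helix <- rep(FALSE, n)
  for (i in seq_len(n - 5L)) {
    if (turn[i] && turn[i + 1L]) helix[(i + 1L):(i + 4L)] <- TRUE
  }

  # strand: Kabsch--Sander bridge definitions, |i-j| >= 3.
  hb_at <- function(i, j) {
    i >= 1L && i <= n && j >= 1L && j <= n && hb[i, j]
  }
  bridge <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 3L) next
      anti <- (hb_at(i, j) && hb_at(j, i)) ||
        (hb_at(i - 1L, j + 1L) && hb_at(j - 1L, i + 1L))
      para <- (hb_at(i + 1L, j) && hb_at(j, i - 1L)) ||
        (hb_at(j + 1L, i) && hb_at(i, j - 1L))
      if (anti || para) { bridge[i] <- TRUE; break }
    }
  }
  ss[bridge] <- "E"
  ss[helix] <- "H"  # helix takes precedence, as in DSSP
  chars_to_seq(ss)
}

#' Maximal beta-strand segments of a secondary-structure string
#'
#' @param ss String over `{H,E,C}`.
#' @param min_len Minimum strand length kept (default 2, matching the
#'   shortest strands emitted by structure-based assigners).
#' @return Data frame with columns `index` (1-based strand ordinal),
#'   `start`, `end` (1-based inclusive residue positions).
#' @export
strand_segments <- function(ss, min_len = 2L) {
  stopifnot(min_len >= 1L)
  chars <- seq_to_chars(ss)
  r <- rle(chars == "E")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(index = seq_len(sum(keep)),
                    start = starts[keep], end = ends[keep])
  rownames(out) <- NULL
  out
}

#' Filter MSA rows by coverage and identity to the master
#'
#' Keeps rows whose non-gap overlap with the master columns is at least
#' `coverage_min` of the master's ungapped length and whose identity to
#' the master over mutually non-gap columns is at least `identity_min`
#' (both inclusive). The master row is always kept.
#'
#' @param msa An `msa`.
#' @param coverage_min Coverage cutoff, default 0.90.
#' @param identity_min Identity cutoff, default 0.30.
#' @param verbose Log dropped rows with the failing criterion.
#' @return Filtered `msa`.
#' @export
filter_msa <- function(msa, coverage_min = 0.90, identity_min = 0.30,
                       verbose = FALSE) {
  master <- seq_to_chars(msa_master_seq(msa))
  mcols <- which(master != "-")
  keep <- logical(length(msa$ids))
  for (r in seq_along(msa$ids)) {
    if (msa$ids[[r]] == msa$master_id) { keep[[r]] <- TRUE; next }
    row <- seq_to_chars(msa$seqs[[r]])
    nongap <- row[mcols] != "-"
    coverage <- mean(nongap)
    identity <- if (any(nongap)) {
      mean(row[mcols][nongap] == master[mcols][nongap])
    } else 0
    ok_cov <- coverage >= coverage_min
    ok_id <- identity >= identity_min
    keep[[r]] <- ok_cov && ok_id
    if (!keep[[r]] && verbose) {
      message("filter_msa: dropping ", msa$ids[[r]], " (",
              if (!ok_cov) sprintf("coverage %.2f < %.2f", coverage,
                                   coverage_min),
              if (!ok_cov && !ok_id) "; ",
              if (!ok_id) sprintf("identity %.2f < %.2f", identity,
                                  identity_min), ")")
    }
  }
  new_msa(msa$ids[keep], msa$seqs[keep], msa$master_id)
}

#' Sliding windows of k consecutive beta-strands
#'
#' @param segments Strand segment data frame from [strand_segments()].
#' @param k Window size in strands, default 4 (the repetitive structural
#'   unit of the beta-trefoil).
#' @return Data frame with columns `first_strand`, `last_strand`,
#'   `start`, `end` (residue range from the start of strand i to the
#'   end of strand i+k-1, including intervening loops).
#' @export
make_windows <- function(segments, k = 4L) {
  n <- nrow(segments)
  if (n < k) {
    return(data.frame(first_strand = integer(0), last_strand = integer(0),
                      start = integer(0), end = integer(0)))
  }
  i <- seq_len(n - k + 1L)
  data.frame(first_strand = i, last_strand = i + k - 1L,
             start = segments$start[i], end = segments$end[i + k - 1L])
}

# ungapped master position of each alignment column (NA at master gaps)
master_positions <- function(msa) {
  master <- seq_to_chars(msa_master_seq(msa))
  pos <- cumsum(master != "-")
  pos[master == "-"] <- NA_integer_
  pos
}

#' Restrict an MSA to a master residue range
#'
#' Keeps the alignment columns where the master has a non-gap residue
#' whose 1-based ungapped position lies in `residue_range`; drops rows
#' left entirely gapped (never the master).
#'
#' @param msa An `msa`.
#' @param residue_range Length-2 integer vector `(start, end)`, 1-based
#'   inclusive in master ungapped coordinates.
#' @return Restricted `msa`.
#' @export
restrict_msa <- function(msa, residue_range) {
  start <- residue_range[[1]]; end <- residue_range[[2]]
  pos <- master_positions(msa)
  mlen <- max(pos, na.rm = TRUE)
  if (start < 1L || end > mlen || start > end) {
    stop("residue range (", start, ",", end,
         ") outside master length ", mlen)
  }
  cols <- which(!is.na(pos) & pos >= start & pos <= end)
  seqs <- vapply(msa$seqs, function(s) {
    chars_to_seq(seq_to_chars(s)[cols])
  }, character(1), USE.NAMES = FALSE)
  keep <- grepl("[^-]", seqs) | msa$ids == msa$master_id
  new_msa(msa$ids[keep], seqs[keep], msa$master_id)
}

#' Cut four-strand fragment windows with their restricted MSAs
#'
#' @param msa Filtered `msa` for the master domain.
#' @param ss Secondary-structure string for the master's ungapped
#'   sequence.
#' @param k Strands per window (default 4).
#' @param min_strand_len Minimum strand length (default 2).
#' @return List of `fragment_window` objects with fields `master_id`,
#'   `strand_span`, `residue_range`, `msa`.
#' @export
fragment_windows <- function(msa, ss, k = 4L, min_strand_len = 2L) {
  master_len <- nchar(gsub("-", "", msa_master_seq(msa), fixed = TRUE))
  if (nchar(ss) != master_len) {
    stop("ss length (", nchar(ss), ") != master ungapped length (",
         master_len, ")")
  }
  segs <- strand_segments(ss, min_strand_len)
  wins <- make_windows(segs, k)
  out <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    out[[i]] <- structure(list(
      master_id = msa$master_id,
      strand_span = c(wins$first_strand[[i]], wins$last_strand[[i]]),
      residue_range = c(wins$start[[i]], wins$end[[i]]),
      msa = restrict_msa(msa, c(wins$start[[i]], wins$end[[i]]))
    ), class = "fragment_window")
  }
  out
}

#' @export
print.fragment_window <- function(x, ...) {
  cat("fragment_window: ", x$master_id, " strands ", x$strand_span[[1]],
      "-", x$strand_span[[2]], ", residues ", x$residue_range[[1]], "-",
      x$residue_range[[2]], " (", length(x$msa$ids), " rows)\n", sep = "")
  invisible(x)
}
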