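# Structural half of the analysis: rigid-body superposition, the
# motif-length-normalized TM-score search for the beta-trefoil-like (bTL)
# motif, segment RMSD for metamorphism statistics, and the conserved-water
# hydrogen-bond geometry (clamp and dry variants).

#' Kabsch least-squares superposition
#'
#' Optimal rigid superposition of `P` onto `Q` (rotation constrained to
#' be proper: determinant +1, reflections corrected).
#'
#' @param P,Q n x 3 coordinate matrices, n >= 3.
#' @return List: `rotation` (3 x 3), `translation` (length 3), `rmsd`.
#'   The superposed copy of `P` is `P %*% t(rotation) + translation`
#'   (rowwise).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) < 3L || nrow(P) != nrow(Q)) {
    stop("kabsch needs equal-length coordinate sets with n >= 3")
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Pr <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

apply_rt <- function(P, rt) {
  sweep(as.matrix(P) %*% t(rt$rotation), 2, rt$translation, "+")
}

#' TM-score distance scale d0
#' @param l_norm Normalization length.
#' @return `1.24 (l_norm - 15)^{1/3} - 1.8`, floored at 0.5 Angstrom
#'   (with a warning for lengths where the floor binds).
#' @export
tm_d0 <- function(l_norm) {
  d0 <- if (l_norm > 15) 1.24 * (l_norm - 15)^(1 / 3) - 1.8 else 0
  if (d0 < 0.5) {
    warning("d0 floor 0.5 A applied for L_norm = ", l_norm)
    d0 <- 0.5
  }
  d0
}

# TM contribution of distances d at scale d0, summed and normalized
tm_sum <- function(d, d0, l_norm) sum(1 / (1 + (d / d0)^2)) / l_norm

#' TM-score of a residue mapping, maximized over superpositions
#'
#' `TM = (1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (L_norm - 15)^{1/3} - 1.8` (floored at 0.5 A). The
#' superposition is optimized TM-style by iterative subset refinement:
#' superpose on the current close-pair subset, recompute distances,
#' re-select pairs with d below a cutoff swept down toward d0, and keep
#' the best score seen.
#'
#' @param mapping Data frame/list with `motif_idx`, `target_idx`
#'   (strictly increasing), or an n x 2 matrix.
#' @param motif_ca,target_ca CA coordinate matrices.
#' @param l_norm Normalization length (the motif length in this
#'   analysis, per the fixed-normalization convention).
#' @return List: `tm` (unitless, in (0,1]), `rmsd` over mapped pairs,
#'   `rt` the best superposition.
#' @export
tm_score <- function(mapping, motif_ca, target_ca, l_norm) {
  mapping <- as.matrix(as.data.frame(mapping))
  stopifnot(nrow(mapping) >= 3L)
  d0 <- tm_d0(l_norm)
  P <- motif_ca[mapping[, 1], , drop = FALSE]
  Q <- target_ca[mapping[, 2], , drop = FALSE]
  n <- nrow(P)
  best <- list(tm = -Inf, rmsd = NA_real_, rt = NULL)
  subset <- seq_len(n)
  for (cutoff in c(Inf, 8, 2 * d0 + 1, max(2 * d0, 3), max(d0 + 0.5, 2))) {
    for (iter in seq_len(20L)) {
      rt <- kabsch(P[subset, , drop = FALSE], Q[subset, , drop = FALSE])
      d <- sqrt(rowSums((apply_rt(P, rt) - Q)^2))
      tm <- tm_sum(d, d0, l_norm)
      if (tm > best$tm) {
        best <- list(tm = tm, rmsd = sqrt(mean(d^2)), rt = rt)
      }
      newsub <- which(d < cutoff)
      if (length(newsub) < 3L) {
        newsub <- order(d)[seq_len(3L)]
      }
      if (identical(newsub, subset)) break
      subset <- newsub
    }
  }
  best
}

#' Extract a (possibly discontinuous) motif from a structure
#'
#' @param structure A `protein_structure`.
#' @param segments Data frame with `start`, `end` author residue
#'   numbers (1-based inclusive), e.g. from [parse_residue_ranges()].
#' @return List: `ca` (CA matrix), `segment_lengths`, `residue_idx`
#'   (indices into the structure), `sequence`.
#' @export
extract_motif <- function(structure, segments) {
  resno <- structure$resno
  idx <- integer(0)
  seg_len <- integer(nrow(segments))
  for (s in seq_len(nrow(segments))) {
    want <- as.character(seq(segments$start[[s]], segments$end[[s]]))
    hit <- match(want, resno)
    if (anyNA(hit)) {
      stop("motif residues ", segments$start[[s]], "-", segments$end[[s]],
           " not all present in structure")
    }
    idx <- c(idx, hit)
    seg_len[[s]] <- length(hit)
  }
  list(ca = structure$atoms$CA[idx, , drop = FALSE],
       segment_lengths = seg_len,
       residue_idx = idx,
       sequence = chars_to_seq(seq_to_chars(structure$sequence)[idx]))
}

# all gapless threadings of motif segments onto target positions:
# returns list of integer vectors (target indices), order-preserving
# with inter-segment gaps >= 0
segment_threadings <- function(segment_lengths, target_len, stride = 1L) {
  n_seg <- length(segment_lengths)
  out <- list()
  rec <- function(seg, min_start, acc) {
    if (seg > n_seg) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    l <- segment_lengths[[seg]]
    remaining <- if (seg < n_seg) {
      sum(segment_lengths[(seg + 1L):n_seg])
    } else 0L
    hi <- target_len - l - remaining + 1L
    if (hi < min_start) return(invisible())
    starts <- seq.int(min_start, hi, by = stride)
    for (s in starts) rec(seg + 1L, s + l, c(acc, seq.int(s, s + l - 1L)))
  }
  if (sum(segment_lengths) <= target_len) rec(1L, 1L, integer(0))
  out
}

# monotone DP alignment of motif positions to target positions maximizing
# sum of 1/(1+(d_ij/d0)^2); gaps cost nothing (unmapped pairs add zero)
monotone_dp_mapping <- function(score) {
  n <- nrow(score); m <- ncol(score)
  dp <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      dp[i + 1L, j + 1L] <- max(dp[i, j] + score[i, j],
                                dp[i, j + 1L], dp[i + 1L, j])
    }
  }
  # traceback
  mi <- integer(0); ti <- integer(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    v <- dp[i + 1L, j + 1L]
    if (v == dp[i, j] + score[i, j]) {
      mi <- c(i, mi); ti <- c(j, ti); i <- i - 1L; j <- j - 1L
    } else if (v == dp[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  cbind(motif_idx = mi, target_idx = ti)
}

#' Search a target chain for the structural motif
#'
#' TM-align-style simplified search: (a) seed with all gapless
#' threadings of the motif segments at all target offsets (segment
#' order preserved, non-negative inter-segment gaps), scored by
#' [tm_score()]; (b) refine the best seeds by iterating superposition
#' on close pairs and monotone dynamic programming on the matrix
#' `1/(1 + (d_ij/d0)^2)` until the mapping is stable (at most 20
#' rounds).
#'
#' @param motif Motif from [extract_motif()] (or a list with `ca` and
#'   `segment_lengths`).
#' @param target_ca Target CA coordinate matrix.
#' @param l_norm Normalization length; defaults to the motif length.
#' @param n_seeds Number of top threadings refined (default 5).
#' @param stride Threading stride over target offsets (default 1: all
#'   offsets).
#' @return Object of class `motif_hit`: `tm_score`, `rmsd`, `mapping`
#'   (strictly increasing in both coordinates), `rt`. When no threading
#'   is feasible the hit has `tm_score = 0` and an empty mapping.
#' @export
motif_search <- function(motif, target_ca, l_norm = NULL, n_seeds = 5L,
                         stride = 1L) {
  motif_ca <- motif$ca
  lm <- nrow(motif_ca)
  l_norm <- l_norm %||% lm
  lt <- nrow(target_ca)
  if (lt < ceiling(lm / 2)) {
    stop("target too short for motif search (", lt, " < ", lm, "/2)")
  }
  d0 <- suppressWarnings(tm_d0(l_norm))
  threads <- segment_threadings(motif$segment_lengths, lt, stride)
  if (length(threads) == 0L) {
    return(structure(list(tm_score = 0, rmsd = NA_real_,
                          mapping = cbind(motif_idx = integer(0),
                                          target_idx = integer(0)),
                          rt = NULL), class = "motif_hit"))
  }
  # quick superposition score for every threading
  quick <- vapply(threads, function(tt) {
    rt <- kabsch(motif_ca, target_ca[tt, , drop = FALSE])
    d <- sqrt(rowSums((apply_rt(motif_ca, rt) -
                         target_ca[tt, , drop = FALSE])^2))
    tm_sum(d, d0, l_norm)
  }, 0)
  seeds <- threads[order(quick, decreasing = TRUE)[
    seq_len(min(n_seeds, length(threads)))]]

  best <- list(tm = -Inf)
  for (tt in seeds) {
    mapping <- cbind(motif_idx = seq_len(lm), target_idx = tt)
    prev <- NULL
    for (iter in seq_len(20L)) {
      sc <- tm_score(mapping, motif_ca, target_ca, l_norm)
      if (sc$tm > best$tm) {
        best <- list(tm = sc$tm, rmsd = sc$rmsd, rt = sc$rt,
                     mapping = mapping)
      }
      # re-derive mapping from the current superposition
      moved <- apply_rt(motif_ca, sc$rt)
      dmat <- outer(rowSums(moved^2), rowSums(target_ca^2), "+") -
        2 * moved %*% t(target_ca)
      dmat[dmat < 0] <- 0
      smat <- 1 / (1 + dmat / d0^2)
      new_mapping <- monotone_dp_mapping(smat)
      if (nrow(new_mapping) < 3L) break
      if (!is.null(prev) && identical(new_mapping, prev)) break
      prev <- mapping
      mapping <- new_mapping
    }
  }
  structure(list(tm_score = best$tm, rmsd = best$rmsd,
                 mapping = best$mapping, rt = best$rt),
            class = "motif_hit")
}

#' @export
print.motif_hit <- function(x, ...) {
  cat(sprintf("motif_hit: TM = %.3f, rmsd = %.2f A over %d pairs\n",
              x$tm_score, x$rmsd, nrow(x$mapping)))
  invisible(x)
}

#' Segment RMSD of an aligned theme (metamorphism measure)
#'
#' Kabsch RMSD over the aligned CA pairs of a theme alignment. Pairs
#' with a missing CA on either side are dropped; fewer than 3 surviving
#' pairs gives NA (flagged undefined).
#'
#' @param alignment Data frame with columns `pos_a`, `pos_b` (or
#'   `master_pos`/`target_pos`).
#' @param coords_a,coords_b CA coordinate matrices indexed by those
#'   positions.
#' @return RMSD in Angstrom, or NA if undefined.
#' @export
theme_rmsd <- function(alignment, coords_a, coords_b) {
  pa <- alignment$pos_a %||% alignment$master_pos
  pb <- alignment$pos_b %||% alignment$target_pos
  ok <- pa >= 1 & pa <= nrow(coords_a) & pb >= 1 & pb <= nrow(coords_b)
  pa <- pa[ok]; pb <- pb[ok]
  A <- coords_a[pa, , drop = FALSE]
  B <- coords_b[pb, , drop = FALSE]
  keep <- !is.na(A[, 1]) & !is.na(B[, 1])
  if (sum(keep) < 3L) return(NA_real_)
  kabsch(A[keep, , drop = FALSE], B[keep, , drop = FALSE])$rmsd
}

# ---------------------------------------------------------------------------
# Conserved-water geometry

#' Find conserved-water hydrogen-bond motifs
#'
#' For every water in the structure, lists backbone N/O atoms of the
#' motif residues within `max_cutoff` and keeps the water when at least
#' three distinct residues have an atom within `short_cutoff` (the
#' hallmark three short backbone hydrogen bonds). Partner context is
#' taken from the secondary structure (`E` -> strand, else loop).
#'
#' @param structure A `protein_structure` with waters and an `ss`
#'   string (or `ss` supplied separately).
#' @param motif_residues Integer indices of motif residues considered
#'   as partners (default: all residues).
#' @param short_cutoff Hydrogen-bond distance for "short" bonds,
#'   default 3.0 Angstrom.
#' @param max_cutoff Listing cutoff for partners, default 3.5 Angstrom.
#' @param ss Optional ss string overriding `structure$ss`.
#' @return List of `water_motif_report` objects: `water_id`, `partners`
#'   (data frame: residue, atom, distance), `partner_context`
#'   (strand/loop per partner), `n_short_hbonds`, `clamp`, `dry`
#'   (clamp/dry start as NA; filled by [hydrophobic_clamp()] /
#'   [detect_dry_motif()] callers). Empty list when there are no
#'   qualifying waters.
#' @export
find_water_motif <- function(structure, motif_residues = NULL,
                             short_cutoff = 3.0, max_cutoff = 3.5,
                             ss = NULL) {
  if (is.null(structure$waters) || nrow(structure$waters) == 0L) {
    return(list())
  }
  ss <- ss %||% structure$ss
  if (is.null(ss)) stop("find_water_motif needs ss assignments")
  ssc <- seq_to_chars(ss)
  motif_residues <- motif_residues %||% seq_len(n_residues(structure))
  reports <- list()
  for (wi in seq_len(nrow(structure$waters))) {
    w <- structure$waters[wi, ]
    partners <- NULL
    for (r in motif_residues) {
      for (a in c("N", "O")) {
        xyz <- structure$atoms[[a]][r, ]
        if (anyNA(xyz)) next
        d <- vnorm(xyz - w)
        if (d <= max_cutoff) {
          partners <- rbind(partners,
                            data.frame(residue = r, atom = a,
                                       distance = d))
        }
      }
    }
    if (is.null(partners)) next
    short <- partners[partners$distance <= short_cutoff, , drop = FALSE]
    if (length(unique(short$residue)) < 3L) next
    ctx <- ifelse(ssc[partners$residue] == "E", "strand", "loop")
    reports[[length(reports) + 1L]] <- structure(list(
      water_id = rownames(structure$waters)[[wi]],
      partners = partners,
      partner_context = ctx,
      n_short_hbonds = nrow(short),
      clamp = NA, dry = NA), class = "water_motif_report")
  }
  reports
}

#' @export
print.water_motif_report <- function(x, ...) {
  cat("water_motif_report: ", x$water_id, ", ", x$n_short_hbonds,
      " short H-bonds, contexts {",
      paste(x$partner_context, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C")

#' Hydrophobic clamp test for the two strand water partners
#'
#' TRUE when both strand-partner residues are hydrophobic
#' (A/V/L/I/M/F/W/Y/C) and their side chains are in contact. With full
#' side chains the criterion is a minimal heavy-atom distance of at
#' most `contact_cutoff`; at backbone resolution the CB--CB distance is
#' used as a proxy with cutoff `cb_cutoff`.
#'
#' @param structure A `protein_structure`.
#' @param strand_partner_residues Integer indices of the two strand
#'   residues whose backbone binds the conserved water.
#' @param contact_cutoff Side-chain heavy-atom cutoff, default 5.0 A.
#' @param cb_cutoff CB-proxy cutoff, default 6.5 A.
#' @return Logical.
#' @export
hydrophobic_clamp <- function(structure, strand_partner_residues,
                              contact_cutoff = 5.0, cb_cutoff = 6.5) {
  stopifnot(length(strand_partner_residues) == 2L)
  r1 <- strand_partner_residues[[1]]; r2 <- strand_partner_residues[[2]]
  seqv <- seq_to_chars(structure$sequence)
  if (!(seqv[[r1]] %in% HYDROPHOBIC && seqv[[r2]] %in% HYDROPHOBIC)) {
    return(FALSE)
  }
  side_atoms <- function(r) {
    out <- NULL
    for (a in c("CB", "CG", "CD", "CE")) {
      m <- structure$atoms[[a]]
      if (!is.null(m) && !anyNA(m[r, ])) out <- rbind(out, m[r, ])
    }
    out
  }
  a1 <- side_atoms(r1); a2 <- side_atoms(r2)
  if (is.null(a1) || is.null(a2)) return(FALSE)
  if (nrow(a1) > 1L && nrow(a2) > 1L) {
    dmin <- min(sqrt(outer(rowSums(a1^2), rowSums(a2^2), "+") -
                       2 * a1 %*% t(a2)))
    return(dmin <= contact_cutoff)
  }
  vnorm(a1[1, ] - a2[1, ]) <= cb_cutoff
}

#' Detect the proline-mediated dry variant of the motif
#'
#' TRUE when the structure has no qualifying conserved water on the
#' mapped motif residues and at least one proline occupies a mapped
#' backbone hydrogen-bond donor position (proline's backbone nitrogen
#' cannot donate, which is what eliminates the water site). Structures
#' with neither water nor donor-position proline are not dry, merely
#' incomplete.
#'
#' @param structure A `protein_structure` (with `ss`).
#' @param motif_hit A `motif_hit` whose mapping identifies the motif
#'   residues on the target.
#' @param donor_motif_idx Motif-frame indices of the water's backbone
#'   donor positions.
#' @param ... Passed to [find_water_motif()].
#' @return Logical.
#' @export
detect_dry_motif <- function(structure, motif_hit, donor_motif_idx, ...) {
  mapped <- motif_hit$mapping[, "target_idx"]
  wet <- find_water_motif(structure, motif_residues = mapped, ...)
  if (length(wet) > 0L) return(FALSE)
  donor_targets <- motif_hit$mapping[
    motif_hit$mapping[, "motif_idx"] %in% donor_motif_idx, "target_idx"]
  if (length(donor_targets) == 0L) return(FALSE)
  any(seq_to_chars(structure$sequence)[donor_targets] == "P")
}
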