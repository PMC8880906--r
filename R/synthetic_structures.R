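# Idealized synthetic structures: a four-strand antiparallel sheet with
# two hairpin turns and a long routed loop, carrying a planted water that
# hydrogen-bonds three designated backbone sites (one on beta1, one on
# beta2, one on the loop) -- the hallmark geometry of the
# beta-trefoil-like motif -- plus helix and coil decoys. Strands are
# built from ideal peptide internal coordinates; strand placement within
# the sheet is solved numerically against explicit hydrogen-bond
# distance targets.

deg2rad <- function(x) x * pi / 180

# place atom D bonded to c: |c-D| = r, angle(b,c,D) = theta,
# torsion(a,b,c,D) = phi (degrees)
place_atom <- function(a, b, c, r, theta, phi) {
  th <- deg2rad(theta); ph <- deg2rad(phi)
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- cbind(bc, pracma_cross(n, bc), n)
  d <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  as.numeric(c + m %*% d)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Ideal backbone from phi/psi torsions (omega fixed at 180).
# Bond lengths/angles: N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231 A;
# N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8 degrees.
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- place_atom(c(0, -1, 0), N[1, ], CA[1, ], 1.525, 111.2, phi[[1]])
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8,
                         psi[[i]] - 180)
    if (i == n) break
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2,
                             psi[[i]])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7,
                              180)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525,
                             111.2, phi[[i + 1]])
  }
  list(N = N, CA = CA, C = C, O = O)
}

# CB at standard geometry (CA-CB 1.53 A, N-CA-CB 110.5 deg,
# torsion C-N-CA-CB 122.55 deg)
place_cb <- function(N, CA, C) {
  place_atom(C, N, CA, 1.53, 110.5, 122.55)
}

# Extend a side chain one bond at a time, bending each new bond as far
# toward `target` as tetrahedral geometry allows (~66 degrees off the
# previous bond direction). Used to give the clamp residues Leu/Ile-like
# CG/CD atoms reaching across the water-binding pair.
bend_side_chain <- function(ca, cb, target, n_atoms = 2L, bond = 1.53) {
  out <- matrix(NA_real_, n_atoms, 3)
  prev_dir <- unit(cb - ca)
  cur <- cb
  for (k in seq_len(n_atoms)) {
    toward <- target - cur
    ortho <- toward - sum(toward * prev_dir) * prev_dir
    if (vnorm(ortho) < 1e-8) {
      ref <- if (abs(prev_dir[[1]]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      ortho <- pracma_cross(prev_dir, ref)
    }
    new_dir <- cos(deg2rad(66)) * prev_dir +
      sin(deg2rad(66)) * unit(ortho)
    cur <- cur + bond * unit(new_dir)
    out[k, ] <- cur
    prev_dir <- unit(new_dir)
  }
  out
}

# rotation matrix from a rotation vector (axis * angle, radians)
rotvec_matrix <- function(v) {
  th <- vnorm(v)
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

transform_atoms <- function(atoms, R, t) {
  lapply(atoms, function(m) sweep(m %*% t(R), 2, t, "+"))
}

# Amide hydrogen positions for a strand atom set (template-internal:
# H_i is placed 1.0 A from N_i opposite the carbonyl of residue i-1;
# residue 1 has no H).
strand_h <- function(atoms) {
  n <- nrow(atoms$N)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    H[i, ] <- atoms$N[i, ] + unit(atoms$C[i - 1, ] - atoms$O[i - 1, ])
  }
  H
}

ks_energy <- function(Ni, Hi, Cj, Oj) {
  q <- 0.084 * 332
  q * (1 / vnorm(Oj - Ni) + 1 / vnorm(Cj - Hi) -
         1 / vnorm(Oj - Hi) - 1 / vnorm(Cj - Ni))
}

# Place a new strand next to a reference strand so that the designed
# narrow (doubly hydrogen-bonded) pairs are genuine Kabsch-Sander
# hydrogen bonds and no backbone/side-chain atoms clash. The new
# strand's uniform (phi, psi) are optimized together with its rigid
# placement, because straight ideal strands cannot satisfy both the
# bond orientations and a physical pleat at fixed torsions. `pairs` is
# a data frame with columns ref_res, new_res listing the narrow pairs.
# Returns the placed atoms (N, CA, C, O, CB) with attribute
# "objective".
place_strand_energy <- function(ref, pairs, flip, init_offset,
                                L = 7L, e_target = -1.3) {
  base <- build_backbone(rep(-139, L), rep(135, L))
  ca <- base$CA
  axis <- unit(ca[L, ] - ca[1, ])
  centroid <- colMeans(ca)
  co <- base$O - base$C
  sgn <- rep_len(c(1, -1), L)
  lateral <- unit(colSums(co * sgn))
  normal <- unit(pracma_cross(axis, lateral))
  cands <- if (flip) {
    list(rotvec_matrix(normal * pi), rotvec_matrix(lateral * pi))
  } else {
    list(diag(3), rotvec_matrix(axis * pi))
  }
  ref_h <- strand_h(ref)
  add_cb <- function(atoms) {
    atoms$CB <- t(vapply(seq_len(L), function(i) {
      place_cb(atoms$N[i, ], atoms$CA[i, ], atoms$C[i, ])
    }, numeric(3)))
    atoms
  }
  pair_d <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    d2[d2 < 0] <- 0
    sqrt(d2)
  }
  build_moved <- function(par, R0) {
    tpl <- add_cb(build_backbone(rep(-139 + 20 * par[[7]], L),
                                 rep(135 + 20 * par[[8]], L)))
    R <- rotvec_matrix(par[1:3]) %*% R0
    t0 <- init_offset + par[4:6] - as.numeric(R %*% centroid) + centroid
    transform_atoms(tpl, R, t0)
  }
  make_obj <- function(R0) {
    function(par) {
      moved <- build_moved(par, R0)
      moved_h <- strand_h(moved)
      err <- 0.05 * (par[[7]]^2 + par[[8]]^2)
      for (r in seq_len(nrow(pairs))) {
        i <- pairs$ref_res[[r]]; l <- pairs$new_res[[r]]
        d1 <- vnorm(ref$N[i, ] - moved$O[l, ])
        d2 <- vnorm(moved$N[l, ] - ref$O[i, ])
        err <- err + pmax(0, d1 - 3.2)^2 + pmax(0, 2.7 - d1)^2 +
          pmax(0, d2 - 3.2)^2 + pmax(0, 2.7 - d2)^2
        if (i >= 2L) {  # ref residue i donates to moved residue l
          e <- ks_energy(ref$N[i, ], ref_h[i, ], moved$C[l, ],
                         moved$O[l, ])
          err <- err + pmax(0, e - e_target)^2
        }
        if (l >= 2L) {  # moved residue l donates to ref residue i
          e <- ks_energy(moved$N[l, ], moved_h[l, ], ref$C[i, ],
                         ref$O[i, ])
          err <- err + pmax(0, e - e_target)^2
        }
      }
      err <- err + sum(pmax(0, 4.2 - pair_d(moved$CA, ref$CA))^2)
      err <- err + sum(pmax(0, 3.6 - pair_d(moved$CB, ref$CB))^2) +
        sum(pmax(0, 3.6 - pair_d(moved$CB, ref$CA))^2) +
        sum(pmax(0, 3.6 - pair_d(moved$CA, ref$CB))^2)
      err
    }
  }
  best <- NULL
  for (R0 in cands) {
    obj <- make_obj(R0)
    fit <- stats::optim(rep(0, 8), obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 500))
    if (is.null(best) || fit$value < best$fit$value) {
      best <- list(fit = fit, R0 = R0)
    }
  }
  out <- build_moved(best$fit$par, best$R0)
  attr(out, "objective") <- best$fit$value
  out
}

# n_interior CA positions on a circular arc from P to Q bulging toward
# `bulge_dir`, with all consecutive chords (including P-first and
# last-Q) equal to `step`. Handles both minor (< 180 degree) and major
# (tight-turn) arcs: the per-chord angle is solved on (0, 2*pi/n) where
# the spanned-chord function is monotone, then the center side and
# rotation sense are chosen so the arc closes on Q and its apex lies on
# the bulge side.
arc_loop <- function(P, Q, n_interior, bulge_dir, step = 3.8) {
  n_chord <- n_interior + 1L
  chord <- vnorm(Q - P)
  if (n_chord * step <= chord) {
    stop("loop too short to span ", round(chord, 1), " A with ",
         n_chord, " steps")
  }
  g <- function(dth) step * sin(n_chord * dth / 2) / sin(dth / 2) - chord
  dth <- stats::uniroot(g, c(1e-6, 2 * pi / n_chord - 1e-6),
                        tol = 1e-12)$root
  R <- step / (2 * sin(dth / 2))
  u <- unit(Q - P)
  b <- bulge_dir - sum(bulge_dir * u) * u
  if (vnorm(b) < 1e-8) stop("bulge direction parallel to chord")
  b <- unit(b)
  mid <- (P + Q) / 2
  h <- sqrt(max(R^2 - (chord / 2)^2, 0))
  pts_for <- function(center, sense) {
    axis <- pracma_cross(P - center, Q - center)
    if (vnorm(axis) < 1e-9) axis <- pracma_cross(P - center, b)
    axis <- unit(axis) * sense
    out <- matrix(NA_real_, n_interior + 1L, 3)
    for (k in seq_len(n_interior + 1L)) {
      Rk <- rotvec_matrix(axis * (k * dth))
      out[k, ] <- center + as.numeric(Rk %*% (P - center))
    }
    out
  }
  best <- NULL
  for (center in list(mid - h * b, mid + h * b)) {
    for (sense in c(1, -1)) {
      pts <- pts_for(center, sense)
      closes <- vnorm(pts[n_interior + 1L, ] - Q) < 1e-3
      if (!closes) next
      apex <- pts[ceiling((n_interior + 1L) / 2), ]
      on_bulge <- sum((apex - mid) * b)
      if (is.null(best) || on_bulge > best$score) {
        best <- list(pts = pts[seq_len(n_interior), , drop = FALSE],
                     score = on_bulge)
      }
    }
  }
  if (is.null(best)) stop("arc construction failed to close")
  best$pts
}

# Route a loop of n_interior CA positions from P to Q by relaxing a
# lifted polyline: stiff springs keep consecutive CA distances at
# `step`, hinge penalties keep the path clear of the already-placed
# context CAs (and of itself), and optional anchors pin designated
# residues (e.g. the water-donor loop residue) at target points.
route_loop <- function(P, Q, n_interior, bulge_dir, context,
                       anchors = list(), avoid = list(), step = 3.8,
                       clearance = 4.4) {
  b <- unit(bulge_dir)
  npts <- n_interior + 2L
  frac <- seq(0, 1, length.out = npts)
  base <- outer(1 - frac, P) + outer(frac, Q)
  lift <- sin(pi * frac)
  path_len <- function(amp) {
    pts <- base + outer(lift * amp, b)
    sum(sqrt(rowSums(diff(pts)^2)))
  }
  target_len <- step * (npts - 1L)
  amp <- if (path_len(0) >= target_len) 0 else {
    stats::uniroot(function(a) path_len(a) - target_len,
                   c(0, 4 * target_len), tol = 1e-8)$root
  }
  init <- (base + outer(lift * amp, b))[2:(npts - 1L), , drop = FALSE]

  obj <- function(x) {
    X <- matrix(x, ncol = 3)
    pts <- rbind(P, X, Q)
    d <- sqrt(rowSums(diff(pts)^2))
    err <- 30 * sum((d - step)^2)
    # self-avoidance (non-consecutive)
    dd <- as.matrix(stats::dist(pts))
    dd[abs(row(dd) - col(dd)) <= 1L] <- Inf
    err <- err + sum(pmax(0, clearance - dd)^2) / 2
    # context avoidance
    dc <- sqrt(outer(rowSums(X^2), rowSums(context^2), "+") -
                 2 * X %*% t(context))
    err <- err + sum(pmax(0, clearance - dc)^2, na.rm = TRUE)
    for (a in anchors) {
      err <- err + 30 * sum((X[a$idx, ] - a$point)^2)
    }
    for (av in avoid) {
      rows <- setdiff(seq_len(nrow(X)), av$exempt %||% integer(0))
      da <- sqrt(rowSums(sweep(X[rows, , drop = FALSE], 2,
                               av$point)^2))
      err <- err + sum(pmax(0, av$radius - da)^2)
    }
    err
  }
  fit <- stats::optim(as.numeric(init), obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  X <- matrix(fit$par, ncol = 3)
  d <- sqrt(rowSums(diff(rbind(P, X, Q))^2))
  if (any(abs(d - step) > 0.1)) {
    stop("loop routing failed: CA spacing off by ",
         round(max(abs(d - step)), 2), " A")
  }
  X
}

# crude backbone atoms for loop residues from a CA path: enough for
# chain continuity and distance-based tests; loops are coil by design
loop_backbone <- function(ca_prev, ca, ca_next, flip = 1) {
  u1 <- unit(ca - ca_prev)
  u2 <- unit(ca_next - ca)
  perp <- pracma_cross(u1, u2)
  perp <- if (vnorm(perp) < 1e-6) {
    u <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    unit(pracma_cross(u1, u))
  } else unit(perp)
  perp <- flip * perp
  N <- ca - 1.2 * u1 + 0.6 * perp
  C <- ca + 1.2 * u2 + 0.6 * perp
  O <- C + 1.231 * perp
  list(N = N, C = C, O = O)
}

#' Generate an idealized beta-trefoil-like motif structure
#'
#' Builds a 44-residue four-strand antiparallel sheet (strands of 7
#' residues; hairpin turns of 4 and 3 residues; a 9-residue loop
#' between strands 3 and 4 routed over the beta1/beta2 end of the
#' sheet). The terminal hydrogen-bond pair of the beta1-beta2 hairpin
#' is splayed and, unless `dry`, a water oxygen is planted there,
#' within 3.0 Angstrom of exactly three designated backbone sites: the
#' N of the last beta1 residue, the O of the first beta2 residue, and
#' the N of a loop residue. The two strand partners carry Leu/Ile with
#' CB atoms in contact (the hydrophobic clamp). In the `dry` variant
#' the water is omitted and the two backbone donor positions are set to
#' proline. Gaussian noise with RMS atomic displacement `noise_sigma`
#' is added to all coordinates.
#'
#' @param noise_sigma RMS displacement of the added coordinate noise, in
#'   Angstrom (per-axis sd `noise_sigma/sqrt(3)`); 0 for the ideal
#'   geometry.
#' @param dry Logical; build the proline "dry" variant without water.
#' @param seed Integer seed (sequence sampling and noise).
#' @return A `protein_structure` with attribute `truth`: list with
#'   `has_motif`, `is_dry`, `ss` (designed H/E/C string),
#'   `clamp_residues`, `water_partners` (data frame residue/atom),
#'   `donor_positions`, `motif_segments` (data frame start/end of the
#'   two search-motif segments), `water` (planted coordinate or NULL).
#' @export
generate_btl_structure <- function(noise_sigma = 0, dry = FALSE,
                                   seed = 1L) {
  stopifnot(noise_sigma >= 0)
  geom <- btl_ideal_geometry()
  n <- length(geom$kind)
  seqv <- withr_seed(seed, sample(AA_ALPHABET, n, replace = TRUE,
                                  prob = background_frequencies()))
  clamp <- geom$clamp_residues
  if (dry) {
    seqv[geom$donor_positions] <- "P"
  } else {
    seqv[clamp[[1]]] <- "L"
    seqv[clamp[[2]]] <- "I"
  }
  atoms <- geom$atoms
  # CB for any non-Gly/Pro strand residue
  atoms$CB <- matrix(NA_real_, n, 3)
  for (i in which(geom$kind == "E")) {
    if (seqv[[i]] %in% c("G", "P")) next
    atoms$CB[i, ] <- place_cb(atoms$N[i, ], atoms$CA[i, ], atoms$C[i, ])
  }
  if (!dry) {
    # Leu/Ile-like CG/CD atoms for the clamp pair, each side chain
    # bending toward the other across the water-binding hydrogen-bond
    # pair (the same-face side chains of a bonded pair meet only at the
    # gamma/delta level)
    atoms$CG <- matrix(NA_real_, n, 3)
    atoms$CD <- matrix(NA_real_, n, 3)
    r1 <- clamp[[1]]; r2 <- clamp[[2]]
    mid_cb <- (atoms$CB[r1, ] + atoms$CB[r2, ]) / 2
    for (r in c(r1, r2)) {
      sc <- bend_side_chain(atoms$CA[r, ], atoms$CB[r, ], mid_cb)
      atoms$CG[r, ] <- sc[1, ]
      atoms$CD[r, ] <- sc[2, ]
    }
  }
  waters <- if (dry) NULL else {
    matrix(geom$water, 1, 3, dimnames = list("W1", NULL))
  }
  if (noise_sigma > 0) {
    sdax <- noise_sigma / sqrt(3)
    atoms <- withr_seed(seed + 7L, {
      lapply(atoms, function(m) {
        m + matrix(stats::rnorm(length(m), 0, sdax), nrow(m), 3)
      })
    })
    if (!is.null(waters)) {
      waters <- waters + withr_seed(seed + 8L,
                                    matrix(stats::rnorm(3, 0, sdax), 1, 3))
    }
  }
  out <- new_structure(chars_to_seq(seqv), atoms, waters = waters,
                       ss = chars_to_seq(geom$kind))
  attr(out, "truth") <- list(
    has_motif = TRUE, is_dry = dry, ss = chars_to_seq(geom$kind),
    clamp_residues = clamp,
    water_partners = geom$water_partners,
    donor_positions = geom$donor_positions,
    motif_segments = geom$motif_segments,
    water = if (dry) NULL else geom$water)
  out
}

# The deterministic ideal geometry is expensive-ish to solve (three
# rigid placements by optimization), so cache it per session.
btl_geometry_cache <- new.env(parent = emptyenv())

btl_ideal_geometry <- function() {
  if (!is.null(btl_geometry_cache$geom)) return(btl_geometry_cache$geom)
  L <- 7L
  template <- build_backbone(rep(-139, L), rep(135, L))
  pairs_df <- function(...) {
    m <- do.call(rbind, list(...))
    data.frame(ref_res = m[, 1], new_res = m[, 2])
  }
  ca <- template$CA
  axis <- unit(ca[L, ] - ca[1, ])
  co <- template$O - template$C
  sgn <- rep_len(c(1, -1), L)
  lateral <- unit(colSums(co * sgn))

  template$CB <- t(vapply(seq_len(L), function(i) {
    place_cb(template$N[i, ], template$CA[i, ], template$C[i, ])
  }, numeric(3)))
  s1 <- template
  # strand 2: antiparallel; narrow (bonded) pairs (1,7),(3,5),(5,3),(7,1)
  s2 <- place_strand_energy(s1, pairs_df(c(1, 7), c(3, 5), c(5, 3),
                                         c(7, 1)),
                            flip = TRUE, init_offset = 4.9 * lateral)
  # strand 3: same orientation as s1, beyond s2;
  # bonded pairs (s2 local, s3 local): (2,6),(4,4),(6,2)
  s3 <- place_strand_energy(s2, pairs_df(c(2, 6), c(4, 4), c(6, 2)),
                            flip = FALSE,
                            init_offset = 2 * 4.9 * lateral)
  # strand 4: antiparallel to s3; bonded pairs (s3 local, s4 local):
  # (1,7),(3,5),(5,3),(7,1)
  s4 <- place_strand_energy(s3, pairs_df(c(1, 7), c(3, 5), c(5, 3),
                                         c(7, 1)),
                            flip = TRUE,
                            init_offset = 3 * 4.9 * lateral)

  up <- axis  # +axis end of s1 is the water-bearing hairpin end
  end_mid <- (s1$N[7, ] + s2$O[1, ]) / 2
  normal <- unit(pracma_cross(up, lateral))

  # water pocket: the point with the designated beta1/beta2 partners
  # (N of s1 residue 7, O of s2 residue 1) within hydrogen-bond reach
  # that is farthest from every other sheet backbone N/O -- found by a
  # coarse deterministic grid search around the hairpin end
  sheet_no <- NULL
  for (st in list(s1, s2, s3, s4)) sheet_no <- rbind(sheet_no, st$N, st$O)
  p1 <- s1$N[7, ]; p2 <- s2$O[1, ]
  is_partner <- rowSums(abs(sweep(sheet_no, 2, p1))) < 1e-9 |
    rowSums(abs(sweep(sheet_no, 2, p2))) < 1e-9
  grid <- as.matrix(expand.grid(a = seq(-5, 5, 0.25),
                                b = seq(-5, 5, 0.25),
                                c = seq(-5, 5, 0.25)))
  cand <- sweep(grid %*% rbind(lateral, up, normal), 2, end_mid, "+")
  ok <- sqrt(rowSums(sweep(cand, 2, p1)^2)) <= 2.95 &
    sqrt(rowSums(sweep(cand, 2, p2)^2)) <= 2.95
  cand <- cand[ok, , drop = FALSE]
  others_sheet <- sheet_no[!is_partner, , drop = FALSE]
  clearance <- apply(cand, 1, function(w) {
    min(sqrt(rowSums(sweep(others_sheet, 2, w)^2)))
  })
  pocket <- cand[which.max(clearance), ]

  # assemble chain: s1(1-7) turn(8-11) s2(12-18) turn(19-21) s3(22-28)
  # loop(29-38) s4(39-45)
  n <- 45L
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  put <- function(strand, at) {
    N[at, ] <<- strand$N; CA[at, ] <<- strand$CA
    C[at, ] <<- strand$C; O[at, ] <<- strand$O
  }
  put(s1, 1:7); put(s2, 12:18); put(s3, 22:28); put(s4, 39:45)

  # hairpin turns and the long loop are routed by spring relaxation
  # against everything already placed (plus the pocket, kept clear for
  # the water); the beta1-beta2 turn bulges away from the pocket side
  n_sign <- if (sum((pocket - end_mid) * normal) >= 0) 1 else -1
  strand_ca <- CA[c(1:7, 12:18, 22:28, 39:45), ]
  ctx1 <- rbind(strand_ca, pocket)
  CA[8:11, ] <- route_loop(CA[7, ], CA[12, ], 4L,
                           up - n_sign * 1.5 * normal, ctx1)
  ctx2 <- rbind(ctx1, CA[8:11, ])
  CA[19:21, ] <- route_loop(CA[18, ], CA[22, ], 3L, -up, ctx2)
  # the long loop passes outside the pocket; its middle residue is
  # anchored one hydrogen-bond-plus-amide offset from the pocket so its
  # amide nitrogen can donate the third bond
  out_dir <- pocket - end_mid
  out_dir <- out_dir - sum(out_dir * up) * up
  out_dir <- if (vnorm(out_dir) < 0.5) -n_sign * normal else unit(out_dir)
  waypoint <- pocket + 4.26 * out_dir
  ctx3 <- rbind(ctx2, CA[19:21, ])
  CA[29:38, ] <- route_loop(CA[28, ], CA[39, ], 10L, up + 0.6 * out_dir,
                            ctx3,
                            anchors = list(list(idx = 5L,
                                                point = waypoint)),
                            avoid = list(list(point = pocket,
                                              radius = 6.0,
                                              exempt = 5L)))

  for (i in c(8:11, 19:21, 29:38)) {
    # alternate the carbonyl face along loops so the two arms of the
    # routed loop cannot pair into a spurious bridge ladder
    bb <- loop_backbone(CA[i - 1L, ], CA[i, ], CA[i + 1L, ],
                        flip = (-1)^i)
    N[i, ] <- bb$N; C[i, ] <- bb$C; O[i, ] <- bb$O
  }
  # point the designated loop donor N toward the water pocket
  N[33, ] <- CA[33, ] + 1.46 * unit(pocket - CA[33, ])

  # re-aim the carbonyl of each loop residue preceding a strand start so
  # that the strand-start amide H (placed opposite that carbonyl) points
  # at its designed acceptor: residue 12 -> O(7), 22 -> O(45), 39 -> O(28)
  for (jn in list(c(11L, 12L, 7L), c(21L, 22L, 45L), c(38L, 39L, 28L))) {
    O[jn[[1]], ] <- C[jn[[1]], ] -
      1.231 * unit(O[jn[[3]], ] - N[jn[[2]], ])
  }

  atoms <- list(N = N, CA = CA, C = C, O = O)
  kind <- rep("C", n)
  kind[c(1:7, 12:18, 22:28, 39:45)] <- "E"

  # no non-consecutive CA pair may clash (arcs are routed, not packed)
  dca <- as.matrix(stats::dist(CA))
  dca[abs(row(dca) - col(dca)) <= 1L] <- Inf
  if (min(dca) < 3.5) {
    stop("internal geometry failure: routed chain self-clash at ",
         round(min(dca), 2), " A")
  }

  # water: 2.8 A from N(7), O(12), N(33); away from everything else
  partners <- list(c("N", 7L), c("O", 12L), c("N", 33L))
  others <- NULL
  other_lbl <- character(0)
  for (i in seq_len(n)) {
    for (a in c("N", "O")) {
      if (any(vapply(partners, function(p) {
        p[[1]] == a && as.integer(p[[2]]) == i
      }, TRUE))) next
      others <- rbind(others, atoms[[a]][i, ])
      other_lbl <- c(other_lbl, paste0(a, i))
    }
  }
  pcoords <- t(vapply(partners, function(p) {
    atoms[[p[[1]]]][as.integer(p[[2]]), ]
  }, numeric(3)))
  wobj <- function(w) {
    derr <- sum((sqrt(rowSums(sweep(pcoords, 2, w)^2)) - 2.8)^2)
    dmin <- sqrt(rowSums(sweep(others, 2, w)^2))
    derr + sum(pmax(0, 3.2 - dmin)^2)
  }
  wfit <- stats::optim(pocket, wobj, method = "BFGS",
                       control = list(maxit = 500))
  water <- wfit$par
  pd <- sqrt(rowSums(sweep(pcoords, 2, water)^2))
  od <- sqrt(rowSums(sweep(others, 2, water)^2))
  if (any(pd > 3.0) || any(od <= 3.05)) {
    near <- order(od)[1:3]
    stop("internal geometry failure: planted water misses a partner or ",
         "clashes (partners ", paste(round(pd, 2), collapse = ", "),
         " A; nearest others ",
         paste(paste0(other_lbl[near], "=", round(od[near], 2)),
               collapse = ", "), " A)")
  }
  geom <- list(
    atoms = atoms, kind = kind, water = water,
    water_partners = data.frame(residue = c(7L, 12L, 33L),
                                atom = c("N", "O", "N")),
    donor_positions = c(7L, 33L),
    clamp_residues = c(7L, 12L),
    motif_segments = data.frame(start = c(1L, 29L), end = c(18L, 39L)))
  btl_geometry_cache$geom <- geom
  geom
}

#' Generate a decoy structure without the motif geometry
#'
#' @param n_res Number of residues (>= 20).
#' @param kind `"helix"` (ideal alpha-helix, phi/psi -57/-47) or
#'   `"random_coil"` (random torsions).
#' @param seed Integer seed.
#' @return A `protein_structure` (no waters) with attribute `truth`
#'   (`has_motif = FALSE`, designed `ss`).
#' @export
generate_decoy_structure <- function(n_res, kind = c("helix",
                                                     "random_coil"),
                                     seed = 1L) {
  stopifnot(n_res >= 20L)
  kind <- match.arg(kind)
  tors <- withr_seed(seed, {
    if (kind == "helix") {
      list(phi = rep(-57, n_res), psi = rep(-47, n_res))
    } else {
      list(phi = stats::runif(n_res, -180, -30),
           psi = stats::runif(n_res, -180, 180))
    }
  })
  bb <- build_backbone(tors$phi, tors$psi)
  seqv <- withr_seed(seed + 1L, random_aa_sequence(n_res))
  ss_truth <- if (kind == "helix") strrep("H", n_res) else strrep("C", n_res)
  out <- new_structure(seqv, bb, ss = ss_truth)
  attr(out, "truth") <- list(has_motif = FALSE, is_dry = FALSE,
                             ss = ss_truth)
  out
}
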