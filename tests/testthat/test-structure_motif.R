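random_points <- function(n) matrix(stats::rnorm(n * 3, sd = 4), n, 3)
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}

test_that("superposition is exact for rigid copies and stays proper", {
  set.seed(91)
  P <- random_points(8)
  k0 <- kabsch(P, P)
  expect_equal(k0$rmsd, 0, tolerance = 1e-9)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)

  for (i in 1:10) {
    R <- random_rotation()
    t <- stats::rnorm(3)
    Q <- P %*% t(R) + matrix(t, nrow(P), 3, byrow = TRUE)
    k <- kabsch(P, Q)
    expect_equal(k$rmsd, 0, tolerance = 1e-8)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  }
  # mirror image of a chiral set cannot be superposed by a proper rotation
  P4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.3, 0), c(0.2, 0.4, 1.7))
  Qm <- P4 %*% diag(c(1, 1, -1))
  km <- kabsch(P4, Qm)
  expect_gt(km$rmsd, 0.1)
  expect_equal(det(km$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch(P4[1:2, ], P4[1:2, ]), "n >= 3")
})

test_that("superposition agrees with an independent structural-biology fit", {
  set.seed(101)
  P <- random_points(12)
  Q <- P %*% t(random_rotation()) + matrix(stats::rnorm(3), 12, 3,
                                           byrow = TRUE) +
    matrix(stats::rnorm(36, sd = 0.4), 12, 3)
  ours <- kabsch(P, Q)$rmsd
  ref <- bio3d::fit.xyz(fixed = as.numeric(t(Q)),
                        mobile = as.numeric(t(P)),
                        fixed.inds = 1:36, mobile.inds = 1:36)
  ref_rmsd <- sqrt(mean(rowSums(
    (matrix(ref, ncol = 3, byrow = TRUE) - Q)^2)))
  expect_equal(ours, ref_rmsd, tolerance = 1e-6)
})

test_that("three-point RMSD matches the rotation-grid oracle", {
  set.seed(111)
  for (i in 1:10) {
    P <- random_points(3)
    Q <- random_points(3)
    expect_equal(kabsch(P, Q)$rmsd, oracle_rmsd_grid(P, Q),
                 tolerance = 1e-4)
  }
})

test_that("the TM distance scale follows the cube-root law with a floor", {
  expect_equal(tm_d0(29), 1.24 * (29 - 15)^(1 / 3) - 1.8,
               tolerance = 1e-12)
  expect_equal(round(tm_d0(29), 3), 1.189)
  expect_warning(d <- tm_d0(16), "floor")
  expect_equal(d, 0.5)
})

test_that("TM-score is 1 for self-mappings and 0.5 at uniform d0 spacing", {
  set.seed(121)
  P <- random_points(29)
  m <- data.frame(motif_idx = 1:29, target_idx = 1:29)
  expect_equal(tm_score(m, P, P, 29)$tm, 1, tolerance = 1e-9)
  # the per-pair contribution at exactly d0 is 1/2 (analytic form)
  d0 <- tm_d0(29)
  expect_equal(trefoilthemes:::tm_sum(rep(d0, 29), d0, 29), 0.5,
               tolerance = 1e-12)
})

test_that("TM-score is invariant to rigid transforms of either side", {
  set.seed(131)
  s <- generate_btl_structure(0, seed = 1)
  motif <- extract_motif(s, attr(s, "truth")$motif_segments)
  target <- generate_btl_structure(0.8, seed = 6)$atoms$CA
  m <- motif_search(motif, target)
  base <- m$tm_score
  for (i in 1:3) {
    R <- random_rotation()
    t <- stats::rnorm(3, sd = 10)
    moved <- target %*% t(R) + matrix(t, nrow(target), 3, byrow = TRUE)
    expect_equal(motif_search(motif, moved)$tm_score, base,
                 tolerance = 1e-6)
  }
})

test_that("an embedded exact copy is found with TM 1 at any flank length", {
  set.seed(141)
  s <- generate_btl_structure(0, seed = 1)
  motif <- extract_motif(s, attr(s, "truth")$motif_segments)
  for (i in 1:5) {
    nf <- sample(5:40, 2)
    flank1 <- generate_decoy_structure(max(nf[1], 20), "random_coil",
                                       seed = 200 + i)$atoms$CA
    flank2 <- generate_decoy_structure(max(nf[2], 20), "random_coil",
                                       seed = 300 + i)$atoms$CA
    R <- random_rotation()
    core <- s$atoms$CA %*% t(R) + 5
    target <- rbind(flank1 + 60, core, flank2 - 60)
    hit <- motif_search(motif, target)
    expect_equal(hit$tm_score, 1, tolerance = 1e-6)
  }
})

test_that("noise degrades the TM-score monotonically on average", {
  s <- generate_btl_structure(0, seed = 1)
  motif <- extract_motif(s, attr(s, "truth")$motif_segments)
  med <- vapply(c(0, 0.5, 1.5), function(sig) {
    stats::median(vapply(1:5, function(i) {
      tgt <- generate_btl_structure(sig, seed = 400 + i)$atoms$CA
      motif_search(motif, tgt)$tm_score
    }, 0))
  }, 0)
  expect_true(all(diff(med) <= 1e-9))
  expect_gte(med[2], 0.8)  # 0.5 A RMS noise stays well above threshold
})

test_that("segment RMSD handles rigid copies and missing coordinates", {
  set.seed(151)
  A <- random_points(10)
  aln <- data.frame(pos_a = 1:10, pos_b = 1:10)
  expect_equal(theme_rmsd(aln, A, A), 0, tolerance = 1e-9)
  R <- random_rotation()
  expect_equal(theme_rmsd(aln, A, A %*% t(R) + 3), 0, tolerance = 1e-8)

  B <- A + matrix(stats::rnorm(30, sd = 1), 10, 3)
  B[4, ] <- NA
  expect_equal(theme_rmsd(aln, A, B),
               kabsch(A[-4, ], B[-4, ])$rmsd, tolerance = 1e-12)
  B2 <- B; B2[c(1:3, 5:9), ] <- NA
  expect_true(is.na(theme_rmsd(aln, A, B2)))
})

test_that("water reports capture the planted three-bond geometry", {
  s <- generate_btl_structure(0, seed = 1)
  reports <- find_water_motif(s)
  expect_length(reports, 1)
  r <- reports[[1]]
  expect_equal(r$n_short_hbonds, 3)
  short <- r$partners$distance <= 3.0
  expect_setequal(r$partner_context[short], c("strand", "strand", "loop"))
  expect_true(all(r$partners$distance > 0))

  # moving the water 1.5 A away from the pocket breaks the triad
  s2 <- s
  s2$waters[1, ] <- s2$waters[1, ] + c(1.5, 0, 0)
  expect_length(find_water_motif(s2), 0)

  s3 <- s; s3$waters <- NULL
  expect_length(find_water_motif(s3), 0)
})

test_that("the hydrophobic clamp requires hydrophobics in contact", {
  s <- generate_btl_structure(0, seed = 1)
  tr <- attr(s, "truth")
  expect_true(hydrophobic_clamp(s, tr$clamp_residues))

  sg <- s
  substr(sg$sequence, tr$clamp_residues[1], tr$clamp_residues[1]) <- "G"
  expect_false(hydrophobic_clamp(sg, tr$clamp_residues))

  far <- s
  for (a in c("CB", "CG", "CD")) {
    far$atoms[[a]][tr$clamp_residues[1], ] <-
      far$atoms[[a]][tr$clamp_residues[1], ] + 12
  }
  expect_false(hydrophobic_clamp(far, tr$clamp_residues))
})

test_that("dry motifs need both the missing water and a donor proline", {
  wet <- generate_btl_structure(0, seed = 1)
  dry <- generate_btl_structure(0, dry = TRUE, seed = 1)
  tr <- attr(wet, "truth")
  motif <- extract_motif(wet, tr$motif_segments)
  seg <- tr$motif_segments
  donor_motif_idx <- vapply(tr$donor_positions, function(p) {
    if (p <= seg$end[1]) p else seg$end[1] + (p - seg$start[2] + 1L)
  }, 0L)

  hit_dry <- motif_search(motif, dry$atoms$CA)
  expect_gte(hit_dry$tm_score, 0.5)
  expect_true(detect_dry_motif(dry, hit_dry, donor_motif_idx))

  hit_wet <- motif_search(motif, wet$atoms$CA)
  expect_false(detect_dry_motif(wet, hit_wet, donor_motif_idx))

  # no proline and no water: incomplete, not dry
  bare <- dry
  bare$sequence <- gsub("P", "A", bare$sequence)
  expect_false(detect_dry_motif(bare, hit_dry, donor_motif_idx))
})
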