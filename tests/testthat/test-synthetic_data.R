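test_that("family generation controls identity and is seed-deterministic", {
  master <- paste(rep("ACDEFGHIKW", 10), collapse = "")
  f0 <- generate_family(master, 5, 0, seed = 1)
  expect_true(all(f0$seqs == master))

  f1 <- generate_family(master, 10, 0.3, seed = 7)
  f2 <- generate_family(master, 10, 0.3, seed = 7)
  expect_identical(f1, f2)

  # binomial expectation: mean identity to master ~ 70% +/- 3 points
  f3 <- generate_family(master, 50, 0.3, seed = 11)
  ident <- vapply(f3$seqs[-1], function(s) {
    mean(strsplit(s, "")[[1]] == strsplit(master, "")[[1]])
  }, 0)
  expect_gt(mean(ident), 0.67)
  expect_lt(mean(ident), 0.73)
  expect_error(generate_family("", 5, 0.1, seed = 1), "empty")
})

test_that("theme planting substitutes in place at the stated divergence", {
  host <- strrep("A", 60)
  theme <- strrep("W", 20)
  p <- plant_theme(theme, host, 11, 0, seed = 1)
  expect_equal(substr(p, 11, 30), theme)
  expect_equal(nchar(p), 60)
  expect_equal(plant_theme(host, host, 1, 0, seed = 1), host)

  # binomial check at divergence 0.2 over length 30
  theme30 <- strrep("W", 30)
  matches <- vapply(1:40, function(i) {
    pl <- plant_theme(theme30, strrep("A", 40), 5, 0.2, seed = 100 + i)
    sum(strsplit(substr(pl, 5, 34), "")[[1]] == "W")
  }, 0)
  expect_gt(mean(matches), 24 - 2)  # E = 24, sd of mean ~ 0.35
  expect_lt(mean(matches), 24 + 2)
  expect_error(plant_theme(strrep("W", 70), host, 1, 0, seed = 1),
               "longer")
})

test_that("scenario construction records consistent ground truth", {
  sc <- generate_theme_scenario(seed = 5)
  expect_gte(nrow(sc$truth), 1)
  expect_gte(sum(startsWith(names(sc$families), "decoy")), 2)
  expect_false(any(grepl("decoy", sc$truth$target_domain)))

  # every truth window overlaps the planted segment by >= half its length
  segs <- strand_segments(sc$donor_ss)
  wins <- make_windows(segs)
  theme_range <- c(sc$theme$donor_pos,
                   sc$theme$donor_pos + nchar(sc$theme$sequence) - 1)
  for (pid in sc$truth$profile_id) {
    w <- as.integer(sub(".*_w", "", pid))
    row <- wins[wins$first_strand == w, ]
    ov <- min(row$end, theme_range[2]) - max(row$start, theme_range[1]) + 1
    expect_gte(ov, nchar(sc$theme$sequence) / 2)
  }

  # deterministic under seed
  expect_identical(generate_theme_scenario(seed = 5)$domains, sc$domains)
})

test_that("scenario writing produces alignments and a truth sidecar", {
  sc <- generate_theme_scenario(seed = 3)
  d <- withr::local_tempdir()
  write_scenario(sc, d)
  expect_true(file.exists(file.path(d, "donor.afa")))
  expect_true(file.exists(file.path(d, "truth.json")))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$theme$sequence, sc$theme$sequence)
})

test_that("idealized motif structures satisfy their geometric contract", {
  s <- generate_btl_structure(0, seed = 2)
  tr <- attr(s, "truth")
  ca <- s$atoms$CA
  d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_true(all(abs(d - 3.8) <= 0.1))

  w <- s$waters[1, ]
  pd <- vapply(seq_len(nrow(tr$water_partners)), function(i) {
    p <- tr$water_partners[i, ]
    sqrt(sum((s$atoms[[p$atom]][p$residue, ] - w)^2))
  }, 0)
  expect_true(all(pd <= 3.0))
  # ... and exactly those three: no other backbone N/O within 3 A
  extras <- 0
  for (i in seq_len(nchar(s$sequence))) {
    for (a in c("N", "O")) {
      if (any(tr$water_partners$residue == i & tr$water_partners$atom == a))
        next
      if (sqrt(sum((s$atoms[[a]][i, ] - w)^2)) <= 3.0) extras <- extras + 1
    }
  }
  expect_equal(extras, 0)

  expect_identical(generate_btl_structure(0, seed = 2)$atoms$CA, ca)
})

test_that("dry variant removes the water and plants donor prolines", {
  s <- generate_btl_structure(0, dry = TRUE, seed = 3)
  tr <- attr(s, "truth")
  expect_null(s$waters)
  expect_true(tr$is_dry)
  seqv <- strsplit(s$sequence, "")[[1]]
  expect_true(all(seqv[tr$donor_positions] == "P"))
})

test_that("decoy structures have the advertised secondary structure", {
  h <- generate_decoy_structure(40, "helix", seed = 4)
  ssh <- strsplit(assign_ss(h), "")[[1]]
  expect_gte(mean(ssh == "H"), 0.8)
  expect_false(attr(h, "truth")$has_motif)

  rc <- generate_decoy_structure(40, "random_coil", seed = 4)
  expect_length(find_water_motif(rc, ss = attr(rc, "truth")$ss), 0)
  expect_identical(generate_decoy_structure(40, "random_coil", seed = 4)$atoms$CA,
                   rc$atoms$CA)
})
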