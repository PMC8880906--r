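test_that("strand segments are maximal runs of E above the length cutoff", {
  segs <- strand_segments("CEEEECCEEECC", min_len = 3)
  expect_equal(segs$start, c(2, 8))
  expect_equal(segs$end, c(5, 10))
  expect_equal(segs$index, c(1, 2))
  expect_equal(nrow(strand_segments("CCCC")), 0)
  expect_equal(nrow(strand_segments("EE", min_len = 3)), 0)
})

test_that("four-strand windows slide one strand at a time", {
  segs <- data.frame(index = 1:6, start = c(1, 10, 20, 30, 40, 50),
                     end = c(5, 15, 25, 35, 45, 55))
  w <- make_windows(segs)
  expect_equal(nrow(w), 3)
  expect_equal(w$first_strand, 1:3)
  expect_equal(w$start, c(1, 10, 20))
  expect_equal(w$end, c(35, 45, 55))
  expect_equal(nrow(make_windows(segs[1:4, ])), 1)
  expect_equal(nrow(make_windows(segs[1:3, ])), 0)

  # invariant: window count = max(0, n - 3) for random strand counts
  for (n in c(0, 1, 4, 7, 12)) {
    ss <- paste(rep(c("EEE", "CC"), n), collapse = "")
    expect_equal(nrow(make_windows(strand_segments(ss))), max(0, n - 3))
  }
})

test_that("MSA filter applies inclusive coverage and identity cutoffs", {
  master <- strrep("A", 10)
  rows <- c(master,
            strrep("A", 10),                      # identical: kept
            paste0(strrep("A", 5), strrep("-", 5)),  # 50% coverage: out
            paste0("AAA", strrep("W", 7)))        # 30% identity: kept
  msa <- new_msa(c("m", "same", "gappy", "edge"), rows)
  kept <- filter_msa(msa)
  expect_setequal(kept$ids, c("m", "same", "edge"))
})

test_that("MSA restriction keeps master-indexed columns and drops empty rows", {
  msa <- new_msa(c("m", "r1", "r2"),
                 c("A-CD", "AW--", "--C-"))
  r <- restrict_msa(msa, c(2, 3))
  expect_equal(r$seqs[[match("m", r$ids)]], "CD")
  expect_false("r1" %in% r$ids)  # entirely gapped in columns 3-4
  expect_true("r2" %in% r$ids)

  full <- restrict_msa(msa, c(1, 3))
  expect_equal(nchar(full$seqs[[1]]), 3)
  # idempotence
  again <- restrict_msa(r, c(1, 2))
  expect_equal(again$seqs[[match("m", again$ids)]], "CD")
  expect_error(restrict_msa(msa, c(2, 9)), "outside")
})

test_that("fragment windows carry restricted MSAs in master coordinates", {
  master <- paste(rep("ACDEFGHIKL", 6), collapse = "")  # 60 residues
  msa <- generate_family(master, 6, 0.1, seed = 2, family_id = "dom")
  ss <- paste(rep(c(strrep("E", 5), strrep("C", 5)), 6), collapse = "")
  wins <- fragment_windows(msa, ss)
  expect_length(wins, 3)  # 6 strands -> 3 windows
  w1 <- wins[[1]]
  expect_equal(w1$residue_range, c(1, 35))
  expect_equal(nchar(w1$msa$seqs[[1]]), 35)
})

test_that("hydrogen-bond ss assignment recovers designed sheets and helices", {
  s <- generate_btl_structure(0, seed = 1)
  truth <- attr(s, "truth")$ss
  got <- assign_ss(s)
  agreement <- mean(strsplit(got, "")[[1]] == strsplit(truth, "")[[1]])
  expect_gte(agreement, 0.95)

  h <- generate_decoy_structure(30, "helix", seed = 2)
  ssh <- strsplit(assign_ss(h), "")[[1]]
  expect_true(all(ssh[5:25] == "H"))

  # a single fully extended chain has no partners: all coil
  lone <- trefoilthemes:::build_backbone(rep(-139, 12), rep(135, 12))
  st <- new_structure(strrep("A", 12), lone)
  expect_equal(assign_ss(st), strrep("C", 12))
})
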