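test_that("FASTA reading normalizes case, strips stops, preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acde", ">b desc", "WXYZ*"), f)
  seqs <- read_fasta(f)
  expect_equal(unname(seqs[1]), "ACDE")
  expect_equal(unname(seqs[2]), "WXYZ")
  expect_equal(names(seqs), c("a", "b desc"))
})

test_that("FASTA writer round-trips random records", {
  set.seed(11)
  seqs <- setNames(
    vapply(1:100, function(i) {
      paste(sample(aa_alphabet(), sample(10:60, 1), replace = TRUE),
            collapse = "")
    }, ""),
    paste0("rec", 1:100))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})

test_that("empty or malformed FASTA errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("alignment reading enforces equal widths and normalizes gaps", {
  f <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">m", "AC-DE", ">r", "AC.DF"), f)
  msa <- read_alignment(f)
  expect_length(msa$ids, 2)
  expect_equal(msa$seqs[[2]], "AC-DF")
  expect_equal(msa$master_id, "m")

  g <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">m", "ACDE", ">bad", "ACD"), g)
  expect_error(read_alignment(g), "bad")
})

test_that("residue ranges parse as 1-based inclusive segments", {
  segs <- parse_residue_ranges("52-69,77-87")
  expect_equal(segs$start, c(52, 77))
  expect_equal(segs$end, c(69, 87))
  expect_equal(segs$end - segs$start + 1, c(18, 11))
  expect_error(parse_residue_ranges("10-5"), "start > end")
})

test_that("group labels parse into X/T/F with partial depth allowed", {
  g <- parse_group("6.1.1")
  expect_equal(c(g$x, g$t, g$f), c(6, 1, 1))
  g2 <- parse_group("6")
  expect_equal(g2$x, 6)
  expect_true(is.na(g2$t) && is.na(g2$f))
  expect_error(parse_group("a.b"), "dot-separated")
})

test_that("domain tables parse ranges and flag bad lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("domain_id\tpdb\tchain\trange\tgroup",
               "e4ow4A1\t4OW4\tA\t52-69,77-87\t6.1.1",
               "eXXX\t1ABC\tB\t1-50\t11.1.1"), f)
  tab <- read_domain_table(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$xgroup, c(6, 11))
  expect_equal(tab$segments[[1]]$end - tab$segments[[1]]$start + 1,
               c(18, 11))

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("domain_id\tpdb\tchain\trange\tgroup",
               "bad\t1ABC\tA\t9-2\t1.1.1"), g)
  expect_error(read_domain_table(g), "line 2")
})

test_that("structures round-trip through PDB within coordinate precision", {
  s <- generate_btl_structure(0, seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f, "A")
  expect_equal(s2$sequence, s$sequence)
  expect_equal(nrow(s2$waters), 1)
  expect_lt(max(abs(s2$atoms$CA - s$atoms$CA)), 1e-3)
  expect_lt(max(abs(s2$waters - s$waters)), 1e-3)
  expect_error(read_structure(f, "Z"), "chain")
})

test_that("hit tables round-trip with fixed columns", {
  hits <- data.frame(profile_id = "p1", master_domain = "m",
                     window_strands = "1-4", target_domain = "t",
                     target_group = "11.1.1", bit_score = 12.5,
                     evalue = 1e-5, shuffle_pvalue = 0.001,
                     aln_master_range = "3-30",
                     aln_target_range = "40-67", segment_rmsd = NA)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, f)
  back <- read_hit_table(f)
  expect_equal(back$bit_score, 12.5)
  expect_equal(names(back), trefoilthemes:::HIT_TABLE_COLS)
})

test_that("profile HMMs serialize and rescore identically", {
  msa <- generate_family(paste(rep("ACDEFGHIKL", 3), collapse = ""),
                         8, 0.2, seed = 4)
  hmm <- build_hmm(msa)
  hmm <- calibrate_evalue(hmm, n_random = 60, random_len = 40,
                          seed = 9, db_size = 10)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmm(hmm, f)
  back <- read_hmm(f)
  seq <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(forward_score(back, seq), forward_score(hmm, seq),
               tolerance = 1e-12)
  expect_equal(back$calibration$mu, hmm$calibration$mu)
})
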