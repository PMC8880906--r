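test_that("profile build instantiates the pseudocount formula", {
  h <- build_hmm(new_msa("a", "ACD"))
  expect_equal(h$M, 3)
  bgA <- background_frequencies()[["A"]]
  expect_equal(unname(h$match_emissions[1, "A"]),
               (1 + 0.5 * bgA) / 1.5,
               tolerance = 1e-12)
  # occupancy: a 40%-occupied column is an insert column at 0.5
  msa <- new_msa(paste0("r", 1:5),
                 c("AC", "AC", "A-", "A-", "A-"))
  h2 <- build_hmm(msa)
  expect_equal(h2$M, 1)
  expect_error(build_hmm(new_msa(c("a", "b"), c("-", "-"))),
               "master row is all gaps")
})

test_that("position-based weights collapse duplicated rows", {
  h1 <- build_hmm(new_msa("a", "ACDEF"))
  h100 <- build_hmm(new_msa(paste0("r", 1:100), rep("ACDEF", 100)))
  expect_equal(h1$match_emissions, h100$match_emissions,
               tolerance = 1e-12)
  expect_equal(h1$transitions, h100$transitions, tolerance = 1e-12)
})

test_that("emission and transition rows are proper distributions", {
  set.seed(21)
  msa <- generate_family(paste(rep("ACDEFGHIKL", 4), collapse = ""),
                         12, 0.25, seed = 5)
  h <- build_hmm(msa)
  expect_true(all(abs(rowSums(h$match_emissions) - 1) < 1e-9))
  expect_true(all(h$match_emissions > 0))
  expect_true(all(abs(rowSums(h$transitions[, c("MM", "MI", "MD")]) - 1)
                  < 1e-9))
  expect_true(all(abs(rowSums(h$transitions[, c("IM", "II")]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(h$transitions[, c("DM", "DD")]) - 1) < 1e-9))
})

test_that("a one-state perfect-match model scores log2(20) bits", {
  hmm <- structure(list(
    M = 1L,
    match_emissions = matrix(c(1, rep(0, 19)), 1, 20,
                             dimnames = list(NULL, aa_alphabet())),
    insert_emissions = matrix(1 / 20, 2, 20),
    transitions = matrix(1, 1, 7,
                         dimnames = list(NULL, trefoilthemes:::TRANS_NAMES)),
    background = stats::setNames(rep(1 / 20, 20), aa_alphabet()),
    provenance = list(profile_id = "unit", master_id = "unit",
                      match_positions = 1L),
    calibration = NULL), class = "profile_hmm")
  expect_equal(forward_score(hmm, "A"), log2(20), tolerance = 1e-9)
  expect_equal(viterbi_align(hmm, "A")$score, log2(20), tolerance = 1e-9)
})

test_that("forward and Viterbi agree with exhaustive path enumeration", {
  set.seed(31)
  for (case in 1:60) {
    M <- sample(1:3, 1)
    L <- sample(1:4, 1)
    hmm <- random_hmm(M)
    seq <- paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
    expect_equal(forward_score(hmm, seq),
                 oracle_hmm_paths(hmm, seq, "sum"), tolerance = 1e-9)
    v <- viterbi_align(hmm, seq)
    o <- oracle_hmm_paths(hmm, seq, "max")
    expect_equal(v$score, o$score, tolerance = 1e-9)
    expect_equal(cbind(v$alignment$node, v$alignment$target_pos),
                 unname(o$path))
  }
})

test_that("Viterbi never exceeds forward and maps the master onto itself", {
  set.seed(41)
  for (case in 1:40) {
    hmm <- random_hmm(sample(2:5, 1))
    seq <- paste(sample(aa_alphabet(), sample(3:8, 1), replace = TRUE),
                 collapse = "")
    expect_lte(viterbi_align(hmm, seq)$score,
               forward_score(hmm, seq) + 1e-9)
  }
  master <- "WWWCCCHHHMMM"
  h <- build_hmm(new_msa("m", master))
  v <- viterbi_align(h, master)
  expect_equal(v$alignment$master_pos, 1:12)
  expect_equal(v$alignment$target_pos, 1:12)
})

test_that("background sequences score at or below zero on average", {
  msa <- generate_family(paste(rep("ACDEFGHIKL", 3), collapse = ""),
                         10, 0.2, seed = 6)
  hmm <- build_hmm(msa)
  scores <- trefoilthemes:::withr_seed(17, {
    vapply(1:1000, function(i) {
      forward_score(hmm, trefoilthemes:::random_aa_sequence(30))
    }, 0)
  })
  expect_lte(mean(scores), 0)
})

test_that("calibration yields the analytic E-value at mu and monotone tails", {
  msa <- generate_family(paste(rep("ACDEFGHIKL", 3), collapse = ""),
                         10, 0.2, seed = 7)
  hmm <- build_hmm(msa)
  hmm <- calibrate_evalue(hmm, n_random = 100, random_len = 40,
                          seed = 3, db_size = 50)
  mu <- hmm$calibration$mu
  expect_equal(evalue_score(hmm, mu), 50 * (1 - exp(-1)),
               tolerance = 1e-9)
  grid <- seq(mu - 5, mu + 15, length.out = 40)
  expect_true(all(diff(evalue_score(hmm, grid)) <= 0))
  upper <- seq(mu, mu + 15, length.out = 30)
  expect_true(all(diff(evalue_score(hmm, upper)) < 0))
  # E-values scale linearly with the database size
  hmm2 <- hmm; hmm2$calibration$db_size <- 500
  expect_equal(evalue_score(hmm2, mu + 2), 10 * evalue_score(hmm, mu + 2),
               tolerance = 1e-9)
})

test_that("degenerate zero-variance null scores abort calibration", {
  hmm <- structure(list(
    M = 1L,
    match_emissions = matrix(1 / 20, 1, 20,
                             dimnames = list(NULL, aa_alphabet())),
    insert_emissions = matrix(1 / 20, 2, 20),
    transitions = matrix(1, 1, 7,
                         dimnames = list(NULL, trefoilthemes:::TRANS_NAMES)),
    background = stats::setNames(rep(1 / 20, 20), aa_alphabet()),
    provenance = list(profile_id = "flat", master_id = "flat",
                      match_positions = 1L),
    calibration = NULL), class = "profile_hmm")
  expect_error(calibrate_evalue(hmm, n_random = 50, random_len = 10,
                                seed = 1, db_size = 5),
               "zero-variance")
})

test_that("database search recovers an undiverged planted theme", {
  p <- theme_scenario_params(theme_divergence = 0)
  sc <- generate_theme_scenario(p, seed = 9)
  msa_f <- filter_msa(sc$families$donor$msa)
  wins <- fragment_windows(msa_f, sc$donor_ss)
  w <- wins[[1]]
  hmm <- build_hmm(w$msa, profile_id = "w1", strand_span = w$strand_span,
                   residue_range = w$residue_range)
  hmm <- calibrate_evalue(hmm, n_random = 200, random_len = 120,
                          seed = 2, db_size = nrow(sc$domains))
  hits <- search_domains(hmm, sc$domains)
  expect_true("recipient_master" %in%
                vapply(hits, `[[`, "", "target_domain"))
  expect_lt(hits[[1]]$evalue, 1e-3)
  # the query lineage itself is excluded
  only_own <- sc$domains[sc$domains$group == "6.1.1", ]
  expect_length(search_domains(hmm, only_own), 0)
  expect_length(search_domains(hmm, sc$domains, evalue_max = 0), 0)
  # score does not depend on database order
  hits_rev <- search_domains(hmm, sc$domains[rev(seq_len(nrow(sc$domains))), ])
  expect_equal(sort(vapply(hits_rev, `[[`, 0, "bit_score")),
               sort(vapply(hits, `[[`, 0, "bit_score")))
  expect_error(search_domains(build_hmm(w$msa), sc$domains),
               "not calibrated")
})
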