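toy_hits <- function() {
  data.frame(
    profile_id = c("p1", "p1", "p2", "p3"),
    master_domain = c("dA", "dA", "dA", "dB"),
    window_strands = "1-4",
    target_domain = c("t1", "t2", "t1", "t3"),
    target_group = c("11.1.1", "11.1.2", "11.1.1", "221.4.1"),
    bit_score = c(20, 18, 15, 12),
    evalue = c(1e-6, 1e-5, 1e-4, 5e-4),
    shuffle_pvalue = NA, aln_master_range = "", aln_target_range = "",
    segment_rmsd = c(1.2, 6.0, NA, 3.0))
}

toy_classification <- function() {
  data.frame(domain_id = c("dA", "dB", "t1", "t2", "t3"),
             group = c("6.1.1", "6.1.2", "11.1.1", "11.1.2", "221.4.1"))
}

test_that("network edges group hits by query F-group and target X-group", {
  net <- build_network(toy_hits(), toy_classification())
  expect_equal(nrow(net$edges), 2)  # (6.1.1, 11) and (6.1.2, 221)
  e11 <- net$edges[net$edges$xgroup == "11", ]
  expect_equal(e11$n_hits, 3)
  expect_equal(e11$n_profiles, 2)
  expect_true(all(c("fgroup", "xgroup") %in% net$nodes$type))

  expect_equal(nrow(build_network(toy_hits()[0, ],
                                  toy_classification())$edges), 0)
  expect_warning(build_network(
    transform(toy_hits()[1, ], master_domain = "unknown"),
    toy_classification()), "unclassified")
})

test_that("unique-theme counts collapse repeated hits by one profile", {
  counts <- count_unique_themes(toy_hits())
  expect_equal(counts$n_themes[counts$xgroup == "11"], 2)
  expect_equal(counts$n_themes[counts$xgroup == "221"], 1)
  one_profile <- toy_hits()[c(1, 1, 1), ]
  expect_equal(count_unique_themes(one_profile)$n_themes, 1)
  expect_equal(nrow(count_unique_themes(toy_hits()[0, ])), 0)
  # invariant: no lineage can have more unique themes than profiles
  expect_true(all(counts$n_themes <=
                    length(unique(toy_hits()$profile_id))))
})

test_that("F-group pair associations deduplicate and bucket by X-group", {
  hits <- toy_hits()
  res <- fgroup_pair_associations(hits, toy_classification())
  # p1 and p2 hit the same (6.1.1, 11.1.1) pair: three unique pairs
  expect_equal(nrow(res$pairs), 3)
  dup <- rbind(hits, hits[1, ])
  expect_equal(nrow(fgroup_pair_associations(dup,
                                             toy_classification())$pairs),
               3)
  # a target with no F-group goes to the T-group-only bucket
  hits$target_group[1] <- "11.1"
  expect_warning(
    res2 <- fgroup_pair_associations(hits, toy_classification()),
    "T-group-only")
  expect_true("T-group-only" %in% res2$pairs$target_fgroup)
})

test_that("strand associations require three stacked aligned pairs", {
  ss <- paste0("C", strrep("E", 4), "C", strrep("E", 4), "CC")
  hit <- list(alignment = data.frame(master_pos = 2:11,
                                     target_pos = 2:11))
  self_pairs <- strand_associations(hit, ss, ss)
  expect_equal(self_pairs$query_strand, self_pairs$target_strand)
  expect_equal(nrow(self_pairs), 2)

  # hand-built alignment mapping query strand 2 onto target strand 5
  ss_q <- paste0(strrep("CE", 0), "CCEEEECCEEEECC")        # strands 1, 2
  ss_t <- paste(rep("CEEEE", 5), collapse = "")            # strands 1..5
  aln <- data.frame(master_pos = 9:12, target_pos = 22:25)
  out <- strand_associations(list(alignment = aln), ss_q, ss_t)
  expect_equal(out, data.frame(query_strand = 2L, target_strand = 5L))

  none <- strand_associations(
    list(alignment = data.frame(master_pos = 1:2, target_pos = 1:2)),
    ss_q, ss_t)
  expect_equal(nrow(none), 0)
  expect_warning(w <- strand_associations(hit, NULL, ss), "missing")
  expect_equal(nrow(w), 0)
})

test_that("metamorphism statistics use strict thresholds and medians", {
  m <- metamorphism_stats(data.frame(segment_rmsd = c(1, 2, 3)))
  expect_equal(m$median_rmsd, 2)
  expect_equal(m$fraction_below, 2 / 3)

  m2 <- metamorphism_stats(data.frame(segment_rmsd = rep(5.6, 4)))
  expect_equal(m2$median_rmsd, 5.6)
  expect_equal(m2$fraction_below, 0)

  m3 <- metamorphism_stats(data.frame(segment_rmsd = 2.5))
  expect_equal(m3$fraction_below, 0)  # strictly below

  m4 <- metamorphism_stats(data.frame(segment_rmsd = NA_real_))
  expect_true(m4$undefined)
  expect_equal(m4$n_missing, 1)

  m5 <- metamorphism_stats(toy_hits())
  expect_equal(m5$n_defined, 3)
  expect_equal(m5$n_missing, 1)
})

test_that("removing hits never adds network edges", {
  hits <- toy_hits()
  full <- build_network(hits, toy_classification())
  less <- build_network(hits[1:2, ], toy_classification())
  expect_lte(nrow(less$edges), nrow(full$edges))
  expect_lte(nrow(full$edges), nrow(hits))
})
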