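# Synthetic sequence families with planted shared segments ("themes").
# These emulate the statistical situation behind the bridging-theme
# search -- families of homologous domains around a master, one segment
# of which recurs, diverged, inside an otherwise unrelated family --
# with recorded ground truth so recovery can be scored.

#' Generate a gapless family MSA around a master sequence
#'
#' Members are derived from the master by i.i.d. substitutions at
#' `substitution_rate` (uniform over the 19 alternative residues), so
#' expected identity to the master is `1 - substitution_rate`.
#'
#' @param master_sequence Amino-acid string.
#' @param n_members Number of derived members (>= 1; the master row is
#'   included in addition, as the first row).
#' @param substitution_rate Per-site substitution probability in [0, 1].
#' @param seed Integer seed (deterministic output).
#' @param family_id Prefix for row ids (default "fam").
#' @return An ungapped [new_msa()] whose master row is
#'   `<family_id>_master`.
#' @export
generate_family <- function(master_sequence, n_members, substitution_rate,
                            seed, family_id = "fam") {
  if (nchar(master_sequence) == 0L) stop("empty master sequence")
  stopifnot(substitution_rate >= 0, substitution_rate <= 1, n_members >= 1)
  master_sequence <- toupper(master_sequence)
  withr_seed(seed, {
    rows <- vapply(seq_len(n_members), function(i) {
      mutate_sequence(master_sequence, substitution_rate)
    }, "")
    new_msa(c(paste0(family_id, "_master"),
              paste0(family_id, "_m", seq_len(n_members))),
            c(master_sequence, rows))
  })
}

# i.i.d. substitution at `rate`, uniform over the 19 alternatives
mutate_sequence <- function(sequence, rate) {
  chars <- seq_to_chars(sequence)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    alternatives <- setdiff(AA_ALPHABET, chars[[i]])
    chars[[i]] <- sample(alternatives, 1L)
  }
  chars_to_seq(chars)
}

#' Plant a (possibly diverged) theme into a host sequence
#'
#' Substitutes the theme, mutated at `divergence_rate`, in place at
#' `position`; host length is preserved.
#'
#' @param theme Theme sequence.
#' @param host_sequence Host sequence (at least as long as the theme).
#' @param position 1-based start position,
#'   `1 <= position <= len(host) - len(theme) + 1`.
#' @param divergence_rate Substitution rate applied to the theme copy.
#' @param seed Integer seed.
#' @return The modified host sequence.
#' @export
plant_theme <- function(theme, host_sequence, position, divergence_rate,
                        seed) {
  lt <- nchar(theme); lh <- nchar(host_sequence)
  if (lt > lh) stop("theme longer than host")
  if (position < 1L || position > lh - lt + 1L) {
    stop("position ", position, " out of range 1..", lh - lt + 1L)
  }
  withr_seed(seed, {
    copy <- mutate_sequence(theme, divergence_rate)
    paste0(substr(host_sequence, 1L, position - 1L), copy,
           substr(host_sequence, position + lt, lh))
  })
}

#' Default parameters for a planted-theme scenario
#'
#' @param n_members Members per family (default 20).
#' @param substitution_rate Within-family divergence (default 0.15).
#' @param master_len Donor/recipient master length (default 120).
#' @param theme_len Planted theme length (default 30, >= 15).
#' @param theme_divergence Theme divergence between donor and recipient
#'   (default 0.3).
#' @param n_decoys Number of decoy families (default 2).
#' @param strand_len,loop_len Strand/loop lengths of the donor master's
#'   secondary-structure annotation (defaults 6 and 3; four strands tile
#'   the theme region).
#' @return Named list of parameters.
#' @export
theme_scenario_params <- function(n_members = 20L, substitution_rate = 0.15,
                                  master_len = 120L, theme_len = 30L,
                                  theme_divergence = 0.3, n_decoys = 2L,
                                  strand_len = 6L, loop_len = 3L) {
  stopifnot(theme_len >= 15L, n_decoys >= 0L)
  as.list(environment())
}

#' Generate a full planted-theme scenario with ground truth
#'
#' Builds a donor family (group 6.1.1, the query lineage) whose master
#' carries the theme as a native segment annotated with four
#' consecutive beta-strands; a recipient family (group 11.1.1) whose
#' master carries the theme diverged at `theme_divergence`; and decoy
#' families with i.i.d. random masters. Truth lists the
#' (profile, target) pairs a perfect search should recover: one pair
#' per four-strand window overlapping the planted segment by at least
#' half the theme length.
#'
#' @param params From [theme_scenario_params()].
#' @param seed Integer seed.
#' @return Object of class `theme_scenario`: `families` (named list
#'   with `msa`, `group` each), `donor_ss` (H/E/C string for the donor
#'   master), `theme` (sequence, donor/recipient positions), `domains`
#'   (search-database data frame of the non-donor masters), `truth`
#'   (data frame `profile_id`, `target_domain`), `params`, `seed`.
#' @export
generate_theme_scenario <- function(params = theme_scenario_params(),
                                    seed = 1L) {
  p <- params
  seeds <- withr_seed(seed, sample.int(1e6, 6 + p$n_decoys))
  theme_pos <- p$loop_len + 1L  # theme starts after a leading loop
  # donor master: random sequence; the theme IS its segment at theme_pos
  donor_master <- withr_seed(seeds[[1]], random_aa_sequence(p$master_len))
  theme <- substr(donor_master, theme_pos, theme_pos + p$theme_len - 1L)

  # four strands tiling the theme region, loops elsewhere; strand i
  # starts at evenly spaced offsets so the fourth strand ends exactly at
  # the theme's last residue
  ss <- rep("C", p$master_len)
  spacing <- (p$theme_len - p$strand_len) / 3
  if (spacing < p$strand_len + 1L) {
    stop("theme too short for four separated strands of length ",
         p$strand_len)
  }
  starts <- theme_pos + round((0:3) * spacing)
  for (s in starts) ss[s:(s + p$strand_len - 1L)] <- "E"
  donor_ss <- chars_to_seq(ss)

  donor <- list(msa = generate_family(donor_master, p$n_members,
                                      p$substitution_rate, seeds[[2]],
                                      family_id = "donor"),
                group = "6.1.1")

  recipient_host <- withr_seed(seeds[[3]], random_aa_sequence(p$master_len))
  rec_pos <- max(1L, p$master_len - p$theme_len - 10L)
  recipient_master <- plant_theme(theme, recipient_host, rec_pos,
                                  p$theme_divergence, seeds[[4]])
  recipient <- list(msa = generate_family(recipient_master, p$n_members,
                                          p$substitution_rate, seeds[[5]],
                                          family_id = "recipient"),
                    group = "11.1.1")

  families <- list(donor = donor, recipient = recipient)
  for (d in seq_len(p$n_decoys)) {
    dm <- withr_seed(seeds[[6 + d]], random_aa_sequence(p$master_len))
    families[[paste0("decoy", d)]] <- list(
      msa = generate_family(dm, p$n_members, p$substitution_rate,
                            seeds[[6 + d]] + 1L,
                            family_id = paste0("decoy", d)),
      group = paste0(300 + d, ".1.1"))
  }

  # truth: windows overlapping the planted segment by >= theme_len / 2
  segs <- strand_segments(donor_ss)
  wins <- make_windows(segs)
  theme_range <- c(theme_pos, theme_pos + p$theme_len - 1L)
  truth <- NULL
  for (i in seq_len(nrow(wins))) {
    ov <- min(wins$end[[i]], theme_range[[2]]) -
      max(wins$start[[i]], theme_range[[1]]) + 1L
    if (ov >= p$theme_len / 2) {
      truth <- rbind(truth, data.frame(
        profile_id = paste0("donor_master_w", wins$first_strand[[i]]),
        target_domain = "recipient_master"))
    }
  }
  if (is.null(truth)) stop("no four-strand window covers the theme")

  domains <- do.call(rbind, lapply(names(families), function(nm) {
    data.frame(domain_id = paste0(nm, "_master"),
               sequence = msa_master_seq(families[[nm]]$msa),
               group = families[[nm]]$group)
  }))
  structure(list(families = families, donor_ss = donor_ss,
                 theme = list(sequence = theme, donor_pos = theme_pos,
                              recipient_pos = rec_pos),
                 domains = domains, truth = truth,
                 params = p, seed = seed),
            class = "theme_scenario")
}

#' @export
print.theme_scenario <- function(x, ...) {
  cat("theme_scenario: ", length(x$families), " families, theme length ",
      nchar(x$theme$sequence), ", ", nrow(x$truth), " truth pair(s)\n",
      sep = "")
  invisible(x)
}

#' Write a scenario to disk (aligned FASTA per family + truth JSON)
#'
#' The sidecar `truth.json` records the planted theme (sequence and
#' positions), the expected (profile, target) pairs, family group
#' labels, and the donor secondary structure.
#'
#' @param scenario A `theme_scenario`.
#' @param dir Output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(scenario$families)) {
    write_alignment(scenario$families[[nm]]$msa,
                    file.path(dir, paste0(nm, ".afa")))
  }
  jsonlite::write_json(list(
    theme = scenario$theme,
    truth = scenario$truth,
    groups = lapply(scenario$families, `[[`, "group"),
    donor_ss = scenario$donor_ss,
    seed = scenario$seed), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
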