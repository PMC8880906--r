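# Aggregation of theme hits into the headline counting objects: the
# bridging-theme network (beta-trefoil F-group nodes vs other-lineage
# X-group nodes), unique-theme counts, F-group pair associations,
# strand associations, and metamorphism statistics.

#' Build the bridging-theme network from a hit table
#'
#' One edge per (query F-group, target X-group) combination observed in
#' the hits, annotated with the distinct supporting profiles and the
#' hits themselves. Hits whose query or target domain is missing from
#' the classification are skipped with a warning.
#'
#' @param hits Hit-table data frame (see [hits_to_table()]), already
#'   filtered at the E-value cutoff of interest.
#' @param classification Data frame mapping `domain_id` to `group`
#'   (dotted X.T.F labels).
#' @return Object of class `theme_network`: `nodes` (data frame: id,
#'   type in {fgroup, xgroup}), `edges` (data frame: fgroup, xgroup,
#'   n_profiles, n_hits, profiles as a semicolon list), `hits`.
#' @export
build_network <- function(hits, classification) {
  lookup <- stats::setNames(classification$group, classification$domain_id)
  rows <- NULL
  for (i in seq_len(nrow(hits))) {
    qg <- unname(lookup[hits$master_domain[[i]]])
    if (is.na(qg)) {
      warning("unclassified query domain ", hits$master_domain[[i]],
              "; hit skipped")
      next
    }
    tg <- hits$target_group[[i]]
    if (is.na(tg) || !nzchar(tg)) {
      tg <- unname(lookup[hits$target_domain[[i]]])
    }
    if (is.na(tg)) {
      warning("unclassified target domain ", hits$target_domain[[i]],
              "; hit skipped")
      next
    }
    rows <- rbind(rows, data.frame(
      fgroup = qg, xgroup = as.character(parse_group(tg)$x),
      profile_id = hits$profile_id[[i]]))
  }
  if (is.null(rows)) {
    return(structure(list(
      nodes = data.frame(id = character(0), type = character(0)),
      edges = data.frame(fgroup = character(0), xgroup = character(0),
                         n_profiles = integer(0), n_hits = integer(0),
                         profiles = character(0)),
      hits = hits), class = "theme_network"))
  }
  key <- paste(rows$fgroup, rows$xgroup, sep = "|")
  edges <- do.call(rbind, lapply(split(rows, key), function(g) {
    data.frame(fgroup = g$fgroup[[1]], xgroup = g$xgroup[[1]],
               n_profiles = length(unique(g$profile_id)),
               n_hits = nrow(g),
               profiles = paste(sort(unique(g$profile_id)),
                                collapse = ";"))
  }))
  rownames(edges) <- NULL
  nodes <- rbind(
    data.frame(id = unique(edges$fgroup), type = "fgroup"),
    data.frame(id = unique(edges$xgroup), type = "xgroup"))
  structure(list(nodes = nodes, edges = edges, hits = hits),
            class = "theme_network")
}

#' @export
print.theme_network <- function(x, ...) {
  cat("theme_network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Write a network as node/edge TSV files
#' @param network A `theme_network`.
#' @param nodes_path,edges_path Output paths.
#' @export
write_network <- function(network, nodes_path, edges_path) {
  utils::write.table(network$nodes, nodes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, edges_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Count unique bridging themes per target lineage
#'
#' A bridging theme is an HMM profile with at least one hit against a
#' sequence outside the query lineage; the count per target X-group is
#' the number of distinct profiles hitting it (multiple hits by one
#' profile collapse).
#'
#' @param hits Hit-table data frame.
#' @return Data frame `xgroup`, `n_themes`, sorted by count descending.
#' @export
count_unique_themes <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(xgroup = character(0), n_themes = integer(0)))
  }
  xg <- as.character(xgroup_of(hits$target_group))
  tab <- lapply(split(hits$profile_id, xg), function(p) {
    length(unique(p))
  })
  out <- data.frame(xgroup = names(tab),
                    n_themes = unlist(tab, use.names = FALSE))
  out[order(-out$n_themes), , drop = FALSE]
}

#' Unique F-group pair associations per target lineage
#'
#' Deduplicated (query F-group, target F-group) pairs, grouped by the
#' target X-group. Targets without a full F-group label are counted in
#' a "T-group-only" bucket.
#'
#' @param hits Hit-table data frame.
#' @param classification Data frame mapping `domain_id` to `group` for
#'   the query masters.
#' @return List with `pairs` (data frame: query_fgroup, target_fgroup,
#'   target_xgroup) and `counts` (data frame: xgroup, n_pairs).
#' @export
fgroup_pair_associations <- function(hits, classification) {
  lookup <- stats::setNames(classification$group, classification$domain_id)
  rows <- NULL
  for (i in seq_len(nrow(hits))) {
    qg <- unname(lookup[hits$master_domain[[i]]])
    if (is.na(qg)) next
    tg <- parse_group(hits$target_group[[i]])
    tf <- if (is.na(tg$f)) "T-group-only" else hits$target_group[[i]]
    if (is.na(tg$f)) {
      warning("target ", hits$target_domain[[i]],
              " lacks an F-group; counted as T-group-only")
    }
    rows <- rbind(rows, data.frame(query_fgroup = qg, target_fgroup = tf,
                                   target_xgroup = as.character(tg$x)))
  }
  if (is.null(rows)) {
    return(list(pairs = data.frame(query_fgroup = character(0),
                                   target_fgroup = character(0),
                                   target_xgroup = character(0)),
                counts = data.frame(xgroup = character(0),
                                    n_pairs = integer(0))))
  }
  pairs <- unique(rows)
  rownames(pairs) <- NULL
  tab <- table(pairs$target_xgroup)
  counts <- data.frame(xgroup = names(tab),
                       n_pairs = as.integer(tab))
  list(pairs = pairs, counts = counts[order(-counts$n_pairs), ,
                                      drop = FALSE])
}

#' Strand associations implied by a theme alignment
#'
#' Maps the aligned residue pairs of one hit onto the beta-strand
#' numbering of the query and target domains: a pair of strands (i, j)
#' is associated when at least `min_pairs` aligned residue pairs fall
#' inside query strand i and target strand j simultaneously.
#'
#' @param hit A `theme_hit` (or list with an `alignment` data frame of
#'   `master_pos`, `target_pos`).
#' @param ss_query_domain,ss_target_domain Full-domain H/E/C strings.
#' @param min_pairs Minimum aligned pairs per association (default 3).
#' @param min_strand_len Strand length passed to [strand_segments()].
#' @return Data frame `query_strand`, `target_strand` (unique pairs);
#'   empty (with a warning) when an ss string is missing.
#' @export
strand_associations <- function(hit, ss_query_domain, ss_target_domain,
                                min_pairs = 3L, min_strand_len = 2L) {
  empty <- data.frame(query_strand = integer(0), target_strand = integer(0))
  if (is.null(ss_query_domain) || is.null(ss_target_domain)) {
    warning("missing secondary structure; no strand associations")
    return(empty)
  }
  aln <- hit$alignment
  if (is.null(aln) || nrow(aln) == 0L) return(empty)
  segs_q <- strand_segments(ss_query_domain, min_strand_len)
  segs_t <- strand_segments(ss_target_domain, min_strand_len)
  strand_of <- function(pos, segs) {
    idx <- rep(NA_integer_, length(pos))
    for (s in seq_len(nrow(segs))) {
      inside <- pos >= segs$start[[s]] & pos <= segs$end[[s]]
      idx[inside] <- segs$index[[s]]
    }
    idx
  }
  qi <- strand_of(aln$master_pos, segs_q)
  ti <- strand_of(aln$target_pos, segs_t)
  ok <- !is.na(qi) & !is.na(ti)
  if (!any(ok)) return(empty)
  tab <- table(paste(qi[ok], ti[ok]))
  keep <- names(tab)[tab >= min_pairs]
  if (length(keep) == 0L) return(empty)
  parts <- do.call(rbind, strsplit(keep, " "))
  out <- data.frame(query_strand = as.integer(parts[, 1]),
                    target_strand = as.integer(parts[, 2]))
  out[order(out$query_strand, out$target_strand), , drop = FALSE]
}

#' Metamorphism statistics over theme segment RMSDs
#'
#' @param hits_with_rmsd Hit-table data frame with a `segment_rmsd`
#'   column (NA where coordinates were unavailable).
#' @param threshold RMSD threshold for the "structurally conserved"
#'   fraction, default 2.5 Angstrom (strict `<`).
#' @return List: `median_rmsd`, `fraction_below` (strict), `n_defined`,
#'   `n_missing`. With no defined values the medians are NA and
#'   `undefined` is TRUE.
#' @export
metamorphism_stats <- function(hits_with_rmsd, threshold = 2.5) {
  r <- hits_with_rmsd$segment_rmsd
  defined <- r[!is.na(r)]
  if (length(defined) == 0L) {
    return(list(median_rmsd = NA_real_, fraction_below = NA_real_,
                n_defined = 0L, n_missing = sum(is.na(r)),
                undefined = TRUE))
  }
  list(median_rmsd = stats::median(defined),
       fraction_below = mean(defined < threshold),
       n_defined = length(defined), n_missing = sum(is.na(r)),
       undefined = FALSE)
}
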