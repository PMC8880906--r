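# Readers and writers for the standard formats the pipeline touches:
# FASTA sequences, aligned FASTA MSAs, legacy PDB structures (with water
# records), ECOD-style domain tables, and the project's hit tables.
# FASTA goes through Biostrings, PDB through bio3d; both are wrapped so the
# rest of the package sees plain R objects.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercased sequences (terminal `*`
#'   stripped), in file order; names are full record ids.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  if (any(!nzchar(names(seqs)))) stop("malformed FASTA header in ", path)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' An `msa` is an ordered set of equal-length aligned sequences with a
#' designated master row whose ungapped sequence defines the coordinate
#' system used by window cutting.
#'
#' @param ids Character vector of row ids.
#' @param seqs Character vector of aligned sequences (gaps `-`).
#' @param master_id Id of the master row; defaults to the first row.
#' @return An object of class `msa` with elements `ids`, `seqs`,
#'   `master_id`.
#' @export
new_msa <- function(ids, seqs, master_id = ids[[1]]) {
  stopifnot(length(ids) == length(seqs), length(ids) >= 1L)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != widths[[1]]][[1]]
    stop("ragged alignment: row '", bad, "' differs in length")
  }
  if (!master_id %in% ids) stop("master id '", master_id, "' not in MSA")
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  m <- seqs[[match(master_id, ids)]]
  if (!grepl("[^-]", m)) stop("master row is all gaps")
  structure(list(ids = ids, seqs = seqs, master_id = master_id),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA: ", length(x$ids), " rows x ", nchar(x$seqs[[1]]),
      " columns (master: ", x$master_id, ")\n", sep = "")
  invisible(x)
}

msa_master_seq <- function(msa) {
  msa$seqs[[match(msa$master_id, msa$ids)]]
}

#' Read an aligned FASTA file as an MSA
#'
#' @param path Path to aligned FASTA; `.` and `-` are both accepted as
#'   gap characters and normalized to `-`.
#' @param master_id Master row id; default the first record.
#' @return An [new_msa()] object.
#' @export
read_alignment <- function(path, master_id = NULL) {
  seqs <- read_fasta(path)
  new_msa(names(seqs), unname(seqs), master_id %||% names(seqs)[[1]])
}

#' Write an MSA to aligned FASTA
#' @param msa An `msa` object.
#' @param path Output path.
#' @export
write_alignment <- function(msa, path) {
  write_fasta(stats::setNames(msa$seqs, msa$ids), path)
}

#' Parse an author-numbered residue range string
#'
#' Ranges are 1-based inclusive comma-separated segments, e.g.
#' `"52-69,77-87"`.
#'
#' @param range_str Range string.
#' @return Data frame with columns `start`, `end`.
#' @export
parse_residue_ranges <- function(range_str) {
  parts <- strsplit(trimws(range_str), ",", fixed = TRUE)[[1]]
  if (length(parts) == 0L) stop("empty residue range: '", range_str, "'")
  segs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^\\s*(-?\\d+)\\s*-\\s*(-?\\d+)\\s*$", p))[[1]]
    if (length(m) != 3L) stop("unparseable residue range segment: '", p, "'")
    s <- as.integer(m[[2]]); e <- as.integer(m[[3]])
    if (s > e) stop("residue range start > end in segment: '", p, "'")
    c(start = s, end = e)
  })
  as.data.frame(do.call(rbind, segs))
}

#' Parse a dotted ECOD-style lineage label
#'
#' @param group Label such as `"6.1.1"` (X.T.F), `"6.1"` or `"6"`.
#' @return List with integer `x`, and `t`, `f` (NA when absent).
#' @export
parse_group <- function(group) {
  fields <- strsplit(trimws(group), ".", fixed = TRUE)[[1]]
  if (length(fields) < 1L || length(fields) > 3L ||
      any(!grepl("^\\d+$", fields))) {
    stop("group label '", group, "' is not 1-3 dot-separated integers")
  }
  fields <- as.integer(fields)
  list(x = fields[[1]],
       t = if (length(fields) >= 2L) fields[[2]] else NA_integer_,
       f = if (length(fields) >= 3L) fields[[3]] else NA_integer_)
}

xgroup_of <- function(group) vapply(group, function(g) parse_group(g)$x, 1L)

#' Read an ECOD-style domain classification table
#'
#' Expects a TSV with header columns `domain_id`, `pdb`, `chain`,
#' `range`, `group`. Ranges are author-numbered 1-based inclusive
#' segment lists (`"52-69,77-87"`).
#'
#' @param path Path to the TSV.
#' @return Data frame with one row per domain: `domain_id`, `pdb`,
#'   `chain`, `range`, `group`, `xgroup`, plus a list column `segments`
#'   of parsed range data frames.
#' @export
read_domain_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("domain_id", "pdb", "chain", "range", "group")
  if (!all(need %in% names(tab))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  segments <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    segments[[i]] <- tryCatch(
      parse_residue_ranges(tab$range[[i]]),
      error = function(e) stop("domain table line ", i + 1L, " (",
                               tab$domain_id[[i]], "): ",
                               conditionMessage(e))
    )
    parse_group(tab$group[[i]])  # validates
  }
  tab$xgroup <- unname(xgroup_of(tab$group))
  tab$segments <- segments
  tab
}

# ---------------------------------------------------------------------------
# Structures

#' Construct a protein structure object
#'
#' Backbone-level representation: per-residue N/CA/C/O (optionally CB)
#' coordinates plus water oxygens. Incomplete residues keep the atoms
#' they have (missing rows are NA) and are flagged.
#'
#' @param sequence One-letter amino-acid string.
#' @param resno Integer-like author residue identifiers (character to
#'   preserve insertion codes); default `1:n`.
#' @param atoms Named list of n x 3 coordinate matrices, names among
#'   `N`, `CA`, `C`, `O`, `CB`.
#' @param waters Optional m x 3 matrix of water oxygen coordinates with
#'   rownames as water identifiers.
#' @param ss Optional per-residue secondary-structure string over
#'   `{H,E,C}`.
#' @return Object of class `protein_structure`.
#' @export
new_structure <- function(sequence, atoms, resno = NULL, waters = NULL,
                          ss = NULL) {
  n <- nchar(sequence)
  resno <- resno %||% as.character(seq_len(n))
  stopifnot(length(resno) == n)
  for (a in names(atoms)) {
    stopifnot(is.matrix(atoms[[a]]), nrow(atoms[[a]]) == n,
              ncol(atoms[[a]]) == 3L)
  }
  if (!is.null(ss) && nchar(ss) != n) {
    stop("ss length (", nchar(ss), ") != sequence length (", n, ")")
  }
  if (!is.null(waters)) {
    stopifnot(is.matrix(waters), ncol(waters) == 3L)
    if (is.null(rownames(waters))) {
      rownames(waters) <- paste0("W", seq_len(nrow(waters)))
    }
  }
  bb <- c("N", "CA", "C", "O")
  present <- vapply(bb, function(a) {
    if (is.null(atoms[[a]])) rep(FALSE, n) else !is.na(atoms[[a]][, 1])
  }, logical(n))
  if (n == 1L) present <- matrix(present, nrow = 1L)
  incomplete <- which(rowSums(present) < 4L)
  structure(list(sequence = sequence, resno = as.character(resno),
                 atoms = atoms, waters = waters, ss = ss,
                 incomplete = incomplete),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  nw <- if (is.null(x$waters)) 0L else nrow(x$waters)
  cat("protein_structure: ", nchar(x$sequence), " residues, ", nw,
      " waters", if (length(x$incomplete)) paste0(" (",
      length(x$incomplete), " incomplete)"), "\n", sep = "")
  invisible(x)
}

n_residues <- function(structure) nchar(structure$sequence)

# three-letter -> one-letter translation (X for anything unknown)
AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
           MSE = "M", SEC = "C")
AA123 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
           X = "UNK")

#' Read a PDB file chain into a `protein_structure`
#'
#' Keeps the first altloc, orders residues by author numbering,
#' preserves insertion codes in residue identifiers, and returns
#' HOH/WAT oxygens as waters. Residues missing any of N/CA/C/O are
#' retained with the atoms present and flagged incomplete.
#'
#' @param path PDB file.
#' @param chain Chain identifier.
#' @return A [new_structure()] object.
#' @export
read_structure <- function(path, chain) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!chain %in% unique(at$chain)) {
    stop("chain '", chain, "' not present in ", path)
  }
  at <- at[at$chain == chain, , drop = FALSE]
  at <- at[at$alt %in% c("", " ", "A", NA), , drop = FALSE]  # first altloc
  is_water <- at$resid %in% c("HOH", "WAT")
  wat <- at[is_water & at$elety == "O", , drop = FALSE]
  prot <- at[!is_water & at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  prot <- prot[prot$resid %in% names(AA321) | prot$resid == "UNK", ,
               drop = FALSE]
  if (nrow(prot) == 0L) stop("no protein residues in chain '", chain, "'")
  ins <- prot$insert
  ins[is.na(ins)] <- ""
  rid <- paste0(prot$resno, ins)
  ord <- order(prot$resno, ins)
  prot <- prot[ord, , drop = FALSE]
  rid <- rid[ord]
  ids <- unique(rid)
  n <- length(ids)
  empty <- function() matrix(NA_real_, n, 3)
  atoms <- list(N = empty(), CA = empty(), C = empty(), O = empty(),
                CB = empty())
  seqv <- character(n)
  for (i in seq_len(n)) {
    rows <- prot[rid == ids[[i]], , drop = FALSE]
    seqv[[i]] <- unname(AA321[rows$resid[[1]]] %||% "X")
    if (is.na(seqv[[i]])) seqv[[i]] <- "X"
    for (a in names(atoms)) {
      hit <- which(rows$elety == a)
      if (length(hit)) {
        atoms[[a]][i, ] <- as.numeric(rows[hit[[1]], c("x", "y", "z")])
      }
    }
  }
  waters <- NULL
  if (nrow(wat) > 0L) {
    waters <- as.matrix(wat[, c("x", "y", "z")])
    insw <- wat$insert
    insw[is.na(insw)] <- ""
    rownames(waters) <- paste0("W", wat$resno, insw)
  }
  new_structure(chars_to_seq(seqv), atoms, resno = ids, waters = waters)
}

#' Write a `protein_structure` to PDB format
#'
#' @param structure A `protein_structure`.
#' @param path Output path.
#' @param chain Chain id to write (default "A").
#' @export
write_structure <- function(structure, path, chain = "A") {
  seqv <- seq_to_chars(structure$sequence)
  n <- length(seqv)
  xyz <- NULL; elety <- character(0); resid <- character(0)
  resno <- integer(0)
  order_names <- c("N", "CA", "C", "O", "CB", "CG", "CD")
  for (i in seq_len(n)) {
    for (a in order_names) {
      m <- structure$atoms[[a]]
      if (!is.null(m) && !is.na(m[i, 1])) {
        xyz <- rbind(xyz, m[i, ])
        elety <- c(elety, a)
        resid <- c(resid, unname(AA123[seqv[[i]]] %||% "UNK"))
        resno <- c(resno, as.integer(gsub("[A-Za-z]", "", structure$resno[[i]])))
      }
    }
  }
  nw <- if (is.null(structure$waters)) 0L else nrow(structure$waters)
  if (nw > 0L) {
    xyz <- rbind(xyz, structure$waters)
    elety <- c(elety, rep("O", nw))
    resid <- c(resid, rep("HOH", nw))
    resno <- c(resno, max(resno) + seq_len(nw))
  }
  na <- nrow(xyz)
  pdb_type <- c(rep("ATOM", na - nw), rep("HETATM", nw))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   type = pdb_type, resno = resno, resid = resid,
                   elety = elety, chain = rep(chain, na),
                   eleno = seq_len(na))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Hit tables

HIT_TABLE_COLS <- c("profile_id", "master_domain", "window_strands",
                    "target_domain", "target_group", "bit_score", "evalue",
                    "shuffle_pvalue", "aln_master_range",
                    "aln_target_range", "segment_rmsd")

#' Write a bridging-theme hit table (TSV)
#'
#' Fixed columns: profile_id, master_domain, window_strands,
#' target_domain, target_group, bit_score, evalue, shuffle_pvalue,
#' aln_master_range, aln_target_range, segment_rmsd.
#'
#' @param hits Data frame of hits (see [hits_to_table()]).
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  for (cn in HIT_TABLE_COLS) if (is.null(hits[[cn]])) hits[[cn]] <- NA
  utils::write.table(hits[, HIT_TABLE_COLS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bridging-theme hit table (TSV)
#' @param path Path written by [write_hit_table()].
#' @return Data frame with the fixed hit-table columns.
#' @export
read_hit_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a secondary-structure table
#'
#' Two-column TSV (`domain_id`, `ss`) giving per-residue H/E/C strings,
#' an alternative to deriving secondary structure from coordinates.
#'
#' @param path Path to the TSV.
#' @return Named character vector of ss strings.
#' @export
read_ss_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("domain_id", "ss") %in% names(tab))) {
    stop("ss table must have columns domain_id, ss")
  }
  stats::setNames(toupper(tab$ss), tab$domain_id)
}
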