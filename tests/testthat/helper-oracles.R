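# Independent oracles: brute-force enumerations and grid searches kept
# deliberately separate from the implementation paths they check.

# -- local alignment by exhaustive enumeration of monotone matchings ---
# gap convention: a gap of length l costs open + (l - 1) * extend;
# terminal gaps are free (local alignment)
oracle_gap_cost <- function(len, open, extend) {
  if (len <= 0) 0 else open + (len - 1) * extend
}

oracle_sw_score <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0
  rec <- function(i, j, score, last_i, last_j) {
    if (i > na || j > nb) return(invisible())
    for (ii in i:na) {
      for (jj in j:nb) {
        gap_a <- if (last_i == 0L) 0L else ii - last_i - 1L
        gap_b <- if (last_j == 0L) 0L else jj - last_j - 1L
        s2 <- score + submat[av[[ii]], bv[[jj]]] -
          oracle_gap_cost(gap_a, gap_open, gap_extend) -
          oracle_gap_cost(gap_b, gap_open, gap_extend)
        if (s2 > best) best <<- s2
        rec(ii + 1L, jj + 1L, s2, ii, jj)
      }
    }
  }
  rec(1L, 1L, 0, 0L, 0L)
  best
}

# -- profile-HMM local path ensemble by explicit recursion --------------
# Entry at any match state with probability 1/M, exit after any match
# state with probability 1/M; flanking residues cancel in log-odds.
oracle_hmm_paths <- function(hmm, sequence, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  M <- hmm$M
  x <- match(strsplit(sequence, "")[[1]], aa_alphabet())
  L <- length(x)
  bg <- hmm$background
  tr <- hmm$transitions
  em <- function(k, i) {
    unname(hmm$match_emissions[k, x[[i]]] / bg[[x[[i]]]])
  }
  emI <- function(k, i) {
    unname(hmm$insert_emissions[k + 1L, x[[i]]] / bg[[x[[i]]]])
  }

  # f(state, k, i): combine over completions after being in `state` at
  # node k having just consumed sequence position i; returns odds (sum
  # mode) or list(value, path) (max mode)
  if (mode == "sum") {
    f <- function(state, k, i) {
      s <- 0
      if (state == "M") {
        s <- s + 1 / M
        if (k < M && i < L) s <- s + tr[k, "MM"] * em(k + 1L, i + 1L) *
            f("M", k + 1L, i + 1L)
        if (i < L) s <- s + tr[k, "MI"] * emI(k, i + 1L) *
            f("I", k, i + 1L)
        if (k < M) s <- s + tr[k, "MD"] * f("D", k + 1L, i)
      } else if (state == "I") {
        if (k < M && i < L) s <- s + tr[k, "IM"] * em(k + 1L, i + 1L) *
            f("M", k + 1L, i + 1L)
        if (i < L) s <- s + tr[k, "II"] * emI(k, i + 1L) *
            f("I", k, i + 1L)
      } else {
        if (k < M && i < L) s <- s + tr[k, "DM"] * em(k + 1L, i + 1L) *
            f("M", k + 1L, i + 1L)
        if (k < M) s <- s + tr[k, "DD"] * f("D", k + 1L, i)
      }
      s
    }
    total <- 0
    for (k in seq_len(M)) {
      for (i in seq_len(L)) {
        total <- total + (1 / (M * L)) * em(k, i) * f("M", k, i)
      }
    }
    return(unname(log2(total)))
  }

  # max mode: track the best completion and its match pairs
  f <- function(state, k, i) {
    best <- if (state == "M") {
      list(v = 1 / M, path = NULL)  # exit
    } else {
      list(v = -Inf, path = NULL)
    }
    consider <- function(mult, nxt_state, nk, ni, pair) {
      sub <- f(nxt_state, nk, ni)
      v <- mult * sub$v
      if (v > best$v) best <<- list(v = v, path = rbind(pair, sub$path))
    }
    if (state == "M") {
      if (k < M && i < L) consider(tr[k, "MM"] * em(k + 1L, i + 1L),
                                   "M", k + 1L, i + 1L,
                                   c(k + 1L, i + 1L))
      if (i < L) consider(tr[k, "MI"] * emI(k, i + 1L), "I", k, i + 1L,
                          NULL)
      if (k < M) consider(tr[k, "MD"], "D", k + 1L, i, NULL)
    } else if (state == "I") {
      if (k < M && i < L) consider(tr[k, "IM"] * em(k + 1L, i + 1L),
                                   "M", k + 1L, i + 1L,
                                   c(k + 1L, i + 1L))
      if (i < L) consider(tr[k, "II"] * emI(k, i + 1L), "I", k, i + 1L,
                          NULL)
    } else {
      if (k < M && i < L) consider(tr[k, "DM"] * em(k + 1L, i + 1L),
                                   "M", k + 1L, i + 1L,
                                   c(k + 1L, i + 1L))
      if (k < M) consider(tr[k, "DD"], "D", k + 1L, i, NULL)
    }
    best
  }
  overall <- list(v = -Inf, path = NULL)
  for (k in seq_len(M)) {
    for (i in seq_len(L)) {
      sub <- f("M", k, i)
      v <- (1 / (M * L)) * em(k, i) * sub$v
      if (v > overall$v) {
        overall <- list(v = v, path = rbind(c(k, i), sub$path))
      }
    }
  }
  list(score = unname(log2(overall$v)),
       path = overall$path)
}

# random fully-parameterized profile HMM for property tests
random_hmm <- function(M, background = background_frequencies()) {
  rrow <- function(n) {
    x <- stats::rgamma(n, shape = 0.8)
    x / sum(x)
  }
  match_em <- t(replicate(M, rrow(20)))
  colnames(match_em) <- aa_alphabet()
  insert_em <- matrix(rep(background, each = M + 1L), M + 1L, 20,
                      dimnames = list(NULL, aa_alphabet()))
  trans <- matrix(0, M, 7,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                          "DM", "DD")))
  for (k in seq_len(M)) {
    trans[k, c("MM", "MI", "MD")] <- rrow(3)
    trans[k, c("IM", "II")] <- rrow(2)
    trans[k, c("DM", "DD")] <- rrow(2)
  }
  structure(list(M = M, match_emissions = match_em,
                 insert_emissions = insert_em, transitions = trans,
                 background = background,
                 provenance = list(profile_id = "random",
                                   master_id = "random",
                                   strand_span = NULL,
                                   residue_range = NULL,
                                   match_positions = seq_len(M)),
                 calibration = NULL), class = "profile_hmm")
}

# -- RMSD by rotation grid + polish, independent of the SVD route ------
oracle_rmsd_grid <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(ang) {
    ca <- cos(ang[[1]]); sa <- sin(ang[[1]])
    cb <- cos(ang[[2]]); sb <- sin(ang[[2]])
    cc <- cos(ang[[3]]); sc <- sin(ang[[3]])
    Rz <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cc, -sc, 0, sc, cc), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  rms <- function(ang) {
    sqrt(mean(rowSums((Pc %*% t(rot(ang)) - Qc)^2)))
  }
  grid <- expand.grid(a = seq(-pi, pi, length.out = 9),
                      b = seq(-pi / 2, pi / 2, length.out = 5),
                      c = seq(-pi, pi, length.out = 9))
  vals <- apply(grid, 1, rms)
  start <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(start, rms, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit$value
}

# substitution matrix shared by alignment tests
blosum62 <- function() {
  get(data(list = "BLOSUM62", package = "Biostrings",
           envir = environment()))
}
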