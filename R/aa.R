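#' @useDynLib trefoilthemes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical 20-letter amino-acid alphabet, fixed ordering used by all
# emission/background vectors in the package.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

# Robinson & Robinson (1991) amino-acid frequencies, the standard
# background used by profile search tools.
ROBINSON_BG <- c(
  A = 0.078047, R = 0.051269, N = 0.044873, D = 0.053640, C = 0.019246,
  Q = 0.042644, E = 0.062949, G = 0.073772, H = 0.021992, I = 0.051420,
  L = 0.090191, K = 0.057438, M = 0.022425, F = 0.038556, P = 0.052028,
  S = 0.071198, T = 0.058413, W = 0.013298, Y = 0.032165, V = 0.064409
)[c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")]

#' Background amino-acid frequencies
#'
#' @param kind `"robinson"` (default) for the Robinson--Robinson
#'   frequencies used by standard profile search tools, or `"uniform"`
#'   for 1/20 per residue.
#' @return Named numeric vector of 20 frequencies summing to 1,
#'   ordered as `aa_alphabet()`.
#' @export
background_frequencies <- function(kind = c("robinson", "uniform")) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    bg <- rep(1 / 20, 20)
    names(bg) <- AA_ALPHABET
    bg
  } else {
    ROBINSON_BG / sum(ROBINSON_BG)
  }
}

#' The amino-acid alphabet used throughout
#' @return Character vector of the 20 canonical one-letter codes.
#' @export
aa_alphabet <- function() AA_ALPHABET

# Map residue letters to 1..20 indices; unknown letters (X, B, Z, ...) -> NA.
aa_index <- function(residues) {
  match(residues, AA_ALPHABET)
}

seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
chars_to_seq <- function(x) paste(x, collapse = "")

# Sample a random background sequence (character string).
random_aa_sequence <- function(n, bg = background_frequencies()) {
  chars_to_seq(sample(AA_ALPHABET, n, replace = TRUE, prob = bg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
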