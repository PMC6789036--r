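# Amino-acid alphabet, background frequencies and the BLOSUM62 table.
# Everything downstream (alignment, profile construction, scoring, simulation)
# works on integer-encoded residues in the fixed order AA_ALPHABET; 'X' is the
# unknown residue and is scored at background.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_X <- "X"
GAP_CHAR <- "-"

# Swiss-Prot-derived background amino-acid frequencies (Robinson & Robinson),
# the null model convention of profile-HMM search tools; renormalised to sum 1.
AA_BACKGROUND <- local({
  f <- c(
    A = 0.0787945, C = 0.0151600, D = 0.0535222, E = 0.0668298,
    F = 0.0397062, G = 0.0695071, H = 0.0229198, I = 0.0590092,
    K = 0.0594422, L = 0.0963728, M = 0.0237718, N = 0.0414386,
    P = 0.0482904, Q = 0.0395639, R = 0.0540978, S = 0.0683364,
    T = 0.0540687, V = 0.0673417, W = 0.0114135, Y = 0.0304133
  )
  f <- f[AA_ALPHABET]
  f / sum(f)
})

# BLOSUM62 in AA_ALPHABET order, embedded as a constant so that alignment
# scoring and tie-breaking are fixed for the life of the package.
BLOSUM62_MATRIX <- local({
  v <- c(
     4,  0, -2, -1, -2,  0, -2, -1, -1, -1, -1, -2, -1, -1, -1,  1,  0,  0, -3, -2,
     0,  9, -3, -4, -2, -3, -3, -1, -3, -1, -1, -3, -3, -3, -3, -1, -1, -1, -2, -2,
    -2, -3,  6,  2, -3, -1, -1, -3, -1, -4, -3,  1, -1,  0, -2,  0, -1, -3, -4, -3,
    -1, -4,  2,  5, -3, -2,  0, -3,  1, -3, -2,  0, -1,  2,  0,  0, -1, -2, -3, -2,
    -2, -2, -3, -3,  6, -3, -1,  0, -3,  0,  0, -3, -4, -3, -3, -2, -2, -1,  1,  3,
     0, -3, -1, -2, -3,  6, -2, -4, -2, -4, -3,  0, -2, -2, -2,  0, -2, -3, -2, -3,
    -2, -3, -1,  0, -1, -2,  8, -3, -1, -3, -2,  1, -2,  0,  0, -1, -2, -3, -2,  2,
    -1, -1, -3, -3,  0, -4, -3,  4, -3,  2,  1, -3, -3, -3, -3, -2, -1,  3, -3, -1,
    -1, -3, -1,  1, -3, -2, -1, -3,  5, -2, -1,  0, -1,  1,  2,  0, -1, -2, -3, -2,
    -1, -1, -4, -3,  0, -4, -3,  2, -2,  4,  2, -3, -3, -2, -2, -2, -1,  1, -2, -1,
    -1, -1, -3, -2,  0, -3, -2,  1, -1,  2,  5, -2, -2,  0, -1, -1, -1,  1, -1, -1,
    -2, -3,  1,  0, -3,  0,  1, -3,  0, -3, -2,  6, -2,  0,  0,  1,  0, -3, -4, -2,
    -1, -3, -1, -1, -4, -2, -2, -3, -1, -3, -2, -2,  7, -1, -2, -1, -1, -2, -4, -3,
    -1, -3,  0,  2, -3, -2,  0, -3,  1, -2,  0,  0, -1,  5,  1,  0, -1, -2, -2, -1,
    -1, -3, -2,  0, -3, -2,  0, -3,  2, -2, -1,  0, -2,  1,  5, -1, -1, -3, -3, -2,
     1, -1,  0,  0, -2,  0, -1, -2,  0, -2, -1,  1, -1,  0, -1,  4,  1, -2, -3, -2,
     0, -1, -1, -1, -2, -2, -2, -1, -1, -1, -1,  0, -1, -1, -1,  1,  5,  0, -2, -2,
     0, -1, -3, -2, -1, -3, -3,  3, -2,  1,  1, -3, -2, -2, -3, -2,  0,  4, -3, -1,
    -3, -2, -4, -3,  1, -2, -2, -3, -3, -2, -1, -4, -4, -2, -3, -3, -2, -3, 11,  2,
    -2, -2, -3, -2,  3, -3,  2, -1, -2, -1, -1, -2, -3, -1, -2, -2, -2, -1,  2,  7
  )
  m <- matrix(v, nrow = 20, byrow = TRUE,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  stopifnot(isTRUE(all.equal(m, t(m))))
  m
})

# Default affine gap penalties for all pairwise and profile alignments.
GAP_OPEN <- -11
GAP_EXTEND <- -1

# residues -> integer codes: 1..20 amino acids, 21 = X, 22 = gap.
# Unknown letters (B, Z, U, ...) are folded into X.
encode_residues <- function(x) {
  codes <- match(strsplit(x, "")[[1]], c(AA_ALPHABET, AA_X, GAP_CHAR))
  codes[is.na(codes)] <- 21L
  as.integer(codes)
}

decode_residues <- function(codes) {
  paste(c(AA_ALPHABET, AA_X, GAP_CHAR)[codes], collapse = "")
}

#' Validate a protein residue string
#'
#' Checks that a string is non-empty and drawn from the 20-letter amino-acid
#' alphabet plus `X`.
#'
#' @param residues Character scalar of residues.
#' @return Invisibly, `residues`; errors otherwise.
#' @keywords internal
check_residues <- function(residues) {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues) ||
      nchar(residues) == 0L) {
    stop("residues must be a non-empty character scalar", call. = FALSE)
  }
  bad <- setdiff(strsplit(residues, "")[[1]], c(AA_ALPHABET, AA_X))
  if (length(bad) > 0L) {
    stop("invalid residue characters: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  invisible(residues)
}
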