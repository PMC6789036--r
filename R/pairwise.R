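# Pairwise alignment, percent identity, and greedy incremental clustering
# (the CD-HIT-like deduplication step used when building seed alignments).

# 21 x 21 substitution score table: BLOSUM62 plus an X row/column scored 0.
subst_matrix21 <- function() {
  m <- matrix(0, 21, 21)
  m[1:20, 1:20] <- BLOSUM62_MATRIX
  m
}

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch with affine gap costs (open -11, extend -1) under
#' BLOSUM62; `X` scores 0 against everything. Ties are broken deterministically
#' (diagonal, then gap in the second sequence, then gap in the first).
#'
#' @param a,b Residue strings or single-row [seq_set()]s.
#' @return A list with `score`, `matches` (identical non-`X` aligned pairs),
#'   and the two aligned strings `a` and `b`.
#' @export
align_global <- function(a, b) {
  a <- as_residues(a); b <- as_residues(b)
  check_residues(a); check_residues(b)
  res <- .nw_align_cpp(encode_residues(a), encode_residues(b),
                       subst_matrix21(), GAP_OPEN, GAP_EXTEND)
  dec <- function(codes) {
    codes[codes == 0L] <- 22L
    decode_residues(codes)
  }
  list(score = res$score, matches = res$matches,
       a = dec(res$a), b = dec(res$b))
}

as_residues <- function(x) {
  if (inherits(x, "seq_set")) {
    stopifnot(nrow(x) == 1L)
    return(x$residues)
  }
  as.character(x)
}

#' Pairwise sequence identity
#'
#' Fraction of identical aligned residue pairs in the global alignment of two
#' sequences, divided by the length of the shorter sequence (the convention of
#' greedy identity-clustering tools). `X` counts as a mismatch. Symmetric in
#' its arguments.
#'
#' @param a,b Residue strings or single-row [seq_set()]s.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("MKTAYIAK", "MKTAYIAK") # 1
#' pairwise_identity("AAAA", "TTTT")         # 0
#' @export
pairwise_identity <- function(a, b) {
  a <- as_residues(a); b <- as_residues(b)
  check_residues(a); check_residues(b)
  ali <- align_global(a, b)
  ali$matches / min(nchar(a), nchar(b))
}

#' Greedy incremental identity clustering
#'
#' Reimplements the semantics of greedy representative-based clustering:
#' sequences are sorted by decreasing length (ties by id) and each joins the
#' first existing cluster whose representative it matches at
#' `identity >= threshold`, otherwise it founds a new cluster. The
#' representative of a cluster is its longest member (ties broken by
#' lexicographically smallest id).
#'
#' @param records A [seq_set()].
#' @param threshold Identity threshold in `(0, 1]`; the pipeline default for
#'   WYL seed deduplication is 0.70.
#' @return An object of class `cluster_set`: a list with `clusters` (list of
#'   member-id vectors), `representatives`, and `identity` (per member,
#'   identity to its representative).
#' @export
greedy_cluster <- function(records, threshold = 0.70) {
  stopifnot(inherits(records, "seq_set"), nrow(records) >= 1L)
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  lens <- nchar(records$residues)
  ord <- order(-lens, records$id)
  reps <- integer(0)              # row indices of representatives
  members <- list()
  idents <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      idy <- pairwise_identity(records$residues[i], records$residues[reps[ci]])
      if (idy >= threshold) {
        members[[ci]] <- c(members[[ci]], records$id[i])
        idents[[ci]] <- c(idents[[ci]], idy)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- records$id[i]
      idents[[length(reps)]] <- 1.0
    }
  }
  out <- list(clusters = members,
              representatives = records$id[reps],
              identity = idents)
  class(out) <- "cluster_set"
  out
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters,",
      sum(lengths(x$clusters)), "members\n")
  invisible(x)
}

#' Write cluster membership to a TSV file
#'
#' Columns: `cluster_id`, `representative`, `member_id`, `identity`.
#'
#' @param cs A `cluster_set` from [greedy_cluster()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clusters <- function(cs, path) {
  stopifnot(inherits(cs, "cluster_set"))
  df <- do.call(rbind, lapply(seq_along(cs$clusters), function(ci) {
    data.frame(cluster_id = ci,
               representative = cs$representatives[ci],
               member_id = cs$clusters[[ci]],
               identity = cs$identity[[ci]],
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
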