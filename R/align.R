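# Multiple sequence alignments: the `msa` container, aligned-FASTA I/O, the
# built-in progressive aligner (UPGMA guide tree over pairwise identities,
# profile-profile merges), trimming, and per-column conservation scoring.

#' Construct a multiple sequence alignment
#'
#' Rows are `(id, aligned string)` pairs of identical width over the residue
#' alphabet plus `-` gaps. Columns consisting only of gaps are removed at
#' construction, so a valid `msa` never contains an all-gap column.
#'
#' @param ids Character vector of unique row ids.
#' @param seqs Character vector of aligned strings (equal width).
#' @return An object of class `msa` with elements `ids` and `seqs`.
#' @export
msa <- function(ids, seqs) {
  ids <- as.character(ids); seqs <- as.character(toupper(seqs))
  stopifnot(length(ids) == length(seqs), length(ids) >= 1L)
  if (anyDuplicated(ids)) stop("duplicate row ids in alignment", call. = FALSE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L || w < 1L) {
    stop("aligned strings must have identical positive width", call. = FALSE)
  }
  for (s in seqs) {
    bad <- setdiff(strsplit(s, "")[[1]], c(AA_ALPHABET, AA_X, GAP_CHAR))
    if (length(bad)) {
      stop("invalid alignment characters: ", paste(bad, collapse = ","),
           call. = FALSE)
    }
    if (gsub("-", "", s) == "") stop("all-gap alignment row", call. = FALSE)
  }
  m <- msa_matrix_strings(seqs)
  keep <- colSums(m != GAP_CHAR) > 0L
  if (!all(keep)) {
    seqs <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  }
  out <- list(ids = ids, seqs = unname(seqs))
  class(out) <- "msa"
  out
}

msa_matrix_strings <- function(seqs) {
  do.call(rbind, strsplit(seqs, ""))
}

# integer-coded matrix (1..20 aa, 21 X, 22 gap)
msa_matrix <- function(aln) {
  do.call(rbind, lapply(aln$seqs, encode_residues))
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$ids), "rows x", n_columns(x), "columns\n")
  n <- min(length(x$ids), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-20s %s%s\n", x$ids[i], substr(x$seqs[i], 1, 50),
                if (n_columns(x) > 50) "..." else ""))
  }
  if (length(x$ids) > n) cat("  ...\n")
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln An [msa()].
#' @return Integer column count.
#' @export
n_columns <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  nchar(aln$seqs[[1]])
}

#' Remove gaps from an alignment row
#' @param aln An [msa()].
#' @param i Row index or id.
#' @return The ungapped residue string.
#' @export
ungap_row <- function(aln, i) {
  stopifnot(inherits(aln, "msa"))
  if (is.character(i)) i <- match(i, aln$ids)
  gsub("-", "", aln$seqs[[i]], fixed = TRUE)
}

#' Read an alignment from aligned FASTA
#' @param path Path to an aligned FASTA file ('-' gaps).
#' @return An [msa()].
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  msa(sub("\\s.*$", "", names(aa)), as.character(aa))
}

#' Write an alignment to aligned FASTA
#' @param aln An [msa()].
#' @param path Output path (60-column wrapping).
#' @return Invisibly, `path`.
#' @export
write_msa <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  aa <- Biostrings::AAStringSet(aln$seqs)
  names(aa) <- aln$ids
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

# 20 x ncol occupancy-weighted residue frequency profile of a coded matrix.
# X spreads its mass over the background; gaps contribute nothing, so column
# sums equal the non-gap occupancy of the column.
profile_of <- function(mat) {
  nr <- nrow(mat)
  out <- matrix(0, 20L, ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    tab <- tabulate(col[col <= 20L], nbins = 20L)
    f <- tab / nr
    nx <- sum(col == 21L)
    if (nx > 0L) f <- f + AA_BACKGROUND * (nx / nr)
    out[, j] <- f
  }
  out
}

#' Progressive multiple alignment
#'
#' Builds a guide tree by UPGMA (average-linkage) clustering of pairwise
#' identity distances, then merges alignments profile-to-profile with affine
#' gap costs under BLOSUM62. Fully deterministic: DP ties prefer the diagonal,
#' then the gap-in-second branch, and guide-tree ties follow input order.
#'
#' @param records A [seq_set()] with at least one record.
#' @return An [msa()] whose row order matches the input; ungapping row `k`
#'   reproduces input record `k` exactly.
#' @export
progressive_align <- function(records) {
  stopifnot(inherits(records, "seq_set"), nrow(records) >= 1L)
  n <- nrow(records)
  if (n == 1L) return(msa(records$id, records$residues))

  # pairwise identity distance matrix
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      idy <- pairwise_identity(records$residues[i], records$residues[j])
      d[i, j] <- d[j, i] <- 1 - idy
    }
  }
  smat20 <- BLOSUM62_MATRIX + 0.0

  merge_two <- function(matA, rowsA, matB, rowsB) {
    moves <- .profile_align_cpp(profile_of(matA), profile_of(matB), smat20,
                                GAP_OPEN, GAP_EXTEND)
    ncol_out <- length(moves)
    outA <- matrix(22L, nrow(matA), ncol_out)
    outB <- matrix(22L, nrow(matB), ncol_out)
    ia <- 0L; ib <- 0L
    for (p in seq_along(moves)) {
      mv <- moves[p]
      if (mv == 1L || mv == 2L) { ia <- ia + 1L; outA[, p] <- matA[, ia] }
      if (mv == 1L || mv == 3L) { ib <- ib + 1L; outB[, p] <- matB[, ib] }
    }
    list(mat = rbind(outA, outB), rows = c(rowsA, rowsB))
  }

  if (n == 2L) {
    tree_merge <- matrix(c(-1L, -2L), 1L, 2L)
  } else {
    tree_merge <- hclust(as.dist(d), method = "average")$merge
  }
  nodes <- vector("list", nrow(tree_merge))
  leaf <- function(i) {
    list(mat = matrix(encode_residues(records$residues[i]), nrow = 1L),
         rows = i)
  }
  for (s in seq_len(nrow(tree_merge))) {
    a <- tree_merge[s, 1L]; b <- tree_merge[s, 2L]
    na <- if (a < 0L) leaf(-a) else nodes[[a]]
    nb <- if (b < 0L) leaf(-b) else nodes[[b]]
    nodes[[s]] <- merge_two(na$mat, na$rows, nb$mat, nb$rows)
  }
  fin <- nodes[[nrow(tree_merge)]]
  ord <- order(fin$rows)
  seqs <- apply(fin$mat[ord, , drop = FALSE], 1L, function(r) {
    decode_residues(r)
  })
  msa(records$id[fin$rows[ord]], seqs)
}

#' Trim an alignment to a column window
#'
#' Returns columns `start_col..end_col` (1-based, inclusive). Rows that become
#' all-gap are dropped and all-gap columns within the window are removed.
#'
#' @param aln An [msa()].
#' @param start_col,end_col Window bounds, `1 <= start_col <= end_col <= n_columns`.
#' @return The trimmed [msa()].
#' @export
trim_alignment <- function(aln, start_col, end_col) {
  stopifnot(inherits(aln, "msa"))
  nc <- n_columns(aln)
  if (!(start_col >= 1L && start_col <= end_col && end_col <= nc)) {
    stop("column window out of range: [", start_col, ", ", end_col,
         "] with ", nc, " columns", call. = FALSE)
  }
  seqs <- substr(aln$seqs, start_col, end_col)
  keep <- gsub("-", "", seqs, fixed = TRUE) != ""
  if (!any(keep)) stop("trimming left no non-empty rows", call. = FALSE)
  msa(aln$ids[keep], seqs[keep])
}

#' Per-column conservation scores
#'
#' The default entropy variant (independent counts) computes gap-excluding
#' amino-acid frequencies `f_a` per column and scores
#' `1 - H / ln(20)` with `H = -sum f_a ln f_a`, giving values in `[0, 1]`
#' (1 = fully conserved). Columns with more than 50% gaps are flagged in the
#' `low_confidence` attribute; all-gap columns (possible only in degenerate
#' windows) score `NA`. The substitution-matrix variant scores the
#' frequency-weighted expected BLOSUM62 value `sum_{a,b} f_a f_b B62(a,b)`;
#' it is not bounded to `[0, 1]`.
#'
#' @param aln An [msa()] with at least 2 rows.
#' @param method `"entropy"` (default) or `"sum_of_pairs"`.
#' @return Numeric vector of per-column scores with a logical
#'   `low_confidence` attribute.
#' @export
conservation_scores <- function(aln, method = c("entropy", "sum_of_pairs")) {
  stopifnot(inherits(aln, "msa"))
  if (length(aln$ids) < 2L) stop("need an alignment with >= 2 rows", call. = FALSE)
  method <- match.arg(method)
  m <- msa_matrix(aln)
  nc <- ncol(m)
  scores <- numeric(nc)
  lowconf <- logical(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    res <- col[col <= 20L]            # X and gaps excluded from counts
    gapfrac <- mean(col == 22L)
    lowconf[j] <- gapfrac > 0.5
    if (length(res) == 0L) {
      scores[j] <- NA_real_
      next
    }
    f <- tabulate(res, nbins = 20L) / length(res)
    if (method == "entropy") {
      fz <- f[f > 0]
      H <- -sum(fz * log(fz))
      scores[j] <- 1 - H / log(20)
    } else {
      scores[j] <- drop(t(f) %*% BLOSUM62_MATRIX %*% f)
    }
  }
  attr(scores, "low_confidence") <- lowconf
  scores
}
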