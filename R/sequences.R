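#' Create a set of protein sequence records
#'
#' A `seq_set` is the package's basic sequence container: a data frame with
#' columns `id` (unique, non-empty), `taxon_id` (may be empty) and `residues`
#' (non-empty strings over the 20-letter amino-acid alphabet plus `X`).
#'
#' @param id Character vector of unique sequence identifiers.
#' @param residues Character vector of residue strings.
#' @param taxon_id Optional character vector of taxon identifiers ("" if
#'   unknown).
#' @return A data frame of class `seq_set`.
#' @examples
#' seq_set(c("a", "b"), c("MKTAYIAK", "MKWA"))
#' @export
seq_set <- function(id, residues, taxon_id = "") {
  id <- as.character(id)
  residues <- as.character(residues)
  taxon_id <- rep_len(as.character(taxon_id), length(id))
  if (length(id) != length(residues)) {
    stop("id and residues must have equal length", call. = FALSE)
  }
  if (any(is.na(id)) || any(id == "")) stop("ids must be non-empty", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  for (r in residues) check_residues(r)
  out <- data.frame(id = id, taxon_id = taxon_id, residues = residues,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", nrow(x), "sequences\n")
  n <- min(nrow(x), 6L)
  for (i in seq_len(n)) {
    r <- x$residues[i]
    cat(sprintf("  %-20s %5d aa  %s%s\n", x$id[i], nchar(r),
                substr(r, 1, 40), if (nchar(r) > 40) "..." else ""))
  }
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A [seq_set()]. The description line up to the first whitespace
#'   becomes the id.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seq_set(ids, toupper(as.character(aa)))
}

#' Write protein sequences to a FASTA file
#'
#' @param x A [seq_set()].
#' @param path Output path; lines are wrapped at 60 columns.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  aa <- Biostrings::AAStringSet(x$residues)
  names(aa) <- x$id
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Concatenate pairs of separately encoded subunit sequences
#'
#' Builds single records from subunit pairs (e.g. separately encoded PafB and
#' PafC proteins) by concatenating their residues N-terminal first, so that
#' conservation can be computed across the full length of naturally fused
#' homologs. The new id is `"<first>|<second>"`.
#'
#' @param pairs A list of two-row [seq_set()]s or length-2 lists, each holding
#'   the first (N-terminal) and second (C-terminal) partner.
#' @return A [seq_set()] with one record per pair, order preserved.
#' @export
concatenate_pairs <- function(pairs) {
  if (length(pairs) == 0L) {
    return(seq_set(character(), character()))
  }
  ids <- character(length(pairs))
  res <- character(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (inherits(p, "seq_set")) {
      stopifnot(nrow(p) == 2L)
      a_id <- p$id[1]; b_id <- p$id[2]
      a_res <- p$residues[1]; b_res <- p$residues[2]
    } else {
      stopifnot(length(p) == 2L)
      a_id <- p[[1]]$id; b_id <- p[[2]]$id
      a_res <- p[[1]]$residues; b_res <- p[[2]]$residues
    }
    if (identical(a_id, b_id)) {
      stop("pair ", i, " has identical member ids", call. = FALSE)
    }
    ids[i] <- paste0(a_id, "|", b_id)
    res[i] <- paste0(a_res, b_res)
  }
  if (anyDuplicated(ids)) {
    stop("concatenation produced duplicate ids", call. = FALSE)
  }
  seq_set(ids, res)
}
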