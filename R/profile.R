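# Profile-HMM construction and the versioned text file format ("WDKHMM1").
# A profile_hmm holds per-node match emissions, background insert emissions,
# node transitions, and optional Gumbel calibration / gathering threshold.

#' Assign match columns of an alignment
#'
#' A column becomes a match (consensus) column when its gap fraction is below
#' `gap_fraction`; the remaining columns are insert columns. This is the
#' standard model-construction rule of profile-HMM builders.
#'
#' @param aln An [msa()].
#' @param gap_fraction Threshold in `(0, 1)`; default 0.5.
#' @return Logical vector of length `n_columns(aln)`; `TRUE` marks match
#'   columns. Errors if no column qualifies.
#' @export
assign_match_columns <- function(aln, gap_fraction = 0.5) {
  stopifnot(inherits(aln, "msa"))
  if (!(gap_fraction > 0 && gap_fraction < 1)) {
    stop("gap_fraction must be in (0, 1)", call. = FALSE)
  }
  m <- msa_matrix(aln)
  gf <- colMeans(m == 22L)
  mask <- gf < gap_fraction
  if (!any(mask)) {
    stop("no column has gap fraction below ", gap_fraction,
         "; curate the alignment before building a model", call. = FALSE)
  }
  mask
}

#' Build a profile HMM from an alignment
#'
#' Match-state emissions are background-mixed counts
#' `(counts + pseudocount_weight * background) / (n + pseudocount_weight)`
#' over the match columns chosen by [assign_match_columns()]; `X` residues
#' contribute background-distributed fractional counts. Node transitions are
#' estimated from the observed match/insert/delete paths of every row with
#' Laplace smoothing; insert emissions equal the background (the Plan7
#' convention, so insert residues score zero bits).
#'
#' @param aln An [msa()] with at least one row.
#' @param pseudocount_weight Positive emission pseudocount mass; default 1.
#' @param gap_fraction Match-column threshold passed to
#'   [assign_match_columns()].
#' @param transition_pseudocount Laplace count added to each transition;
#'   default 1.
#' @param name,clan Model name and optional clan label.
#' @return A `profile_hmm` object.
#' @export
build_profile <- function(aln, pseudocount_weight = 1, gap_fraction = 0.5,
                          transition_pseudocount = 1,
                          name = "model", clan = "") {
  stopifnot(inherits(aln, "msa"), pseudocount_weight > 0)
  mask <- assign_match_columns(aln, gap_fraction)
  m <- msa_matrix(aln)
  nrows <- nrow(m)
  M <- sum(mask)
  node_of_col <- cumsum(mask)        # model node index for match columns

  # emissions
  em <- matrix(0, M, 20L)
  for (j in which(mask)) {
    k <- node_of_col[j]
    col <- m[, j]
    cnt <- tabulate(col[col <= 20L], nbins = 20L)
    nx <- sum(col == 21L)
    cnt <- cnt + AA_BACKGROUND * nx
    em[k, ] <- em[k, ] + cnt
  }
  em <- em + pseudocount_weight * rep(AA_BACKGROUND, each = M)
  em <- em / rowSums(em)

  # transition counts per from-node 0..M-1 (node 0 = begin)
  # columns: MM MI MD IM II DM DD
  tc <- matrix(0, M + 1L, 7L,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (r in seq_len(nrows)) {
    state <- "M"; node <- 0L        # begin treated as M_0
    for (j in seq_len(ncol(m))) {
      x <- m[r, j]
      if (mask[j]) {
        nxt <- if (x == 22L) "D" else "M"
        key <- paste0(state, nxt)
        # I->D has no Plan7 transition; the event is skipped in counting
        if (key %in% colnames(tc)) tc[node + 1L, key] <- tc[node + 1L, key] + 1
        state <- nxt; node <- node_of_col[j]
      } else if (x != 22L) {        # insert residue (D->I likewise skipped)
        key <- paste0(state, "I")
        if (key %in% colnames(tc)) tc[node + 1L, key] <- tc[node + 1L, key] + 1
        state <- "I"
      }
    }
  }
  # smoothing and normalization; node M is a fixed convention (exit only)
  tr <- matrix(0, M + 1L, 7L, dimnames = dimnames(tc))
  for (k in seq_len(M)) {           # from-node k-1
    mtri <- tc[k, c("MM", "MI", "MD")] + transition_pseudocount
    itri <- tc[k, c("IM", "II")] + transition_pseudocount
    dtri <- tc[k, c("DM", "DD")] + transition_pseudocount
    tr[k, c("MM", "MI", "MD")] <- mtri / sum(mtri)
    tr[k, c("IM", "II")] <- itri / sum(itri)
    tr[k, c("DM", "DD")] <- dtri / sum(dtri)
  }
  tr[M + 1L, ] <- c(1, 0, 0, 1, 0, 1, 0)

  model <- structure(list(
    name = name, clan = clan, M = M,
    match_emissions = em,
    insert_emissions = AA_BACKGROUND,
    transitions = tr,
    background = AA_BACKGROUND,
    calibration = NULL,
    gathering_threshold = NULL
  ), class = "profile_hmm")
  validate_profile(model)
  model
}

#' Validate a profile HMM
#'
#' Checks the structural invariants: emission rows and transition groups sum
#' to one within 1e-9, `M >= 1`, and a positive Gumbel lambda when calibrated.
#'
#' @param model A `profile_hmm`.
#' @return Invisibly, `model`; errors on violation.
#' @export
validate_profile <- function(model) {
  stopifnot(inherits(model, "profile_hmm"))
  if (model$M < 1L) stop("model must have M >= 1", call. = FALSE)
  if (nrow(model$match_emissions) != model$M) {
    stop("emission table does not match M", call. = FALSE)
  }
  if (any(abs(rowSums(model$match_emissions) - 1) > 1e-9)) {
    stop("match emission rows must sum to 1", call. = FALSE)
  }
  if (abs(sum(model$insert_emissions) - 1) > 1e-9 ||
      abs(sum(model$background) - 1) > 1e-9) {
    stop("insert emissions and background must sum to 1", call. = FALSE)
  }
  tr <- model$transitions
  if (nrow(tr) != model$M + 1L) stop("transition table must have M+1 nodes", call. = FALSE)
  sums <- cbind(rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE]),
                rowSums(tr[, c("IM", "II"), drop = FALSE]),
                rowSums(tr[, c("DM", "DD"), drop = FALSE]))
  if (any(abs(sums - 1) > 1e-9)) {
    stop("transition groups must each sum to 1", call. = FALSE)
  }
  if (!is.null(model$calibration)) {
    if (!(length(model$calibration) == 2L && model$calibration[2] > 0)) {
      stop("calibration must be (mu, lambda) with lambda > 0", call. = FALSE)
    }
  }
  invisible(model)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm", x$name,
      if (nzchar(x$clan)) paste0("(clan ", x$clan, ")") else "",
      "M =", x$M, "\n")
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibrated: mu = %.3f bits, lambda = %.4f\n",
                x$calibration[1], x$calibration[2]))
  }
  if (!is.null(x$gathering_threshold)) {
    cat("  gathering threshold:", x$gathering_threshold, "bits\n")
  }
  invisible(x)
}

#' Consensus sequence of a profile HMM
#'
#' The highest-probability residue of each match state.
#'
#' @param model A `profile_hmm`.
#' @return A residue string of length `M`.
#' @export
consensus_sequence <- function(model) {
  stopifnot(inherits(model, "profile_hmm"))
  paste(AA_ALPHABET[apply(model$match_emissions, 1L, which.max)], collapse = "")
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a profile HMM to its text format
#'
#' Line-oriented versioned format with header `WDKHMM1`; probabilities are
#' printed with 17 significant digits so that a read/write round trip is
#' exact.
#'
#' @param model A `profile_hmm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hmm <- function(model, path) {
  validate_profile(model)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("WDKHMM1")
  w("NAME ", model$name)
  w("CLAN ", if (nzchar(model$clan)) model$clan else "-")
  w("LENG ", model$M)
  w("GA ", if (is.null(model$gathering_threshold)) "-" else fmt_num(model$gathering_threshold))
  w("CALIB ", if (is.null(model$calibration)) "-" else
      paste(fmt_num(model$calibration), collapse = " "))
  w("ALPH ", paste(AA_ALPHABET, collapse = ""))
  w("BG ", paste(fmt_num(model$background), collapse = " "))
  w("INSEMIT ", paste(fmt_num(model$insert_emissions), collapse = " "))
  for (k in 0:model$M) {
    if (k >= 1L) {
      w("MATCH ", k, " ", paste(fmt_num(model$match_emissions[k, ]), collapse = " "))
    }
    w("TRANS ", k, " ", paste(fmt_num(model$transitions[k + 1L, ]), collapse = " "))
  }
  w("END")
  invisible(path)
}

#' Read a profile HMM from its text format
#'
#' @param path Path to a `WDKHMM1` file written by [write_hmm()].
#' @return A `profile_hmm`.
#' @export
read_hmm <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || lines[1] != "WDKHMM1") {
    stop("not a WDKHMM1 file: ", path, call. = FALSE)
  }
  field <- function(key) {
    hit <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    if (is.na(hit)) stop("missing ", key, " line", call. = FALSE)
    sub(paste0("^", key, " "), "", hit)
  }
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  M <- as.integer(field("LENG"))
  ga <- field("GA")
  calib <- field("CALIB")
  em <- matrix(0, M, 20L)
  tr <- matrix(0, M + 1L, 7L,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (ln in lines) {
    if (startsWith(ln, "MATCH ")) {
      v <- nums(sub("^MATCH ", "", ln))
      em[v[1], ] <- v[-1]
    } else if (startsWith(ln, "TRANS ")) {
      v <- nums(sub("^TRANS ", "", ln))
      tr[v[1] + 1L, ] <- v[-1]
    }
  }
  clan <- field("CLAN")
  model <- structure(list(
    name = field("NAME"),
    clan = if (identical(clan, "-")) "" else clan,
    M = M,
    match_emissions = em,
    insert_emissions = setNames(nums(field("INSEMIT")), AA_ALPHABET),
    transitions = tr,
    background = setNames(nums(field("BG")), AA_ALPHABET),
    calibration = if (identical(calib, "-")) NULL else nums(calib),
    gathering_threshold = if (identical(ga, "-")) NULL else as.numeric(ga)
  ), class = "profile_hmm")
  validate_profile(model)
  model
}
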