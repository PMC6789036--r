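# Scoring engine: Plan7-style local multi-hit Viterbi/Forward wrappers,
# domain envelope extraction, Gumbel calibration and E-values, and the
# threshold-driven search/scan drivers.

# Precompute log2 score vectors for the DP kernels. Local entry is uniform
# over match states (B->M_k = 1/M); local exit folds an exit hazard
# e_k = 1/(M-k+1) into the match transitions, so exit positions are uniform
# and every state's outgoing probabilities still sum to one. N/C/J loops are
# conditioned on the target length L; multi-hit mode opens the E->J loop with
# probability 1/2.
model_scores <- function(model, L, multihit = TRUE) {
  M <- model$M
  msc <- cbind(log2(model$match_emissions) - rep(log2(model$background), each = M),
               rep(0, M))  # X column scores 0 (background emission)
  k <- seq_len(M)
  ek <- 1 / (M - k + 1)
  keep <- log2(1 - ek)            # -Inf at k = M, as intended
  tr <- model$transitions
  tmm <- log2(tr[k + 1L, "MM"]) + keep
  tmi <- log2(tr[k + 1L, "MI"]) + keep
  tmd <- log2(tr[k + 1L, "MD"]) + keep
  tim <- log2(tr[k + 1L, "IM"])
  tii <- log2(tr[k + 1L, "II"])
  tdm <- log2(tr[k + 1L, "DM"])
  tdd <- log2(tr[k + 1L, "DD"])
  tim[M] <- tii[M] <- tdm[M] <- tdd[M] <- -Inf
  tmi[M] <- -Inf
  tbm <- rep(log2(1 / M), M)
  tme <- log2(ek)
  if (multihit) {
    loop <- log2(L / (L + 3)); move <- log2(3 / (L + 3))
    ej <- log2(0.5); ec <- log2(0.5)
  } else {
    loop <- log2(L / (L + 2)); move <- log2(2 / (L + 2))
    ej <- -Inf; ec <- 0
  }
  list(msc = msc, tmm = tmm, tmi = tmi, tmd = tmd, tim = tim, tii = tii,
       tdm = tdm, tdd = tdd, tbm = tbm, tme = tme,
       loop = loop, move_nb = move, move_jb = move, move_ct = move,
       ej = ej, ec = ec)
}

# geometric null-length correction (i.i.d. background null model)
null_transition_score <- function(L) {
  L * log2(L / (L + 1)) + log2(1 / (L + 1))
}

seq_codes <- function(seq) {
  seq <- as_residues(seq)
  check_residues(seq)
  codes <- encode_residues(seq)
  if (any(codes == 22L)) stop("gap characters in sequence", call. = FALSE)
  codes
}

#' Viterbi score and state path
#'
#' Scores a sequence against a profile in local multi-hit (default) or
#' single-hit mode and returns the maximum-probability alignment in bits
#' (log2 odds against an i.i.d. background null with geometric length
#' correction) together with the optimal state path.
#'
#' @param model A `profile_hmm`.
#' @param seq Residue string or single-row [seq_set()].
#' @param multihit Allow multiple domain hits per sequence (default TRUE).
#' @return List with `bit_score` and `path`, a data frame of
#'   `(state, node, pos)` with states `N,B,M,I,D,E,J,C`.
#' @export
viterbi <- function(model, seq, multihit = TRUE) {
  validate_profile(model)
  codes <- seq_codes(seq)
  sc <- model_scores(model, length(codes), multihit)
  res <- .viterbi_cpp(sc$msc, sc$tmm, sc$tmi, sc$tmd, sc$tim, sc$tii,
                      sc$tdm, sc$tdd, sc$tbm, sc$tme, codes,
                      sc$loop, sc$move_nb, sc$move_jb, sc$move_ct,
                      sc$ej, sc$ec, TRUE)
  states <- c("N", "B", "M", "I", "D", "E", "J", "C")
  path <- data.frame(state = states[res$path[, 1]],
                     node = res$path[, 2],
                     pos = res$path[, 3],
                     stringsAsFactors = FALSE)
  list(bit_score = res$score - null_transition_score(length(codes)),
       path = path)
}

# score-only variant used in hot loops
viterbi_score <- function(model, codes, multihit = TRUE) {
  sc <- model_scores(model, length(codes), multihit)
  res <- .viterbi_cpp(sc$msc, sc$tmm, sc$tmi, sc$tmd, sc$tim, sc$tii,
                      sc$tdm, sc$tdd, sc$tbm, sc$tme, codes,
                      sc$loop, sc$move_nb, sc$move_jb, sc$move_ct,
                      sc$ej, sc$ec, FALSE)
  res$score - null_transition_score(length(codes))
}

#' Forward score
#'
#' Log-sum score over all alignments in bits; always at least the Viterbi
#' score of the same model/sequence pair.
#'
#' @inheritParams viterbi
#' @return Bit score (numeric scalar).
#' @export
forward_score <- function(model, seq, multihit = TRUE) {
  validate_profile(model)
  codes <- seq_codes(seq)
  sc <- model_scores(model, length(codes), multihit)
  raw <- .forward_cpp(sc$msc, sc$tmm, sc$tmi, sc$tmd, sc$tim, sc$tii,
                      sc$tdm, sc$tdd, sc$tbm, sc$tme, codes,
                      sc$loop, sc$move_nb, sc$move_jb, sc$move_ct,
                      sc$ej, sc$ec)
  raw - null_transition_score(length(codes))
}

#' Extract per-domain hits from the optimal alignment
#'
#' Segments the multi-hit Viterbi path into domain cores (aligned spans on
#' sequence and model), merges adjacent complementary partial cores of the
#' same occurrence, extends each core to its envelope by the number of
#' unmatched flanking model nodes (capped at 5 residues and bounded by
#' neighbouring domains and the sequence ends), rescores every envelope in
#' single-hit mode for an independent per-domain bit score, and attaches
#' independent E-values when the model is calibrated.
#'
#' @param model A `profile_hmm`.
#' @param seq Residue string or single-row [seq_set()]; a `seq_set` supplies
#'   the `sequence_id`.
#' @param db_size Effective database size for independent E-values.
#' @return Data frame of domain hits sorted by `env_from` with columns
#'   `sequence_id, model, clan, env_from, env_to, ali_from, ali_to, hmm_from,
#'   hmm_to, score_bits, i_evalue`.
#' @export
find_domains <- function(model, seq, db_size = 1) {
  sid <- if (inherits(seq, "seq_set")) seq$id[1] else ""
  residues <- as_residues(seq)
  L <- nchar(residues)
  vit <- viterbi(model, residues, multihit = TRUE)
  path <- vit$path
  # segment boundaries: each B ... E stretch is one domain
  b_rows <- which(path$state == "B")
  e_rows <- which(path$state == "E")
  n_dom <- length(e_rows)
  if (n_dom == 0L) return(empty_hits())
  ali_from <- ali_to <- hmm_from <- hmm_to <- integer(n_dom)
  for (d in seq_len(n_dom)) {
    seg <- path[(b_rows[d] + 1L):(e_rows[d] - 1L), , drop = FALSE]
    mrows <- seg[seg$state == "M", , drop = FALSE]
    ali_from[d] <- min(mrows$pos); ali_to[d] <- max(mrows$pos)
    hmm_from[d] <- min(mrows$node); hmm_to[d] <- max(mrows$node)
  }
  # merge adjacent complementary partial cores of the same occurrence:
  # when the second core resumes at a later model node and the sequence gap
  # is commensurate with the skipped model span, the optimal path split one
  # noisy domain instance across the J loop
  d <- 1L
  while (d < length(ali_from)) {
    model_gap <- hmm_from[d + 1L] - hmm_to[d] - 1L
    seq_gap <- ali_from[d + 1L] - ali_to[d] - 1L
    # tolerate a few re-matched nodes (model_gap slightly negative); a
    # genuine second copy restarts near node 1, far below this bound
    if (model_gap >= -10L &&
        seq_gap <= max(40L, 2L * max(model_gap, 0L) + 20L)) {
      ali_to[d] <- ali_to[d + 1L]; hmm_to[d] <- hmm_to[d + 1L]
      ali_from <- ali_from[-(d + 1L)]; ali_to <- ali_to[-(d + 1L)]
      hmm_from <- hmm_from[-(d + 1L)]; hmm_to <- hmm_to[-(d + 1L)]
    } else {
      d <- d + 1L
    }
  }
  n_dom <- length(ali_from)
  env_from <- env_to <- integer(n_dom)
  for (d in seq_len(n_dom)) {
    lo <- if (d == 1L) 1L else ali_to[d - 1L] + 1L
    hi <- if (d == n_dom) L else ali_from[d + 1L] - 1L
    env_from[d] <- max(lo, ali_from[d] - min(hmm_from[d] - 1L, 5L))
    env_to[d] <- min(hi, ali_to[d] + min(model$M - hmm_to[d], 5L))
  }
  score_bits <- vapply(seq_len(n_dom), function(d) {
    sub <- substr(residues, env_from[d], env_to[d])
    viterbi_score(model, encode_residues(sub), multihit = FALSE)
  }, numeric(1))
  iev <- if (is.null(model$calibration)) {
    rep(NA_real_, n_dom)
  } else {
    evalue(score_bits, model, db_size)
  }
  data.frame(sequence_id = sid, model = model$name, clan = model_clan(model),
             env_from = env_from, env_to = env_to,
             ali_from = ali_from, ali_to = ali_to,
             hmm_from = hmm_from, hmm_to = hmm_to,
             score_bits = score_bits, i_evalue = iev,
             stringsAsFactors = FALSE)
}

model_clan <- function(model) {
  if (nzchar(model$clan)) model$clan else model$name
}

empty_hits <- function() {
  data.frame(sequence_id = character(), model = character(), clan = character(),
             env_from = integer(), env_to = integer(),
             ali_from = integer(), ali_to = integer(),
             hmm_from = integer(), hmm_to = integer(),
             score_bits = numeric(), i_evalue = numeric(),
             stringsAsFactors = FALSE)
}

# maximum-likelihood Gumbel fit (location mu, scale beta) via the standard
# fixed-point iteration; deterministic.
fit_gumbel <- function(x, tol = 1e-10, max_iter = 500L) {
  if (length(x) < 2L || sd(x) == 0) {
    stop("degenerate score distribution; cannot calibrate", call. = FALSE)
  }
  beta <- sd(x) * sqrt(6) / pi
  xbar <- mean(x)
  for (it in seq_len(max_iter)) {
    w <- exp(-(x - xbar) / beta)        # shift by xbar for stability
    beta_new <- xbar - sum(x * w) / sum(w)
    if (abs(beta_new - beta) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  mu <- xbar - beta * log(mean(exp(-(x - xbar) / beta)))
  c(mu = mu, lambda = 1 / beta)
}

#' Calibrate a profile's E-value statistics
#'
#' Scores `n_random` i.i.d. background sequences of the given length in
#' multi-hit Viterbi mode and fits a Gumbel distribution to the bit scores by
#' maximum likelihood. Bit-for-bit reproducible under a fixed seed.
#'
#' @param model A `profile_hmm`.
#' @param n_random Number of random sequences (>= 100; default 200).
#' @param length Length of each random sequence; default 350.
#' @param seed Integer seed (mandatory).
#' @return The model with `calibration = c(mu, lambda)` set.
#' @export
calibrate <- function(model, n_random = 200L, length = 350L, seed) {
  validate_profile(model)
  if (n_random < 100L) stop("n_random must be >= 100", call. = FALSE)
  if (missing(seed)) stop("calibration requires an explicit seed", call. = FALSE)
  scores <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      codes <- sample.int(20L, length, replace = TRUE, prob = model$background)
      viterbi_score(model, as.integer(codes), multihit = TRUE)
    }, numeric(1))
  })
  fit <- fit_gumbel(scores)
  model$calibration <- unname(fit)
  model
}

#' Independent E-value of a bit score
#'
#' `E = db_size * (1 - exp(-exp(-lambda * (score - mu))))`, the Gumbel
#' exceedance probability scaled by the database size; monotone decreasing in
#' the score.
#'
#' @param score Bit score(s).
#' @param model A calibrated `profile_hmm`.
#' @param db_size Number of independent comparisons (>= 1).
#' @return E-value(s).
#' @export
evalue <- function(score, model, db_size = 1) {
  if (is.null(model$calibration)) {
    stop("model '", model$name, "' is not calibrated", call. = FALSE)
  }
  stopifnot(db_size >= 1)
  mu <- model$calibration[1]; lambda <- model$calibration[2]
  db_size * (-expm1(-exp(-lambda * (score - mu))))
}

#' Reporting and inclusion thresholds for search and scan
#'
#' The defaults mirror the survey's command-line settings:
#' `search_thresholds()` gives `(E 1, domE 1, incE 0.01, incdomE 0.03)` and
#' `scan_thresholds()` gives `(E 0.1, domE 0.1, incE 0.01, incdomE 0.03)`.
#'
#' @param report_E,report_domE Reporting E-value bounds (sequence, domain).
#' @param include_E,include_domE Inclusion E-value bounds; must not exceed
#'   the reporting bounds.
#' @param min_domain_score Optional bit-score floor for domain inclusion.
#' @return A `search_thresholds` object.
#' @export
search_thresholds <- function(report_E = 1, report_domE = 1,
                              include_E = 0.01, include_domE = 0.03,
                              min_domain_score = NULL) {
  stopifnot(report_E > 0, report_domE > 0, include_E > 0, include_domE > 0)
  if (include_E > report_E || include_domE > report_domE) {
    stop("inclusion bounds must not exceed reporting bounds", call. = FALSE)
  }
  structure(list(report_E = report_E, report_domE = report_domE,
                 include_E = include_E, include_domE = include_domE,
                 min_domain_score = min_domain_score),
            class = "search_thresholds")
}

#' @rdname search_thresholds
#' @export
scan_thresholds <- function(report_E = 0.1, report_domE = 0.1,
                            include_E = 0.01, include_domE = 0.03,
                            min_domain_score = NULL) {
  search_thresholds(report_E, report_domE, include_E, include_domE,
                    min_domain_score)
}

#' Search a profile against a sequence database
#'
#' Scores every sequence (multi-hit Viterbi), reports those with
#' full-sequence `E <= report_E` together with their domains at
#' `i_evalue <= report_domE`, and marks as included the sequences meeting
#' `include_E` and their domains meeting `include_domE` (and, if set,
#' `min_domain_score`).
#'
#' @param model A calibrated `profile_hmm`.
#' @param db A [seq_set()].
#' @param th A [search_thresholds()].
#' @return List with `sequences` (id, bit_score, evalue, included; ordered by
#'   E-value then id) and `hits` (domain table with `included` flag).
#' @export
hmm_search <- function(model, db, th = search_thresholds()) {
  if (is.null(model$calibration)) stop("model must be calibrated", call. = FALSE)
  stopifnot(inherits(db, "seq_set"), inherits(th, "search_thresholds"))
  Z <- nrow(db)
  if (Z == 0L) {
    return(list(sequences = data.frame(sequence_id = character(),
                                       bit_score = numeric(),
                                       evalue = numeric(),
                                       included = logical()),
                hits = cbind(empty_hits(), included = logical())))
  }
  bits <- vapply(db$residues, function(r) {
    viterbi_score(model, encode_residues(r))
  }, numeric(1), USE.NAMES = FALSE)
  ev <- evalue(bits, model, Z)
  seq_df <- data.frame(sequence_id = db$id, bit_score = bits, evalue = ev,
                       included = ev <= th$include_E,
                       stringsAsFactors = FALSE)
  hit_list <- list()
  for (i in which(ev <= th$report_E)) {
    h <- find_domains(model, db[i, , drop = FALSE], db_size = Z)
    h <- h[h$i_evalue <= th$report_domE, , drop = FALSE]
    if (nrow(h) == 0L) next
    inc <- seq_df$included[i] & h$i_evalue <= th$include_domE
    if (!is.null(th$min_domain_score)) {
      inc <- inc & h$score_bits > th$min_domain_score
    }
    h$included <- inc
    hit_list[[length(hit_list) + 1L]] <- h
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else
    cbind(empty_hits(), included = logical())
  ord <- order(seq_df$evalue, seq_df$sequence_id)
  seq_df <- seq_df[ord, , drop = FALSE]
  rownames(seq_df) <- rownames(hits) <- NULL
  list(sequences = seq_df, hits = hits)
}

#' Scan a sequence against a library of profiles
#'
#' Runs per-model domain extraction with E-values computed against
#' `db_size = number of models`, filters by the scan thresholds, and returns
#' the merged hit list sorted by envelope start.
#'
#' @param models List of calibrated `profile_hmm`s.
#' @param seq Residue string or single-row [seq_set()].
#' @param th A [search_thresholds()]; defaults to [scan_thresholds()].
#' @return Domain-hit data frame with `included` flag, sorted by `env_from`.
#' @export
hmm_scan <- function(models, seq, th = scan_thresholds()) {
  stopifnot(is.list(models), length(models) >= 1L)
  Z <- length(models)
  out <- list()
  for (model in models) {
    if (is.null(model$calibration)) {
      stop("model '", model$name, "' is not calibrated", call. = FALSE)
    }
    residues <- as_residues(seq)
    bit <- viterbi_score(model, encode_residues(residues))
    ev <- evalue(bit, model, Z)
    if (ev > th$report_E) next
    h <- find_domains(model, seq, db_size = Z)
    h <- h[h$i_evalue <= th$report_domE, , drop = FALSE]
    if (nrow(h) == 0L) next
    inc <- (ev <= th$include_E) & (h$i_evalue <= th$include_domE)
    if (!is.null(th$min_domain_score)) inc <- inc & h$score_bits > th$min_domain_score
    h$included <- inc
    out[[length(out) + 1L]] <- h
  }
  hits <- if (length(out)) do.call(rbind, out) else
    cbind(empty_hits(), included = logical())
  hits <- hits[order(hits$env_from, hits$model), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write a domain-hit table to TSV
#'
#' Mirrors a domain-table layout with an `included` 0/1 column.
#'
#' @param hits Hit data frame from [search()], [scan()] or [find_domains()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  df <- hits
  if ("included" %in% names(df)) df$included <- as.integer(df$included)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a domain-hit TSV written by [write_hits()]
#' @param path Input path.
#' @return Hit data frame (`included` as logical, when present).
#' @export
read_hits <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("included" %in% names(df)) df$included <- df$included == 1L
  df
}
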