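# Iterative HMM seed maturation: length-stratified sampling of composite
# hits, automated seed curation, boundary definition from short-hit C-termini,
# the rebuild-and-research loop, and the wing-type split for the two HTH
# profiles.

#' Maturation configuration
#'
#' Carries the knobs of the seed-maturation protocol. The defaults are the
#' WYL protocol: 127-residue length split, 250 sequences per stratum, 70%
#' clustering identity, gathering threshold 27.0 bits, three iterations.
#' [hth_maturation_config()] (90% identity, one iteration, gathering 30.0)
#' and [wcx_maturation_config()] (no iteration, gathering 30.0) carry the
#' protocols of the two other custom profiles.
#'
#' @param length_threshold Envelope-length split in residues (default 127).
#' @param n_per_stratum Sequences sampled per stratum (default 250).
#' @param cluster_identity Seed deduplication identity (default 0.70).
#' @param gathering_threshold Bit-score cutoff for keeping search hits
#'   (default 27.0).
#' @param iterations Number of rebuild-and-research iterations (default 3).
#' @param seed Integer seed (mandatory).
#' @param curation_max_gap_fraction Row gap-fraction limit within the
#'   conserved block for [curate_seed()] (default 0.5).
#' @return A `maturation_config` object.
#' @export
maturation_config <- function(length_threshold = 127L, n_per_stratum = 250L,
                              cluster_identity = 0.70,
                              gathering_threshold = 27.0,
                              iterations = 3L, seed,
                              curation_max_gap_fraction = 0.5) {
  if (missing(seed)) stop("maturation requires an explicit seed", call. = FALSE)
  stopifnot(length_threshold > 0, n_per_stratum >= 1, iterations >= 0,
            cluster_identity > 0, cluster_identity <= 1,
            curation_max_gap_fraction > 0, curation_max_gap_fraction <= 1)
  structure(list(length_threshold = as.integer(length_threshold),
                 n_per_stratum = as.integer(n_per_stratum),
                 cluster_identity = cluster_identity,
                 gathering_threshold = gathering_threshold,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 curation_max_gap_fraction = curation_max_gap_fraction),
            class = "maturation_config")
}

#' @rdname maturation_config
#' @export
hth_maturation_config <- function(seed, ...) {
  maturation_config(cluster_identity = 0.90, gathering_threshold = 30.0,
                    iterations = 1L, seed = seed, ...)
}

#' @rdname maturation_config
#' @export
wcx_maturation_config <- function(seed, ...) {
  maturation_config(gathering_threshold = 30.0, iterations = 0L, seed = seed,
                    ...)
}

#' Read / write a maturation configuration as YAML
#' @param cfg A [maturation_config()].
#' @param path YAML file path.
#' @return `write_maturation_config` returns `path` invisibly;
#'   `read_maturation_config` returns the configuration.
#' @export
write_maturation_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "maturation_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_maturation_config
#' @export
read_maturation_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(maturation_config, x)
}

#' Seed alignment with domain boundaries
#'
#' @param alignment An [msa()].
#' @param domain_start_col,domain_end_col 1-based boundary columns within the
#'   alignment.
#' @param provenance Character vector of source hit ids (unique).
#' @return A `seed_alignment` object.
#' @export
seed_alignment <- function(alignment, domain_start_col = 1L,
                           domain_end_col = n_columns(alignment),
                           provenance = alignment$ids) {
  stopifnot(inherits(alignment, "msa"))
  nc <- n_columns(alignment)
  if (!(domain_start_col >= 1 && domain_start_col <= domain_end_col &&
        domain_end_col <= nc)) {
    stop("domain boundary columns out of range", call. = FALSE)
  }
  if (anyDuplicated(provenance)) stop("provenance ids must be unique", call. = FALSE)
  structure(list(alignment = alignment,
                 domain_start_col = as.integer(domain_start_col),
                 domain_end_col = as.integer(domain_end_col),
                 provenance = provenance),
            class = "seed_alignment")
}

hit_ids <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  paste0(hits$sequence_id, ":", hits$env_from, "-", hits$env_to)
}

#' Length-stratified sampling of domain hits
#'
#' Splits hits into a long stratum (envelope length strictly greater than
#' `cfg$length_threshold`) and a short stratum (everything else; a length of
#' exactly the threshold goes to the short stratum) and samples up to
#' `cfg$n_per_stratum` hits from each without replacement, reproducibly under
#' `cfg$seed`. Hits are expected to be pre-filtered to the protocol's score
#' and E-value cutoffs.
#'
#' @param hits Domain-hit data frame (needs `env_from`, `env_to`).
#' @param cfg A [maturation_config()].
#' @return List with `long` and `short`, each a hit data frame carrying a
#'   `hit_id` column. An empty stratum produces a warning and an empty frame.
#' @export
stratified_sample <- function(hits, cfg) {
  stopifnot(inherits(cfg, "maturation_config"))
  len <- hits$env_to - hits$env_from + 1L
  long <- hits[len > cfg$length_threshold, , drop = FALSE]
  short <- hits[len <= cfg$length_threshold, , drop = FALSE]
  take <- function(df, stream) {
    if (nrow(df) == 0L) {
      warning("empty stratum in stratified_sample", call. = FALSE)
      df$hit_id <- character(0)
      return(df)
    }
    df <- df[order(hit_ids(df)), , drop = FALSE]   # stable under input order
    n <- min(cfg$n_per_stratum, nrow(df))
    idx <- with_seed(derive_seed(cfg$seed, stream),
                     sample.int(nrow(df), n, replace = FALSE))
    out <- df[sort(idx), , drop = FALSE]
    out$hit_id <- hit_ids(out)
    rownames(out) <- NULL
    out
  }
  list(long = take(long, 1L), short = take(short, 2L))
}

# conserved block = columns with >= 50% occupancy
conserved_block <- function(aln) {
  m <- msa_matrix(aln)
  which(colMeans(m != 22L) >= 0.5)
}

#' Automated curation of a seed alignment
#'
#' Drops rows that are obviously defective within the conserved block (the
#' columns with at least 50% occupancy): rows whose gap fraction inside the
#' block exceeds `cfg$curation_max_gap_fraction`, or that have no residue in
#' one of the three terciles of the block (e.g. truncated instances missing
#' the C-terminal half). Deterministic; errors if nothing survives.
#'
#' @param aln An [msa()].
#' @param cfg A [maturation_config()].
#' @return The curated [msa()].
#' @export
curate_seed <- function(aln, cfg) {
  stopifnot(inherits(aln, "msa"), inherits(cfg, "maturation_config"))
  m <- msa_matrix(aln)
  block <- conserved_block(aln)
  if (length(block) == 0L) stop("no conserved block to curate against", call. = FALSE)
  terciles <- split(block, cut(seq_along(block), 3L, labels = FALSE))
  keep <- vapply(seq_len(nrow(m)), function(r) {
    row <- m[r, block]
    if (mean(row == 22L) > cfg$curation_max_gap_fraction) return(FALSE)
    for (tc in terciles) {
      if (all(m[r, tc] == 22L)) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!any(keep)) stop("curation dropped all rows", call. = FALSE)
  msa(aln$ids[keep], aln$seqs[keep])
}

#' Define domain boundary columns from short-hit C-termini
#'
#' The N-terminal boundary is the first column with at least 50% occupancy;
#' the C-terminal boundary is the median (rounded down for even counts) of
#' the alignment columns where the short-stratum hits end.
#'
#' @param aln An [msa()].
#' @param short_hit_ends Integer vector of C-terminal columns of short hits.
#' @return `c(start_col, end_col)`; errors when inverted.
#' @export
define_boundaries <- function(aln, short_hit_ends) {
  stopifnot(inherits(aln, "msa"), length(short_hit_ends) >= 1L)
  block <- conserved_block(aln)
  start_col <- min(block)
  s <- sort(as.integer(short_hit_ends))
  n <- length(s)
  end_col <- if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else
    (s[n %/% 2L] + s[n %/% 2L + 1L]) %/% 2L   # floor of the midpoint
  if (!(start_col < end_col)) {
    stop("inverted domain boundaries (", start_col, " >= ", end_col, ")",
         call. = FALSE)
  }
  c(start_col = start_col, end_col = as.integer(end_col))
}

model_checksum <- function(model) {
  tf <- tempfile(fileext = ".hmm")
  on.exit(unlink(tf))
  write_hmm(model, tf)
  unname(tools::md5sum(tf))
}

# cluster seed rows at the configured identity and keep representatives
dedupe_seed_rows <- function(aln, identity) {
  recs <- seq_set(aln$ids, vapply(seq_along(aln$ids),
                                  function(i) ungap_row(aln, i), character(1)))
  cs <- greedy_cluster(recs, identity)
  keep <- aln$ids %in% cs$representatives
  msa(aln$ids[keep], aln$seqs[keep])
}

#' Iteratively mature a profile HMM
#'
#' Runs the rebuild-and-research protocol: per iteration, (i) cluster the
#' seed rows at `cfg$cluster_identity` keeping cluster representatives,
#' (ii) build and calibrate a profile from the seed, (iii) search the
#' database keeping included hits with bit score above
#' `cfg$gathering_threshold`, and (iv) align the hit envelopes and trim the
#' alignment to its occupied block as the next seed. With `iterations = 0`
#' the model is built directly from the initial seed (the WCX protocol).
#' The returned model carries the gathering threshold and is calibrated;
#' identical inputs give byte-identical model files.
#'
#' @param db A [seq_set()] database to search against.
#' @param initial_seed A [seed_alignment()], already curated.
#' @param cfg A [maturation_config()].
#' @return A `maturation_result`: list with `model` (calibrated
#'   `profile_hmm`) and `report` (per-iteration data frame: iteration,
#'   n_hits, n_kept, start_col, end_col, M, checksum).
#' @export
mature_hmm <- function(db, initial_seed, cfg) {
  stopifnot(inherits(db, "seq_set"), inherits(initial_seed, "seed_alignment"),
            inherits(cfg, "maturation_config"))
  seed_aln <- trim_alignment(initial_seed$alignment,
                             initial_seed$domain_start_col,
                             initial_seed$domain_end_col)
  report <- list()
  build_and_calibrate <- function(aln, stream) {
    model <- build_profile(aln, name = "matured")
    model$gathering_threshold <- cfg$gathering_threshold
    calibrate(model, seed = derive_seed(cfg$seed, 1000L + stream))
  }
  if (cfg$iterations >= 1L) {
    for (it in seq_len(cfg$iterations)) {
      seed_aln <- dedupe_seed_rows(seed_aln, cfg$cluster_identity)
      model <- build_and_calibrate(seed_aln, it)
      res <- hmm_search(model, db)
      hits <- res$hits[res$hits$included &
                         res$hits$score_bits > cfg$gathering_threshold, ,
                       drop = FALSE]
      if (nrow(hits) == 0L) {
        stop("maturation iteration ", it,
             " produced no hits above the gathering threshold", call. = FALSE)
      }
      env <- vapply(seq_len(nrow(hits)), function(i) {
        r <- db$residues[match(hits$sequence_id[i], db$id)]
        substr(r, hits$env_from[i], hits$env_to[i])
      }, character(1))
      recs <- seq_set(make.unique(hit_ids(hits), sep = "_"), env)
      full <- progressive_align(recs)
      block <- conserved_block(full)
      seed_aln <- trim_alignment(full, min(block), max(block))
      report[[it]] <- data.frame(
        iteration = it, n_hits = nrow(res$hits), n_kept = nrow(hits),
        start_col = min(block), end_col = max(block),
        M = model$M, checksum = model_checksum(model),
        stringsAsFactors = FALSE)
    }
  }
  final <- build_and_calibrate(seed_aln, cfg$iterations + 1L)
  report[[length(report) + 1L]] <- data.frame(
    iteration = cfg$iterations + 1L, n_hits = NA_integer_,
    n_kept = length(seed_aln$ids), start_col = 1L,
    end_col = n_columns(seed_aln), M = final$M,
    checksum = model_checksum(final), stringsAsFactors = FALSE)
  structure(list(model = final, report = do.call(rbind, report)),
            class = "maturation_result")
}

#' @export
print.maturation_result <- function(x, ...) {
  cat("maturation_result: final model M =", x$model$M, "\n")
  print(x$report)
  invisible(x)
}

#' Split an HTH seed alignment into wing-type groups
#'
#' With explicit per-row `labels` the partition follows the labels (the
#' survey's PafB-like/PafC-like split was manual). Without labels, rows are
#' partitioned by complete-linkage clustering of pairwise identities over the
#' wing-region columns, cut into two groups.
#'
#' @param aln A curated [msa()].
#' @param labels Optional per-row group labels (exactly two distinct values).
#' @param wing_cols Optional integer range of wing-region columns; defaults
#'   to the whole alignment.
#' @return List of two [seed_alignment()]s, ordered by decreasing size.
#' @export
split_wing_groups <- function(aln, labels = NULL, wing_cols = NULL) {
  stopifnot(inherits(aln, "msa"))
  n <- length(aln$ids)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    lv <- unique(labels)
    if (length(lv) != 2L) stop("labels must define exactly two groups", call. = FALSE)
    groups <- lapply(lv, function(l) which(labels == l))
  } else {
    if (n < 2L) stop("need at least two rows for an unsupervised split", call. = FALSE)
    cols <- if (is.null(wing_cols)) seq_len(n_columns(aln)) else wing_cols
    wing <- substr(aln$seqs, min(cols), max(cols))
    wing <- gsub("-", "", wing, fixed = TRUE)
    if (any(wing == "")) stop("some rows have no residues in the wing region",
                              call. = FALSE)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d[i, j] <- d[j, i] <- 1 - pairwise_identity(wing[i], wing[j])
      }
    }
    cl <- cutree(hclust(as.dist(d), method = "complete"), k = 2L)
    groups <- lapply(1:2, function(g) which(cl == g))
  }
  if (any(lengths(groups) == 0L)) {
    stop("one wing group is empty; provide explicit labels", call. = FALSE)
  }
  groups <- groups[order(-lengths(groups))]
  lapply(groups, function(idx) {
    sub <- msa(aln$ids[idx], aln$seqs[idx])
    seed_alignment(sub, provenance = aln$ids[idx])
  })
}
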