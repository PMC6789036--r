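# Domain-architecture classification: proteome annotation against a model
# library, clan-level overlap resolution, ordered architecture signatures,
# class grouping with the survey's statistics, and display filtering.

#' Build a clan map for a model library
#'
#' Maps every model name to a clan label; models without an explicit clan (or
#' override) map to their own name, so the map is total over the library.
#'
#' @param models List of `profile_hmm`s.
#' @param overrides Optional named character vector `model -> clan`.
#' @return Named character vector `model name -> clan`.
#' @export
clan_map <- function(models, overrides = NULL) {
  cm <- vapply(models, model_clan, character(1))
  names(cm) <- vapply(models, function(m) m$name, character(1))
  if (!is.null(overrides)) {
    stopifnot(!is.null(names(overrides)))
    cm[names(overrides)] <- overrides
  }
  cm
}

#' Annotate a proteome with domain hits
#'
#' Scans every sequence against the model library and retains the included
#' hits. A per-sequence operation: the result is independent of database
#' order, and sequences without hits are kept with empty hit lists.
#'
#' @param models List of calibrated `profile_hmm`s.
#' @param db A [seq_set()].
#' @param th A [search_thresholds()]; defaults to [scan_thresholds()].
#' @return A `proteome_annotation`: list with `hits` (included domain hits,
#'   all sequences) and `sequence_ids` (every id in `db`).
#' @export
annotate_proteome <- function(models, db, th = scan_thresholds()) {
  stopifnot(inherits(db, "seq_set"))
  out <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    h <- hmm_scan(models, db[i, , drop = FALSE], th)
    out[[i]] <- h[h$included, , drop = FALSE]
  }
  hits <- if (length(out)) do.call(rbind, out) else
    cbind(empty_hits(), included = logical())
  rownames(hits) <- NULL
  structure(list(hits = hits, sequence_ids = db$id),
            class = "proteome_annotation")
}

#' @export
print.proteome_annotation <- function(x, ...) {
  cat("proteome_annotation:", length(x$sequence_ids), "sequences,",
      nrow(x$hits), "included hits\n")
  invisible(x)
}

# all maximal conflict-free subsets handled exactly: connected components of
# the same-clan >50%-overlap graph are searched exhaustively for the subset
# maximizing summed bit score (ties: lower total i-evalue, then model names)
overlaps_conflict <- function(h, i, j) {
  if (h$clan[i] != h$clan[j]) return(FALSE)
  ov <- min(h$env_to[i], h$env_to[j]) - max(h$env_from[i], h$env_from[j]) + 1L
  if (ov <= 0L) return(FALSE)
  shorter <- min(h$env_to[i] - h$env_from[i], h$env_to[j] - h$env_from[j]) + 1L
  ov > 0.5 * shorter
}

#' Resolve same-clan overlapping hits of one sequence
#'
#' Hits of the same clan whose envelopes overlap by more than 50% of the
#' shorter envelope conflict; among every set of conflicting hits the
#' conflict-free subset with the largest summed bit score is kept (ties
#' broken by lower total independent E-value, then by model names).
#' Cross-clan overlaps are retained. Output is sorted by envelope start.
#'
#' @param hits Domain-hit data frame for a single sequence.
#' @param clans Optional named clan map overriding the hits' `clan` column.
#' @return The non-overlapping hit data frame.
#' @export
resolve_overlaps <- function(hits, clans = NULL) {
  if (nrow(hits) <= 1L) {
    return(hits[order(hits$env_from), , drop = FALSE])
  }
  h <- hits
  if (!is.null(clans)) h$clan <- unname(clans[h$model])
  n <- nrow(h)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      conflict[i, j] <- conflict[j, i] <- overlaps_conflict(h, i, j)
    }
  }
  # connected components of the conflict graph
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, which(conflict[v, ] & comp == 0L))
    }
  }
  keep <- logical(n)
  for (cc in seq_len(cur)) {
    idx <- which(comp == cc)
    if (length(idx) == 1L) { keep[idx] <- TRUE; next }
    if (length(idx) > 20L) {
      # degenerate pile-up: greedy by score, deterministic
      ord <- idx[order(h$i_evalue[idx], -h$score_bits[idx], h$model[idx])]
      taken <- integer(0)
      for (v in ord) {
        if (!any(conflict[v, taken])) taken <- c(taken, v)
      }
      keep[taken] <- TRUE
      next
    }
    best <- NULL
    best_key <- NULL
    for (bits in 0:(2^length(idx) - 1L)) {
      sel <- idx[bitwAnd(bits, 2^(seq_along(idx) - 1L)) > 0L]
      if (length(sel) > 1L) {
        ok <- TRUE
        for (a in seq_len(length(sel) - 1L)) {
          if (any(conflict[sel[a], sel[(a + 1L):length(sel)]])) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      key <- list(sum(h$score_bits[sel]), -sum(h$i_evalue[sel]),
                  paste(sort(h$model[sel]), collapse = "|"))
      better <- is.null(best_key) ||
        key[[1]] > best_key[[1]] + 1e-12 ||
        (abs(key[[1]] - best_key[[1]]) <= 1e-12 &&
           (key[[2]] > best_key[[2]] + 1e-15 ||
              (abs(key[[2]] - best_key[[2]]) <= 1e-15 && key[[3]] < best_key[[3]])))
      if (better) { best <- sel; best_key <- key }
    }
    keep[best] <- TRUE
  }
  out <- h[keep, , drop = FALSE]
  out <- out[order(out$env_from, out$env_to, out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Architecture signature of resolved hits
#'
#' The ordered (N- to C-terminal) clan labels of the hits passing the
#' independent E-value cut (default 0.01, the clan-level categorisation
#' threshold). Repeated clans are kept, so tandem fusions remain
#' distinguishable.
#'
#' @param hits Resolved, env-start-sorted hit data frame of one sequence.
#' @param evalue_cut Independent E-value threshold (default 0.01).
#' @return Character vector of clan labels; `character(0)` when no hit
#'   passes (the protein is reported unclassified).
#' @export
signature_of <- function(hits, evalue_cut = 0.01) {
  h <- hits[!is.na(hits$i_evalue) & hits$i_evalue < evalue_cut, , drop = FALSE]
  h <- h[order(h$env_from, h$env_to, h$model), , drop = FALSE]
  as.character(h$clan)
}

signature_string <- function(sig) paste(sig, collapse = "+")

class_labels <- function(n) {
  single <- LETTERS
  if (n <= 26L) return(single[seq_len(n)])
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(single, extra)[seq_len(n)]
}

#' Group annotated proteins into architecture classes
#'
#' One class per distinct non-empty signature, with the number of member
#' sequences, the median and standard deviation of protein length, and
#' median per-domain envelope boundaries. Classes are sorted by decreasing
#' size and labelled `A`, `B`, `C`, ... in that order; proteins with empty
#' signatures form the reported pseudo-class `unclassified`, never merged.
#'
#' @param proteins Data frame with `sequence_id`, `signature` (string form),
#'   and `length` per protein.
#' @param hits Resolved hit data frame covering the classified proteins
#'   (used for boundary medians); optional.
#' @return An `architecture_classes` data frame: `label`, `signature`,
#'   `n_sequences`, `median_length`, `length_sd`, `median_boundaries`
#'   (list column of per-domain `(start, end)` medians), plus the
#'   `unclassified` attribute (ids with empty signatures).
#' @export
group_classes <- function(proteins, hits = NULL) {
  stopifnot(all(c("sequence_id", "signature", "length") %in% names(proteins)))
  cls <- proteins[proteins$signature != "", , drop = FALSE]
  uncls <- proteins$sequence_id[proteins$signature == ""]
  if (nrow(cls) == 0L) {
    out <- data.frame(label = character(), signature = character(),
                      n_sequences = integer(), median_length = numeric(),
                      length_sd = numeric(), stringsAsFactors = FALSE)
    out$median_boundaries <- list()
    attr(out, "unclassified") <- uncls
    class(out) <- c("architecture_classes", "data.frame")
    return(out)
  }
  sp <- split(cls, cls$signature)
  ord <- order(-vapply(sp, nrow, integer(1)), names(sp))
  sp <- sp[ord]
  bounds <- vector("list", length(sp))
  if (!is.null(hits)) {
    for (ci in seq_along(sp)) {
      ids <- sp[[ci]]$sequence_id
      hh <- hits[hits$sequence_id %in% ids, , drop = FALSE]
      hh <- hh[order(hh$sequence_id, hh$env_from), , drop = FALSE]
      ndom <- length(strsplit(names(sp)[ci], "+", fixed = TRUE)[[1]])
      pos <- stats::ave(seq_len(nrow(hh)), hh$sequence_id, FUN = seq_along)
      bd <- lapply(seq_len(ndom), function(d) {
        sel <- pos == d
        c(start = median(hh$env_from[sel]), end = median(hh$env_to[sel]))
      })
      bounds[[ci]] <- bd
    }
  }
  out <- data.frame(
    label = class_labels(length(sp)),
    signature = names(sp),
    n_sequences = vapply(sp, nrow, integer(1)),
    median_length = vapply(sp, function(d) median(d$length), numeric(1)),
    length_sd = vapply(sp, function(d) {
      if (nrow(d) > 1L) sd(d$length) else 0
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$median_boundaries <- bounds
  attr(out, "unclassified") <- uncls
  class(out) <- c("architecture_classes", "data.frame")
  out
}

#' Display filter for architecture classes
#'
#' Returns the classes with at least `min_members` sequences (default 100,
#' the survey's display rule). The full class set should always be retained
#' in machine output; this filter only serves presentation.
#'
#' @param classes An `architecture_classes` data frame.
#' @param min_members Minimum class size (>= 1).
#' @return The filtered classes.
#' @export
filter_display_classes <- function(classes, min_members = 100L) {
  stopifnot(min_members >= 1L)
  classes[classes$n_sequences >= min_members, , drop = FALSE]
}

#' Split composite-domain hits by envelope length
#'
#' Partitions hits of a single composite model at the length threshold
#' (default 127 residues); a hit exactly at the threshold goes to the short
#' stratum, matching the stratified-sampling tie rule.
#'
#' @param hits Hit data frame of one composite model.
#' @param threshold Length threshold in residues (default 127).
#' @return List with `long` and `short` hit data frames (with `hit_id`).
#' @export
composite_length_split <- function(hits, threshold = 127L) {
  len <- hits$env_to - hits$env_from + 1L
  long <- hits[len > threshold, , drop = FALSE]
  short <- hits[len <= threshold, , drop = FALSE]
  long$hit_id <- hit_ids(long); short$hit_id <- hit_ids(short)
  rownames(long) <- rownames(short) <- NULL
  list(long = long, short = short)
}

#' Classify a proteome end to end
#'
#' Annotates every sequence against the model library, resolves same-clan
#' overlaps, forms clan-level signatures at the E-value cut, and groups the
#' proteins into architecture classes.
#'
#' @param db A [seq_set()].
#' @param models List of calibrated `profile_hmm`s.
#' @param th Scan thresholds; defaults to [scan_thresholds()].
#' @param evalue_cut Signature E-value cut (default 0.01).
#' @param clans Optional clan-map override (named `model -> clan`).
#' @return List with `proteins` (sequence_id, signature, length),
#'   `classes` (from [group_classes()]), `hits` (resolved included hits),
#'   and `annotation` (the raw [annotate_proteome()] result).
#' @export
classify_proteome <- function(db, models, th = scan_thresholds(),
                              evalue_cut = 0.01, clans = NULL) {
  ann <- annotate_proteome(models, db, th)
  resolved <- list()
  sigs <- character(nrow(db))
  for (i in seq_len(nrow(db))) {
    h <- ann$hits[ann$hits$sequence_id == db$id[i], , drop = FALSE]
    if (nrow(h)) {
      r <- resolve_overlaps(h, clans)
      resolved[[length(resolved) + 1L]] <- r
      sigs[i] <- signature_string(signature_of(r, evalue_cut))
    }
  }
  hits <- if (length(resolved)) do.call(rbind, resolved) else ann$hits
  proteins <- data.frame(sequence_id = db$id, signature = sigs,
                         length = nchar(db$residues),
                         stringsAsFactors = FALSE)
  list(proteins = proteins,
       classes = group_classes(proteins, hits),
       hits = hits,
       annotation = ann)
}

#' Report long domain-free regions
#'
#' Lists regions of at least `min_len` residues without any included hit, as
#' candidates for manual inspection by alignment (no automatic
#' reclassification is performed).
#'
#' @param annotation A `proteome_annotation`.
#' @param db The annotated [seq_set()].
#' @param min_len Minimum region length (default 80).
#' @return Data frame `sequence_id, from, to, length`.
#' @export
domain_free_regions <- function(annotation, db, min_len = 80L) {
  out <- list()
  for (i in seq_len(nrow(db))) {
    id <- db$id[i]
    L <- nchar(db$residues[i])
    h <- annotation$hits[annotation$hits$sequence_id == id, , drop = FALSE]
    covered <- rep(FALSE, L)
    for (j in seq_len(nrow(h))) covered[h$env_from[j]:h$env_to[j]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- !r$values & r$lengths >= min_len
    if (any(sel)) {
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = id, from = starts[sel], to = ends[sel],
        length = r$lengths[sel], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sequence_id = character(), from = integer(), to = integer(),
               length = integer(), stringsAsFactors = FALSE)
}
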