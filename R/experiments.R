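# Packaged simulation experiments: the composite-domain length analysis and
# the boundary-recovery study that validate the 127-residue WYL/WCX split
# and the iterative maturation protocol on planted ground truth.

#' Train a calibrated profile from noisy copies of an archetype
#'
#' Draws `n` mutated instances of the archetype consensus, aligns them with
#' the progressive aligner, builds a profile and calibrates it — the
#' package's stand-in for adopting an external family profile.
#'
#' @param archetype A `domain_archetype`.
#' @param n Number of training instances (default 30).
#' @param substitution_rate,indel_rate Mutation rates for the training draws.
#' @param seed Integer seed.
#' @return A calibrated `profile_hmm` named and clanned after the archetype.
#' @export
train_profile_from_archetype <- function(archetype, n = 30L,
                                         substitution_rate = 0.15,
                                         indel_rate = 0.01, seed) {
  stopifnot(inherits(archetype, "domain_archetype"))
  if (missing(seed)) stop("training requires a seed", call. = FALSE)
  recs <- with_seed(seed, {
    kernel <- substitution_kernel()
    seq_set(paste0(archetype$name, "_t", seq_len(n)),
            vapply(seq_len(n), function(i) {
              mutate_instance(archetype$consensus, substitution_rate,
                              indel_rate, kernel)
            }, character(1)))
  })
  aln <- progressive_align(recs)
  model <- build_profile(aln, name = archetype$name, clan = archetype$clan)
  calibrate(model, seed = derive_seed(seed, 17L))
}

#' The fused WYL+WCX composite archetype
#'
#' Concatenates the WYL and WCX archetype consensus sequences into the
#' 160-residue composite that emulates the original two-domain family
#' profile subjected to the 127-residue length analysis.
#'
#' @param library Archetype library containing `WYL` and `WCX`.
#' @return A `domain_archetype` named `WYLcomposite` (clan `WYL`).
#' @export
composite_wyl_archetype <- function(library = wyl_archetype_library()) {
  structure(list(name = "WYLcomposite", clan = "WYL",
                 consensus = paste0(library$WYL$consensus,
                                    library$WCX$consensus),
                 length = library$WYL$length + library$WCX$length),
            class = "domain_archetype")
}

#' Generator settings for the composite-domain simulation
#'
#' One bacterial phylum whose planted proteins carry a single composite
#' region: either a lone WYL (90 residues at zero noise) or a fused WYL+WCX
#' (160 residues), the bimodal length distribution around the 127-residue
#' split.
#'
#' @param seed Integer seed.
#' @param substitution_rate,indel_rate Noise levels (defaults 0.10 / 0.01).
#' @param n_species,rate Species count and planting rate.
#' @return A [generator_config()] in composite mode.
#' @export
composite_generator_config <- function(seed, substitution_rate = 0.10,
                                       indel_rate = 0.01, n_species = 12L,
                                       rate = 4.0) {
  generator_config(
    seed = seed,
    phyla = data.frame(phylum = "Actinobacteria", superkingdom = "Bacteria",
                       n_species = as.integer(n_species), rate = rate,
                       stringsAsFactors = FALSE),
    architecture_menu = list(list(archs = "WYLcomposite", freq = 1)),
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    composite_mode = TRUE)
}

# align sampled hit envelopes; returns the alignment plus, per hit id, the
# alignment column of the hit's core C-terminus (ali_to)
align_hit_envelopes <- function(hits, db) {
  env <- character(nrow(hits))
  core_end_off <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    res <- db$residues[match(hits$sequence_id[i], db$id)]
    env[i] <- substr(res, hits$env_from[i], hits$env_to[i])
    core_end_off[i] <- hits$ali_to[i] - hits$env_from[i] + 1L
  }
  ids <- make.unique(hit_ids(hits), sep = "_")
  aln <- progressive_align(seq_set(ids, env))
  core_end_col <- vapply(seq_along(ids), function(i) {
    row <- strsplit(aln$seqs[match(ids[i], aln$ids)], "")[[1]]
    which(row != "-")[core_end_off[i]]
  }, integer(1))
  names(core_end_col) <- ids
  list(alignment = aln, core_end_col = core_end_col, ids = ids)
}

#' One replicate of the WYL/WCX boundary-recovery study
#'
#' Runs the full protocol on a fresh composite simulation: search with the
#' composite profile, keep hits above the domain-score/E-value prefilter,
#' stratify at 127 residues, align the sampled envelopes, define the domain
#' boundaries from the short-stratum core C-termini, then run the iterative
#' maturation. Boundary recovery is measured in consensus columns against
#' the planted WYL length of 90.
#'
#' @param seed Integer replicate seed.
#' @param library Archetype library (default [wyl_archetype_library()]).
#' @param composite_model A calibrated composite profile; trained on the
#'   fly when `NULL`.
#' @param iterations Maturation iterations (default 3, the WYL protocol).
#' @return List with `defined_length` (boundary-stage WYL length estimate),
#'   `matured_length` (final model length), `define_error`, `matured_error`
#'   (absolute errors in columns vs the planted 90), and `n_short`.
#' @export
boundary_recovery_replicate <- function(seed,
                                        library = wyl_archetype_library(),
                                        composite_model = NULL,
                                        iterations = 3L) {
  if (is.null(composite_model)) {
    composite_model <- train_profile_from_archetype(
      composite_wyl_archetype(library), n = 25L, substitution_rate = 0.10,
      seed = derive_seed(seed, 50L))
  }
  true_wyl <- library$WYL$length
  coll <- emit_collection(composite_generator_config(seed = seed), library)
  res <- hmm_search(composite_model, coll$proteins,
                    search_thresholds(min_domain_score = 30))
  hits <- res$hits[res$hits$included & res$hits$i_evalue < 0.001, ,
                   drop = FALSE]
  cfg <- maturation_config(seed = seed, iterations = as.integer(iterations))
  st <- stratified_sample(hits, cfg)
  samp <- rbind(st$long, st$short)
  al <- align_hit_envelopes(samp, coll$proteins)
  short_ids <- al$ids[samp$hit_id %in% st$short$hit_id]
  b <- define_boundaries(al$alignment, al$core_end_col[short_ids])
  occ <- conserved_block(al$alignment)
  defined_length <- sum(occ >= b[1] & occ <= b[2])
  mat <- mature_hmm(coll$proteins,
                    seed_alignment(al$alignment, b[1], b[2]), cfg)
  list(defined_length = defined_length,
       matured_length = mat$model$M,
       define_error = abs(defined_length - true_wyl),
       matured_error = abs(mat$model$M - true_wyl),
       n_short = length(short_ids),
       model = mat$model)
}

#' Composite length split against planted truth
#'
#' At zero noise, searches the composite profile against a composite
#' simulation and splits the recovered hits at the length threshold,
#' counting misassignments against the planted short/long truth.
#'
#' @param seed Integer seed.
#' @param library Archetype library.
#' @param composite_model Calibrated composite profile (trained when `NULL`).
#' @param threshold Length threshold (default 127).
#' @param substitution_rate,indel_rate Noise (defaults 0: the zero-noise
#'   bimodal design).
#' @return List with `n_long`, `n_short`, `n_misassigned`, `n_planted`.
#' @export
composite_split_experiment <- function(seed,
                                       library = wyl_archetype_library(),
                                       composite_model = NULL,
                                       threshold = 127L,
                                       substitution_rate = 0,
                                       indel_rate = 0) {
  if (is.null(composite_model)) {
    composite_model <- train_profile_from_archetype(
      composite_wyl_archetype(library), n = 25L, substitution_rate = 0.10,
      seed = derive_seed(seed, 50L))
  }
  coll <- emit_collection(
    composite_generator_config(seed = seed,
                               substitution_rate = substitution_rate,
                               indel_rate = indel_rate), library)
  res <- hmm_search(composite_model, coll$proteins,
                    search_thresholds(min_domain_score = 30))
  hits <- res$hits[res$hits$included, , drop = FALSE]
  sp <- composite_length_split(hits, threshold)
  truth_long <- coll$truth$sequence_id[
    coll$truth$architecture == "WYLcomposite_long"]
  truth_short <- coll$truth$sequence_id[
    coll$truth$architecture == "WYLcomposite_short"]
  mis <- sum(sp$long$sequence_id %in% truth_short) +
    sum(sp$short$sequence_id %in% truth_long)
  list(n_long = nrow(sp$long), n_short = nrow(sp$short),
       n_misassigned = mis, n_planted = nrow(coll$truth))
}
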