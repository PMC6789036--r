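# Synthetic reference-proteome generator: domain archetype libraries,
# collections of species-labelled proteomes with planted domain
# architectures under substitution/indel noise, full ground truth, and
# recovery scoring against that truth.

#' Create a library of dissimilar domain archetypes
#'
#' Consensus sequences are drawn from the background amino-acid frequencies;
#' any archetype with pairwise identity >= 0.3 to an earlier one is redrawn
#' (bounded retries). Deterministic under the seed.
#'
#' @param seed Integer seed.
#' @param n_domains Number of archetypes (>= 1).
#' @param length_range Length range `c(min, max)` in residues (>= 20).
#' @param names,clans Optional archetype names / clan labels.
#' @param max_retries Redraw budget per archetype (default 50).
#' @return List of `domain_archetype` objects (`name, clan, consensus,
#'   length`).
#' @export
make_domain_library <- function(seed, n_domains = 4L,
                                length_range = c(60L, 100L),
                                names = NULL, clans = NULL,
                                max_retries = 50L) {
  stopifnot(n_domains >= 1L, length_range[1] >= 20L)
  if (is.null(names)) names <- paste0("dom", seq_len(n_domains))
  if (is.null(clans)) clans <- names
  stopifnot(length(names) == n_domains, !anyDuplicated(names))
  with_seed(seed, {
    lib <- list()
    for (i in seq_len(n_domains)) {
      len <- if (length(unique(length_range)) == 1L) length_range[1] else
        sample(seq.int(length_range[1], length_range[2]), 1L)
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cons <- paste(sample(AA_ALPHABET, len, replace = TRUE,
                             prob = AA_BACKGROUND), collapse = "")
        if (i == 1L ||
            all(vapply(lib, function(a) {
              pairwise_identity(a$consensus, cons) < 0.3
            }, logical(1)))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not draw archetype ", names[i],
             " dissimilar from the library", call. = FALSE)
      }
      lib[[i]] <- structure(list(name = names[i], clan = clans[i],
                                 consensus = cons, length = len),
                            class = "domain_archetype")
    }
    names(lib) <- names
    lib
  })
}

#' Default WYL-survey archetype library
#'
#' Four archetypes emulating the survey's domain families: a winged HTH
#' (60 aa), the WYL domain (90 aa), its C-terminal extension WCX (70 aa) and
#' a C-terminal helicase domain (110 aa). The WYL/WCX lengths are chosen so
#' that a fused WYL+WCX composite instance is 160 residues and a lone WYL 90
#' — the bimodal composite length distribution around the 127-residue split.
#'
#' @param seed Integer seed (default 7041).
#' @return List of four `domain_archetype`s named HTH, WYL, WCX,
#'   Helicase_C3.
#' @export
wyl_archetype_library <- function(seed = 7041L) {
  nm <- c("HTH", "WYL", "WCX", "Helicase_C3")
  lens <- c(HTH = 60L, WYL = 90L, WCX = 70L, Helicase_C3 = 110L)
  lib <- list()
  for (i in seq_along(nm)) {
    one <- make_domain_library(derive_seed(seed, i), 1L,
                               length_range = rep(lens[[i]], 2L),
                               names = nm[i])[[1]]
    # enforce dissimilarity to the already drawn archetypes
    tries <- 0L
    while (length(lib) > 0L &&
           any(vapply(lib, function(a) {
             pairwise_identity(a$consensus, one$consensus) >= 0.3
           }, logical(1)))) {
      tries <- tries + 1L
      if (tries > 50L) stop("archetype library dissimilarity failed", call. = FALSE)
      one <- make_domain_library(derive_seed(seed, i + 100L * tries), 1L,
                                 length_range = rep(lens[[i]], 2L),
                                 names = nm[i])[[1]]
    }
    lib[[nm[i]]] <- one
  }
  lib
}

# BLOSUM62-conditioned substitution kernel: P(b | a) ~ bg_b * 2^(B62[a,b]/2),
# b != a; keeps profile recovery at realistic noise non-trivial but feasible.
substitution_kernel <- function() {
  K <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (a in seq_len(20)) {
    w <- AA_BACKGROUND * 2^(BLOSUM62_MATRIX[a, ] / 2)
    w[a] <- 0
    K[a, ] <- w / sum(w)
  }
  K
}

#' Generator configuration for synthetic proteome collections
#'
#' The defaults are the package's study conditions: five taxa (four bacterial
#' phyla with planting rates echoing the observed per-organism averages, plus
#' a small archaeal group exercising non-bacterial exclusion), an
#' architecture menu of the four planted classes (60% HTH+WYL+WCX, 15%
#' HTH+WYL, 10% tandem fusion, 15% helicase-associated WYL), 15% substitution
#' noise and 1% indels.
#'
#' @param seed Integer seed (mandatory).
#' @param phyla Data frame `phylum, superkingdom, n_species, rate`
#'   (`rate` = expected planted proteins per species, Poisson).
#' @param architecture_menu List of `list(archs = <ordered archetype names>,
#'   freq = <probability>)`; frequencies must sum to 1.
#' @param substitution_rate,indel_rate Per-residue rates in `[0, 0.5)`.
#' @param linker_length `c(min, max)` flanking/inter-domain linker lengths.
#' @param background_proteins_per_species Count of random background
#'   proteins per species (length 150-600).
#' @param composite_mode Plant single fused WYL+WCX (long) or lone WYL
#'   (short) composite regions annotated as one truth span with the split
#'   position recorded — the substrate for the 127-residue length analysis.
#' @param composite_short_freq Fraction of short composites in composite
#'   mode (default 0.5).
#' @param defective_rate Fraction of planted instances truncated to their
#'   N-terminal half (exercises seed curation; default 0).
#' @return A `generator_config` object.
#' @export
generator_config <- function(seed,
                             phyla = default_phyla(),
                             architecture_menu = default_architecture_menu(),
                             substitution_rate = 0.15,
                             indel_rate = 0.01,
                             linker_length = c(15L, 40L),
                             background_proteins_per_species = 1L,
                             composite_mode = FALSE,
                             composite_short_freq = 0.5,
                             defective_rate = 0) {
  if (missing(seed)) stop("generator_config requires a seed", call. = FALSE)
  stopifnot(is.data.frame(phyla),
            all(c("phylum", "superkingdom", "n_species", "rate") %in% names(phyla)),
            substitution_rate >= 0, substitution_rate < 0.5,
            indel_rate >= 0, indel_rate < 0.5,
            length(linker_length) == 2L, linker_length[1] >= 0,
            background_proteins_per_species >= 0)
  freqs <- vapply(architecture_menu, function(m) m$freq, numeric(1))
  if (length(architecture_menu) == 0L || abs(sum(freqs) - 1) > 1e-9) {
    stop("architecture menu frequencies must sum to 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), phyla = phyla,
                 architecture_menu = architecture_menu,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 linker_length = as.integer(linker_length),
                 background_proteins_per_species =
                   as.integer(background_proteins_per_species),
                 composite_mode = isTRUE(composite_mode),
                 composite_short_freq = composite_short_freq,
                 defective_rate = defective_rate),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_phyla <- function() {
  data.frame(
    phylum = c("Actinobacteria", "Firmicutes", "Proteobacteria",
               "Bacteroidetes", "Euryarchaeota"),
    superkingdom = c("Bacteria", "Bacteria", "Bacteria", "Bacteria",
                     "Archaea"),
    n_species = c(40L, 35L, 55L, 20L, 3L),
    rate = c(5.0, 2.8, 2.0, 2.1, 1.0),
    stringsAsFactors = FALSE
  )
}

#' @rdname generator_config
#' @export
default_architecture_menu <- function() {
  list(
    list(archs = c("HTH", "WYL", "WCX"), freq = 0.60),
    list(archs = c("HTH", "WYL"), freq = 0.15),
    list(archs = c("HTH", "WYL", "WCX", "HTH", "WYL", "WCX"), freq = 0.10),
    list(archs = c("Helicase_C3", "WYL"), freq = 0.15)
  )
}

#' Read / write a generator configuration as YAML
#' @param cfg A [generator_config()].
#' @param path YAML file path.
#' @return `write_generator_config` returns `path` invisibly;
#'   `read_generator_config` the configuration.
#' @export
write_generator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "generator_config"))
  x <- unclass(cfg)
  x$phyla <- lapply(seq_len(nrow(cfg$phyla)), function(i) as.list(cfg$phyla[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$phyla <- do.call(rbind, lapply(x$phyla, as.data.frame))
  do.call(generator_config, x)
}

# mutate one domain instance; returns list(residues, deleted_prefix = 0)
mutate_instance <- function(consensus, sub_rate, indel_rate, kernel) {
  codes <- encode_residues(consensus)
  n <- length(codes)
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    for (i in hit) {
      codes[i] <- sample.int(20L, 1L, prob = kernel[codes[i], ])
    }
  }
  if (indel_rate > 0) {
    max_del <- floor(0.1 * n)          # never truncate > 10% of an instance
    deleted <- 0L
    out <- integer(0)
    for (i in seq_len(n)) {
      u <- runif(1)
      if (u < indel_rate / 2 && deleted < max_del) {
        deleted <- deleted + 1L        # delete this residue
        next
      }
      out <- c(out, codes[i])
      if (u >= indel_rate / 2 && u < indel_rate) {
        ins_len <- rgeom(1L, 0.5) + 1L
        out <- c(out, sample.int(20L, ins_len, replace = TRUE,
                                 prob = AA_BACKGROUND))
      }
    }
    codes <- out
  }
  decode_residues(codes)
}

random_residues <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = AA_BACKGROUND),
        collapse = "")
}

#' Generate a synthetic reference-proteome collection
#'
#' Per species: `background_proteins_per_species` random proteins plus a
#' Poisson(`rate`) number of planted proteins, each assembled as linker +
#' mutated domain instances + linker according to the architecture menu (or
#' the composite design in `composite_mode`). True domain spans are recorded
#' after indel application. Byte-identical output under a fixed seed.
#'
#' @param cfg A [generator_config()].
#' @param library Archetype library from [make_domain_library()] /
#'   [wyl_archetype_library()].
#' @return A `synthetic_collection`: list with `proteins` ([seq_set()]),
#'   `taxonomy` (`taxonomy_table`), `truth` (per planted protein:
#'   sequence_id, species_id, phylum, architecture, composite_split), and
#'   `truth_domains` (per planted instance: sequence_id, domain_index,
#'   archetype, clan, start, end).
#' @export
emit_collection <- function(cfg, library = wyl_archetype_library()) {
  stopifnot(inherits(cfg, "generator_config"))
  menu_archs <- unique(unlist(lapply(cfg$architecture_menu, `[[`, "archs")))
  if (!cfg$composite_mode) {
    miss <- setdiff(menu_archs, names(library))
    if (length(miss)) stop("menu archetypes missing from library: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  kernel <- substitution_kernel()
  freqs <- vapply(cfg$architecture_menu, `[[`, numeric(1), "freq")
  with_seed(cfg$seed, {
    ids <- character(0); seqs <- character(0); tax_rows <- list()
    truth <- list(); truth_dom <- list()
    sp_idx <- 0L
    for (p in seq_len(nrow(cfg$phyla))) {
      ph <- cfg$phyla[p, ]
      for (s in seq_len(ph$n_species)) {
        sp_idx <- sp_idx + 1L
        species <- sprintf("sp%04d", sp_idx)
        serial <- 0L
        add_protein <- function(res) {
          serial <<- serial + 1L
          id <- sprintf("%s_p%02d", species, serial)
          ids <<- c(ids, id); seqs <<- c(seqs, res)
          tax_rows[[length(tax_rows) + 1L]] <<- data.frame(
            sequence_id = id, species_id = species,
            superkingdom = ph$superkingdom, phylum = ph$phylum,
            class = paste0(ph$phylum, "_cl"), order = paste0(ph$phylum, "_or"),
            family = paste0(ph$phylum, "_fa"), genus = species,
            stringsAsFactors = FALSE)
          id
        }
        for (b in seq_len(cfg$background_proteins_per_species)) {
          add_protein(random_residues(sample(150:600, 1L)))
        }
        n_plant <- rpois(1L, ph$rate)
        for (q in seq_len(n_plant)) {
          if (cfg$composite_mode) {
            plant <- plant_composite(cfg, library, kernel)
          } else {
            mi <- sample.int(length(cfg$architecture_menu), 1L, prob = freqs)
            plant <- plant_architecture(cfg, library, kernel,
                                        cfg$architecture_menu[[mi]]$archs)
          }
          id <- add_protein(plant$residues)
          truth[[length(truth) + 1L]] <- data.frame(
            sequence_id = id, species_id = species, phylum = ph$phylum,
            architecture = plant$architecture,
            composite_split = plant$composite_split,
            stringsAsFactors = FALSE)
          if (nrow(plant$domains)) {
            d <- plant$domains
            d$sequence_id <- id
            truth_dom[[length(truth_dom) + 1L]] <- d
          }
        }
      }
    }
    structure(list(
      proteins = seq_set(ids, seqs,
                         taxon_id = vapply(tax_rows, `[[`, character(1),
                                           "species_id")),
      taxonomy = taxonomy_table(do.call(rbind, tax_rows)),
      truth = if (length(truth)) do.call(rbind, truth) else NULL,
      truth_domains = if (length(truth_dom)) do.call(rbind, truth_dom) else NULL
    ), class = "synthetic_collection")
  })
}

# assemble one planted protein from an ordered architecture
plant_architecture <- function(cfg, library, kernel, archs) {
  lk <- function() sample(seq.int(cfg$linker_length[1], cfg$linker_length[2]), 1L)
  res <- random_residues(lk())
  dom <- list()
  for (d in seq_along(archs)) {
    a <- library[[archs[d]]]
    inst <- mutate_instance(a$consensus, cfg$substitution_rate,
                            cfg$indel_rate, kernel)
    if (cfg$defective_rate > 0 && runif(1) < cfg$defective_rate) {
      inst <- substr(inst, 1L, nchar(inst) %/% 2L)   # truncated instance
      defective <- TRUE
    } else {
      defective <- FALSE
    }
    start <- nchar(res) + 1L
    res <- paste0(res, inst)
    dom[[d]] <- data.frame(sequence_id = "", domain_index = d,
                           archetype = a$name, clan = a$clan,
                           start = start, end = nchar(res),
                           defective = defective, stringsAsFactors = FALSE)
    if (d < length(archs)) res <- paste0(res, random_residues(lk()))
  }
  res <- paste0(res, random_residues(lk()))
  list(residues = res, architecture = paste(archs, collapse = "+"),
       composite_split = NA_integer_, domains = do.call(rbind, dom))
}

# composite mode: one WYL (short) or fused WYL+WCX (long) region per protein,
# recorded as a single composite truth span with the WYL/WCX split position
plant_composite <- function(cfg, library, kernel) {
  lk <- function() sample(seq.int(cfg$linker_length[1], cfg$linker_length[2]), 1L)
  short <- runif(1) < cfg$composite_short_freq
  wyl <- mutate_instance(library$WYL$consensus, cfg$substitution_rate,
                         cfg$indel_rate, kernel)
  if (short) {
    inst <- wyl
    split <- NA_integer_
    arch <- "WYLcomposite_short"
  } else {
    wcx <- mutate_instance(library$WCX$consensus, cfg$substitution_rate,
                           cfg$indel_rate, kernel)
    inst <- paste0(wyl, wcx)
    split <- nchar(wyl)                # WYL part length after noise
    arch <- "WYLcomposite_long"
  }
  pre <- random_residues(lk())
  res <- paste0(pre, inst, random_residues(lk()))
  dom <- data.frame(sequence_id = "", domain_index = 1L,
                    archetype = "WYLcomposite", clan = "WYL",
                    start = nchar(pre) + 1L, end = nchar(pre) + nchar(inst),
                    defective = FALSE, stringsAsFactors = FALSE)
  list(residues = res, architecture = arch,
       composite_split = split, domains = dom)
}

#' Write a synthetic collection to disk
#'
#' Emits `<prefix>.fasta`, `<prefix>_taxonomy.tsv`, `<prefix>_truth.tsv` and
#' `<prefix>_truth_domains.tsv`.
#'
#' @param coll A `synthetic_collection`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_collection <- function(coll, prefix) {
  stopifnot(inherits(coll, "synthetic_collection"))
  paths <- c(fasta = paste0(prefix, ".fasta"),
             taxonomy = paste0(prefix, "_taxonomy.tsv"),
             truth = paste0(prefix, "_truth.tsv"),
             truth_domains = paste0(prefix, "_truth_domains.tsv"))
  write_fasta(coll$proteins, paths["fasta"])
  write_taxonomy(coll$taxonomy, paths["taxonomy"])
  write.table(coll$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(coll$truth_domains, paths["truth_domains"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Score pipeline outputs against planted ground truth
#'
#' Compares predicted architecture signatures with the planted truth
#' (archetype names mapped to clans) and, where the signature matches,
#' collects per-domain envelope boundary errors.
#'
#' @param coll A `synthetic_collection`.
#' @param proteins Classification output: data frame `sequence_id,
#'   signature` (clan signature strings).
#' @param hits Resolved hit data frame (for boundary errors); optional.
#' @param library The archetype library used for generation (for the
#'   archetype-to-clan map).
#' @return List with `by_architecture` (planted architecture, n, recall),
#'   `overall_recall`, `boundary_errors` (per matched domain,
#'   `|predicted - true|` for start and end), and `n_truth`.
#' @export
score_recovery <- function(coll, proteins, hits = NULL,
                           library = wyl_archetype_library()) {
  stopifnot(inherits(coll, "synthetic_collection"))
  truth <- coll$truth
  miss <- setdiff(truth$sequence_id, proteins$sequence_id)
  if (length(miss)) {
    stop("predictions missing for planted sequences: ",
         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  arch_to_clans <- function(a) {
    paste(vapply(strsplit(a, "+", fixed = TRUE)[[1]],
                 function(nm) library[[nm]]$clan, character(1)),
          collapse = "+")
  }
  expected <- vapply(truth$architecture, arch_to_clans, character(1),
                     USE.NAMES = FALSE)
  got <- proteins$signature[match(truth$sequence_id, proteins$sequence_id)]
  ok <- got == expected
  by_arch <- aggregate(ok, list(architecture = truth$architecture),
                       function(x) mean(x))
  names(by_arch)[2] <- "recall"
  by_arch$n <- as.integer(table(truth$architecture)[by_arch$architecture])
  errs <- numeric(0)
  if (!is.null(hits) && !is.null(coll$truth_domains)) {
    for (sid in truth$sequence_id[ok]) {
      td <- coll$truth_domains[coll$truth_domains$sequence_id == sid, ,
                               drop = FALSE]
      hh <- hits[hits$sequence_id == sid, , drop = FALSE]
      hh <- hh[order(hh$env_from), , drop = FALSE]
      if (nrow(hh) != nrow(td)) next
      errs <- c(errs, abs(hh$env_from - td$start), abs(hh$env_to - td$end))
    }
  }
  list(by_architecture = by_arch,
       overall_recall = mean(ok),
       boundary_errors = errs,
       n_truth = nrow(truth))
}
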