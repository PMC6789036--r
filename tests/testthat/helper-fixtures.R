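# Shared fixtures, built once per test run and cached. Everything is
# generated in code under fixed seeds chosen when the suite was written.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# mutated copies of an archetype consensus (training/family material)
mutated_copies <- function(archetype, n, rate, seed, indel_rate = 0.01,
                           prefix = archetype$name) {
  wyldomkit:::with_seed(seed, {
    kernel <- wyldomkit:::substitution_kernel()
    seq_set(paste0(prefix, "_i", seq_len(n)),
            vapply(seq_len(n), function(i) {
              wyldomkit:::mutate_instance(archetype$consensus, rate,
                                          indel_rate, kernel)
            }, character(1)))
  })
}

# build + calibrate a model from noisy instances of one archetype
train_archetype_model <- function(archetype, n = 30, rate = 0.15,
                                  seed = 500) {
  recs <- mutated_copies(archetype, n, rate, seed)
  aln <- progressive_align(recs)
  model <- build_profile(aln, name = archetype$name, clan = archetype$clan)
  calibrate(model, seed = seed + 1L)
}

wyl_library <- function() fixture("wyl_library", wyl_archetype_library)

wyl_models <- function() {
  fixture("wyl_models", function() {
    lib <- wyl_library()
    lapply(seq_along(lib), function(i) {
      train_archetype_model(lib[[i]], seed = 500L + i)
    })
  })
}

# the packaged study collection (the default generator conditions, seed 42)
study_collection <- function() {
  fixture("study_collection", function() {
    emit_collection(generator_config(seed = 42L), wyl_library())
  })
}

study_classification <- function() {
  fixture("study_classification", function() {
    coll <- study_collection()
    classify_proteome(coll$proteins, wyl_models())
  })
}

# composite-mode material for the 127-residue length analysis: a fused
# WYL+WCX archetype model trained on noisy fused instances
composite_archetype <- function() {
  fixture("composite_archetype", function() {
    lib <- wyl_library()
    structure(list(name = "WYLcomposite", clan = "WYL",
                   consensus = paste0(lib$WYL$consensus, lib$WCX$consensus),
                   length = lib$WYL$length + lib$WCX$length),
              class = "domain_archetype")
  })
}

composite_model <- function() {
  fixture("composite_model", function() {
    train_archetype_model(composite_archetype(), n = 25, rate = 0.10,
                          seed = 901L)
  })
}

composite_config <- function(seed, substitution_rate = 0.10,
                             indel_rate = 0.01) {
  generator_config(
    seed = seed,
    phyla = data.frame(phylum = "Actinobacteria", superkingdom = "Bacteria",
                       n_species = 12L, rate = 4.0, stringsAsFactors = FALSE),
    architecture_menu = list(list(archs = "WYLcomposite", freq = 1)),
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    composite_mode = TRUE)
}

# tiny three-model library over distinct clans for fast engine-level tests
tiny_model_library <- function() {
  fixture("tiny_model_library", function() {
    lib <- make_domain_library(321L, 3L, c(40L, 50L),
                               names = c("alpha", "beta", "gamma"))
    lapply(lib, function(a) train_archetype_model(a, n = 15, seed = 777L))
  })
}
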