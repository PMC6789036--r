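# wyldomkit

Profile-HMM survey tools for WYL domain-containing bacterial transcription
factors.

WYL domains are widespread but poorly characterised bacterial domains (named
after a conserved W-Y-L motif) found in transcription factors such as the
mycobacterial DNA damage response regulator PafBC. Structurally, the region
historically annotated as a single "WYL" family is in fact two domains: the
WYL domain proper (an Sm-fold) and a C-terminal extension, WCX
(ferredoxin-like fold), usually preceded by a winged helix-turn-helix (HTH)
DNA-binding domain. Surveying these proteins therefore requires building and
maturing dedicated profile hidden Markov models, annotating proteomes with
them, classifying proteins into clan-level domain-architecture classes
(class A = HTH–WYL–WCX, class B = HTH–WYL, tandem PafBC fusions,
helicase-associated WYL, ...), and summarising their taxonomic distribution.

`wyldomkit` implements that entire computational pipeline as a tested,
self-contained R package, for bioinformaticians who want to reproduce,
stress-test or extend this kind of domain survey without external databases
or binaries:

* **`msa_core`** — FASTA/MSA handling, global pairwise alignment (BLOSUM62,
  affine gaps −11/−1), shorter-sequence percent identity, greedy
  representative clustering (CD-HIT-like semantics), a deterministic
  progressive aligner (UPGMA guide tree, profile–profile merges), alignment
  trimming, and per-column conservation (entropy with independent counts,
  plus a BLOSUM62 sum-of-pairs variant).
* **`phmm_engine`** — a Plan7-style local multi-hit profile-HMM engine:
  model construction from alignments, Viterbi and Forward scoring in bits
  (log₂ odds against an i.i.d. background null with geometric length
  correction), domain envelope extraction, Gumbel E-value calibration on
  random sequences, and threshold-driven `hmm_search()` / `hmm_scan()`
  (defaults `-E 1 -domE 1 -incE 0.01 -incdomE 0.03` for search and
  `-E 0.1 -domE 0.1` for scan). Viterbi/Forward cores are compiled (Rcpp)
  and validated against an exhaustive path-enumeration oracle.
* **`hmm_maturation`** — the iterative seed protocol used to define the
  custom profiles: 127-residue length stratification (250 sequences per
  stratum), automated seed curation, boundary definition from short-hit
  C-termini, and the cluster–build–search–trim loop (WYL: 70% identity,
  gathering 27.0 bits, three iterations; HTH wing types: 90%, one
  iteration; WCX: no iteration), plus the PafB-like/PafC-like wing split.
* **`architecture_classifier`** — proteome annotation against a model
  library, exact same-clan overlap resolution, ordered clan signatures
  (independent E-value < 0.01), class grouping with median length/SD and
  boundary statistics, and the <100-sequence display filter.
* **`taxonomy_stats`** — non-bacterial exclusion, per-taxon species and
  sequence counts, the two per-species denominators (species-with-hits vs
  all species in the collection), and the 1.5% small-group display filter.
* **`synthetic_data`** — a fully deterministic reference-proteome generator
  with labelled phyla, planted domain architectures, BLOSUM62-biased
  substitution/indel noise and complete ground truth, so every stage of the
  pipeline is verifiable at desk scale.

## Worked example

Simulate a reference-proteome collection, train one profile per domain
family from noisy instances, classify every protein and summarise the
taxonomy:

```r
library(wyldomkit)

lib    <- wyl_archetype_library()                 # HTH, WYL, WCX, Helicase_C3
models <- lapply(seq_along(lib), function(i)
  train_profile_from_archetype(lib[[i]], n = 30, seed = 500 + i))

coll <- emit_collection(generator_config(seed = 42), lib)
coll$proteins
#> seq_set with 604 sequences
#>   sp0001_p01             198 aa  MSFTIPATDKDMSKMCAKIYAWMLIEYEFPNEDLFLGYRV...
#>   ...

res <- classify_proteome(coll$proteins, models)
head(res$classes[, c("label", "signature", "n_sequences",
                     "median_length", "length_sd")], 4)
#>   label               signature n_sequences median_length length_sd
#> 1     A             HTH+WYL+WCX         252         329.5  15.44069
#> 2     B                 HTH+WYL          74         238.0  13.90112
#> 3     C         Helicase_C3+WYL          62         285.0  11.75658
#> 4     D HTH+WYL+WCX+HTH+WYL+WCX         46         641.0  19.82961
```

Class labels are assigned by decreasing size; the signature is the ordered
(N→C) clan composition of each protein, so class A is the canonical
HTH–WYL–WCX architecture and class D the tandem PafBC-like fusion. Against
the generator's ground truth:

```r
rec <- score_recovery(coll, res$proteins, res$hits, lib)
round(rec$overall_recall, 3)
#> [1] 0.962
```

96% of planted proteins get exactly the planted clan signature at 15%
substitution noise. Taxonomic distribution of the classified bacterial
sequences:

```r
part <- exclude_nonbacterial(coll$truth$sequence_id, coll$taxonomy)
arch <- subset(res$proteins, sequence_id %in% part$bacterial & signature != "")
head(summarize_taxa(arch, coll$taxonomy, "phylum"), 4)
#>            taxon   rank n_species n_sequences avg_per_species fraction_of_species
#> 4 Proteobacteria phylum        49         110        2.244898           0.3525180
#> 1 Actinobacteria phylum        39         204        5.230769           0.2805755
#> 3     Firmicutes phylum        33          96        2.909091           0.2374101
#> 2  Bacteroidetes phylum        18          37        2.055556           0.1294964
```

`avg_per_species` is the sequences-per-species ring metric (species with at
least one hit); `per_organism_average()` provides the companion statistic
whose denominator includes zero-hit species.

A thin command line wraps the same functions
(`system.file("scripts", "wyldomkit.R", package = "wyldomkit")`), with
subcommands `simulate`, `build-seed`, `mature`, `scan`, `classify` and
`taxstats`; repeated runs with the same seed are byte-identical.

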