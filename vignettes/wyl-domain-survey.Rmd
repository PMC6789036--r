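---
title: "Methods: profile-HMM survey of WYL domain architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-HMM survey of WYL domain architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`wyldomkit` implements the computational survey of WYL domain-containing
bacterial transcription factors as a reusable pipeline: profile-HMM
construction and scoring, the iterative protocol that defines the WYL, WCX
and winged-HTH profiles, clan-level architecture classification, and
taxonomic summaries. Because the survey's real substrate (a reference
proteome collection and a family database) is neither small nor stable,
the package ships a deterministic synthetic-proteome generator with planted
ground truth; every stage of the pipeline is validated against that truth
at desk scale. This vignette records the models, conventions and parameter
choices, including the places where a design decision had to be made.

# The scoring model

## Topology

Profiles are Plan7-style: match states `M_1..M_M` with 20-way emission
distributions, insert states emitting the background (so insert residues
score zero bits), delete states, and the flanking special states
`N, B, E, J, C` providing local alignment and multiple hits per sequence.
Conventions fixed by this package:

* **Local entry** is uniform over match states, `P(B -> M_k) = 1/M`.
* **Local exit** folds a hazard `e_k = 1 / (M - k + 1)` into each match
  state's outgoing distribution (`M_k -> E` with probability `e_k`, core
  transitions scaled by `1 - e_k`), making the exit node uniform while
  keeping every outgoing distribution normalised. `e_M = 1`, so the final
  node always exits. Exit through mid-model delete states is not allowed.
* **Multi-hit mode** sets `P(E -> J) = P(E -> C) = 1/2`; the `N`, `C` and
  `J` loops are conditioned on the target length `L` with loop probability
  `L / (L + 3)` (`L / (L + 2)` in single-hit mode).
* **Null model**: i.i.d. background residues with a geometric length
  distribution, contributing `L log2(L/(L+1)) + log2(1/(L+1))` to the
  denominator of the reported bit score.

This is a semantic reimplementation of the conventions of the standard
search tools, not a bit-exact one; its scores live on a slightly different
scale, which is why the package calibrates its own E-values (below) and why
bit thresholds carried over from the original protocol (27.0, 30.0) are
configurable conventions rather than cross-tool equivalences.

Background frequencies are the Swiss-Prot-derived values commonly used as
the search null; `X` residues emit the background (zero bits) and count as
mismatches in percent identity.

## Construction from an alignment

Columns with gap fraction below 0.5 become match columns (configurable).
Match emissions are background-mixed counts with a single pseudocount mass
(`pseudocount_weight`, default 1.0) rather than Dirichlet mixtures: the
simpler estimator is deterministic and its scale differences are absorbed
by the package's own calibration. Transitions are counted from each row's
match/insert/delete path with Laplace smoothing (one count per transition);
the two transitions Plan7 lacks (`I->D`, `D->I`) are skipped when counting.
Rows are weighted uniformly; with the deduplication step of the maturation
protocol (cluster representatives at 70% or 90% identity) uniform weights
are close to position-based weighting at a fraction of the complexity.

## Dynamic programming and its oracle

Viterbi (with traceback) and Forward run in compiled code over precomputed
log2-odds scores. Ties in every DP — pairwise, profile–profile and
Viterbi — are broken in a fixed order (diagonal, then the gap branch
consuming the first argument, then the other; for Viterbi: entry before
match before insert before delete), so all outputs are deterministic
functions of their inputs. The test suite checks both recursions against an
independent top-down enumeration over all legal state paths (tolerance
1e-9 bits) for every model size up to M = 5 and sequence length up to 8
over a reduced alphabet; the literal path enumeration validates a memoized
variant on the smaller sizes, which then covers the full sweep within the
suite's time budget.

## Domains, envelopes and E-values

Domains are the `B..E` segments of the multi-hit Viterbi path. Two
post-processing rules are applied before envelopes are computed:

* **Split-core merging.** Under indel noise the optimal path occasionally
  threads one domain instance through the `J` loop as two partial cores.
  Adjacent cores of the same model are merged when the second resumes at a
  model node no more than 10 nodes before the first ended and the sequence
  gap is commensurate with the skipped model span. A genuine second copy
  of the domain restarts near node 1 and is never merged.
* **Envelope extension.** Each core is extended outwards by the number of
  unmatched flanking model nodes, capped at 5 residues and bounded by
  neighbouring domains and the sequence ends. The cap matters: hits of a
  composite (two-domain) profile that match only its first half would
  otherwise inherit the full model length, corrupting the 127-residue
  length analysis that the envelope lengths feed.

Each envelope is rescored in single-hit mode for an independent per-domain
bit score. Calibration draws `n_random` (default 200) background sequences
of fixed length (default 350), scores them in multi-hit Viterbi mode and
fits a Gumbel distribution by maximum likelihood; E-values are
`E = Z * (1 - exp(-exp(-lambda (s - mu))))`. Calibration takes an explicit
integer seed and is bit-for-bit reproducible; a zero-variance score
distribution is an error rather than a silent degenerate fit.

Search and scan use the survey's threshold sets as defaults — reporting
`E <= 1`, `domE <= 1` (search) or `0.1/0.1` (scan), inclusion
`incE <= 0.01`, `incdomE <= 0.03` — with scan E-values computed against
`Z =` number of models and search E-values against `Z =` database size.

# Seed maturation

The protocol that defines a new domain profile from composite hits is
parameterised by `maturation_config()`:

| parameter | default | meaning |
|---|---|---|
| `length_threshold` | 127 residues | long/short stratum split on envelope length |
| `n_per_stratum` | 250 | sample size per stratum, without replacement |
| `cluster_identity` | 0.70 (WYL) / 0.90 (HTH) | seed deduplication identity |
| `gathering_threshold` | 27.0 bits (WYL) / 30.0 | hit retention during iteration |
| `iterations` | 3 (WYL) / 1 (HTH) / 0 (WCX) | rebuild-and-research rounds |
| `curation_max_gap_fraction` | 0.5 | row gap limit within the conserved block |

Decisions taken where the protocol left room:

* **The 127-residue tie.** "Greater than 127" and "less than 127" leave a
  length of exactly 127 unassigned; it goes to the short stratum, and the
  same rule is used by `composite_length_split()`.
* **Curation** replaces manual inspection: within the conserved block
  (columns with >= 50% occupancy) a row is dropped if its gap fraction
  exceeds the configured limit or if any tercile of the block is entirely
  gapped (catching truncated instances). The rule is deterministic and
  idempotent on the alignments it is designed for. It is *not* applied
  inside the boundary-recovery experiment, whose alignments deliberately
  mix half-length (WYL-only) and full-length (WYL+WCX) instances that the
  tercile rule would misread as defects.
* **Boundaries.** The N-terminal boundary is the first conserved-block
  column; the C-terminal boundary is the median of the alignment columns
  holding the short-stratum hits' *core* C-termini (the `ali_to`
  coordinate, not the envelope end, whose small flank would bias the
  boundary outwards). An even number of ends takes the floor of the
  midpoint. The crystal-structure input of the original boundary choice has
  no machine-readable analogue here; the short-hit median carries the
  decision alone, and an explicit override is available via
  `seed_alignment()`.
* **Iteration.** Each round clusters the seed rows keeping representatives,
  builds and calibrates a profile, searches the database keeping included
  hits above the gathering threshold, aligns the hit envelopes with the
  internal progressive aligner and trims the result to its conserved block
  as the next seed. Aligning envelopes (rather than model-aligning them) is
  the simpler of the two defensible choices and keeps the loop's behaviour
  independent of the model being refined.
* **Wing split.** With labels the split is label-driven (the original split
  was visual/manual); without labels a complete-linkage clustering of
  wing-region pairwise identities cut at two groups recovers well-separated
  archetypes exactly.

# Classification and taxonomy

Signatures are ordered (N- to C-terminal by envelope start, ties by end
then model name) clan labels of resolved hits with independent E-value
below 0.01; repeated clans are kept, so tandem fusions stay
distinguishable. Same-clan hits whose envelopes overlap by more than 50% of
the shorter envelope conflict; within each connected component of the
conflict graph the package keeps the conflict-free subset with maximal
summed bit score, found exhaustively (components are tiny in practice; a
deterministic greedy fallback guards pathological pile-ups beyond 20
hits). For two conflicting hits this reduces to keeping the stronger hit.
Cross-clan overlaps are always retained. Classes are one per distinct
signature, labelled `A`, `B`, `C`, ... by decreasing size, with median and
standard deviation of protein length and median per-domain boundaries;
proteins without a passing hit form a reported, never merged,
`unclassified` pseudo-class, and regions of at least 80 residues without
any included hit are emitted for manual inspection rather than
reclassified. The display filter hides classes under 100 sequences from
presentation output only.

Taxonomy input is a flat lineage TSV (no live taxonomy service), and two
per-species statistics are deliberately distinct: `summarize_taxa()`
divides sequences by species *with hits* (the circular-plot ring metric),
while `per_organism_average()` divides by all species of the taxon in the
collection, including zero-hit species — which is why it requires the
collection-wide table. The small-group display filter is a species
fraction (default 1.5%), with a sequence-fraction alternative exposed,
since the reference metric for "total number" is ambiguous between the
two. Non-bacterial sequences are excluded by superkingdom with a per-group
report; candidate-species judgment is out of automated scope.

# The synthetic generator

`emit_collection()` emulates a reference-proteome collection: labelled
phyla with per-species Poisson planting rates, one background protein per
species (length 150–600), and planted proteins assembled as linker +
mutated domain instances + linker from an architecture menu. Default study
conditions: four bacterial phyla (40, 35, 55, 20 species at rates 5.0,
2.8, 2.0, 2.1 — echoing the observed per-organism averages) plus a
three-species archaeal group exercising non-bacterial exclusion; a menu of
60% HTH+WYL+WCX, 15% HTH+WYL, 10% tandem fusion and 15%
helicase-associated WYL (planted as Helicase_C3 followed by WYL; the
reference composition does not fix the order); 15% per-residue
substitutions biased by BLOSUM62-derived conditional probabilities
(`P(b|a) ~ bg_b * 2^(B62(a,b)/2)`), 1% indels with geometric lengths, and
deletions capped at 10% of an instance so truth spans stay meaningful. A
separate `defective_rate` plants half-length instances to exercise
curation. Archetype consensus sequences are background draws kept below
30% pairwise identity. In composite mode each planted protein carries one
region that is either a lone WYL (90 residues at zero noise) or a fused
WYL+WCX (160 residues) with the split position recorded — the bimodal
design around the 127-residue threshold.

Everything is driven by one integer seed through a local RNG scope, and
identical configurations produce byte-identical FASTA/TSV output.

What the generator does **not** emulate: phylogenetic correlation between
sequences (no tree-based evolution), compositional bias, disorder, signal
peptides, or homology between different archetypes. Passing tests
therefore demonstrate that the pipeline's logic is correct and its
statistics well-calibrated on controlled input, not that the profiles would
match the sensitivity of mature family databases on real proteomes.

# Problem sizes and experiments

The packaged experiments are sized for single-CPU runs of a few minutes:
the study collection holds ~600 proteins across 153 species; the
boundary-recovery study runs 20 replicates of a 12-species composite
simulation (substitution rate 0.10) through the full 3-iteration
maturation, measuring the recovered WYL model length against the planted
90-column split; the composite length split is checked at zero noise; the
per-organism rate simulation uses 60 species per phylum at rates 5.0 and
2.0 (60 rather than the minimal 30 keeps the Poisson standard error of the
mean comfortably inside the ±0.5 assessment band) plus a one-species
phylum planted below the 1.5% display threshold. Conservation scoring
offers both an entropy variant (independent counts, the default, bounded
in [0, 1]) and a BLOSUM62 sum-of-pairs variant, since the reference tool
offers several outputs without the protocol fixing one.

# Known limitations

* Bit scores are not comparable to external tools' scores; gathering
  thresholds carried from the original protocol are conventions on this
  engine's scale.
* Gumbel calibration is fitted on 200 samples by default; E-values far
  below ~1e-6 are extrapolations of that fit (ranking is unaffected).
* The progressive aligner targets determinism and envelope-scale inputs,
  not full ClustalO fidelity on divergent full-length proteins.
* The exhaustive overlap resolution is exponential in the size of a
  conflict component; components beyond 20 hits fall back to a greedy
  rule (never observed in the packaged simulations).
* Automatic class merging ("grouped together with other classes, where
  appropriate") is not attempted — the criteria were manual; a class-merge
  map can be applied downstream by relabelling signatures before
  `group_classes()`.
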