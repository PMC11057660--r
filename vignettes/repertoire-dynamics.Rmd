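---
title: "Longitudinal TCRβ repertoire dynamics with clonodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal TCRβ repertoire dynamics with clonodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

clonodyn analyses longitudinal bulk TCRβ repertoire studies: serial blood
draws and surgically excised bilateral tumours from treated subjects, each
sample a clonotype count table. The package covers the analysis layer only
— it consumes UMI/PID-corrected clonotype counts as produced by an upstream
aligner and never touches raw reads.

A **clonotype** is a distinct TCRβ rearrangement. Two identity definitions
are used, both deliberately exposed as explicit schemes:

* `cdr3aa` — clonal T cells defined by the distinct CDR3 amino-acid
  sequence alone. This is the default for every diversity, overlap and
  tracking statistic, because transcripts converging on one junction
  protein are functionally one clone.
* `vjcdr3aa` — CDR3 plus exact (allele-stripped, prefix-unified) V- and
  J-gene agreement. This stricter key is reserved for matching public
  antigen-associated clonotype panels, where gene context is part of the
  published definition.

Within a sample, rows are stored at the finer `vjcdr3aa` resolution and
collapsed on the fly, so both views are always available without
re-reading data.

## Filtering

CDR3s shorter than 8 or longer than 20 amino acids are excluded, as are
sequences containing stop (`*`), frameshift (`_`) or ambiguity (`X`)
characters — the amino-acid clonal definition implies productive chains.
The residue-alphabet filter is a toggle (`standard_aa_only`) because some
upstream pipelines pre-filter unproductive rearrangements and some do not;
the length filter is always available with its bounds as arguments.
Filtering is idempotent and recomputes totals and richness.

# Statistics

All cross-sample comparisons are computed on data **rarefied to the
smallest sample**: a single multivariate hypergeometric draw (uniform
subsampling without replacement) at a recorded seed. A single draw rather
than an average of many keeps every downstream number attributable to one
concrete dataset; callers wanting variance control can rarefy repeatedly
with different seeds, and the rarefaction seed is threaded through
`diversity_table()` and `build_report()` so bundles reproduce exactly.
Rarefaction never upsamples.

With clone frequencies $p_i$ ($\sum_i p_i = 1$, $S$ clones):

* **Shannon entropy** $H = -\sum_i p_i \ln p_i$ (nats), reported with the
  Pielou-normalized form $H/\ln S$ (0 for a single clone). Natural
  logarithms are used throughout; the normalized value is base-invariant,
  and an evenness-style normalization is the only reading consistent with
  near-uniform blood repertoires scoring ≈ 0.97.
* **Rényi profile** $H_\alpha = \ln(\sum_i p_i^\alpha)/(1-\alpha)$ over
  the conventional grid $\{0, 0.25, 0.5, 1, 2, 4, 8, \infty\}$ with the
  analytic limits $H_0 = \ln S$, $H_1 = H$, $H_\infty = -\ln\max p_i$.
  The profile is non-increasing in $\alpha$.
* **Gini index**: the standard inequality coefficient
  $G = \sum_{ij}|x_i-x_j| / (2S^2\bar x)$. Orientation conventions for
  "Gini diversity" genuinely conflict across the literature (some report
  inequality, some its complement), so both `gini` and
  `evenness_gini = 1 - G` are emitted under explicit names, and reporting
  uses the evenness orientation (1 = even/diverse). The single-clone case
  has no measurable inequality; $G = 0$ by stated convention, flagged.
* **Rank-abundance bands** (default 1–10, 11–100, 101–1000, >1000) and
  **large-clone counts** (clones strictly above 0.5% of the repertoire).
  All rankings break count ties by lexicographic clonotype key, so every
  ranking is deterministic.
* **Morisita–Horn overlap**
  $MH = 2\sum_i x_i y_i \,/\, ((\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2)XY)$
  over the union of clone keys: 1 for identical repertoires, 0 for
  disjoint ones, invariant to uniform count scaling. The implementation
  arranges the denominator as $\sum x_i^2 (Y/X) + \sum y_i^2 (X/Y)$ so
  self-comparison returns exactly 1 in floating point.
* **Clone trajectories**: a clone is *persistent and abundant* when it
  ranks in the top 100 (configurable) at two or more timepoints. Clones
  tying the 100th-ranked count are all included — any other tie rule is
  arbitrary; this one is deterministic and stated. Absent clones carry
  frequency 0 and no rank, keeping absence distinguishable from low rank.

# Antigen-panel matching

Panels are user-supplied CSVs of (V, J, CDR3) triples. Matching is exact
string equality on the chosen key after gene-label normalization on both
sides (allele suffixes stripped, `TCRBV`→`TRBV`), because public panels
mix nomenclatures. No fuzzy or distance-based matching is offered: the
question answered is "is this published clonotype present", not "is
something similar present". D-gene agreement is not required — public
panel definitions name V, J and CDR3 only, and D assignments are the
least reliable call in short junctions. The package ships
`synthetic_gp70AH1_like_panel.csv`, a 60-entry **synthetic stand-in**
with the shape of a public tumour-antigen panel, for examples and tests;
it is labelled as such and matches nothing real.

# The signature classifier

The repertoire classification protocol is: learn a per-sequence scoring
function from labeled samples, score every TCRβ, aggregate to a
per-sample *weighted signature proportion*, and validate with sample-level
cross-validation plus label permutation. clonodyn implements this as a
transparent linear multiple-instance model rather than a neural one:

* **Features**: position-free CDR3 3-mer counts ⊕ one-hot V gene ⊕
  one-hot J gene ⊕ CDR3 length. The vocabulary is frozen on the training
  clones; unseen features are dropped at scoring time.
* **Fit**: ridge-penalized logistic regression in which every clone
  inherits its sample's label with loss weight equal to its within-sample
  frequency, so each sample contributes unit weight regardless of depth.
  Frequency weighting (rather than raw counts) is the default because it
  makes the fitted model depth-invariant; a count-weight option exists.
* **Aggregation**: the sample score is $\sum_i p_i \,\mathrm{score}_i$, a
  frequency-weighted mean of per-clone probabilities — the natural
  multiple-instance reading of a "weighted proportion of signature";
  predicted labels use the 0.5 threshold. Clones with no vocabulary
  overlap receive the training base rate rather than an arbitrary 0.5.
* **Penalty strength** is chosen by an inner cross-validation that splits
  at the sample level on training samples only; clone-level splitting
  would leak shared clonotypes between folds.
* **Validation**: Monte-Carlo CV with sample-level splits; AUC by the
  Mann-Whitney rank statistic with mid-ranks (deterministic under ties);
  a permutation null built by shuffling sample labels while preserving
  each sample's clonotypes, refitting under the same protocol. Permuted
  refits reuse the penalty chosen on the observed data, the standard
  economy in permutation testing.

A linear model was chosen deliberately: the reproducible content of the
protocol is per-sequence scoring, frequency-weighted aggregation,
timepoint-restricted training and permutation validation — none of which
depends on a neural featurizer — and a linear model is deterministic,
seconds-fast and inspectable (coefficients name the k-mers and genes that
carry the signature). Unsupervised deep TCR clustering is out of scope.

# The synthetic study generator

`simulate_study()` produces ground-truthed studies with the structure of
a bilateral-tumour serial-sampling design, and its defaults *are* the
study conditions used by the package's tests:

* 8 subjects per response group, timepoints day 0/2/4/6; tumour samples
  on both flanks, blood at every timepoint.
* Tumour sample depths log-uniform in $[10^3, 10^5]$ and background
  richness log-uniform in $[10^2, 10^4]$, the ranges typical of bulk
  TCRβ-sequenced murine tumours.
* Background clone sizes follow a power law (Zipf exponent 0.8, putting
  pre-treatment top-10 clone mass near 19%); a lognormal alternative is
  available.
* A 50-clone tumour-specific panel carrying a planted CDR3 motif enters
  at 10% total mass. Within-panel sizes are themselves power-law
  (exponent 1.2): antigen-driven expansion is oligoclonal, dominated by a
  few large clones, and this skew is what drives post-expansion top-10
  mass towards half the repertoire. Half of each subject's panel is drawn
  from a study-wide shared pool (public clonotypes); the rest is private.
* Per timepoint step, panel frequencies are multiplied by the group's
  fold (responders 2.0, non-responders 1.2, controls 1.0) and the
  distribution renormalized. Expansion acts on latent frequencies, not
  counts, so depth and clonal structure stay independently controllable.
* Both flanks are independent multinomial draws from the *same* subject
  distribution — bilateral symmetry is sampling noise only — while
  different subjects' backgrounds are disjoint by construction, matching
  the near-zero between-animal overlap seen in real repertoires.
* Blood uses a near-uniform latent distribution (lognormal weight jitter,
  σ = 0.7 over 5000 clones at depth $10^4$, calibrated once so normalized
  Shannon sits near 0.97) with the panel down-weighted to 0.05% — blood
  evenness is high and antigen-specific clones occupy well under a
  percent there.

Everything is reproducible: one seed determines the study byte-for-byte,
and the generative truth (latent frequencies, panel membership, expected
panel-mass schedule) is returned alongside the samples. `truth_check()`
verifies emitted counts against that truth within multinomial sampling
error.

What the generator does **not** emulate: V(D)J recombination statistics,
thymic selection, sequencing error, cross-reactive convergence between
subjects beyond the public panel, or responder/non-responder differences
other than the planted expansion schedule. Tests passing on this
generator therefore demonstrate that the pipeline recovers a known
planted signal of realistic size and shape — not that any particular
biological dataset contains such a signal.

# Group statistics and reporting

`compare_groups()` maps each metric onto the nonparametric test a
repertoire study design calls for — Mann-Whitney between two groups per
timepoint, Kruskal-Wallis across several groups, Friedman for
within-subject series — with Holm-Bonferroni or Benjamini-Hochberg
adjustment applied family-wise across timepoints within a metric.
Standard library implementations back the tests (exact small-sample
Mann-Whitney without ties, normal approximation with tie correction
otherwise); the module's contract is the design mapping, not a
re-derivation of rank tests. Degenerate strata (n < 2 per group, all
values tied, incomplete Friedman blocks) are flagged rows without
p-values, never silent drops.

`build_report()` chains the stages on one study — per-compartment
rarefied diversity with tests, within/between-subject overlap strata,
persistent-clone counts, panel trajectories, optional classifier
validation — and writes one JSON plus CSV tables. Sections without
inputs are marked absent. Reruns with the same study and seed are
identical.

# Numerical and design notes

* Deterministic ordering everywhere: descending count, lexicographic key.
* Seeds are explicit arguments; seeded draws restore the ambient RNG
  state, so library calls never perturb user code.
* Problem sizes in the test suite: oracle equivalence uses 200 random
  repertoires (S ≤ 50, depth ≤ 500) against brute-force defining sums at
  1e-10; rarefaction calibration uses 10,000 draws; study-design recovery
  uses 20 replicate default studies; classifier validation uses two
  4-subject two-timepoint studies with distinct planted motifs and 50
  label permutations. These sizes give stable Monte-Carlo verdicts on a
  single CPU in a few minutes.
* Known limitations: no Chao/ACE richness estimation or Hill-number
  framework beyond the Rényi grid; exact-match panel lookup only; binary
  labels only in the classifier; no TCRα pairing in bulk mode.
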