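---
title: "Methods: domain-insertion tolerance profiling with inserttol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-insertion tolerance profiling with inserttol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the models and procedures it
implements, the parameters that matter, the design choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The screen and its readout

A domain-insertion library places one insert domain after every residue of
a parent protein (site *i* = the parent residue immediately preceding the
insert, sites 1..L−1; terminal fusions are not part of the library).
Functional variants are enriched by FACS; the initial and sorted pools are
deep-sequenced. The quantity of interest per site is the log2 ratio of the
site's read *fraction* after sorting to its fraction before:

    score_i = log2[ (sorted_i / Σ sorted) / (initial_i / Σ initial) ]

Working with within-pool fractions makes the score invariant to sequencing
depth (rescaling either pool's counts leaves it unchanged) and antisymmetric
under swapping the pools.

Two count configurations need conventions rather than arithmetic:

* **sorted = 0, initial > 0** — the variant disappeared during sorting and
  cannot be log2-scaled. It receives a *detection floor* of −10 (log2
  units), chosen to sit at or below the lowest finite scores such screens
  produce. The floor is applied per replicate *before* replicate averaging,
  so a variant extinct in one replicate but weakly present in the other
  averages to an intermediate value rather than being clamped.
* **initial = 0** — the variant was never in the library; the site is
  flagged missing and excluded from every downstream statistic. Missing in
  any replicate means missing overall.

No pseudocounts are used anywhere: zeros are handled by the floor and the
missing flag, not by smoothing. Replicates are combined by arithmetic mean
and summarized with Pearson correlation (floored values participate at
−10). The depleted fraction is the share of non-missing sites with negative
combined score.

## Insertion-site calling

Reads are assigned by exact matching against precomputed *junction
signatures*: for each site, the 2k-nt window of the insertion-variant CDS
spanning the 5′ (parent→insert) and the 3′ (insert→parent) junction, with
k nt (default 18) on either side. Index construction rejects any signature
that is duplicated or occurs inside the plain parent or insert sequence, so
a matched read identifies its site unambiguously; a read matching both
junctions of one site counts once.

Two deliberate restrictions:

* Orientations whose parent-side flank would be shorter than k (sites
  within k/3 residues of a terminus) are *not* indexed. A clipped flank of
  a few nucleotides collides with any other junction whose preceding
  nucleotides happen to match — in simulations this produced a measurable
  ambiguous-read rate — whereas every site of a parent with ≥ 12 residues
  retains at least one full-flank orientation.
* Matching is exact. The screen's quality-control step ("filter corrupted
  reads") is realized in its strictest reproducible form: any substitution
  inside the signature window discards the read (categorized `corrupted`
  when insert-derived k-mer content is still present, `no_insert`
  otherwise) rather than risking misassignment. Under 1% per-base errors
  this trades ~30% of reads for an assigned-read accuracy above 99%.

Reads are scanned on the given strand; the simulator emits sense-strand
reads. Counting is order-independent and per-pool tallies satisfy
`n_assigned + n_discarded = n_total`, `Σ counts = n_assigned`. Pools at the
sizes this package targets (10^5 reads) are loaded whole via Biostrings;
`count_reads()` accepts read batches where incremental processing is
needed.

## Positional features

**Conservation.** For each parent position, the amino-acid frequencies of
the alignment column (gaps and nonstandard letters excluded, renormalized;
the query row is part of the alignment) are compared to background
frequencies by a base-10 Kullback–Leibler divergence. The background is the
Swiss-Prot database composition (bundled, overridable; a uniform background
is available for analytic checks: a fully conserved column scores
log10(20) ≈ 1.301, a 50/50 column exactly 1). The divergence is 0 iff the
column matches the background, and gaps never enter — defining a gap
background is the alternative we deliberately avoid.

**Indel statistics.** Computed from *pairwise* global alignments of the
query against each homolog (Needleman–Wunsch–Gotoh, BLOSUM62, gap open −11,
extend −1, a gap run of length g scoring open + (g−1)·extend). Ties are
broken by a fixed rule — substitution over gap-in-homolog over gap-in-query
— which matters only for reproducibility, since only gap statistics feed
downstream. Insertion frequency at site *i* is the fraction of homologs
with ≥ 1 internal homolog-side insertion run anchored between residues *i*
and *i+1*; deletion frequency at residue *i* is the fraction of homologs
aligning it to a gap; mean/median insertion lengths are taken over inserting
homologs and set to 0 (not missing) where none insert, keeping the feature
matrix dense. Terminal gap runs are excluded: homolog sets gathered by
local search make terminal gaps uninformative about insertion tolerance.
Deletion frequency is computed per residue and then site-mapped like any
residue feature (the alternative — computing it per site directly — is not
what we do, and the choice is recorded here because it is not forced).

**Structure features.** Per-residue ASA, 3-state secondary structure and
pLDDT either come from a precomputed TSV (the escape hatch for real data,
e.g. DSSP output) or are extracted from a PDB file: pLDDT from the B-factor
column, ASA by the rolling-probe (Shrake–Rupley) algorithm with a 1.4 Å
probe and 96 sphere points, and secondary structure from a
hydrogen-bond-pattern heuristic (Kabsch–Sander electrostatic energy with
inferred amide hydrogens; helix from consecutive i+4→i bonds, strand from
bridge patterns, coil otherwise). The heuristic reproduces ideal-geometry
assignments (≥ 80% helix on a constructed α-helix backbone) but is not a
full 8-state implementation.

**Site mapping.** Numeric residue features map to sites as the mean of the
two flanking residues. Categorical features (amino-acid identity, secondary
structure) become indicator blocks in which *both* flanking categories are
positive — a site between an H and an E residue carries ss_H = ss_E = 1 —
so each categorical group has one or two positive labels per site. The
numeric mapping is linear; site-native indel statistics pass through
unchanged. Spearman correlations of each numeric feature against combined
scores (missing sites excluded, constant features flagged as undefined
rather than erroring) reproduce the screen-analysis summary.

## Tolerance classification

Labels: combined score > 0 → 1, otherwise 0 (a score of exactly 0 is
non-positive and labelled 0); missing sites are dropped. The dataset is
split 80:20 — stratified by label; grouping by protein is a config-level
alternative we did not make the default — and min-max scaled with ranges
fit on the training split only. Fitting the scaler on all data would leak
test information; the cost is that test values may leave [0, 1], which the
trees tolerate.

The classifier is gradient-boosted regression trees: 100 estimators,
learning rate 0.1, maximum depth 4, exponential (AdaBoost-type) boosting
loss. It is realized through xgboost with a custom exponential objective;
the node split quality is xgboost's gradient/hessian gain rather than a
literal squared-error criterion, a library-semantics difference that leaves
the loss being optimized unchanged. Folds for five-fold cross-validation
are stratified — at the ~20–35% positive rates these screens produce,
unstratified folds degenerate. Metrics are AUROC and average precision per
held-out fold. Benchmarks on the withheld test set: a seeded random-score
baseline and each feature used directly as a ranking score with its sign
chosen on training data.

Importance is reported two ways: Gini (the booster's normalized total
impurity-gain share; zero for unused features, summing to 1) and
permutation importance (mean accuracy drop over 10 seeded shuffles per
feature). Backward elimination tries candidates in ascending Gini order and
removes the first whose removal keeps the mean CV AUROC within a tolerance
(default 0.005) of the best mean seen so far, stopping when nothing can be
removed; trying candidates beyond the single least-important feature makes
the procedure robust to CV noise on individual evaluations.

## Switch calling

Profiles of the same library sorted in darkness and under illumination are
compared per site on combined scores, with replicate-wise deltas retained.
With two replicates per condition a formal test is underpowered, so calls
use an effect-size threshold plus sign consistency: `light_ON` iff
delta ≥ +τ with all replicate deltas positive, `light_OFF` mirrored,
τ = 2 log2 units by default. Floored scores enter deltas as-is —
extinction under exactly one condition is the signature of a strong switch,
not an artifact to mask. The rule is symmetric under swapping condition
labels, and raising τ never increases the number of calls.

## The synthetic-data generator

The generator exists so that every stage above can be tested against known
ground truth. Its defaults are the working conditions of the analyses in
this package:

* parent of 300 residues (the screened effectors are 239–300 residues),
  every internal site mutagenized; insert CDS of 86 codons (PDZ-domain
  sized; a fixed synthetic sequence, not a natural domain);
* two biological replicates, 10^5 reads per pool, 100-nt single-end reads,
  0.1% per-base substitution errors, constant Q30 qualities;
* per-site true log2 enrichment factors λ ~ N(−3, 2²), putting ~93% of
  sites below zero — strong depletion, as such screens show; a mixture
  option exists for planting exact depleted fractions;
* initial abundances from a symmetric Dirichlet(α = 5): near-complete but
  uneven library coverage. α is a free knob, not a calibrated value — read
  coverage uniformity of the real libraries is not known to us;
* back-translation with one fixed codon per residue, so junction k-mers
  are unambiguous and mapping is deterministic;
* reads are single-end junction-spanning fragments (windows of the variant
  CDS guaranteed to contain a full junction signature, uniformly placed).
  The real screen used tagmented paired-end sequencing; insertion-site
  calling only needs the junction, so paired-end fragment-size modelling,
  quality-dependent errors, indel errors and adapter content are
  deliberately out of scope;
* illumination enters as a {dark = 0, light = 1} multiplier on a per-site
  switch effect; ON and OFF switches are the two signs. Sorted-pool
  abundances are proportional to p_i · 2^(λ_i + condition·Δ_i),
  renormalized — one effective selection rather than two sequential sorting
  rounds, matching the initial-vs-final scores the analysis uses;
* homolog families are generated by per-residue substitutions at rate
  proportional to 1 − conservation weight, and indels at planted
  per-position rates with geometric lengths (mean 3), with every event
  logged.

Two simulator identities anchor the oracle tests: per-pool true counts sum
to the configured depth, and scoring the *expected* pool fractions recovers
λ exactly up to the shared normalization constant (the log2 of the mean
enrichment factor). One stated expectation did not survive calibration:
λ = −8 does *not* guarantee extinction at default depth (it still expects a
few sorted reads over 300 sites); guaranteed floor exercise needs λ below
about −13, and tests use −30.

What passing these tests shows — and does not show — about real data: the
generator emulates multinomial sampling noise, library unevenness,
extinction, sequencing errors and planted feature–tolerance couplings, but
not PCR jackpotting, FACS gate impurity, replicate-specific biology, or
homology-search biases. Recovery rates measured here are upper bounds on
real-data performance.

## Label noise in the classifier-recovery experiments

The planted-signal experiments generate labels by thresholding a linear
combination of computed conservation/indel features, with 10% of labels
flipped. The flips are realized as additive Gaussian noise on the decision
score before thresholding, with the noise scale calibrated (by solving
E[Φ(−|margin|/σ)] = 0.10) so that exactly 10% of labels flip in
expectation. This boundary-concentrated noise is how label noise arises in
the screen itself — binarization errors cluster at enrichment scores near
zero. The alternative, flipping 10% of labels uniformly at random, caps
the achievable AUROC against the observed labels at exactly 0.90 for
balanced classes, turning any ≥ 0.9 recovery requirement into a coin flip
even for a perfect model; under the boundary model the mislabelled sites
are also the hard-to-rank ones, and a well-fit model measurably exceeds
0.9.

## Problem sizes and numerical choices

The validation suite runs at: 300-site libraries at 10^5 reads per pool for
enrichment and switch recovery (two conditions × two replicates for the
latter); 10^5 reads for calling accuracy; 500 sites × 60 homologs for
classifier recovery with 3 informative + 17 noise features; 200 random
pairs of length ≤ 12 against an exhaustive-enumeration alignment oracle;
analytic KLD and floor constants to 10^−12. These sizes were chosen as the
smallest at which the stochastic recovery targets are comfortably
identifiable.

Numerical conventions worth knowing: enrichment is computed in double
precision with no smoothing; alignment tie-breaks are fixed as described;
xgboost runs single-threaded with a seeded RNG for bit-reproducibility;
stratified folds and splits derive their seeds from the model seed;
min-max scaling maps constant training features to 0 and flags them; the
exponential objective clamps its exponent at 30 to avoid overflow on
extreme margins; every generator restores the caller's RNG state, so
identical configurations and seeds give byte-identical outputs.

## Known limitations

* Exact-match calling discards all reads with junction-window errors; for
  higher-error chemistry a mismatch-tolerant caller would recover more
  depth at some misassignment risk.
* The secondary-structure heuristic distinguishes three states only and
  approximates strand detection; supply DSSP output via the TSV path where
  fidelity matters.
* The bundled linker-propensity scale is a constructed placeholder (marked
  synthetic); substitute a published AAindex entry for real analyses.
* Switch calling is an effect-size rule, not an error-controlled test; with
  more replicates a count-model test would be preferable.
* Per-protein datasets are concatenated without normalization beyond the
  global min-max scaling when combining proteins.
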