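# inserttol

Profiling where a protein tolerates the insertion of a whole domain.

Domain-insertion screens fuse a receptor domain (a PDZ domain, the
light-sensing LOV2 domain, ...) after every single residue of an effector
protein, express the pooled variant library, enrich functional variants by
FACS, and sequence the pools before and after sorting. `inserttol` is an R
package for the analysis side of such screens, from raw junction-spanning
reads to candidate optogenetic switches, plus a fully seeded synthetic-data
generator so that every stage can be validated against planted ground truth
without any external data.

## What it computes

**Per-site enrichment.** Each read is assigned to the insertion site it
spans (exact matching against indexed junction signatures, site = parent
residue preceding the insert). For site *i* the enrichment score is

```
score_i = log2[ (sorted_i / Σ sorted) / (initial_i / Σ initial) ]
```

Variants present in the initial pool with zero reads after sorting cannot be
log2-scaled and receive a detection floor of −10; variants missing from the
initial library are excluded. Replicates are combined by their arithmetic
mean and summarized with Pearson correlation.

**Per-position features.** Positional conservation as a base-10
Kullback–Leibler divergence of alignment-column amino-acid frequencies from
Swiss-Prot background composition (gaps excluded),

```
Divergence_i = Σ_a f_i(a) · log10( f_i(a) / b(a) )
```

insertion/deletion frequencies and insertion-length statistics from global
affine-gap pairwise alignments against homologs, amino-acid scales
(AAindex-format reader, bundled hydropathy and a synthetic linker-propensity
scale), and structure-derived ASA / secondary structure / pLDDT (from a
precomputed TSV or extracted from a PDB file). Residue features map onto
sites as the mean of the two flanking residues; categorical features use
indicator encodings in which both flanking categories are positive.

**Tolerance classification.** Sites are labelled tolerated (combined score
> 0) or depleted, split 80:20, min-max scaled on the training split, and
classified with gradient-boosted trees (100 estimators, learning rate 0.1,
depth 4, exponential loss) under stratified five-fold cross-validation, with
ROC/AUROC and precision/average-precision metrics, random and single-feature
benchmarks, Gini and permutation importances, and backward feature
elimination under an AUROC guard.

**Switch calling.** Enrichment profiles of the same library sorted under two
illumination conditions are compared per site; a site is a `light_ON`
(`light_OFF`) candidate when the light-minus-dark delta is ≥ +τ (≤ −τ,
default τ = 2) with replicate-consistent signs.

## Worked example

Simulate a 120-residue parent screened at 5×10⁴ reads per pool in two
replicates, score it, and correlate features with enrichment:

```r
library(inserttol)

cfg   <- simulation_config(parent_length = 120, depth_initial = 5e4,
                           depth_sorted = 5e4, n_replicates = 2, seed = 42)
truth <- simulate_ground_truth(cfg)
sim   <- generate_library_reads(truth, cfg)
idx   <- build_junction_index(truth$parent_cds, truth$insert_cds, 18)
prof  <- score_simulated_screen(sim, idx)$none

prof
#> enrichment_profile [protein, none]: 119 sites, 2 replicates, 0 missing, 0 floored
replicate_correlation(prof)
#> [1] 0.990
depleted_fraction(prof)
#> [1] 0.731
usable <- !prof$missing & !apply(prof$floored, 1, any)
cor(prof$combined[usable], truth$log2_lambda[usable])
#> [1] 0.998
```

The replicate correlation (0.99) reflects shared planted enrichment factors
read out through independent multinomial sequencing noise; 73% of sites are
depleted under the default factor distribution; and the recovered scores
track the planted per-site log2 factors almost perfectly at this depth.
Downstream, `residue_feature_table()` + `map_to_sites()` build the feature
matrix, `cross_validate()` / `importance()` / `backward_eliminate()` run the
classification analysis, and `compare_conditions()` + `call_switches()`
screen for condition-dependent variants. `run_pipeline()` (or the
`exec/inserttol` script) chains all stages and writes TSV/JSON outputs plus
a manifest.

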