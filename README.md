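# concordtf

Discovery of interacting transcription-factor (TF) pairs, tissue and
tissue-type TF pairs, TF–TF interaction networks and conserved three-TF
modules from paired orthologous promoter sequences of two species.

## Who this is for and what it computes

Regulatory genomicists who want to predict *combinations* of TFs driving
tissue gene expression from sequence alone. The package implements a
function-conservation approach: an unordered pair of position weight
matrices (PWMs) is scored by coupling two 10-point profiles over a
distance-constraint grid (maximum gaps of 20–200 bp in 20 bp steps):

- the **site enrichment profile** — at each cutoff *d*, the number of genes
  whose promoters carry both binding sites within an edge-to-edge gap ≤ *d*,
  divided by the same count in per-promoter shuffled backgrounds
  (denominator floored at 1);
- the **ortholog-overlap enrichment profile** — the number of orthologous
  gene pairs carrying the co-occurrence in *both* species, divided by the
  shuffled-background overlap.

Candidate pairs (site ratio > 1 in more than 5 of the 10 cutoffs, and at
least 10 % orthologous-gene overlap at every populated cutoff) are tested
by the Pearson correlation *r* between the two profiles, with a one-sided
permutation p-value, p = (1 + #{r_perm ≥ r_obs}) / (n_perm + 1), and
Benjamini–Hochberg q-values per gene list. A pair is called when q < 0.05
with each species' corpus as the enrichment foreground. Housekeeping
subtraction yields tissue TF pairs; clustering (binary distance, complete
linkage), tissue-type pairs (≥ 50 % of a group's tissues), TF–TF networks
(joined pairs sharing a TF, with bootstrap enrichment tests for designated
TF sets at internal positions) and conserved three-TFBS modules (shared
identical site, same cross-species order and orientation, support ≥ 10
orthologous genes at q < 0.05) build on the calls.

A first-class synthetic-data module generates two-species promoter corpora
with planted, distance-constrained, conserved site pairs and triplets plus
a ground-truth manifest, so the whole pipeline is testable at desk scale.
A Match-style PWM scanner (information-weighted matrix similarity in
[0, 1], thresholds calibrated to minimise false positives plus false
negatives) and mononucleotide / dinucleotide-preserving
(Altschul–Erickson) promoter shuffles are included.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script prints what it found and writes tables under `results/analysis/`.

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_scan.R
Rscript analysis/03_pairs.R
Rscript analysis/04_tissues.R
Rscript analysis/05_networks.R
Rscript analysis/06_triplets.R
Rscript analysis/07_recovery.R
```

Output of a seed-1 run:

```
simulated 1900 orthologous promoter pairs (1000 tissue + 900 housekeeping genes),
planted 7 pair elements and 1 triplet element(s); seed 1
calibrated 40 PWMs (thresholds 0.77-0.93)
scanned 5842 real and 2118 background hits across both species
T1: 12 called, 0% removed by housekeeping, 12 tissue pairs
T2: 1 called, 0% removed by housekeeping, 1 tissue pairs
T3: 1 called, 0% removed by housekeeping, 1 tissue pairs
T4: 1 called, 0% removed by housekeeping, 1 tissue pairs
total: 15 tissue TF pairs across 4 tissues (15 unique keys)
15 candidate triplet keys, 1 called:
   tissue              triplet support            p            q
1:     T1 PWM015:PWM016:PWM017      30 1.873886e-39 2.810829e-38
planted pair recall: 5/5
housekeeping pairs: 2/2 called in HK, 0 leaked into tissue sets
tissue pair calls: 15 (0 without planted signal)
planted triplet called: 1/1
```

Reading this: the generator planted 5 conserved tissue pairs, 2
housekeeping pairs and one 30-carrier triplet. The pipeline called all 5
planted pairs in their tissues, both housekeeping pairs from the
housekeeping list (and none leaked into tissue sets), every one of the 15
tissue-pair calls carries planted signal, and the triplet was recovered
with support 30 of 250 genes (hypergeometric p ≈ 1.9e-39). Tissue T1
carries more calls because its planted triplet and two planted pairs
create additional genuine cross-element co-occurrences.

Equivalent results come from the in-process API:

```r
library(concordtf)
res <- run_synthetic_study(seed = 1)
evaluate_recovery(res)
```

## Repository layout

```
R/, src/          implementation (R + Rcpp scanner core)
analysis/         numbered workflow drivers (simulate ... recovery)
scripts/          acceptance.R
tests/testthat/   unit, property and acceptance suites
vignettes/        methods vignette: models, parameters, design decisions
```
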