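# herbmicrobeMR

An R package implementing, as one tested pipeline, the analytical chain that
links traditional-Chinese-medicine (TCM) prescription mining to gut-microbiota
causal inference for hepatitis B cirrhosis:

1. **Corpus statistics** — per-herb frequency, rate (% of prescriptions),
   proportion (% of all herb occurrences), dose ranges, and
   occurrence-weighted property / flavor / meridian percents over
   literature-mined prescription corpora, split into compensated and
   decompensated disease stages.
2. **Ordination** — Bray-Curtis dissimilarity on herb profiles,
   `d(i,j) = Σ|x_i − x_j| / Σ(x_i + x_j)`, principal coordinates analysis
   (classical scaling of the Gower-centered −d²/2), one-way PERMANOVA with a
   seeded permutation p-value, and two-class PLS-DA.
3. **Association rules** — a full Apriori miner (level-wise candidate
   generation with the downward-closure prune) producing single-consequent
   rules with support, confidence and lift = confidence / support(consequent).
4. **Target overlap and networks** — ADME screening (OB ≥ 30%, DL ≥ 0.18),
   exact three-way target-set intersection, degree-based hub ranking on a
   score-thresholded (≥ 0.4) interaction network, hypergeometric pathway
   over-representation with Benjamini–Hochberg adjustment, and the
   microbe → metabolite → target → pathway linkage table.
5. **Two-sample Mendelian randomization** — instrument selection
   (P < 1 × 10⁻⁵, greedy clumping at 500 kb / r² > 0.1, F = (β/se)² > 10),
   allele harmonization with frequency-resolved palindromes, the Wald ratio,
   random-effects IVW (the primary analysis), MR-Egger, weighted median, and
   simple/weighted mode estimators, plus Cochran's Q, the MR-Egger intercept,
   MR-PRESSO (global, outlier, distortion tests) and the Steiger
   directionality test.

A synthetic-data module (`simulate_corpus()`, `simulate_gwas()`,
`simulate_target_sets()`) generates every input the pipeline consumes — with
planted co-occurrence blocks, planted set overlaps and a configurable
fraction of invalid (pleiotropic) instruments — so the whole chain runs and
is tested fully offline.

## Worked example

The numbered drivers under `analysis/` run the whole chain on synthetic
inputs (`Rscript analysis/01_simulate.R` … `06_mr.R`). The MR stage, for a
simulated taxon with a true odds ratio of 1.27 on cirrhosis risk
(instrumented at the scale of a 16S microbiome GWAS of 18,340 individuals
against a case-control outcome of 3,970 cases / 373,307 controls), prints:

```
instruments: 27 selected, 26 usable after harmonization
IVW: OR = 1.22 (95% CI 1.07-1.39), p = 0.00253  [true OR 1.27]
egger            OR = 1.10 (0.57-2.09), p = 0.783
weighted_median  OR = 1.20 (1.02-1.42), p = 0.0268
simple_mode      OR = 1.31 (0.98-1.74), p = 0.0644
weighted_mode    OR = 1.24 (0.96-1.60), p = 0.102
Cochran Q = 32.50 (df 25, p = 0.14); Egger intercept p = 0.74
MR-PRESSO global p = 0.10, outliers: none
Steiger: exposure -> outcome direction TRUE (p = 4.8e-284)
```

The IVW interval covers the planted effect; heterogeneity, pleiotropy and
reverse-causation diagnostics are all quiet, as they should be for a dataset
simulated with valid instruments only. Equivalently, `run_pipeline()` runs
all stages from one seeded configuration and writes provenance-headed TSVs:

```r
library(herbmicrobeMR)
manifest <- run_pipeline(list(seed = 5, synthetic = TRUE, out_dir = "out"))
```

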