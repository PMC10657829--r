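---
title: "From prescription mining to microbiota Mendelian randomization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From prescription mining to microbiota Mendelian randomization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbmicrobeMR)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where several defensible choices
existed.

## The analytical chain

The package treats the question "do the herbal formulas prescribed for
compensated and decompensated hepatitis B cirrhosis share structure with the
gut microbes that causally influence the disease?" as a chain of five
analyses. Prescription corpora (one row per prescription-herb pair, with a
disease-stage label and a dose in grams) are summarized into frequency and
attribute tables; ordinated to test whether the two stages use
distinguishable herb profiles; mined for association rules that identify
the core herb combinations; the targets of those core herbs are intersected
with microbial-metabolite targets and disease targets and ranked on an
interaction network; and finally two-sample Mendelian randomization (MR)
asks whether microbial taxa sharing those targets causally affect disease
risk.

## Corpus statistics

For a corpus of $n$ prescriptions with $T$ total herb occurrences, an herb
appearing in $f$ prescriptions has rate $100f/n$ and proportion $100f/T$.
Three conventions are fixed here:

* **Occurrence-weighted attribute counting.** A property, flavor or meridian
  level carried by an herb contributes that herb's full prescription
  frequency to the level's count. A bitter-cold herb used 40 times adds 40
  to *bitter* and 40 to *cold*; axis totals therefore exceed the number of
  distinct herbs, matching how such tables are tallied in the clinical
  literature. Percents are within-axis.
* **Half-up rounding.** Printed percents use half-up rounding to two
  decimals (`round_half_up()`), the convention of clinical frequency tables;
  exact ratios are always retained alongside. Published tables of this kind
  are occasionally internally inconsistent (an axis total that does not
  match its printed percents); the package always reports the exact ratio of
  its own counts and leaves reconciliation to the analyst.
* **Observed doses only.** Dose minimum/maximum/mean/sd are computed over
  prescriptions that record a dose; missing doses are excluded, not imputed.
  An herb is flagged `exceeds_recommended` when its mean dose exceeds the
  upper bound of the dictionary's recommended range.

## Ordination

Herb profiles default to binary presence/absence — formula composition, not
dosage, is the unit of prescribing practice — with a dose-weighted mode
available (`incidence_matrix(weighted = TRUE)`). Bray-Curtis dissimilarity
on binary profiles equals one minus the Sørensen similarity.

PCoA is classical scaling: eigendecomposition of the double-centered
$-d^2/2$ matrix, coordinates scaled by $\sqrt{\lambda}$. Bray-Curtis is
non-Euclidean, so negative eigenvalues occur; they are reported but excluded
from the variance-explained denominator, and **no Cailliez or Lingoes
correction is applied** — corrections change the variance-explained
percentages, and the uncorrected spectrum is the interpretable default.

PERMANOVA partitions squared dissimilarities
($SS_\text{total} = \sum_{i<j} d_{ij}^2 / n$, within-group analogously) and
reports the pseudo-F with a label-permutation p-value using the $+1$
correction, $p = (1 + \#\{F^\pi \ge F\})/(1 + B)$, $B = 999$ by default and
seeded. On univariate Euclidean input the pseudo-F equals the classical
ANOVA F exactly, which the tests use as an oracle (along with
`vegan::adonis2`).

PLS-DA uses NIPALS against a centered ±1 class vector. Per-component
"variance explained" is the percent of **predictor (X) variance** captured
by each rank-one deflation step — these sum to 100 over a full-rank
decomposition. The Y-variance convention exists in the literature; the
X-variance one is emitted because it is the quantity the deflation
identity makes exact.

## Association rules

The Apriori miner enumerates frequent itemsets level-wise with the
downward-closure prune and is, by construction and by test, identical to
exhaustive enumeration. Defaults follow mining practice for prescription
corpora: minimum support 0.16, minimum confidence 0.9, single-item
consequents (every printed rule in this literature has a one-herb
consequent), and a high-frequency floor (herbs used more than 10 times in
the smaller corpus, more than 20 in the larger) applied **before** support
computation; `floor_before_mining = FALSE` restricts the floor to display
instead. Ties in "highest support/confidence/lift" are reported as the full
tied set. Hub herbs are ranked by the number of rules they participate in.

## Target overlap and networks

ADME screening keeps ingredients with oral bioavailability ≥ 30% and
drug-likeness ≥ 0.18, boundary inclusive. Gene symbols are uppercased and
whitespace-stripped on ingestion; alias resolution is deliberately left to
an optional user-supplied map, since symbol normalization is done upstream
(e.g. via UniProt) in this field's workflows. The three-way intersection
reports all seven exclusive Venn regions, whose cardinalities always sum to
the union (tested exactly). Hub ranking counts edges at combined score
≥ 0.4 — the conventional medium-confidence interaction threshold — with
lexicographic tie-breaks. Pathway over-representation uses the upper-tail
hypergeometric probability with a Benjamini–Hochberg adjustment (raw and
adjusted both emitted); the universe defaults to the union of pathway
members, the least-assuming choice when no background is stated.
Hypergeometric p-values are discrete, hence conservative
(super-uniform) under the null — the calibration test checks
$P(p \le \alpha) \le \alpha$ rather than exact uniformity.

## The MR engine

Instrument selection applies three screens in order: association
$P < 10^{-5}$ (microbiome abundance loci rarely reach $5\times10^{-8}$),
greedy clumping (sweep SNPs by ascending p; retain unless within 500 kb of a
retained SNP with $r^2 > 0.1$ — the standard index-SNP rule; pairs absent
from the LD input are treated as independent), then instrument strength
$F = (\beta/se)^2 > 10$. The squared-z form of F is the default because
per-SNP $r^2$ and exact per-SNP sample sizes are often unpublished; a
variance-explained route is available through the Steiger machinery when
$n$ is supplied.

Harmonization aligns the outcome to the exposure's effect allele: matching
alleles kept, swapped alleles flipped (sign and frequency), anything else —
including cross-strand reports such as A/C vs G/T — dropped as incompatible
rather than strand-inferred. Palindromic (A/T, C/G) variants are resolved by
allele frequency only when both frequencies lie outside (0.42, 0.58), the
conventional ambiguity band, and dropped otherwise. Every action is recorded
(`kept` / `flipped` / `dropped` with reason) so harmonization is auditable.

Estimators, all on the harmonized scale:

* **Wald ratio** $\hat\theta_j = \beta_{Yj}/\beta_{Xj}$ with first-order
  $se = se_{Yj}/|\beta_{Xj}|$ (second-order delta-method variant behind
  `second_order = TRUE`).
* **IVW**: weighted regression through the origin, weights $1/se_{Yj}^2$.
  Random effects (the primary analysis) use the multiplicative
  over-dispersion model — fixed-effect $se$ inflated by
  $\sqrt{\max(1, Q/(n-1))}$, never deflated. One SNP reduces exactly to the
  Wald ratio. P-values use normal quantiles by default (`use_t = TRUE` for
  the t alternative).
* **MR-Egger**: weighted regression *with* intercept after orienting all
  $\beta_X \ge 0$; the intercept estimates directional pleiotropy, tested on
  $t_{n-2}$ with the same multiplicative variance floor.
* **Weighted median**: linear interpolation of the inverse-variance-weighted
  cumulative ratio distribution at 0.5; consistent while valid instruments
  hold > 50% of the weight. Bootstrap SEs (1,000 parametric draws, seeded).
* **Modes**: Gaussian-kernel density over the ratios (unweighted /
  inverse-variance weighted), bandwidth $0.9\min(sd, \text{mad})\,n^{-1/5}$
  times a user factor; zero ratio spread degenerates cleanly to the common
  ratio with zero SE.

Diagnostics: Cochran's Q with first-order weights against $\chi^2_{n-1}$;
MR-PRESSO with the leave-one-out residual-sum-of-squares global test,
per-SNP outlier test (Bonferroni at $\alpha = 0.05$) and a distortion test
whose null removes random subsets of the flagged size, all simulated under
the fitted no-pleiotropy model and seeded; Steiger directionality via
$r^2 = F/(F + n - 2)$ per side and the z-test on Fisher-transformed
correlations. Exposures reporting fewer SNPs than a method's minimum (3 for
Egger/median/modes, 4 for MR-PRESSO) get that method marked not-applicable
rather than an error, and estimators with opposite signs across methods are
flagged (`sign_disagreement`) but never reconciled — the disagreement is
itself the finding. Confounder screening is a join of a user-supplied
SNP-trait annotation against an exclusion list (`screen_confounders()`),
not a live query.

## What the generator emulates — and what it does not

`simulate_corpus()` reproduces the *statistical* structure the corpus
analyses assume: stage-specific planted co-occurrence blocks (core formula
backbones), independent background herbs, and truncated-normal doses with a
hard positive floor (frequency tables report mean ± sd of strictly positive
doses). Defaults mirror the reference study sizes: 98 compensated and 241
decompensated prescriptions over a 40-herb universe, 2–24 herbs per
prescription. It does not emulate synonymy noise in herb naming, correlated
background co-prescription beyond the planted blocks, or dose-indication
interactions.

`simulate_gwas()` draws per-SNP summary statistics under
$\beta_Y = \theta\,\beta_X + \alpha + \varepsilon$, with $\alpha = 0$ for
valid instruments and $\alpha \sim N(\mu_\alpha, \sigma_\alpha)$ for a
configurable invalid fraction. Standard errors follow
$se = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$; for the binary outcome
the effective sample size $n_\text{cases} n_\text{controls}/n$ is used — at
the default 3,970 cases / 373,307 controls this is ≈ 3,928, which is what
makes simulated confidence intervals the width actually seen for
case-control outcomes of this design. Exposure effects default to
$N(0.08, 0.02)$ at $n = 18{,}340$, giving instrument F-statistics in the
15–120 range typical of 16S abundance GWAS instruments that pass an F > 10
screen. A fixed fraction of SNPs (default 0.2) is reported on swapped
alleles and a fraction (default 0.1) is palindromic, exercising every
harmonization branch. LD is block-constant by construction and supplied as
an r² lookup — the generator does not simulate individual-level genotypes or
realistic LD decay, and real microbiome GWAS effects are neither normal nor
independent of allele frequency. Passing tests therefore demonstrate the
estimators' statistical properties under their stated models, not
performance on any particular real dataset.

All generators draw from per-generator child streams
(`child_seed(root, name)`, a stable string hash), so adding a generator
never perturbs another's stream and every output is reproducible from one
root seed.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to what the
statistical check needs rather than more: 1,000 replicates for IVW recovery
(mean bias and 95% CI coverage) and Egger type-I error, 200 replicates for
MR-PRESSO power (1,000 null simulations each) and Steiger direction, 3-SE
Monte-Carlo bands for all empirical rates, 999 permutations for PERMANOVA,
and 100 random small corpora for the Apriori-vs-enumeration identity.
Numerical tie-breaks are lexicographic throughout (rule sorting, hub
ranking); eigenvalues below `max(eigenvalue) * 1e-12` are treated as zero in
PCoA; symmetry of distance matrices is required to `1e-12`.

## Known limitations

* The pipeline operates on pre-fetched tables; database retrieval (target
  prediction, interaction scores, pathway membership, phenome scans) is out
  of scope by design.
* LD r² is an input, never computed from a reference panel.
* Multivariable MR, CAUSE-style and contamination-mixture estimators are not
  implemented; the five-estimator battery plus sensitivity analyses is the
  intended scope.
* PLS-DA component percents depend on the X-variance convention above;
  analysts comparing against software using the Y-variance convention should
  expect different (typically smaller) numbers.
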