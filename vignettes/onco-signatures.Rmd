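---
title: "Deriving and scoring mutation-anchored onco-signatures"
author: "oncosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and scoring mutation-anchored onco-signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncosig)
```

# The problem

Tumors carrying a somatic mutation in the same driver gene often share a
downstream transcriptional footprint, even across tissues. `oncosig`
derives such footprints — *onco-signatures* — from a cohort of tumors with
matched mutation calls and a panel of normal reference samples, scores
every signature in every sample with a single-sample rank test, screens
the scores for survival association, and clusters samples on the screened
scores to expose subgroups with distinct outcomes.

The whole pipeline is exercised end-to-end on a bundled synthetic-cohort
generator with planted ground truth, so every statistical property the
method relies on is testable without any external download.

# The model, stage by stage

## Reference binarization

Normal samples define a per-gene null. For raw RNA-seq counts each gene is
modelled as negative binomial with method-of-moments estimates: mean
$\hat\mu_g$ = sample mean and size $\hat r_g = \hat\mu_g^2 / (s_g^2 -
\hat\mu_g)$. Method-of-moments (not MLE) is the default because it is
closed-form and stable at the cohort sizes this package targets; genes
whose sample variance does not exceed the mean have no admissible NB size
and fall back to Poisson. Normalized (continuous) data use a Gaussian
(mean, sd) fit instead.

A tumor observation $x_{gj}$ is converted to $\{-1, 0, +1\}$ by tail
probabilities under the gene's fitted null: $+1$ if $P(X \ge x_{gj}) <
\alpha$, $-1$ if $P(X \le x_{gj}) < \alpha$, else $0$, with $\alpha =
0.05$ per tail by default. For discrete families $P(X \ge x)$ is the
survival function at $x - 1$, so "equal or greater" is honored exactly.
Two consequences worth knowing:

* discreteness makes the calls conservative — the realized per-tail flag
  rate is below $\alpha$ when tumors truly follow the reference, and only
  estimation error on the normals pushes it back up toward $\alpha$;
* calls are monotone in $x$ for every gene ($-1 \to 0 \to +1$), which the
  test suite asserts on a value grid.

Degenerate genes with reference mean 0 flag any positive tumor count as
$+1$ and never $-1$ (a point mass at zero has $P(X \le x) = 1$ for all
observable $x$).

## Signature derivation

For each driver gene, the binary matrix is restricted to the mutated
samples (the cohort is binarized once — the binarization does not depend
on the driver) and the *support count* of every gene is the number of
mutated samples with a nonzero call. Genes whose count is **strictly
greater** than the type-7 98th-percentile of the count vector are
candidate markers; a gene appearing in the candidate set of two or more
drivers is removed from all of them; signatures keeping at least 5 unique
markers are retained. Marker direction is the majority sign of the
nonzero calls (ties give 0). Two design points were genuinely open:

* *Uniqueness before the size filter.* Cross-signature exclusivity is
  applied to the candidate collection first and the $\ge 5$ filter
  second; the post-filter alternative is available via
  `assignUniqueMarkers()` on pre-filtered sets.
* *Support counts the sign-agnostic way.* A sample showing $-1$ counts
  the same as one showing $+1$; direction is recorded but does not gate
  the count.

The strict ">" on a type-7 quantile caps a signature's candidate set at
roughly 2% of the transcriptome. This interacts with the synthetic
defaults (below): planted target sets of 40 genes are fully recoverable
only when the simulated transcriptome has at least 2000 genes, which is
why the default scenario uses exactly that size.

## Single-sample enrichment (NES)

Each signature is scored per sample with a competitive
Mann–Whitney–Wilcoxon gene-set test. With $m$ profiled marker genes, $n$
genes outside the set, and $T$ the sum of in-set midranks,

$$U = mn + \frac{m(m+1)}{2} - T, \qquad \mathrm{NES} = 1 - \frac{U}{mn}.$$

NES is exactly the probability that a random in-set gene is expressed
above a random out-set gene in that sample (ties count one half), so it
lives in $[0, 1]$, satisfies $\mathrm{NES}(S) + \mathrm{NES}(S^c) = 1$,
and is invariant under any strictly monotone transform of the profile —
all three properties are asserted against a brute-force pairwise oracle.
The $m(m+1)/2$ term is the standard MWW identity; dropping the $/2$ would
let NES leave $[0, 1]$ and break its probability reading. Marker
directions are ignored by the score (the test is competitive on the plain
set); plain NES, not its logit, feeds all downstream stages.

## Survival screening and clustering

Each signature gets a univariate Cox proportional-hazards fit with its
NES as the only covariate (Efron tie handling) and is *selected* when the
raw Wald p-value is below 0.05 — deliberately unadjusted; a BH-adjusted
column is emitted for transparency but does not gate selection. Constant
or non-convergent covariates are flagged non-estimable, never selected.

Samples are then clustered on the NES rows of the selected signatures:
Euclidean distance between sample columns, Ward.D2 linkage (the
unsquared-distance Ward convention), tree cut at $k = 4$. The orientation
was an open point — the same matrix supports clustering signatures
instead — but the meaningful output of the pipeline is sample subgroups,
so samples are clustered by default and the signature dendrogram remains
available from the returned tree. Labels are renumbered 1..k by
decreasing cluster size, making the labelling deterministic and
order-invariant.

Cluster outcomes are compared with Kaplan–Meier curves and the k-group
log-rank test; the two clusters with extreme observed event fractions are
contrasted by rank-sum differential expression at |log2FC| ≥ 1.5 (1.0 for
miRNA) and BH FDR < 0.05. The fold-change uses a pseudocount,
$\log_2((\bar x_A + 1)/(\bar x_B + 1))$. A deliberate deviation: the DE
step is a self-contained rank-sum test rather than a negative-binomial
GLM framework (edgeR and kin), because the pipeline contract is
cluster-level gene lists, not moderated coefficients; an external DE
table in the same column layout can be substituted wherever a DE result
is consumed.

## Promoter motif scanning

Promoter windows span 1500 nt upstream to 500 nt downstream of the TSS
(2000 nt total), in 0-based half-open coordinates; minus-strand windows
are reverse-complemented so the sequence always reads 5'→3' with the
upstream flank first, and out-of-bounds windows are an error rather than
clipped. JASPAR-style count matrices become log2-odds PWMs against a
uniform background with 0.25 pseudocount. A hit is any offset, on either
strand, scoring at least `min + fraction * (max - min)` of the PWM's
attainable score range (default fraction 0.8, the convention of the
matchPWM tool family; 1.0 keeps only perfect matches). `N` bases score as
the column minimum. Reverse-strand hits are reported at their forward
start, so scanning a sequence and its reverse complement yields
mirror-image hit lists.

# The synthetic cohort generator

`defaultScenario()` fixes the study conditions used throughout the tests
and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| nGenes | 2000 | transcriptome size; 40-gene targets = top 2% |
| nNormals / nTumors | 200 / 400 | reference and cohort sizes |
| NB mean range | 10–1000 (log-uniform) | per-gene baseline expression |
| NB size | 10 | shared dispersion; variance $\mu + \mu^2/10$ |
| drivers | 3 × (rate 0.3, 40 disjoint targets, \|log2FC\| 1.5) | planted MUT effects (up, down, up) |
| subtypes | 4 × 25%, drivers none/1/2/3 active | ground-truth clusters |
| hazard multipliers | 1 / 1.8 / 3 / 6 | subtype survival separation |
| survival | exp(2e-4/day), censoring exp(1.5e-4/day), 10 y | ~40% events |

Subtype–driver coupling is deterministic (a subtype's active drivers are
forced mutated) so cluster recovery has a well-defined truth; survival is
exponential — the minimal proportional-hazards model — so power and
calibration have closed-form sanity checks. All generators are pure
functions of (scenario, seed); each stage draws from its own derived
stream so adding samples to one stage does not shift another.

What the generator does **not** emulate: realistic TCGA marginals
(library-size variation, GC content, gene-length effects), gene–gene
correlation, batch structure, copy-number or methylation signal, and
sample-level outliers. Passing tests therefore demonstrate the
correctness and calibration of the algorithms under the stated model, not
robustness to the full messiness of real cohorts.

# Numerical conventions

* All quantiles package-wide are type-7 (linear interpolation), including
  the 98th-percentile support cutoff and upper-quartile normalization.
* Upper-quartile normalization scales each sample so its 75th percentile
  over *nonzero* genes equals the across-sample mean of those
  percentiles; it is invariant to per-sample positive rescaling.
* Cluster label ties (equal sizes) break by the original cutree label;
  support-direction ties give direction 0; GMT direction suffixes are
  ASCII `+`, `-`, `.`.
* Isoform aggregation sums counts per group id and orders groups
  lexicographically (radix order, locale-independent). Whether miRNA
  counts are re-normalized after aggregation is left to the caller —
  aggregation and normalization are separate, composable steps.
* Pipeline outputs contain no timestamps, so identical (config, seed,
  inputs) reruns are byte-identical.

# Problem sizes used in the checks

The bundled checks run at desk scale, chosen so the full suite completes
in about a minute: NES oracle on 1000 random instances (m ≤ 10, n ≤ 50,
with ties, agreement within 1e-12); binarization calibration on 1000
genes × 500 tumors drawn from a reference fitted on 200 normals
(per-tail flag rate ≤ 6% at α = 0.05); 500 random NB/Poisson tail models
against pmf summation (1e-10); signature recovery on the default
scenario (≥ 80% of each planted target set, ≤ 5% stray markers); Cox
type-I on 1000 null signatures (5% ± 2%) and power at log-HR 0.7 per NES
SD with n = 500 (≥ 90%); cluster recovery over 50 seeds (ARI ≥ 0.9 and
extreme-pair log-rank p < 0.05 in ≥ 90%). The derivation scales linearly
in genes × samples × drivers, so pan-cancer sizes are a matter of
runtime, not algorithm.

# Known limitations

* **Null-cohort signature retention with few drivers.** Under a null
  cohort (no planted effects) the candidate set of every driver is the
  top ~2% of genes by support count. Those counts share each gene's
  flagging propensity (discreteness plus reference-fit error) across
  drivers, but carry independent binomial noise, so with only three
  drivers the candidate sets overlap partially and each driver can keep
  five or more unique genes — i.e. spurious signatures can survive the
  uniqueness rule. The rule becomes an effective null filter only when
  many drivers are screened (hundreds, as in a pan-cancer catalog),
  because high-propensity genes then recur in most candidate sets and are
  removed everywhere. Interpret signatures derived from small driver
  panels accordingly, or tighten `minMarkers`/`supportQuantile`.
* Method-of-moments NB fitting is biased for small normal panels; with
  fewer than ~50 normals the realized flag rate can exceed the nominal
  tail α noticeably.
* The Cox screen is univariate and unadjusted by design, mirroring a
  discovery screen; it is not a multivariable prognostic model.
* `ward.D2` on NES columns assumes scores on a common [0, 1] scale; no
  further standardization is applied.
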