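# oncosig

Mutation-anchored expression signatures ("onco-signatures") for tumor
cohorts: derivation, single-sample scoring, survival screening, and
subtype discovery.

## The problem

Tumors mutated in the same driver gene often share a downstream
transcriptional footprint. Given (i) a gene-by-sample expression matrix
for tumors, (ii) one for normal reference samples, (iii) a binary
samples-by-drivers mutation table and (iv) clinical follow-up, `oncosig`:

1. **Binarizes** tumor expression against per-gene reference
   distributions fitted on the normals (negative binomial by method of
   moments for counts, with a Poisson fallback for underdispersed genes;
   Gaussian for normalized data). An observation becomes +1 / −1 when its
   tail probability P(X ≥ x) / P(X ≤ x) under the reference falls below
   α = 0.05, else 0.
2. **Derives signatures** per driver: count, gene by gene, the mutated
   samples showing a nonzero call; keep genes strictly above the
   98th percentile of the count distribution; drop genes shared between
   drivers (markers must be unique); retain signatures with ≥ 5 markers.
3. **Scores** every signature in every sample with a competitive
   single-sample Mann–Whitney–Wilcoxon gene-set test. With m in-set
   genes, n outside, and T the in-set midrank sum,

       U = mn + m(m+1)/2 − T,   NES = 1 − U/(mn) ∈ [0, 1]

   — the probability that an in-set gene is expressed above an out-set
   gene in that sample.
4. **Screens** signatures with univariate Cox proportional-hazards fits
   on NES (selected at raw Wald p < 0.05), **clusters** samples on the
   selected NES rows (Euclidean, Ward.D2, k = 4), and **characterizes**
   the clusters by Kaplan–Meier / log-rank comparison and rank-sum
   differential expression at |log2FC| ≥ 1.5, BH FDR < 0.05.

A synthetic-cohort generator with planted drivers, subtypes, and
survival structure makes the whole pipeline verifiable end-to-end; see
the methods vignette (`vignettes/onco-signatures.Rmd`) for the model,
parameter meanings and design decisions.

## Worked example

```r
library(oncosig)

sc     <- defaultScenario(seed = 42)        # 2000 genes, 200 normals, 400 tumors
cohort <- simulateCohort(sc)                # planted drivers + subtypes + survival

model <- fitReferenceModel(cohort$normals)
deg   <- binarizeMatrix(cohort$tumors, model, 0.05)
sigs  <- deriveSignatures(deg, cohort$mutations, oncoConfig(seed = 42))
sigs
#> OncoSignatureSet with 3 signatures
#>   DRV1: 40 markers
#>   DRV2: 39 markers
#>   DRV3: 39 markers

nes <- nesMatrix(cohort$tumors, sigs)
nes
#> NESMatrix: 3 signatures x 400 samples, range [0.284, 0.794]

coxScreen(nes, cohort$clinical)[, c("signature", "log_hazard_ratio",
                                    "p_value", "selected")]
#>   signature log_hazard_ratio      p_value selected
#> 1      DRV1       -0.6675789 0.3506077357    FALSE
#> 2      DRV2       -1.8519304 0.0056462027     TRUE
#> 3      DRV3        2.9883504 0.0000045615     TRUE

cl <- wardCluster(nes, 4)
cl
#> ClusterAssignment: 400 samples in 4 clusters (sizes: 107, 105, 101, 87)

lr <- logrankTest(cohort$clinical, clusterLabels(cl))
sprintf("log-rank chisq = %.2f, df = %d, p = %.3g",
        lr$statistic, lr$df, lr$p_value)
#> "log-rank chisq = 29.61, df = 3, p = 1.67e-06"
```

All three planted driver signatures are recovered with their 40-gene
target sets essentially intact; the two signatures whose subtypes carry
elevated hazards are flagged by the Cox screen; and the four recovered
clusters separate strongly in overall survival.

`runPipeline(oncoConfig(seed = 42), "run_dir")` executes the same chain
in one call and writes every artifact (reference model, signature GMT,
NES TSV, Cox screen, cluster assignments, KM curves, log-rank summary,
DE table, machine-readable run log) to `run_dir`, byte-identically
across reruns with the same seed. A thin command-line wrapper with
`run` / `simulate` / `derive` / `nes` subcommands is in
`inst/scripts/oncosig.R`.

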