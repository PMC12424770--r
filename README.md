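# retroprev

Do mammals whose genomes carry more recently active non-LTR
retrotransposons — full-length LINE-1 (L1) copies and the 100–400 bp
SINEs they mobilise — or larger repertoires of cancer gene orthologs
(CGOs), show higher cancer prevalence? `retroprev` is an R package for
comparative oncologists and genome biologists that implements this
analysis end to end: it builds per-species genomic predictors from
repeat and gene annotations, transforms the traits, and fits
necropsy-weighted phylogenetic regressions with estimated phylogenetic
signal.

The statistical core is a weighted phylogenetic generalized least
squares (PGLS) model with jointly estimated Pagel's λ and per-species
sampling error:

    y ~ N( Xβ,  σ² C(λ) + τ² diag(w²) ),    w_i = 1/√n_i

where `C` is the Brownian variance–covariance matrix of the phylogeny
(`C[i,j]` = shared root-to-MRCA branch length), `C(λ)` scales its
off-diagonals by λ ∈ [0, 1], and `n_i` is species *i*'s necropsy count.
β is profiled out by GLS; (λ, σ², τ²) maximise the exact multivariate
normal likelihood. Each model is additionally refit at λ = 0 and λ = 1
and compared by AIC = −2 ln L + 2k, p-values are Benjamini–Hochberg
FDR-adjusted within each result table, and residual diagnostics
(Shapiro–Wilk, a Breusch–Pagan-type score test, VIFs) are computed on
normalized residuals.

Around that core the package provides:

* **Cohort handling** — necropsy tallies to prevalences, the ≥ 20-record
  filter, exclusion logging, 1/√n sampling weights
  (`readCohortTable`, `filterCohort`, `samplingWeight`).
* **Active-element classification** — RepeatMasker `.out` / BED parsing;
  L1s within ±10% of the 6.1 kb consensus and SINEs of 100–400 bp, both
  ≤ 5% diverged (`readRepeatAnnotation`, `isActiveL1`, `isActiveSine`,
  `countActiveElements`).
* **Proximity and genic insertion** — closest-feature distances
  (edge-gap convention), IQR-trimmed distance summaries, unique-overlap
  insertion counts (`closestDistances`, `proximityStats`,
  `genicInsertionCount`).
* **Cancer-gene-ortholog load** — OrthoFinder orthogroup parsing and
  per-category CGO counting (`readOrthogroups`, `countCgo`).
* **Trait transforms** — Tukey ladder of powers (Shapiro–Wilk
  objective), min–max normalization, Grubbs outlier screening
  (`tukeyTransform`, `minmaxNormalize`, `grubbsTest`).
* **Synthetic data** — seed-deterministic generators for ultrametric
  trees, λ-structured traits, binomial necropsy tallies, and annotation
  landscapes with brute-force ground truth (`simulateTree`,
  `simulateTraits`, `simulateNecropsies`, `simulateRepeatLandscape`,
  `simulateStudy`).
* **Pipeline** — the four model families (Abundance, Proximity,
  Genic-Insertion, Cancer Gene Load) × {neoplasia, malignancy} ×
  {L1, L1+SINE} × {± longevity} from one YAML config
  (`runPipeline`, `buildPredictorTable`), plus a thin CLI at
  `inst/cli/retroprev.R` (`run` / `simulate` / `validate`).

## A worked example

Fit a weighted λ-PGLS on simulated data with a known slope of 0.8 and
λ = 0.6:

```r
library(retroprev)

tr <- simulateTree(40, seed = 7)          # pure-birth ultrametric tree
C  <- vcvFromTree(tr)
set.seed(8)
df <- data.frame(x = rnorm(40), row.names = tr$tip.label)
df$y <- 0.8 * df$x + as.vector(simulateTraits(C, lambda = 0.6, sigma2 = 0.4))

fit <- fitPgls(y ~ x, df, C)
fit
#> PglsFit: y ~ x
#>   n = 40 species; lambda (ML) = 0.4148; sigma2 = 0.3426; tau2 = 0
#>             Estimate  StdErr        t       p
#> (Intercept) -0.38503 0.19202 -2.00516 0.05211
#> x            0.79034 0.07559 10.45498 0.00000
#>   logLik = -32.194; AIC = 72.388 (k = 4); R2 = 0.7321

compareLambdaModels(y ~ x, df, C)$table
#>      model    lambda    loglik k       aic
#> 1  lambda0 0.0000000 -36.94495 3  79.88990
#> 2 lambdaML 0.4147765 -32.19401 4  72.38802
#> 3  lambda1 1.0000000 -87.51584 3 181.03168
```

The true slope 0.8 is recovered (0.790 ± 0.076) and strongly
significant; the λ estimate (0.41, with Monte-Carlo scatter around the
simulated 0.6) beats both the star-phylogeny (λ = 0) and
Brownian-motion (λ = 1) fits on AIC, the λ = 1 model being far worse —
the typical pattern when phylogenetic signal in the residuals is
moderate.

A complete scaled-down study — cohort, tree, per-species annotations,
orthogroups, config — ships as a synthetic fixture:

```r
report <- runPipeline(system.file("extdata", "synthetic-study",
                                  "config.yaml", package = "retroprev"))
subset(report$models, model_id == "abundance.neoplasia.n_combined",
       c(n_species, slope, p, p_adj, lambda_hat, r2))
#>   n_species     slope            p        p_adj lambda_hat        r2
#> 3        12 0.4891403 2.218747e-07 8.874987e-07          1 0.9271233
```

The fixture was generated with a positive effect of combined L1+SINE
burden on neoplasia prevalence, and the pipeline recovers it: a
positive, FDR-significant slope. Each `report$models` row carries the
model's n, slope, p, FDR-adjusted p, λ̂, R², the λ ∈ {0, λ̂, 1} AIC
triple, and residual diagnostics.

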