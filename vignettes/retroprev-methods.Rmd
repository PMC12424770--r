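---
title: "Methods: retrotransposon activity, cancer gene load, and cancer prevalence across mammals"
author: "retroprev authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrotransposon activity and cancer prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question

Across mammals, both the burden of recently active non-LTR
retrotransposons (nLTRs: autonomous LINE-1 elements and the SINEs they
mobilise in trans) and the size of a species' cancer-gene repertoire are
plausible correlates of cancer susceptibility. `retroprev` implements a
reusable, tested version of the comparative analysis that asks: do
species with more potentially active L1/SINE copies, with active copies
closer to (or inside) protein-coding genes and cancer gene orthologs
(CGOs), or with more CGOs, show higher neoplasia and malignancy
prevalence in necropsy records?

Species are not independent observations — closely related species share
both genome composition and physiology — so every regression is a
phylogenetic generalized least squares (PGLS) fit with the residual
covariance structured by the phylogeny, and prevalence estimates from
small necropsy samples are noisier than those from large ones, so each
species carries a sampling-error term scaled by $1/\sqrt{n}$.

## Data model

**Cohort.** Each species contributes necropsy tallies: total necropsies
$n$, necropsies reporting any tumor (neoplasia), and necropsies reporting
malignant tumors. Prevalence is the plain fraction (neoplasia prevalence
$=$ tumor-positive necropsies / $n$), stored as a fraction in $[0,1]$;
percentages are formatting only. Species with fewer than 20 necropsies
are excluded (prevalence from tiny samples is dominated by sampling
error), as are species with zero recorded neoplasia or malignancy —
cancer occurs in essentially all mammals, so observed zeros in this range
of sample sizes are undersampling artifacts, not biology. Whether
zero-malignancy species are dropped globally or only from malignancy
models is a genuinely open choice; the default drops them globally (the
stricter reading), and `filterCohort(require_malignant = FALSE)` gives
the permissive alternative. Missing longevity drops a species only from
models that include longevity, never globally, to maximise per-model
sample size.

**Repeat annotations.** RepeatMasker-style annotations are read either as
native `.out` files (1-based inclusive) or as the BED dialect produced by
`rmsk2bed`-style conversion (0-based half-open); both normalise to the
same intervals. An element is *potentially active* — a recent, intact
insertion — if it is an L1 within $\pm 10\%$ of the 6.1 kb consensus
length (5490–6710 bp) or a SINE of 100–400 bp, in both cases with
$\le 5\%$ divergence from the family consensus. All bounds are
inclusive: the divergence bound is stated as $\le$, and the length
bounds follow the same convention (the thresholds are configurable, so
the exclusive reading can be tested). Element length is the annotated
interval length; fragments split across annotation rows are not merged —
there is no defragmentation step, and full-length filtering makes
merging moot for L1. Divergence is taken from the annotation's per-hit
substitution percentage as given, not recomputed.

**Proximity and genic insertion.** Distances from active elements to
their nearest gene use a pure edge-gap convention: overlap (≥ 1 shared
base) and bookended intervals are distance 0; otherwise the gap in
bases. Some closest-feature tools report gap + 1 for non-overlapping
pairs; because every inference is a relative cross-species comparison
the choice is immaterial, and the `gap1` dialect is available as a
switch. Strand is ignored. Queries on chromosomes without any target are
excluded from the statistics and counted, never given sentinel
distances. Because genomic distance distributions are heavy-tailed, the
per-species summary is the median plus the *IQR mean*: the mean over
distances inside the Tukey fences $[Q_1 - 1.5\,\mathrm{IQR},\,
Q_3 + 1.5\,\mathrm{IQR}]$, with quartiles by linear interpolation
between order statistics (position $(n-1)p$ — the default convention of
mainstream statistical environments; the quartile type is configurable
because conventions differ). Genic-insertion counts are the number of
active elements overlapping at least one gene by at least one base, each
element counted once however many genes it overlaps. Gene intervals are
taken as given spans (no exon/transcript resolution); distances for
combined L1+SINE models pool both superfamilies' distances rather than
averaging per superfamily first.

**Cancer gene orthologs.** Orthogroup tables in the OrthoFinder text
layout are parsed and cross-validated (member lists versus gene counts).
Each cancer gene contributes, to each species, that species' gene count
in the orthogroup containing the gene's query protein; unassigned
proteins contribute zero (no detectable ortholog) rather than erroring.
Counting is per cancer gene: two cancer genes collapsing into one
orthogroup both contribute the species count. This matches counting
"orthologs for each cancer gene"; a `dedupe` switch collapses shared
orthogroups for sensitivity analysis. Genes whose role is *both*
oncogene and tumor suppressor contribute to both category tallies —
deliberate double counting, which inflates the oncogene–TSG correlation
and is therefore surfaced in the interrelationship panel rather than
hidden.

## Trait transformation

Prevalences and count predictors are strongly right-skewed with many
zeros. Each response and predictor is passed through Tukey's ladder of
powers: over a grid of exponents $p \in [-2, 2]$ in steps of 0.025, the
transform $x^p$ ($p>0$), $\log x$ ($p=0$), or $-(x^p)$ ($p<0$, sign flip
preserving order) that maximises the Shapiro–Wilk $W$ of the transformed
vector is selected. The objective and grid mirror the conventional
ladder-search implementation; both are configurable. Vectors containing
zeros restrict the grid to positive powers rather than receiving an
arbitrary offset (an optional `offset` argument exists). Note one
practical caveat established by the test suite: when a variable's
coefficient of variation is small, all powers act nearly affinely and
the $W$ profile is almost flat, so the selected exponent is weakly
identified — harmless, because all near-optimal exponents give nearly
identical transformed data.

After transformation, predictors (not the response) are min–max
normalised to $[0,1]$ so that effect sizes are comparable across models.
Transform first, then normalise: normalisation is affine and does not
change Shapiro–Wilk, so the other order would make the ladder search
operate on an arbitrarily scaled variable for no benefit.

Longevity outliers (and CGO-count outliers) are screened with Grubbs'
test — $G = \max_i |x_i - \bar x| / s$ against the classical critical
value from the $t$ quantile at $\alpha/(2n)$ with $n-2$ df — but flagged
points are *reported, never removed*: exceptionally long-lived or
gene-rich species are biology, not error.

## The statistical core

The regression model is

$$ y \sim \mathcal{N}\!\big(X\beta,\; \sigma^2 C(\lambda) + \tau^2
\operatorname{diag}(w^2)\big), $$

where $C$ is the Brownian-motion variance–covariance matrix of the
phylogeny ($C_{ij}$ = shared root-to-MRCA branch length), $C(\lambda)$
multiplies its off-diagonal entries by Pagel's $\lambda \in [0,1]$, and
$w_i = 1/\sqrt{n_i}$ is the per-species sampling-error scale. $\beta$
is profiled out by GLS at each variance-parameter value; the variance
parameters (and $\lambda$, unless fixed) maximise the exact multivariate
normal log-likelihood (ML by default; REML available).

Design choices worth making explicit:

* **Sampling-error scale.** After Tukey transformation the response is
  on an arbitrary scale, so the raw $1/\sqrt n$ weights cannot enter
  with a fixed unit variance. The default therefore estimates a
  proportionality constant $\tau^2$ (internally $V = \sigma^2(C(\lambda)
  + \gamma D)$ with $\gamma = \tau^2/\sigma^2$ profiled), which makes
  the fit invariant to the unknown weight scale. A strict mode
  (`tau = "fixed"`) pins $\tau^2 = 1$ for the classical
  known-measurement-error formulation. When all weights are zero the
  term vanishes and is not counted as a parameter.
* **$\lambda$ search.** $\lambda$ is restricted to $[0,1]$ and located
  by an 11-point grid on the interval, Brent refinement inside the
  bracketing subinterval, and an explicit comparison against both
  boundaries. This is a denser deterministic multi-start than a few
  random initial points, is robust to the mild multimodality of
  $\lambda$ profiles, and can return exactly 0 or 1 — so when
  $\hat\lambda = 0$ the estimated-$\lambda$ fit reproduces the
  $\lambda=0$ fit's likelihood exactly.
* **Inference.** Coefficient tests are $t$-tests on $n - p$ df (the
  conventional GLS choice). $R^2$ is GLS-weighted:
  $1 - e^\top V^{-1} e \,/\, y_c^\top V^{-1} y_c$ with $y_c$ the
  response centred at its GLS (intercept-only, same $V$) mean; adjusted
  $R^2$ uses the usual $(n-1)/(n-p)$ correction. Because published
  comparative analyses rarely state which $R^2$ they report, absolute
  $R^2$ values are comparable only within this package.
* **AIC.** $\mathrm{AIC} = -2\ln L + 2k$ with $k$ = coefficients
  $+\,\sigma^2$ $+\,[\lambda\ \text{estimated}]$
  $+\,[\tau^2\ \text{estimated}]$. Each model is refit with $\lambda$
  fixed at 0 (star phylogeny) and 1 (Brownian motion) alongside the
  estimated-$\lambda$ fit; the estimated fit carries one extra
  parameter, and its log-likelihood can never fall below either fixed
  fit's.
* **Diagnostics.** Residual checks are computed on normalized residuals
  $V^{-1/2} e$: Shapiro–Wilk for normality, a Breusch–Pagan-type score
  test (squared normalized residuals on fitted values, $nR^2$ against
  $\chi^2_1$) for heteroscedasticity, and variance inflation factors
  $1/(1-R^2_j)$ for multiple regressions, flagged above 5. Multiple
  testing is controlled at 5% FDR with Benjamini–Hochberg, applied
  within each model-family × response result table (the granularity at
  which results are reported); a global family is available by
  configuration.

## The synthetic-data generator

No real genomes or necropsy databases ship with the package; every
pipeline stage is exercised against generated data carrying exact ground
truth.

* **Phylogenies** are pure-birth (Yule) trees rescaled to unit depth —
  the simplest ultrametric model; tree shape is not a quantity of
  interest here.
* **Traits** are drawn from exactly the generative model the fit
  assumes, $\mathcal{N}(X\beta, \sigma^2 C(\lambda) +
  \operatorname{diag}(w^2))$, so parameter-recovery and type-I-error
  simulations probe the estimator, not a model mismatch.
* **Necropsy tallies** are hierarchical binomials: neoplasia counts
  binomial in the necropsy total, malignant counts binomial in the
  neoplasia count, so the count nesting holds by construction.
* **Annotation landscapes** place genes and repeats uniformly on a
  synthetic chromosome; active elements are constructed inside the
  activity windows and inactive ones to violate at least one criterion.
  Ground-truth distances and overlap counts come from an independent
  $O(nm)$ brute-force scan, and repeat–repeat overlap is not prevented
  (no analysis metric depends on repeat–repeat arrangement).
* **The full study generator** couples these: true neoplasia prevalence
  is $0.05 + 0.35 \cdot \text{minmax(combined active count)}$ plus a
  $\lambda$-structured deviation (λ = 0.5, sd 0.05), clamped to
  $[0.01, 0.95]$; 45% of neoplasia cases progress to malignancy;
  necropsy totals are $20 + \mathrm{NB}(\mu = 80, k = 2)$ per species.
  These defaults are chosen once as a plausible, strongly powered
  regime: prevalence spans roughly 0.05–0.45 across species, as in
  large zoological necropsy compilations, and the effect is strong
  enough that an analysis of ~25–55 species should detect it
  essentially always, making end-to-end recovery a meaningful check of
  the plumbing rather than a marginal power experiment.

What the generator does **not** emulate: assembly-quality variation and
annotation error, fragmented elements, gene-density heterogeneity along
chromosomes, correlated placement of repeats and genes, body-mass or
life-history confounding, and non-binomial overdispersion of necropsy
outcomes. Passing tests therefore demonstrate that the machinery is
correct under its assumed model, not that the biological findings would
replicate on real genomes.

## Problem sizes used in the checks

The shipped checks use deliberately scaled-down sizes chosen to keep the
whole suite fast while leaving Monte-Carlo error well inside the margins
being asserted: interval oracles on hundreds of random instances of up
to 200×200 intervals; λ/slope recovery on a 200-tip tree (100 replicates
per λ value); type-I error on a 100-tip tree (1000 replicates in the
test suite); end-to-end recovery on 100 replicate studies of 25 species
with ~100-element landscapes. The bundled example study
(`inst/extdata/synthetic-study`) is a 12-species fileset generated by
the same code path.

## Numerical and degenerate-input behaviour

Cholesky factorisation underlies every likelihood evaluation; a
covariance that fails to factor gets one retry with a tiny diagonal
ridge ($10^{-8}$ of the mean tip depth), and failure after that is an
error, never a silent fallback. Noise-free data (zero residual variance)
are handled by flooring the profiled $\sigma^2$ at the smallest positive
double, so exact interpolation returns the exact coefficients with
$R^2 = 1$. Constant vectors are rejected by the transforms and
correlation; empty distance sets are an error ("no distances
computable") rather than a zero. Filtering is idempotent, and every
exclusion — cohort thresholds, target-free chromosomes, unassigned
cancer genes, per-model missing data — is logged with a reason rather
than silently dropped.

## Known limitations

* The PGLS machinery covers Gaussian responses only — no phylogenetic
  logistic/Poisson models, Ornstein–Uhlenbeck correlation structures, or
  ancestral-state reconstruction.
* Prevalence enters as a transformed continuous response, as in the
  source analysis framework, rather than through a binomial likelihood;
  the $1/\sqrt n$ weighting is the standard compensation.
* Orthology, repeat annotation, and gene-model inference are upstream of
  this package: it consumes their text outputs and inherits their
  errors.
* The λ-model AIC comparison penalises the estimated-λ model by one
  parameter even when $\hat\lambda$ lands on a boundary, where the usual
  regularity conditions for AIC do not strictly hold; interpret
  near-ties accordingly.
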