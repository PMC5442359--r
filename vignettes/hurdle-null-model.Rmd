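---
title: "A hurdle negative binomial null model for Hi-C interaction calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hurdle negative binomial null model for Hi-C interaction calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicnull)
```

## The model

A Hi-C contact matrix entry $(i, j)$ holds the count $y_{ij}$ of unique
read pairs joining genomic intervals $I_i$ and $I_j$.  Even deep
experiments are dominated by background: random ligation whose rate decays
with the genomic distance $d_{ij}$ between interval midpoints, scaled by
sequence biases.  `hicnull` models that background per chromosome as a
hurdle (zero-truncated) negative binomial regression:

$$
P(y_{ij} = 0) = \pi_{ij}, \qquad
P(y_{ij} = y \mid y \ge 1)
  = \frac{f_{NB}(y;\, \mu_{ij}, \alpha)}{1 - f_{NB}(0;\, \mu_{ij}, \alpha)},
$$

with a log-linear mean

$$
\log \mu_{ij} = \beta_0 + \sum_k \beta_k B_k(d_{ij})
  + \beta_{gc}\, x^{gc}_{ij} + \beta_{map}\, x^{map}_{ij}
  \;(+\; \beta_{eff}\, x^{eff}_{ij}),
$$

NB2 dispersion $\alpha$ ($\mathrm{Var} = \mu + \alpha\mu^2$) shared across
the chromosome, and a logit model $\pi_{ij} =
\mathrm{logit}^{-1}(\gamma' x_{ij})$ over the same design.  Two properties
of Hi-C counts motivate the two parts: overdispersion (clonal ligation,
locus-level variability) and zero inflation (library drop-out of rare
ligation products, analogous to drop-out in single-cell RNA-seq).  A null
model lacking either — a Poisson or plain NB regression, or a binomial
background — understates the null tail and inflates significance; the
package's `model = "poisson"` variant exists precisely to demonstrate that
inflation on overdispersed data.

Significance is the upper tail of the fitted null:
$p_{ij} = P(Y \ge y_{ij})$, so $y = 0$ gives $p = 1$ and $y = 1$ gives
$1 - \pi_{ij}$, computed in log space.  q values are Benjamini–Hochberg,
pooled across chromosomes after per-chromosome fitting (a per-chromosome
mode exists); pooling matches genome-wide FDR reporting.  O/E
normalization divides $y_{ij}$ by the mean of the full hurdle law,
$E[Y] = (1-\pi)\mu / (1 - f_{NB}(0;\mu,\alpha))$.

### The distance basis

The distance decay is a B-spline in raw genomic distance with six degrees
of freedom, inner knots at the 25/50/75% quantiles of the training
distances, and boundary knots at 0 and 2 Mb (the intra-chromosomal
distance cap).  We read "order 3" literally — an order-3 (quadratic)
basis — because that is the only convention under which the stated knot
arithmetic (inner knots = df − order, 3 = 6 − 3) and the basis-function
count are simultaneously consistent; the six functions of the full basis
with boundary multiplicity 3 then form a partition of unity, equal
$(1,0,\dots,0)$ at $d = 0$, and are evaluated by the Cox–de Boor recursion
(`splines::splineDesign`; an independently hand-coded recursion serves as
the test oracle).  Because a partition of unity is collinear with an
intercept, the regression design drops the first basis function and keeps
an explicit intercept — a pure reparameterization spanning the same
function space, so fitted decay curves are unaffected.  The package
reports coefficients as `(Intercept), s1..s5, gcz, mapz[, effz]`.

### Covariates

Per bin, GC content and mappability are averaged over the *effective
regions* — bases within 500 bp of a restriction site, the only places a
ligatable read can start.  Pair-level raw features are the product of the
two bins' values (the HiCNorm convention for bias covariates; whether the
original combined by product or mean is not stated), log-transformed and
z-scored per chromosome over **all** enumerated records, not the training
sample, so covariates do not depend on the sampling seed.  With uniform
bins the product of effective fractions enters as an additional
"effective sequence space" covariate.  Bins with no restriction site,
all-N effective sequence or zero mappability stay in the bin table but
their records are excluded from fitting and reported with `NA` p values.

### Two-pass training

`estimate_null()` draws a seeded simple random sample of records (1% by
default; the seed is a required, logged argument), fits the hurdle model,
computes each training record's upper-tail probability under its own
fitted law, removes records with tail probability below $0.025$ (the
97.5% trimming rule; candidate true interactions), and refits on the
remainder with the same knots.  Both fits are kept: `fit1` (pass 1) and
`fit` (pass 2), and `plot()` overlays their decay curves.

Two numerical consequences are worth knowing.  First, on *pure null* data
trimming removes genuine upper-tail counts, so the pass-2 null is slightly
deflated — by design: the procedure trades a conservative bias for
robustness against contamination by real interactions.  The tests
therefore check the p-value calibration and O/E unbiasedness contracts on
the untrimmed maximum-likelihood fit, where both hold with room to spare,
and check the trimmed fraction (≤ 2.5% + tolerance) separately.  Second,
the deflation concentrates where counts are small and discrete — the
longest distances — because removing the few records with $y \ge 3$ there
excises a large share of the positive mass.  In our simulations this
deflation exceeds the perturbation that a 1% contamination of 5× spikes
inflicts on pass 1, so pass-2 coefficients are usually *farther* from the
generating coefficients in L2 on contaminated-null data, even though the
trimmed fit is the right null for calling; one acceptance check asserts
the opposite ordering and is accordingly left failing rather than
weakened.

### Optimization and numerics

The two likelihood parts are separable.  The zero part is fit by
iteratively reweighted least squares with a fixed ridge of $10^{-6}$ on
all coefficients, which keeps complete separation (e.g. no zero counts)
finite with a warning.  The count part maximizes the zero-truncated NB
log-likelihood over $(\beta, \log\alpha)$ by BFGS with analytic gradients,
initialized from a Poisson fit to the positive counts and $\alpha = 0.5$,
with $\log\alpha$ clamped to $[-20, 10]$.  Convergence requires the mean
per-observation score below $10^{-6}$ in max-norm and a relative
log-likelihood change below the optimizer tolerance; fits that miss it are
returned with `converged = FALSE` and a warning.  Wald standard errors
come from the observed information (numerical Hessian with analytic
gradient for the count part, penalized IRLS information for the zero
part).  Tail quantities use `pnbinom`/`ppois` in log space;
$\alpha < 10^{-12}$ switches to the exact zero-truncated Poisson limit.

## The synthetic world

`simulation_scenario()` fixes the generator's stated world once:
MboI-like digestion (target fragment spacing 256 bp, matching the motif's
expected frequency), GC around 0.41 with isochore-scale (100 kb)
sinusoidal variation, mappability near 0.9 with smooth dips, a decay from
$\mu \approx 20$ at zero distance to $\approx 0.25$ at 2 Mb, zero
inflation rising from ~0.12 to ~0.80 with distance, NB2 dispersion 0.3,
and spikes of 1% of mid-range records at 5× the local mean.  These values
were chosen once as desk-scale analogues of a deep, fine-binned
experiment and are not adjusted to test outcomes.  Spiked records are
redrawn from the full hurdle law with mean $5\mu$ — keeping the zero gate,
so `spike_fold = 1` reproduces the null exactly (redrawing only the
positive part would make fold 1 detectably non-null, breaking
self-consistency).

Two generators exist deliberately.  `simulate_dataset()` runs the whole
chain (toy FASTA → digestion → binning → features → enumeration → counts)
and exercises plumbing; `simulate_records()` draws records directly with
uniform distances and standard-normal covariates so that every spline
column has support — the right harness for estimator properties (coverage,
error decay), which on a 300 kb toy chromosome would otherwise be
confounded by unsupported long-distance basis columns.  Stage seeds are
derived from the scenario seed by an LCG scramble rather than `seed +
offset`: adjacent Mersenne–Twister seeds are not reliably independent,
and with plain offsets the covariate stream of one replicate coincided
with the count stream of another, visibly tilting coefficient recovery.

What a green simulation test does **not** establish: the generator is the
model, so passing tests demonstrate correct inference under correct
specification, plus the intended direction of misspecification effects
(Poisson inflation).  Real Hi-C adds TAD structure (distance-matched
records are not exchangeable), distance-varying dispersion, and
inter-chromosomal contacts — all outside this null and listed as known
limitations below.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `max_distance` | 2 Mb | bp | sub-TAD focus; spline boundary knot |
| `n_per_bin` / `bin_width` | 10 / 5 kb | fragments / bp | fragment-merged vs uniform binning |
| `flank` | 500 | bp | effective region around a restriction site |
| `sample_frac` | 0.01 | — | training sample; the model needs only a sample |
| `outlier_q` | 0.975 | — | trimming quantile (a "top 3%" reading appears in one figure caption; the Methods value is authoritative) |
| `fdr` | 0.01 | — | significance threshold on BH q |
| `include_diagonal` | TRUE | — | drop only for comparisons with tools that filter $d=0$ |
| `seed` | required | — | training-sample draw; logged and serialized |

## Downstream analyses

Hotspots: per bin, the maximum $-\log_{10} p$ over incident significant
(q < FDR) records at distance > 50 kb.  Enrichment: contacts partitioned
into 10 kb distance bands; per band and unordered label pair, a one-sided
Fisher exact test of significant × label-bearing (an enrichment question,
hence one-sided; two-sided available); band p values pooled over 100 kb
(epigenomic) or 50 kb (genomic) regions and compared against all other
label pairs by one-sided Wilcoxon rank-sum (midranks under ties; both the
statistic and p are reported since the figure-level "relative enrichment"
quantity is ambiguous).  Compartments: counts aggregated to 100 kb
meta-bins, PC1 of the row-correlation matrix, sign oriented so the group
richer in open-chromatin signal (DNase peak density when available, else
GC) is "A".  Downsampling: an exact multivariate-hypergeometric thinning
of the read list, preserving totals; precision-recall against full-depth
truth (positives q < 0.05, negatives q > 0.1, the stratum between
excluded).  Promoter networks: significant 1.5–2 Mb records with both
endpoints promoter-labelled, with per-chromosome counts (raw and per Mb)
and connected components.

## Degenerate inputs and tie-breaks

Empty site lists are valid (one fragment per chromosome; effective
fraction 0).  Remainder fragments at a chromosome end form a final short
bin.  All-tied training distances nudge knots apart deterministically.
Records at zero expected count get `NA` O/E with a warning.  A chromosome
whose fit fails is skipped with a warning naming it; other chromosomes
are unaffected and its records keep `NA` p.  BH passes `NA` through
without counting them as tests.

## Known limitations

Fixed $\alpha$ per chromosome (dispersion demonstrably varies with
distance); no modelling of hierarchy among bins (TAD-internal pairs are
treated like any pair at that distance); intra-chromosomal only; pair
counting assigns by coordinate-in-bin rather than fragment identity;
restriction motifs must be palindromic (MboI, HindIII, NcoI built in).
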