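---
title: "Methods: statistics of a dual-assay gene-trap radiation screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics of a dual-assay gene-trap radiation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapscreen)
```

## The screen and its data model

A gene-trap screen irradiates a library of mutant ESC clones — each carrying
one defined insertional mutation with a β-geo reporter — at several absorbed
doses (Gy) plus a 0-Gy control, and assays every clone 24 h later in
duplicate wells. Two luminescent readouts are taken per well: the
cytotoxicity assay's dead-cell and total-cell protease signals (RLU), and
β-galactosidase activity reporting the trapped gene's expression. Wild-type
ESC replicate wells, which carry no trap, accompany the clones as the
viability control; they have no β-gal signal.

`trapscreen` stores the data long, one row per well, and derives the
live-cell signal as `total − dead` — the assay measures dead cells first and
everything after lysis, so dead and total are the primary measurements.
Wells where the dead signal exceeds the total are physically impossible and
are excluded with a QC flag at load time. Doses are arbitrary non-negative
reals, so validation doses (2, 10, 15 Gy) parse without code changes.

## Viability statistics

Percent viability per well is $V = (\mathrm{total}-\mathrm{dead})/\mathrm{total}$.
Duplicates are averaged on the viability scale (averaging commutes with the
dose contrast, which the test suite checks), and each clone's response is
$\Delta V = V_{\mathrm{dose}} - V_{0\,\mathrm{Gy}}$.

The wild-type replicate wells define the null:
$z = (\Delta V - \mu_{wt})/\sigma_{wt}$ with $\mu_{wt}, \sigma_{wt}$ the
per-dose sample mean and SD (denominator $n-1$; the control sample is small,
typically 22 wells, so the unbiased-variance convention matters). Nulls are
fitted **per dose contrast**: the published tables imply clearly different
scales at 0.5 Gy and 4 Gy (≈ 0.067 vs ≈ 0.080), so pooling doses would
miscalibrate both. P-values are two-tailed normal, $p = 2\Phi(-|z|)$,
computed with the full-precision tail; for finite $z$ the result is never
exactly 0 (the smallest positive double is substituted at underflow and the
exact `log10_p` is carried alongside). Hits at $p < 0.01$ are partitioned by
dose and direction.

Direction is the sign of $\Delta V - \mu_{wt}$, not of raw $\Delta V$: a
clone drifting exactly with the wild type should not be called directional.
For real hit tables the two signs coincide because hit effects dwarf
$|\mu_{wt}|$. The phrase "normalized to the wild-type change" is implemented
*once*, as the Z-score centering itself — not as an extra subtraction before
scoring.

`implied_null()` inverts the published tables: since $z$ is affine in the
statistic, an OLS fit of printed Z on printed $\Delta V$ recovers
$\sigma_{wt}$ (inverse slope) and $\mu_{wt}$ ($-$intercept/slope) to the
rounding precision of the printed values. The back-fit gives
$\mu_{wt} = -0.0149$, $\sigma_{wt} = 0.0665$ at 0.5 Gy and
$\mu_{wt} = -0.0272$, $\sigma_{wt} = 0.0800$ at 4 Gy — consistent with a
wild-type viability loss under 3% even at the high dose — and these values
seed the synthetic generator's defaults.

## Expression statistics

Normalized expression is β-gal RLU divided by live-cell RLU; wells with no
live signal are dead-well errors and their clones are excluded from the
expression analysis (with a message). Duplicates are averaged at the
normalized-expression level, and the per-clone response is
$\log_{10}(E_{\mathrm{dose}}/E_{0\,\mathrm{Gy}})$ — base 10 is pinned by the
convention $\log(2.76) = 0.44$ used in the screen's reporting.

There is no wild-type control for this assay, so the null must come from
the clone population itself, which *contains* the true hits as outliers. The
package estimates it with a RANSAC-style robust consensus:

1. Draw `n_iterations` (default 2000) random minimal samples of
   `min_sample` (default 5) values; each proposes a candidate centre (its
   mean).
2. Score each candidate by the **median absolute residual** over all values
   (the least-median-of-squares criterion) and keep the best.
3. Take as consensus the values within `inlier_threshold` (default 2.5)
   robust-scale units (1.4826 × the best median residual) of the winning
   centre, then refine by iterated hard rejection: refit mean and SD on the
   inliers, re-select inliers within 2.5 refitted SDs, repeat to
   convergence.
4. Report the consensus mean, the consistency-corrected consensus SD, and
   the inlier ids. A consensus below `min_consensus_fraction` (default 0.5)
   of the data is a failure, with advice to fall back to a trimmed estimate.

Two numerical choices deserve emphasis. First, the candidate score is the
median residual, **not** the inlier count within a candidate-scaled band.
Count-based consensus is degenerate in one dimension: a candidate whose
5-point sample happens to straddle both the null bulk and the outliers has a
huge SD, its band swallows every point, and the "largest consensus" is
always the full sample — simulation shows the resulting estimate equals the
naive mean at every contamination level. The least-median score has a 50%
breakdown point and no such failure mode. Second, the reported scale is the
consensus SD divided by the truncated-normal consistency factor
$\sqrt{1 - 2c\,\varphi(c)/(2\Phi(c)-1)}$ at $c$ = `inlier_threshold`
(0.9547 at $c = 2.5$), exactly analogous to MAD's 1.4826. Without it the
hard cut biases $\sigma$ low by ≈ 4.5% and inflates the null hit rate at
$\alpha = 0.01$ to ≈ 0.014. The correction is exposed as
`correct_scale = TRUE`.

With this estimator, simulation at the package's test sizes shows location
bias below $0.1\sigma$ up to 30% one-sided contamination at 5$\sigma$
(where the naive mean is biased by $1.5\times$ the contamination fraction),
agreement with plain sample moments within 0.02 on clean data, and an
empirical null hit rate at $\alpha = 0.01$ inside the exact binomial 95%
interval on a 10,000-test null screen.

Whether the published analysis used the consensus SD or a full-sample SD
after outlier removal is not recoverable; the consensus SD is implemented,
and `correct_scale`/`ransac_config()` expose the knobs. The hyperparameter
defaults are declared choices sized for ~400-point 1-D problems, not values
inferred from the publication, which names only "the robust RANSAC
algorithm".

## Enrichment

Hits are pooled across doses within each of four phenotype categories
(increased/decreased viability/expression). For each gene set, membership is
first intersected with the screened background (the analysis set of genes
with usable data — not the library, not the genome), giving the population
count $K$ with the same semantics as published "total in population"
columns. Terms with $K \ge 3$ screened members and $k \ge 2$ hit members
survive; the one-sided hypergeometric tail $P(X \ge k)$ is computed for the
survivors via `phyper`, and Benjamini–Hochberg q-values are computed **over
the surviving family only** (filtering before adjustment, so the family
size equals the number of tested terms). Symbols match case-insensitively
because mouse-symbol capitalization varies across annotation sources.
Annotations are counted flat, as given in the GMT; q-values therefore depend
on the annotation release, which is why the package validates the statistic
and the filter semantics, not any particular published q-value.

## The synthetic generator

`simulate_screen()` emulates the study conditions: 386 clones (one per
gene), 22 wild-type replicate units, doses 0/0.5/4 Gy, duplicate wells;
wild-type $\Delta V$ null with the back-derived per-dose means and SDs
above; mean 0-Gy viability 0.6; expression log-ratio null centred at 0 with
SD 0.14 (0.5 Gy) and 0.20 (4 Gy), the scales implied by the published
expression tables; planted hits additive on the viability fraction or on
log10 expression.

The configured null SDs are the SDs of the *observable* duplicate-averaged
statistics — that is what any downstream estimate converges to. Internally
each clone (or wild-type unit) receives one shared draw per dose, and wells
add independent Gaussian noise on the viability fraction
(`viability_well_sd`, default 0.046) and on log10 expression
(`expr_well_log10_sd`, default 0.028); the clone-level variance is obtained
by subtraction so the observable SD matches the configuration exactly. The
well-noise defaults are set so duplicate concordance lands near the
moderate (≈ 0.7, viability) and high (≈ 0.98, β-gal) Pearson correlations
reported for real screens of this design. Raw RLU magnitudes carry
multiplicative lognormal noise (`measurement_cv`, default 0.06) for realism;
it cancels in the normalized ratios the pipeline consumes, which is why the
structural noise is injected on the fraction/log scales where the
statistics live. Viability is clipped to [0.02, 0.98] (clipped wells are
counted and reported) to avoid degenerate RLU.

All draws derive from one config seed through fixed substream offsets, so a
config regenerates byte-identical data even after unrelated edits. The
generator does **not** emulate plate-geometry artifacts (edge effects,
gradients), between-day batch structure, or mechanistic dose-response
(LQ-type survival); passing tests therefore demonstrate the statistics'
calibration and power under the assumed noise model, not robustness to
spatial artifacts real plates may show.

## Calibration facts and limitations

- **Wild-type-null inflation.** With normal-quantile p-values and a null
  estimated from $n$ wild-type replicates, the exact null hit rate is
  $2\,P\!\left(t_{n-1} < z_{\alpha/2}/\sqrt{1+1/n}\right)$ — at $n = 22$,
  $\alpha = 0.01$ this is 0.0199, about twice nominal. This is a property
  of the published design (Z-scores with a 22-replicate null), not an
  implementation artifact; the unit suite verifies the pipeline reproduces
  exactly this rate. The expression path, whose null rests on the full
  clone population, is nominally calibrated. Users wanting exact viability
  calibration can enlarge the wild-type replicate set.
- **Power at the published effect sizes.** A planted $\Delta V$ of −0.30
  against $\sigma_{wt} = 0.0665$, or a log10 effect of ±0.9 against
  $\sigma = 0.20$, is an ≈ 4.5σ shift; with the estimated nulls the exact
  detection probability at $p<0.01$ is ≈ 0.96–0.97, which the acceptance
  suite measures over 50 seeded replicate screens.
- **Problem sizes.** The test suite uses 10,000 wild-type units for
  convergence checks, a 10,000-clone null screen for type-I calibration,
  100 robust-fit replicates of 400 points for the contamination sweep, and
  50 replicate screens of 100 clones for recovery — sizes chosen to put
  Monte-Carlo error well inside the asserted tolerances.
- **Underflow policy.** p-values are reported alongside `log10_p`; rendered
  tables print p in scientific notation (≥ 3 significant figures) with a
  `"<1e-300"` sentinel, so a printed 0 can never silently mean underflow.
- **ΔΔCt orientation.** ΔCt is reference-minus-gene, so positive ΔΔCt
  means up-regulation and fold change is $2^{\Delta\Delta Ct}$. This is the
  reverse of the more common gene-minus-reference convention; it is stated
  on the function and tested, to avoid silent sign errors.
- **Replicate-concordance metric.** Which metric the published duplicate
  correlations were computed on is unstated; the package uses the
  per-duplicate dose contrast against the clone's averaged 0-Gy reference
  (Pearson by default, Spearman optional). Reproducing any particular
  published correlation exactly would require the original well-level data.
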