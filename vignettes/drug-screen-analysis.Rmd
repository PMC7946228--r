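---
title: "Methods: from raw plates to response biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw plates to response biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrt)
```

`dsrt` implements the analysis chain of a multi-dose cell-line drug
sensitivity study: a primary 384-well viability screen scored by area
under the log-dose curve, live-cell growth-kinetics calls, growth-rate
corrected (GR) dose-response fitting, and expression-biomarker discovery.
This vignette explains each model, its assumptions, the tunable parameters
and their defaults, what the synthetic-data generator emulates, and the
numerical choices made where the design was genuinely open.

## The screen model

Each well's luminescence is proportional to ATP content, a proxy for the
number of viable cells. Per plate, normalized viability anchors on the
control medians:

$$v = \frac{\mathrm{signal} - \mathrm{med}(\mathrm{BzCl})}
           {\mathrm{med}(\mathrm{DMSO}) - \mathrm{med}(\mathrm{BzCl})}$$

where benzethonium chloride (BzCl) wells define complete kill and
DMSO-only wells no effect. Medians (not means) anchor the normalization so
a few aberrant control wells cannot shift an entire plate. Normalized
values may transiently leave $[0,1]$; they are deliberately *not* clipped
at this step, so plate QC sees over-unity wells, and the bounding happens
only inside the constrained smoothing step.

Plate quality is summarized by the z'-factor
$1 - 3(\sigma_{pos}+\sigma_{neg})/|\mu_{neg}-\mu_{pos}|$ (acceptable above
0.5) and, as a fallback for plates with inflated control variance, the
strictly standardized mean difference
$\beta = (\mu_{pos}-\mu_{neg})/\sqrt{\sigma_{pos}^2+\sigma_{neg}^2}$,
with $|\beta| \ge 3$ indicating adequate separation. The sign convention
puts a strong kill control at large negative $\beta$.

### Monotone-constrained smoothing

The five-point dose-viability profile is adjusted by a qualitatively
constrained median smoother: the closest curve under the $L_1$ norm that
is non-increasing in concentration and bounded in $[0,1]$. At five support
points a roughness penalty is negligible, so the smoother reduces exactly
to bounded antitonic $L_1$ regression, solved by pool-adjacent-violators
with block medians followed by clipping (clipping preserves optimality for
this separable convex program). The operation is idempotent and leaves any
already-monotone, bounded profile untouched. The test suite verifies
$L_1$-optimality against an exact dynamic-programming oracle over the full
grid of $11^5$ five-point profiles with values in $\{0, 0.1, \ldots, 1\}$.

### AUC scoring and hit selection

The combined-viability score is the trapezoidal integral of smoothed
viability over $\log_{10}$ concentration. With the standard design — five
10-fold concentrations from 1 nM to 10 µM — each panel has unit width and
the score runs from 0 (kill at every dose) to 4 (no effect anywhere):

```{r auc-examples}
conc <- 10^(0:4)
auc_score(smooth_profile(c(1, 1, 0.5, 0, 0), conc), conc)  # half effect: 2
auc_score(rep(0, 5), conc)                                 # complete kill: 0
auc_score(rep(1, 5), conc)                                 # inactive: 4
```

A compound is a hit when its score is at or below half scale (default
threshold 2.0, inclusive — "viability reduced to at least 50%") in at
least one cell line; hits rank by minimum score, then by the number of
qualifying lines. Untested compound–line cells are simply ignored.

## Growth kinetics from confluence series

Live-cell imaging yields percent confluence every 3 h. Two operational
concentrations are called per cell line × compound:

* **growth-reducing**: the lowest dose whose 40–72 h confluence change is
  significantly lower than vehicle. A one-way linear model on the window
  deltas feeds least-square-mean contrasts of each dose against vehicle
  (via `emmeans`), one-sided for a decrease with Holm adjustment at
  $\alpha = 0.05$. Holm is a deliberate, conservative choice — the
  contrast family needs *some* multiplicity control, and Holm requires no
  distributional extras. With replicate-identical (noise-free) input the
  residual variance is zero and t statistics are undefined; the call then
  degenerates to exact mean comparison, which is the correct limit.
* **growth-arresting**: the minimal dose whose 96–120 h change, median
  across replicates, stays below 3 percentage points of confluence. The
  "3%" is read as percentage points, not relative change, because
  confluence is reported in percent units throughout. The late window
  ensures arrest is stable rather than transient.

Window endpoints (40 h in particular) fall between 3-hourly samples and
are located by linear interpolation. Reversibility after drug withdrawal
has no standard numeric definition; for symmetry the same 3-point/72 h
criterion is reused: a condition is reversible when confluence gains at
least 3 percentage points in the 72 h after washout. Apoptosis summaries
classify the percentage-point increase of the apoptotic fraction over
control as strong (> 15), moderate (> 5) or none, and cell-cycle summaries
are kept only when some phase shifts by more than 5 points — both
thresholds strict, as printed.

## GR dose-response fitting

Relative viability conflates drug effect with growth rate: a slow-growing
line looks resistant simply because its untreated control grows little.
The GR value corrects this at the endpoint level:

$$\mathrm{GR}(c) = 2^{\log_2(x_c/x_0)/\log_2(x_{ctrl}/x_0)} - 1,$$

which is +1 for untreated growth, 0 for cytostasis and approaches −1 for
complete cell loss. GR requires control growth ($x_{ctrl} > x_0$) and is
invariant to the measurement scale. Dose dependence is modelled by the
three-free-parameter log-logistic curve

$$\mathrm{GR}(c) = \mathrm{GR}_{inf} +
  \frac{1 - \mathrm{GR}_{inf}}{1 + (c/\mathrm{GEC}_{50})^h},$$

fit by bounded Levenberg–Marquardt least squares with
$\mathrm{GR}_{inf} \in [-1, 1]$, $h \in [0.1, 5]$ and $\mathrm{GEC}_{50}$
within two decades of the tested range. Replicates enter the loss jointly,
without pre-averaging. Starting values multi-start over a 9-point
log-spaced GEC50 grid restricted to the tested concentrations (outside the
range the model is flat in GEC50 and the Jacobian singular) crossed with
hill starts {0.5, 1, 2}. The sigmoid must beat the flat constant-GR model
in an F-test at $\alpha = 0.05$; otherwise the fit is flagged
non-converged, the asymptote collapses to the mean GR and GR50 is reported
as the `Inf` sentinel ("beyond the tested range") rather than
extrapolated. GR50 itself is closed-form:
$\mathrm{GR}_{50} = \mathrm{GEC}_{50}\,((1-\mathrm{GR}_{inf})/(0.5-\mathrm{GR}_{inf}) - 1)^{1/h}$,
finite exactly when $\mathrm{GR}_{inf} < 0.5$.

### GR50 versus IC50

A frequently stated intuition is that the growth-rate correction can only
shift the half-effect concentration downward. That holds only for slowly
growing controls: at the relative-viability IC50, the GR value equals
$2^{1 - 1/n} - 1$ for $n$ control doublings over the assay, which crosses
0.5 at $n \approx 2.41$. Below that (e.g. 1.5 doublings in 72 h)
GR50 ≤ IC50; at 3 doublings the inequality reverses. The property test
therefore asserts the ordering at 1.5 control doublings, and the package
makes no general claim about the direction.

## Biomarker discovery

Expression preprocessing follows the standard FPKM pipeline: duplicate
gene rows resolved by keeping the highest-variance row, quantile
normalization across samples (`limma::normalizeQuantiles`, ties receiving
the mean of the spanned reference quantiles), then $\log_{10}(x + 10^{-5})$.
Genes below 10 FPKM in *every* line are dropped before single-gene
analysis; whether that floor should also restrict the enrichment ranking
is genuinely ambiguous, so the ranking defaults to all genes with the
filter available as an option.

Per compound, each gene's processed expression is rank-correlated
(Spearman, average ranks) with GR50 across the panel; since high GR50
means low sensitivity, $\rho < 0$ marks *sensitizing* genes. Two-sided
p-values use the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ — at $n = 13$ exact enumeration is
infeasible, and the suite cross-checks the approximation against the
exact permutation distribution at $n = 6$. A gene passes the single-panel
criterion at $|\rho| \ge 0.65$ and $p < 0.05$.

Robustness comes from leave-one-out cross-validation: the correlation is
recomputed once per cell line with that line excluded, and a biomarker
must satisfy $|\rho| > 0.8$ (strict, as printed) in **every** fold. A
sign-consistency requirement across folds is added — mixed-sign
"consistent" association is not meaningful — and any fold with undefined
$\rho$ disqualifies the gene. This construction specifically rejects
associations carried by one outlier line, which the single-panel test
cannot.

Pre-ranked gene-set enrichment uses the classic weighted
Kolmogorov–Smirnov running sum with weight exponent 1 on $|\rho|$. The
null comes from gene-label permutations; for a fixed ranking the null ES
distribution depends only on set size, so permutations are drawn once per
distinct size (1000 by default, seeded). NES divides ES by the mean
absolute null ES of matching sign; FDR follows the standard signed-pool
procedure on NES. Sets are restricted to genes present in the ranking and
to sizes 15–500. Significance is flagged at FDR < 0.001 and
$|\mathrm{ES}| > 0.5$. The running-sum statistic is verified against
brute-force enumeration on all small inputs and against an independent
implementation (`fgsea::calcGseaStat`).

## The synthetic-data generator

Every stage is exercised on data with known ground truth:

* **Plates**: expected drug-well signal
  `pos_level + v · (neg_level − pos_level)` with `v` the latent 4PL
  viability, so normalization is an exact round trip; multiplicative
  lognormal noise (plate reads are positive and right-skewed), default
  CV 5%; 16 DMSO + 16 BzCl wells per 384-well plate, positive-control
  floor at 1% of the negative level.
* **Confluence**: logistic growth with intrinsic rate
  $\ln 2 \times$ doublings/h, dose-dependent multiplicative rate
  suppression, additive Gaussian noise (default SD 1 percentage point,
  typical of live-cell imaging), truncated to $[0, 100]$; optional
  withdrawal with rate reversion for reversible truths.
* **GR assay**: treated endpoint counts constructed by inverting the GR
  transform, so the noise-free transform returns the latent GR exactly.
* **Expression**: lognormal background FPKM; planted biomarkers mix the
  standardized log-GR50 of their compound with unit Gaussian noise at a
  chosen signal-to-noise ratio, variance-standardized so planted genes
  stay on the background dynamic range; a configurable fraction of genes
  sits below the FPKM floor in all lines.
* **Gene sets**: uniform random draws plus an optional planted set.

A single run seed fans out to named per-stream child seeds
(`child_seed`), so adding a generator never shifts another's draws, and
identical configurations give byte-identical outputs.

What the generator does **not** emulate: spatial plate effects (edge
evaporation, dispense gradients), luminescence drift, contact inhibition
beyond simple logistic saturation, mixtures of cell populations,
expression covariance structure between genes, or batch effects. Passing
tests therefore certify the analysis logic under the stated noise models,
not robustness to these real-data artifacts.

## Default study shape and problem sizes

The default pipeline scenario mirrors the shape of a focused screen:
13 cell lines, 10 compounds of which 6 are planted hits, one plate per
line; kinetics, GR fits and biomarkers run on hit compounds only, as
downstream assays follow the screen's selection. Expression defaults to
600 genes with 3 planted biomarkers per hit and 40 random gene sets —
sizes chosen so a complete run takes seconds on a laptop while preserving
the panel shape. The heavier verification suites (the full $11^5$
smoothing grid, 100-seed kinetic and biomarker recovery runs, 1000
permutation GSEA) run inside the test suite in about a minute total.

## Known limitations

* The 4PL fit fixes the upper asymptote at 1; assays where even vehicle
  wells drift need a free upper asymptote.
* The flat-model F-test assumes approximately Gaussian residuals; heavy
  tails will over-reject the flat model.
* The Spearman t approximation is anticonservative for $n \lesssim 6$;
  the package targets panels of ~13 lines.
* FDR resolution is limited by the permutation count: with 1000
  permutations per size, FDR values below 1/1000 are reported as 0.
* Kinetic calls assume a shared sampling grid per condition and at least
  two replicates per dose.
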