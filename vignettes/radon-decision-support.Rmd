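---
title: "Adaptive fuzzy-rule and regression-tree decision support for indoor radon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive fuzzy-rule and regression-tree decision support for indoor radon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radonwatch)
```

## The problem

Radon (Rn-222) is a radioactive soil gas that accumulates indoors and is a
recognised lung-cancer risk. Whether a given concentration reading is
alarming depends on the weather: the stack effect (indoor-outdoor
temperature difference) draws soil gas into buildings, rainfall saturates
soil pores and suppresses exhalation, and concentrations are typically
higher at night and in winter. `radonwatch` implements a decision-support
pipeline for a continuously monitored room: it scores each twice-daily
sensor snapshot, adapts itself to the site as history accumulates, and
grades six concrete actions for the operator rather than raising a binary
alarm.

The pipeline has three stages, run per reading:

1. **FIS-1, correction factor** $F_c \in [0, 10]$. A weighted-rule
   Mamdani fuzzy inference system over the radon reading and seven
   atmospheric variables, expressing how favourable current conditions are
   to a radon rise.
2. **FIS-2, radon risk** $R_R \in [0, 100]$. A second Mamdani system
   combining the radon reading with $F_c$ into an exposure-hazard
   percentage.
3. **Six CART regression trees** trained on the accumulated, user-labelled
   knowledge base predict the strength, on $[0, 5]$, of six
   recommendations: three preventive (activate forced evacuation,
   de-activate forced evacuation, natural ventilation) and three checking
   (check sensors, check inference, check exposure time). They are drawn
   as a spider-web diagram.

## The inference systems

Both systems are Mamdani type with trapezoidal membership functions
throughout: every variable is partitioned into qualifiers (at least low /
medium / high) over its technical measurement range, rule antecedents are
combined with AND (minimum), implication truncates the consequent at the
weighted firing strength, aggregation is disjunctive (pointwise maximum),
and the crisp output is the centroid of the aggregated set, evaluated on a
uniform grid of 1001 points over the output domain (configurable; the
single-rule centroid error against the closed-form value is below $10^{-3}$
at that resolution).

### Rule base and adaptive weights

FIS-1's rule base pairs each atmospheric variable $v$ with the radon
reading: for every qualifier combination $(L_v, L_{radon})$ it contains a
*direct* rule `IF v is L AND radon is L_r THEN Fc is L` and its *inverse*
mirror with consequent low/high swapped — 7 variables x 9 combinations x 2
polarities = 126 rules, every one initialised at the standard weight 0.25.
Deliberately contradictory pairs coexist because the data decide between
them: after each ingested reading the Pearson correlation

$$\rho(a, b) = \frac{\mathrm{cov}(a, b)}{\sigma_a\,\sigma_b}$$

of each atmospheric variable with radon concentration is recomputed over
the stored history, and rule weights are rewritten through the sigmoid

$$w(\rho; b, c) = \frac{1}{1 + e^{-b(|\rho| - c)}},$$

applied to the absolute correlation. The sign acts only as a gate: a
positive $\rho_v$ gives the direct family of $v$ the transformed weight
and zeroes the inverse family, a negative $\rho_v$ mirrors the assignment,
and $\rho_v = 0$ (including the zero-variance degenerate case) gives both
families the same small weight $w(0)$ so an uninformative variable neither
dominates nor vanishes. Defaults $b = 10$, $c = 0.5$ give a smooth
mid-centred transition; both are user configuration, since moving the
centre left makes the system more sensitive to weak correlations and a
larger $b$ sharpens the low/high weighting split.

Two numerical choices matter here. Weights multiply the truncation level
(standard weighted-Mamdani semantics) and are used as given, without
renormalisation to unit sum — the centroid is scale-free when activations
stay proportional, and renormalising would couple unrelated variables.
And under the initial uniform 0.25 weights the mirrored rule pairs make
FIS-1 exactly symmetric, so $F_c$ is pinned at the domain midpoint 5 until
the first reweighting breaks the symmetry; this is the designed cold-start
behaviour (no evidence, no correction), not a defect.

### Degenerate inputs

Inputs outside a variable's technical range are clamped to the nearest
bound and flagged — a sensor spike should trigger the check-sensors
pathway downstream, not crash inference. If no rule fires (possible only
with a gutted rule base), the low-level centroid primitive raises an
error, and the system-level pass instead returns the output-domain
midpoint with a `no_rule_fired` flag that callers can escalate.

### The risk system

FIS-2's radon qualifiers are anchored at the regulatory reference levels:
the low plateau ends at the 100 Bq/m³ WHO reference, medium reaches full
membership at the 148 Bq/m³ EPA action level (4 pCi/L), and the high
plateau starts at the 300 Bq/m³ EU workplace reference (Directive
2013/59/EURATOM). Its nine rules ladder (radon level, $F_c$ level) onto
the risk consequent. A design point that was genuinely open: with only
three output qualifiers, adjacent antecedent cells necessarily share a
consequent, and under max aggregation the shared consequent's activation
dips at membership crossovers, producing dips of a unit or two in the
defuzzified surface. The shipped configuration therefore grades the risk
output over five qualifiers (very_low .. very_high) with the strictly
increasing consequent index $i + j - 1$; the resulting surface is
non-decreasing in both the radon reading and $F_c$ over a 50x50
verification grid, which is the property a risk score must have.

## Regression trees

The six recommendation trees are CART regression trees grown from scratch
on the shared 12-feature table (day serial, hour, the eight sensor
channels, $F_c$, $R_R$). Node impurity is the residual sum of squares

$$\sum_{k=1}^{m} (y_k - \bar y)^2,$$

candidate thresholds are the midpoints between consecutive distinct sorted
values of each feature, and the split minimising total child RSS is taken,
recursively, until a node is pure, the depth budget (default `max_depth`
5) or leaf floor (default `min_leaf` 2) is hit, or no split reduces the
RSS by `min_impurity_decrease` (default 0, i.e. any strict reduction
admits). Ties in RSS are broken by lowest feature index then lowest
threshold, which makes growing deterministic and invariant to row order.
Leaves predict their region mean, so predictions are convex combinations
of training labels and can never leave $[0, 5]$. Cost-complexity pruning
is out of scope; the depth and leaf-size limits are the stopping control.

Training is triggered whenever 14 new records have accumulated — one week
of twice-daily sampling — and each tree's RMSE
$\sqrt{\tfrac1n \sum (\hat y - y)^2}$ on the current training window is
reported as the monitoring statistic. Training-window RMSE is the shipped
default (a held-out split is a config option) because the statistic's role
here is drift detection: a previously near-zero RMSE that jumps after
retraining signals inconsistent labels or a failing sensor. The feature
order is frozen and fingerprinted; a serialized forest refuses to predict
on a differently ordered vector.

## The synthetic generator

`simulate_series()` emulates the study conditions: twice-daily readings at
12.00 and 24.00 h (the 24.00 h reading closes the named day), with day
serials in the spreadsheet convention that codes 2020-09-01 as 44075.
Weather channels are mean-reverting AR(1) processes (shared autocorrelation
0.8 per reading); rainfall is intermittent (30% wet readings, exponential
depth, mean 4 mm); and radon is

baseline 120 Bq/m³ + seasonal sinusoid (amplitude 40, 365-day period
peaking mid-January) + diurnal alternation (±30, night-positive) + linear
couplings (−5 per mm rainfall, +2 per °C of indoor-outdoor difference) +
Gaussian noise (SD 15), clipped at zero.

The qualitative mechanisms (night > day, winter > summer, rain suppression,
stack-effect enhancement) are the domain phenomenology; the coefficients
are one realistic parameterisation of a temperate dwelling with a moderate
radon baseline, chosen once and kept fixed. What the generator does *not*
emulate: heavy-tailed radon bursts, sensor drift and dropouts, pressure
fronts correlated across channels, or any advection/diffusion physics. A
passing end-to-end suite therefore demonstrates that the machinery
(inference, weighting, training, prediction) is self-consistent under
realistic magnitudes — not that the default configuration is calibrated
for any particular building.

The bootstrap labelling step — in operation, the user sets the six levels
for the first stored records — is stood in for by a deterministic
threshold policy (`default_label_policy()`): actuation levels step at the
100/148/300 Bq/m³ anchors, the sensor check fires on saturation-suspect
humidity (> 95%), the inference check on a risk score that contradicts the
raw reading, and the exposure check on high risk. It is labelled synthetic
throughout: it encodes no field expertise beyond the anchors, and exists
so that tree training has a recoverable ground truth.

## Verification choices and problem sizes

The test suite pins every worked value to an independent oracle: centroids
against exact piecewise-linear integrals, the Pearson path against a
hand-coded covariance formula (to $10^{-12}$), and grown trees against an
exhaustive re-derivation of the recursive splitting (every candidate split
at every node enumerated by brute force) on all-small datasets, plus an
`rpart` cross-check on a clean stump problem. Stochastic checks run at
sizes chosen to keep the full suite under a minute of inference time:
randomized domain-containment sweeps use 10⁴ points, noise-recovery uses
n = 200 over 20 seeds (training RMSE within $[0.5\sigma, 1.5\sigma]$), the
end-to-end policy-recovery run uses 300 records (150 days), and the
coupling-sign check uses 1000 records (500 days). The acceptance sweep of
FIS-1 evaluates the full factorial grid of 5 levels per input variable
(5⁸ = 390 625 points) through a vectorised batch-inference path.

## Known limitations

- The correlation-to-weight mechanism is linear-in-history Pearson; a site
  with genuinely non-monotone weather-radon relationships will gate the
  wrong polarity family. The sigmoid shape mitigates, but cannot repair,
  this.
- The default membership partitions (three equal segments with 20%-of-range
  crossovers) are generic technical-range splits, not site calibrations;
  real deployments should edit the shipped YAML configuration.
- Recommendation quality is bounded by the user's bootstrap labels; the
  trees interpolate those labels and cannot exceed them.
- With fewer than two stored records, correlations are undefined and FIS-1
  stays in its symmetric cold-start state.
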