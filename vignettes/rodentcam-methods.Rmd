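---
title: "Models and methods behind rodentcam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rodentcam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodentcam)
```

rodentcam analyses motion-triggered camera-trap surveys of small,
trap-adverse mammals — invasive rodents on seabird islands being the
motivating system. This vignette explains the statistical models the
package implements, the parameters that matter and their defaults, the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## From triggers to events

A camera "trigger" is one motion activation (a short photo burst). A
rodent sitting at a bait lure can fire dozens of triggers, so triggers
are not a usable activity measure. The package collapses them into
**events**: at most one presence of a species per clock-aligned 15-minute
interval per site. The 15-minute window is a deliberate compromise — long
enough that an individual lingering at an olfactory lure is mostly
counted once, short enough to retain resolution across a night.

Two conventions are configurable but have firm defaults:

* **Survey nights run noon-to-noon** local time, night 1 beginning at the
  noon boundary at or before the camera was set. Rodents are nocturnal;
  a midnight boundary would split every active night in two.
* **Intervals are clock-aligned** (`:00/:15/:30/:45`) rather than aligned
  to the deployment start. Clock alignment makes the event table
  deterministic and order-invariant: re-binning shuffled input yields an
  identical table.

The **activity index** for a site is total events divided by nights
observed — events per 24 h. Nights observed default to the exact
deployment duration in days (a camera set at 16:00 and collected eight
noons later contributes 7.83 nights); an integer-nights mode is
available. Zero-event sites are kept with index 0; they carry real
information about absence.

The **detection history** reduces each site-night to detected / not
detected, with nights outside a site's deployment marked missing. The
history matrix is ragged by construction: nothing assumes a fixed number
of nights, and the night-varying model's parameter count follows the
data (a study whose longest deployment spans 11 nights yields 11 nightly
detection parameters plus occupancy, K = 12).

## Occupancy and detection

Let $\psi$ be the probability a site is occupied and $p_t$ the
probability an occupant is detected on night $t$. With history
$y_{st} \in \{0, 1, \mathrm{NA}\}$, the site likelihood is the standard
zero-inflated Bernoulli form

$$L_s = \psi \prod_{t \in \mathrm{obs}(s)} p_t^{y_{st}} (1-p_t)^{1-y_{st}}
      \;+\; (1-\psi)\, \mathbf{1}\!\left[\textstyle\sum_t y_{st} = 0\right],$$

an all-zero history being ambiguous between a vacant site and an
occupied-but-missed one. Two detection structures are supported:
constant ($p_t \equiv p$, K = 2) and night-varying (one $p_t$ per night,
K = T + 1), both with constant occupancy. Covariates on $\psi$ or $p$
are out of scope.

Numerical choices:

* Maximisation is on the **logit scale**, which enforces the $[0,1]$
  bounds, using BFGS from five starts (naive estimates, all-0.5, 0.2,
  0.8, and a perturbed naive start), keeping the best likelihood.
* **Standard errors** come from the inverse observed information at the
  optimum; probability-scale SEs by the delta method, and 95% intervals
  as logit-scale Wald intervals back-transformed — the convention of
  occupancy software, keeping intervals inside $[0,1]$.
* **Boundary data** (all detections, or none) are returned as exact
  boundary fits flagged `"boundary"` rather than letting the optimiser
  chase infinite logits; estimates with $|\mathrm{logit}| > 9$ also earn
  the flag. All-zero histories additionally warn that $\psi$ is
  unidentifiable.
* Model comparison tie-breaks: best log-likelihood, then smallest K.

The **cumulative detection probability** after $n$ nights is
$P_n = 1 - \prod_{i \le n}(1 - p_i)$; interval endpoints for the $p_i$
propagate through the same product. The smallest $n$ with
$P_n \ge 0.95$ is the number of undetected nights after which absence
can be declared with 95% confidence; for constant $p$ it has the closed
form $\lceil \log(0.05)/\log(1-p) \rceil$, and for a night-varying
vector the nights are consumed in order, possibly never reaching the
level (reported as such, with the achieved $P$).

## Habitat covariates

Three covariate classes are computed per site:

* **Seabird burrow density** by the point-centre-quarter (PCQ) method:
  the distance to the nearest burrow in each compass quadrant (NE, NW,
  SE, SW), searched to 40 m. The classic estimator takes
  $D = 1/\mu^2$ per m² ($\times 10^4$ for per-ha) with $\mu$ the mean
  quadrant distance. Applied per site with only four distances this
  estimator is **upward-biased by roughly a quarter** on a Poisson
  burrow field (Jensen's inequality on $1/\mu^2$), so per-site values
  should be read as a relative index — which is how they enter the
  activity models. Two consistent alternatives are provided: the
  per-site Pollard estimator $12/(\pi \sum d_i^2)$ (unbiased per point),
  and a pooled estimator that averages distances across all sites before
  squaring (the form in which the PCQ method is usually applied, and the
  one used by the package's consistency checks against simulated fields
  of known intensity).
* Quadrants with no burrow within 40 m substitute the truncation
  distance into the mean — a conservative rule that biases density
  toward zero; sites with no burrow in any quadrant get density 0. A
  recorded distance of 0 is rejected (cameras are never placed on a
  burrow). Penguin and shearwater burrows are estimated separately
  (`Emden`, `Atden`) and summed into `BD`.
* **Structural complexity** from a 1-m touch pole read at eight points
  per site: touches per 100-mm height band, 0–10. The near-ground band
  100–400 mm (`C10_40`) is the default summary: the mean over poles of
  the summed touches in bands 2–4. Cover above 1 m (`C_gt1m`) is a
  visual percentage estimate, not a pole measure.
* **Floristic covers**: visually estimated percentages of the four
  dominant plants (`Poa`, `Tetra`, `Rhag`, `Disphyma`) plus `Other`.

Covariates are used unstandardized by default (coefficients then sit on
interpretable per-unit scales); z-scoring is opt-in and recorded in the
table's attributes. A collinearity screen flags pairs with
$|r| > 0.55$. `Disphyma` is carried in the covariate table but does not
enter the candidate models.

## Activity models and model selection

Activity counts are overdispersed — a handful of sites host extreme
activity — so candidate models are **negative-binomial GLMs** with log
link. The response is the per-site total event count with
$\log(\text{nights observed})$ as offset, which keeps the likelihood on
genuine integers; per-night rows with a unit offset work identically if
finer replication is wanted.

The dispersion $\theta$ is estimated by **profile likelihood**: for any
fixed $\theta$ the coefficients are an IRLS fit (a `glm` with the
negative-binomial family), and $\theta$ is maximised by univariate
search over $\log\theta \in [\log 10^{-3}, \log 10^6]$. The more common
alternating update can diverge on exactly the data this pipeline
produces (occupancy zeros under high conditional means); the profile is
evaluated defensively, treating parameter regions where IRLS breaks
down as likelihood floor. A maximum on the upper boundary signals
Poisson-like data and is flagged; fixing $\theta$ very large reproduces
the Poisson fit to high precision, which the tests exploit as an
independent oracle.

Candidate sets are **a priori**: twelve models for the black rat
(upper-storey structure, near-ground structure, floristic composition,
burrow densities, selected interactions, and a constant baseline) and
thirteen for the house mouse, which adds black-rat activity (`RR`) to
probe interference by the dominant rodent. Interactions are always
hierarchical.

Models are ranked by **AICc** $= -2\ell + 2K + 2K(K{+}1)/(n{-}K{-}1)$
with $n$ the number of sites and $K$ counting the dispersion; plain AIC
is always reported alongside, and the detection-model comparison is
ranked by AIC, whose arithmetic the published detection tables follow
exactly ($\mathrm{criterion} = -2\ell + 2K$). Akaike weights are
$\omega_i \propto e^{-\Delta_i/2}$, invariant to rebasing the $\Delta$s.

**Model averaging** is triggered when the top model's weight falls below
0.9 — "selection uncertainty" has no canonical definition, so the
threshold is explicit and configurable. Averaging is full-set with
shrinkage: a term absent from a model contributes 0 there, the average
is $\bar\beta = \sum_i \omega_i \beta_i$ over the whole set, and the
unconditional standard error follows Burnham–Anderson,
$\sum_i \omega_i \sqrt{SE_i^2 + (\beta_i - \bar\beta)^2}$. This matches
the use-case of effect-size inference across the set; conditional
averaging (over containing models only) is available via a flag.

## The synthetic-study generator

`simulate_study()` produces a full input bundle — trigger table,
deployment log, habitat surveys — plus a truth record, under the
conditions of a peninsula-scale survey: **276 sites**, nominally
**8 nights** each, cameras set mid-afternoon so the first night is
partial (mean nights observed ≈ 7.9).

The species layer couples occupancy, detection and activity:

1. Occupancy $z_s \sim \mathrm{Bern}(\psi)$; unoccupied sites emit
   nothing.
2. On each night, an occupied site is visited with probability $p_t$,
   so the nightly detection probability is exactly $p_t$ and detection
   histories derived from the triggers follow the occupancy model by
   construction.
3. Given a visit, the number of events is a zero-truncated negative
   binomial with mean $\lambda_s$ and dispersion $\theta$, where
   $\log \lambda_s$ is a linear function of the site's standardized
   habitat covariates. Events occupy distinct 15-minute bins of the
   night, and each event is expanded into 1–3 triggers uniformly placed
   inside its bin (cameras fire repeatedly at a lingering animal).

Default species parameters encode the two focal rodents: black rat
$\psi = 0.90$, nightly detection declining 0.79 → 0.30 across the
deployment (bait-novelty peak, then habituation), activity mean 5.4
events/night with $\theta = 0.8$ and a positive `C_gt1m` effect; house
mouse $\psi = 0.58$, detection 0.59 → 0.29, activity mean 1.4 with
$\theta = 0.6$ and effects tied to `Rhag` and near-ground structure.
The detection vectors were calibrated once so that cumulative detection
crosses 95% at 3 nights (rat) and 5 nights (mouse), the design
conclusions a survey of this kind turns on. Habitat defaults: Dirichlet
covers scaled to 100%, Beta-driven pole-touch profiles decaying with
height, and seabird colonies covering ~30% of sites with Gamma-mixed
Poisson burrow intensities (shearwater mean 0.02/m², penguin 0.008/m²)
— chosen as field-plausible magnitudes for a colonial-seabird headland.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring sites, camera failures and full memory cards, weather- or
moon-driven detection covariates, individual heterogeneity in detection,
and animal movement between sites. Passing recovery tests therefore show
the estimators are correct **under the model's own assumptions**; they
do not certify robustness to the violations real field data carry.

## Problem sizes and regimes used by the checks

The test-suite simulations are sized to be decisive yet quick: 200
replicates of the 276 × 8 design for occupancy recovery (mean
$\hat\psi$ within ±0.02 of 0.9, CI coverage 0.92–0.98), 5 000 sample
points for PCQ consistency (within 10% of a 0.05/m² field), a
$10^{-3}$-step exhaustive grid as the occupancy-MLE oracle, and 1 000
random vectors for cumulative-detection monotonicity.

The selection-consistency check (data generated from the `C_gt1m`
model, asking how often it tops the table) runs at n = 20 sites. That
choice is substantive: AIC-family criteria are efficient, not
consistent, so against nested rivals the top-model probability levels
off near 75–80% at large n no matter how strong the effect. At small n
the AICc correction actively penalises the richer nested models and the
true model wins ~85–90% of replicates — the regime the correction was
designed for, and the regime in which an a-priori candidate set of this
size would be used on a pilot study.

## Known limitations

* Occupancy models carry no site covariates and a single season;
  abundance-from-detection models (Royle–Nichols and relatives) are
  deliberately out of scope.
* The activity index assumes activity is monotone in density; the
  package measures activity, not density.
* Per-site PCQ density is a biased small-sample estimator (see above);
  comparative analyses are safe, absolute densities should use the
  pooled or Pollard forms.
* The NB GLMs ignore spatial structure; residual autocorrelation would
  understate the reported standard errors.
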