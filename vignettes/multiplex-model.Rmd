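---
title: "The multiplex bioenergetic model: equations, generators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multiplex bioenergetic model: equations, generators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiwebsim)
```

`multiwebsim` simulates the dynamics of model ecological communities in
which species interact through feeding *and* through six non-trophic
mechanisms, and quantifies how those extra interaction layers reshape
species diversity, community biomass and production, and the
biodiversity–ecosystem-functioning (BEF) relationship.  This vignette is
the package's own account of the science: the equations, what the
generators emulate, the parameters and their defaults, the numerical
choices, and the design decisions that were genuinely open.

## The trophic core

Communities hold `S` species (default 100): plants (primary producers,
default 20) and consumers.  The change of biomass density \(B_i\) follows
an allometric bioenergetic balance,

\[
\frac{dB_i}{dt} \;=\; g_i\Big(r_i^{new} G_i \;+\; \sum_{j \in diet(i)}
\epsilon_{ij} F_{ij} \;-\; x_i\Big) B_i
\;-\; \sum_{k \in pred(i)} B_k F_{ki} \;-\; d_i^{new} B_i ,
\]

with logistic plant growth \(G_i = 1 - B_i/K_i\), assimilation efficiency
\(\epsilon_{ij}\) (0.45 on plant resources, 0.85 otherwise), metabolic
demand \(x_i\) (consumers only; plant maintenance is folded into the
growth rate) and background mortality \(d_i\).  The feeding rate is a
multi-prey saturating functional response with Hill exponent \(1+q\)
(default 1.5, between type II and type III) and Beddington–DeAngelis
predator interference,

\[
F_{ij} \;=\; \frac{w_i\, a_{ij} B_j^{1+q}}
{m_i\Big(1 + i_{0,intra} B_i + i_0 \sum_{s \in pred(j),\, s \neq i}
\delta_{si} B_s + w_i \sum_{k \in diet(i)} a_{ik} h_{ik}
B_k^{1+q}\Big)} ,
\]

where \(w_i = 1/|diet(i)|\) splits consumption over the structural diet,
\(a_{ij}\) is the capture coefficient, \(h_{ij}\) the handling time and
\(m_i\) the consumer body mass (required for unit consistency).
Intraspecific interference (\(i_{0,intra} = 0.8\)) is active in every run;
without it steady-state diversity is much lower.

All rates derive from body mass, and body mass from the prey-averaged
trophic level \(TL_i\) (1 for plants, otherwise one plus the mean level of
the diet, cannibalistic self-loops excluded): \(m_i = expo^{TL_i - 1}\)
with \(expo = 50\).  The allometries are quarter-power laws:
\(r_i = r_0 m_i^{-1/4}\) (plants), \(K_i = K_0 m_i^{1/4}\),
\(x_i = 0.314\, m_i^{-1/4}\) (consumers),
\(d_i = 0.1 \cdot x_{species}\, m_i^{-1/4}\) with \(x_{species}\) 0.138
for plants and 0.314 otherwise, handling
\(h_{ij} = 0.3\, m_i^{-0.48} m_j^{-0.66}\), and capture coefficients with
three mobility cases (both mobile: \(a_0 m_i^{0.45} m_j^{0.15}\); sessile
consumer: \(a_0 m_j^{0.15}\); sessile resource, mobile consumer:
\(a_0 m_i^{0.45}\); all \(a_0\) default 50).  When both sides are sessile
— a case the mobility rules leave open — the sessile-consumer form is
used, since it is the consumer's foraging mode that the coefficient
encodes.

## The six non-trophic mechanisms

Each mechanism makes one trophic parameter a linear function of the
biomass of the species exerting the effect:

* **Competition for space** multiplies the net growth term by
  \(g_i = 1 - c_0 \sum_l \gamma_{il} B_l\) (only when net growth is
  positive, else \(g_i = 1\)), with
  \(\gamma_{il} = \gamma_0\, m_l^{2/3}\) — the space an individual
  occupies scales as a body surface.  Links run between sessile species
  and are directed, so competition is asymmetric.
* **Predator interference** adds the \(\delta_{si}\) term above on links
  between mobile consumers sharing at least one prey, with
  \(\delta_{si} = 1/(1 + |\ln m_s - \ln m_i|)\): similar-sized predators
  interfere most.  Natural logarithms are used; the base only rescales
  \(\delta\).
* **Refuge provisioning** divides every capture coefficient on prey
  \(j\) by \(1 + r_0 \sum_k \phi_{kj} B_k\) (sessile protector \(k\)), so
  capture tends to zero under abundant facilitators.
* **Recruitment facilitation** multiplies plant growth by
  \(1 + e_0 \sum_k \eta_{ki} B_k\); only plants are eligible targets.
* **Mortality increase / decrease** rescale mortality as
  \(d_i^{new} = d_i (1 + n_0 \sum_k n_{ki} B_k)/(1 + p_0 \sum_k p_{ki}
  B_k)\); any species pair is eligible.

### The competition factor is clamped at zero

The linear form of \(g_i\) is unbounded below, and the \(m^{2/3}\)
weights of heavy sessile consumers reach the thousands.  During the
initial transient, when such consumers still hold order-one biomass, the
unclamped factor drops to values around \(-2\) to \(-15\) for some
targets, turning the growth term into a strong decay and wiping out a
third of the community even at the *bottom* of the calibrated intensity
range — inconsistent with those ranges being calibrated to 2.5–10%
diversity effects.  The package therefore treats \(g_i\) as a
growth-reduction factor bounded in \([0, 1]\) (`clamp_g = TRUE`, the
default).  Under the clamp the calibrated maximum \(c_0 = 0.012\)
reproduces the intended ≈10% mean diversity loss (the acceptance suite
verifies this); the unclamped form remains available via
`default_config(clamp_g = FALSE)`.  At the range minimum the effect
remains stronger than the nominal 2.5% because the transient still
saturates the clamp; this residual mismatch is a property of the printed
weight scale, not of the solver, and we chose not to re-scale the weights
away from their stated form.

## Network generation

Trophic webs come from the classic niche model: niche values uniform on
\([0,1]\), feeding ranges beta-distributed so the expected connectance
matches the target (default 0.06, about 600 directed links at
\(S = 100\)), centres uniform on \([r_i/2, n_i]\), and the smallest-niche
species forced basal.  Whole webs are rejection-sampled until they have
exactly the configured number of plants, no cycle of length two or more
(cannibalism allowed), and no isolated species; species with identical
diets are not rejected.  Mobility is a per-species Bernoulli trait
(sessile with probability 0.8 for plants, 0.2 otherwise), redrawn until
exactly 33 species are sessile.

Non-trophic layers place links independently at the configured per-pair
probability over the eligible pairs of their mechanism.  Two placement
details were open:

* *Interference* links are drawn once per unordered pair and stored
  symmetrically (the \(\delta\) weight is symmetric); the realized link
  count of a layer is its number of nonzero matrix elements, which makes
  the six stated probabilities (0.098, 0.15, 0.01, 0.01, 0.033, 0.063)
  each yield ≈100 links on the standard webs.
* *Recruitment* sources are consumer species.  Allowing plant sources
  would make the eligible set \(99 \times 20\) pairs and the expected
  count 124.7, incompatible with the ≈100-links-per-type design that the
  probabilities encode; with consumer sources the expectation is 100.8.

## Simulation engine

The system is integrated with an embedded Runge–Kutta–Fehlberg 4(5)
pair with adaptive steps (maximum-norm error control), implemented in
C++ for speed; an independent vectorised R implementation of the same
right-hand side is kept for analysis and is tested to agree to numerical
precision.  Tolerances default to `rtol = 1e-8`, `atol = 1e-10`; the test
suite checks that tightening them tenfold leaves diversity unchanged and
total biomass within 0.1%.  Whenever a species' biomass falls below the
extinction threshold \(10^{-6}\) at an accepted step it is clamped to
zero and frozen — zero biomass is absorbing, and no event location is
attempted because the threshold sits far below all dynamical scales.
"Steady state" is simply the state at \(t = 5000\); no averaging window
or oscillation detection is applied.

Initial biomasses are i.i.d. uniform on \([0.05, 1]\) — of the order of
the plant carrying-capacity scale, and strictly above the extinction
threshold.  Paired with/without runs share the web, the traits, the
initial biomasses and the layer topologies, so every difference in the
outcome is attributable to the non-trophic intensities.

## Ensemble experiments and the plant filter

The experiment layer orchestrates four designs: single-mechanism
intensity sweeps over the calibrated ranges (8 grid points by default),
the mixed ensemble (five mechanisms together, decrease-in-mortality
dropped for its negligible individual effect, negative-type link
probabilities quartered so positive and negative links are equally
abundant, intensities uniform in their ranges), the link-count ensemble
(intensities fixed at their calibrated maxima, relative link abundances
varied), and a sensitivity suite that repeats the mixed ensemble under
\(q \in \{0.3, 0.7\}\), \(a_0 \in \{10, 250\}\) (with \(h_0 = 0.1\) at
\(a_0 = 10\) to avoid massive extinctions) and \(expo \in \{25, 75\}\).

Ensembles were meant to keep only runs in which no surviving plant is
left without a surviving consumer at the end of the dynamics.  Under the
default parameters this predicate essentially never holds: consumers on
high trophic levels are energetically marginal (their mass-specific
capture scales as \(m^{-0.55}\) against a metabolic demand scaling of
\(m^{-0.25}\)), most of them go extinct in every run, and each web ends
with several surviving plants whose consumers are gone.  Strict rejection
sampling on this filter therefore cannot terminate.  The ensembles use a
soft policy instead: a few candidates are tried against the strict
predicate, the best one (fewest disconnected plants) is kept, and the
count is recorded in every output row so analyses can condition on it.

Intensity calibration (`calibrate_intensity()`) bisects an intensity
until the mean diversity ratio of a fixed calibration ensemble (same
webs, layers and initial biomasses at every evaluation; 20 webs × 5
draws by default) reaches a target magnitude within ±0.005; an
unreachable target — as for decreases in mortality, whose effect
saturates — is reported with the maximum achieved effect rather than
forced.

### Problem sizes

The defaults are desk-scale: 20 webs × 10 draws for sweeps, 50 webs ×
10 draws for the mixed ensemble, 8-point intensity grids, and a
`scale_factor` argument scales them further.  The acceptance checks use
200 webs for the trophic link count, 500 webs for the layer counts, 20 ×
10 paired runs for the competition endpoint and 50 × 10 for the BEF
comparison.  These sizes give Monte-Carlo errors comfortably inside the
tolerances being checked while keeping a full run of the suite short.

## Statistics

`fit_linear()` is ordinary least squares with the two-sided t-test on
the slope; `ancova_slopes()` fits `y ~ x * group` and reports the
interaction p-value — the classical ANCOVA test for equal slopes, with
no heteroscedasticity correction.  The diversity-ratio histogram uses a
bin width of 0.01 (diversity is integer-valued over ~100 species, so
ratios land near multiples of 1/diversity) and reports per-bin mean
intensities normalized to \([0,1]\) over their configured ranges.  Sweep
regressions are unweighted.  Both routines are tested against closed-form
normal equations.

## What the generator does and does not emulate

The synthetic networks reproduce the *counts and placement rules* of a
rocky-shore multiplex network — link abundances per mechanism,
eligibility by mobility and diet overlap — but not its empirically
observed inter-layer correlations (which species participate in several
mechanisms at once), degree distributions or phylogenetic structure.
Passing tests therefore show that the mechanisms behave as specified on
rule-generated networks, not that the model reproduces any particular
field system.

## Known limitations

* High-trophic-level persistence is low under the printed allometries,
  which makes the strict disconnected-plant filter unusable (handled by
  the soft policy above) and leaves the competition mechanism's
  dose-response saturated at the low end of its calibrated range.
* The consumption split \(w_i\) is fixed at the structural diet; there
  is no adaptive foraging, no renormalisation as prey go extinct.
* Producers are logistic in isolation; nutrients are not explicit.
* Interaction intensities are constant through time, and the refuge
  mechanism acts only on capture coefficients (the alternative of
  modifying the Hill exponent of protected prey is not implemented).
* The CLI and experiment tables cover basic reporting; figure-quality
  plotting is left to the user.
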