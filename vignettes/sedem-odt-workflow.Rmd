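---
title: "SeDeM-ODT scoring and the ODT development workflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SeDeM-ODT scoring and the ODT development workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedemodt)
```

This vignette explains the science implemented in `sedemodt`, the modelling
assumptions behind each stage, and the design choices made where conventions
in the field are genuinely open. It is the package's methods reference; the
README shows the quick worked example.

## The SeDeM expert system

Direct compression is the cheapest route to a tablet, but it only works if
the powder blend flows and compacts well enough on its own. The SeDeM expert
system condenses a powder's suitability into a single score built from 12
experimental parameters (15 in the ODT variant, which adds a
*disgregability* group for orally disintegrating tablets: effervescence time
and disintegration time with and without disc).

Each experimental value $v$ is rescaled to a radius $r$ on a nominal 0--10
scale by an affine transform anchored at the method's standard limit values,
with 10 the most favourable pole. `sedem_rules()` tabulates the anchors: for
example bulk and tapped density map 0--1 g/mL onto 0--10 ($r = 10v$), the
Carr index maps 0--50 % onto 0--10 ($r = v/5$), the Hausner ratio maps its
3--1 range onto 0--10 ($r = 10(3-v)/2$), and "downhill" quantities such as
loss on drying run reversed ($r = 10 - v$ over 0--10 %). Radii are **not
capped by default**: an interparticle porosity beyond 1.2 legitimately
scores above 10 (the bundled excipient data contain a 10.19), and capping is
available as an option (`convert_parameters(cap = TRUE)`). Values outside a
limit range warn rather than fail, because they are physically possible.

From a radius profile the system reports:

* **incidence factors** — arithmetic means of the radii within each named
  group (dimension, compressibility, flowability, lubricity/stability,
  lubricity/dosage, disgregability);
* **IP**, the fraction of radii at least 5 (a radius of exactly 5 counts as
  acceptable — this tie-break is required for consistency with the bundled
  blend data, where 10 of 15 radii at or above 5 gives IP = 0.67);
* **IPP**, the mean of all radii;
* **IGC / IGCB**, the IPP multiplied by a reliability factor $f$ that
  discounts the radar polygon relative to the full circle.

The reliability factors are fixed constants: $f = 0.952$ for the
12-parameter diagram and $f = 0.950$ for the 15-parameter variant. These are
the values that reproduce the bundled reference indices exactly; note they
are *not* the regular-polygon area ratios $\tfrac{n}{2\pi}\sin(2\pi/n)$
(0.9549 and 0.9712), which do not reproduce them. An index at or above 5
reads "suitable for direct compression" (grade A), 3--5 "corrigible with a
suitable excipient", below 3 "inadequate".

Reported values use half-up rounding at 2 decimals; every chained
computation uses unrounded values throughout.

### Corrective dose

When one incidence of the API is deficient, the least amount of a corrective
excipient is found from linear blending of the incidence radius: requiring
the mixture radius to reach the target $R$ (default 5) gives

$$CP = 100\,\frac{R - R_P}{R_E - R_P},$$

with $R_P$ the API's and $R_E$ the excipient's incidence radius. This is a
mass balance, so it is monotone the way intuition demands — a more deficient
API (lower $R_P$) needs more excipient, a higher target needs more — and it
returns 0 when the API already meets the target. The complementary
expression $100(R_E - R)/(R_E - R_P)$, which sometimes appears in write-ups
of the method, is the *API proportion* of the corrected blend, not the
excipient dose; the two are easily conflated. For the bundled
compressibility incidences (excipient 7.07, API 3.00) the dose is 49.14 %.

### Disgregability incidence caveat

In the bundled blend table the published disgregability incidence values sit
systematically about 0.04--0.08 *below* the mean of their three radii (e.g.
mean(9.54, 9.45, 9.32) = 9.44 against a published 9.39). The package
implements the plain arithmetic mean, consistent with every other incidence
group, and does not attempt to reverse-engineer whatever intermediate
rounding produced the published column; tests assert the other five groups
exactly and the disgregability group only as a mean.

## Central composite design and composition arithmetic

The formulation study varies two excipients — ludipress (52 ± 3 %) and
croscarmellose sodium (3 ± 2 %) — in a two-factor rotatable central
composite design: 4 factorial points, 4 axial points at coded distance
$\alpha = \sqrt{2}$ (which makes prediction variance a function of distance
from the center only), and one center run. Runs are emitted in a fixed
canonical order so designs are reproducible run-for-run; randomization of
execution order is a lab concern, out of scope here.

Composition arithmetic treats the API as a fixed 100 mg dose: the excipient
percents (the two factors plus fixed aerosil 0.14 %, talc 2.36 %, aspartame
1 %, magnesium stearate 1 %) leave `100 - sum` percent for the API, the
tablet weight follows as `dose / (API% / 100)`, and each ingredient's mg
content as `percent × weight / 100`. Display values truncate (never round)
to 3 decimals, which is the convention the bundled reference table uses.

One data quirk is worth knowing: the bundled reference table's own
arithmetic used its axial factor levels at the *displayed* precision, which
varies by run (one run needs the level at 4 decimals, others at 2--3). The
`flurbiprofen_design()` fixture therefore records the levels exactly as that
arithmetic used them, while `generate_ccd()` always returns the exact
$\pm\alpha$ levels; feeding either into `composition_from_point()` is a
choice the caller makes (`formulation_table(levels = "exact" | "display")`).

## Response-surface evaluation

`fit_response_surface()` is ordinary least squares on the coded factors
(linear, or full second-order), with the ANOVA against the intercept-only
null: $F = MS_{model}/MS_{residual}$, p-value from the F distribution.
*Adequate precision*, the design-of-experiments signal-to-noise diagnostic,
is `(max fitted - min fitted) / sqrt(p · MS_res / n)` with `p` coefficients
including the intercept; above 4 the model is considered able to navigate
the design space. Constant responses are flagged degenerate (F reported 0
rather than undefined); an exact fit reports infinite adequate precision
with a flag, with residual mean squares below floating-point dust treated
as zero. Published F-values for responses measured on this design depend on
a response table that is not available as data, so the package's tests
validate these statistics by oracle equivalence against explicit matrix
algebra on synthetic responses instead of asserting published figures.

## Release kinetics

Four classical dissolution models are fitted **on the observed-release
scale**, so their coefficients of determination are directly comparable:

| model | release form | parameters |
|---|---|---|
| first order | $Q_t = Q_0(1 - e^{-k_1 t})$ | $k_1$ |
| Higuchi | $Q_t = k_H \sqrt{t}$ | $k_H$ |
| Hixson--Crowell | $Q_t = Q_0 - (Q_0^{1/3} - k_{HC}\,t)^3$ | $k_{HC}$ |
| Weibull | $Q_t = Q_0(1 - e^{-(t - T_i)^\beta/\alpha})$ | $\alpha, \beta, T_i$ |

The first-order model is classically written in log-decay form
($\ln Q_{remaining} = \ln Q_0 - k_1 t$); fitting the release-scale form is
the convention of the dissolution-modelling software this field uses, and
the decay form remains available (`form = "decay"`). Rate constants carry
the reciprocal unit of the input time grid — the package does not second-
guess the grid's unit.

Numerical choices: one-parameter models use closed forms (Higuchi) or 1-D
minimisation to tolerance $10^{-12}$; the Weibull model uses bounded
Levenberg--Marquardt least squares multi-started from five deterministic
shape values ($\beta \in \{0.4, 0.7, 1, 1.4, 2\}$), with the lag $T_i$ fixed
at 0 by default since immediate-release data rarely identify it. Points at
or beyond complete release are trimmed except the first — the cube-root and
exponential forms degenerate once release is complete. $r^2$ is the plain
(not adjusted) coefficient of determination. Model selection takes the
largest $r^2$, breaking ties toward the model with fewer parameters.

The bundled fit-summary fixture is used two ways: its $r^2$ matrix as a
model-selection fixture (all nine formulations select Higuchi), and its rate
constants as generating truths for synthetic round-trip tests. The raw
dissolution curves behind it exist only as a published figure, so the
package never asserts those $r^2$ values from data.

## Shelf life

`estimate_shelf_life()` follows the ICH-style convention: OLS of assay on
storage time, then the earliest time where the one-sided lower confidence
bound on the *mean* line meets the specification limit. Defaults: limit
90 % of label claim (a common assay specification; configurable),
confidence 0.95 one-sided. The bound is concave in time with asymptotic
slope $b - t_{crit}\,s/\sqrt{S_{xx}}$, so existence of a crossing is decided
analytically; when one exists it is bracketed and bisected to 0.001 month.
With zero residual variance the bound collapses onto the fitted line and
the estimate equals $(b_0 - \text{limit})/|b|$ exactly.

There is deliberately **no default horizon**: the estimate is the crossing
time wherever it lies, which is how stability-analysis software reports it;
`horizon` is an optional reporting cap that turns later crossings into
`Inf`. On the nine bundled assay series the defaults give finite positive
estimates ranging from under 10 to about 155 months — wide, because three
time points at 0/3/6 months leave 1 residual degree of freedom, making the
bound extremely sensitive to the residual scatter of each series. No
accelerated-to-long-term extrapolation factor is applied, and formulations
are fitted separately (poolability testing is out of scope).

## Quality attributes

`limit_checks()` applies the compendial limits: friability < 1 %,
disintegration < 180 s (the pharmacopoeial ODT limit of 3 minutes), assay
within a configurable 95--105 % band, and weight variation within ±7.5 %
(the tier for 130--324 mg tablets, which all bundled batches occupy). The
weight test is the simple single-tier check of every tablet against the
batch mean; when only a batch mean is available the mean is checked against
the nominal (theoretical) weight instead. The bundled quality table reports
mean ± SD only, so `synthetic_tablet_weights()` deterministically
reconstructs a 20-tablet set with exactly the reported moments for the
per-tablet test — a labelled stand-in, not measured data. One entry of the
bundled table (batch F4 dissolution, published as 990.66 %) is an evident
decimal slip and is shipped corrected to 99.66 %.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of an integer seed under one fixed,
named RNG (Mersenne-Twister with inversion sampling), so fixtures are
portable across platforms; the caller's RNG state is restored afterwards.

* `gen_powder_set()` draws each experimental value uniformly within its
  SeDeM limit range, or biases radii toward a target IPP via a clipped
  normal (SD 1.5 by default — wide enough to exercise both sides of the
  acceptability threshold, chosen once as a realistic between-blend spread).
* `gen_dissolution()` evaluates a release model on the study's 2--15 min
  seven-point grid and adds independent Gaussian noise (clipped to
  [0, 105] %); 1 % noise is typical UV-assay repeatability.
* `gen_stability()` is a linear degradation signal plus noise at 0/3/6
  months (default slope −0.2 %/month, noise SD 0.3 % — the magnitude the
  bundled assay series exhibit).
* `gen_response_surface()` evaluates a known coded-coefficient surface on
  the CCD runs plus noise.

These emulate the *statistical structure* each stage assumes — independent
additive Gaussian noise on smooth signals, uniform powders within method
limits. They do not emulate correlated assay drift, heteroscedastic
dissolution error, batch effects, or any powder physics; a pipeline that
passes on synthetic data is validated as *software*, not as a predictor of
any particular formulation's behaviour.

Test problem sizes are the package's own choices: 200 replicates for the
ANOVA/adequate-precision oracle equivalences, 500 seeds for the Higuchi
recovery study (closed-form fits, so cheap), 500 series for slope recovery,
and a 0.001-month grid scan as the bisection oracle.

## Known limitations

* The scoring system's conversion anchors are the standard limit values;
  laboratories using house limits must supply their own `sedem_rules()`
  table.
* Only two-factor CCDs are generated; no blocking, no desirability
  optimisation, no D-optimal augmentation.
* No Korsmeyer--Peppas or zero-order release models, and no f1/f2 profile
  similarity.
* Shelf-life estimation does no Arrhenius temperature extrapolation and no
  cross-formulation pooling.
* The verdict bands ("A" / corrigible / inadequate) follow the standard
  interpretation; source tables that grade everything "A" regardless are
  reproduced in their numbers, not in their remarks column.
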