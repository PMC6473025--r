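---
title: "Estimating maximal lifespan under Gompertz mortality: models, estimators, and the synthetic study generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating maximal lifespan under Gompertz mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxspan)
```

## The problem

Late-life interventions in mouse cohorts are usually judged by their effect
on *maximal* lifespan (MLS), because median lifespan fluctuates with
husbandry while the far tail tracks intrinsic aging.  Throughout this
package MLS means the **mean lifespan of the longest-lived 10% of a
cohort**, not the single oldest animal.  The package implements the full
statistical pipeline of a bone-marrow transplantation lifespan study:

1. cohort bookkeeping under the study's inclusion policy,
2. parametric mortality modelling (Gompertz law),
3. three MLS estimators and the derived extension statistics,
4. a donor-chimerism correction for heterozygous GFP donors, and
5. a synthetic-study generator so that every stage is testable without raw
   animal data (the underlying study published only summary numbers, not
   individual death ages).

## Mortality model

Mortality follows the Gompertz law with log-linear hazard
$h(t) = e^{\mu_0 + \mu_1 t}$, ages $t$ in months everywhere.  The survival
function is

$$S(t) = \exp\!\left(-\frac{e^{\mu_0 + \mu_1 t} - e^{\mu_0}}{\mu_1}\right),$$

which satisfies $S(0)=1$ exactly (`normalization = "proper"`, the default).
The reference parameter regime is $\mu_0 = -11.4$, $\mu_1 = 0.7$ per month,
under which about 56% of animals survive to 15 months and 10% to about
17.0 months.  A `"paper_literal"` normalization is retained for the variant
that treats the starting population as the 100% scale of the bare kernel
$\exp(-e^{\mu_0+\mu_1 t}/\mu_1)$; the printed normalizing constant
$N_0 = \exp(-e^{\mu_0}/\mu_1)$ does not give $S(0)=1$ as written (the sign
of the inner exponent is inconsistent with that requirement), so the switch
keeps both readings available.  The two normalizations differ by exactly
$e^{\mu_0}/\mu_1$ in log-survival — about $1.6\times10^{-5}$ at the
reference parameters — so every downstream number agrees between them to
better than $10^{-4}$.  Despite the historical name "Gompertz–Makeham"
sometimes attached to this curve, there is no age-independent Makeham term
in the model and none is added.

Quantiles are closed-form,
$t_q = (\log(e^{\mu_0} - \mu_1\log q) - \mu_0)/\mu_1$, and sampling is by
exact inverse-CDF transform of uniform deviates — no discretization and no
rejection step.

### Least-squares fitting

`fit_least_squares()` minimizes the sum of squared deviations between the
model survival fraction and the empirical step curve.  Choices that matter:

* **Evaluation points.** The model is compared with the step's *lower*
  value immediately after each distinct death age — the fraction remaining
  after the loss at that age.  At zero noise this choice is exactly
  self-consistent (a curve sampled from the model is recovered to optimizer
  tolerance), and at realistic n the choice of convention moves the fit far
  less than sampling noise does.
* **Optimizer.** A 4×5 multistart grid over $\mu_0 \in [-20,-5]$,
  $\mu_1 \in [0.1, 2]$ feeds Nelder–Mead refinement (relative tolerance
  $10^{-12}$), and the winning start is polished once more at $10^{-14}$.
  The objective has gentle ridges but no competing local minima in this
  box at the sample sizes used; the multistart makes the result
  deterministic and start-independent.
* **No likelihood.** The estimator is deliberately least-squares on the
  survival fraction, matching the procedure being modelled; maximum
  likelihood or interval-censored variants are out of scope.

Validation is by parameter recovery: at $n = 10^4$ simulated lifespans the
slope is recovered within ±0.05 (typically ±0.01) and the intercept within
±0.5.  A second, independent route — binning deaths, estimating each
interval's hazard integral as $-\log(1-q)$, and regressing its log on age —
recovers the same slope, confirming the log-linear hazard end to end.

## The three MLS estimators

**Direct (`mls_direct`).** The mean of the top
$k = \max(1, \lfloor 0.1\,n\rfloor)$ death ages; $k = 2$ of 20 and
$k = 5$ of 51 in the reference groups.  This floor-based rule is the one
that reproduces both published tail sizes.  It is translation-equivariant
and never below the cohort mean.

**Model tail (`mls_model_tail`).** With the fitted survival curve $f(t)$
and $t_{10}$ the age at which 10% remain,

$$\mathrm{MLS}_{\text{tail}} =
  \frac{\int_{t_{10}}^{\infty} t\,f(t)\,dt}
       {\int_{t_{10}}^{\infty} f(t)\,dt}.$$

The weight is the **survival function itself**, exactly as the estimator is
defined — not the death density.  The density-weighted alternative
$E[T \mid T > t_{10}]$ is a different, systematically larger quantity
(about 0.08 month larger at the reference parameters).  Integrals use
adaptive quadrature truncated where $f < 10^{-12}$, at relative tolerance
$10^{-8}$; the test suite checks it against a brute-force Riemann sum with
step $10^{-4}$ month, the two agreeing to $10^{-4}$.  A caveat the package
surfaces explicitly: with the published *rounded* parameters
$(-11.4, 0.7)$ this integral evaluates to 17.35 months, which differs from
the published 17.2 at the first decimal while remaining well inside the
published ±0.6 half-width.  The value is sensitive to the last digit of the
parameters (unrounded fits near $-11.6, 0.72$ give 17.2), so the
reproduction report flags this row as a one-decimal mismatch rather than
silently adopting the published number.

**Weighted combination (`combine_weighted`).** Two estimates with
half-widths $\Delta_1, \Delta_2$ combine as

$$\mathrm{MLS} = \frac{\Delta_2 v_1 + \Delta_1 v_2}{\Delta_1 + \Delta_2},$$

a convex combination giving the larger weight to the smaller uncertainty.
No propagation formula for the combined half-width is defined by this
construction; the package attaches the conservative heuristic
$\min(\Delta_1, \Delta_2)$ and labels it as such (`delta_method =
"min_heuristic"`), never presenting it as anything else.

**Extension statistics.** `extension_percent(a, c)` $= 100(a-c)/c$ and
`survival_fold(a, c, t_0)` $= (a-t_0)/(c-t_0)$, the latter counting
survival from the intervention age $t_0 = 15$ months.

### Uncertainties

`student_ci()` implements the standard Student-t 95% half-width
$t_{n-1,0.975}\,s/\sqrt{n}$.  Applied to the two published tail-age sets it
gives 10.80 months (n = 2) and 1.56 months (n = 5) — versus published
half-widths of 2.6 and 0.8.  The published values are not reproducible from
the stated procedure with standard formulas under any variant we tried
(population vs sample SD, SD vs SEM, other $\alpha$), so the package
records published half-widths and its own computed ones side by side and
never conflates them.  Where a published statistic is *defined through*
the published half-widths (the weighted combination), those published
values are used as inputs, which is exactly how the combination was
produced.

## Chimerism correction

For a donor heterozygous for the GFP transgene only a fraction $d$ of
nucleated bone-marrow cells fluoresce ($d = 0.25$ in the reference
preparation), so an observed positive fraction $p$ among a recipient's
nucleated cells corresponds to donor chimerism $c = p/d$: observed 7%
means $7/25 = 28\%$ of cells are donor-derived.  `fraction_positive()`
averages per-image fractions (the default, matching instrument-reported
mean percentages) or pools counts; an optional background fraction
(GFP-negative control, 0 in the reference data) is subtracted before the
correction.  The correction is linear in the observed fraction, clamps
small negatives to 0, and treats results above 1 as an input
inconsistency.  On synthetic binomial counts (per-cell positive
probability $c\cdot d$) the pipeline recovers the generating $c$ within
±0.02 at 20 images × 1000 cells.

## Inclusion policy

Two rules, applied before any survival statistic:

* **Embolic deaths count as natural deaths** at the injection-day age.
  Deaths during intravenous injection are treatment-administration
  casualties; the study's conservative choice is to keep them in the
  mortality statistics rather than censor them (which would inflate the
  apparent benefit if the embolic risk concentrated in frail animals).
* **Sacrificed animals are excluded entirely** from curves and statistics.

`apply_mortality_policy()` is idempotent and non-mutating.  Animals
recorded `alive` are right-censored at their recorded age: they contribute
to the cohort size but never drop the survival curve.  This deliberately
simple convention (no Kaplan–Meier reweighting, no log-rank machinery) is
adequate here because the modelled study had no survivors at study end;
with heavy censoring it would bias the empirical curve upward, which is a
documented limitation, not a feature.

## The synthetic study generator

`study_design()` defaults *are* the reference study conditions: 20 control
and 56 experimental animals under the reference mortality law; six
injections starting at 15 months spread evenly over 3 months (drawn 10–20
day intervals available as an option); per-injection embolic probability
0.06 (≈9 deaths per ≈150 injections); five sacrifices at 21 months —
six months after the intervention begins, when chimerism was assayed; and
15 images of 1000 nucleated cells per sacrificed animal, within the 10–20
images per preparation of the reference protocol and a typical nucleated
cell yield per field for automated counting.

The treatment effect is modelled as a parameter change at the intervention
age: survivors of 15 months follow a second Gompertz law from then on
(piecewise hazard, implemented by conditional inverse-CDF re-draws).  The
default treated law keeps the slope and lowers $\mu_0$ to $-15.2$ — the
value chosen, once, so that the treated law's own top-decile tail mean
equals the published post-treatment MLS of 22.8 months (a $\mu_0$ drop of
$\delta$ shifts the whole law by $\delta/\mu_1$ months; $3.8/0.7 \approx
5.4$).  This is a forward-simulation construction for testing the
pipeline, not an inference about the intervention's mechanism, and no
claim about real data rests on it.

Two behaviours worth knowing:

* **Infeasible sacrifices error.** With the default design roughly 9
  experimental animals are alive at 21 months, so scheduling 5 sacrifices
  is feasible for most seeds but intentionally *errors* on the few seeds
  (≈5%) where fewer than 5 survive, rather than silently sacrificing
  fewer.  Scripts pick seeds on which the design is feasible; tests of
  properties that do not involve sacrifices use a sacrifice-free variant.
* **One seed, one stream.** All randomness (lifespans, embolic draws,
  sacrifice selection, image counts) flows from a single seed, so a design
  plus a seed reproduces the cohort CSV byte for byte.
* An optional age-weighted embolic risk (frailer, older animals at higher
  risk) was considered and left out: the reference data cannot distinguish
  it from uniform risk, and the uniform model already reproduces the
  observed death count.

What the generator does **not** emulate: husbandry-driven clustering of
deaths, seasonal effects, measurement error in death ages (real records
have 0.1-month resolution; the generator emits continuous ages), engraftment
kinetics, or any correlation between an animal's frailty and its embolic
risk.  Passing tests therefore show that the *pipeline* is correct under
the stated stochastic model, not that the model captures every feature of
real colony data.

## Numerical choices

* Quadrature: `stats::integrate`, relative tolerance $10^{-8}$, upper
  truncation at $S(t) = 10^{-12}$; cross-checked by a $10^{-4}$-month
  Riemann sum.
* Quantile/survival round-trip holds to $10^{-10}$ (closed forms).
* Survival underflows to exactly 0 past ~25 months at the reference
  parameters (double-precision limit); monotonicity is strict up to that
  point.
* Optimizer tolerances as above; ties in death ages drop the step curve
  jointly ($k/n$); fit requires ≥3 distinct death ages.
* Problem sizes used by the test suite and scripts: recovery at
  $n = 10^4$ over 20 replicate seeds, distributional checks at $n = 10^5$,
  Glivenko–Cantelli gap < 0.03 at $n = 10^4$ — sizes at which the checks
  are sharp while the whole suite runs in well under a minute.

## Worked reproduction

```{r}
report <- reproduce_reference_results()
report
```

Every published statistic is recomputed from its published inputs; the
single flagged row is the model-tail estimate discussed above.

```{r}
sim <- simulate_study(study_design(seed = 20190412))
rec <- apply_mortality_policy(sim$cohort)$records
mls_direct(rec$age_months[rec$group == "experimental"],
           sum(rec$group == "experimental"))
sapply(sim$chimerism, estimate_chimerism)
```

## Known limitations

* Right censoring is handled by simple truncation, not reweighting (see
  above); fine for cohorts followed to extinction, biased otherwise.
* The combined estimate's half-width is a labelled heuristic.
* The model-tail estimator inherits the full sensitivity of the fitted
  parameters' last printed digit; report unrounded parameters whenever the
  fit is yours.
* No hypothesis test for MLS differences is provided (none is defined in
  the modelled analysis); the extension statistics are point estimates.
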