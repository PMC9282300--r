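---
title: "Extending the force of selection to intergenerational transfers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extending the force of selection to intergenerational transfers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elderfit)
```

## The problem

Hamilton's classical force of selection — the sensitivity of population
fitness to age-specific mortality or fertility — declines to zero once
reproduction ceases. Under that accounting, postreproductive life is
invisible to selection, which sits uneasily with the long postreproductive
lifespans of humans and a few other social mammals. In species with pooled
energy budgets, however, older individuals keep contributing calories (and
skills) to kin. `elderfit` quantifies that channel: it converts age profiles
of food production $P_x$, caloric demand $D_x$, survival $p_x$ and fertility
$m_x$ into three transfer-based fitness metrics that extend the force of
selection beyond the last reproductive age.

## The nutrition pathway

A focal sharing group pools production and redistributes it by caloric need,
so every member's intake is the same fraction of its demand — the food ratio

$$E = \frac{P_T}{D_T}, \qquad
  P_T = \sum_x P_x l_x, \quad D_T = \sum_x D_x l_x,$$

with $l_x$ the survivorship schedule. Vital rates respond to nutrition
through the concave scalar

$$Z(E, \gamma) = \frac{E(\gamma + 1)}{E + \gamma},$$

applied multiplicatively to fertility, $m_x(E) = Z\,m_x^{(0)}$, and
divisively to mortality, $q_x(E) = q_x^{(0)}/Z$. The curvature parameter
$\gamma > 0$ (dimensionless) spans weak, saturating responses (small
$\gamma$: only severe deprivation matters) to nearly linear ones (large
$\gamma$). $Z(1,\gamma) = 1$ for every $\gamma$; intake above replete confers
no benefit (no hypernutrition), so $Z$ is capped at 1. The exact derivatives
used throughout are

$$\frac{dm_x}{dE} = m_x^{(0)}\frac{\gamma(\gamma+1)}{(E+\gamma)^2},
\qquad
\frac{dp_x}{dE} = q_x^{(0)}\frac{\gamma}{(\gamma+1)E^2},$$

both verified against central finite differences in the test suite.

## Calibration

`calibrate_profiles()` anchors the analysis at empirically motivated growth
rates in two steps:

1. **Replete scale.** Production is rescaled so $P_T = D_T$ at replete
   vital rates ($E = 1$), where growth attains its maximum $r_{\max}$
   (3%/yr for the built-in chimpanzee-like and forager-like regimes; input
   rates are treated as the replete rates, with an optional
   `rescale_fertility` switch to force $r(1) = r_{\max}$ exactly).
2. **Baseline reduction.** Production is reduced proportionally at every age
   (multiplier $\rho$) until the intrinsic growth rate falls to
   `r_target` = 1%/yr, the contemporary hunter-gatherer average. The food
   ratio there is the baseline $E_0$; the stationarity threshold $E_{\min}$
   ($\lambda = 1$) is recorded as the crash boundary.

$E_0$ is found by root finding on the strictly increasing map $E \mapsto
r(E)$ (tolerance $10^{-12}$); $\rho$ follows in closed form from the
self-consistency condition $E_0 = \rho P_T(l(E_0))/D_T(l(E_0))$, in which
survivorship feeds back on nutrition. All *derivatives* downstream are then
evaluated at the baseline point holding $l_x$ and $D_T$ fixed — a local,
one-shot convention mirroring $dE/dP_x = l_x / D_T$ — so the analytic chain
and its finite-difference oracle probe exactly the same map.

## The three metrics

**Production sensitivity and indirect contributions.** The serial chain

$$s_{Px} = \frac{d\lambda}{dP_x} = \tilde r_x k
  \left(\sum_y s_{y+1,y}\frac{dp_y}{dE}
      + \sum_y s_{1y}\frac{dm_y}{dE}\right)\frac{l_x}{D_T}$$

passes the effect of one extra kcal/day produced at age $x$ through the food
ratio into every recipient age's survival and fertility, weighted by the
Leslie-matrix eigenvalue sensitivities $s_{ij} = v_i w_j / \langle v, w
\rangle$. The social discounts are the cooperation probability $k \in [0,1]$
and mean donor relatedness $r_x \in [0, 0.5]$, scaled to the
direct-offspring benchmark $\tilde r_x = r_x / 0.5$. Recipient sums run over
all ages including the donor's own (self-provisioning is not excluded).
Indirect fitness contributions are $\Delta\lambda_{Px} = P_x s_{Px}$ — the
first-order fitness lost if all age-$x$ individuals stopped foraging.

**Production elasticities.** $e_{Px} = s_{Px} P_x / \lambda$ gives the
percent change in fitness per 1% change in age-$x$ production. These do not
live on the unit-sum scale of vital-rate elasticities, so they are rescaled
to sum to the total fertility elasticity $\sum_x e_{mx}$, which makes age
profiles comparable across populations.

**Productive value.** The transfer analogue of Fisher's reproductive value:

$$PV_x = \tilde r_x k\, \frac{\lambda^{x-1}}{l_x}
  \sum_{y \ge x} \lambda^{-y}\, \Delta R_{Py},$$

where $\Delta R_{Py} = R_0^{(0)} - R_0^*$ is the drop in net reproductive
rate when age-$y$ production is zeroed (recomputing $E$ one-shot at baseline
survivorship, then re-applying the nutritional response). Replacing
$\Delta R_{Py}$ by $l_y m_y$ recovers the classic discrete reproductive-value
recursion exactly, which is what makes the two age profiles directly
comparable; the suite asserts this identity to $10^{-10}$. Because PV is
used as a shape, normalized curves are invariant to $\gamma$ (rank
correlation 1 across $\gamma \in \{0.2, 1\}$ in the tests).

**Fertility equivalents.** Setting $s_{mx} m_x^* = s_{Px} P_x$ expresses
production transfers as the extra daughters per year that would buy the same
fitness; `tfr50()` reports $2\sum_{x=50}^{80} m_x^*$, the both-sex offspring
equivalent of postreproductive production for a mother living from 50 to 80
(unconditioned on survival, per its definition as a hypothetical
continued-life schedule).

## Demographic conventions

* **Bookkeeping.** Birth-pulse, pre-breeding census with $F_x = m_x$ in the
  first row and $p_x$ on the subdiagonal. This matches the serial chain's
  indexing ($s_{1x}$ = fertility-at-age-$x$ as a single entry) and gives the
  Euler–Lotka form $\sum_x \lambda^{-(x+1)} l_x m_x = 1$, asserted to
  $10^{-8}$ on every matrix the suite touches.
* **Eigenstructure.** $\lambda$ comes from a dense eigensolve
  (matrices at most 131×131); $w_x \propto l_x \lambda^{-x}$ and the
  reproductive values come from the exact backward recursion
  $\lambda v_x = m_x + p_x v_{x+1}$, which yields exact zeros at
  postreproductive ages instead of eigensolver noise.
* **Life table.** Closed at a finite $\omega$ with $q_\omega = 1$;
  $e_0 = \sum_x l_x$ with no half-interval correction ($e_0$ is
  reporting-only and feeds no metric).
* **Mortality clipping.** $q_x = q_x^{(0)}/Z$ is clipped at 1 with a warning;
  calibration never enters that regime because $E_0 > E_{\min}$.

## Weighting conventions

Two printed-summary conventions were genuinely open and are resolved as
follows:

* **"Production remaining after age $a$"** weights by survivorship,
  $\sum_{x>a} P_x l_x / \sum_x P_x l_x$ — the same weighting that defines
  $P_T$. Unweighted and stable-structure variants are available through
  `cumulative_shares()` inputs for sensitivity analysis.
* **Mean ages** $x_M, x_P, x_D$ in `selection_report()` also use
  survivorship weighting. The unweighted textbook formula
  $\sum x s_x / \sum s_x$ (the `mean_age()` default) makes the mean age of a
  flat demand schedule $\approx \omega/2$, which would place mean production
  age *below* mean consumption age in any long-lived population — the
  opposite of the downward net flow of transfers that pooled-budget data
  show. Survivorship weighting restores the population-level reading: a gap
  of several years in the forager regime, near zero in the chimpanzee-like
  regime.

With flat $r_x$ and $k$, discounting scales magnitudes only:
$\Delta\lambda_{Px} / (P_x l_x \tilde r_x)$ is constant across donor ages
(asserted to $10^{-12}$), so share summaries are invariant to the social
parameters — changing kinship or cooperation changes how much fitness
transfers buy, not *when* in life they are bought.

## The synthetic regimes

No field data ship with the package; `synth_profiles()` generates the two
stylized study conditions from smooth parametric curves (Siler mortality,
unimodal fertility, saturating demand, rise-and-senesce production):

* **chimp-like** ($\omega = 60$): foraging self-sufficiency by age ~5,
  production peak before 20, essentially no surplus after 40, high adult
  mortality, no mid-life reproductive cessation.
* **human-like** ($\omega = 90$): net caloric consumption for about two
  decades, production crossing demand near age 20 and peaking at 30–45 with
  surpluses past 60, lower adult mortality, fertility confined to [15, 50).

Fertility level is solved (not hand-set) so replete growth is exactly
$r_{\max} = 3\%$/yr in both regimes, matching the calibration's anchor.
Generation is deterministic given a seed; optional lognormal multiplicative
noise applies to production only. These stand-ins reproduce the qualitative
structure of composite chimpanzee/forager data — survivorship-weighted
production shares after 30/40/50 of roughly 61/37/19% (forager) versus
15/5/1% (chimpanzee), a total fertility elasticity near 3.3%, and ~11% of
the stable population over age 50 — but they are smooth idealizations: they
carry no sampling noise, no secular trends, no sex differences, and their
chimpanzee mean-age gap $x_P - x_D$ sits near zero rather than slightly
positive. Passing tests therefore demonstrate correctness of the machinery
and fidelity of the stylized shapes, not agreement with any particular
field dataset.

## Pedagogy

Information transfers are modeled on a skill-based production function
$P_x = p_{\max} M_x S_x^w$: a logistic-rise, senescing biomechanical
capacity $M_x$ and a saturating skill curve $S_x = 1 - e^{-\rho_s x}$
accumulating with foraging experience, blended by the skill weight $w$. The
high-skill preset ($w = 0.8$, slow saturation) and low-skill preset
($w = 0.25$, fast saturation) live in the exported `pedagogy_presets`
configuration object, not in code. A regime $(\varphi, \theta, a, b, t)$
multiplies pupils' skill-acquisition rate by $(1 + \theta_{\mathrm{eff}})$
during ages $[a, a+t)$ and teachers' production by $(1 - \varphi)$ during
$[b, b+t)$; the fitness gain re-solves the self-consistent food ratio under
the modified schedule and reports the change in intrinsic growth, discounted
by teacher relatedness and cooperation.

The underlying skill model is external to the transfer framework, so two
design choices were made here and matter for the teacher-age optimum:
teaching effectiveness scales with the teachers' own mean skill over the
teaching window (knowledge persists into old age even as capacity senesces)
and with demographic availability, the survivorship-weighted abundance of
teachers relative to pupils, capped at 1. Young teachers are unskilled and
very old teachers are scarce, which produces interior optimal teacher ages;
higher teaching costs push the optimum older because the cost term peaks at
prime production ages. Quantitative growth-gain figures from this module are
preset-dependent illustrations; only its qualitative orderings (null regime
is an exact fixed point, gains rise in $\theta$ and fall in $\varphi$,
costlier teaching favors older teachers, skills-intensive niches profit
more) are treated as results.

## Numerical choices

* Root finding uses `stats::uniroot` at tolerance $10^{-12}$ (calibration)
  and $10^{-10}$ (self-consistent food ratio). The self-consistent residual
  is non-monotone — survivorship collapses at starvation-level $E$ — so the
  solver brackets the root nearest the replete state by scanning down from
  $E = 1$ in steps of 0.02.
* The end-to-end oracle for $s_{Px}$ perturbs one production entry by
  $10^{-4} P_x$ and recomputes $\lambda$ through the one-shot pipeline;
  agreement is required to $10^{-3}$ relative. Matrix-entry sensitivities
  are checked against central differences at $h = 10^{-6}$ to $10^{-6}$
  relative on dense random matrices whose sensitivities sit well above the
  difference quotient's rounding floor.
* Problem sizes: ages run 0–90 (humans) and 0–60 (chimpanzee-like), so all
  eigenproblems are at most 91×91 and the full suite, including the
  50-matrix and 20-profile sweeps, runs in well under a minute.

## Worked example

```{r example, eval = FALSE}
hg <- synth_profiles("human-like", seed = 1)
cal <- calibrate_profiles(hg$lh, hg$sub, gamma = 0.3)
rep <- selection_report(cal, social_profile(0.2, k = 0.5, omega = 90))
print(rep)
head(rep$table)
```

## Known limitations

One-sex (female) model; no density dependence, stochasticity or individual
heterogeneity; need-based equal sharing only (no age-targeted sharing rules,
which would raise the benefits further); the cooperation coefficient is an
exogenous discount, not an endogenous sharing equilibrium; relatedness ramps
are linear stand-ins for empirically varied age-kinship profiles; and the
pedagogy skill model is a parametric stand-in whose absolute gains should
not be over-read.
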