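# elderfit

Age-structured inclusive-fitness analysis for social species with pooled
energy budgets: an extension of Hamilton's force of selection that accounts
for intergenerational food (and information) transfers.

## The problem

Classical selection gradients — the sensitivities and elasticities of the
population growth rate λ to age-specific survival and fertility — fall to
zero once reproduction ceases, leaving postreproductive life in a "selection
shadow" where late-acting deleterious mutations accumulate unopposed. Yet in
humans and other cooperatively provisioning species, older adults keep
producing food surpluses that raise the survival and fertility of kin.
`elderfit` is for evolutionary demographers and human behavioral ecologists
who want to quantify that indirect channel from standard age schedules.

## The model in brief

Given one-year age schedules of survival p_x, fertility m_x, caloric
production P_x and caloric demand D_x (kcal/day), the package:

1. Models group nutrition through the food ratio
   **E = Σ P_x l_x / Σ D_x l_x** and the concave vital-rate scalar
   **Z = E(γ+1)/(E+γ)**, with fertility multiplied by Z and mortality
   divided by it.
2. Calibrates a Leslie-matrix baseline: production scaled so demand is met
   at replete nutrition (E = 1, maximal growth r_max ≈ 3%/yr), then reduced
   proportionally until intrinsic growth is 1%/yr (the food ratio there is
   E₀; the crash threshold E_min has λ = 1).
3. Computes three transfer-based fitness metrics at that baseline, each
   discounted by cooperation k and by donor relatedness scaled to the
   direct-offspring benchmark (r_x / 0.5):
   * **Δλ_Px = P_x dλ/dP_x** — indirect fitness contributions via the serial
     chain dλ/dP_x = Σ_ij s_ij (da_ij/dE) (dE/dP_x);
   * **e_Px = s_Px P_x / λ** — production elasticities, rescaled to sum to
     the total fertility elasticity for cross-population comparison;
   * **PV_x** — productive value, the transfer analogue of Fisher's
     reproductive value, built from discounted future drops in R₀ when each
     age's production is removed.

   Plus fertility equivalents m_x\* (s_mx m_x\* = s_Px P_x) and their
   postreproductive total TFR₅₀, mean ages of production/demand/reproduction,
   cumulative-share summaries, counterfactual life-history × subsistence
   permutations, and a pedagogy module that propagates teaching (costs to
   teachers, accelerated skill acquisition by pupils) to fitness through the
   same nutrition pathway.

No field data are bundled; a deterministic generator supplies stylized
"chimp-like" and "human-like" study profiles, and any population can be
analyzed from a five-column CSV (`age,px,mx,Px,Dx`, with `qx` accepted in
place of `px`).

## Worked example

```r
library(elderfit)
hg  <- synth_profiles("human-like", seed = 1)       # forager-like schedules, ages 0-90
cal <- calibrate_profiles(hg$lh, hg$sub, gamma = 0.3)
rep <- selection_report(cal, social_profile(0.2, k = 0.5, omega = 90))
print(rep)
```

```
Transfer-selection report
  lambda = 1.010050 (r = 0.0100)   E0 = 0.3731   Emin = 0.2766   gamma = 0.3
  mean ages: reproduction 30.2, production 36.3, demand 31.1 (x_P - x_D = 5.2)
  total fertility elasticity = 0.0326 of all vital-rate elasticities
  production share remaining: after30 60.8%, after40 37.5%, after50 18.6%
  indirect-contribution share remaining: after30 60.8%, after40 37.5%, after50 18.6%
  fertility-contribution share remaining: after30 43.9%, after40 7.9%, after50 0.0%
  TFR_50 = 0.846 offspring (both sexes, ages 50-80)
  stable population share over age 50 = 10.9%
```

Reading: at a 1% growth baseline with moderate curvature (γ = 0.3), group
members related at 0.2 who cooperate half the time still derive 18.6% of all
indirect fitness contributions from ages past 50 — ages at which direct
fertility contributions are already zero — while those ages hold only 10.9%
of the stable population. Per-age detail lives in `rep$table`
(columns `age, px, mx, Px, Dx, lx, s_mx, s_px, e_mx, e_px_scaled,
dlambda_Px, m_star, RV, PV`); note how productive value PV remains positive
through the 60s while reproductive value RV hits zero at cessation:

```
   age        Px dlambda_Px  m_star      RV      PV
31  30 1172.3825    0.00015 0.01569 1.67958 0.34637
51  50 1123.9151    0.00010 0.01838 0.00000 0.17489
66  65  738.6532    0.00003 0.01403 0.00000 0.06528
```

A thin CLI covers the same pipeline
(`inst/cli/elderfit <calibrate|metrics|counterfactual|pedagogy|synth>`).

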