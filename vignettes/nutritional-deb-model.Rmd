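---
title: "A nutritional bioenergetic model for farmed fish: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A nutritional bioenergetic model for farmed fish: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriDEB)
```

# The model

`nutriDEB` simulates the energy and mass budget of an individual farmed fish
under an explicit feeding regime. The core is a standard Dynamic Energy
Budget (DEB) abj model — reserve $E$, structure $V$, maturity $E_H$,
reproduction buffer $E_R$ — extended with a digestion module in which food is
made of **two complementary substrates**, a protein part and a non-protein
(lipid + carbohydrate) part, that are processed in parallel by a
synthesising unit (SU) to build reserve. The stomach is a fifth state
variable, $M_X$ (C-mol of ash-free dry food), filled instantaneously at
meals and drained continuously by digestion.

## Digestion and assimilation

Digestion products are generated at a rate proportional to the digestive
surface ($L^2$, with $L = V^{1/3}$ the structural length) and the stomach
content. Assimilation is

$$\dot J_{EA} = \dot J_{EAm} \, s_M \, c_T \, f_X \, L^2, \qquad
  f_X = \frac{M_X}{M_X + M_{KX}},$$

where $s_M$ is the abj acceleration factor, $c_T$ the Arrhenius temperature
factor, and the half-saturation constant follows from
parallel-complementary SU kinetics:

$$M_{KX} = \frac{\dot J_{EAm}}{\dot J_{Xgm}}
  \left( A + B - \frac{1}{A^{-1} + B^{-1}} \right),
  \qquad A = \frac{q_P}{a_P}, \quad B = \frac{q_{nP}}{1 - a_P}.$$

Here $a_P$ is the C-mol fraction of the stomach content that is protein and
$q_P$, $q_{nP}$ are the C-mol of absorbed protein / non-protein substrate
needed per C-mol of reserve. **A note on the bracket grouping**: the
expression above is the standard parallel-complementary SU closed form; it
is the unique grouping under which $M_{KX} \to \infty$ (so assimilation is
nullified) when the diet contains only one of the two substrates
($a_P \in \{0, 1\}$), which is the behaviour the model is built around.

Between meals the stomach drains at
$\mathrm d M_X / \mathrm d t = -(q_P + q_{nP} + y_{PE}) \dot J_{EA}$:
absorbed substrate plus the indigestible companions that leave as faeces.
For constant $L$ this ODE is separable with the implicit solution
$M_X(t) - M_X(0) + M_{KX}\ln(M_X(t)/M_X(0)) = -kt$, which we use both as an
independent oracle for the integrator and, solved by bisection, as the
smooth inner kernel of the response-surface code.

## From proximate composition to stoichiometry

A feed is entered as proximate fractions (protein / fat / carbohydrate /
ash on dry matter, plus moisture) with apparent digestibility coefficients
(ADC). Each macronutrient is a generalised compound $\mathrm{CH}_{n_H}
\mathrm{O}_{n_O}\mathrm{N}_{n_N}$; the shipped indices, chemical potentials
and densities are conventional values for generalised protein
($\mathrm{CH_{1.6}O_{0.32}N_{0.26}}$), lipid
($\mathrm{CH_{1.92}O_{0.12}}$) and carbohydrate ($\mathrm{CH_2O}$), and are
configuration — every entry can be overridden. $a_P$ is defined on a C-mol
basis of ash-free dry matter; mass-based input is converted internally.
Ash is inert: it never enters the food/reserve dynamics and is traced to
the faecal output in proportion to the ash-free matter leaving the stomach.

The coupling yields are a documented reconstruction, since the mapping from
proximate analysis to stoichiometric coefficients admits more than one
closure. The scheme shipped here uses two rules:

1. **Carbon**: reserve synthesis consumes $1 + \sigma_A$ C-mol of absorbed
   substrate per C-mol reserve; the overhead $\sigma_A$ (default 0.2) is
   respired as assimilation CO$_2$.
2. **Nitrogen**: all reserve N comes from the protein substrate, fixing the
   protein share of the absorbed pool at $\theta_P = n_{NE}/n_{N,prot}$.

So $q_P = (1+\sigma_A)\theta_P$ and $q_{nP} = (1+\sigma_A)(1-\theta_P)$.
Absorbing $q$ C-mol of a substrate with digestibility ADC drags
$q\,(1-\mathrm{ADC})/\mathrm{ADC}$ C-mol of indigestible material out as
faeces, which sets $y_{PE}$ and the faeces composition (the fat:carbohydrate
split inside the non-protein part is taken at the *indigestible*
proportions, not the average ones). This scheme was chosen because it
reproduces the qualitative protein-to-energy response surfaces with a
single free constant ($\sigma_A$).

A consequence worth knowing: because $q_P + q_{nP} - 1 = \sigma_A$ for every
diet, the assimilation CO$_2$ coefficient is composition-invariant; the
diet-dependence of assimilation chemistry shows up in the oxygen and water
coefficients.

## Mineral fluxes and the nitrogen closure

Oxygen consumption, CO$_2$, and non-faecal ammonia (TAN) are weighted sums
of the three basic powers (assimilation $p_A$, dissipation $p_D$, growth
$p_G$); the weights are solved from the C/H/O/N balance of all organic
compounds against the minerals CO$_2$, H$_2$O, O$_2$ and NH$_3$. They are
derived quantities, recomputed whenever a composition changes.

The TAN flux carries **no assimilation term**
($\dot J_N = \eta_{ND} p_D + \eta_{NG} p_G$). To keep the element balance
exact under that form, the small N surplus of assimilation
($\sigma_A n_{NE}$ per C-mol reserve) is routed into the faeces composition.
Whether that surplus is truly faecal or branchial is not observable at this
model's granularity; the switch `ammonia_assim = TRUE` in
`coupling_yields()` moves it to ammonia instead, for sensitivity analysis.
Metabolic water is computed internally for the H/O balance but not
reported. Elemental closure at every output step — residuals at round-off
level, orders of magnitude below the 1e-9 requirement — is the module's
central correctness property and is asserted in the test suite by a
brute-force audit that sums element flows compound by compound.

## Stomach capacity, meals and wet weight

The stomach volume is $\delta_g V$. Ingested dry food is moisturised with
$y_{HXd}$ g of water per g of dry food (default 0.8425, the slope of the
water-vs-dry-content line; configurable), so the volume-specific capacity is

$$[M_{gm}] = \left( \frac{y_{HXd} d_{Xd}}{d_H} + 1 \right)^{-1}
  \frac{d_{Xd}}{w_X}\,\delta_g .$$

A meal offers $k_X W$ grams of as-fed feed ($k_X$ re-evaluated against the
current model weight); the amount eaten is the minimum of the offer and the
remaining stomach deficit, applied as an instantaneous jump; the remainder
is logged as uneaten feed. Wet weight is
$W = d_{Vw} V + (E + E_R)\, w_{Ed} / (d_{Ed}\, \mu_E)$ — structure at its
wet density plus the wet volume of reserve — with stomach content excluded
(the gut is environment, not body).

# Numerical design

* **Integration**: `deSolve::lsoda` (stiff-safe, adaptive) between meal
  events at `rtol = 1e-8`, `atol = 1e-10`; meals and temperature switches
  are stop–jump–restart breakpoints, so no discontinuity is ever stepped
  over. Output is produced hourly and aggregated to daily means/sums on
  request, making the daily table exactly the aggregate of the hourly one.
* **Response surfaces** use the analytic implicit solution of the
  between-meal ODE (bisection to `1e-14` relative), because finite
  differencing a surface built on an adaptive integrator produces spurious
  sign changes near flat optima.
* **Boundary handling**: single-substrate diets return
  $M_{KX} = \infty$ and zero assimilation rather than an error, so
  composition sweeps run unattended.
* **Starvation**: maintenance is paid from reserve with growth and
  maturation clamped at zero (no shrinking or rejuvenation rules); if the
  reserve is exhausted, the run truncates with a diagnostic.
* **Temperature**: one Arrhenius factor multiplies every rate parameter
  (assimilation, digestion, conductance, maintenance); series are
  piecewise-constant between supplied points.
* **Acceleration**: both surface-specific digestion rates scale with the
  abj factor $s_M$, as does assimilation — standard abj practice. The
  lengths at birth and metamorphosis ($L_b$, $L_j$) are parameters
  consistent with the maturity thresholds rather than being re-detected in
  every run, which keeps runs that start mid-life well defined.

## Satiation

"Ad libitum" is operationally fuzzy; here **satiation feeding** for the
response surfaces means refilling the stomach to capacity at each of a
configurable number of meals per day (default 2) with the fish state held
fixed, and reporting the periodic daily intake. Intake and assimilation are
both expressed as ash-free dry mass, assimilation as the food mass actually
absorbed, hence always below intake.

# Parameters

Units are J, mol, cm, g, d, K throughout; conversion happens only at the
I/O boundary (temperatures in °C, feed in g). The bundled set is a
**rainbow-trout-like fixture**, not a published estimate: values were
chosen once for realistic magnitudes — a 150 g fish at 15 °C clears a
ration of ~1.2 % BW/d with the stomach roughly emptying between daily
meals; gastric evacuation runs from hours (large fish, 15 °C) to several
days (small fish, 5 °C); the von Bertalanffy asymptote at sustained
moderate feeding sits near half a metre. Reference temperature is 15 °C,
the main demonstration temperature. Key tunables:

| parameter | default | unit | meaning |
|---|---|---|---|
| `p_Am` | 1200 | J/d/cm² | max. surface-specific assimilation (before acceleration) |
| `J_Xg_m` | 0.098 | 1/d/cm² | max. surface-specific digestion coefficient |
| `delta_g` | 0.12 | — | stomach volume / structural volume |
| `y_HXd` | 0.8425 | g/g | water added per g ingested dry food |
| `sigma_A` | 0.2 | C-mol/C-mol | assimilation CO₂ overhead |
| `kappa` | 0.75 | — | allocation to soma |
| `p_M` | 106 | J/d/cm³ | somatic maintenance |
| `T_A` | 8000 | K | Arrhenius temperature |

# What the synthetic data do and do not show

The fixture generators (`synth_evacuation()`, `synth_stomach_water()`,
`synth_growth_trial()`) emulate the *designs* of typical calibration
experiments — evacuation curves over a temperature × size grid, water
vs dry stomach content pairs, weight time series — with multiplicative
lognormal noise (positive, heteroscedastic data; an additive option would
understate scatter at large values). They are reproducible from
`(seed, config)` alone.

Passing parameter-recovery tests on these fixtures demonstrates that the
estimation machinery is unbiased at zero noise and stable at realistic
noise, and that the model's qualitative responses (temperature ordering,
protein-optimum, intake–energy trade-off) are genuine properties of the
equations. It does **not** demonstrate predictive accuracy on real trout:
the generating model and the fitted model are the same object, so
structural error is zero by construction. Validation against independent
literature datasets is outside this package's scope.

# Known limitations

* The gut is one pool: no particle-size effects, no compartmentalisation,
  no electrolyte/water dynamics beyond the fixed moisturising coefficient.
* Stomach composition is treated as constant between meals even though the
  SU draws the two substrates in stoichiometric, not stomach, proportions;
  the inconsistency is second-order for realistic diets.
* Amino-acid / fatty-acid quality, body-composition responses and ash
  nutrition are not modelled; nitrogenous waste is ammonia only.
* Runs start at exogenous feeding; embryos and egg production beyond the
  $E_R$ buffer are out of scope.
* Stomach capacity uses one allometry ($\delta_g V$) across sizes; if the
  very young stages follow a different allometry, capacity-sensitive
  outputs for small fish inherit that bias.

# Problem sizes used in the shipped checks

The test-suite scenarios are desk-scale by design: 30-day group runs at
hourly resolution (721 output steps), 200-point composition grids, a
3 × 3 temperature–size recovery design with 6 sampling times, and a 150-day
constant-f growth run for the von Bertalanffy comparison.
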