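---
title: "A compartment hydraulic model of plant dehydration during drought"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartment hydraulic model of plant dehydration during drought}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrodry)
```

## The problem

When water is withheld from a potted tree, its dehydration unfolds in two
phases. While stomata are open, transpiration draws the pot down quickly;
as leaf turgor falls, stomata close and the plant enters a slow phase in
which water escapes only through the cuticle, "leaky" stomata and bark.
Residual losses keep lowering the water potential until xylem tensions
embolize enough conduits that the hydraulic pathway fails. `hydrodry`
simulates both phases from measurable traits and asks which traits control
the time to stomatal closure (`T_close`), the time from closure to
hydraulic failure (`T_cav`), and their sum (`THF`).

## Model structure

The soil–plant–atmosphere continuum is discretized into five compartments
in series: soil, root, trunk, branch, leaf. Each plant compartment `i`
carries a symplast water pool on its pressure–volume curve and a
cavitation-releasable apoplast pool; water moves between compartments down
water-potential gradients:

$$C_i(\Psi)\,\frac{d\Psi_i}{dt} \;=\; \sum_j K_{ij}\,(\Psi_j - \Psi_i)
\;-\; E_i \;+\; R_i$$

with capacitance $C_i$ from the pressure–volume relation, evaporative sinks
$E_i$ and apoplastic release $R_i$ proportional to the increment in percent
loss of conductivity (PLC).

### Response curves

* **Symplast water relations.** $\Psi(R) = \pi_0/R + \max(0,\,-\pi_0 -
  \varepsilon\,(1-R))$ for relative water content $R$: an osmotic dilution
  term plus a linear-elastic turgor term. Turgor vanishes at
  $R_{tlp} = 1 + \pi_0/\varepsilon$, giving a derived turgor loss point
  $\pi_0/R_{tlp}$. Trait tables sometimes also report a measured TLP; the
  two are not numerically consistent for all species (e.g. the Aleppo pine
  fixture's measured TLP of −2.15 MPa versus −1.458 MPa derived from its
  $\pi_0 = -1.26$ and $\varepsilon = 9.27$ MPa). The package always
  computes with the $(\pi_0, \varepsilon)$-derived value and carries the
  measured TLP as metadata only; resolving the inconsistency is a
  measurement question, not a modelling one.
* **Xylem vulnerability.** $PLC(\Psi) = 100/(1 + \exp((s/25)(\Psi -
  P_{50})))$, parameterized so the slope of the curve at $P_{50}$ equals
  the trait $s$ in % MPa⁻¹ — the convention of centrifuge-derived curves.
  Leaves and stems share one curve (a stated assumption of the source trait
  sets; species with strong vulnerability segmentation would need two).
  PLC is kept as a running maximum: embolized conduits do not refill within
  a dry-down.
* **Stomata.** $g_s = g_{smax} \cdot \text{light} \cdot
  (\text{turgor}/-\pi_0)$ — linear in relative turgor, the simplest
  continuous rule that makes closure emerge exactly at the derived turgor
  loss point, with a binary light factor (PAR threshold 10 µmol m⁻² s⁻¹).
  Canopy transpiration is $E = g_s \cdot \mathrm{VPD}/P_{atm}$ over the
  remaining leaf area.
* **Residual and bark conductance.** Residual conductance follows a
  two-phase Q10 response about the transition temperature $T_p$:
  $g(T) = g_{res}\,Q_{10a}^{(T-25)/10}$ below $T_p$, continuing with
  $Q_{10b}$ above it (reference temperature 25 °C). Bark conductance is
  twice the leaf/shoot residual conductance, applied over the trunk and
  branch lateral surfaces.
* **Leaf shedding.** Drought-deciduous species shed canopy along
  $PLF = 100/(1+\exp(4\,(\Psi_{leaf}+1.8)))$ (% of initial leaf area; the
  built-in poplar constants). The applied loss is the running maximum of
  PLF — regrowth within a dry-down would be unphysical.
* **Atmosphere.** VPD from the Tetens saturation vapour pressure,
  atmospheric pressure 101.3 kPa by default (configurable; the reference
  site sits at ~350 m).

### Plant architecture

A fractal allometric scheme turns height, basal diameter and leaf area into
compartment dimensions: the trunk is a cylinder; branch and root ensembles
scale from it by fixed ratios (branch volume 0.8× trunk, branch diameter
one third of basal, root volume 1.0× trunk); bark area is the lateral
surface of the trunk and branch cylinders. Whole-plant conductance
$k_{plant} \times LA$ (default $k_{plant} = 1.5$ mmol s⁻¹ m⁻² MPa⁻¹) is
partitioned in series: 50% of the resistance in the root, 12.5% trunk,
12.5% branch, 25% leaf. Symplast water scales as
`symplast_volume_per_area` × LA (default 0.1 L m⁻², split 10/20/20/50%
across root/trunk/branch/leaf); the cavitation-releasable apoplast adds
$a/(1-a)$ times that (default apoplastic fraction $a = 0.4$, split
20/30/30/20%). These partition constants are declared model defaults, not
measured quantities, and are deliberately exposed: the two storage
parameters participate in the sensitivity analysis.

### Pot soil

One soil layer (the pot surface is film-covered, so soil evaporation is
zero). Relative water content is expressed as percent of pot volume;
retention is Campbell, $\Psi = \Psi_e\,\theta_{eff}^{-b}$ with $b = 6$
(sandy clay) and $\Psi_e$ solved so the curve passes through −0.033 MPa at
field capacity (37%, residual 9%). The soil-to-root interface conductance
declines as $\theta_{eff}^{\,2b+3}$ from a deliberately large saturated
value, so the interface only throttles supply as the soil approaches
residual content. Two consequences of this retention shape are worth
knowing: most of the pot's extractable water sits near field capacity, and
the soil effectively disconnects from the root once it is a few tenths of
a MPa dry.

**Initial condition.** Simulations start with the soil at field capacity.
A freely drained pot cannot hold water above field capacity — an
irrigation system maintaining "saturation" leaves the pot at its capacity
once gravitational drainage has finished — and the model has no drainage
term, so initializing at the retention curve's nominal saturation would
force the plant to transpire water that in reality drains away. The
initial content is exposed as `theta_init` for users who want otherwise.

## Numerics

The stepper is semi-implicit: at each sub-step the forcing is interpolated,
stomatal conductance and the evaporative sinks are evaluated explicitly at
the current state, and the linearized five-node chain is advanced by
backward Euler, solved directly as a tridiagonal system in compiled code.
Sub-steps adapt so that no compartment potential moves more than
`dpsi_max` (0.05 MPa by default) per step, between `dt_min` (1 s) and
`dt_max` (600 s); the leaf pool's time constant is tens of seconds at
realistic parameterizations, which an explicit scheme at 600 s cannot
handle. Water pools are tracked in moles with antisymmetric fluxes, so mass
is conserved by construction; the only losses of accounting fidelity are
explicit pool clamps (relative content floored at 0.01, soil potential
clipped at −50 MPa), which are accumulated and reported, and every run
warns if the residual exceeds `mass_balance_tol` (0.1% of initial water per
simulated day). Output is hourly regardless of internal sub-stepping. Runs
stop at 99% leaf PLC (`stop_plc`) or after `max_days`.

## Dehydration metrics

Stomatal closure is diagnosed operationally, as in dry-down experiments: the
water potential at an 88% reduction of midday transpiration. The threshold
is applied relative to the trajectory's own maximum midday E rather than to
a measured closure potential, so the metric remains self-consistent when
traits are perturbed in sensitivity runs; the measured value stays available
for validation. Midday is the 12:00–14:00 mean; predawn is the 05:00
sample; crossing times are linearly interpolated. The 88% reduction is
applied to transpiration (the balance-measured quantity), not to stomatal
conductance. Hydraulic failure is the first crossing of
$\Psi$ at 99% PLC on the species vulnerability curve; `T_cav` and `THF` are
flagged unreached (NA) when a run never gets there — as happens for
late-season experimental dry-downs — rather than extrapolated.

## Trait extraction

Each fitter mirrors how the corresponding bench measurement is analysed,
and each is tested by round-tripping the package's own forward model:

* `midday_transpiration_from_mass()` — least-squares slope of pot mass over
  the two hours around midday, normalized by leaf area; the slope over all
  in-window samples is what makes a 50 g balance quantization tolerable.
* `fit_pgs88()` — Weibull curve $E = E_{max}\exp(-((-\Psi)/b)^c)$ fitted on
  tension (so $b > 0$) by multi-start nonlinear least squares; the closure
  point is where the fitted curve reaches 12% of its own $E_{max}$, not of
  the largest observed point.
* `fit_pressure_volume()` — the classical $-1/\Psi$ versus $1-RWC$
  analysis; the post-turgor-loss segment is chosen by maximizing tail
  linearity, and TLP is reported from the fitted $(\pi_0, \varepsilon)$.
* `fit_residual_conductance()` — detects the post-closure phase as the
  longest terminal window with a stable mass-loss slope (halves agreeing
  within 10%), then normalizes by VPD/P and surface area (double-sided leaf
  area plus stem cylinder for broadleaves, projected leaf area for
  conifers).
* `fit_temperature_response()` — two-segment fit of $\ln g$ against $1/T$
  with an exhaustive breakpoint search over interior splits (cheap at six
  levels, and immune to the instability of derivative-based breakpoint
  detection); $T_p$ is the segment intersection. Each Arrhenius slope is
  converted to a Q10 at its own segment-mean temperature — converting both
  at a single fixed temperature injects a systematic ~10% curvature error
  into the upper segment over a 30–55 °C span, which would break the
  round-trip against the package's native Q10 form. Slopes that differ by
  less than 15% are declared indeterminate (a single-Q10 response bends by
  about that much on the Arrhenius axis over this span).

## Sensitivity analysis

`saltelli_design()` draws the base matrices from a Halton low-discrepancy
sequence with a seeded Cranley–Patterson shift; `sobol_total_indices()`
implements the Jansen total-order estimator (lower variance than the
alternative total-order forms at equal N), with bootstrap confidence
intervals over design rows, imputing up to 10% failed runs by the median
response. The estimator is verified against the closed-form Ishigami
indices and analytic additive models. `run_sensitivity()` perturbs each
selected trait within ±10% of its base value, standardizes plant size and
pot across species, forces the constant synthetic summer-day climate, and
returns indices for `T_close`, `T_cav` and `THF`. The default 12-parameter
subset ($\pi_0$, $\varepsilon$, $g_{smax}$, $g_{res}$, $Q_{10a}$,
$Q_{10b}$, $T_p$, $P_{50}$, slope, apoplastic fraction, symplast volume per
area, $k_{plant}$) covers every trait that plausibly moves a dehydration
time in this model at desk scale; the list is configurable.

## Synthetic observations

`generate_observed_dataset()` emulates the pot experiment's data streams:
balance mass every 5 minutes quantized to 50 g (tare held constant, soil
evaporation zero under film, watering events out of scope — a dry-down
only); predawn and midday water potentials every few days with additive
Gaussian noise (0.15 MPa default, homoscedastic; an optional mode doubles
the noise after closure, mimicking the higher variability seen near peak
stress in shedding canopies); and daily shed-leaf dry mass for deciduous
runs (at a nominal 100 g m⁻² leaf dry mass). The noise-free truth is kept
alongside so recovery can be measured. What it does **not** emulate:
within-canopy variability, micro-CT embolism observations, rewatering
recovery, or instrument drift — so a pipeline that passes these tests is
validated for estimator correctness, not for robustness to every field
artefact.

## Study conditions and problem sizes

The package's standardized comparisons use a common plant (leaf area
1.5 m², height 1.5 m, basal diameter 3 cm), a 25 L pot, and a synthetic
summer day cycling 15–32 °C and 30–80% relative humidity with a 1800 µmol
m⁻² s⁻¹ PAR peak — a realistic mid-size sapling configuration whose full
dry-downs complete in one to five simulated weeks, keeping four-species
panels and N = 128 Saltelli designs (1792 simulations per species) fast
enough to run routinely. The test suite uses these sizes throughout; the
sensitivity tests additionally check that top-ranked traits are stable
between N = 64 and N = 128.

## Known limitations

* **Cross-species THF ordering is sensitive to the shared-vulnerability
  assumption.** With one vulnerability curve for leaf and stem, a species
  with a very shallow slope (the holm oak fixture: 23% MPa⁻¹ at
  $P_{50} = -7.13$) must dehydrate to ≈ −12 MPa to reach 99% PLC and
  therefore survives post-closure longer than a conifer whose threshold
  sits at −6.8 MPa, despite nearly identical residual conductances. Under
  the standardized panel this places the holm oak above the cedar in THF;
  configurations with vulnerability segmentation or different storage
  scaling could reverse that pair.
* **Early-phase sensitivity reflects the pot's retention shape.** Because
  the Campbell curve anchored at field capacity concentrates extractable
  water near saturation, the pre-closure phase is dominated by bulk drain
  at open stomata, making $g_{smax}$ (and $k_{plant}$) the leading
  controls of `T_close` for most parameterizations, with $\pi_0$ second;
  $\pi_0$ leads only where transpiration is strongly supply-limited (the
  poplar fixture). Flatter field-soil retention would shift weight toward
  the closure threshold and hence $\pi_0$.
* Single soil layer, no root growth, no rooting-depth variation, no
  refilling or rewatering recovery, no photosynthesis/carbon coupling, no
  ABA signalling; the five-compartment topology and its partition
  constants are declared simplifications whose adequacy is judged by the
  oracle and property suites, not by equivalence to any larger model.

## A minimal session

```{r example, eval = FALSE}
tr <- load_species_traits("Pin_hale")
climate <- synthesize_climate(60)
traj <- run_dehydration(tr, soil = soil_params(pot_volume = 100),
                        climate = climate)
dehydration_times(traj)

panel <- simulate_species_panel(builtin_species(), standardized = TRUE,
                                climate = climate)
sapply(names(panel), function(nm)
  dehydration_times(panel[[nm]], load_species_traits(nm))$thf)

sens <- run_sensitivity("Pop_nigr", N = 128, seed = 7)
rank_sensitivity(sens, "t_cav")
```
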