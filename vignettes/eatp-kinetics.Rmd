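---
title: "Modelling extracellular ATP turnover in intestinal epithelial cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling extracellular ATP turnover in intestinal epithelial cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purinome)
```

## The system being modelled

Intestinal epithelial cells release intracellular ATP (iATP) into the
extracellular space and, at the same time, express a set of
membrane-bound ecto-enzymes that interconvert and degrade extracellular
nucleotides. The concentration of extracellular ATP (eATP) measured by
luciferin–luciferase luminometry is therefore the net result of several
competing fluxes:

* **release** — a small constitutive leak, a strong but transient
  *non-lytic* release triggered by hypotonic swelling, and (only under
  severe, 100 mOsm, shocks) a *lytic* component;
* **hydrolysis** — ecto-ATPase (eATP → eADP), ecto-ADPase
  (eADP → eAMP), ecto-5′-nucleotidase (eAMP → adenosine) and
  ecto-NTPDase activity on non-adenine triphosphates;
* **synthesis** — ecto-adenylate kinase (ecto-AK, 2 eADP ⇌ eATP + eAMP,
  blocked by Ap5A) and ecto-NDP kinase (ecto-NDPK,
  eADP + eNTP ⇌ eATP + eNDP, fed by eCTP, eUTP or eGTP).

`purinome` implements these fluxes as an eight-species ODE system —
the adenine ladder eATP, eADP, eAMP, eADO plus two donor pairs
eUTP/eUDP and eCTP/eCDP — together with the estimators used to
parameterize it from luminometry time courses.

## State, units and sign conventions

Concentrations are in µM referred to the assay volume (100 µL in the
underlying experiments). Time is in minutes. Every rate constant is
stored *per mg of cell protein* and multiplied by the assay protein
mass `M_cell` (default 0.2 mg) inside flux evaluation; this lets
per-mg constants reported by plate assays be used verbatim, and makes
"µM/mg protein" reporting a view (`tc_species(tc, per_mg = TRUE)`)
rather than a stored quantity.

Both ecto-kinase fluxes are signed in the **eATP-consuming** direction,
so the ODEs read

$$\frac{d\,\mathrm{eATP}}{dt} = J_{ATP} - (J_{ATPase} + J_{AK} + J_{NDPK}),
\qquad
\frac{d\,\mathrm{eADP}}{dt} = J_{ATPase} - J_{ADPase} + 2 J_{AK} + J_{NDPK},$$

$$\frac{d\,\mathrm{eAMP}}{dt} = J_{ADPase} - (J_{AK} + J_{AMPase}),
\qquad
\frac{d\,\mathrm{eADO}}{dt} = J_{AMPase},$$

and for each donor pair $d\,\mathrm{eNTP}/dt = J_{NDPK} - J_{NTPase}$,
$d\,\mathrm{eNDP}/dt = -J_{NDPK} + J_{NTPase}$. Two exact algebraic
identities follow and are enforced by property tests: the sum of the
four adenine derivatives equals the release flux $J_{ATP}$ (all
enzymatic fluxes cancel), and each NTP + NDP pair total is conserved.
eCTP hydrolysis is represented by the same NTPase term with a
per-compartment constant: zero for non-polarized and basolateral
parameter sets, positive apically.

## Rate laws and the committed functional forms

Measured activities pin down the *linear* laws directly:
ecto-ATPase and ecto-ADPase rates are $k\cdot[\mathrm{substrate}]$
per mg (constants 0.1 and 0.008 for non-polarized cells; 1.70 vs 0.36
for the apical vs basolateral ecto-ATPase), and ecto-5′-nucleotidase is
Michaelis–Menten. For the two ecto-kinases the source literature names
the parameters but not a closed-form rate expression, so the package
commits to specific forms chosen to honour every measured property:

**Ecto-AK.** A reversible Hill-2 expression,

$$J_{AK} = V_{max,AK}\,
\frac{[\mathrm{eATP}][\mathrm{eAMP}]/K_{eq,AK} - [\mathrm{eADP}]^2}
{K_{half}^2 + [\mathrm{eADP}]^2 + [\mathrm{eATP}][\mathrm{eAMP}]/K_{eq,AK}},$$

which is thermodynamically null when
$[\mathrm{eADP}]^2 = [\mathrm{eATP}][\mathrm{eAMP}]/K_{eq,AK}$
(here $K_{eq,AK} \approx 0.44$ is the equilibrium constant of
2 eADP ⇌ eATP + eAMP), sigmoidal in eADP on the synthesis branch —
reproducing the observation that ecto-AK activity is very low below
3 µM eADP — and reaches half its maximal synthesis rate exactly at
$[\mathrm{eADP}] = K_{half}$ (6 µM by default). $V_{max,AK}$ is not
free: it derives from the kinetic scheme as
$F_{tr,AK}\,k_{-2}k_1/(k_{-2}+k_1)$ (`vmax_ak_from_scheme()`). Ap5A is
modelled as a hard switch setting $J_{AK}=0$; the residual ~10%
activity reported at 48 µM eADP is deliberately not modelled.

**Ecto-NDPK.** A reversible ping-pong bi-bi expression per donor pair,
with substrates $A=[\mathrm{eADP}]$, $B=[\mathrm{eNTP}]$ and products
$P=[\mathrm{eATP}]$, $Q=[\mathrm{eNDP}]$:

$$J_{NDPK} = -V_{max}\,\frac{AB - PQ/K_{eq}}{D},\qquad
D = K_{mAD}B\Big(1+\tfrac{Q_{pool}}{K_{iNDP}}\Big)
  + K_{mNTP}A\Big(1+\tfrac{P}{K_{iADP}}\Big)
  + AB + \frac{K_{mAT}Q + K_{mNTP}P + PQ}{K_{eq}}.$$

The flux vanishes exactly at the mass-action equilibrium, saturates at
$-V_{max}$ (full-speed synthesis) under saturating substrates, and is
driven into net eATP consumption by product excess. One detail matters
for the eUDP-competition experiment: the donor pairs share a single
enzyme, so the $K_{iNDP}$ product term uses the *pooled* non-adenine
NDP concentration ($Q_{pool} = \mathrm{eUDP}+\mathrm{eCDP}$). This is
what lets 5 mM eUDP — added as an ordinary addition event, not a
special inhibitor — suppress CTP-driven eATP synthesis by ~91% purely
through the rate law. GTP-donor protocols reuse the eUTP/eUDP state
slots with GTP-specific constants, since the guanine pair obeys the
same equation pattern.

**Release.** $J_{ATP} = J_{leak} + J_{NL}(t) + J_L(t)$, with
$J_{NL}=0$ before the stimulus and
$A_{NL}(\mathrm{osm})\,e^{-k_{obs}(t-t_s)}$ afterwards — an
instantaneous rise with first-order inactivation, the simplest shape
consistent with a release flux that peaks immediately and inactivates
within minutes. $J_L$ is a constant $k_L$ from the stimulus onward,
only for 100 mOsm. Amplitudes are osmolarity-specific; unregistered
osmolarities interpolate linearly between the four calibrated anchors.

## Default parameter values

The printed, directly measured constants are used verbatim:
$k_{ATPase}$ = 0.1 (non-polarized), 1.70 (apical), 0.36 (basolateral);
$k_{ADPase}$ = 0.008 with the basolateral value 0; peak 180 mOsm
release flux 1.2 µM/min/mg; assay protein mass 0.2 mg; basal eADP
0.22 µM pre-stimulus (the directly measured 0.15 µM is available as an
override — which value the original fit used is not stated, so the
model's own pre-stimulus value is the default).

Constants not printed anywhere were fixed once at literature-scale
values and calibrated against the reported observations, then frozen:
$K_{half}$ = 6 µM (makes synthesis at 1 µM eADP < ¼ of that at 3 µM);
$k_{obs}$ = 0.5/min and $J_{leak}$ = 0.004 µM/min/mg (together with
$A_{NL}(180)=1.2$ these place the eATP peak at ~12-fold basal and
~3.5% of the intracellular pool, matching the reported 3.6%);
NDPK constants $V_{max}=5$ µM/min/mg, $K_{mAD}=50$, $K_{mAT}=170$,
$K_{mNTP}=100$, $K_{iADP}=100$, $K_{iNDP}=300$ µM, $K_{eq}=1$
(phosphotransfer between NTPs is nearly isoenergetic; $K_{iNDP}$ set so
pooled-NDP inhibition reproduces the observed ~91% eUDP suppression);
ecto-kinase maximal velocities ordered apical > non-polarized >
basolateral as the polarized fits require. A note on one figure
caption: the "12-fold" ecto-ADPase increase is implemented as
12 × 0.008 = 0.096, treating the printed 0.96 as a typo.

## Numerical choices

Integration uses LSODA (automatic stiff/non-stiff switching — release
transients of seconds coexist with enzymatic decays of tens of
minutes) with relative tolerance 1e-6, absolute tolerance 1e-12 and at
most 1e5 internal steps. Addition events are instantaneous
concentration jumps with an integrator restart; the stimulus time is
also forced as a restart point. Trajectories are reported on the
protocol grid; tightening tolerances ten-fold changes bundled
scenarios by less than 0.1% (sup-norm). Tiny negative excursions
(within 1e6 × the absolute tolerance) are clipped to zero; larger ones
abort with a diagnostic. The value reported *at* an event time is the
pre-event state.

Uncertainty envelopes follow a full-grid parameter scan: each scanned
parameter takes exactly four values spanning best ± SE. The source
procedure states only "one at the lowest value, one at the highest and
two in the middle"; the two interior points are placed at ± SE/3 (even
spacing), a choice that affects band width only marginally since the
envelope is dominated by the endpoints. More than six scanned
parameters (4⁷ = 16k simulations) requires `force = TRUE`.

## Estimators

`fit_initial_velocity()` fits $eATP = A(1-e^{-kt})$ to the first five
minutes after substrate addition (time re-zeroed, last pre-addition
point as baseline) and reports $v_0 = A\,k$, the exact derivative at
$t=0$; it is exact on noiseless data of that form. `fit_ectoatpase_constant()`
turns decay curves at ≥ 3 eATP levels into per-mg initial decay
velocities and regresses them on concentration; the slope is
$k_{ATPase}$.

`fit_global()` fits free parameters to several experiments
simultaneously by weighted least squares: residuals per scenario are
normalized by that scenario's maximum observed concentration (the
original estimation software's weighting scheme is unstated; max
normalization keeps µM-scale NDPK assays from dominating nM-scale
basal data), each replicate is simulated with its own recorded protein
mass, and optimization runs Levenberg–Marquardt on log-transformed
parameters — optionally preceded by a seeded random multistart stage
(`strategy = "global"`), whose trace is guaranteed non-increasing.
Standard errors come from the Gauss–Newton curvature at the optimum
with a delta-method transform back to the natural scale; parameters
with SE > 10× their value are flagged as weakly identified, not
hidden. A bootstrap is intentionally not bundled: the reported
"best ± standard deviation" convention does not specify a method, and
the curvature-based SE is the one the parameter-scan envelope
consumes.

## What the synthetic generator does and does not emulate

`generate_timecourses()` mimics the luminometry measurement chain:
simulate with a replicate-specific protein mass (normal around 0.2 mg,
CV 15%), apply a linear light → concentration calibration whose slope
is jittered per replicate (SD 2%), then add an additive noise floor
(0.02 µM) plus a 5% multiplicative term, clipping at zero. Replicate
counts default to the experimental range (2–7; the suite uses 3). The
generator records its truth, so `make_recovery_suite()` gives an
end-to-end parameter-recovery harness.

It deliberately does **not** simulate photon counts, luciferase
consumption of eATP, temperature effects, receptor feedback or spatial
gradients across a monolayer. Passing recovery tests therefore shows
the estimators are consistent under the model's own noise assumptions —
not that the model is correct for any particular real cell
preparation.

Test and recovery problem sizes (3 scenarios × 2–3 replicates,
141-point grids, ≤ 40 LM iterations, 20-replicate stability loops) were
chosen as the smallest sets in which all free parameters remain
identifiable; recovery errors at these sizes are ~1–2% for the release
and hydrolysis constants and within 30% for the AK parameters, which
are weakly informed below a few µM eADP.

## Interpretation conventions

`percent_inhibition()` subtracts the pre-stimulus baseline by default,
so it measures inhibition of eATP *synthesis*; with a hard AK block
this yields exactly 100%, matching the "non-detected" treated wells it
models. The raw concentration ratio (which is ~94% for the same
comparison because basal eATP never vanishes) is available with
`baseline = FALSE`. `delta_atp()` uses the mean of all pre-stimulus
points as its baseline — the alternative single-point convention makes
no practical difference on flat baselines but averages out noise on
real data.

One reported number deserves a caveat: the claim that eATP rises
~12-fold "to a maximum in less than 2 seconds" under 180 mOsm is not
jointly realizable with a peak release flux of 1.2 µM/min/mg (0.24
µM/min in a 0.2 mg assay cannot move ~0.4 µM of eATP in 2 s). The
package takes the *release flux* to peak instantaneously at the
stimulus, with the eATP maximum (~11.5-fold basal under default
calibration) following over minutes, which is consistent with every
other quantity reported.

## Known limitations

* Intracellular metabolism, P1/P2 receptor dynamics, luciferase
  consumption of eATP and spatial gradients are out of scope.
* The deposited reference parameter files are not bundled; the default
  `parameter_set` is this package's own calibration to the printed
  constants and observations, and quantitative predictions that depend
  on unprinted fitted values (e.g. the exact 17%/33% ecto-ADPase
  scaling figures, reproduced here as ~15%/36%) should be read at that
  precision.
* SBML support is structural: documents are written with explicit
  MathML and validated for required structure, and re-import recovers
  parameters, initial state and events (not arbitrary third-party
  kinetic laws).

## A worked example

```{r example, eval = FALSE}
library(purinome)
p <- default_parameters()
tc <- simulate_protocol(build_scenario("hypotonic_180"), p)
max(tc_species(tc, "eATP"))          # ~0.46 uM peak
delta_atp(tc)                        # ~0.28 uM accumulated at 30 min
percent_iatp(max(tc_species(tc, "eATP")) / p$M_cell)  # ~3.5% of iATP

ctrl <- simulate_protocol(build_scenario("ndpk_ctp100_adp12"), p)
udp  <- simulate_protocol(build_scenario("ndpk_ctp100_adp12_udp5mM"), p)
percent_inhibition(ctrl, udp)        # ~91% suppression by 5 mM eUDP
```
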