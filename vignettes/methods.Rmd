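---
title: "Models and methods behind sarcphos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sarcphos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcphos)
```

sarcphos analyses spatially controlled phosphorylation of the cardiac myosin
regulatory light chain (RLC) and its mechanical consequences for the
sarcomere. This vignette documents the models, the defaults and the design
choices, in the order the pipeline uses them.

## Thick-filament geometry

The half thick filament is a stack of myosin crowns indexed from the M-line,
partitioned contiguously into the P-zone (proximal to the bare zone), the
C-zone (the cMyBP-C-containing region) and the D-zone (toward the filament
tip). The default configuration — 49 crowns of 3 myosin dimers (294 heads per
half filament), 14.33 nm crown spacing, 80 nm bare-zone half width, zones
P = 4, C = 27, D = 18 crowns — was chosen so that

* the C-zone carries 27/49 = 55.1% of the heads, the accepted fraction for
  rodent cardiac thick filaments;
* the mirrored A-band doublet spans 1.56 µm, inside the 1.52–1.58 µm range
  measured for ventricular myofibrils;
* the C-zone doublet outer width is about 1.05 µm, matching C-zone width
  estimates from electron microscopy and cMyBP-C imaging (~1–1.1 µm).

Each dimer carries exactly one *blocked* and one *free* head, the two
conformationally distinct heads of the folded interacting-heads motif.

## Two-population phosphorylation kinetics

RLC phosphorylation in the intact filament lattice behaves as (at least) two
head populations with very different kinase susceptibility. Each population
follows mass-action kinase/phosphatase kinetics, giving the closed form

$$p_i(t) = p_{ss,i} + (p_{0,i} - p_{ss,i})\,
  e^{-(k_{P,i}[K] + k_{D,i}[P])\,t}, \qquad
  p_{ss,i} = \frac{k_{P,i}[K]}{k_{P,i}[K] + k_{D,i}[P]}.$$

The total signal is the fraction-weighted sum scaled by `p_max`, the
attainable ceiling (about 0.65 with BDM and 0.95 with blebbistatin as the
myosin inhibitor — represented *only* through `p_max`, with no mechanistic
state coupling). Michaelis–Menten saturation of the kinase is deliberately
not modelled: the observables here are phenomenological exponentials and
hyperbolae, and mass action reproduces them exactly.

Defaults: the fast population comprises the P- and C-zone heads (fraction
31/49 = 0.633) with $k_P$ ten times the slow (D-zone) population's, and
$k_D/k_P$ ratios of 0.01 and 0.1 µM, so that at 0.1 µM phosphatase the two
steady-state half-max kinase concentrations are 0.01 and 0.1 µM. The
time-course fixture uses kinase only (no phosphatase), making the observed
rates 0.2 and 0.02 min⁻¹ — exactly one order of magnitude apart. An
alternative `fast = "C"` fixture (0.551/0.449) is available; whether P-zone
heads belong with the fast population is not established experimentally, and
nothing downstream depends on the choice except the precise spillover onset.
The ADP-biosensor readout is strictly linear in transferred phosphate by
construction.

Model selection between mono- and biexponential fits uses a residual F-test
at $\alpha = 0.05$ on nested least-squares fits (Levenberg–Marquardt, three
heuristic starts each).

## Synthetic immunofluorescence profiles and FWHM

Profiles are rendered for a single A-band doublet: every crown of both
mirrored half filaments contributes a 1-D Gaussian PSF weighted by heads ×
occupancy. The PSF sigma defaults to 60 nm (FWHM ≈ 140 nm, plausible for a
spinning-disk super-resolution system; no instrument value is available) and
the pixel size to 32.5 nm. FWHM is measured after subtracting a background
estimated from the outer 10% of pixels, as the distance between the
*outermost* linear-interpolated half-maximum crossings — the right convention
for a doublet with a central dip. Note that the FWHM of a plateau-like
profile is almost independent of the PSF width (a Gaussian-blurred step
crosses half-maximum at the step), so these widths are set by the geometry,
not the optics.

Occupancy placement offers a *sequential* mode — the C-zone fills uniformly
first, then D-zone crowns fill one by one outward from the C/D boundary,
then the P-zone (`fill_order = "C_then_D"`); or P and C filling together
first (`"PC_then_D"`) — and a *kinetic* mode that places the two-population
time course's fast/slow occupancies on their zones at the time matching the
requested global level. Head-weighted mean occupancy always equals the
requested level exactly.

A known limitation: at a global level of 0.6 the strict sequential model
spills only ~2.4 crowns (~35 nm) into the D-zone, so the rendered doublet
width grows to ~1.13 µm. Measured profiles at that level are wider
(~1.25 µm); real images include sarcomere-registration jitter, antibody
displacement and residual optical blur that a noise-free single-sarcomere
render deliberately excludes. The package reports what the geometric model
produces rather than inflating the PSF to force agreement — any spillover
front with the same spilled mass crosses half-maximum at nearly the same
place, so this gap is informative about the model, not a tuning failure.

## The mechanosensing half-sarcomere model

Myosin heads cycle independently through OFF (folded), ON (available) and FG
(force-generating, attached):

$$\mathrm{OFF}
  \underset{k_2}{\overset{k_1(F)}{\rightleftharpoons}} \mathrm{ON}
  \underset{k_4}{\overset{k_3 \cdot a \cdot \lambda}{\rightleftharpoons}}
  \mathrm{FG},$$

with $k_1(F) = k_1^0 (1 + g\,k_F\,F_{sense})$. Thick-filament mechanosensing
enters only here: $F_{sense}$ is the *whole half-filament* force (active
plus titin-like passive, $F_{pas} = G_{pas}\max(0, SL - SL_{slack})$), and
the phosphorylation factor $g = \phi_P$ applies only to heads selected by
the placement variant — Model A (C-zone blocked heads), Model B (blocked
heads everywhere), Model C (both C-zone heads). $\phi_P$ multiplies the
force-dependent term, not $k_1^0$, so phosphorylation has no effect at zero
load, consistent with the near-absence of structural change in relaxed
muscle. Whether the in-vivo sensor is node-local or filament-global is not
known; the global choice keeps the mean-field and stochastic engines
exactly comparable.

Thin-filament regulation uses 26 units of 7 actins per thin filament (two
thin filaments per thick at desk scale). A unit activates at
$a_{on}[Ca](1 + a_{coop}\,n_{active\ neighbours})$ and deactivates at
$a_{off}(1 - f_{att})^{a_{hold}}$, where $f_{att}$ is the attached fraction
of the heads the unit regulates: bound crossbridges hold their unit on, the
classical second source of force–pCa cooperativity. The exponent
$a_{hold} = 1.5$ is a soft version of the hard "cannot switch off while
occupied" rule, chosen together with $a_{coop} = 4$ so the baseline Hill
coefficient sits near the experimental ~3–4 without making the
force-feedback loop bistable (a hard block on ~6 heads per unit makes the
activation switch unrealistically steep at this small system size, and a
near-critical mechanosensing loop produces giant, phosphorylation-insensitive
pCa50 shifts).

Filament overlap gates attachment per crown from the sarcomere length and a
1.12 µm thin filament; at the lengths studied (1.9–2.3 µm) all crowns
overlap, so length dependence enters through passive force — which is also
why the model's baseline pCa50 shift with length is calibrated through
`passive_gain`. Attached heads bear a constant 2 pN (no strain dependence,
no compliance, single attached state): isometric steady states and
redevelopment rates at desk scale do not require a strain-resolved
crossbridge, and this keeps the likelihood evaluations fast enough for
ensemble MCMC in R.

Default rates ($k_1^0 = 5$, $k_2 = 80$, $k_3 = 80$, $k_4 = 12$ s⁻¹,
$k_F = 0.0045$ pN⁻¹, $\phi_P = 6$) put ~6% of heads ON at zero load and let
load recruit the rest; $a_{kon}$ and `passive_gain` are not fixtures but
calibration outputs (see below). $k_2$ was raised from an initial guess of
50 s⁻¹ because the lower OFF bias made the fitted phosphorylation response
too weak at long sarcomere length; the kinetic scheme itself has no
published rate values to inherit.

### Engines

* `mean_field_ss` — the algebraic fixed point of the coupled
  (activation, force) system, iterated monotonically from the relaxed state;
  this is the engine inside likelihoods and calibration.
* `mean_field` — `deSolve::lsoda` integration of the class-aggregated ODEs;
  used for protocols (ktr, slack–restretch) and to verify that the algebraic
  steady state equals the long-time ODE limit.
* `monte_carlo` — per-head tau-leaping at dt = 0.5 ms with seeded RNG.
  Head transition probabilities are rate × dt (with a hard error if any
  head rate × dt exceeds 0.1); regulatory-unit switching uses the exact
  exponential probability $1 - e^{-r\,dt}$ because calcium binding rates at
  saturating Ca²⁺ can exceed the tau-leap comfort zone while remaining a
  simple two-state toggle.

In slack–restretch protocols the preparation is unloaded between release and
restretch ($F_{sense} = 0$, recorded force 0); the restretch forcibly
detaches all attached heads (FG → ON) and force redevelopment is fitted with
a single exponential to give ktr.

### Calibration and fitting

`calibrate_baseline()` root-finds $a_{kon}$ so the unphosphorylated pCa50 at
SL 1.9 µm equals 5.56, then `passive_gain` so the SL 2.3 µm pCa50 equals
5.64 (+0.08 with length). Because titin slack length is taken as 1.9 µm,
passive force vanishes at short SL and the two root-finds nest cleanly.

The four experimental force–pCa conditions are reconstructed as Hill curves
through the published sensitivities (5.56/5.64 at short SL, 5.64/5.76 at
long SL) with $n_H = 4$ fixtures except the phosphorylated long-SL curve
($n_H = 2.8$, encoding the observed loss of cooperativity; the value is a
fixture, not a measurement), observation sigma 0.03. The free parameters
$\{\phi_P, k_F\}$ are sampled with a Goodman–Weare affine-invariant ensemble
(implemented in the package; log-uniform priors, $\phi_P \in [1, 40]$,
$k_F \in [10^{-4}, 0.2]$ pN⁻¹, default 16 walkers × 150 steps, burn-in a
third) against the mean-field steady-state engine; stochastic-engine checks
are run afterwards at the MAP. Model discrimination evaluates variants B and
C at Model A's best-fit parameters: both roughly double the summed squared
residual because they boost about twice as many heads, overshooting the
measured shifts.

Problem sizes were chosen for a desk-scale analysis: one thick filament per
half-sarcomere, 9-point pCa grids inside the likelihood, a 19-point grid
(pCa 6.6–4.8, step 0.1) for reported pCa50 values, and reduced walker/step
counts in the test suite (12 × 60).

## Orientation analysis

The RLC E-helix orientation is described by Euler angles: β between the
E-helix and the filament axis, γ the rotation about the E-helix. Polarized
fluorescence cannot distinguish (β, γ) from (180° − β, γ + 180°), so all
orientation densities are shown with both partners.

`max_entropy_map()` solves the least-informative distribution on a 2° (β, γ)
grid consistent with measured ⟨P₂⟩ (and optionally ⟨P₄⟩) values of one or
more probe axes: $f \propto \exp\left(\sum_j \lambda_{j2} P_2(\cos\theta_j) +
\lambda_{j4} P_4(\cos\theta_j)\right)$ with the multipliers found by BFGS on
the convex dual; achieved moments match inputs to 10⁻⁴, and the degeneracy
symmetry is automatic because $P_2$ and $P_4$ are even in $\cos\theta$. The
rank-4 truncation matches what single-photon polarized fluorescence
determines. ⟨P₂⟩ extraction from raw intensities is out of scope: the module
ingests order parameters.

`euler_from_structure()` reads atomic models through bio3d, takes the
first principal axis of the E-helix Cα span (oriented N→C), and fixes the
γ = 0 convention to "reference vector in the (E-helix, filament-axis)
plane". Residue spans are user inputs since no single convention exists.

⟨P₂⟩ transients are analysed as two single-exponential phases: Ph1 between
release and restretch (recovery toward the relaxed value as heads detach)
and Ph2 after restretch (heads leaving OFF and attaching). The simulator's
occupancies map onto predicted ⟨P₂⟩ through per-state basis values
(defaults OFF 0.15, ON −0.05, FG −0.15 — ordered so activation lowers ⟨P₂⟩,
i.e. heads become more perpendicular; the absolute values are fixtures).

## What the synthetic data do and do not show

The generators reproduce the *statistical structure* each stage assumes —
Hill-shaped force–pCa points with Gaussian noise, biexponential time
courses, Poisson-noise doublet profiles, two-phase transients with the
published rate ordering (Ph2 ≈ ktr ≈ 13 s⁻¹ before phosphorylation; Ph2
≈ 24 s⁻¹ > ktr ≈ 16 s⁻¹ after). Passing the recovery suites shows the
estimators are unbiased at these noise levels; it does not validate the
biology of tissue-dependent magnitudes (absolute ⟨P₂⟩ levels, Ph1 rates,
basal phosphorylation), which enter only as fixture values and are asserted
only directionally.

## Known limitations

* No filament compliance, strain-dependent detachment, or realistic lattice
  geometry; twitch dynamics and ADP/Pi dependence are out of scope.
* The mean-field thin-filament closure (expected neighbours = 2a, smooth
  hold factor) differs from the discrete 26-unit chain away from saturation;
  the two engines are compared quantitatively only at saturating calcium.
* The sequential spillover model understates measured doublet widths at
  intermediate phosphorylation levels, as discussed above.
* MCMC posteriors here quantify fit uncertainty under the reconstructed-Hill
  targets, not experimental uncertainty: the curves are idealizations with
  an assumed sigma.
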