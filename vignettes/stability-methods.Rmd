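---
title: "Models and methods for protein stability and hydrodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for protein stability and hydrodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabfit)
```

This vignette is the package's own account of the science it
implements: the models, their assumptions, the numerical choices, and
what the synthetic-data validation does and does not establish about
real instrument data.

## Spectral observables

A fluorescence emission spectrum is reduced to the intensity-weighted
average emission wavelength,

$$\langle\lambda\rangle = \frac{\sum_i \lambda_i I_i}{\sum_i I_i},$$

the Royer-style scalar that tracks tryptophan solvent exposure more
robustly than the band maximum. It is invariant under intensity
rescaling and bounded by the wavelength grid; an all-zero spectrum is
a hard error rather than a silent `NaN`. The conventional acquisition
grid is 300–400 nm at 1-nm steps (the generator default), but any
strictly increasing grid is accepted.

Curves assembled from spectra are sorted by condition on ingest.
Duplicate conditions with identical signals are collapsed; duplicate
conditions with *different* signals are an error, not an average —
silent averaging would make fits depend on invisible preprocessing.

For overlaying probes with very different signal scales, curves can
be normalized to the value at the lowest condition (the first point
becomes exactly 1). The operation is sign-preserving and idempotent,
and none of the fitted midpoints (pKa, $[U]_{50\%}$, $T_m$) depend on
whether it was applied.

## Chemical denaturation

The linear extrapolation model (LEM) assumes
$\Delta G = m([U]_{50\%} - [U])$. The two-state observable with
linear baselines is

$$X(U) = \frac{X_N + X_D e^{-\Delta G/RT}}{1 + e^{-\Delta G/RT}},
\qquad X_N = \alpha_N + \beta_N U,\; X_D = \alpha_D + \beta_D U,$$

with $R = 1.987\times10^{-3}$ kcal·mol⁻¹·K⁻¹ and a default fit
temperature of 298.15 K (25 °C experiments), overridable. The
unfolded fraction at the midpoint is exactly one half, and the LEM
free energy in water is $m \cdot [U]_{50\%}$.

The three-state extension is the minimal sequential scheme
N ⇌ I ⇌ U with a *constant* intermediate signal level $\alpha_I$:

$$X(U) = \frac{X_N + \alpha_I K_1 + X_D K_1 K_2}{1 + K_1 + K_1 K_2},
\qquad K_i = e^{-m_i([U]_{50\%,i} - U)/RT}.$$

A constant (rather than sloped) intermediate level was chosen because
an intermediate's baseline is never observable over a wide enough
concentration window to constrain a slope; the scheme nests the
two-state model and reproduces probe-dependent apparent midpoints
when one probe loses its signal in the first transition and another
in the second. The joint two-probe fit shares the four thermodynamic
parameters and keeps per-probe baselines; whether baselines should
also be shared across probes is not determinable in general, so the
joint fit deliberately does not force it.

Midpoints are reported ordered ($U_{50,1} \le U_{50,2}$), enforced by
relabelling after the fit rather than by a constrained
parameterization, which keeps the optimizer's geometry simple.

**Model selection.** A three-state fit of data that a two-state model
explains is intrinsically degenerate (any placement of the
intermediate between the baselines fits). Two diagnostics are
reported: the maximum intermediate population along the fitted curve
(flagged below 5%), and — for single-curve fits — a nested two-state
refit; if the two-state sum of squares is within 5% of the
three-state one, the intermediate is declared not required.

## Thermal denaturation

Temperature enters through the Gibbs–Helmholtz relation

$$\Delta G(T) = \Delta H(T_m)\left(1 - \frac{T}{T_m}\right) +
\Delta C_p\left[(T - T_m) - T\ln\frac{T}{T_m}\right],$$

inside the same two-state Boltzmann expression with baselines linear
in temperature. Instrument I/O is in °C, computation in K (conversion
constant 273.15); the derived midpoint entropy
$\Delta S(T_m) = \Delta H(T_m)/T_m$ is reported alongside.

$\Delta C_p$ may be fitted freely or fixed at 1.2 kcal·mol⁻¹·K⁻¹, a
usual standard value for a small single-domain protein. Because the
transition region itself carries little $\Delta C_p$ information, the
fitted $T_m$ should be (and, on synthetic scans, is) insensitive to
the choice; the test suite asserts agreement within 0.1 °C. All
thermal fits are *equilibrium* fits: when a scan is not reversible
the parameters are apparent, and every fit result carries a
reversibility caveat in its metadata rather than pretending the model
covers irreversibility. Kinetic (scan-rate-dependent) models are out
of scope.

## Differential scanning calorimetry

The baseline-subtracted excess heat capacity of a two-state
transition is the van't Hoff form

$$C_{p,\mathrm{ex}}(T) = \frac{\Delta H_{vH}^2}{R T^2}
\frac{K}{(1+K)^2}, \qquad K = e^{-\Delta H_{vH}(1 - T/T_m)/RT},$$

which integrates to $\Delta H_{vH}$. A sequential three-state trace
is modelled as the sum of two independent such terms — an
approximation that ignores inter-transition coupling in the partition
function but resolves two maxima for well-separated midpoints and
keeps each transition's enthalpy interpretable. Note one genuinely
physical subtlety the test suite encodes: the $1/T^2$ prefactor
shifts the apparent maximum slightly *below* $T_m$ (≈0.15 °C for a
~60 kcal/mol transition), so "peak = midpoint" only holds to that
accuracy, and overlapping transitions pull their apparent maxima
together.

`fit_dsc` reports per-transition $(T_m, \Delta H_{vH})$, the
calorimetric enthalpy by trapezoidal integration, the temperature of
the trace maximum $T_{max}$, and $\Delta H_{vH}/\Delta H_{cal}$ — the
standard two-state diagnostic (≈1 for two-state). A systematic
negative lobe whose integrated area exceeds 5% of the endotherm area
aborts the fit as a baseline-subtraction failure; point-wise noise
excursions below zero are tolerated, since any realistic noise level
produces them. Amplitude-scaled traces emulate partially irreversible
re-heating scans: the integral scales with the refolded fraction
while $T_{max}$ does not move.

## pH titrations

Single transitions use the base-10 Henderson–Hasselbalch sigmoid with
an optional Hill coefficient (default 1, since no cooperativity model
is usually justified; bounds (0, 4]):

$$y = y_{low} + \frac{y_{high} - y_{low}}{1 + 10^{\,n(pK_a - pH)}}.$$

Double transitions use a *sum* of two signed sigmoids (not a
product): the sum nests the single model exactly at $A_2 = 0$ and
produces the "bump" shape of dye-binding titrations with
opposite-sign amplitudes, whose maximum for equal amplitudes sits at
the mean of the two pKas.

Withholding unreliable pKas is operationalized: a plateau supported
by fewer than 2 points beyond one pH unit from the midpoint, or a
fitted plateau standard error above half the amplitude, yields a
verdict of `no_acid_baseline` / `no_base_baseline`; transitions
closer than 0.5 pH units are `unidentifiable`. This mirrors the
experimental practice of reporting "could not be determined due to
the absence of baseline" instead of a number.

## Hydrodynamics

SEC elution is summarized by the partition coefficient
$\sigma = (V_e - V_o)/V_i$. Elution later than the total volume
($\sigma > 1$) is *flagged* as probable analyte–column interaction
rather than rejected, because late elution at extreme pH is real,
interpretable behaviour. The Ackers calibration
$R_S = a + b\,\mathrm{erfc}^{-1}(\sigma)$ is fitted by linear least
squares on $\mathrm{erfc}^{-1}(\sigma)$; `erfc` here is the standard
complement $1 - \mathrm{erf}$, implemented through the normal
quantile/distribution functions and verified against the defining
identities to $10^{-12}$. The calibration inverse
$V_e = V_o + V_i\,\mathrm{erfc}((R_S - a)/b)$ round-trips volumes to
$10^{-9}$ ml and powers the standards generator.

Theoretical estimators: anhydrous sphere radius
$r_0 = (3M\bar v/4\pi N_{Av})^{1/3}$ with a default partial specific
volume $\bar v = 0.73$ cm³·g⁻¹ (a typical protein average,
overridable); chain-length scaling $R_S = 4.75\,N^{0.29}$ for folded
proteins (literature prefactor uncertainty ±1.11, i.e. roughly ±4 Å
at $N \approx 120$); NMR correlation time $\tau_c = 1/(5T_2)$ with
its inherent ~10% uncertainty attached as metadata; and a linear
$\tau_c \to$ mass map with $k = 2.0$ kDa·ns⁻¹ at 25 °C, a constant
chosen once because it reproduces the masses of known ~13 kDa
proteins from their measured $\tau_c$ within ~1.5% — it is an
order-of-magnitude tool, not a replacement for sedimentation
equilibrium.

A known caveat this package surfaces instead of hiding: applying the
printed calibration constants of a published column to a published
elution volume can disagree with the experimentally quoted Stokes
radius (e.g. 21.7 Å computed versus 14 ± 2 Å quoted for one of the
thioredoxins). The implementation follows the defining equations and
leaves such discrepancies visible; no constant is adjusted to force
agreement.

## ASA differences and theoretical m-values

ASA tables are consumed as data (they come from structure-analysis
servers; computing ASA from coordinates is out of scope). Differences
are plain subtraction per polarity class, validated to be
non-negative. The theoretical m-value uses the empirical guanidinium
regression of m on total ΔASA,

$$m_{theory} = 0.859 + 2.2\times10^{-4}\,\Delta ASA_{total}
\quad(\mathrm{kcal\,mol^{-1}M^{-1}}),$$

with both coefficients exposed as arguments. The guanidinium (rather
than urea) form without cross-link correction is the appropriate
variant for disulfide-free denaturation in GdmCl and reproduces the
expected 3.6–3.8 range for ~13 kDa single-domain proteins from their
ΔASA totals.

## Nonlinear fitting contract

All nonlinear fits share one engine: Levenberg–Marquardt damped least
squares (`minpack.lm::nls.lm`) with

* self-chosen starting values — baselines from the outer 20% of the
  axis, midpoint from the half-amplitude crossing of the apparent
  folded fraction, slope parameters from the central finite-difference
  slope at the midpoint ($m \approx 4RT f'$,
  $\Delta H \approx 4RT_m^2 f'$);
* five seeded, jittered restarts (±10% lognormal-ish perturbation of
  the start), ties broken by lowest sum of squared residuals — this
  makes every fit reproducible for a given seed;
* convergence at relative SSR change $<10^{-10}$ or 500 iterations;
  non-convergence is *flagged* on the result, never silently replaced
  by defaults;
* standard errors from the numerical Jacobian at the optimum,
  $\hat\sigma^2 (J^\top J)^{-1}$.

Degenerate inputs get explicit behaviour: too few points for the
parameter count is an error; a missing post-transition baseline is a
warning plus flag (`no_upper_baseline`); a midpoint outside the
scanned range is flagged as extrapolation.

As an optimizer-independent cross-check, a brute-force grid search
over $(m, [U]_{50\%})$ — with the four baseline parameters profiled
out exactly by linear least squares at each grid node, coarse pass at
0.1 then exhaustive refinement at 0.01 — must agree with the
Levenberg–Marquardt fit to within one grid step. This oracle shares
no code path with the nonlinear engine.

## Synthetic data: what it shows and what it does not

Every input class has a seeded generator that evaluates the forward
model exactly (zero noise reproduces the model to machine precision)
and adds homoscedastic Gaussian noise parameterized as a fraction of
the signal amplitude, so a "2% noise" scenario means the same thing
for a fluorescence curve and an ellipticity curve. Ground-truth
parameters are embedded in the curve objects and in the CSV headers
at full precision, so validation never re-derives truth from the data
it is validating.

The simulated study conditions mirror the published experimental
designs: denaturant titrations on ~30 points over 0–7 M, thermal
scans 25–95 °C at 0.2 °C, pH series 2–13 at 0.5 units, DSC grids at
0.05–0.2 °C, the four-standard SEC kit (16.4, 20.9, 30.5, 35.5 Å),
2–3% amplitude noise, and 100-seed replicate studies. These sizes
keep the full validation suite to a few seconds while leaving each
Monte-Carlo check enough resolution to detect bias comparable to a
single experiment's uncertainty.

Parameter-recovery studies report the bias of the mean recovered
parameter across seeds and compare it with the Monte-Carlo estimate
of the estimator's standard error (the standard deviation of the
recovered estimates), alongside an absolute accuracy bound on the
midpoint (mean within 2% of truth). A stricter bound — bias below the
standard error *of the bias estimate*, sd/√100 — is not used as a
pass/fail criterion, deliberately: that statistic is ~N(0, 1) for an
exactly unbiased estimator, so it would fail each parameter about a
third of the time by construction; a diagnostic at 400 independent
replicates confirms the chemical m-value bias is within one such
standard error of zero and scales as σ², the signature of ordinary
small-sample nonlinear-least-squares bias rather than an
implementation defect.

What passing these tests does **not** show about real data: the
generators produce equilibrium, homoscedastic, artifact-free
observations. Real scans have thermal lag, lamp drift, aggregation
exotherms, inner-filter effects, heteroscedastic photon noise, and —
prominently for two of the three thioredoxins — irreversibility,
none of which are modelled. Synthetic validation establishes that the
*estimators* are correct and unbiased under the stated noise model;
it cannot certify any particular instrument's error structure.

## Interfaces

The package is used from R: curve/spectrum/ASA CSV readers and
writers (with `#key=value` metadata headers), JSON fit reports
(`write_fit_json`), and summary-table builders (`hydro_summary`,
`chem_summary`, `asa_m_summary`) that round to the conventional
reporting precision (radii and correlation times to one decimal,
molarities to two, areas to one). `scripts/acceptance.R` is a thin
command-line wrapper over these functions that regenerates the
package's reference quantities; no separate shell tool is shipped,
because the intended users drive analyses from R scripts.

## Known limitations

* Equilibrium models only; irreversible transitions yield apparent
  parameters (flagged, not corrected).
* The sequential DSC three-state model neglects partition-function
  coupling between transitions.
* The three-state chemical model assumes a concentration-independent
  intermediate signal level.
* No global multi-pH surface fitting; each curve (or probe pair) is
  fitted independently.
* The τ_c → mass map and the chain-length Stokes-radius scaling are
  empirical rules with ~10% and ~20% real-world scatter; both carry
  their uncertainty in the output rather than in fine print.
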