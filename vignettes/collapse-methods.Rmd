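---
title: "Methods: coil-globule collapse and heterogeneous binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coil-globule collapse and heterogeneous binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpcollapse)
```

This vignette documents the models behind `idpcollapse`, the conventions and
numerical choices the implementation commits to, and what the synthetic-data
module does and does not emulate. The package addresses a recurring
experimental situation: a small intrinsically disordered protein (IDP) whose
dimensions shrink continuously with temperature, probed by dynamic light
scattering (DLS), differential scanning calorimetry (DSC), spectroscopic
melts, and ligand-binding titrations that refuse to fit a simple 1:1 model.

## Hydrodynamics and chain dimensions

DLS yields translational diffusion coefficients at several protein
concentrations per temperature. Solution non-ideality is removed by the
linear model $D = D_0 (1 + aC)$ (ordinary least squares;
`fit_diffusion_series()`), and the intercept is converted through
Stokes–Einstein, $R_h = k_B T / (6\pi \eta(T) D_0)$. Both the fitted $D_0$
and the measured $D$ at the lowest concentration are retained
(`dls_to_radii(use =)`); the default uses $D_0$, since the intercept removes
non-ideality exactly, and the lowest-concentration variant is kept as a
cross-check — the two differ by $\sim aC_{\min}$, under 1% for typical
$a \approx 0.01$ mL mg$^{-1}$.

Water viscosity uses the Vogel-type correlation
$\eta(T) = 2.414\times10^{-5} \cdot 10^{247.8/(T-140)}$ Pa s, accurate to a
few tenths of a percent across 273–373 K and isolated in
`water_viscosity()` so another correlation can be dropped in.

$R_h$ and $R_G$ are interconverted with an empirical disordered-chain ratio
that interpolates linearly in $R_G$ between globule and coil size scalings:
$$\alpha(R_G, N) = \frac{R_G}{R_h}
  = a_1\,\frac{R_G - a_2 N^{0.33}}{N^{0.60} - N^{0.33}} + a_3,$$
with $a_1 = 0.216\ \text{Å}^{-1}$, $a_2 = 4.06$ Å, $a_3 = 0.821$
(`chain_conversion_constants()`, overridable). The exponents 0.33 and 0.60
are literal constants of the empirical form. The inverse map `rh_to_rg()`
is a bracketed root find on $R_G \in [2, 5N^{0.6}]$ Å, where the forward
map is strictly monotone (verified numerically in the tests), so the
inversion is unique; the round trip closes to $10^{-9}$. Note the inversion
is steep ($dR_G/dR_h \approx 2.9$ at $N = 66$ near the coil end), so
sub-ångström uncertainty in $R_h$ propagates to $\sim$3-fold larger
uncertainty in $R_G$.

The Flory law $R_G = \rho_0 N^{\nu}$ (`scaling_rg()`) defaults to the
Θ-state values $\rho_0 = 2.2$ Å, $\nu = 1/2$; exponents outside
$[1/3, 3/5]$ are allowed but warned about, since they have no standard
polymer-physics interpretation.

## Absolute heat capacity

A DSC scan measures the apparent heat-capacity difference between the
protein solution and buffer. Because protein displaces its own volume of
buffer,
$$\Delta C_p^{app}(T) = m_P\left[c_{p,P}(T)
  - \bar v\, \rho_w(T)\, c_{p,w}(T)\right],$$
with $m_P$ the protein mass in the cell, $\bar v$ the partial specific
volume (default 0.73 mL g$^{-1}$) and $\rho_w c_{p,w}$ the volumetric heat
capacity of water. `absolute_cp()` regresses the apparent signal against
$m_P$ at each temperature over a concentration series (at least two
concentrations; per-temperature ordinary least squares) and corrects the
slope by the displaced-buffer term. The same water-property functions are
used by the generator and the extraction, so the round trip is exact at
zero noise. Thermograms on different grids are interpolated onto their
common overlap with a warning; extrapolation is refused.

Two reference baselines bracket the absolute curve: a folded baseline
linear in temperature (defaults giving $\approx 1.33$ J g$^{-1}$ K$^{-1}$
at 298 K, slope $6.6\times10^{-3}$ J g$^{-1}$ K$^{-2}$) and an unfolded
baseline formed as the composition-weighted sum of tabulated per-residue
unfolded-state heat capacities, spline-interpolated between six anchor
temperatures. The shipped coefficient tables are nominal literature-style
defaults, editable by the user; no quantitative result of the package
depends on their exact values. The excess heat capacity is defined as the
absolute curve minus the **folded** baseline (the subtraction choice is a
convention; an instrument-derived native baseline would serve equally), and
the enthalpy fluctuations follow as
$\delta H^2(T) = R T^2 C_{p,exc}(T)$.

## The variable-barrier (Landau) model

Enthalpy $H$ is the order parameter (zero at the reference mode). At the
characteristic temperature $T_0$ the free-energy functional is an
asymmetric quartic
$$G_0(H) = -2\beta (H/\alpha)^2 + |\beta| (H/\alpha)^4, \qquad
  \alpha = \alpha_1\ (H<0),\ \alpha_2\ (H\ge 0),$$
with $\alpha_1 + \alpha_2 = \Sigma\alpha$ and asymmetry
$f = \min(\alpha_1,\alpha_2)/\max(\alpha_1,\alpha_2) \in (0,1]$. For
$\beta < 0$ the profile has a single minimum — a barrierless (downhill,
second-order-like) transition; $\beta > 0$ would carve two minima separated
by a barrier of height $\beta$.

**Asymmetry convention.** $f$ alone does not say which side the wider lobe
sits on. The package defaults to the wider lobe at positive enthalpy
(`big_lobe = "high"`), which skews the densities toward high $H$, the
behaviour expected when the high-enthalpy (expanded) branch is
conformationally broader; the opposite convention is available as a switch.
Round-trip fits are valid under either fixed convention.

**Temperature dependence.** The model is closed by a temperature-independent
entropy functional fixed at $T_0$:
$$S_0(H) = \frac{H - G_0(H)}{T_0}, \qquad
  P(H, T) \propto \exp\!\left[\frac{S_0(H)}{R} - \frac{H}{RT}\right],$$
which reduces to $P \propto e^{-G_0/RT_0}$ at $T_0$ and agrees to first
order in $G_0/H$ with writing
$G(H,T) = G_0(H) - (T-T_0)H/T_0$ inside a Boltzmann factor. The
microcanonical form is chosen deliberately: with a $T$-independent density
of states the thermodynamic identity
$C_p(T) = d\langle H\rangle/dT = (\langle H^2\rangle - \langle H\rangle^2)/RT^2$
holds exactly (the tests verify both routes agree to $10^{-4}$ and better),
whereas a $T$-dependent effective entropy breaks the fluctuation–dissipation
link between the fitted heat capacity and the reported enthalpy
fluctuations. As a consequence of this construction, the excess-$C_p$
maximum of the printed downhill parameter set
($\Sigma\alpha = 1554.9$, $\beta = -173.7$ kJ mol$^{-1}$, $T_0 = 291.7$ K,
$f = 0.535$) falls at 313 K — i.e. maximal enthalpic heterogeneity right at
the collapse midpoint, which the tests assert. The $\delta H^2$ curve
itself peaks later (322 K) because of the $T^2$ weighting.

**Numerics.** Densities are evaluated on a uniform grid of 2001 points
spanning $\pm 2.5\,\Sigma\alpha$, normalized by trapezoidal quadrature. If
more than $10^{-6}$ of the mass sits in the outermost cells the span is
doubled once; a second failure errors with the measured edge mass.
`vb_fit()` minimizes squared residuals of `vb_cp` with Levenberg–Marquardt
in the transformed coordinates $(\log \Sigma\alpha, \text{signed-log}\,
\beta, T_0, \text{logit} f)$, keeping the scale positive and
$f \in (0,1]$. Multistart (default 5) perturbs every raw parameter
uniformly by ±20% under a caller seed; the first start is unperturbed, and
the lowest-deviance converged start wins. On the noiseless forward curve
all five starts return to the generating parameters (tested: $T_0$ within
0.2 K, $f$ within 0.01, and invariance under 2× grid decimation).

## Two-state melts and spectral SVD

Probe curves are fit to
$$S(T) = P_E(T) S_E(T) + [1 - P_E(T)] S_C(T), \qquad
  P_E = \frac{1}{1 + e^{-\Delta G/RT}}, \quad
  \Delta G(T) = \Delta H_{vH}\left(1 - T/T_m\right),$$
with linear baselines for both states (standard practice when no better
physical baseline model exists) and $\Delta C_p$ of the transition fixed at
0 by default (exposed as an argument; the van't Hoff form is the common
choice when the transition enthalpy is small and baselines are free).
Starting values come from end-segment baseline fits and the half-amplitude
crossing; fits whose transition amplitude falls below three times the
per-point residual scale are rejected as "no transition". $P_{U_E}$ is
returned on the data grid and satisfies $P_{U_E} + P_{U_C} = 1$ by
construction. `collapse_summary()` reports the probe-ordered midpoint table
and the max–min spread; for the default synthetic probes (fluorescence
shift 301 K, near-UV CD 307 K, DLS 312 K) the spread is 11 K — the
decoupling signature the multi-probe analysis is designed to expose.

Estimator precision was characterized on synthetic melts: for a
cooperative transition ($\Delta H_{vH} = 250$ kJ mol$^{-1}$) sampled every
0.5 K over 278–350 K at a signal-to-noise ratio of 20 (noise s.d. =
transition amplitude at $T_m$ / 20), the fitted $T_m$ stays within 1 K of
truth in every one of 100 seeded replicates, and the van't Hoff enthalpy is
recovered with an RMS error below 10%. Broader transitions or sparser
sampling degrade both figures — enthalpy dispersion roughly doubles at a
2 K step — so the per-replicate enthalpy error is a dispersion-level
statistic, not a guaranteed bound.

`svd_spectra()` decomposes a complete wavelength × temperature matrix with
an uncentered SVD, so the leading component is the average spectrum and the
second captures the dominant deviation (for a red-shifting band, a
derivative-shaped mode whose temperature amplitude crosses zero at the
shift midpoint). Sign indeterminacy is resolved by orienting each basis
spectrum to non-negative mean and flipping its amplitude vector to match.
Missing cells are refused rather than imputed.

## Binding heterogeneity

The Hill equation
$f = [L]^{n_H} / (K_{1/2}^{n_H} + [L]^{n_H})$ is fit by
Levenberg–Marquardt with uniform weights; for anisotropy data the
amplitudes $r_{free}, r_{bound}$ are fit jointly, for fraction-bound data
they are fixed at 0 and 1.

The heterogeneity model assigns each molecule one quenched standard binding
free energy $\Delta G \sim \mathcal N(\mu, \sigma^2)$ (kJ mol$^{-1}$, 1 M
reference), hence $K_d = e^{\Delta G/RT}$, and averages the per-molecule
1:1 isotherms. Two averaging modes are implemented and tested against each
other: Monte-Carlo (explicit $n$-molecule ensemble, default 1000, seeded)
and 64-node Gauss–Hermite quadrature (deterministic; the oracle mode). The
bulk isotherm uses total titrant as free concentration, valid when
$K_{1/2}$ is far above the reporter concentration (tens of μM vs hundreds
of nM here); a depletion correction was considered and omitted as a
non-goal at these concentration ratios.

Because the $\Delta G$ distribution is Gaussian, the bulk curve is
symmetric in $\log[L]$ about the median $K_d = e^{\mu/RT}$: the fraction
bound there is exactly 1/2, the fitted $K_{1/2}$ tracks the median $K_d$
(within 2% on the default grid), and $n_H$ is invariant to $\mu$. An
independent oracle for the fitted slope is the logit derivative at the
midpoint, $n_H^{mid} = 4\,E[f(1-f)]$ at $L = $ median $K_d$
(`midpoint_slope_nh()`); it sits a few percent below the full-curve fit,
which averages shallower wings. $n_H$ decreases strictly with $\sigma$,
equalling 1 at $\sigma = 0$.

`infer_sigma()` exploits that monotonicity: bisection on
$\sigma \in [0, 12]$ kJ mol$^{-1}$ (tolerance 0.01 kJ mol$^{-1}$) matches
the fitted $n_H$, and $\mu$ is then set so the fitted midpoint matches the
target $K_{1/2}$ — a sequential (σ then μ) match, chosen because the two
parameters act on nearly orthogonal features of the curve (shape vs
position). The titration grid is part of the fit's provenance: the default
is 24 log-spaced points over 1 nM–100 μM, and $n_H$ shifts by a few
hundredths if the grid is truncated well inside the transition.

Temperature must be supplied explicitly wherever free energies and
dissociation constants are interconverted; no default temperature is
assumed for ensemble demonstrations.

## The synthetic-data module

Generators exist for all five input classes (DLS series, DSC thermograms,
anisotropy isotherms, melt curves, spectral matrices). Design rules:

* **Exact inverse.** Every generator applies the same forward relations its
  analysis stage inverts, so at zero noise the round trip closes to solver
  tolerance (tested for DLS, DSC, melts, isotherms and SVD rank).
* **Noise model.** Additive Gaussian noise on the measured signal, the
  simplest model consistent with unweighted least squares downstream.
  Measurement-error magnitudes are assumptions, not measured values:
  instruments report none here, so defaults are zero and every test states
  the noise it injects.
* **Seeding.** All randomness flows from one integer seed per generator
  call (`noise_spec()`, or the model seed for Monte-Carlo ensembles);
  zero-noise calls never touch the RNG, and identical seeds give
  bitwise-identical output.
* **Default scenario.** 24 Å coil and 17 Å globule baselines mixed by a
  two-state equilibrium at $T_c = 312$ K with
  $\Delta H_c = 150$ kJ mol$^{-1}$ (a package default chosen to make the
  transition span the 283–333 K DLS window; the instruments' printed
  concentration series 0.45/0.90/1.35 mg mL$^{-1}$ and 52/110 μM are the
  generator defaults). Anisotropy amplitudes default to
  $r_{free} = 0.06$, $r_{bound} = 0.16$, typical of a dye-labelled
  oligonucleotide reporter. All are overridable.

What the generators deliberately do **not** emulate: raw DLS
autocorrelation functions and raw DSC power traces (generation starts at
derived per-scan quantities), instrument baseline drift, scan-rate effects,
ligand depletion, photobleaching, and correlated (non-white) noise.
Passing round-trip tests therefore demonstrates correctness of the
analysis algebra and estimator calibration under idealized noise — not
robustness to every instrument artefact of real data.

## Problem sizes and runtime

Default problem sizes were chosen so the full test suite runs in well under
a minute: VB work uses the 2001-point enthalpy grid and 96-point
temperature grids; the melt-precision study uses 100 replicates of
145-point curves; Monte-Carlo ensembles use 1000 molecules (the size at
which sampling error is a few times $10^{-3}$ in fraction bound, small
enough to compare against quadrature at 3.5 standard errors).

## Known limitations

* The $R_G \leftrightarrow R_h$ conversion is an empirical disordered-chain
  relation; applying it to folded or highly charged chains is
  unsupported, and its steep inverse amplifies $R_h$ uncertainty.
* Baseline coefficient tables are nominal defaults; quantitative absolute-Cp
  work should substitute coefficients appropriate to the system.
* The melt analysis fits probes independently; no global multi-probe
  linkage model is attempted (by design — probe decoupling is the
  observable of interest).
* `infer_sigma` assumes a Gaussian free-energy distribution; skewed or
  multimodal heterogeneity maps onto an effective width.
* The binding model is strictly 1:1 per molecule: Hill coefficients below
  one are interpreted as quenched heterogeneity, never as kinetic or
  multi-site effects.
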