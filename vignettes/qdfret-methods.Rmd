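---
title: "Models and numerical choices in qdfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in qdfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdfret)
```

`qdfret` quantifies Förster resonance energy transfer (FRET) in
quantum-dot (QD) / dye assemblies whose geometry is set by DNA: dyes
hybridized to strands wrapped on the QD surface, or placed on wireframe
DNA-origami scaffolds. This vignette records the models, their
assumptions, the conventions behind every default, and what the test
suite does and does not demonstrate.

## Förster theory

The spectral overlap integral is

$$J = \int \bar I_D(\lambda)\, \varepsilon_A(\lambda)\, \lambda^4\,
  d\lambda,$$

with $\bar I_D$ the **area-normalized** donor emission spectrum,
$\varepsilon_A$ the acceptor molar absorptivity in
M^-1^ cm^-1^, and $\lambda$ in nm, so $J$ carries units
M^-1^ cm^-1^ nm^4^ and the Förster distance

$$R_0 = 0.0211\,[\kappa^2 \Phi_D n^{-4} J]^{1/6}$$

comes out in nm. Defaults: $\kappa^2 = 2/3$ (dynamic orientational
averaging — appropriate for dyes on flexible DNA tethers and the
isotropic emission of a QD) and $n = 1.35$ (aqueous buffer). Both are
plain arguments, never hidden.

**Quadrature.** No quadrature scheme is canonical for Eq.-style overlap
integrals; `overlap_integral()` uses the trapezoidal rule on the union
of the two wavelength grids restricted to their common support, with
linear interpolation and no extrapolation (spectra contribute zero
outside their own support). The integration grid is returned as an
attribute so a report can state it. Against a 10^6^-point quadrature of
smooth Gaussian bands the module agrees to better than 0.1% for
typical ~0.25–1 nm instrument gridding; disjoint spectra return
J = 0 with a warning rather than an error, since a zero overlap is a
physically meaningful answer.

## Efficiencies, rates, and inversions

Measured efficiencies come from intensities, $E = 1 - I_{DA}/I_D$, or
amplitude-weighted lifetimes, $E = 1 - \tau_{DA}/\tau_D$. Negative
values (quenched sample brighter than donor-only) are **warnings, not
errors**: they flag enhancement or noise, which a pipeline should
surface.

A QD donor surrounded by $n$ equidistant acceptors follows

$$E = \frac{n R_0^6}{n R_0^6 + R^6},$$

with closed-form inversions $n = E R^6 / ((1-E) R_0^6)$ and
$R = R_0 (n(1-E)/E)^{1/6}$. Both are exact inverses of the forward
model (round-trip residual below 10^-12^ in the tests). The acceptor
count is reported both real-valued and as the round-half-to-even
integer; rounding conventions matter when the answer is "19".

Rate form: $k_{D\to A} = k_D (R_0/R)^6$ with $k_D$ the donor's natural
relaxation rate (ns^-1^; $k_D = 1/\tau_D$), relative rate
$\gamma = k_{D\to A}/k_D = (R_0/R)^6$, and
$E = \gamma/(1+\gamma)$ — algebraically identical to
$k_{D\to A}/(k_D + k_{D\to A})$, which the tests verify to machine
precision.

## The three-node concentric network

The network is fixed at the experimentally realized topology — initial
donor (QD), relay (e.g. AF647), terminal acceptor (e.g. AF750) — with
three edges $\gamma_1$ (donor→relay), $\gamma_2$ (donor→acceptor),
$\gamma_3$ (relay→acceptor):

- donor quench: $Q_{QD} = (\gamma_1+\gamma_2)/(1+\gamma_1+\gamma_2)$;
- competitive relay quench:
  $Q_c = 1 - (1+\gamma_1)/(1+\gamma_1+\gamma_2)$;
- sequential relay quench: $Q_s = \gamma_3/(1+\gamma_3)$;
- total: $Q_{relay} = 1 - (1-Q_c)(1-Q_s)$.

Assumptions: the QD is the sole initially excited species (direct
excitation of the dyes at the blue excitation wavelengths used for QDs
is negligible), no back-transfer or homo-FRET, and only relative rates
matter (the radiative/non-radiative partition of $k_D$ cancels). An
N-node generalization is deliberately out of scope: the three-node
closed forms are verifiable against an independent kinetic Monte-Carlo
branching simulation, which the suite runs on 20 random networks at
10^6^ trials each (agreement within 0.5%). Distances are
center-to-center; when both a direct $\gamma$ and an $(R_0, R)$ pair
are supplied for one edge, the direct rate wins with a warning.

## TCSPC lifetime fitting

Decays are fit with $I(t) = C\sum_i \gamma_i e^{-t/\tau_i}$ plus a
constant background, $\sum_i\gamma_i = 1$, and summarized by the
amplitude-weighted lifetime $\tau = \sum_i \gamma_i\tau_i$ — the
average that belongs in the lifetime efficiency relation.

Numerical choices:

- **Tail fitting, no IRF reconvolution.** QD lifetimes (tens of ns) are
  long against the instrument response, so the window starts at the
  histogram peak + 2 bins by default; the window is always reported.
- **Weights.** Neyman, $1/\max(y, 1)$.
- **Optimizer.** Levenberg–Marquardt (`minpack.lm`) with box
  constraints (amplitudes ≥ 0, lifetimes above a tenth of the bin
  width), restarted from 5 log-spaced, seed-jittered lifetime
  initializations; best loss wins.
- **Amplitude reference.** Fitted amplitudes are back-projected from
  the window start to $t = 0$ (the excitation pulse) via
  $a_i(0) = a_i(t_0)\,e^{t_0/\tau_i}$, so reported fractions are
  comparable across windows and match the generating fractions of
  synthetic data.
- **Degenerate inputs.** A fit that fails to improve on a constant-only
  model by at least 1% in weighted chi-square errors out ("no decaying
  component") instead of returning a silent bad fit.
- **Pruning.** Components with amplitude fraction < 0.5% are removed
  with a warning.
- **Model order.** `select_component_count()` adds components until
  the reduced chi-square improves by < 5% (configurable) and returns
  the simpler model, logging the chi-square trace.

Closed-loop recovery on synthetic Poisson data (γ = 0.6/0.4,
τ = 2/10 ns, 10^6^ counts): amplitudes within ±0.03, lifetimes within
±3%, median amplitude-weighted-lifetime error under 2% across 50
seeds, cross-checked against an independent Nelder-Mead fit of the
same loss.

## Scaffold geometry and the polymer mapping

Wireframe polyhedra are idealized regular solids — a regular
tetrahedron or an equilateral pentagonal pyramid (all ten edges equal;
the published design specifies only the edge length, so equilateral is
the least-assumption model) — with edge length `edge_bp` × 0.34 nm/bp
(B-DNA rise) and centroid at the origin. 52 bp edges give 17.68 nm
(~18 nm); 63 bp give 21.42 nm (~21 nm). Real origami coordinates
deviate from the ideal solid; labeled sites therefore take a radial
offset (nm, outward from the centroid) so stated distances such as
7.1/7.8/12.2 nm can be matched explicitly rather than inferred from
unpublished overhang geometry. For dyes tethered at a spherical
particle's surface, `radial_dye_distance()` models the
center-to-fluorophore distance as particle radius + spacer (7.1 nm QD
radius + 0.68 nm polyT spacer → 7.8 nm).

Bond angles are interior angles in [0°, 180°] from the clipped
normalized dot product; `angle_distribution_stats()` reports the
Gaussian maximum-likelihood mean and sd (denominator $n$) and the
empirical fraction inside a stated interval.

The ssDNA conformation mapping inverts the self-avoiding-walk scaling
$R_{ee} = b\,(L/b)^\nu$ for the Kuhn length $b$, with contour length
$L$ = nucleotides × 0.63 nm/nt, Flory exponent $\nu = 0.588$
(good solvent), and $R_{ee} = \sqrt{6.25}\,R_g$ (the SAW prefactor;
$\sqrt 6$ recovers the ideal-chain form $b = 6R_g^2/L$ at
$\nu = 1/2$). **Convention:** persistence length = Kuhn length / 2,
always; every convention used is echoed in the returned object because
published statements of Kuhn vs persistence length do not always agree
on the factor of two. With the defaults, $R_g$ = 6.2 nm for a 51 nt
strand maps to $b \approx 5.5$ nm (persistence ≈ 2.7 nm). An inversion
yielding $b \ge L$ errors: the data would imply a chain stiffer than
its own contour.

## Synthetic data: what it emulates, and what it does not

The generators produce Gaussian-band emission spectra (QD emission is
nearly Gaussian; centers such as 600/630/660 nm), absorptivity bands
with an optional power-law UV tail mimicking QD absorption, mixture
absorbance spectra with additive Gaussian noise, TCSPC histograms with
per-bin Poisson draws including wrap-around between pulses (400 ns
period, i.e. 2.5 MHz — non-negligible for tens-of-ns QD lifetimes),
lognormal multiplicative noise on intensity/lifetime observables, and
Gaussian bond-angle ensembles reflected at 0°/180° (reflection keeps
the support valid without biasing the center). Every generator is a
pure function of its arguments and a seed; one global seed fans out to
per-generator substreams via a label hash, so adding generators never
shifts existing streams, and each output carries its ground truth as
an attribute.

Not emulated: instrument response functions, detector nonlinearity,
QD blinking, spectrally correlated noise, scattering baselines beyond
a flat offset, and real origami coordinate disorder. Passing
closed-loop tests therefore demonstrates correctness of the estimators
under the stated noise models, not robustness to every instrumental
artifact.

Default study conditions used in the tests mirror the characterized
system: 10^6^-count histograms, 2% observable noise with 3 replicates,
1% spectral noise with 100 replicates for unmixing, 1000-angle
ensembles at 15° spread — sizes at which the stated tolerances are
comfortably identifiable.

## Workflows

`run_pair_workflow()`, `run_network_workflow()`,
`run_geometry_workflow()` and `run_synth_workflow()` are the
config-driven entry points (YAML or JSON, flags > file > defaults in
the thin CLI wrapper). Every report embeds the fully resolved config —
all defaults made explicit — and the package version, so deterministic
workflows reproduce bitwise from their own reports. Constants that are
measured quantities (κ² = 2/3, n = 1.35, Φ~s~ = 0.92 for rhodamine
101, 0.34 nm/bp) ship as the defaults and are never silently changed.

## Known limitations

- The scalar κ² treatment cannot represent static orientational
  disorder; only the dynamic-averaging regime is modeled.
- Tail fitting discards the rising edge; for lifetimes comparable to
  the IRF width a reconvolution fit would be required.
- The equilateral pentagonal pyramid and regular tetrahedron are
  idealizations of 2-helix-bundle wireframe origami; site radial
  offsets are the user's responsibility when matching measured
  distances.
- The SAW mapping assumes a free chain in good solvent; a strand
  partially adsorbed on a nanoparticle surface violates this, so the
  returned Kuhn length is an effective, convention-dependent quantity.
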