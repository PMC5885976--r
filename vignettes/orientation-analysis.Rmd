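---
title: "Determining helix tilt at an interface from polarized SFG amide-I spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining helix tilt at an interface from polarized SFG amide-I spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfgtilt)
```

# The measurement and the model

Sum-frequency generation (SFG) is a second-order nonlinear optical process
that vanishes in centrosymmetric bulk media, which makes it selectively
sensitive to molecules at interfaces. For an adsorbed alpha-helical
peptide, the amide-I band near 1650 cm⁻¹ recorded under the *ssp* and
*ppp* polarization combinations encodes the helix tilt angle θ — the angle
between the helix main axis and the surface normal — through the ratio of
effective second-order susceptibilities χ_ppp/χ_ssp. `sfgtilt` implements
the complete chain from raw polarized intensity spectra to a tilt angle
and a standing/tilted/lying pose call, together with the matching analysis
of structure snapshots, and a synthetic-data layer that replaces every
wet-lab input for development and testing.

Throughout, the substrate surface is the plane z = 0 with the solution at
z > 0, user-facing angles are degrees, wavenumbers are cm⁻¹, and tilt
angles are folded into [0°, 90°] (a helix axis and its negation are the
same physical orientation).

## Line-shape model

A polarized SFG intensity spectrum is modelled as the squared modulus of a
coherent sum of a nonresonant background and signed Lorentzian resonances,

$$I(\omega) = \Big| A_{NR} e^{i\varphi} + \sum_q
  \frac{A_q}{\omega - \omega_q + i\Gamma_q} \Big|^2 ,$$

with amplitude $A_q$, center $\omega_q$ and half-width $\Gamma_q$ per
resonance. Because the intensity is a squared modulus, two global
ambiguities exist. First, flipping the sign of every $A_q$ together with
$\varphi \to \varphi + \pi$ leaves $I$ unchanged; `fit_spectrum()`
therefore reports the branch with the dominant resonance amplitude
positive whenever the fitted background is negligible (below machine scale
relative to the amplitudes), which makes amplitude ratios between
polarizations reproducible. Second, with no background at all the overall
sign is strictly unobservable; in that regime the ppp/ssp ratio is a ratio
of magnitudes with the positive branch chosen, which is consistent with
the forward model in the tilt range where the orientation curve is
positive. A useful consequence of the squared-modulus form worth knowing
when reading fits: between two peaks, *equal-sign* amplitudes interfere
destructively (a dip between the peaks) and opposite signs constructively.

The nonresonant phase $\varphi$ is fixed at 0 by default because it is
weakly identifiable against a single dominant resonance; `fit_phase =
TRUE` frees it.

## Helix amide-I hyperpolarizability

The forward optical model starts from one amide-I oscillator per peptide
unit. Unit $k$ sits at helix azimuth $\psi_k = k\,\tau$ (twist $\tau$ per
residue); its IR transition dipole makes an angle δ with the helix axis,
and its Raman polarizability derivative tensor is taken cylindrical about
the dipole with a transverse/longitudinal ratio $r$. The helix amide-I
band comprises exciton modes of azimuthal order $m$: the axial A mode
($m = 0$) and the doubly degenerate transverse E1 pair ($m = \pm 1$). For
each mode the hyperpolarizability is the product of the two *collective*
derivative sums,

$$\beta^{(m)}_{ijk} = \frac{1}{N} \Big( \sum_k \alpha'_{k,ij}
  e^{-i m \psi_k} \Big) \Big( \sum_l \mu'_{l,k} e^{+i m \psi_l} \Big) .$$

This product-of-sums structure is essential and easy to get wrong: the
Raman and IR derivatives belong to the *same* collective normal
coordinate, so each is summed over units first. Summing per-unit products
$\alpha'_k \mu'_k$ with mode phases instead makes every azimuthally
averaged susceptibility component proportional to a single scalar, so the
χ_ppp/χ_ssp ratio would lose all dependence on helix length — visibly
wrong, since the ratio-versus-θ curves for different helix lengths are
distinct. With the correct construction, an integer number of turns gives
the classic axially symmetric A tensor ($\beta_{aac} = \beta_{bbc}$,
$\beta_{ccc}$) and off-diagonal E1 tensor; the boundary (partial-turn)
sums add the length dependence.

A related subtlety fixed a default. At a twist of exactly 100°/residue,
the boundary sums satisfy $|G_1|^2 = |G_2|^2$ (with
$G_n = \sum_k e^{i n \psi_k}$) simultaneously for several helix lengths,
making e.g. the 17-, 18- and 19-residue orientation curves numerically
*identical*. The package therefore uses the equally standard 3.615
residues per turn (τ = 99.59°/residue) as its default helix periodicity,
which keeps the length family distinguishable while changing individual
curves only in the fourth decimal.

## Orientational averaging

`chi_lab()` maps the molecular tensors into the lab frame of an
azimuthally isotropic film. Azimuth φ and twist ψ are always averaged
uniformly (the film has no in-plane order and the analysis uses a single
orientation parameter); the tilt distribution is a delta function at θ by
default, with a Gaussian option. Under uniform (φ, ψ) averaging only
seven achiral molecular components survive in the achiral lab components
(xxz, xzx, zxx, zzz), and each lab component is a linear form in
⟨cos θ⟩ and ⟨cos³ θ⟩ — the closed forms coded in the package were derived
symbolically once and are verified in the test suite against a
brute-force Euler-grid average (the separable equivalent of a 720 × 720
(φ, ψ) grid) to 10⁻⁶ relative, over 20 random (θ, δ, r) parameter sets.
Two limits are enforced to 10⁻¹⁰: every component vanishes at θ = 90°
(each term carries a cos θ factor — the physical basis of the "no signal
from a lying film" argument), and for an isotropic distribution
(⟨cos θ⟩ = ⟨cos³ θ⟩ = 0).

For the Gaussian option the distribution is a Gaussian in θ itself
(degrees), truncated to [0, π] and *not* weighted by sin θ. This is the
convention commonly used when reporting a tilt-plus-width, and it keeps
the delta limit exact; the difference from a sin-weighted prior only
matters for widths much larger than those of interest here.

## Fresnel factors and effective susceptibilities

The measured quantities mix the lab components with geometry- and
index-dependent local-field (Fresnel) factors. `fresnel_factors()`
implements the standard three-layer model (incidence medium / interfacial
layer of index n′ / solution) via the transmission Fresnel coefficients,
per beam (SFG, visible, IR). Beyond the critical angle the factors are
complex (total internal reflection); exactly at the critical angle the
formulas are singular and the function errors with advice to offset the
angle by a fraction of a degree. The effective susceptibilities are

$$\chi_{ssp} \propto L_{yy}^{SFG} L_{yy}^{vis} L_{zz}^{IR}
  \sin\beta_{IR}\, \chi_{yyz}$$

and the standard four-term signed combination of (xxz, xzx, zxx, zzz) for
ppp. `ratio_curve(..., bare = TRUE)` bypasses the Fresnel factors
(keeping the projection angles) for sensitivity analysis, since published
curve families do not always state whether bare or Fresnel-weighted
ratios are plotted.

Default optical constants — n₁ = 1.43 (CaF₂-type prism, all beams),
n₂ = 1.33 (water), n′ = 1.18 (slab-model interpolation), visible
incidence 60°, IR incidence 54°, SFG angle from in-plane phase matching
at 532 nm / 1650 cm⁻¹ — describe a representative inverted
total-internal-reflection geometry. They are deliberately exposed as
plain arguments (`optical_geometry()`, YAML-configurable in the
pipeline): exact published optical constants for any given instrument are
rarely complete, so curves computed here reproduce the *structure* of
published curve families (five distinct, monotone curves for 17–21
residues), not digit-for-digit values. The substrate monolayer is treated
as optically negligible (thickness ≪ wavelength) — a stated modelling
simplification, not an oversight.

The per-unit tensor defaults δ = 38°, r = 0.32 are representative
literature values for amide-I helix analysis. No headline result depends
on their exact values: the end-to-end checks are round trips that use the
same parameters forward and inverse, and the overall strength cancels
from every ratio (verified as a homogeneity property in the tests).

## Inversion, uncertainty, pose

`invert_ratio()` finds all solutions of curve(θ) = measured ratio: sign
changes on the tabulated grid (which must be finer than 1°) are bracketed
and refined by bisection to 0.01° on the continuous forward model (for
curves re-read from CSV, on a spline through the tabulated values). The
uncertainty interval inverts value ± σ on each monotone branch that
contains a solution, clamping to the branch ends when value ± σ leaves
the curve's range there; this makes the interval provably monotone in σ.
A measured ratio outside the model's range returns an *empty* solution
set with an explicit flag — never an exception — because that outcome is
scientifically meaningful (wrong model, wrong length, or no signal).

`classify_pose()` encodes the pose logic: standing if every solution is
below 30° (configurable; any boundary at or above the upper end of a
typical standing interval is consistent), tilted up to 80°, lying beyond.
The 80° lying threshold reflects the forward model itself: the signal is
tiny above ~80° and vanishes at 90°, so "lying" and "no amide-I signal"
become observationally equivalent. That motivates the no-signal branch:
no signal *plus* independent evidence of an adsorbed helix (in practice a
circular-dichroism measurement, summarized as the `helicity_ok` flag) is
classified lying; no signal without that evidence is undetermined, since
an empty surface and a lying film are then indistinguishable.

## Structure snapshots

The snapshot side reproduces the same observables from coordinates. The
helix axis is the leading principal component of the centred Cα trace
(sign folded to the upper hemisphere), with an explicit error when the
two leading variances coincide; an independent local-axes estimator
(mean of consecutive 4-residue window axes) is kept as a cross-check
against end effects and agrees within 1° on ideal 26-mers. Helicity is
the fraction of residues with both backbone dihedrals inside a broad
alpha window (φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°]); chain termini and
residues with missing backbone atoms are excluded and reported as
coverage. A residue contacts the surface when its lowest atom is within
z_cutoff = 4 Å (a typical heavy-atom contact distance) of the plane; the
binding terminus compares contact counts between the N- and C-terminal
halves (boundary at ⌊n/2⌋), reporting "both" when each half has at least
a third of its residues in contact. Trajectory tilt is summarized by a
circular-aware mean — the doubled-angle circular mean of the folded
per-snapshot tilts — with the standard deviation and the first/last
snapshot values also reported, since published single-number simulation
tilts rarely state which convention they used.

# The synthetic-data layer

`make_ideal_helix()` builds backbone-only (N, Cα, C, O) ideal helices on
coaxial cylinders: rise 1.5 Å/residue, Cα radius 2.3 Å, twist
99.59°/residue, with per-atom-type radius/phase/z offsets calibrated once
from an internal-coordinate construction at (φ, ψ) = (−57°, −47°) so the
generated backbone's dihedrals land in the alpha window exactly. One
design choice deserves emphasis: the generator aligns the *principal Cα
axis* of the finite chain — the same axis definition the estimator uses —
onto the prescribed tilt direction. A finite spiral's principal axis
deviates from its cylinder axis by up to ~0.8° through end effects; since
"tilt" is defined by the principal axis, placing that axis (rather than
the cylinder axis) at the requested angle is the consistent convention,
and it makes generator→estimator round trips exact rather than merely
close. `build_backbone()` constructs chains from arbitrary per-residue
(φ, ψ, ω) by sequential internal-coordinate placement, for non-helical
and mixed fixtures.

`synth_spectrum()` evaluates the line-shape model on a wavenumber grid
(default 1500–1800 cm⁻¹ at 1 cm⁻¹, the amide-I window) and adds optional
Gaussian intensity noise under a caller-supplied seed, leaving the
global RNG stream untouched. Additive Gaussian noise on intensity is the
simplest stand-in for detector noise; it does not emulate shot-noise
scaling, baseline drift, or wavenumber jitter. `forward_spectra()` closes
the loop by assigning forward-model effective susceptibilities as the
amplitudes of a synthetic ssp/ppp pair.

What passing tests on these fixtures demonstrate — and what they do not:
they validate the *computational chain* (fitting recovers generating
parameters; the inversion recovers generating tilts; the pose logic and
contact analysis behave per their definitions). They do not validate the
optical constants against any particular instrument, nor the helix
geometry against real peptide ensembles with solvent, substrate atoms
and thermal disorder; the generator's Gaussian coordinate jitter is a
placeholder for conformational spread, not an MD ensemble.

The four 26-residue peptide sequences (the cecropin–melittin hybrid and
its three N-terminal mutants) ship with the package under their synthesis
labels. Because the letter labels and the narrative descriptions of the
mutants are attached differently in different places, descriptive aliases
(`extra_aromatic`, `serine_substituted`, `aromatics_removed`) record the
description-based mapping; both are documented in `?get_peptide` and the
package takes no position on which scheme is authoritative.

# Numerical choices

* Optimizer: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`),
  ftol = ptol = 10⁻¹², up to 1000 iterations. Half-widths are bounded to
  [2, 50] cm⁻¹ and centers to the fit window, which prevents peak
  swapping and absurdly broad "background" Lorentzians; the background
  amplitude is bounded below by 0. Non-convergence sets
  `converged = FALSE` on the result and is never silent; ratios from
  unconverged fits are refused.
* Peak seeding: without initial values, centers start at the n largest
  local maxima in the window, amplitudes at √I·Γ with Γ = 8 cm⁻¹. The fit
  is deterministic for fixed inputs (single start; no randomness).
* Standard errors come from the Gauss–Newton covariance scaled by the
  residual variance; on noise-free fixtures they are ~0 and the
  propagated ratio σ is 0.
* Bisection tolerance 0.01° for inversion; reported solutions re-evaluate
  onto the measured ratio within slope × tolerance.
* Degenerate inputs error early and explicitly: empty grids, files
  without Cα atoms, zero axis vectors, coincident principal variances
  (relative gap < 10⁻⁹), the critical-angle singularity, and a vanishing
  ssp amplitude (|A_ssp| at machine scale relative to A_ppp) all raise
  targeted messages rather than propagating NaNs.

Problem sizes in the shipped tests and acceptance script are desk-scale
by design: 26-residue helices, 301-point spectra, 0.25–0.5° curve grids,
and 180-point azimuthal oracle grids where the full 720-point grid is
mathematically equivalent by separability; the whole suite runs in well
under a minute.

# Known limitations

* The A and E1 exciton branches are summed at a single resonance
  frequency; amide-I A/E1 frequency splitting and the associated line
  shape asymmetry are not modelled.
* No refractive-index dispersion across the IR band, no chiral
  polarization combinations (e.g. psp), no absolute intensity
  calibration.
* The tilt distribution is a single delta (or one Gaussian); joint
  inference of mean and width from one ratio is deliberately out of
  scope, as a single ratio cannot constrain both.
* PDB handling targets standard ATOM/HETATM snapshot files; trajectory
  formats (DCD/XTC) are not read — export snapshots to PDB first.
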