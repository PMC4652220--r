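---
title: "Models and methods behind ssbcondense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssbcondense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbcondense)
```

This vignette is the package's own account of what it computes, which
parts are models of the measurement process, and where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The scientific setting

*E. coli* SSB is a homotetramer that wraps single-stranded DNA with an
occluded site size set by salt: roughly 35 nt per tetramer at low salt,
65 nt when fully wrapped at high salt. Flow-stretched single fibers of
SSB-coated ssDNA shorten dramatically as monovalent salt rises — far more
than the ~2-fold a wrapping-mode change can supply — and magnetic-tweezer
force-extension curves show that the coated fiber behaves as a reversible,
hysteresis-free equilibrium structure, unlike bare ssDNA, whose
salt-stabilized secondary structure makes pulling and relaxing branches
diverge. The package quantifies all three observations: titration
stoichiometry, single-fiber geometry, and force-extension energetics.

## The synthetic polymer law (and what it is not)

No elasticity model for ssDNA is asserted anywhere in the analysis path;
a force-extension law lives **only in the generator**, where a closed form
is needed so that every downstream estimate can be checked against an
exact oracle. The structure-free law is the saturating two-parameter form

$$L(F) = L_{\max}\,\frac{F}{F + F_{1/2}(c_s)},\qquad
  F_{1/2}(c_s) = F_0\left(1 + \frac{c_s}{s}\right),$$

with $L_{\max}$ = contour length (nt) × rise per nucleotide. Defaults:
13,552 nt (the tweezer substrate), 0.5 nm/nt, $F_0 = 1.2$ pN, $s = 300$
mM. These are chosen once as plausible single-molecule magnitudes — a
~6.8 µm saturating contour, ~90% extension at 10.5 pN, and a stiffening
with salt that mirrors the observation that more force is needed to
stretch ssDNA at high salt. They are *not* fitted to any published curve,
and the law is deliberately not a worm-like or freely-jointed chain: only
the analysis, not the polymer physics, must be faithful. Its virtue is
the closed-form work

$$\int_{F_1}^{F_2} F\,\mathrm{d}L
  = L_{\max}F_{1/2}\left[\ln(F+F_{1/2}) +
    \frac{F_{1/2}}{F+F_{1/2}}\right]_{F_1}^{F_2},$$

which `polymer_work()` exposes and the trapezoidal integrator is tested
against at the 0.1% level.

## Hysteresis and bridging as a single calibrated knob

Secondary structure on the pulling branch is modeled as a sequestered
contour fraction $\varphi(F) = \varphi_0\,(1 - F/F_c)_+$ that vanishes at
the critical force $F_c$ (default 8 pN): the pulling branch is
$L(F)(1-\varphi(F))$, the relaxing branch is structure-free. The measured
loop energy of such a pair, defined exactly as the analysis measures it
($W_{\text{pull}} - W_{\text{relax}}$ with $W = \int F\,\mathrm{d}L$ over
the schedule), is linear in $\varphi_0$:

$$\Delta W(\varphi_0) = \varphi_0\left[F_1 D(F_1) - F_2 D(F_2) +
  \int_{F_1}^{F_2} D\,\mathrm{d}F\right],\quad
  D(F) = L(F)\,(1-F/F_c)_+ ,$$

so a prescribed loop energy (e.g. the 1400 k_BT secondary-structure
budget, or a 2000 k_BT RecOR bridging energy on a coated curve) is
realized by a one-line solve for $\varphi_0$, with rejection when the
required fraction exceeds 1. The recorded truth is computed by quadrature
of the generating functions at `rel.tol = 1e-9`, and the suite checks that
trapezoidal re-measurement recovers the target within 1%.

SSB coating multiplies both branches by a condensation factor
$c \in (0,1]$ and removes hysteresis; `calibrate_condensation()` solves
(closed form, again linear in $c$) for the factor that injects a
prescribed net energy ΔΔE after branch completion, which is how the
3100 k_BT recovery criterion is constructed without circular reference to
the estimator.

## Work, completion, and the energy ledger

Work is defined as $\int F\,\mathrm{d}L$ with extension as the
integration variable, positive for stretching, so pulling − relaxing is
the classical hysteresis loop area. The alternative convention (force as
abscissa) differs only by the boundary terms of integration by parts;
the generator's calibration uses exactly the convention the ledger
measures, so the two stay consistent by construction.

Curves measured only to 10.5 pN are completed by a straight segment to
the bare-ssDNA convergence extension at 17.5 pN. The reported worst-case
area uncertainty of that segment is $\tfrac12\,\Delta F\,\Delta L$ — the
maximal deviation of any monotone completion from the chord — which for
realistic geometries is a few hundred to a few thousand pN·nm and is
carried per branch rather than folded into the energies.

Ledger conventions:

- ΔE = (W − W_ref)/k_BT against bare ssDNA at 0 mM (relaxing by
  default); k_BT fixed at the conventional 4.1 pN·nm (25 °C), while
  `kBT_pNnm()` computes the physical value (4.116…) for verification.
- ΔΔE is taken against the **relaxing** bare-ssDNA branch at matching
  salt by default: the coated complex shows no hysteresis, so the
  secondary-structure-free branch is the biologically relevant baseline.
  The pulling baseline is available by flag.
- Hysteresis is (W_pull − W_relax)/k_BT per condition, and the suite
  asserts the identity hysteresis = ΔE_pull − ΔE_relax exactly.
- Tetramer counts use round-half-away-from-zero on length/site-size;
  the site size is a user input because the plausible range (43–70 nt)
  spans 194–315 tetramers on the 13,552-nt substrate, and the true bound
  count cannot be observed in the tweezer assay.

For zero-bridging detection, `hysteresis_noise_bound()` propagates
i.i.d. per-point extension noise through the trapezoidal weights of both
branches and returns a 95% two-sided bound; the acceptance criterion asks
that bridging-free coated curves fall below it in ≥95% of seeds.

## Breakpoint fitting

The titration fit operates on the baseline-subtracted signal
(fold-enhancement − 1), reconciling a normalized baseline of 1 with the
constraint that the rising segment pass through the origin and the
plateau have zero slope, with continuity at the breakpoint. For a fixed
breakpoint the plateau amplitude is solved in closed form, so the
residual sum of squares is a one-dimensional profile. Rather than a
fixed 1-nt grid plus refinement, the profile is minimized **exactly**:
between consecutive data ratios the active set is constant and the
profile smooth, so optimizing within every such interval and comparing
endpoint values yields the global minimizer. This is a strict
strengthening of a coarse-grid-plus-polish search — it provably matches
the exhaustive 0.1-nt grid oracle and, because the candidate intervals
are data-derived, it makes the estimator exactly scale-equivariant
(a fixed 1-nt grid is not). Ties break toward the smaller breakpoint.
Standard errors come from a seeded case-resampling bootstrap (1000
resamples by default; the original analysis reported fit errors without
stating a method).

The salt back-titration midpoint is the inflection of a declining-line ×
logistic model fitted (Nelder–Mead on a profiled start) to the points past
the signal maximum only; the sharp initial rise and shallow decline are
excluded from the window by construction.

## Image quantification

Fiber length is the contiguous above-threshold run from the tether pixel
along the flow axis (image rows), times the pixel size, with threshold =
background mean + 3 background s.d. estimated from the flanking columns.
The contiguous-run rule (rather than counting all bright pixels) is an
implementation convention — the original length operator is unstated —
chosen for robustness to detached debris; it is validated only against
synthetic truth (±2 px across a 6.5→0.5 µm condensation schedule at
PSF σ = 1 px). Pixel indices are 1-based, following R convention.
Length-population summaries report the sample mean and sample (n−1)
standard deviation, the bin-free equivalent of a Gaussian histogram fit;
the strict MLE σ differs by √((n−1)/n) and the package follows the
mean/s.d. convention its invariants name.

## What the generators do and do not emulate

Emulated: saturating force-extension with salt stiffening; linear-decay
secondary-structure hysteresis with calibrated loop energy; multiplicative
SSB compaction with optional calibrated bridging; piecewise-linear
titration isotherms; rise/decline/logistic back-titrations; exponential
force-step relaxations; Gaussian-profiled single fibers with sub-pixel
ends, Gaussian PSF and Gaussian background, at a conventional 0.16 µm
pixel. Noise is additive, Gaussian, i.i.d. per point throughout — the
simplest testable model; no published noise spectra exist for these data.

Not emulated: SSB binding-mode kinetics, octamer formation or
intersegmental transfer; bead/trap physics and force calibration; camera
noise beyond Gaussian background; crowded fields of view, drift, or
photobleaching. A green recovery test therefore establishes that the
estimators are correct and well-conditioned under the stated noise model —
not that the instrument systematics of real recordings are handled.

Noise defaults used by the recovery criteria, chosen once as realistic
magnitudes: 10 nm extension noise (bead-tracking scale for µm-long
tethers), 2% of plateau for titrations, 5% for back-titrations and
condensation profiles.

## Degenerate inputs and numerical choices

- Zero noise + zero hysteresis + c = 1 collapses every force-extension
  generator onto the bare polymer law (tested).
- Constant time traces return amplitude 0, converged, and an `NA` tau
  sentinel; the equilibrium criterion (fitted drift over the final 20%
  of the segment < 1% of amplitude) is an invented operationalization of
  "reached equilibrium".
- 0 mM points are excluded from log-salt slope fits (ln 0 undefined);
  callers drop them explicitly.
- Flow-force matching breaks ties toward the smallest force and reports
  the interval of forces within 2× the minimal misfit.
- All seeds are mandatory arguments; no generator touches global random
  state (`withr::with_seed` scoping).

## File formats

Tidy CSV with mandatory headers for branches, time traces and titrations;
JSON for fits, ledgers (with a TSV mirror of the condition × direction
energy layout) and all truth sidecars. Image stacks use a long-format
CSV (frame,row,col,value; 16-bit integer values) with a JSON sidecar: the
environment provides no TIFF reader for R and the repository is
text-only, so the multi-page-TIFF interface is replaced by this portable
text format with the in-memory contract unchanged.

## Known limitations

- The polymer law is a stand-in; absolute works are meaningful only
  within the synthetic world, and only differences/recoveries are tested.
- Completion error is bounded, not corrected; branches that truly deviate
  from the chord between 10.5 and 17.5 pN bias works within that bound.
- The breakpoint bootstrap resamples cases and can be optimistic for the
  very sparse (< 10-point) titrations the preconditions warn about.
- One fiber per stack; no segmentation of crowded fields.
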