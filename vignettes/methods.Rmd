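---
title: "Diffraction-data triage: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffraction-data triage: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(refltriage)
```

This vignette explains the statistical models behind each `refltriage`
analysis, the assumptions they rest on, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## Symmetry machinery

Space groups are represented explicitly as operator lists (rotation part
acting on fractional coordinates as `x' = R x + t`; Miller indices act as
row vectors, `h' = h R`). Translations are stored as integer twelfths, so
centricity, epsilon factors and systematic-absence tests are exact
integer arithmetic with no floating-point tolerance anywhere in the group
algebra. The built-in symbol table covers the common macromolecular
groups in their standard settings (triclinic through cubic, including the
chiral screw groups and C/I centring); any other group can be supplied as
explicit `"x,y,z"` triplets, which must already close under composition.
Lattice centrings are ordinary group elements, which makes centring
absences and merging fall out of the same logic as screw absences.

The canonical asymmetric-unit representative of an index is the
lexicographically greatest among its symmetry equivalents (and Friedel
mates, unless the set is anomalous). This ordering is group-agnostic and
total, which makes merging, completeness and pair lookups trivially
consistent; it does not coincide with the conventional reciprocal-space
ASU wedges, which nothing downstream requires.

## Normalization and the twinning screens

All intensity statistics assume, per resolution shell, the ideal
Wilson-regime distributions: exponential intensities for acentric
reflections and the half-normal-derived distribution for centric ones.
Normalized intensities are `E^2 = I / (eps * <I/eps>_shell)` with shell
means over measured, non-absent reflections; `<E^2> = 1` holds per shell
by construction (the test suite asserts it to 1e-10). Shells are
equal-reciprocal-volume (equal 1/d^3 increments, default 20 shells,
coalesced below 40 reflections) so that shell populations are roughly
equal.

**Moments.** For ideal acentric data `<I^2>/<I>^2 = 2`; the incoherent
twin sum `I' = (1-a) I_1 + a I_2` of independent intensities pulls the
moment monotonically down to 1.5 at `a = 0.5`. The reported reference
values are produced at run time by a small Monte-Carlo sampler
(`mcReferenceMoments()`), not hard-coded, so the report and its
references can never drift apart.

**L-test.** `L = (I_1 - I_2)/(I_1 + I_2)` over pairs of reflections
close in reciprocal space. Pairing uses a fixed all-even offset set
{(0,0,2), (0,2,0), (2,0,0), (0,2,2), (2,0,2), (2,2,0), (2,2,2)} with a
seeded per-reflection choice. The even offsets are the point of the
statistic: translational NCS close to half-cell vectors modulates
intensities with index parity, and even offsets keep both pair members in
the same modulation class. The test suite demonstrates the rationale
directly: with a near-half-cell tNCS simulation the all-even pairing
stays at `<|L|> ~ 0.5` while an odd-offset pairing is visibly biased
upward. Pairs are formed on `E^2` rather than raw `I`; with raw
intensities the resolution falloff between pair members biases `<|L|>`
upward by about 0.01 on typical cells, which is comparable to the
distance between the untwinned and twinned references and therefore
matters. Members with non-positive (noise) intensities are discarded: a
ratio statistic is undefined for unmeasurably weak data.

**H-test.** For twin-related pairs, the twin sum scales the pair
difference by `(1 - 2a)` and preserves the pair sum, so
`H = |I(h) - I(Th)| / (I(h) + I(Th))` is uniform on `[0, 1-2a]` and
`a = 1/2 - <H>`. This is the headline twin-fraction estimate. A slope
fit of the cumulative distribution through the origin (over `S <= 0.8`,
avoiding the saturated head) is reported as a consistency check, not
averaged in.

**Britton plot.** Detwinning at trial `a` below the true fraction keeps
both detwinned intensities non-negative on noise-free data; above it,
negatives appear and grow steeply. A line is fitted to the rising region
of the negative-count curve — counts between 10% and 60% of the maximum,
bounds chosen to avoid the noisy toe and the saturated head — and its
alpha-axis intercept, clipped to [0, 0.5), is the estimate.

**Twin law enumeration.** Merohedral candidates come from a small table
of coset representatives keyed by crystal family and point-group order
(tetragonal, trigonal, hexagonal, cubic). Pseudo-merohedral candidates
are proposed only when the metric cooperates: monoclinic beta within
0.5 degrees of 90, or orthorhombic `a` and `b` equal within 0.5%
(both configurable). Every candidate must satisfy `T^2` in the group and
`T` not in the group. This is deliberately not a lattice-reduction
engine; laws for exotic pseudo-symmetries must be supplied by the user.

**Twinning versus under-assigned symmetry.** A twin-related intensity
correlation near 1 is ambiguous: near-perfect twinning and too-low
assigned symmetry look the same to the H-test. The disambiguation is the
merging R under the augmented group (the assigned group plus the twin
operator): genuine symmetry merges cleanly (R below 0.1 by default),
twinning does not. Correlations are computed on `E^2` so that the shared
falloff does not inflate them.

## Wilson and anisotropic scaling

The Wilson fit regresses `ln(<I/eps>_shell / sum_j f_j^2(s))` on
`s^2 = 1/(4 d^2)` over shells with mean d below 4.5 A (the roughly
linear regime; configurable). Slope is `-2B`, intercept `ln K`. Atomic
form factors come from a built-in 4-Gaussian table (H, C, N, O, P, S;
other elements fall back to a constant equal to the electron count),
adequate for Wilson-level statistics. When no composition is given, a
protein-like mix scaled to the cell volume is used; the composition only
shapes the denominator, so it affects K but barely B.

The anisotropy fit generalizes this per reflection:
`ln(I / sum f^2) = ln K - 2 u' beta u` with `u` the Cartesian
reciprocal vector, solved by least squares with the tensor constrained by
the crystal family (diagonal for orthorhombic, `b11 = b22` for
tetragonal/trigonal/hexagonal, `b13` free for monoclinic). Eigenvalues
are reported on the conventional B scale (`B = 4 beta`). Dividing by the
scattering sum first matters: otherwise the form-factor falloff would
masquerade as several A^2 of isotropic B and bias small eigenvalues far
beyond the 15% recovery target. For the cubic family the quadratic form
is isotropic by constraint and the fit simply delegates to the Wilson
fit — which also makes "isotropically constrained anisotropy equals the
Wilson B" an identity rather than an approximation.

## Screw axes, ice rings, data quality

**Screw axes** are inferred from axial mean I/sigma: for each hypothesis
compatible with the family (2-fold screws on principal axes, 4(2)/4(1)
along c for tetragonal, 3(1) for trigonal, 6(3)/6(2)/6(1) for
hexagonal), the predicted-absent class must sit at noise level (mean
I/sigma below 1) while the predicted-present class is clearly observed
(above 3). Both cutoffs are configuration keys. With no axial data the
verdict is "indeterminate", never silently negative.

**Ice rings.** Mean intensity in thin shells (width 0.002 in 1/d^2
units — narrow enough to separate the 3.90/3.67/3.44 A ring triplet) is
compared on the log scale against a local linear baseline fitted through
the 10 neighboring shells, and the residual is scored against the
per-shell standard error of the log-mean. The local fit removes the
Wilson falloff without absorbing a one-shell spike; a shell-normalized
statistic (Z) was rejected because the normalization itself absorbs a
large part of any ring, capping the attainable significance below a
usable threshold. Flagged shells intersecting the built-in hexagonal-ice
list (3.90 ... 1.92 A) are reported as ice rings; other flagged shells
as generic mean-intensity anomalies. The scan is skipped, with a logged
notice, when the data end above 4 A.

**Completeness** counts observed unique reflections against the full
enumerated sphere to d_min, with systematic absences excluded from the
denominator and Friedel mates collapsed unless the set is anomalous.
Merging uses inverse-variance weighted means with
`R_merge = sum |I_i - <I>| / sum I_i` over multiply-observed uniques and
the `sqrt(n/(n-1))`-corrected `R_meas`.

## Patterson tNCS search

The native Patterson is the FFT of raw merged intensities over the
Friedel-completed full sphere, on a grid with spacing at most
d_min/3 (dimensions rounded up to 2,3,5-smooth sizes; rounding changes
cost, not values), origin-normalized to 100. Raw `I` coefficients are the
classic choice; an origin-removal switch subtracts shell means for
sharper off-origin features. Peak search keeps local maxima at least
10 A from the origin (and from its lattice images), refines positions by
per-axis quadratic interpolation, and collapses centrosymmetric mates.
Two equal copies related by translation `t` put roughly half the origin
weight at `t`; the default 20%-of-origin warning threshold is
conventional practice, deliberately configurable because no universal
cutoff exists.

## Anomalous measurability

Bijvoet pairs are matched per acentric unique reflection (centrics are
excluded — their true anomalous difference is zero by symmetry), and
measurability is the fraction of pairs with
`|I+ - I-| / sqrt(sig+^2 + sig-^2)` above a significance cut, default
3 sigma. Under pure noise this fraction is the two-sided normal tail,
0.27% — the test suite verifies that calibration by simulation, and that
measurability rises monotonically with the simulated f'' of the sulfur
substructure. The cut is configurable and echoed in the report; no
attempt is made to model the expected-information refinements of more
elaborate treatments.

## The simulator: what it emulates, and what it does not

`simulateDataset()` builds random uniform atom positions (protein-like
element mix), expands them by the space group, enumerates all unique
indices to d_min (systematically absent indices included, carrying their
near-zero computed intensities, so absence detection is testable against
emergent rather than assumed zeros), computes structure factors by exact
direct summation with the Debye-Waller convention `exp(-B/(4 d^2))` on
amplitudes, then applies the twin sum, and finally a two-parameter
counting-like Gaussian noise model
`sigma = k sqrt(max(I, <I>/100) <I>)` with negatives retained. All
randomness derives from the single mandatory seed; a dataset is
regenerable bit-identically from its configuration.

What this reproduces faithfully: Wilson-regime intensity statistics,
centric/acentric moments, absences, Bijvoet differences from complex
form factors, twin sums, tNCS interference. What it does not attempt:
bulk solvent (so low-resolution means are too clean), atomic-resolution
features, radiation damage, detector artifacts, outliers, or
multi-sweep scaling. Passing parameter-recovery tests therefore shows
the estimators are correct under the stated statistical model, not that
real data never violate it — real Wilson plots, for instance, bend at
low resolution where the solvent term lives, which is why the fit range
starts at 4.5 A.

Default study conditions used by the tests and the acceptance script:
the L-test/moment/N(Z) references use a ~50,000-reflection noise-free
triclinic dataset on an orthorhombic-metric cell (so the twofold
`h,-k,-l` is a valid twin operation of the lattice); twin-fraction
recovery uses noise-free tetragonal P41 data (~4,300 uniques, ~1,700
twin pairs); tNCS and screw checks use ~5,000-10,000-reflection
monoclinic/triclinic sets with 5% noise; the end-to-end false-warning
and detection rates run 20 clean and 20 pathology-injected triage jobs.
These sizes keep the full suite under a minute while leaving every
tolerance dominated by the estimator, not the sample size.

## Verdicts and thresholds

Every threshold lives in `triageConfig()` and is echoed verbatim in the
report: twinning warns when `<|L|> < 0.465` or the acentric second
moment is below 1.7, and escalates to severe when a twin-fraction
estimate exceeds 0.1; tNCS warns at a 20%-of-origin peak;
symmetry-too-low requires twin correlation above 0.95 *and* augmented-
symmetry merging R below 0.1; anomalous signal is called useful at 5%
measurability; data quality warns below 85% completeness or mean
I/sigma of 2. Detected screw axes are evidence, not warnings — a screw
axis is crystallography, not pathology. The CLI encodes the worst
verdict in its exit status (0/1/2).

## Numerical choices and degenerate inputs

* Group algebra is exact (integer twelfths); no tolerance.
* Pseudo-merohedry metric tolerances: 0.5 degrees / 0.5%, configurable.
* Detwinning refuses `alpha >= 0.5` (singular); sigmas propagate through
  the same linear combination in quadrature.
* Negative intensities are kept everywhere (merging, moments,
  normalization); only ratio statistics (L, H) drop non-positive
  members, and the Britton count treats them as data.
* Empty shells are coalesced at binning time; shells without data report
  NA, never 0.
* `noise_k = 0` keeps intensities exact but floors sigmas at a tiny
  positive value so I/sigma stays defined.
* Patterson peak interpolation falls back to the grid node when the
  local curvature is not negative along an axis.
* Free-set selection is `min(round(0.05 n), 2000)` reflections, the
  conventional cross-validation size cap.

## Known limitations

Space-group coverage is the documented list plus explicit triplets; no
non-standard settings or full International Tables machinery. Twin-law
enumeration does not perform lattice reduction, so pseudo-merohedry on
specialized cells outside the two metric checks must be supplied
manually. The anisotropy fit is least-squares on log intensities, not a
likelihood treatment, and is reported as such. Measurability implements
the plain significance-fraction criterion only. Unmerged multi-sweep
scaling is out of scope: `mergeEquivalents()` assumes observations on a
common scale.
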