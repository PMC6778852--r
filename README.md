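# refltriage

Quality triage of X-ray diffraction data for macromolecular
crystallography, before any structure determination is attempted.

Macromolecular crystals are prone to pathologies that corrupt downstream
phasing and refinement if they go unnoticed: **merohedral twinning**
(intergrown domains whose lattices superpose under a twin operator, so
every measured spot is a weighted sum of two true intensities),
**translational noncrystallographic symmetry** (tNCS: molecular copies
related by a pure translation, which modulates the whole intensity
distribution), unmodelled **screw axes**, **ice rings**, strong
**anisotropy**, and **under-assigned symmetry**. `refltriage` screens a
merged or unmerged reflection dataset for all of these and reports
data-quality indicators alongside, in the spirit of the classic
command-line triage tools.

## The statistics at its core

For measured intensities *I*(**h**) with symmetry-enhancement factor
ε(**h**) and shell means ⟨·⟩:

* **Normalization**: E²(**h**) = I/(ε·⟨I/ε⟩), Z = I/⟨I⟩. For ideal
  acentric data ⟨I²⟩/⟨I⟩² = 2 and N(Z) = 1 − e^(−Z); a perfect twin gives
  1.5 and a sigmoidal N(Z).
* **L-test** (local pair statistic): L = (I₁ − I₂)/(I₁ + I₂) over pairs
  of reflections close in reciprocal space, paired through a fixed
  all-even index offset set so tNCS modulation cancels. Untwinned:
  ⟨|L|⟩ = 1/2, ⟨L²⟩ = 1/3; perfect twin: 3/8 and 1/5.
* **H-test**: for twin-related pairs, H = |I(**h**) − I(T**h**)| /
  (I(**h**) + I(T**h**)) is uniform on [0, 1 − 2α]; the twin fraction is
  α = 1/2 − ⟨H⟩.
* **Britton plot**: detwin on a trial-α grid and count negative
  intensities; the rising-region intercept estimates α.
* **Wilson fit**: ln(⟨I/ε⟩/Σfⱼ²) against s² = 1/(4d²) gives the overall
  scale K (intercept) and B factor (−slope/2); a symmetry-constrained
  tensor version quantifies anisotropy.
* **Native Patterson**: FFT of the intensities; an off-origin peak of
  roughly half the origin height at vector **t** is the signature of a
  two-copy tNCS translation **t**.
* **Systematic absences**: mean I/σ of axial reflection classes tests
  each screw-axis hypothesis.
* **Bijvoet measurability**: fraction of acentric pairs with
  |I⁺ − I⁻|/σ(ΔI) above a significance cut — the achieved anomalous
  signal.
* **R factors**: R = Σ|F_obs − k·F_model| / ΣF_obs on work and held-out
  (free) reflection subsets.

A ground-truth simulator (random structures, direct-summation structure
factors, injectable twinning / tNCS / anomalous signal / noise) makes
every statistic testable by parameter recovery.

## Worked example

```r
library(refltriage)

# simulate a twinned tetragonal dataset and write it to disk
cfg <- syntheticConfig(sg = "P41", n_atoms = 80, d_min = 2.3,
                       alpha_true = 0.35, noise_k = 0.05, seed = 72)
ds <- simulateDataset(cfg, dir = "demo")

# full triage on the mmCIF file
report <- runTriage("demo/reflections.cif")
print(report)
```

```
refltriage 0.9.0 triage report
input: demo/reflections.cif (4312 unique, 55.00-2.30 A, P41)

verdicts:
  [severe ] twinning          mean_abs_L=0.3883  acentric_i2_over_i_sq=1.602  alpha_estimates=0.3444/0.3444
  [ok     ] tncs              n_peaks=0  top_peak
  [ok     ] ice_rings         n_flagged=0  d_flagged=NA  n_other_anomalies=0
  [ok     ] screw_axes        detected=4(2) along c,4(1)/4(3) along c
  [ok     ] anisotropy        delta_B=0.453  ratio=0.02494  eigenvalues=18.47/18.02/18.02
  [ok     ] data_quality      completeness=1  i_over_sigma=17.18
  [ok     ] symmetry_too_low  max_correlation=0.8244  min_r_merge_augmented=0.1576

Wilson: B = 19.8 A^2, K = 0.0523
L-test: <|L|> = 0.388, <L^2> = 0.215 (3189 pairs)
completeness: 100.0%
mean I/sigma: 17.2

not performed:
  anomalous: no Bijvoet-separated data
```

Reading the verdict lines: the mean |L| of 0.388 is far below the
untwinned expectation of 0.5, the acentric second moment 1.60 is much
closer to the perfect-twin value 1.5 than to the untwinned 2.0, and both
twin-fraction estimators (H-test and Britton plot) recover α ≈ 0.344
against the injected 0.35 — a severe twinning call. The 4₁ screw along
**c** is correctly read off the axial absences, and the twin-related
correlation of 0.82 with a merging R of 0.16 under the augmented symmetry
rules out mere symmetry under-assignment (that verdict would require
correlation > 0.95 with augmented R < 0.1).

The same report serializes losslessly to JSON with
`renderReport(report, "json")`. A thin command-line wrapper lives at
`inst/cli/refltriage.R`:

```sh
Rscript inst/cli/refltriage.R run demo/reflections.cif --json report.json
# exit code: 0 ok / 1 warning / 2 severe
```

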