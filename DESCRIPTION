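Package: refltriage
Title: Diffraction Data Triage for Macromolecular Crystallography
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality triage of merged or unmerged X-ray reflection data.
    Detects crystal pathologies before structure determination: twinning
    (L-test, H-test, Britton plot, twin-law enumeration and detwinning),
    translational noncrystallographic symmetry via the native Patterson
    function, systematic absences and screw axes, ice rings and
    mean-intensity anomalies, overall anisotropy, and under-assigned
    symmetry. Also reports Wilson scale and B factor, normalized-intensity
    (E-value) moments and N(Z) cumulative distributions, merging statistics,
    completeness and signal-to-noise, Bijvoet-difference anomalous
    measurability, and R-work/R-free model-versus-data agreement. A
    direct-summation structure-factor simulator with injectable pathologies
    provides ground truth for parameter-recovery testing. Reads and writes
    structure-factor mmCIF and a documented CSV dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'refltriage-package.R'
    'AllGenerics.R'
    'cell.R'
    'spacegroup.R'
    'formfactors.R'
    'ReflectionSet.R'
    'io.R'
    'merge.R'
    'normalize.R'
    'aniso.R'
    'screw.R'
    'twinning.R'
    'patterson.R'
    'anomalous.R'
    'simulator.R'
    'triage.R'
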