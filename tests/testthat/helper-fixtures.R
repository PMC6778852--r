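# Shared simulated datasets, built once per test run. All fixtures are
# generated in code from fixed seeds; nothing is stored on disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Clean monoclinic dataset with modest noise: the all-purpose input.
cleanP21 <- function() fixture("p21", function()
  simulateDataset(syntheticConfig(sg = "P21", n_atoms = 80, d_min = 2.3,
                                  noise_k = 0.05, seed = 7)))

# Large noise-free triclinic dataset on an orthorhombic-metric cell
# (~50k unique): host for the L-test / moment / N(Z) reference statistics.
# The orthorhombic metric makes the twofold h,-k,-l a valid (pseudo-
# merohedral) twin operation of the lattice.
bigP1 <- function() fixture("p1big", function()
  simulateDataset(syntheticConfig(sg = "P1", cell = UnitCell(55, 60, 58),
                                  n_atoms = 120, d_min = 2.0, noise_k = 0,
                                  b_iso = 15, seed = 11)))

# Noise-free tetragonal dataset: host for twin-fraction recovery.
cleanP41 <- function() fixture("p41", function()
  simulateDataset(syntheticConfig(sg = "P41", n_atoms = 80, d_min = 2.3,
                                  noise_k = 0, b_iso = 15, seed = 5)))

p41Law <- function() candidateTwinLaws(cleanP41()$set@cell,
                                       cleanP41()$set@sg)[[1]]

# Twofold along a as a bare matrix (valid on any orthogonal-metric lattice).
lawTwofoldA <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3, byrow = TRUE)

# Tiny unmerged set for merge arithmetic.
tinyUnmerged <- function(df, sgsym = "P21",
                         cell = UnitCell(30, 40, 35, 90, 100, 90))
  reflectionSet(cell, sgsym, df)
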