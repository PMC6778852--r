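test_that("structure generation counts sites and reproduces by seed", {
  cfg <- syntheticConfig(sg = "P212121", n_atoms = 50, seed = 3)
  a1 <- generateStructure(cfg)
  expect_identical(nrow(a1), 50L)
  expect_identical(a1, generateStructure(cfg))
  ex <- expandSymmetry(a1, cfg$sg)
  expect_identical(nrow(ex), 50L * 4L)
  cfgT <- syntheticConfig(sg = "P212121", n_atoms = 50,
                          tncs_vector = c(0.5, 0, 0), seed = 3)
  expect_identical(nrow(generateStructure(cfgT)), 100L)
  expect_error(syntheticConfig(sg = "P1"), "seed")
})

test_that("direct summation obeys phase, cancellation and absence algebra", {
  cl <- UnitCell(10, 12, 14)
  hkl <- rbind(c(1, 0, 0), c(2, 3, 1), c(0, 0, 5))
  # one atom at the origin, B = 0: F is the bare form factor, phase zero
  at0 <- data.frame(element = "C", x = 0, y = 0, z = 0, B = 0, occ = 1)
  sf <- calcStructureFactors(at0, hkl, cl)
  s2 <- 1 / (4 * dSpacing(hkl, cl)^2)
  expect_equal(sf$reF, scatteringFactor("C", s2), tolerance = 1e-12)
  expect_equal(sf$imF, rep(0, 3), tolerance = 1e-12)
  # two equal atoms half a cell apart along x cancel all odd h
  at2 <- data.frame(element = "C", x = c(0.13, 0.63), y = 0.4, z = 0.7,
                    B = 5, occ = 1)
  hklo <- rbind(c(1, 0, 0), c(3, 0, 0), c(2, 0, 0))
  sfo <- calcStructureFactors(at2, hklo, cl)
  expect_lt(sfo$F[1], 1e-10)
  expect_lt(sfo$F[2], 1e-10)
  expect_gt(sfo$F[3], 1)
  # P21 expansion produces the (0,k,0) odd absences numerically
  cfg <- syntheticConfig(sg = "P21", n_atoms = 20, d_min = 3, noise_k = 0,
                         seed = 5)
  atoms <- expandSymmetry(generateStructure(cfg), cfg$sg)
  kax <- cbind(0L, 1:12, 0L)
  sfk <- calcStructureFactors(atoms, kax, cfg$cell)
  odd <- kax[, 2] %% 2 == 1
  expect_lt(max(sfk$F[odd]), 1e-8)
  expect_gt(min(sfk$F[!odd]), 1e-4)
})

test_that("emergent absences coincide exactly with symbolic predictions", {
  for (sym in c("P21", "P41", "C2221")) {
    ds <- fixture(paste0("abs_", sym), function()
      simulateDataset(syntheticConfig(sg = sym, n_atoms = 30, d_min = 3,
                                      noise_k = 0, seed = 17)))
    I <- ds$truth$sf$I
    hkl <- cbind(ds$truth$sf$h, ds$truth$sf$k, ds$truth$sf$l)
    emergent <- I < 1e-12 * mean(I)
    expect_identical(emergent, isAbsent(hkl, ds$set@sg), info = sym)
  }
})

test_that("Friedel symmetry is exact without and broken with f''", {
  cfg0 <- syntheticConfig(sg = "P1", cell = UnitCell(15, 16, 17),
                          n_atoms = 10, d_min = 4, noise_k = 0, seed = 6)
  atoms <- expandSymmetry(generateStructure(cfg0), cfg0$sg)
  hkl <- rbind(c(1, 2, 0), c(2, -1, 3), c(0, 1, -2))
  sfP <- calcStructureFactors(atoms, hkl, cfg0$cell)
  sfM <- calcStructureFactors(atoms, -hkl, cfg0$cell)
  expect_equal(sfP$I, sfM$I, tolerance = 1e-12)
  atomsS <- atoms; atomsS$element <- "S"
  sfPa <- calcStructureFactors(atomsS, hkl, cfg0$cell, fdp = c(S = 4))
  expect_gt(mean(abs(sfPa$Iplus - sfPa$Iminus)), 0)
})

test_that("noise model floors sigmas, reproduces, and yields negatives", {
  I <- rexp(5000) * 100
  nz0 <- addNoise(I, 0, seed = 1)
  expect_identical(nz0$I, I)
  expect_true(all(nz0$sigI > 0))
  nz1 <- addNoise(I, 0.3, seed = 2)
  expect_identical(nz1$I, addNoise(I, 0.3, seed = 2)$I)
  expect_gt(sum(nz1$I < 0), 0)
  expect_false(identical(nz1$I, addNoise(I, 0.3, seed = 3)$I))
})

test_that("full pipeline produces the expected dataset shape and files", {
  dir <- withr::local_tempdir()
  cfg <- syntheticConfig(seed = 1)   # defaults: 150 atoms, P21, 2.0 A
  ds <- fixture("defaultP21", function() simulateDataset(cfg))
  expect_gt(nrow(ds$set@data), 5000)
  expect_true(ds$set@merged)
  # byte-identical regeneration from config + seed
  dir1 <- file.path(dir, "a"); dir2 <- file.path(dir, "b")
  d1 <- simulateDataset(syntheticConfig(sg = "P21", n_atoms = 25,
                                        d_min = 3.2, seed = 9),
                        dir = dir1)
  d2 <- simulateDataset(syntheticConfig(sg = "P21", n_atoms = 25,
                                        d_min = 3.2, seed = 9),
                        dir = dir2)
  expect_identical(readLines(d1$files[["csv"]]),
                   readLines(d2$files[["csv"]]))
  expect_true(file.exists(d1$files[["pdb"]]))
  expect_true(file.exists(d1$files[["mmcif"]]))
  # an invalid twin configuration fails before any computation
  expect_error(simulateDataset(syntheticConfig(
    sg = "P212121", alpha_true = 0.3, seed = 2)), "no twin law")
})

test_that("a heavily twinned dataset is flagged downstream", {
  ds <- fixture("twin45", function()
    simulateDataset(syntheticConfig(sg = "P41", n_atoms = 60, d_min = 2.4,
                                    noise_k = 0.05, alpha_true = 0.45,
                                    seed = 13)))
  lt <- lTest(ds$set, seed = 1)
  expect_lt(lt$mean_abs_L, 0.465)
  ht <- hTest(ds$set, p41Law())
  expect_gt(ht$alpha_mean, 0.35)
})
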