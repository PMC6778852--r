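test_that("candidate twin laws respect family, point group and metric", {
  # orthorhombic holohedry with a general cell: nothing to propose
  expect_length(candidateTwinLaws(UnitCell(40, 50, 60),
                                  parseSpaceGroup("P212121")), 0)
  # tetragonal point group 4: one merohedral twofold
  laws <- candidateTwinLaws(UnitCell(42, 42, 55), parseSpaceGroup("P41"))
  expect_length(laws, 1)
  expect_identical(laws[[1]]@kind, "merohedral")
  Tm <- laws[[1]]@operator
  expect_identical(abs(round(det(Tm))), 1)
  # the holohedral 422 setting has no merohedral law left
  expect_length(candidateTwinLaws(UnitCell(42, 42, 55),
                                  parseSpaceGroup("P41212")), 0)
  # trigonal point group 3 offers several twofolds
  expect_gt(length(candidateTwinLaws(UnitCell(45, 45, 50, 90, 90, 120),
                                     parseSpaceGroup("P31"))), 1)
  # monoclinic pseudo-merohedry only when beta is near 90
  expect_length(candidateTwinLaws(UnitCell(40, 50, 45, 90, 90.2, 90),
                                  parseSpaceGroup("P21")), 1)
  expect_identical(candidateTwinLaws(UnitCell(40, 50, 45, 90, 90.2, 90),
                                     parseSpaceGroup("P21"))[[1]]@kind,
                   "pseudo-merohedral")
  expect_length(candidateTwinLaws(UnitCell(40, 50, 45, 90, 100, 90),
                                  parseSpaceGroup("P21")), 0)
  # orthorhombic with a ~ b: pseudo-tetragonal swap
  expect_length(candidateTwinLaws(UnitCell(50, 50.1, 60),
                                  parseSpaceGroup("P222")), 1)
})

test_that("L statistics sit at the untwinned / perfect-twin references", {
  set0 <- bigP1()$set
  lt <- lTest(set0, seed = 3)
  expect_equal(lt$mean_abs_L, 0.5, tolerance = 0.01)
  expect_equal(lt$mean_L2, 1 / 3, tolerance = 0.01)
  tw <- applyTwin(set0, lawTwofoldA, 0.5)
  lt2 <- lTest(tw, seed = 3)
  expect_equal(lt2$mean_abs_L, 0.375, tolerance = 0.012)
  expect_equal(lt2$mean_L2, 0.2, tolerance = 0.012)
  # cumulative curve tracks its reference
  expect_lt(max(abs(lt$curve$N - lt$curve$N_untwinned)), 0.02)
  expect_lt(max(abs(lt2$curve$N - lt2$curve$N_perfect)), 0.03)
  # identical intensities give L = 0 exactly
  df <- data.frame(h = rep(1:30, each = 30), k = rep(1:30, 30),
                   l = 3, I = 5, sigI = 1)
  cset <- reflectionSet(UnitCell(90, 90, 20), "P1", df, merged = TRUE)
  ltc <- suppressWarnings(lTest(cset, seed = 1))
  expect_equal(ltc$mean_abs_L, 0)
})

test_that("H-test and Britton recover injected twin fractions", {
  set0 <- cleanP41()$set
  law <- p41Law()
  for (a in c(0, 0.2, 0.35)) {
    tw <- applyTwin(set0, law, a)
    ht <- hTest(tw, law)
    expect_lt(abs(ht$alpha_mean - a), 0.02)
    expect_lt(abs(ht$alpha_slope - a), 0.03)
    br <- britton(tw, law)
    expect_lt(abs(br$alpha_estimate - a), 0.05)
  }
  # H = 0 for identical pairs means a perfect twin
  twp <- applyTwin(set0, law, 0.5)
  htp <- hTest(twp, law)
  expect_equal(htp$alpha_mean, 0.5, tolerance = 1e-9)
})

test_that("detwinning inverts twinning exactly and propagates sigmas", {
  set0 <- cleanP41()$set
  law <- p41Law()
  for (a in c(0.1, 0.25, 0.45)) {
    tw <- applyTwin(set0, law, a)
    dt <- detwin(tw, law, a)
    m <- match(refltriage:::hklKey(cbind(dt@data$h, dt@data$k, dt@data$l)),
               refltriage:::hklKey(cbind(set0@data$h, set0@data$k, set0@data$l)))
    relerr <- abs(dt@data$I - set0@data$I[m]) /
      pmax(abs(set0@data$I[m]), 1e-300)
    expect_lt(max(relerr), 1e-9)
  }
  # alpha = 0 is the identity
  dt0 <- detwin(set0, law, 0)
  expect_equal(dt0@data$I, set0@data$I)
  expect_error(detwin(set0, law, 0.5), "singular")
  # hand arithmetic on one pair
  df <- data.frame(h = c(2, 2), k = c(1, -1), l = c(5, -5),
                   I = c(80, 20), sigI = c(1, 1))
  pset <- reflectionSet(UnitCell(42, 42, 55), "P41", df, merged = TRUE,
                        anomalous = TRUE)  # keep both rows distinct
  dts <- detwin(pset, lawTwofoldA, 0.25)
  expect_equal(dts@data$I[1], (0.75 * 80 - 0.25 * 20) / 0.5)
  expect_equal(dts@data$I[2], (0.75 * 20 - 0.25 * 80) / 0.5)
})

test_that("twin sum arithmetic matches the weighted-overlap definition", {
  df <- data.frame(h = c(2, 2), k = c(1, -1), l = c(5, -5),
                   I = c(100, 20), sigI = c(1, 1))
  pset <- reflectionSet(UnitCell(42, 42, 55), "P41", df, merged = TRUE,
                        anomalous = TRUE)
  tw <- applyTwin(pset, lawTwofoldA, 0.3)
  expect_equal(tw@data$I, c(0.7 * 100 + 0.3 * 20, 0.7 * 20 + 0.3 * 100))
  expect_identical(applyTwin(pset, lawTwofoldA, 0)@data$I, pset@data$I)
  tw5 <- applyTwin(pset, lawTwofoldA, 0.5)
  expect_equal(tw5@data$I[1], tw5@data$I[2])
})

test_that("second moment decreases monotonically with the twin fraction", {
  set0 <- bigP1()$set
  ratios <- vapply(seq(0, 0.5, by = 0.1), function(a) {
    tw <- applyTwin(set0, lawTwofoldA, a)
    momentStats(normalizeIntensities(tw), mc_n = 1000)$
      acentric$i2_over_i_sq
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("twin-related correlation separates twinning from symmetry", {
  set0 <- cleanP41()$set
  law <- p41Law()
  expect_lt(abs(twinCorrelation(set0, law)$correlation), 0.1)
  expect_gt(twinCorrelation(applyTwin(set0, law, 0.5),
                            law)$correlation, 0.98)
  # data carrying the higher symmetry relabelled in the subgroup
  sgHi <- parseSpaceGroup("P41212"); sgLo <- parseSpaceGroup("P41")
  cl <- UnitCell(42, 42, 55)
  cfg <- syntheticConfig(sg = sgHi, cell = cl, n_atoms = 40, d_min = 2.5,
                         noise_k = 0.03, seed = 74)
  atoms <- expandSymmetry(generateStructure(cfg), sgHi)
  uniq <- enumerateReflections(cl, sgLo, 2.5, includeAbsent = TRUE)
  sf <- calcStructureFactors(atoms, as.matrix(uniq[, c("h", "k", "l")]),
                             cl)
  nz <- addNoise(sf$I, 0.03, 99)
  relab <- reflectionSet(cl, sgLo,
                         data.frame(h = sf$h, k = sf$k, l = sf$l,
                                    I = nz$I, sigI = nz$sigI),
                         merged = TRUE)
  expect_gt(twinCorrelation(relab, law)$correlation, 0.95)
})

test_that("L statistics are insensitive to tNCS by the offset rule", {
  # near-half-cell tNCS: the classic case the all-even offsets are built
  # for (delta . t is then close to an integer, so both pair members share
  # nearly the same interference modulation)
  dsT <- fixture("tncsHalf", function()
    simulateDataset(syntheticConfig(sg = "P1", cell = UnitCell(36, 40, 44),
                                    n_atoms = 80, d_min = 2.4,
                                    noise_k = 0.05,
                                    tncs_vector = c(0.48, 0, 0),
                                    seed = 46)))
  lt <- lTest(dsT$set, seed = 9)
  expect_lt(abs(lt$mean_abs_L - 0.5), 0.02)
  # ... whereas odd-offset neighbour pairing is biased: the tNCS
  # interference modulates intensities with h parity, so pairs differing
  # by an odd h offset mix the strong and weak classes
  norm <- normalizeIntensities(dsT$set)
  ok <- !norm$centric & !norm$absent
  key <- refltriage:::hklKey(cbind(norm$h, norm$k, norm$l))
  mate <- refltriage:::hklKey(cbind(norm$h + 1L, norm$k, norm$l))
  pos <- match(mate, key)
  I1 <- norm$E2[ok & !is.na(pos)]
  I2 <- norm$E2[pos[ok & !is.na(pos)]]
  keep <- !is.na(I2) & (I1 + I2) > 0
  Lodd <- (I1[keep] - I2[keep]) / (I1[keep] + I2[keep])
  expect_gt(mean(abs(Lodd)), 0.53)   # visibly biased above 1/2
})
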