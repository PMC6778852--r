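test_that("Wilson fit recovers scale and B from noise-free data", {
  ds <- fixture("wilsonB20", function()
    simulateDataset(syntheticConfig(sg = "P21", n_atoms = 80, d_min = 2.0,
                                    noise_k = 0, b_iso = 20, seed = 23)))
  wf <- wilsonFit(ds$set)
  expect_lt(abs(wf$B_iso - 20) / 20, 0.10)
  # multiplying intensities by 10 scales K by 10, leaves B unchanged
  df <- ds$set@data; df$I <- df$I * 10
  wf10 <- wilsonFit(reflectionSet(ds$set@cell, ds$set@sg, df,
                                  merged = TRUE))
  expect_equal(wf10$K / wf$K, 10, tolerance = 1e-9)
  expect_equal(wf10$B_iso, wf$B_iso, tolerance = 1e-9)
  # B = 0 comes back near zero
  ds0 <- simulateDataset(syntheticConfig(sg = "P21", n_atoms = 50,
                                         d_min = 2.5, noise_k = 0,
                                         b_iso = 0, seed = 24))
  expect_lt(abs(wilsonFit(ds0$set)$B_iso), 1)
  # too few shells inside the fit range
  low <- reflectionSet(ds$set@cell, ds$set@sg,
                       ds$set@data[ds$set@data$d > 4.6, ], merged = TRUE)
  expect_error(suppressWarnings(wilsonFit(low)), "resolution too low")
})

test_that("normalization gives unit mean E^2 per shell by construction", {
  ds <- cleanP21()
  sch <- binResolution(ds$set)
  norm <- normalizeIntensities(ds$set, sch)
  work <- !norm$absent & !is.na(norm$E2)
  for (s in unique(norm$shell[work]))
    expect_equal(mean(norm$E2[work & norm$shell == s]), 1,
                 tolerance = 1e-10)
  # epsilon halves E^2 relative to the naive Z for an axial reflection
  ax <- which(norm$eps > 1 & work)[1]
  expect_equal(norm$E2[ax] * norm$eps[ax] *
                 mean(norm$I[work & norm$shell == norm$shell[ax]] /
                        norm$eps[work & norm$shell == norm$shell[ax]]),
               norm$I[ax], tolerance = 1e-9)
})

test_that("acentric moments match Monte-Carlo references for ideal data", {
  # the module's own MC reference against closed forms
  ref0 <- mcReferenceMoments(0, n = 500000, seed = 1)
  expect_equal(ref0$i2_over_i_sq, 2, tolerance = 0.02)
  expect_equal(ref0$mean_abs_e2m1, 2 / exp(1), tolerance = 0.01)
  ref5 <- mcReferenceMoments(0.5, n = 500000, seed = 1)
  expect_equal(ref5$i2_over_i_sq, 1.5, tolerance = 0.02)
  # simulated data against the references
  norm <- normalizeIntensities(bigP1()$set)
  mom <- momentStats(norm, mc_n = 100000)
  expect_equal(mom$acentric$i2_over_i_sq, mom$ref_untwinned$i2_over_i_sq,
               tolerance = 0.04)
  expect_equal(mom$acentric$mean_abs_e2m1,
               mom$ref_untwinned$mean_abs_e2m1, tolerance = 0.02)
  # constant intensities: second moment exactly 1
  df <- data.frame(h = 1:600, k = 1, l = 0, I = 7, sigI = 1)
  cset <- reflectionSet(UnitCell(2000, 30, 20), "P1", df, merged = TRUE)
  momc <- momentStats(normalizeIntensities(
    cset, binResolution(cset, n_shells = 1)), mc_n = 1000)
  expect_equal(momc$acentric$i2_over_i_sq, 1, tolerance = 1e-12)
})

test_that("N(Z) curves follow the ideal laws and count negatives low", {
  norm <- normalizeIntensities(bigP1()$set)
  nz <- nzCurves(norm)
  expect_equal(nz$ref_acentric, 1 - exp(-nz$z), tolerance = 1e-12)
  i1 <- which.min(abs(nz$z - 1))
  expect_equal(nz$N_acentric[i1], 1 - exp(-1), tolerance = 0.01)
  expect_lt(max(abs(nz$N_acentric - nz$ref_acentric)), 0.02)
  # noise-free positive data have N(0+) ~ 0
  expect_lt(nz$N_acentric[1], 0.05)
})

test_that("ice-ring scan flags a constructed spike only at ice spacings", {
  ds <- cleanP21()
  clean <- iceRingScan(ds$set)
  expect_false(clean$skipped)
  expect_identical(nrow(clean$ice), 0L)
  # multiply intensities by 5 in a 0.03 A wide band around d0
  spike <- function(set, d0, width = 0.015) {
    df <- set@data
    hit <- abs(df$d - d0) < width
    df$I[hit] <- df$I[hit] * 5
    reflectionSet(set@cell, set@sg, df, merged = TRUE)
  }
  withIce <- iceRingScan(spike(ds$set, 3.67))
  expect_gt(nrow(withIce$ice), 0)
  expect_true(any(abs(withIce$ice$d - 3.67) < 0.1))
  # a spike away from any ice ring lands in the generic anomaly list
  withOther <- iceRingScan(spike(ds$set, 3.10))
  expect_false(any(abs(withOther$ice$d - 3.10) < 0.1))
  expect_true(any(abs(withOther$anomalies$d - 3.10) < 0.1))
  # low-resolution-only data skip the scan
  lowres <- reflectionSet(ds$set@cell, ds$set@sg,
                          ds$set@data[ds$set@data$d > 4.2, ],
                          merged = TRUE)
  expect_true(iceRingScan(lowres)$skipped)
})

test_that("anisotropic fit recovers an injected B tensor and constraints", {
  dsa <- fixture("aniso", function()
    simulateDataset(syntheticConfig(sg = "P1", cell = UnitCell(40, 50, 60),
                                    n_atoms = 100, d_min = 2.0,
                                    noise_k = 0,
                                    b_tensor = diag(c(10, 10, 40)),
                                    seed = 31)))
  af <- anisoFit(dsa$set)
  expect_lt(abs(af$eigenvalues[1] - 40) / 40, 0.15)
  expect_lt(abs(af$eigenvalues[2] - 10) / 10, 0.15)
  expect_lt(abs(af$eigenvalues[3] - 10) / 10, 0.15)
  # isotropic control: small delta_B
  ds <- cleanP21()
  expect_lt(anisoFit(ds$set)$delta_B, 2 + 2)  # noise allowance
  # isotropic constraint reduces exactly to the Wilson B
  afi <- anisoFit(ds$set, constrain = "isotropic")
  expect_equal(afi$eigenvalues[1], wilsonFit(ds$set)$B_iso,
               tolerance = 1e-12)
  expect_identical(afi$delta_B, 0)
  # cubic family is isotropic by constraint
  dsc <- simulateDataset(syntheticConfig(sg = "P213", n_atoms = 30,
                                         d_min = 3.0, noise_k = 0.05,
                                         seed = 33))
  expect_identical(anisoFit(dsc$set)$delta_B, 0)
})

test_that("screw axes are detected in P21/P41 and absent in P2/P4", {
  verdictFor <- function(sym, seed) {
    ds <- simulateDataset(syntheticConfig(sg = sym, n_atoms = 50,
                                          d_min = 2.5, noise_k = 0.05,
                                          seed = seed))
    detectScrewAxes(ds$set)
  }
  s21 <- verdictFor("P21", 91)
  expect_identical(s21$verdict[s21$axis == "b"], "screw present")
  s2 <- verdictFor("P2", 92)
  expect_false(any(s2$verdict == "screw present"))
  s41 <- verdictFor("P41", 93)
  expect_true(all(s41$verdict[s41$axis == "c"] == "screw present"))
  s4 <- verdictFor("P4", 94)
  expect_false(any(s4$verdict == "screw present"))
  # no axial reflections: indeterminate
  ds <- simulateDataset(syntheticConfig(sg = "P21", n_atoms = 30,
                                        d_min = 3, noise_k = 0.05,
                                        seed = 95))
  df <- ds$set@data
  ax <- (df$h == 0 & df$l == 0)
  noax <- reflectionSet(ds$set@cell, ds$set@sg, df[!ax, ], merged = TRUE)
  sa <- detectScrewAxes(noax)
  expect_identical(sa$verdict[sa$axis == "b"], "indeterminate")
})

test_that("R factors match hand arithmetic and absorb uniform scale", {
  Fo <- c(10, 20, 30); Fm <- c(10, 20, 60)
  r <- rFactors(Fo, Fm)
  k_hand <- sum(Fo * Fm) / sum(Fm^2)
  r_hand <- sum(abs(Fo - k_hand * Fm)) / sum(Fo)
  expect_equal(r$k, k_hand, tolerance = 1e-15)
  expect_equal(r$r_work, r_hand, tolerance = 1e-15)
  for (c0 in c(0.5, 1, 2, 17)) {
    rr <- rFactors(Fo, c0 * Fo, free_flags = c(FALSE, FALSE, TRUE))
    expect_equal(rr$r_work, 0, tolerance = 1e-12)
    expect_equal(rr$r_free, 0, tolerance = 1e-12)
    expect_equal(rr$k, 1 / c0, tolerance = 1e-12)
  }
  # rescaling either input leaves R unchanged
  set.seed(8)
  Fo <- rexp(200) + 0.1; Fm <- Fo * (1 + rnorm(200, 0, 0.1))
  fl <- seq_along(Fo) %% 10 == 0
  r1 <- rFactors(Fo, Fm, fl)
  r2 <- rFactors(Fo * 3.7, Fm, fl)
  r3 <- rFactors(Fo, Fm / 5.1, fl)
  expect_equal(r1$r_work, r2$r_work, tolerance = 1e-12)
  expect_equal(r1$r_free, r3$r_free, tolerance = 1e-12)
  expect_true(is.na(rFactors(Fo, Fm, rep(FALSE, 200))$r_free))
})
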