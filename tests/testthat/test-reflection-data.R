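test_that("CSV and mmCIF round trips preserve indices and values", {
  ds <- cleanP21()
  dir <- withr::local_tempdir()
  for (fmt in c("csv", "mmcif")) {
    p <- file.path(dir, paste0("rt.", if (fmt == "csv") "csv" else "cif"))
    writeReflections(ds$set, p, fmt)
    back <- readReflections(p)
    expect_identical(back@data$h, ds$set@data$h)
    expect_identical(back@data$k, ds$set@data$k)
    expect_identical(back@data$l, ds$set@data$l)
    expect_equal(back@data$I, ds$set@data$I, tolerance = 1e-5)
    expect_equal(back@data$sigI, ds$set@data$sigI, tolerance = 1e-5)
    expect_true(back@merged)
    expect_equal(cellVolume(back@cell), cellVolume(ds$set@cell),
                 tolerance = 1e-5)
    expect_identical(back@sg@symbol, "P21")
  }
})

test_that("anomalous round trip preserves Bijvoet columns", {
  ds <- fixture("anom_small", function()
    simulateDataset(syntheticConfig(sg = "P21", n_atoms = 40, d_min = 3,
                                    noise_k = 0.05, fdp = c(S = 4),
                                    seed = 81)))
  dir <- withr::local_tempdir()
  for (fmt in c("csv", "mmcif")) {
    p <- file.path(dir, paste0("a.", fmt))
    writeReflections(ds$set, p, fmt)
    back <- readReflections(p, format = fmt)
    expect_true(back@anomalous)
    expect_equal(back@data$Iplus, ds$set@data$Iplus, tolerance = 1e-5)
    expect_equal(back@data$sigIminus, ds$set@data$sigIminus,
                 tolerance = 1e-5)
  }
})

test_that("degenerate records are rejected and counted; empty write errors", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.csv")
  writeLines(c("# cell 20 20 20 90 90 90", "# spacegroup P1",
               "h,k,l,I,sigI", "1,0,0,10,1", "0,0,0,5,1", "2,1,0,8,1"),
             p)
  expect_message(set <- readReflections(p), "rejected")
  expect_identical(nrow(set@data), 2L)
  expect_identical(attr(set, "rejected"), 1L)
  # missing symmetry
  p2 <- file.path(dir, "nosym.csv")
  writeLines(c("h,k,l,I,sigI", "1,0,0,10,1"), p2)
  expect_error(readReflections(p2), "symmetry required")
  expect_identical(
    readReflections(p2, cell = UnitCell(10, 10, 10), sg = "P1")@data$I, 10)
  # empty set refuses to write
  empty <- reflectionSet(UnitCell(10, 10, 10), "P1",
                         data.frame(h = integer(0), k = integer(0),
                                    l = integer(0), I = numeric(0),
                                    sigI = numeric(0)))
  expect_error(writeReflections(empty, file.path(dir, "e.csv")), "empty")
})

test_that("merging follows inverse-variance arithmetic and the R formulas", {
  # two identical observations: R_merge 0, sigma / sqrt(2)
  m0 <- mergeEquivalents(tinyUnmerged(data.frame(
    h = c(1, 1), k = c(2, 2), l = c(3, 3), I = c(50, 50),
    sigI = c(4, 4))))
  expect_equal(m0$stats$r_merge, 0)
  expect_equal(m0$set@data$I, 50)
  expect_equal(m0$set@data$sigI, 4 / sqrt(2))
  # hand arithmetic: 90 and 110 with equal sigma
  m1 <- mergeEquivalents(tinyUnmerged(data.frame(
    h = c(1, 1), k = c(2, 2), l = c(3, 3), I = c(90, 110),
    sigI = c(5, 5))))
  expect_equal(m1$set@data$I, 100)
  expect_equal(m1$stats$r_merge, 0.10)
  expect_equal(m1$stats$r_meas, 0.10 * sqrt(2))
  # symmetry mates in P21: (1,2,3) and (-1,2,-3) are one unique
  m2 <- mergeEquivalents(tinyUnmerged(data.frame(
    h = c(1, -1), k = c(2, 2), l = c(3, -3), I = c(50, 70),
    sigI = c(2, 2))))
  expect_identical(m2$stats$n_unique, 1L)
  expect_equal(m2$set@data$I, 60)
  # merged input refuses to merge again; permuted input merges identically
  expect_error(mergeEquivalents(m2$set), "already merged")
  m3 <- mergeEquivalents(tinyUnmerged(data.frame(
    h = c(-1, 1), k = c(2, 2), l = c(-3, 3), I = c(70, 50),
    sigI = c(2, 2))))
  expect_identical(m3$set@data, m2$set@data)
})

test_that("merging n identical observations divides sigma by sqrt(n)", {
  for (n in c(2, 5, 9)) {
    m <- mergeEquivalents(tinyUnmerged(data.frame(
      h = rep(2, n), k = rep(0, n), l = rep(1, n), I = rep(33, n),
      sigI = rep(3, n))))
    expect_equal(m$set@data$I, 33)
    expect_equal(m$set@data$sigI, 3 / sqrt(n))
    expect_equal(m$stats$multiplicity, n)
  }
})

test_that("resolution binning yields near-equal shells and coalesces", {
  ds <- cleanP21()
  sch <- binResolution(ds$set, n_shells = 15)
  counts <- tabulate(shellAssign(ds$set@data$d, sch), sch@n_shells)
  expect_true(all(counts >= 40))
  expect_identical(sum(counts), nrow(ds$set@data))
  expect_lt(diff(range(counts)) / mean(counts), 0.35)
  # n_shells = 1 covers the full range
  sch1 <- binResolution(ds$set, n_shells = 1)
  expect_identical(sch1@n_shells, 1L)
  expect_true(all(!is.na(shellAssign(ds$set@data$d, sch1))))
  # 30 reflections with n_shells = 20: coalesced down to one shell
  tiny <- reflectionSet(ds$set@cell, ds$set@sg,
                        ds$set@data[1:30, ], merged = TRUE)
  expect_identical(binResolution(tiny, n_shells = 20)@n_shells, 1L)
  # fewer reflections than shells: single shell with warning
  tinier <- reflectionSet(ds$set@cell, ds$set@sg,
                          ds$set@data[1:10, ], merged = TRUE)
  expect_warning(scht <- binResolution(tinier, n_shells = 20), "too few")
  expect_identical(scht@n_shells, 1L)
})

test_that("completeness counts observed over possible, absences excluded", {
  ds <- cleanP21()
  cm <- completeness(ds$set)
  expect_equal(cm$overall, 1, tolerance = 1e-12)
  expect_true(all(abs(cm$shells$completeness - 1) < 1e-12))
  # deleting every second reflection halves it, monotonically
  half <- reflectionSet(ds$set@cell, ds$set@sg,
                        ds$set@data[seq(1, nrow(ds$set@data), 2), ],
                        merged = TRUE)
  expect_equal(completeness(half)$overall, 0.5, tolerance = 0.01)
  quarter <- reflectionSet(ds$set@cell, ds$set@sg,
                           ds$set@data[seq(1, nrow(ds$set@data), 4), ],
                           merged = TRUE)
  expect_lt(completeness(quarter)$overall, completeness(half)$overall)
  expect_error(completeness(tinyUnmerged(data.frame(
    h = c(1, 1), k = c(2, 2), l = c(3, 3), I = c(1, 1),
    sigI = c(1, 1)))), "merged")
  # absent axial indices do not enter the denominator: a P21 set stripped
  # of its absent rows is still complete
  keep <- !isAbsent(cbind(ds$set@data$h, ds$set@data$k, ds$set@data$l),
                    ds$set@sg)
  noabs <- reflectionSet(ds$set@cell, ds$set@sg, ds$set@data[keep, ],
                         merged = TRUE)
  expect_equal(completeness(noabs)$overall, 1, tolerance = 1e-12)
})

test_that("I/sigma means are exact on constructed data and NA when empty", {
  df <- data.frame(h = 1:60, k = 1, l = 0, I = 10, sigI = 2)
  set <- reflectionSet(UnitCell(200, 30, 20), "P1", df, merged = TRUE)
  ios <- iOverSigma(set, binResolution(set, n_shells = 1))
  expect_equal(ios$overall, 5)
  expect_equal(ios$shells$i_over_sigma, 5)
  # a scheme covering range beyond the data leaves outer shells NA
  sch <- new("ShellScheme", n_shells = 2L,
             boundaries = c(300, dRange(set)["d_min"] - 1e-6, 1))
  ios2 <- iOverSigma(set, sch)
  expect_true(is.na(ios2$shells$i_over_sigma[2]))
  expect_equal(ios2$shells$i_over_sigma[1], 5)
})

test_that("free-set flags follow min(5% n, 2000) and reproduce by seed", {
  ds <- cleanP21()
  fl <- assignFreeSet(ds$set, seed = 10)
  expect_identical(sum(fl), as.integer(round(0.05 * nrow(ds$set@data))))
  expect_identical(fl, assignFreeSet(ds$set, seed = 10))
  expect_false(identical(fl, assignFreeSet(ds$set, seed = 11)))
})
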