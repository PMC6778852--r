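#' Twin law
#'
#' A candidate twin operator: an integer matrix acting on Miller indices
#' (row-vector convention, h' = h T) that maps the lattice onto itself but
#' is not a symmetry operator of the crystal. Merohedral laws come from the
#' lattice holohedry; pseudo-merohedral laws require a special cell metric
#' (e.g. monoclinic beta near 90 degrees) and are only proposed when the
#' metric test passes.
#'
#' @slot operator 3x3 integer matrix
#' @slot kind "merohedral", "pseudo-merohedral" or "user"
#' @slot description human-readable description of the operation
#' @export
setClass("TwinLaw",
  representation(operator = "matrix", kind = "character",
                 description = "character"),
  validity = function(object) {
    Tm <- object@operator
    if (!all(Tm == round(Tm))) return("operator must be integral")
    if (abs(round(det(Tm))) != 1L)
      return("operator must map the lattice to itself (det +/-1)")
    if (!object@kind %in% c("merohedral", "pseudo-merohedral", "user"))
      return("unknown twin-law kind")
    TRUE
  })

setMethod("show", "TwinLaw", function(object) {
  cat(sprintf("TwinLaw (%s): %s  [%s]\n", object@kind, object@description,
              paste(apply(object@operator, 1, paste, collapse = " "),
                    collapse = " / ")))
})

twinLaw <- function(operator, kind = "user", description = "") {
  storage.mode(operator) <- "integer"
  new("TwinLaw", operator = operator, kind = kind,
      description = description)
}

lawMatrix <- function(law) {
  m <- if (is(law, "TwinLaw")) law@operator else as.matrix(law)
  storage.mode(m) <- "integer"
  m
}

# A valid 2-fold twin law: T^2 must be (the rotation of) a group element
# and T itself must not be.
checkTwinLaw <- function(Tm, sg) {
  inGroup <- function(M) any(vapply(sg@rotations, function(R)
    all(R == M), logical(1)))
  if (inGroup(Tm))
    stop("twin operator is already a symmetry operator of the group")
  if (!inGroup(Tm %*% Tm))
    stop("twin operator squared is not a symmetry operator")
  invisible(TRUE)
}

#' Enumerate candidate twin laws
#'
#' Merohedral candidates come from a built-in table keyed by crystal
#' family and point group (the coset representatives of the lattice
#' holohedry over the crystal point group, for the supported groups).
#' Pseudo-merohedral candidates are proposed only when the cell metric
#' satisfies the necessary constraint within tolerance: monoclinic with
#' beta within `angle_tol` of 90 degrees (twofold along a), orthorhombic
#' with a and b equal within `length_tol` (pseudo-tetragonal swap).
#'
#' @param cell a [UnitCell-class]
#' @param sg a [SpaceGroup-class]
#' @param angle_tol pseudo-merohedral angle tolerance, degrees (0.5)
#' @param length_tol relative cell-length tolerance (0.005)
#' @return list of [TwinLaw-class] (possibly empty)
#' @export
candidateTwinLaws <- function(cell, sg, angle_tol = 0.5,
                              length_tol = 0.005) {
  laws <- list()
  rotKeys <- vapply(sg@rotations, function(R) paste(R, collapse = ","),
                    character(1))
  addIfNew <- function(Tm, kind, desc) {
    if (paste(Tm, collapse = ",") %in% rotKeys) return()
    for (lw in laws) if (all(lw@operator == Tm)) return()
    law <- twinLaw(Tm, kind, desc)
    ok <- tryCatch({ checkTwinLaw(Tm, sg); TRUE }, error = function(e)
      FALSE)
    if (ok) laws[[length(laws) + 1L]] <<- law
  }
  m2 <- function(...) {
    m <- matrix(c(...), 3, 3, byrow = TRUE)
    storage.mode(m) <- "integer"
    m
  }
  fam <- sg@family
  nrot <- length(unique(rotKeys))
  if (fam == "tetragonal" && nrot <= 4) {
    # point group 4 in holohedry 422: twofold along a (or equivalently 110)
    addIfNew(m2(1, 0, 0, 0, -1, 0, 0, 0, -1), "merohedral",
             "2-fold along a (h,-k,-l)")
  } else if (fam == "trigonal") {
    if (nrot <= 3) {
      addIfNew(m2(-1, 0, 0, 0, -1, 0, 0, 0, 1), "merohedral",
               "2-fold along c (-h,-k,l)")
      addIfNew(m2(0, 1, 0, 1, 0, 0, 0, 0, -1), "merohedral",
               "2-fold along a+b (k,h,-l)")
      addIfNew(m2(0, -1, 0, -1, 0, 0, 0, 0, 1), "merohedral",
               "2-fold along a-b (-k,-h,l)")
    } else {
      addIfNew(m2(-1, 0, 0, 0, -1, 0, 0, 0, 1), "merohedral",
               "2-fold along c (-h,-k,l)")
    }
  } else if (fam == "hexagonal" && nrot <= 6) {
    addIfNew(m2(0, 1, 0, 1, 0, 0, 0, 0, -1), "merohedral",
             "2-fold along a+b (k,h,-l)")
  } else if (fam == "cubic" && nrot <= 12) {
    # point group 23 in holohedry 432: twofold along the face diagonal
    addIfNew(m2(0, 1, 0, 1, 0, 0, 0, 0, -1), "merohedral",
             "2-fold along a+b (k,h,-l)")
  } else if (fam == "monoclinic") {
    if (abs(cell@beta - 90) < angle_tol)
      addIfNew(m2(1, 0, 0, 0, -1, 0, 0, 0, -1), "pseudo-merohedral",
               sprintf("2-fold along a (beta = %.2f deg)", cell@beta))
  } else if (fam == "orthorhombic") {
    if (abs(cell@a - cell@b) / max(cell@a, cell@b) < length_tol)
      addIfNew(m2(0, 1, 0, 1, 0, 0, 0, 0, -1), "pseudo-merohedral",
               sprintf("pseudo-tetragonal swap a<->b (|a-b|/a = %.3f%%)",
                       100 * abs(cell@a - cell@b) / cell@a))
  }
  laws
}

# Acentric, non-absent rows of a merged set; I is the epsilon-corrected
# normalized intensity E^2, which removes the resolution falloff so that
# statistics over pairs of nearby reflections are unbiased.
acentricData <- function(set) {
  norm <- normalizeIntensities(set)
  ok <- !norm$centric & !norm$absent & !is.na(norm$E2)
  list(hkl = cbind(norm$h, norm$k, norm$l)[ok, , drop = FALSE],
       I = norm$E2[ok], d = norm$d[ok], which = which(ok))
}

# Twin-related acentric pairs (each counted once): rows i, j of the merged
# set with canon(h_i T) = h_j, j != i, both acentric and measured.
twinPairs <- function(set, law) {
  Tm <- lawMatrix(law)
  hkl <- hklMatrix(set)
  idx <- twinPartnerIndex(set, Tm)
  cen <- isCentric(hkl, set@sg)
  abs_ <- isAbsent(hkl, set@sg)
  ok <- !is.na(idx) & idx != seq_len(nrow(hkl)) & !cen & !abs_ &
    !is.na(set@data$I)
  ok <- ok & !cen[ifelse(is.na(idx), 1L, idx)] &
    !is.na(set@data$I[ifelse(is.na(idx), 1L, idx)])
  i <- which(ok); j <- idx[ok]
  first <- i < j
  list(i = i[first], j = j[first])
}

#' L-test for twinning
#'
#' The local intensity-difference statistic L = (I1 - I2) / (I1 + I2)
#' computed over pairs of reflections close in reciprocal space. Each
#' acentric reflection h is paired with h + delta where delta is drawn
#' (seeded, per reflection) from the fixed all-even offset set
#' {(0,0,2),(0,2,0),(2,0,0),(0,2,2),(2,0,2),(2,2,0),(2,2,2)}; all-even
#' offsets keep the statistic insensitive to the parity-dependent intensity
#' modulation caused by translational NCS. Pairs where either member is
#' absent, centric or unmeasured, or where the two are symmetry-related,
#' are discarded. For untwinned acentric data <|L|> = 1/2 and <L^2> = 1/3;
#' for a perfect twin <|L|> = 3/8 and <L^2> = 1/5.
#'
#' @param set a merged [ReflectionSet-class]
#' @param seed RNG seed for the per-reflection offset choice
#' @param n_grid grid points of the cumulative N(|L|) table (50)
#' @return list: mean_abs_L, mean_L2, n_pairs, and `curve` data.frame with
#'   columns L, N (empirical), N_untwinned = L, N_perfect = L(3-L^2)/2
#' @export
lTest <- function(set, seed = 1, n_grid = 50) {
  ac <- acentricData(set)
  if (length(ac$I) < 2000)
    warning("fewer than 2000 acentric reflections; L-test is unreliable")
  offsets <- rbind(c(0, 0, 2), c(0, 2, 0), c(2, 0, 0), c(0, 2, 2),
                   c(2, 0, 2), c(2, 2, 0), c(2, 2, 2))
  pick <- withSeed(seed, sample.int(7L, length(ac$I), replace = TRUE))
  mate <- ac$hkl + offsets[pick, , drop = FALSE]
  # look mates up through their canonical equivalents
  mateCanon <- asuIndex(mate, set@sg, anomalous = set@anomalous)
  selfKey <- hklKey(asuIndex(ac$hkl, set@sg, anomalous = set@anomalous))
  pos <- match(hklKey(mateCanon), selfKey)
  ok <- !is.na(pos) & hklKey(mateCanon) != selfKey
  I1 <- ac$I[ok]; I2 <- ac$I[pos[ok]]
  # a ratio statistic needs measurably positive members; negative noise
  # observations would make L unbounded
  keep <- I1 > 0 & I2 > 0
  L <- (I1[keep] - I2[keep]) / (I1[keep] + I2[keep])
  if (length(L) < 200) stop("insufficient pairs for the L-test")
  grid <- seq(0, 1, length.out = n_grid)
  curve <- data.frame(L = grid,
                      N = vapply(grid, function(g) mean(abs(L) <= g),
                                 numeric(1)),
                      N_untwinned = grid,
                      N_perfect = grid * (3 - grid^2) / 2)
  list(mean_abs_L = mean(abs(L)), mean_L2 = mean(L^2),
       n_pairs = length(L), curve = curve)
}

#' H-test twin-fraction estimate
#'
#' For twin-related acentric pairs, H = |I(h) - I(Th)| / (I(h) + I(Th)).
#' Under the twin sum the true pair difference is scaled by (1 - 2 alpha)
#' while the sum is preserved, so H is uniform on [0, 1 - 2 alpha] and
#' alpha = 1/2 - <H>. A second estimate comes from the slope of the
#' cumulative distribution S(H) = H / (1 - 2 alpha) fitted through the
#' origin over its linear region (S <= 0.8).
#'
#' @param set a merged [ReflectionSet-class]
#' @param law a [TwinLaw-class] or 3x3 matrix
#' @return list: alpha_mean, alpha_slope, n_pairs, n_negative_excluded
#' @export
hTest <- function(set, law) {
  pr <- twinPairs(set, law)
  I1 <- set@data$I[pr$i]; I2 <- set@data$I[pr$j]
  pos <- (I1 + I2) > 0
  nneg <- sum(!pos)
  I1 <- I1[pos]; I2 <- I2[pos]
  if (length(I1) < 500) stop("insufficient twin-related pairs for H-test")
  H <- abs(I1 - I2) / (I1 + I2)
  alpha_mean <- min(max(0.5 - mean(H), 0), 0.5)
  Hs <- sort(H)
  S <- seq_along(Hs) / length(Hs)
  lin <- S <= 0.8
  m <- sum(Hs[lin] * S[lin]) / sum(Hs[lin]^2)
  alpha_slope <- min(max((1 - 1 / m) / 2, 0), 0.5)
  list(alpha_mean = alpha_mean, alpha_slope = alpha_slope,
       n_pairs = length(H), n_negative_excluded = nneg)
}

#' Britton-plot twin-fraction estimate
#'
#' Detwins the data at each trial alpha on a grid and counts negative
#' detwinned intensities. Below the true twin fraction (noise-free) no
#' negatives occur; above it they rise steeply, so the alpha-axis
#' intercept of a line fitted to the rising region (counts between 10%
#' and 60% of the maximum) estimates alpha.
#'
#' @inheritParams hTest
#' @param grid_step trial-alpha spacing (0.01)
#' @return list: alpha_grid, n_negative, alpha_estimate, flag (character;
#'   "ok" or "no rising region")
#' @export
britton <- function(set, law, grid_step = 0.01) {
  pr <- twinPairs(set, law)
  if (length(pr$i) < 500)
    stop("insufficient twin-related pairs for Britton plot")
  I1 <- set@data$I[pr$i]; I2 <- set@data$I[pr$j]
  grid <- seq(0, 0.49, by = grid_step)
  nneg <- vapply(grid, function(a) {
    d1 <- ((1 - a) * I1 - a * I2) / (1 - 2 * a)
    d2 <- ((1 - a) * I2 - a * I1) / (1 - 2 * a)
    sum(d1 < 0) + sum(d2 < 0)
  }, numeric(1))
  mx <- max(nneg)
  rising <- which(nneg >= 0.10 * mx & nneg <= 0.60 * mx & nneg > 0)
  if (mx == 0 || length(rising) < 2) {
    return(list(alpha_grid = grid, n_negative = nneg, alpha_estimate = 0,
                flag = "no rising region"))
  }
  fit <- lm(nneg[rising] ~ grid[rising])
  est <- -coef(fit)[[1]] / coef(fit)[[2]]
  list(alpha_grid = grid, n_negative = nneg,
       alpha_estimate = min(max(est, 0), 0.4999), flag = "ok")
}

#' Detwin intensities at a known twin fraction
#'
#' Exact algebraic inverse of the twin sum for a pair (I1, I2):
#' I1' = ((1-alpha) I1 - alpha I2) / (1 - 2 alpha) and symmetrically for
#' I2'. Sigmas are propagated through the same linear combination in
#' quadrature. Reflections without a twin mate in the set are left
#' unchanged and counted (attribute `"unpaired"`).
#'
#' @inheritParams hTest
#' @param alpha twin fraction, 0 <= alpha < 0.5
#' @return a [ReflectionSet-class] with detwinned I (and sigI)
#' @export
detwin <- function(set, law, alpha) {
  if (alpha >= 0.5) stop("detwinning singular at alpha >= 0.5")
  stopifnot(alpha >= 0)
  Tm <- lawMatrix(law)
  idx <- twinPartnerIndex(set, Tm)
  df <- set@data
  ok <- !is.na(idx) & idx != seq_len(nrow(df))
  i2 <- idx[ok]
  I1 <- df$I[ok]; I2 <- df$I[i2]
  df$I[ok] <- ((1 - alpha) * I1 - alpha * I2) / (1 - 2 * alpha)
  if (!all(is.na(df$sigI))) {
    s1 <- set@data$sigI[ok]; s2 <- set@data$sigI[i2]
    df$sigI[ok] <- sqrt(((1 - alpha) * s1)^2 + (alpha * s2)^2) /
      (1 - 2 * alpha)
  }
  out <- reflectionSet(set@cell, set@sg, df, merged = set@merged,
                       anomalous = set@anomalous)
  attr(out, "unpaired") <- sum(!ok & !is.na(df$I))
  out
}

#' Correlation of twin-related intensities
#'
#' Pearson correlation of (I(h), I(Th)) over twin-related pairs. Near 1 it
#' indicates either near-perfect twinning or that the true symmetry is
#' higher than assumed; combined with a low merging R under the augmented
#' symmetry the latter interpretation wins (see [runTriage()]).
#'
#' @inheritParams hTest
#' @return list: correlation, n_pairs
#' @export
twinCorrelation <- function(set, law) {
  pr <- twinPairs(set, law)
  if (length(pr$i) < 10) stop("insufficient twin-related pairs")
  # correlate normalized intensities so the shared resolution falloff does
  # not masquerade as twin-related correlation
  norm <- normalizeIntensities(set)
  list(correlation = cor(norm$E2[pr$i], norm$E2[pr$j]),
       n_pairs = length(pr$i))
}
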