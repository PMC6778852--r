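# Default protein-like cell contents for Wilson-level statistics when no
# composition is given: average protein stoichiometry at ~1 atom / 12 A^3,
# 50% solvent ignored (only the shape of sum f^2 matters for B; the scale
# is absorbed in K).
defaultComposition <- function(cell) {
  n <- cellVolume(cell) / 12
  c(C = 0.55, N = 0.16, O = 0.24, S = 0.05) * n
}

#' Wilson fit of overall scale and B factor
#'
#' Straight-line fit of ln(<I/epsilon>_shell / sum_j f_j^2(s)) against
#' s^2 = 1/(4 d^2) over shells with d below `fit_d_max` (default 4.5 A,
#' the start of the roughly linear Wilson regime). The slope is -2B and
#' the intercept ln K. Systematically absent reflections are excluded from
#' the shell means.
#'
#' @param set a merged [ReflectionSet-class]
#' @param composition named atom counts by element; a protein-like default
#'   scaled to the cell volume is used when NULL
#' @param fit_d_max only shells with mean d below this (A) enter the fit
#' @param scheme a [ShellScheme-class]
#' @return list: K, B_iso (A^2), fit_d_max, residual (RMS of the linear
#'   fit), n_shells_fit
#' @export
wilsonFit <- function(set, composition = NULL, fit_d_max = 4.5,
                      scheme = binResolution(set)) {
  if (is.null(composition)) composition <- defaultComposition(set@cell)
  df <- set@data
  keep <- !isAbsent(hklMatrix(set), set@sg) & !is.na(df$I)
  eps <- epsilonFactor(hklMatrix(set)[keep, , drop = FALSE], set@sg)
  sh <- shellAssign(df$d[keep], scheme)
  Ieps <- df$I[keep] / eps
  ok <- !is.na(sh)
  mI <- tapply(Ieps[ok], sh[ok], mean)
  ms2 <- tapply(1 / (4 * df$d[keep][ok]^2), sh[ok], mean)
  md <- tapply(df$d[keep][ok], sh[ok], mean)
  use <- md < fit_d_max & mI > 0
  if (sum(use) < 3) stop("resolution too low for Wilson fit")
  y <- log(mI[use] / sumFsq(composition, ms2[use]))
  fit <- lm(y ~ ms2[use])
  list(K = exp(coef(fit)[[1]]), B_iso = -coef(fit)[[2]] / 2,
       fit_d_max = fit_d_max,
       residual = sqrt(mean(fit$residuals^2)),
       n_shells_fit = sum(use))
}

#' Normalize intensities to E^2 and Z
#'
#' E^2(h) = I(h) / (epsilon(h) <I/epsilon>_shell) and Z(h) =
#' I(h) / <I>_shell, with shell means taken over non-absent measured
#' reflections. By construction <E^2> = 1 within every shell (centric and
#' acentric combined). The centric/acentric flag and epsilon accompany
#' each reflection.
#'
#' @param set a merged [ReflectionSet-class]
#' @param scheme a [ShellScheme-class]
#' @return data.frame: h, k, l, d, I, sigI, eps, centric, absent, shell,
#'   E2, Z; the scheme is attached as attribute `"scheme"`
#' @export
normalizeIntensities <- function(set, scheme = binResolution(set)) {
  df <- set@data
  hkl <- hklMatrix(set)
  eps <- epsilonFactor(hkl, set@sg)
  cen <- isCentric(hkl, set@sg)
  abs_ <- isAbsent(hkl, set@sg)
  sh <- shellAssign(df$d, scheme)
  work <- !abs_ & !is.na(df$I) & !is.na(sh)
  mIeps <- rep(NA_real_, scheme@n_shells)
  mI <- rep(NA_real_, scheme@n_shells)
  t1 <- tapply(df$I[work] / eps[work], sh[work], mean)
  t2 <- tapply(df$I[work], sh[work], mean)
  mIeps[as.integer(names(t1))] <- t1
  mI[as.integer(names(t2))] <- t2
  out <- data.frame(h = df$h, k = df$k, l = df$l, d = df$d, I = df$I,
                    sigI = df$sigI, eps = eps, centric = cen,
                    absent = abs_, shell = sh,
                    E2 = df$I / (eps * mIeps[sh]), Z = df$I / mI[sh])
  attr(out, "scheme") <- scheme
  out
}

#' Monte-Carlo reference moments for (possibly twinned) acentric data
#'
#' Samples ideal acentric intensities (unit exponential), applies the twin
#' sum with an independent mate at the given twin fraction, and returns
#' the same moments [momentStats()] reports. Serves as the reference the
#' observed moments are compared with, avoiding hard-coded constants.
#'
#' @param alpha twin fraction (0 = untwinned, 0.5 = perfect twin)
#' @param n sample size
#' @param seed RNG seed
#' @return list: i2_over_i_sq, mean_abs_e2m1, f_sq_ratio
#' @export
mcReferenceMoments <- function(alpha = 0, n = 200000, seed = 42) {
  withSeed(seed, {
    I1 <- rexp(n); I2 <- rexp(n)
    I <- (1 - alpha) * I1 + alpha * I2
    E2 <- I / mean(I)
    F <- sqrt(E2)
    list(i2_over_i_sq = mean(I^2) / mean(I)^2,
         mean_abs_e2m1 = mean(abs(E2 - 1)),
         f_sq_ratio = mean(F)^2 / mean(F^2))
  })
}

#' Intensity-moment twinning screen
#'
#' Second-moment and related statistics of the normalized intensities,
#' reported separately for acentric and centric reflections next to
#' Monte-Carlo reference values for untwinned and perfectly twinned
#' acentric data. For ideal acentric data <I^2>/<I>^2 = 2 (untwinned) and
#' 1.5 (perfect twin); twinning pushes every moment toward the twinned
#' reference.
#'
#' @param norm a [normalizeIntensities()] table
#' @param mc_n Monte-Carlo sample size for the references
#' @param seed seed for the reference sampler
#' @return list of class `"MomentReport"`: acentric / centric moment
#'   lists, references, n_acentric, n_centric, warning flag
#' @export
momentStats <- function(norm, mc_n = 200000, seed = 42) {
  momentsOf <- function(E2) {
    E2 <- E2[!is.na(E2)]
    if (!length(E2)) return(list(i2_over_i_sq = NA_real_,
                                 mean_abs_e2m1 = NA_real_,
                                 f_sq_ratio = NA_real_))
    F <- sqrt(pmax(E2, 0))
    list(i2_over_i_sq = mean(E2^2) / mean(E2)^2,
         mean_abs_e2m1 = mean(abs(E2 - 1)),
         f_sq_ratio = mean(F)^2 / mean(F^2))
  }
  ac <- norm$E2[!norm$centric & !norm$absent]
  ce <- norm$E2[norm$centric & !norm$absent]
  structure(list(acentric = momentsOf(ac), centric = momentsOf(ce),
                 ref_untwinned = mcReferenceMoments(0, mc_n, seed),
                 ref_perfect_twin = mcReferenceMoments(0.5, mc_n, seed),
                 n_acentric = sum(!is.na(ac)), n_centric = sum(!is.na(ce)),
                 low_count = sum(!is.na(ac)) < 500),
            class = "MomentReport")
}

#' Cumulative intensity distributions N(Z)
#'
#' Empirical cumulative fraction of reflections with Z = I/<I> below each
#' grid value, for the acentric and centric subsets, next to the ideal
#' references 1 - exp(-Z) (acentric) and erf(sqrt(Z/2)) (centric).
#' Twinned data show a sigmoidal departure below the acentric reference at
#' small Z. Negative observed Z counts below every positive grid point.
#'
#' @param norm a [normalizeIntensities()] table
#' @param n_points grid size (50), spanning Z in (0, 1]
#' @return data.frame: z, N_acentric, N_centric, ref_acentric, ref_centric
#' @export
nzCurves <- function(norm, n_points = 50) {
  z <- seq(0, 1, length.out = n_points + 1)[-1]
  Za <- norm$Z[!norm$centric & !norm$absent & !is.na(norm$Z)]
  Zc <- norm$Z[norm$centric & !norm$absent & !is.na(norm$Z)]
  cum <- function(Z, g) if (length(Z)) mean(Z <= g) else NA_real_
  data.frame(z = z,
             N_acentric = vapply(z, function(g) cum(Za, g), numeric(1)),
             N_centric = vapply(z, function(g) cum(Zc, g), numeric(1)),
             ref_acentric = 1 - exp(-z),
             ref_centric = 2 * pnorm(sqrt(z)) - 1)
}

# Hexagonal-ice powder-ring d-spacings >= 1.9 A.
.iceRings <- c(3.90, 3.67, 3.44, 2.67, 2.25, 2.07, 1.95, 1.92)

#' Scan for ice rings and mean-intensity anomalies
#'
#' Mean intensity in thin resolution shells (width 0.002 in 1/d^2 units,
#' narrow enough to separate the closely spaced ice rings near 3.7 A) is
#' compared on the log scale against a local baseline fitted through its
#' 10 neighboring shells; a robust z-score of the residual above `z_cut`
#' flags the shell. The local linear fit removes the Wilson falloff
#' without absorbing a one-shell spike (a shell-normalized statistic
#' would dilute the very ring it is looking for). Flagged shells whose d
#' range intersects the built-in hexagonal-ice ring list are reported as
#' ice rings, the rest as generic mean-intensity anomalies. Skipped (with
#' a notice) when the data do not extend beyond 4 A.
#'
#' @param set a merged [ReflectionSet-class]
#' @param z_cut robust z-score threshold (default 5)
#' @param width thin-shell width in 1/d^2 units (default 0.002)
#' @return list: `skipped` (logical), `ice` and `anomalies` data.frames
#'   (d, z_score, n), `table` of all scanned shells
#' @export
iceRingScan <- function(set, z_cut = 5, width = 0.002) {
  if (dRange(set)["d_min"] > 4)
    return(list(skipped = TRUE,
                notice = "resolution does not extend beyond 4 A",
                ice = data.frame(), anomalies = data.frame()))
  df <- set@data
  ok <- !isAbsent(hklMatrix(set), set@sg) & !is.na(df$I)
  invd2 <- 1 / df$d[ok]^2
  I <- df$I[ok]
  edges <- seq(min(invd2), max(invd2) + width, by = width)
  bin <- findInterval(invd2, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  mz <- rep(NA_real_, nb); cnt <- integer(nb); sdI <- rep(NA_real_, nb)
  t1 <- tapply(I, bin, mean); t2 <- tapply(I, bin, length)
  t3 <- tapply(I, bin, sd)
  mz[as.integer(names(t1))] <- t1
  cnt[as.integer(names(t2))] <- t2
  sdI[as.integer(names(t3))] <- t3
  lnI <- ifelse(mz > 0, log(mz), NA_real_)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  dmid <- 1 / sqrt(mid)
  resid <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    if (is.na(lnI[i]) || cnt[i] < 5) next
    nbr <- setdiff(max(1, i - 5):min(nb, i + 5), i)
    nbr <- nbr[!is.na(lnI[nbr]) & cnt[nbr] >= 5]
    if (length(nbr) < 5) next
    fit <- lm(lnI[nbr] ~ mid[nbr])
    resid[i] <- lnI[i] - (coef(fit)[[1]] + coef(fit)[[2]] * mid[i])
  }
  # per-shell noise of ln(mean I): the standard error of the shell mean on
  # the log scale (sd/mean/sqrt(n)); near-ideal acentric shells have
  # sd ~ mean, so this is about 1/sqrt(n)
  sigma <- pmax(sdI / mz / sqrt(cnt), 0.02)
  zscore <- resid / sigma
  hits <- which(!is.na(zscore) & zscore > z_cut)
  isIce <- vapply(hits, function(i) {
    lo <- 1 / sqrt(edges[i + 1]); hi <- 1 / sqrt(edges[i])
    any(.iceRings >= lo - 0.02 & .iceRings <= hi + 0.02)
  }, logical(1))
  tab <- data.frame(d = dmid, mean_I = mz, n = cnt, z_score = zscore)
  list(skipped = FALSE,
       ice = data.frame(d = dmid[hits[isIce]],
                        z_score = zscore[hits[isIce]],
                        n = cnt[hits[isIce]]),
       anomalies = data.frame(d = dmid[hits[!isIce]],
                              z_score = zscore[hits[!isIce]],
                              n = cnt[hits[!isIce]]),
       table = tab)
}
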