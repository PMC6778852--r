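#' Resolution shell scheme
#'
#' Partition of a resolution range into shells of equal reciprocal volume
#' (equal increments of 1/d^3). `boundaries` is a strictly decreasing
#' vector of d values of length `n_shells + 1`, from d_max down to d_min.
#'
#' @slot n_shells integer
#' @slot boundaries numeric, decreasing d values in Angstrom
#' @export
setClass("ShellScheme",
  representation(n_shells = "integer", boundaries = "numeric"),
  validity = function(object) {
    b <- object@boundaries
    if (length(b) != object@n_shells + 1L)
      return("boundaries must have n_shells + 1 entries")
    if (any(diff(b) >= 0)) return("boundaries must be strictly decreasing")
    TRUE
  })

setMethod("show", "ShellScheme", function(object) {
  cat(sprintf("ShellScheme: %d shells, %.2f - %.2f A\n", object@n_shells,
              object@boundaries[1], object@boundaries[length(
                object@boundaries)]))
})

#' Assign reflections to resolution shells
#' @param d d-spacings in Angstrom
#' @param scheme a [ShellScheme-class]
#' @return integer shell index (1 = lowest resolution); NA outside range
#' @export
shellAssign <- function(d, scheme) {
  b <- scheme@boundaries
  idx <- findInterval(1 / d^3, 1 / b^3, rightmost.closed = TRUE)
  idx[idx < 1L | idx > scheme@n_shells] <- NA_integer_
  idx
}

#' Bin a reflection set into resolution shells
#'
#' Shells of equal reciprocal volume between the set's d limits. Shells
#' holding fewer than `min_per_shell` reflections are coalesced with a
#' neighbor; the returned scheme reports the final shell count. With fewer
#' reflections than `n_shells` a single shell is returned with a warning.
#'
#' @param set a [ReflectionSet-class]
#' @param n_shells requested number of shells (default 20)
#' @param min_per_shell minimum population per shell (default 40)
#' @return a [ShellScheme-class]
#' @export
binResolution <- function(set, n_shells = 20, min_per_shell = 40) {
  d <- set@data$d
  if (length(d) < n_shells || length(d) < 2L) {
    if (length(d) < n_shells)
      warning("too few reflections for ", n_shells, " shells; using 1")
    n_shells <- 1
  }
  lo <- min(1 / d^3) * (1 - 1e-9); hi <- max(1 / d^3) * (1 + 1e-9)
  s3 <- seq(lo, hi, length.out = n_shells + 1)
  counts <- tabulate(findInterval(1 / d^3, s3, rightmost.closed = TRUE),
                     nbins = n_shells)
  # coalesce under-populated shells with the smaller neighbor
  while (length(counts) > 1L && any(counts < min_per_shell)) {
    i <- which.min(counts)
    j <- if (i == 1L) 2L
         else if (i == length(counts)) i - 1L
         else if (counts[i - 1L] <= counts[i + 1L]) i - 1L else i + 1L
    k <- min(i, j)
    counts[k] <- counts[i] + counts[j]
    counts <- counts[-max(i, j)]
    s3 <- s3[-(max(i, j))]
  }
  new("ShellScheme", n_shells = length(counts),
      boundaries = 1 / s3^(1 / 3))
}

#' Merge symmetry-equivalent observations
#'
#' Groups observations under their canonical asymmetric-unit index
#' (Friedel mates collapsed unless the set is anomalous), replaces each
#' group by the inverse-variance weighted mean intensity with
#' sigma = 1/sqrt(sum 1/sigma_i^2), and reports merging statistics:
#' R_merge = sum_h sum_i |I_i - <I>_h| / sum_h sum_i I_i and R_meas, its
#' multiplicity-corrected form with per-group factor sqrt(n/(n-1)), both
#' over multiply-observed reflections only. High R values under a given
#' symmetry, contrasted with low values under an augmented symmetry, are
#' the classic sign of under- or over-assigned symmetry.
#'
#' @param set an unmerged [ReflectionSet-class] with positive sigmas
#' @return list with `set` (merged [ReflectionSet-class]) and `stats`
#'   (list: r_merge, r_meas, multiplicity, n_unique, n_obs)
#' @export
mergeEquivalents <- function(set) {
  if (set@merged) stop("already merged")
  df <- set@data
  if (any(is.na(df$I)) || any(df$sigI <= 0, na.rm = TRUE) ||
      any(is.na(df$sigI)))
    stop("merging requires intensities with positive sigmas")
  canon <- asuIndex(hklMatrix(set), set@sg, anomalous = set@anomalous)
  key <- hklKey(canon)
  ord <- order(key)
  key <- key[ord]; canon <- canon[ord, , drop = FALSE]
  I <- df$I[ord]; sig <- df$sigI[ord]
  grp <- cumsum(!duplicated(key))
  w <- 1 / sig^2
  sw <- rowsum(w, grp); swI <- rowsum(w * I, grp)
  Im <- as.numeric(swI / sw)
  sigm <- as.numeric(1 / sqrt(sw))
  nobs <- as.numeric(rowsum(rep(1, length(grp)), grp))
  first <- !duplicated(grp)
  # merging statistics over multiply-observed groups
  dev <- abs(I - Im[grp])
  multi <- nobs[grp] > 1
  sumdev <- rowsum(dev[multi], grp[multi])
  sumI <- rowsum(I[multi], grp[multi])
  nmulti <- nobs[nobs > 1]
  denom <- sum(sumI)
  r_merge <- if (length(nmulti) && denom > 0) sum(sumdev) / denom else 0
  r_meas <- if (length(nmulti) && denom > 0)
    sum(sqrt(nmulti / (nmulti - 1)) * as.numeric(sumdev)) / denom else 0
  out <- data.frame(h = canon[first, 1], k = canon[first, 2],
                    l = canon[first, 3], I = Im, sigI = sigm)
  merged <- reflectionSet(set@cell, set@sg, out, merged = TRUE,
                          anomalous = set@anomalous)
  list(set = merged,
       stats = list(r_merge = r_merge, r_meas = r_meas,
                    multiplicity = length(grp) / length(nobs),
                    n_unique = length(nobs), n_obs = length(grp)))
}

#' Enumerate the theoretically possible unique reflections
#'
#' Full reciprocal sphere to `d_min`, collapsed to canonical
#' asymmetric-unit indices (Friedel mates collapsed unless `anomalous`),
#' systematic absences excluded unless `includeAbsent`. Since
#' |h_i| <= a_i / d_min inside the resolution sphere, a box enumeration
#' suffices.
#'
#' @param cell a [UnitCell-class]
#' @param sg a [SpaceGroup-class]
#' @param d_min resolution limit in Angstrom
#' @param anomalous keep Friedel mates distinct?
#' @param includeAbsent keep systematically absent indices?
#' @return data.frame: h, k, l, d
#' @export
enumerateReflections <- function(cell, sg, d_min, anomalous = FALSE,
                                 includeAbsent = FALSE) {
  lens <- c(cell@a, cell@b, cell@c)
  lim <- as.integer(ceiling(lens / d_min)) + 1L
  grid <- expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2],
                      l = -lim[3]:lim[3])
  hkl <- as.matrix(grid)
  storage.mode(hkl) <- "integer"
  keep <- rowSums(hkl != 0L) > 0L
  hkl <- hkl[keep, , drop = FALSE]
  d <- dSpacing(hkl, cell)
  hkl <- hkl[d >= d_min, , drop = FALSE]
  d <- d[d >= d_min]
  if (!includeAbsent) {
    keep <- !isAbsent(hkl, sg)
    hkl <- hkl[keep, , drop = FALSE]; d <- d[keep]
  }
  canon <- asuIndex(hkl, sg, anomalous = anomalous)
  key <- hklKey(canon)
  first <- !duplicated(key)
  data.frame(h = canon[first, 1], k = canon[first, 2], l = canon[first, 3],
             d = d[first])
}

#' Data completeness per resolution shell
#'
#' Fraction of theoretically possible unique reflections actually present:
#' the reciprocal sphere is enumerated to the set's d_min, systematic
#' absences are excluded from the denominator, and Friedel mates are
#' collapsed unless the set is anomalous.
#'
#' @param set a merged [ReflectionSet-class]
#' @param scheme a [ShellScheme-class] (default: [binResolution()] of `set`)
#' @return list with `overall` fraction and `shells` data.frame
#'   (d_max, d_min, n_obs, n_possible, completeness)
#' @export
completeness <- function(set, scheme = binResolution(set)) {
  if (!set@merged) stop("completeness requires a merged set")
  dr <- dRange(set)
  poss <- enumerateReflections(set@cell, set@sg, dr["d_min"],
                          anomalous = set@anomalous)
  shellP <- shellAssign(poss$d, scheme)
  obs <- set@data
  keepO <- !isAbsent(hklMatrix(set), set@sg)
  shellO <- shellAssign(obs$d[keepO], scheme)
  ns <- scheme@n_shells
  nP <- tabulate(shellP, nbins = ns)
  nO <- tabulate(shellO, nbins = ns)
  b <- scheme@boundaries
  shells <- data.frame(d_max = b[-length(b)], d_min = b[-1],
                       n_obs = nO, n_possible = nP,
                       completeness = ifelse(nP > 0, nO / nP, NA_real_))
  list(overall = sum(nO) / max(sum(nP), 1L), shells = shells)
}

#' Mean signal-to-noise per resolution shell
#'
#' Arithmetic mean of I/sigma(I) per shell and overall. Shells without
#' reflections are reported as NA, never 0.
#'
#' @inheritParams completeness
#' @return list with `overall` and `shells` data.frame
#'   (d_max, d_min, n, i_over_sigma)
#' @export
iOverSigma <- function(set, scheme = binResolution(set)) {
  df <- set@data
  ok <- !is.na(df$I) & !is.na(df$sigI) & df$sigI > 0
  ios <- df$I[ok] / df$sigI[ok]
  sh <- shellAssign(df$d[ok], scheme)
  ios <- ios[!is.na(sh)]; sh <- sh[!is.na(sh)]
  ns <- scheme@n_shells
  n <- tabulate(sh, nbins = ns)
  s <- rep(NA_real_, ns)
  agg <- rowsum(ios, sh)
  s[as.integer(rownames(agg))] <- as.numeric(agg)
  b <- scheme@boundaries
  list(overall = mean(ios),
       shells = data.frame(d_max = b[-length(b)], d_min = b[-1], n = n,
                           i_over_sigma = ifelse(n > 0, s / n, NA_real_)))
}

#' Assign a cross-validation (free) reflection set
#'
#' Marks a uniformly random subset of reflections as "free" for R_free
#' cross-validation. The free count is min(round(fraction * n), max_count);
#' the cap reflects the convention that a few thousand reflections suffice
#' for cross-validation regardless of dataset size. Reproducible for a
#' given seed.
#'
#' @param set a merged [ReflectionSet-class]
#' @param fraction target free fraction (default 0.05)
#' @param max_count cap on the free-set size (default 2000)
#' @param seed RNG seed (required)
#' @return logical vector, TRUE = free, in the row order of the set
#' @export
assignFreeSet <- function(set, fraction = 0.05, max_count = 2000, seed) {
  if (!set@merged) stop("free-set assignment requires a merged set")
  n <- nrow(set@data)
  if (n < 100) warning("fewer than 100 reflections; free set of limited use")
  n_free <- min(round(fraction * n), max_count)
  flags <- rep(FALSE, n)
  flags[withSeed(seed, sample.int(n, n_free))] <- TRUE
  flags
}
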