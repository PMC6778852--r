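#' Patterson map grid
#'
#' Origin-normalized native Patterson map: the inverse Fourier transform
#' of the measured intensities, sampled on a real-space grid over one unit
#' cell. P(0) is scaled to 100, so peak heights read directly as percent
#' of origin. The map is centrosymmetric (P(u) = P(-u)) by Friedel
#' completion.
#'
#' @slot dims integer grid dimensions along a, b, c
#' @slot values 3D numeric array of map values
#' @slot cell the [UnitCell-class] the map belongs to
#' @export
setClass("PattersonGrid",
  representation(dims = "integer", values = "array", cell = "UnitCell"),
  validity = function(object) {
    if (!all(dim(object@values) == object@dims))
      return("values array does not match dims")
    TRUE
  })

setMethod("show", "PattersonGrid", function(object) {
  cat(sprintf("PattersonGrid %d x %d x %d, origin = %.1f\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@values[1, 1, 1]))
})

# Smallest 2,3,5-smooth integer >= n (FFT-friendly grid dimension).
smoothDim <- function(n) {
  k <- as.integer(n)
  repeat {
    m <- k
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(k)
    k <- k + 1L
  }
}

#' Native Patterson map from intensities
#'
#' FFT synthesis P(u) = sum_h I(h) exp(2 pi i h.u) over the full sphere:
#' the merged intensities are expanded with all symmetry equivalents and
#' Friedel mates (I(-h) = I(h)), so the map is real and centrosymmetric.
#' Interatomic difference vectors appear as peaks; a translational-NCS
#' relationship between molecular copies produces a large off-origin peak
#' at the translation vector. Grid spacing is at most d_min/grid_factor
#' along each axis (dimensions rounded up to FFT-friendly sizes).
#'
#' Coefficients are the raw merged intensities (the classic native
#' Patterson); `origin_removal` subtracts the shell mean from each
#' intensity first, sharpening off-origin features.
#'
#' @param set a merged [ReflectionSet-class]
#' @param grid_factor minimum samples per d_min (default 3)
#' @param origin_removal subtract shell-mean intensities (default FALSE)
#' @return a [PattersonGrid-class], origin scaled to 100
#' @export
nativePatterson <- function(set, grid_factor = 3, origin_removal = FALSE) {
  df <- set@data
  if (nrow(df) == 0L) stop("empty reflection set")
  Ival <- df$I
  if (origin_removal) {
    norm <- normalizeIntensities(set)
    Ival <- Ival - Ival / ifelse(is.na(norm$Z) | norm$Z == 0, NA, norm$Z)
    Ival[is.na(Ival)] <- 0
  }
  ok <- !is.na(Ival)
  hkl <- hklMatrix(set)[ok, , drop = FALSE]
  Ival <- Ival[ok]
  d_min <- min(df$d)
  dims <- vapply(c(set@cell@a, set@cell@b, set@cell@c), function(len)
    smoothDim(ceiling(grid_factor * len / d_min)), integer(1))
  # expand to the full sphere: all rotations and Friedel mates
  allH <- list(); allI <- list()
  for (R in set@sg@rotations) for (sgn in c(1L, -1L)) {
    allH[[length(allH) + 1L]] <- (hkl %*% R) * sgn
    allI[[length(allI) + 1L]] <- Ival
  }
  H <- do.call(rbind, allH)
  Iall <- unlist(allI)
  first <- !duplicated(hklKey(H))
  H <- H[first, , drop = FALSE]; Iall <- Iall[first]
  lin <- (H[, 1] %% dims[1]) + 1L +
    (H[, 2] %% dims[2]) * dims[1] +
    (H[, 3] %% dims[3]) * (dims[1] * dims[2])
  A <- array(0, dims)
  A[lin] <- A[lin] + Iall   # lin is duplicate-free after the key filter
  P <- Re(fft(A, inverse = TRUE))
  org <- P[1, 1, 1]
  if (org <= 0) stop("non-physical intensity set: Patterson origin <= 0")
  new("PattersonGrid", dims = dims, values = P * (100 / org),
      cell = set@cell)
}

#' Off-origin Patterson peak search (tNCS detection)
#'
#' Finds local maxima of the Patterson map farther than `min_distance`
#' from the origin (and from the origin's lattice images), with height at
#' least `threshold_pct` percent of the origin. Peak positions are refined
#' by per-axis quadratic interpolation; centrosymmetric mates (+u / -u)
#' are collapsed to one entry. Peaks are returned sorted by height. A peak
#' of 35-65% of origin at a chemically sensible vector is the classic
#' signature of two molecular copies related by pure translation.
#'
#' @param grid a [PattersonGrid-class]
#' @param min_distance minimum distance from the origin in Angstrom (10)
#' @param threshold_pct minimum height, percent of origin (20)
#' @return data.frame: u1, u2, u3 (fractional, in \[0,1)), height_pct,
#'   d_origin (Angstrom); zero rows when nothing qualifies
#' @export
findTncsPeaks <- function(grid, min_distance = 10, threshold_pct = 20) {
  P <- grid@values
  dims <- grid@dims
  M <- orthoMatrix(grid@cell)
  # local maxima: strictly greater than all 26 circularly-shifted copies
  isMax <- array(TRUE, dims)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- P[((seq_len(dims[1]) - 1 + dx) %% dims[1]) + 1,
            ((seq_len(dims[2]) - 1 + dy) %% dims[2]) + 1,
            ((seq_len(dims[3]) - 1 + dz) %% dims[3]) + 1]
    isMax <- isMax & (P >= sh)
  }
  cand <- which(isMax & P >= threshold_pct, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(u1 = numeric(0), u2 = numeric(0), u3 = numeric(0),
                      height_pct = numeric(0), d_origin = numeric(0)))
  out <- list()
  for (r in seq_len(nrow(cand))) {
    ijk <- cand[r, ]
    u <- (ijk - 1) / dims
    # quadratic sub-grid interpolation along each axis
    du <- numeric(3)
    val <- P[ijk[1], ijk[2], ijk[3]]
    for (ax in 1:3) {
      im <- ijk; ip <- ijk
      im[ax] <- ((ijk[ax] - 2) %% dims[ax]) + 1
      ip[ax] <- (ijk[ax] %% dims[ax]) + 1
      fm <- P[im[1], im[2], im[3]]; fp <- P[ip[1], ip[2], ip[3]]
      den <- fm - 2 * val + fp
      if (den < 0) du[ax] <- 0.5 * (fm - fp) / den / dims[ax]
    }
    u <- (u + du) %% 1
    # distance to nearest origin lattice image
    uc <- ((u + 0.5) %% 1) - 0.5
    dmin <- sqrt(min(colSums((M %*% (t(expand.grid(-1:1, -1:1, -1:1)) +
                                       uc))^2)))
    if (dmin < min_distance) next
    out[[length(out) + 1L]] <- data.frame(
      u1 = u[1], u2 = u[2], u3 = u[3], height_pct = val, d_origin = dmin)
  }
  if (!length(out))
    return(data.frame(u1 = numeric(0), u2 = numeric(0), u3 = numeric(0),
                      height_pct = numeric(0), d_origin = numeric(0)))
  pk <- do.call(rbind, out)
  # collapse centrosymmetric mates: one representative per {u, -u} class
  keys <- vapply(seq_len(nrow(pk)), function(r) {
    u <- as.numeric(pk[r, 1:3])
    k1 <- paste(round(u * dims) %% dims, collapse = ",")
    k2 <- paste(round((-u) %% 1 * dims) %% dims, collapse = ",")
    min(k1, k2)
  }, character(1))
  pk <- pk[!duplicated(keys), , drop = FALSE]
  rownames(pk) <- NULL
  pk[order(-pk$height_pct), , drop = FALSE]
}
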