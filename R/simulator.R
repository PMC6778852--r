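#' Configuration for a synthetic dataset
#'
#' Bundles everything the simulator needs to produce a ground-truth
#' dataset: cell, symmetry, contents, displacement model, resolution
#' limit, injected pathologies (twin fraction, tNCS translation, anomalous
#' scatterers) and the noise level. All randomness derives from `seed`, so
#' a dataset is regenerable bit-identically from its configuration.
#'
#' Defaults describe a small protein-like crystal: 150 protein-composition
#' atoms in P21, B = 20 A^2, 2.0 A data, 5% counting-like noise and no
#' pathology.
#'
#' @param sg space-group symbol or [SpaceGroup-class] (default "P21")
#' @param cell [UnitCell-class]; a family-appropriate default is chosen
#'   when NULL
#' @param n_atoms atoms in the asymmetric unit (before symmetry expansion)
#' @param elements named probability vector for element sampling
#' @param b_iso isotropic B (A^2): a single value or c(min, max) range
#' @param b_tensor optional overall symmetric 3x3 Cartesian B tensor (A^2)
#'   replacing `b_iso`
#' @param d_min resolution limit (A)
#' @param alpha_true twin fraction in \[0, 0.5\]
#' @param twin_law 3x3 integer matrix or [TwinLaw-class]; when NULL the
#'   first tabulated candidate law for the group is used (required only if
#'   `alpha_true > 0`)
#' @param tncs_vector fractional translation of a second copy, or NULL
#' @param fdp named vector of anomalous f'' by element (electrons),
#'   e.g. `c(S = 4)`
#' @param noise_k fractional noise scale (0 = noise-free; sigmas then use
#'   a tiny floor so they remain positive)
#' @param occupancy site occupancy in (0, 1]
#' @param seed RNG seed (mandatory)
#' @return a list of class `"SyntheticConfig"`
#' @export
syntheticConfig <- function(sg = "P21", cell = NULL, n_atoms = 150,
                            elements = c(C = 0.55, N = 0.16, O = 0.24,
                                         S = 0.05),
                            b_iso = 20, b_tensor = NULL, d_min = 2.0,
                            alpha_true = 0, twin_law = NULL,
                            tncs_vector = NULL, fdp = NULL, noise_k = 0.05,
                            occupancy = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.character(sg)) sg <- parseSpaceGroup(sg)
  if (is.null(cell)) cell <- defaultCellFor(sg)
  stopifnot(alpha_true >= 0, alpha_true <= 0.5, d_min > 0, n_atoms >= 1,
            noise_k >= 0, occupancy > 0, occupancy <= 1)
  structure(list(sg = sg, cell = cell, n_atoms = as.integer(n_atoms),
                 elements = elements / sum(elements), b_iso = b_iso,
                 b_tensor = b_tensor, d_min = d_min,
                 alpha_true = alpha_true, twin_law = twin_law,
                 tncs_vector = tncs_vector, fdp = fdp, noise_k = noise_k,
                 occupancy = occupancy, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# A generic cell of sensible macromolecular size per crystal family,
# respecting the family's metric constraints.
defaultCellFor <- function(sg) {
  switch(sg@family,
         triclinic    = UnitCell(40, 50, 45, 85, 95, 105),
         monoclinic   = UnitCell(40, 50, 45, 90, 100, 90),
         orthorhombic = UnitCell(40, 50, 60),
         tetragonal   = UnitCell(42, 42, 55),
         trigonal     = UnitCell(45, 45, 50, 90, 90, 120),
         hexagonal    = UnitCell(45, 45, 50, 90, 90, 120),
         cubic        = UnitCell(60, 60, 60))
}

#' Generate a random atomic structure
#'
#' Uniform random fractional positions for `n_atoms` sites with elements
#' sampled from the configured mix and B factors from the configured value
#' or range. If a tNCS vector is set, a second copy of every atom is added
#' at `frac + t (mod 1)`. Deterministic for a given seed.
#'
#' @param config a [syntheticConfig()] list
#' @return data.frame: element, x, y, z (fractional), B, occ
#' @export
generateStructure <- function(config) {
  withSeed(config$seed, {
    n <- config$n_atoms
    el <- sample(names(config$elements), n, replace = TRUE,
                 prob = config$elements)
    xyz <- matrix(runif(3 * n), n, 3)
    B <- if (length(config$b_iso) == 2)
      runif(n, config$b_iso[1], config$b_iso[2])
    else rep(config$b_iso[1], n)
    atoms <- data.frame(element = el, x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], B = B, occ = config$occupancy)
    if (!is.null(config$tncs_vector)) {
      t <- config$tncs_vector
      copy <- atoms
      copy$x <- (copy$x + t[1]) %% 1
      copy$y <- (copy$y + t[2]) %% 1
      copy$z <- (copy$z + t[3]) %% 1
      atoms <- rbind(atoms, copy)
    }
    atoms
  })
}

#' Expand an asymmetric unit to the full cell (P1)
#'
#' Applies every operator of the group to the fractional coordinates.
#'
#' @param atoms data.frame as from [generateStructure()]
#' @param sg a [SpaceGroup-class]
#' @return data.frame with `nrow(atoms) * groupOrder(sg)` sites
#' @export
expandSymmetry <- function(atoms, sg) {
  xyz <- t(as.matrix(atoms[, c("x", "y", "z")]))
  out <- vector("list", groupOrder(sg))
  for (i in seq_len(groupOrder(sg))) {
    xi <- (sg@rotations[[i]] %*% xyz + sg@translations[i, ] / 12) %% 1
    a <- atoms
    a$x <- xi[1, ]; a$y <- xi[2, ]; a$z <- xi[3, ]
    out[[i]] <- a
  }
  do.call(rbind, out)
}

#' Structure factors by direct summation
#'
#' F(h) = sum_j occ_j f_j(s) exp(-B_j s^2) exp(2 pi i h.x_j) with
#' s^2 = (sin(theta)/lambda)^2 = 1/(4 d^2) and form factors from the
#' built-in table. With anomalous scattering (`fdp`), f_j gains an
#' imaginary part and Friedel symmetry breaks: F+ (at h) and F- (at -h)
#' are computed separately. With an overall B tensor the Debye-Waller
#' factor becomes exp(-u' B u / 4) with u the Cartesian reciprocal vector.
#'
#' @param atoms data.frame: element, x, y, z, B, occ (P1 sites; expand
#'   symmetry first, see [expandSymmetry()])
#' @param hkl n x 3 integer matrix of Miller indices
#' @param cell a [UnitCell-class]
#' @param fdp optional named f'' vector by element
#' @param b_tensor optional overall 3x3 Cartesian B tensor replacing
#'   per-atom B
#' @return data.frame: h, k, l, I (=|F|^2), F (modulus), reF, imF; with
#'   `fdp`, also Iplus/Iminus
#' @export
calcStructureFactors <- function(atoms, hkl, cell, fdp = NULL,
                                 b_tensor = NULL) {
  stopifnot(nrow(atoms) >= 1, nrow(hkl) >= 1)
  hkl <- asHKLMatrix(hkl)
  Fc <- directSumF(atoms, hkl, cell, fdp, b_tensor)
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    I = Mod(Fc)^2, F = Mod(Fc), reF = Re(Fc), imF = Im(Fc))
  if (!is.null(fdp) && any(fdp > 0)) {
    Fm <- directSumF(atoms, -hkl, cell, fdp, b_tensor)
    out$Iplus <- Mod(Fc)^2
    out$Iminus <- Mod(Fm)^2
    out$I <- (out$Iplus + out$Iminus) / 2
    out$F <- sqrt(out$I)
  }
  out
}

directSumF <- function(atoms, hkl, cell, fdp = NULL, b_tensor = NULL) {
  n <- nrow(hkl)
  d <- dSpacing(hkl, cell)
  s2 <- 1 / (4 * d^2)
  dwAniso <- NULL
  if (!is.null(b_tensor)) {
    u <- hkl %*% solve(orthoMatrix(cell))      # Cartesian reciprocal, 1/A
    dwAniso <- exp(-rowSums((u %*% b_tensor) * u) / 4)
  }
  Fc <- complex(real = numeric(n), imaginary = numeric(n))
  chunk <- max(1L, floor(4e6 / max(nrow(atoms), 1L)))
  for (el in unique(atoms$element)) {
    sel <- atoms$element == el
    f0 <- scatteringFactor(el, s2)
    fel <- if (!is.null(fdp) && el %in% names(fdp) && !is.na(fdp[[el]]))
      complex(real = f0, imaginary = rep(fdp[[el]], n)) else f0
    xyz <- t(as.matrix(atoms[sel, c("x", "y", "z")]))   # 3 x m
    B <- atoms$B[sel]; occ <- atoms$occ[sel]
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      ph <- (hkl[idx, , drop = FALSE] %*% xyz) * (2 * pi)   # nidx x m
      dw <- if (is.null(dwAniso)) exp(-outer(s2[idx], B)) else
        matrix(dwAniso[idx], length(idx), length(B))
      contrib <- (dw * cos(ph)) %*% occ +
        1i * ((dw * sin(ph)) %*% occ)
      Fc[idx] <- Fc[idx] + fel[idx] * as.vector(contrib)
    }
  }
  Fc
}

#' Twin a set of intensities
#'
#' Applies the incoherent twin sum I_obs(h) = (1-alpha) I(h) +
#' alpha I(T h): the measured spot is the domain-fraction-weighted sum of
#' the two overlapping reflections. Reflections whose twin mate is not in
#' the set are dropped and counted (attribute `"dropped"`). Bijvoet
#' columns, if present, are twinned with the same weights.
#'
#' @param set a [ReflectionSet-class] (typically simulator truth)
#' @param law a [TwinLaw-class] or 3x3 integer matrix acting on row hkl
#' @param alpha twin fraction in \[0, 0.5\]
#' @return a [ReflectionSet-class] with twinned intensities
#' @export
applyTwin <- function(set, law, alpha) {
  stopifnot(alpha >= 0, alpha <= 0.5)
  Tm <- lawMatrix(law)
  df <- set@data
  if (alpha == 0) return(set)
  idx <- twinPartnerIndex(set, Tm)
  keep <- !is.na(idx)
  df <- df[keep, , drop = FALSE]
  idx <- idx[keep]
  for (col in intersect(c("I", "Iplus", "Iminus"), names(df)))
    df[[col]] <- (1 - alpha) * df[[col]] + alpha * set@data[[col]][idx]
  dropped <- sum(!keep)
  out <- reflectionSet(set@cell, set@sg, df, merged = set@merged,
                       anomalous = set@anomalous)
  attr(out, "dropped") <- dropped
  out
}

# Row index of each reflection's twin mate canon(h T) within the set;
# NA where the mate is not present.
twinPartnerIndex <- function(set, Tm) {
  hkl <- hklMatrix(set)
  mate <- asuIndex(hkl %*% Tm, set@sg, anomalous = set@anomalous)
  match(hklKey(mate), hklKey(asuIndex(hkl, set@sg,
                                      anomalous = set@anomalous)))
}

#' Add counting-like Gaussian noise to intensities
#'
#' Two-parameter noise model: sigma(h) = k sqrt(max(I(h), m/100) * m) with
#' m the mean intensity, so strong reflections get roughly fractional
#' errors and weak ones a noise floor. I_obs = I + N(0, sigma); negative
#' observations are retained. With `noise_k = 0` the intensities are exact
#' and sigmas use a tiny floor (k = 1e-6) so they stay positive.
#'
#' @param I true intensities
#' @param noise_k fractional noise scale (>= 0)
#' @param seed RNG seed
#' @return list with `I` (noisy) and `sigI`
#' @export
addNoise <- function(I, noise_k, seed) {
  stopifnot(noise_k >= 0)
  m <- mean(pmax(I, 0))
  if (m <= 0) m <- 1
  k <- max(noise_k, 1e-6)
  sig <- k * sqrt(pmax(I, m / 100) * m)
  Iobs <- if (noise_k > 0)
    I + withSeed(seed, rnorm(length(I), 0, sig)) else I
  list(I = Iobs, sigI = sig)
}

#' Simulate a complete ground-truth dataset
#'
#' Full pipeline: random structure (optionally with a tNCS copy) ->
#' symmetry expansion -> Miller-index enumeration to d_min (systematically
#' absent indices included, carrying their near-zero computed intensities,
#' so absence detection is testable) -> direct-summation structure factors
#' (optionally anomalous) -> twinning -> noise. Returns the observed
#' [ReflectionSet-class] together with the ground truth; optionally writes
#' CSV, structure-factor mmCIF and a PDB coordinate file.
#'
#' @param config a [syntheticConfig()] list
#' @param dir when non-NULL, directory to write `reflections.csv`,
#'   `reflections.cif` and `model.pdb` into
#' @return a list of class `"SyntheticDataset"`: `config`, `atoms` (asym
#'   unit), `truth` (noise-free data.frame incl. true I before twinning,
#'   `alpha_true`, `twin_law`, `tncs_vector`), `set` (observed
#'   [ReflectionSet-class]) and `files`
#' @export
simulateDataset <- function(config, dir = NULL) {
  sg <- config$sg
  cell <- config$cell
  anom <- !is.null(config$fdp) && any(config$fdp > 0)
  law <- NULL
  if (config$alpha_true > 0) {
    law <- config$twin_law
    if (is.null(law)) {
      cand <- candidateTwinLaws(cell, sg)
      if (!length(cand))
        stop("alpha_true > 0 but no twin law known for this group; ",
             "supply config$twin_law")
      law <- cand[[1]]
    }
    checkTwinLaw(lawMatrix(law), sg)
  }
  atoms <- generateStructure(config)
  expanded <- expandSymmetry(atoms, sg)
  uniq <- enumerateReflections(cell, sg, config$d_min, anomalous = anom,
                          includeAbsent = TRUE)
  sf <- calcStructureFactors(expanded, as.matrix(uniq[, c("h", "k", "l")]),
                             cell, fdp = config$fdp,
                             b_tensor = config$b_tensor)
  truth <- sf
  truth$d <- uniq$d
  obs <- sf
  setTrue <- reflectionSet(cell, sg,
                           obs[, intersect(c("h", "k", "l", "I", "Iplus",
                                             "Iminus"), names(obs))],
                           merged = TRUE, anomalous = anom)
  if (!is.null(law)) setTrue <- applyTwin(setTrue, law, config$alpha_true)
  df <- setTrue@data
  nz <- addNoise(df$I, config$noise_k, config$seed + 1L)
  df$I <- nz$I; df$sigI <- nz$sigI
  if (anom) {
    nzp <- addNoise(setTrue@data$Iplus, config$noise_k, config$seed + 2L)
    nzm <- addNoise(setTrue@data$Iminus, config$noise_k, config$seed + 3L)
    df$Iplus <- nzp$I; df$sigIplus <- nzp$sigI
    df$Iminus <- nzm$I; df$sigIminus <- nzm$sigI
    df$I <- (df$Iplus + df$Iminus) / 2
    df$sigI <- sqrt(df$sigIplus^2 + df$sigIminus^2) / 2
  }
  set <- reflectionSet(cell, sg, df, merged = TRUE, anomalous = anom)
  files <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fcsv <- file.path(dir, "reflections.csv")
    fcif <- file.path(dir, "reflections.cif")
    fpdb <- file.path(dir, "model.pdb")
    writeReflections(set, fcsv, "csv")
    writeReflections(set, fcif, "mmcif")
    writePDB(atoms, cell, sg, fpdb)
    files <- c(csv = fcsv, mmcif = fcif, pdb = fpdb)
  }
  structure(list(config = config, atoms = atoms,
                 truth = list(sf = truth, alpha_true = config$alpha_true,
                              twin_law = law,
                              tncs_vector = config$tncs_vector,
                              b_iso = config$b_iso,
                              b_tensor = config$b_tensor,
                              fdp = config$fdp),
                 set = set, files = files),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat("SyntheticDataset:", nrow(x$set@data), "unique reflections\n")
  cat("  sg:", x$config$sg@symbol, " alpha_true:", x$config$alpha_true,
      " tncs:", if (is.null(x$config$tncs_vector)) "none" else
        paste(round(x$config$tncs_vector, 3), collapse = ","),
      " noise_k:", x$config$noise_k, "\n")
  invisible(x)
}

# Minimal PDB coordinate writer for the simulated asymmetric unit.
writePDB <- function(atoms, cell, sg, path) {
  M <- orthoMatrix(cell)
  xyz <- t(M %*% t(as.matrix(atoms[, c("x", "y", "z")])))
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                   cell@a, cell@b, cell@c, cell@alpha, cell@beta,
                   cell@gamma,
                   if (nzchar(sg@symbol)) sg@symbol else "P 1")
  for (i in seq_len(nrow(atoms))) {
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s UNK A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, substr(atoms$element[i], 1, 2), i, xyz[i, 1], xyz[i, 2],
      xyz[i, 3], atoms$occ[i], atoms$B[i], toupper(atoms$element[i])))
  }
  writeLines(c(lines, "END"), path)
}
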