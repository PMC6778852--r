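#' Anisotropic overall scale fit
#'
#' Symmetry-constrained least-squares fit of
#' ln I(h) = ln K - 2 u' beta u, with u the Cartesian reciprocal-space
#' vector (1/A) and beta a symmetric tensor constrained by the crystal
#' family (e.g. beta11 = beta22 and no off-diagonals for tetragonal).
#' Intensities are first divided by the expected scattering sum f^2(s) so
#' the form-factor falloff does not masquerade as an isotropic B
#' contribution. The tensor is reported on the conventional B scale
#' (B = 4 beta, so an isotropic crystal with Wilson B gives eigenvalues
#' equal to B).
#'
#' For the cubic family (or `constrain = "isotropic"`) the quadratic form
#' is rank-deficient up to a multiple of the identity; the fit then
#' reduces to the Wilson fit and delta_B = 0 by construction.
#'
#' @param set a merged [ReflectionSet-class] with at least 1000
#'   reflections
#' @param composition named atom counts (default: protein-like)
#' @param constrain `"family"` (default) or `"isotropic"`
#' @return list of class `"AnisoFit"`: beta (3x3, B scale), eigenvalues
#'   B1 >= B2 >= B3 (A^2), delta_B = B1 - B3, ratio = delta_B / mean(B),
#'   K, n_used
#' @export
anisoFit <- function(set, composition = NULL,
                     constrain = c("family", "isotropic")) {
  constrain <- match.arg(constrain)
  if (is.null(composition)) composition <- defaultComposition(set@cell)
  fam <- set@sg@family
  if (constrain == "isotropic" || fam == "cubic") {
    wf <- wilsonFit(set, composition = composition)
    B <- wf$B_iso
    return(structure(list(beta = diag(rep(B, 3)),
                          eigenvalues = rep(B, 3), delta_B = 0, ratio = 0,
                          K = wf$K, n_used = nrow(set@data)),
                     class = "AnisoFit"))
  }
  df <- set@data
  keep <- !isAbsent(hklMatrix(set), set@sg) & !is.na(df$I) & df$I > 0
  if (sum(keep) < 1000) stop("too few reflections for anisotropy fit")
  hkl <- hklMatrix(set)[keep, , drop = FALSE]
  u <- hkl %*% solve(orthoMatrix(set@cell))
  s2 <- 1 / (4 * df$d[keep]^2)
  y <- log(df$I[keep] / sumFsq(composition, s2))
  # quadratic-form regressors for the 6 unique tensor components
  q <- cbind(u[, 1]^2, u[, 2]^2, u[, 3]^2,
             2 * u[, 1] * u[, 2], 2 * u[, 1] * u[, 3],
             2 * u[, 2] * u[, 3])
  # family constraint: columns of C map free parameters to (b11,b22,b33,
  # b12,b13,b23)
  C <- switch(fam,
    triclinic = diag(6),
    monoclinic = {                       # unique axis b: b12 = b23 = 0
      M <- matrix(0, 6, 4)
      M[1, 1] <- 1; M[2, 2] <- 1; M[3, 3] <- 1; M[5, 4] <- 1
      M
    },
    orthorhombic = diag(6)[, 1:3, drop = FALSE],
    tetragonal = cbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0)),
    trigonal = cbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0)),
    hexagonal = cbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0)))
  X <- q %*% C
  fit <- lm(y ~ X)
  theta <- as.numeric(C %*% coef(fit)[-1])
  beta <- matrix(c(theta[1], theta[4], theta[5],
                   theta[4], theta[2], theta[6],
                   theta[5], theta[6], theta[3]), 3, 3)
  beta <- -beta / 2           # y = c0 - 2 u' beta u
  Bt <- 4 * beta              # conventional B scale
  ev <- sort(eigen(Bt, symmetric = TRUE)$values, decreasing = TRUE)
  structure(list(beta = Bt, eigenvalues = ev, delta_B = ev[1] - ev[3],
                 ratio = (ev[1] - ev[3]) / mean(ev),
                 K = exp(coef(fit)[[1]]), n_used = sum(keep)),
            class = "AnisoFit")
}
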