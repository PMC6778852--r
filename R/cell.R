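#' Unit cell
#'
#' Triclinic unit-cell parameters: edge lengths in Angstrom and inter-axial
#' angles in degrees. The validity method requires positive lengths, angles
#' strictly inside (0, 180) and a positive-definite direct metric tensor
#' (i.e. the three angles must describe a realizable parallelepiped).
#'
#' @slot a,b,c edge lengths (Angstrom)
#' @slot alpha,beta,gamma inter-axial angles (degrees)
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"),
  validity = function(object) {
    p <- c(object@a, object@b, object@c)
    ang <- c(object@alpha, object@beta, object@gamma)
    if (any(!is.finite(p)) || any(p <= 0))
      return("cell lengths must be positive and finite")
    if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
      return("cell angles must lie in (0, 180) degrees")
    if (det(directMetric(object)) <= 0)
      return("cell angles do not define a positive-definite metric")
    TRUE
  })

#' Construct a unit cell
#'
#' @param a,b,c edge lengths in Angstrom
#' @param alpha,beta,gamma angles in degrees (default 90)
#' @return a [UnitCell-class] object
#' @examples
#' UnitCell(78.2, 78.2, 37.1, 90, 90, 90)
#' @export
UnitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma))
}

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell  %.3f %.3f %.3f  %.2f %.2f %.2f  (V = %.0f A^3)\n",
              object@a, object@b, object@c,
              object@alpha, object@beta, object@gamma, cellVolume(object)))
})

#' Direct metric tensor G (Angstrom^2)
#' @param cell a [UnitCell-class]
#' @return 3x3 symmetric matrix with G[i,j] = a_i . a_j
#' @export
directMetric <- function(cell) {
  ca <- cos(cell@alpha * pi / 180)
  cb <- cos(cell@beta * pi / 180)
  cg <- cos(cell@gamma * pi / 180)
  a <- cell@a; b <- cell@b; cc <- cell@c
  matrix(c(a * a,      a * b * cg, a * cc * cb,
           a * b * cg, b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), 3, 3)
}

#' Reciprocal metric tensor G* = G^-1 (Angstrom^-2)
#' @inheritParams directMetric
#' @export
reciprocalMetric <- function(cell) solve(directMetric(cell))

#' Cell volume in cubic Angstrom
#' @inheritParams directMetric
#' @export
cellVolume <- function(cell) sqrt(det(directMetric(cell)))

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Columns are the cell basis vectors in a Cartesian frame (a along x,
#' b in the xy plane). Cartesian coordinates of a fractional point u are
#' `M %*% u`; the Cartesian reciprocal vector of Miller index h (row) is
#' `h %*% solve(M)`, whose length is 1/d.
#'
#' @inheritParams directMetric
#' @return 3x3 matrix (Angstrom)
#' @export
orthoMatrix <- function(cell) {
  ca <- cos(cell@alpha * pi / 180)
  cb <- cos(cell@beta * pi / 180)
  cg <- cos(cell@gamma * pi / 180); sg <- sin(cell@gamma * pi / 180)
  v <- sqrt(1 - ca * ca - cb * cb - cg * cg + 2 * ca * cb * cg)
  matrix(c(cell@a, cell@b * cg, cell@c * cb,
           0,      cell@b * sg, cell@c * (ca - cb * cg) / sg,
           0,      0,           cell@c * v / sg),
         3, 3, byrow = TRUE)
}

#' Resolution (d-spacing) of reflections
#'
#' 1/d^2 = h G* h^T with G* the reciprocal metric tensor.
#'
#' @param hkl integer vector of length 3 or an n x 3 matrix of Miller indices
#' @param cell a [UnitCell-class]
#' @return d in Angstrom (vector of length n)
#' @examples
#' dSpacing(c(1, 0, 0), UnitCell(10, 10, 10))  # 10 A
#' @export
dSpacing <- function(hkl, cell) {
  hkl <- asHKLMatrix(hkl)
  if (any(rowSums(hkl != 0L) == 0L))
    stop("undefined d-spacing for (0,0,0)")
  gstar <- reciprocalMetric(cell)
  invd2 <- rowSums((hkl %*% gstar) * hkl)
  1 / sqrt(invd2)
}

# Coerce to an n x 3 integer matrix; accepts a length-3 vector.
asHKLMatrix <- function(hkl) {
  if (is.null(dim(hkl))) {
    stopifnot(length(hkl) == 3L)
    hkl <- matrix(hkl, 1L, 3L)
  }
  storage.mode(hkl) <- "integer"
  hkl
}
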