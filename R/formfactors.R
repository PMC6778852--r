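# 4-Gaussian atomic scattering-factor coefficients (International Tables
# vol. C parameterization): f0(s) = sum_i a_i exp(-b_i s^2) + c with
# s = sin(theta)/lambda = 1/(2d) in 1/Angstrom. Light elements relevant to
# Wilson-level protein statistics; anything else falls back to a constant
# equal to the electron count.
.ff4 <- list(
  H = list(a = c(0.493002, 0.322912, 0.140191, 0.040810),
           b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038),
  C = list(a = c(2.31, 1.02, 1.5886, 0.865),
           b = c(20.8439, 10.2075, 0.5687, 51.6512), c = 0.2156),
  N = list(a = c(12.2126, 3.1322, 2.0125, 1.1663),
           b = c(0.0057, 9.8933, 28.9975, 0.5826), c = -11.529),
  O = list(a = c(3.0485, 2.2868, 1.5463, 0.867),
           b = c(13.2771, 5.7011, 0.3239, 32.9089), c = 0.2508),
  P = list(a = c(6.4345, 4.1791, 1.78, 1.4908),
           b = c(1.9067, 27.157, 0.526, 68.1645), c = 1.1149),
  S = list(a = c(6.9053, 5.2034, 1.4379, 1.5863),
           b = c(1.4679, 22.2151, 0.2536, 56.172), c = 0.8669)
)

.electronCount <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16,
                    SE = 34, FE = 26, ZN = 30, MG = 12, CA = 20, MN = 25,
                    NA. = 11, K = 19, CL = 17, BR = 35, I = 53)

#' Atomic scattering factor f0(s)
#'
#' Elastic X-ray form factor from the built-in 4-Gaussian table
#' (H, C, N, O, P, S); other known elements fall back to a constant f0
#' equal to their electron count.
#'
#' @param element element symbol (case-insensitive)
#' @param s2 squared scattering vector (sin(theta)/lambda)^2 = 1/(4 d^2),
#'   in 1/Angstrom^2 (vectorized)
#' @return numeric vector of f0 values (electrons)
#' @examples
#' scatteringFactor("C", 0)      # 5.9992, the carbon electron count
#' @export
scatteringFactor <- function(element, s2) {
  el <- toupper(element)
  key <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
  key <- sub(" *$", "", key)
  cf <- .ff4[[key]]
  if (is.null(cf)) cf <- .ff4[[el]]
  if (!is.null(cf)) {
    f <- rep(cf$c, length(s2))
    for (i in 1:4) f <- f + cf$a[i] * exp(-cf$b[i] * s2)
    return(f)
  }
  z <- .electronCount[[el]]
  if (is.null(z) || is.na(z)) stop("unknown element: ", element)
  rep(as.numeric(z), length(s2))
}

#' Expected squared scattering per cell content
#'
#' Sum over a composition of occupancy-weighted squared form factors,
#' the denominator of the Wilson-plot ordinate.
#'
#' @param composition named numeric vector of atom counts by element,
#'   e.g. `c(C = 500, N = 130, O = 160, S = 5)`
#' @param s2 squared scattering vector(s), 1/Angstrom^2
#' @return numeric vector, sum_j n_j f_j(s)^2
#' @export
sumFsq <- function(composition, s2) {
  out <- numeric(length(s2))
  for (el in names(composition))
    out <- out + composition[[el]] * scatteringFactor(el, s2)^2
  out
}
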