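# Screw-axis hypotheses compatible with each crystal family: along each
# candidate principal axis, reflections with axial index not divisible by
# `modulus` are predicted absent.
.screwHypotheses <- function(family) {
  h <- function(axis, name, modulus)
    list(axis = axis, screw = name, modulus = modulus)
  switch(family,
    monoclinic = list(h("b", "2(1)", 2L)),
    orthorhombic = list(h("a", "2(1)", 2L), h("b", "2(1)", 2L),
                        h("c", "2(1)", 2L)),
    tetragonal = list(h("a", "2(1)", 2L), h("b", "2(1)", 2L),
                      h("c", "4(2)", 2L), h("c", "4(1)/4(3)", 4L)),
    trigonal = list(h("c", "3(1)/3(2)", 3L)),
    hexagonal = list(h("c", "6(3)", 2L), h("c", "6(2)/6(4)", 3L),
                     h("c", "6(1)/6(5)", 6L)),
    cubic = list(h("a", "2(1)", 2L), h("b", "2(1)", 2L),
                 h("c", "2(1)", 2L)),
    list())
}

#' Infer screw axes from systematic absences
#'
#' For each principal axis and each screw hypothesis compatible with the
#' crystal family, compares the mean I/sigma of axial reflections the
#' hypothesis predicts absent with that of the reflections it predicts
#' present. A screw is called present when the predicted-absent class is
#' at noise level (mean I/sigma < `absent_max`) while the predicted-present
#' class is clearly observed (mean I/sigma > `present_min`).
#'
#' The test uses the lattice symmetry only (the set's group is used merely
#' to locate the axial rows), so it works on data merged in a
#' screw-free setting.
#'
#' @param set a [ReflectionSet-class] containing axial reflections,
#'   including any systematically absent ones
#' @param absent_max threshold for the absent class (default 1)
#' @param present_min threshold for the present class (default 3)
#' @return data.frame: axis, screw, modulus, n_violating, n_conforming,
#'   i_over_sig_violating, i_over_sig_conforming, verdict ("screw present",
#'   "no screw", "indeterminate")
#' @export
detectScrewAxes <- function(set, absent_max = 1, present_min = 3) {
  hyp <- .screwHypotheses(set@sg@family)
  df <- set@data
  hkl <- hklMatrix(set)
  axisIndex <- list(a = 1L, b = 2L, c = 3L)
  rows <- lapply(hyp, function(hp) {
    ai <- axisIndex[[hp$axis]]
    others <- setdiff(1:3, ai)
    sel <- hkl[, others[1]] == 0L & hkl[, others[2]] == 0L &
      hkl[, ai] != 0L & !is.na(df$I) & !is.na(df$sigI) & df$sigI > 0
    n <- sum(sel)
    base <- data.frame(axis = hp$axis, screw = hp$screw,
                       modulus = hp$modulus, n_violating = 0L,
                       n_conforming = 0L,
                       i_over_sig_violating = NA_real_,
                       i_over_sig_conforming = NA_real_,
                       verdict = "indeterminate",
                       stringsAsFactors = FALSE)
    if (n == 0L) return(base)
    idx <- abs(hkl[sel, ai])
    ios <- df$I[sel] / df$sigI[sel]
    viol <- idx %% hp$modulus != 0L
    base$n_violating <- sum(viol)
    base$n_conforming <- sum(!viol)
    if (base$n_violating == 0L || base$n_conforming == 0L) return(base)
    base$i_over_sig_violating <- mean(ios[viol])
    base$i_over_sig_conforming <- mean(ios[!viol])
    base$verdict <-
      if (base$i_over_sig_violating < absent_max &&
          base$i_over_sig_conforming > present_min) "screw present"
      else "no screw"
    base
  })
  do.call(rbind, rows)
}

#' R factors between observed and model amplitudes
#'
#' The model amplitudes are first put on the observed scale with the
#' least-squares factor k minimizing sum (F_obs - k F_model)^2 over the
#' work set; then R = sum |F_obs - k F_model| / sum F_obs is evaluated
#' separately on the work and free (cross-validation) subsets. R_free on
#' held-out reflections guards against overfitting; see [assignFreeSet()]
#' for the conventional free-set selection.
#'
#' @param F_obs observed amplitudes
#' @param F_model calculated model amplitudes, matched index by index
#' @param free_flags logical vector, TRUE = free; NULL means all work
#' @return list: r_work, r_free (NA when the free set is empty), k
#' @export
rFactors <- function(F_obs, F_model, free_flags = NULL) {
  stopifnot(length(F_obs) == length(F_model))
  if (is.null(free_flags)) free_flags <- rep(FALSE, length(F_obs))
  stopifnot(length(free_flags) == length(F_obs))
  work <- !free_flags
  if (!any(work)) stop("empty work set")
  k <- sum(F_obs[work] * F_model[work]) / sum(F_model[work]^2)
  rOf <- function(sel)
    if (any(sel)) sum(abs(F_obs[sel] - k * F_model[sel])) /
      sum(F_obs[sel]) else NA_real_
  list(r_work = rOf(work), r_free = rOf(free_flags), k = k)
}
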