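#' Reflection data container
#'
#' The universal input object: a unit cell, a space group and a table of
#' reflection observations. The table always has integer columns `h,k,l`
#' and numeric `I,sigI`; optional columns are the Bijvoet-separated
#' intensities `Iplus,sigIplus,Iminus,sigIminus`, an amplitude `F`, and the
#' derived resolution `d` (recomputed at construction). Negative
#' intensities are legitimate (weak data are never clamped).
#'
#' When `merged` is TRUE no two rows are symmetry-equivalent (Friedel mates
#' included unless `anomalous`); rows are then stored under their canonical
#' asymmetric-unit index (see [asuIndex()]).
#'
#' @slot cell a [UnitCell-class]
#' @slot sg a [SpaceGroup-class]
#' @slot data data.frame of observations
#' @slot merged logical
#' @slot anomalous logical; TRUE when Bijvoet-separated columns carry signal
#' @export
setClass("ReflectionSet",
  representation(cell = "UnitCell", sg = "SpaceGroup", data = "data.frame",
                 merged = "logical", anomalous = "logical"),
  validity = function(object) {
    d <- object@data
    need <- c("h", "k", "l", "I", "sigI", "d")
    if (!all(need %in% names(d)))
      return(paste("missing columns:",
                   paste(setdiff(need, names(d)), collapse = ", ")))
    if (nrow(d) == 0L) return(TRUE)
    if (any(d$h == 0L & d$k == 0L & d$l == 0L))
      return("(0,0,0) is not a reflection")
    if (any(!is.na(d$sigI) & d$sigI <= 0))
      return("sigI must be positive where present")
    if (object@merged) {
      key <- hklKey(asuIndex(cbind(d$h, d$k, d$l), object@sg,
                             anomalous = object@anomalous))
      if (anyDuplicated(key))
        return("merged set contains symmetry-equivalent reflections")
    }
    TRUE
  })

#' Construct a ReflectionSet
#'
#' @param cell a [UnitCell-class]
#' @param sg a [SpaceGroup-class] (or a symbol / triplet vector,
#'   passed to [parseSpaceGroup()])
#' @param data data.frame with columns `h,k,l,I,sigI` and optionally
#'   `Iplus,sigIplus,Iminus,sigIminus,F`
#' @param merged is the data merged (one row per unique reflection)?
#' @param anomalous keep Friedel mates distinct / Bijvoet columns present?
#' @return a [ReflectionSet-class]
#' @export
reflectionSet <- function(cell, sg, data, merged = FALSE,
                          anomalous = any(c("Iplus", "Iminus") %in%
                                          names(data))) {
  if (is.character(sg)) sg <- parseSpaceGroup(sg)
  data <- as.data.frame(data)
  for (col in c("h", "k", "l")) data[[col]] <- as.integer(data[[col]])
  if (is.null(data$I)) data$I <- NA_real_
  if (is.null(data$sigI)) data$sigI <- NA_real_
  data$d <- if (nrow(data)) dSpacing(cbind(data$h, data$k, data$l), cell)
            else numeric(0)
  rownames(data) <- NULL
  new("ReflectionSet", cell = cell, sg = sg, data = data,
      merged = as.logical(merged), anomalous = as.logical(anomalous))
}

#' @rdname accessors
#' @export
setMethod("unitCell", "ReflectionSet", function(x) x@cell)

#' @rdname accessors
#' @export
setMethod("spaceGroup", "ReflectionSet", function(x) x@sg)

#' @rdname accessors
#' @export
setMethod("reflections", "ReflectionSet", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("isMerged", "ReflectionSet", function(x) x@merged)

#' @rdname accessors
#' @export
setMethod("isAnomalous", "ReflectionSet", function(x) x@anomalous)

#' Resolution range of a set
#' @param set a [ReflectionSet-class]
#' @return c(d_min, d_max) in Angstrom
#' @export
dRange <- function(set) {
  d <- set@data$d
  c(d_min = min(d), d_max = max(d))
}

setMethod("show", "ReflectionSet", function(object) {
  n <- nrow(object@data)
  cat(sprintf("ReflectionSet: %d reflections, %s, %s%s\n", n,
              if (nzchar(object@sg@symbol)) object@sg@symbol
              else sprintf("<%d ops>", groupOrder(object@sg)),
              if (object@merged) "merged" else "unmerged",
              if (object@anomalous) ", anomalous" else ""))
  show(object@cell)
  if (n) {
    dr <- dRange(object)
    cat(sprintf("  resolution %.2f - %.2f A\n", dr[2], dr[1]))
  }
})

# hkl of a set as an n x 3 integer matrix
hklMatrix <- function(set) {
  cbind(set@data$h, set@data$k, set@data$l)
}

# Evaluate an expression with a temporary RNG state seeded from `seed`,
# restoring the caller's state afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
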