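#' Space-group operator set
#'
#' A crystallographic space group represented explicitly as its list of
#' symmetry operators (rotation part + fractional translation). Operators
#' act on fractional coordinates as `x' = R x + t` and on Miller indices as
#' row vectors, `h' = h R`. Translations are stored exactly as integer
#' twelfths, so absence tests are exact integer arithmetic. Lattice
#' centrings (C, I, F) are ordinary group elements with identity rotation.
#'
#' Validity: the identity is present, all rotation determinants are +/-1
#' with entries in {-1,0,1}, the set is closed under composition modulo
#' lattice translations, and the order divides 192.
#'
#' @slot symbol Hermann-Mauguin-style text symbol (may be empty for groups
#'   given as explicit triplets)
#' @slot rotations list of 3x3 integer matrices
#' @slot translations integer matrix (n x 3) of translations in twelfths
#' @slot family crystal family: triclinic, monoclinic, orthorhombic,
#'   tetragonal, trigonal, hexagonal or cubic
#' @export
setClass("SpaceGroup",
  representation(symbol = "character", rotations = "list",
                 translations = "matrix", family = "character"),
  validity = function(object) {
    n <- length(object@rotations)
    if (n < 1L) return("group is empty")
    if (nrow(object@translations) != n)
      return("rotation/translation length mismatch")
    for (R in object@rotations) {
      if (!all(R %in% c(-1L, 0L, 1L)))
        return("rotation entries must be in {-1,0,1}")
      if (abs(round(det(R))) != 1L)
        return("rotation determinant must be +1 or -1")
    }
    keys <- opKeys(object@rotations, object@translations)
    if (anyDuplicated(keys)) return("duplicate operators")
    if (!(opKeys(list(diag(3L)), matrix(0L, 1, 3)) %in% keys))
      return("identity operator missing")
    if (192L %% n != 0L) return("group order must divide 192")
    # closure mod lattice
    for (i in seq_len(n)) for (j in seq_len(n)) {
      Rij <- object@rotations[[i]] %*% object@rotations[[j]]
      tij <- (object@rotations[[i]] %*% object@translations[j, ] +
              object@translations[i, ]) %% 12L
      if (!(opKeys(list(Rij), matrix(as.integer(tij), 1, 3)) %in% keys))
        return("not a group: operators do not close under composition")
    }
    if (!object@family %in% c("triclinic", "monoclinic", "orthorhombic",
                              "tetragonal", "trigonal", "hexagonal",
                              "cubic"))
      return("unknown crystal family")
    TRUE
  })

setMethod("show", "SpaceGroup", function(object) {
  cat(sprintf("SpaceGroup %s  (%s, %d operators)\n",
              if (nzchar(object@symbol)) object@symbol else "<custom>",
              object@family, length(object@rotations)))
})

#' Number of operators in a space group
#' @param sg a [SpaceGroup-class]
#' @export
groupOrder <- function(sg) length(sg@rotations)

# Unique text key per operator (rotation entries + translation twelfths).
opKeys <- function(rotations, translations) {
  vapply(seq_along(rotations), function(i) {
    paste(c(rotations[[i]], translations[i, ] %% 12L), collapse = ",")
  }, character(1))
}

# ---- triplet notation ----------------------------------------------------

# Parse one "x,y,z"-style triplet into rotation (3x3 int) + translation
# (length-3 int, twelfths). Accepts fractions like 1/2, 2/3, 0.25.
parseTriplet <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3L) stop("malformed triplet: ", s)
  R <- matrix(0L, 3L, 3L); tr <- numeric(3)
  for (i in 1:3) {
    comp <- parts[i]
    if (!grepl("^[xyz0-9+./-]+$", comp)) stop("malformed triplet: ", s)
    ev <- function(x, y, z) eval(parse(text = comp),
                                 envir = list(x = x, y = y, z = z))
    c0 <- ev(0, 0, 0)
    R[1, i] <- as.integer(round(ev(1, 0, 0) - c0))
    R[2, i] <- as.integer(round(ev(0, 1, 0) - c0))
    R[3, i] <- as.integer(round(ev(0, 0, 1) - c0))
    tr[i] <- c0
  }
  t12 <- round(tr * 12)
  if (max(abs(t12 - tr * 12)) > 1e-9)
    stop("translation not a multiple of 1/12 in: ", s)
  # R built with columns = output components: x'_i = sum_j R[j,i] x_j,
  # i.e. coordinate action uses t(R); store so that x' = R x + t.
  list(R = t(R), t = as.integer(t12) %% 12L)
}

# Emit "x,y,z" triplet text for one operator.
formatTriplet <- function(R, t12) {
  vars <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    terms <- ""
    for (j in 1:3) {
      cij <- R[i, j]
      if (cij == 1L) terms <- paste0(terms, "+", vars[j])
      else if (cij == -1L) terms <- paste0(terms, "-", vars[j])
      else if (cij != 0L) stop("unexpected rotation entry")
    }
    tt <- t12[i] %% 12L
    if (tt != 0L) {
      g <- gcdInt(tt, 12L)
      terms <- paste0(terms, "+", tt %/% g, "/", 12L %/% g)
    }
    comp[i] <- sub("^\\+", "", terms)
    if (!nzchar(comp[i])) comp[i] <- "0"
  }
  paste(comp, collapse = ",")
}

gcdInt <- function(a, b) if (b == 0L) a else gcdInt(b, a %% b)

#' Triplet representation of a space group
#'
#' @param sg a [SpaceGroup-class]
#' @return character vector of "x,y,z"-style triplets, one per operator
#' @export
spaceGroupTriplets <- function(sg) {
  vapply(seq_len(groupOrder(sg)), function(i)
    formatTriplet(sg@rotations[[i]], sg@translations[i, ]), character(1))
}

# ---- symbol table --------------------------------------------------------

# Generators only; full groups are produced by closure. Standard settings
# (monoclinic unique axis b). Covers the common macromolecular groups;
# anything else must be supplied as explicit triplets.
.sgTable <- list(
  "P1"       = list(fam = "triclinic",    gen = c("x,y,z")),
  "P-1"      = list(fam = "triclinic",    gen = c("-x,-y,-z")),
  "P2"       = list(fam = "monoclinic",   gen = c("-x,y,-z")),
  "P21"      = list(fam = "monoclinic",   gen = c("-x,y+1/2,-z")),
  "C2"       = list(fam = "monoclinic",   gen = c("-x,y,-z", "x+1/2,y+1/2,z")),
  "P222"     = list(fam = "orthorhombic", gen = c("-x,-y,z", "x,-y,-z")),
  "P212121"  = list(fam = "orthorhombic",
                    gen = c("x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2")),
  "C2221"    = list(fam = "orthorhombic",
                    gen = c("-x,-y,z+1/2", "x,-y,-z", "x+1/2,y+1/2,z")),
  "P4"       = list(fam = "tetragonal",   gen = c("-y,x,z")),
  "P41"      = list(fam = "tetragonal",   gen = c("-y,x,z+1/4")),
  "P41212"   = list(fam = "tetragonal",
                    gen = c("-y+1/2,x+1/2,z+1/4", "y,x,-z")),
  "P3"       = list(fam = "trigonal",     gen = c("-y,x-y,z")),
  "P31"      = list(fam = "trigonal",     gen = c("-y,x-y,z+1/3")),
  "P3121"    = list(fam = "trigonal",     gen = c("-y,x-y,z+1/3", "y,x,-z")),
  "P6"       = list(fam = "hexagonal",    gen = c("x-y,x,z")),
  "P61"      = list(fam = "hexagonal",    gen = c("x-y,x,z+1/6")),
  "P213"     = list(fam = "cubic",
                    gen = c("z,x,y", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2")),
  "I213"     = list(fam = "cubic",
                    gen = c("z,x,y", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                            "x+1/2,y+1/2,z+1/2"))
)

#' Supported space-group symbols
#' @return character vector of built-in symbols
#' @export
supportedSpaceGroups <- function() names(.sgTable)

# Close a generator set under composition (mod lattice translations).
closeGroup <- function(rotations, translations) {
  keys <- opKeys(rotations, translations)
  i <- 1L
  while (i <= length(rotations)) {
    for (j in seq_along(rotations)) {
      R <- rotations[[i]] %*% rotations[[j]]
      t12 <- as.integer((rotations[[i]] %*% translations[j, ] +
                         translations[i, ]) %% 12L)
      k <- opKeys(list(R), matrix(t12, 1, 3))
      if (!(k %in% keys)) {
        rotations[[length(rotations) + 1L]] <- R
        translations <- rbind(translations, t12)
        keys <- c(keys, k)
        if (length(rotations) > 192L)
          stop("not a group: generator closure exceeds order 192")
      }
    }
    i <- i + 1L
  }
  rownames(translations) <- NULL
  list(rotations = rotations, translations = translations)
}

# Infer crystal family from the rotation parts (used for triplet input):
# classify by the maximum rotation order and axis count.
inferFamily <- function(rotations) {
  orders <- vapply(rotations, function(R) {
    if (round(det(R)) < 0) R <- -R  # proper part
    M <- diag(3L); o <- 1L
    repeat {
      M <- M %*% R
      if (all(M == diag(3L))) break
      o <- o + 1L
      if (o > 6L) break
    }
    o
  }, integer(1))
  n3 <- sum(orders == 3L); maxo <- max(orders)
  if (n3 >= 8L) return("cubic")          # four body-diagonal 3-folds (x2 each)
  if (maxo == 6L) return("hexagonal")
  if (maxo == 4L) return("tetragonal")
  if (maxo == 3L) return("trigonal")
  n2 <- sum(orders == 2L)
  if (n2 >= 3L) return("orthorhombic")
  if (n2 >= 1L) return("monoclinic")
  "triclinic"
}

#' Parse a space group from a symbol or explicit triplets
#'
#' Builds the full operator list by brute-force closure of the generators.
#' Symbols cover a documented list of common macromolecular groups (see
#' [supportedSpaceGroups()]); any other group must be given as a character
#' vector of "x,y,z"-style triplets (the mmCIF
#' `_symmetry_equiv_pos_as_xyz` notation).
#'
#' @param spec a symbol such as `"P212121"` (spaces ignored), or a character
#'   vector of two or more triplets (or one triplet, for P1)
#' @param family crystal family override for triplet input; inferred from
#'   the rotation orders when `NULL`
#' @return a [SpaceGroup-class]
#' @examples
#' parseSpaceGroup("P21")
#' parseSpaceGroup(c("x,y,z", "-x,y+1/2,-z"))
#' @export
parseSpaceGroup <- function(spec, family = NULL) {
  if (length(spec) == 1L && !grepl(",", spec)) {
    sym <- toupper(gsub("[[:space:]()]", "", spec))
    entry <- .sgTable[[sym]]
    if (is.null(entry))
      stop("unsupported space group: ", spec,
           " (supply explicit triplets instead)")
    ops <- lapply(c("x,y,z", entry$gen), parseTriplet)
    fam <- entry$fam
    symbol <- sym
  } else {
    if (length(spec) < 1L) stop("empty triplet list")
    ops <- lapply(unique(c("x,y,z", spec)), parseTriplet)
    fam <- family
    symbol <- ""
  }
  rotations <- lapply(ops, `[[`, "R")
  translations <- do.call(rbind, lapply(ops, `[[`, "t"))
  keys <- opKeys(rotations, translations)
  dup <- duplicated(keys)
  rotations <- rotations[!dup]
  translations <- translations[!dup, , drop = FALSE]
  closed <- closeGroup(rotations, translations)
  if (!nzchar(symbol) && length(closed$rotations) > length(rotations)) {
    # explicit triplet input must already be the full group (identity aside)
    stop("not a group: triplet list does not close under composition")
  }
  if (is.null(fam)) fam <- inferFamily(closed$rotations)
  new("SpaceGroup", symbol = symbol, rotations = closed$rotations,
      translations = closed$translations, family = fam)
}

# ---- reflection classification ------------------------------------------

# h %*% R for all ops: returns list of n x 3 integer matrices, one per op.
applyRotations <- function(hkl, sg) {
  lapply(sg@rotations, function(R) hkl %*% R)
}

#' Symmetry enhancement factor epsilon
#'
#' Number of operators whose rotation part leaves the Miller index fixed
#' (row-vector action h' = h R). Divides the group order; equals 1 for a
#' general reflection in P1.
#'
#' @param hkl length-3 integer vector or n x 3 matrix
#' @param sg a [SpaceGroup-class]
#' @return integer vector of epsilon factors
#' @export
epsilonFactor <- function(hkl, sg) {
  hkl <- asHKLMatrix(hkl)
  eps <- integer(nrow(hkl))
  for (hR in applyRotations(hkl, sg))
    eps <- eps + as.integer(rowSums(hR == hkl) == 3L)
  eps
}

#' Centric reflection test
#'
#' TRUE where some operator's rotation maps hkl to -hkl; centric
#' reflections have restricted phases and different intensity statistics
#' than acentric ones.
#'
#' @inheritParams epsilonFactor
#' @return logical vector
#' @export
isCentric <- function(hkl, sg) {
  hkl <- asHKLMatrix(hkl)
  cen <- logical(nrow(hkl))
  for (hR in applyRotations(hkl, sg))
    cen <- cen | (rowSums(hR == -hkl) == 3L)
  cen
}

#' Systematic absence test
#'
#' TRUE where some operator fixes hkl by rotation while h.t is not an
#' integer: the translational part (screw axis, glide, centring) forces the
#' structure factor to zero. Exact integer arithmetic in twelfths.
#'
#' @inheritParams epsilonFactor
#' @return logical vector
#' @export
isAbsent <- function(hkl, sg) {
  hkl <- asHKLMatrix(hkl)
  abs_ <- logical(nrow(hkl))
  for (i in seq_len(groupOrder(sg))) {
    hR <- hkl %*% sg@rotations[[i]]
    fixes <- rowSums(hR == hkl) == 3L
    ht <- as.vector(hkl %*% sg@translations[i, ]) %% 12L
    abs_ <- abs_ | (fixes & ht != 0L)
  }
  abs_
}

#' Canonical asymmetric-unit representative
#'
#' Maps each Miller index to its canonical symmetry equivalent: the
#' lexicographically greatest (h, then k, then l) among all `h R` (and
#' their Friedel mates `-h R` unless `anomalous`). Group-agnostic total
#' ordering used as the merging key throughout the package.
#'
#' @inheritParams epsilonFactor
#' @param anomalous if TRUE, Friedel mates are kept distinct
#' @return n x 3 integer matrix of canonical indices
#' @export
asuIndex <- function(hkl, sg, anomalous = FALSE) {
  hkl <- asHKLMatrix(hkl)
  best <- NULL; bestKey <- NULL
  candidates <- applyRotations(hkl, sg)
  if (!anomalous)
    candidates <- c(candidates, lapply(candidates, function(m) -m))
  for (hR in candidates) {
    key <- hklKey(hR)
    if (is.null(best)) {
      best <- hR; bestKey <- key
    } else {
      upd <- key > bestKey
      if (any(upd)) {
        best[upd, ] <- hR[upd, , drop = FALSE]
        bestKey[upd] <- key[upd]
      }
    }
  }
  best
}

# Encode hkl rows as one exactly-representable double for ordering/matching.
# Valid for |index| < 1024.
hklKey <- function(hkl) {
  (hkl[, 1] + 1024) * 2048 * 2048 + (hkl[, 2] + 1024) * 2048 +
    (hkl[, 3] + 1024)
}
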