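#' Read reflection data
#'
#' Reads a structure-factor mmCIF (`_refln` loop) or the package CSV
#' dialect. Cell and symmetry are taken from the file when present
#' (mmCIF `_cell.*` and `_symmetry.space_group_name_H-M` /
#' `_symmetry_equiv.pos_as_xyz`; CSV `# cell` / `# spacegroup` header
#' comments) and may be overridden or supplied through the arguments.
#' Records with index (0,0,0) or without any data value are rejected and
#' counted; the count is attached as attribute `"rejected"` of the returned
#' object and reported with a message.
#'
#' The CSV dialect is: optional `#` metadata comments, then a header line
#' `h,k,l,I,sigI[,Iplus,sigIplus,Iminus,sigIminus,F]`, comma-separated
#' values.
#'
#' @param path file to read
#' @param format `"auto"` (by extension), `"mmcif"` or `"csv"`
#' @param cell optional [UnitCell-class] override
#' @param sg optional space group override (object, symbol or triplets)
#' @return a [ReflectionSet-class]; the `merged` flag reflects the file
#'   content (no symmetry-duplicate indices present)
#' @export
readReflections <- function(path, format = c("auto", "mmcif", "csv"),
                            cell = NULL, sg = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
              else "mmcif"
  parsed <- if (format == "csv") readReflCSV(path) else readReflCIF(path)
  if (!is.null(cell)) parsed$cell <- cell
  if (!is.null(sg))
    parsed$sg <- if (is(sg, "SpaceGroup")) sg else parseSpaceGroup(sg)
  if (is.null(parsed$cell) || is.null(parsed$sg))
    stop("symmetry required: file carries no cell/space group and none given")
  df <- parsed$data
  hasI <- "I" %in% names(df) && any(!is.na(df$I))
  hasAnom <- any(c("Iplus", "Iminus") %in% names(df)) &&
    any(!is.na(df$Iplus) | !is.na(df$Iminus))
  hasF <- "F" %in% names(df) && any(!is.na(df$F))
  if (!hasI && !hasAnom && !hasF) stop("no data columns in ", path)
  bad <- (df$h == 0L & df$k == 0L & df$l == 0L)
  novals <- rep(TRUE, nrow(df))
  for (col in intersect(c("I", "Iplus", "Iminus", "F"), names(df)))
    novals <- novals & is.na(df[[col]])
  reject <- bad | novals
  if (any(reject)) {
    message(sum(reject), " record(s) rejected (null index or no data)")
    df <- df[!reject, , drop = FALSE]
  }
  key <- hklKey(asuIndex(cbind(df$h, df$k, df$l), parsed$sg,
                         anomalous = hasAnom))
  set <- reflectionSet(parsed$cell, parsed$sg, df,
                       merged = !anyDuplicated(key), anomalous = hasAnom)
  attr(set, "rejected") <- sum(reject)
  set
}

#' Write reflection data
#'
#' Inverse of [readReflections()]: emits structure-factor mmCIF or the CSV
#' dialect, embedding cell, symmetry and the merged/anomalous flags so a
#' round trip reproduces indices exactly and values to 6 significant
#' figures.
#'
#' @param set a non-empty [ReflectionSet-class]
#' @param path output file
#' @param format `"auto"` (by extension), `"mmcif"` or `"csv"`
#' @return `path`, invisibly
#' @export
writeReflections <- function(set, path, format = c("auto", "mmcif", "csv")) {
  format <- match.arg(format)
  if (nrow(set@data) == 0L) stop("refusing to write an empty reflection set")
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
              else "mmcif"
  if (format == "csv") writeReflCSV(set, path) else writeReflCIF(set, path)
  invisible(path)
}

.reflCols <- c("I", "sigI", "Iplus", "sigIplus", "Iminus", "sigIminus", "F")

num6 <- function(x) ifelse(is.na(x), "?", sprintf("%.6g", x))

# ---- CSV dialect ---------------------------------------------------------

readReflCSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  getMeta <- function(tag) {
    m <- grep(paste0("^#\\s*", tag, "\\b"), meta, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(paste0("^#\\s*", tag, "\\s*"), "", m[1]))
  }
  cell <- NULL
  cm <- getMeta("cell")
  if (!is.null(cm)) {
    v <- as.numeric(strsplit(cm, "[,[:space:]]+")[[1]])
    if (length(v) == 6 && all(is.finite(v))) cell <- do.call(UnitCell,
                                                             as.list(v))
  }
  sgm <- getMeta("spacegroup")
  sg <- if (!is.null(sgm)) parseSpaceGroup(strsplit(sgm, "\\s*;\\s*")[[1]])
        else NULL
  df <- read.csv(text = paste(body, collapse = "\n"),
                 stringsAsFactors = FALSE)
  if (!all(c("h", "k", "l") %in% names(df)))
    stop("CSV header must contain h,k,l")
  for (col in c("h", "k", "l")) df[[col]] <- as.integer(df[[col]])
  for (col in intersect(.reflCols, names(df)))
    df[[col]] <- as.numeric(df[[col]])
  list(cell = cell, sg = sg, data = df)
}

writeReflCSV <- function(set, path) {
  cols <- intersect(c("h", "k", "l", .reflCols), names(set@data))
  drop <- vapply(set@data[cols], function(x) all(is.na(x)), logical(1))
  cols <- cols[!drop]
  df <- set@data[cols]
  for (col in intersect(.reflCols, cols))
    df[[col]] <- ifelse(is.na(df[[col]]), "", sprintf("%.6g", df[[col]]))
  con <- file(path, "w"); on.exit(close(con))
  cl <- set@cell
  writeLines(c("# refltriage reflection CSV",
               sprintf("# cell %.6g %.6g %.6g %.6g %.6g %.6g",
                       cl@a, cl@b, cl@c, cl@alpha, cl@beta, cl@gamma),
               sprintf("# spacegroup %s",
                       if (nzchar(set@sg@symbol)) set@sg@symbol
                       else paste(spaceGroupTriplets(set@sg),
                                  collapse = " ; "))), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
}

# ---- structure-factor mmCIF ---------------------------------------------

readReflCIF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  items <- list()      # scalar _tag value pairs
  loops <- list()      # each: list(tags=..., values=character token vector)
  i <- 1L
  tok <- function(s) scan(text = s, what = "character", quiet = TRUE,
                          quote = "'\"", strip.white = TRUE)
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line) || grepl("^data_", line)) { i <- i + 1L; next }
    if (identical(tolower(line), "loop_")) {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1L
      }
      vals <- character(0)
      while (i <= n) {
        l2 <- trimws(lines[i])
        if (!nzchar(l2) || grepl("^(_|loop_|data_)", l2)) break
        vals <- c(vals, tok(l2)); i <- i + 1L
      }
      loops[[length(loops) + 1L]] <- list(tags = tolower(tags), values = vals)
    } else if (grepl("^_", line)) {
      parts <- tok(line)
      if (length(parts) >= 2)
        items[[tolower(parts[1])]] <- parts[2]
      i <- i + 1L
    } else i <- i + 1L
  }
  getNum <- function(tag) {
    v <- items[[tag]]
    if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  cellv <- c(getNum("_cell.length_a"), getNum("_cell.length_b"),
             getNum("_cell.length_c"), getNum("_cell.angle_alpha"),
             getNum("_cell.angle_beta"), getNum("_cell.angle_gamma"))
  cell <- if (all(is.finite(cellv))) do.call(UnitCell, as.list(cellv))
          else NULL
  sg <- NULL
  sym <- items[["_symmetry.space_group_name_h-m"]]
  if (!is.null(sym)) sg <- tryCatch(parseSpaceGroup(sym), error = function(e)
    NULL)
  if (is.null(sg)) {
    for (lp in loops) {
      j <- grep("pos_as_xyz", lp$tags)
      if (length(j)) {
        m <- matrix(lp$values, ncol = length(lp$tags), byrow = TRUE)
        sg <- parseSpaceGroup(m[, j[1]])
        break
      }
    }
  }
  refln <- NULL
  for (lp in loops)
    if (any(grepl("^_refln\\.", lp$tags))) { refln <- lp; break }
  if (is.null(refln)) stop("no _refln loop in ", path)
  ncolr <- length(refln$tags)
  if (length(refln$values) %% ncolr != 0L)
    stop("ragged _refln loop in ", path)
  m <- matrix(refln$values, ncol = ncolr, byrow = TRUE)
  colnames(m) <- refln$tags
  numcol <- function(tag) {
    if (!tag %in% refln$tags) return(NULL)
    v <- m[, tag]
    v[v %in% c("?", ".")] <- NA
    suppressWarnings(as.numeric(v))
  }
  df <- data.frame(h = as.integer(numcol("_refln.index_h")),
                   k = as.integer(numcol("_refln.index_k")),
                   l = as.integer(numcol("_refln.index_l")))
  map <- c(I = "_refln.intensity_meas", sigI = "_refln.intensity_sigma",
           Iplus = "_refln.pdbx_i_plus", sigIplus = "_refln.pdbx_i_plus_sigma",
           Iminus = "_refln.pdbx_i_minus",
           sigIminus = "_refln.pdbx_i_minus_sigma",
           F = "_refln.f_meas_au")
  for (col in names(map)) {
    v <- numcol(map[[col]])
    if (!is.null(v)) df[[col]] <- v
  }
  list(cell = cell, sg = sg, data = df)
}

writeReflCIF <- function(set, path) {
  cl <- set@cell
  cols <- intersect(.reflCols, names(set@data))
  cols <- cols[vapply(set@data[cols], function(x) any(!is.na(x)), logical(1))]
  map <- c(I = "_refln.intensity_meas", sigI = "_refln.intensity_sigma",
           Iplus = "_refln.pdbx_I_plus", sigIplus = "_refln.pdbx_I_plus_sigma",
           Iminus = "_refln.pdbx_I_minus",
           sigIminus = "_refln.pdbx_I_minus_sigma",
           F = "_refln.F_meas_au")
  hdr <- c("data_refltriage",
           sprintf("_cell.length_a    %.6g", cl@a),
           sprintf("_cell.length_b    %.6g", cl@b),
           sprintf("_cell.length_c    %.6g", cl@c),
           sprintf("_cell.angle_alpha %.6g", cl@alpha),
           sprintf("_cell.angle_beta  %.6g", cl@beta),
           sprintf("_cell.angle_gamma %.6g", cl@gamma))
  if (nzchar(set@sg@symbol))
    hdr <- c(hdr, sprintf("_symmetry.space_group_name_H-M '%s'",
                          set@sg@symbol))
  hdr <- c(hdr, "loop_", "_symmetry_equiv.pos_as_xyz",
           sprintf("'%s'", spaceGroupTriplets(set@sg)),
           "loop_", "_refln.index_h", "_refln.index_k", "_refln.index_l",
           map[cols])
  rows <- do.call(paste, c(list(set@data$h, set@data$k, set@data$l),
                           lapply(set@data[cols], num6)))
  writeLines(c(hdr, rows), path)
}
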