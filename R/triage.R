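#' Triage configuration
#'
#' All thresholds the triage verdicts use, in one place with documented
#' defaults. Every report echoes the configuration it was produced with;
#' no verdict rule is hidden in code.
#'
#' @param n_shells resolution shells for binned statistics (20)
#' @param l_mean_warn twinning warning when mean |L| falls below this
#'   (0.465; the untwinned expectation is 0.5)
#' @param i2_ratio_warn twinning warning when the acentric second moment
#'   falls below this (1.7; untwinned 2.0, perfect twin 1.5)
#' @param alpha_severe twinning severe when, in addition, a twin-fraction
#'   estimate exceeds this (0.1)
#' @param tncs_threshold_pct tNCS warning when an off-origin Patterson
#'   peak reaches this percent of origin (20)
#' @param tncs_min_distance origin-exclusion radius, Angstrom (10)
#' @param sym_corr_min symmetry-too-low warning requires twin-related
#'   correlation above this (0.95) ...
#' @param sym_rmerge_max ... and merging R under the augmented symmetry
#'   below this (0.1)
#' @param anom_useful anomalous signal called useful when overall
#'   measurability reaches this (0.05)
#' @param ice_z_cut robust z-score for ice-ring flags (5)
#' @param screw_absent_max,screw_present_min screw-axis verdict
#'   thresholds on mean I/sigma of the predicted-absent / -present classes
#'   (1 and 3)
#' @param aniso_delta_warn anisotropy warning when B1 - B3 exceeds this,
#'   Angstrom^2 (10), with ratio above `aniso_ratio_warn` (0.5)
#' @param aniso_ratio_warn see above
#' @param completeness_warn data-quality warning below this overall
#'   completeness (0.85)
#' @param i_over_sigma_warn data-quality warning below this overall mean
#'   I/sigma (2)
#' @param wilson_fit_d_max high-d cutoff of the Wilson fit, Angstrom (4.5)
#' @param grid_factor Patterson samples per d_min (3)
#' @return a named list of class `"TriageConfig"`
#' @export
triageConfig <- function(n_shells = 20, l_mean_warn = 0.465,
                         i2_ratio_warn = 1.7, alpha_severe = 0.1,
                         tncs_threshold_pct = 20, tncs_min_distance = 10,
                         sym_corr_min = 0.95, sym_rmerge_max = 0.1,
                         anom_useful = 0.05, ice_z_cut = 5,
                         screw_absent_max = 1, screw_present_min = 3,
                         aniso_delta_warn = 10, aniso_ratio_warn = 0.5,
                         completeness_warn = 0.85, i_over_sigma_warn = 2,
                         wilson_fit_d_max = 4.5, grid_factor = 3) {
  structure(as.list(environment()), class = "TriageConfig")
}

toolVersion <- function() {
  tryCatch(as.character(utils::packageVersion("refltriage")),
           error = function(e) "unknown")
}

# Serializable snapshots of the S4 inputs.
cellAsList <- function(cell)
  list(a = cell@a, b = cell@b, c = cell@c, alpha = cell@alpha,
       beta = cell@beta, gamma = cell@gamma)

sgAsList <- function(sg)
  list(symbol = sg@symbol, family = sg@family, n_ops = groupOrder(sg),
       triplets = spaceGroupTriplets(sg))

#' Run the full diffraction-data triage
#'
#' Executes every analysis on an input reflection file (or an existing
#' [ReflectionSet-class]) in order: read, merge if needed, resolution
#' shells, completeness and signal-to-noise, Wilson fit, normalization,
#' moments and N(Z), ice rings, anisotropy, screw axes, twin-law
#' enumeration with L/H/Britton/correlation per law, native Patterson tNCS
#' search, and Bijvoet measurability when anomalous data are present. Any
#' stage whose preconditions fail is skipped with a logged reason, never
#' silently. Verdicts are derived from the thresholds in `config` and
#' echoed with their evidence.
#'
#' @param input path to a reflection file, or a [ReflectionSet-class]
#' @param config a [triageConfig()] list
#' @param cell,sg optional overrides passed to [readReflections()]
#' @param seed RNG seed for the seeded analyses (L-test pairing)
#' @return a list of class `"TriageReport"`; see [renderReport()]
#' @export
runTriage <- function(input, config = triageConfig(), cell = NULL,
                      sg = NULL, seed = 1) {
  skipped <- list()
  skip <- function(stage, reason) {
    skipped[[stage]] <<- reason
    NULL
  }
  tryStage <- function(stage, expr)
    tryCatch(expr, error = function(e) skip(stage, conditionMessage(e)))

  set <- if (is(input, "ReflectionSet")) input
         else readReflections(input, cell = cell, sg = sg)
  path <- if (is.character(input)) input else "<in-memory>"

  merge_stats <- NULL
  if (!set@merged) {
    m <- mergeEquivalents(set)
    set <- m$set
    merge_stats <- m$stats
  }
  dr <- dRange(set)
  scheme <- binResolution(set, n_shells = config$n_shells)

  comp <- tryStage("completeness", completeness(set, scheme))
  ios <- tryStage("i_over_sigma", iOverSigma(set, scheme))
  wilson <- tryStage("wilson", wilsonFit(
    set, fit_d_max = config$wilson_fit_d_max, scheme = scheme))
  norm <- normalizeIntensities(set, scheme)
  mom <- tryStage("moments", momentStats(norm))
  nz <- tryStage("nz_curves", nzCurves(norm))
  ice <- tryStage("ice_rings", iceRingScan(set, z_cut = config$ice_z_cut))
  aniso <- tryStage("anisotropy", anisoFit(set))
  screws <- tryStage("screw_axes", detectScrewAxes(
    set, absent_max = config$screw_absent_max,
    present_min = config$screw_present_min))
  ltest <- tryStage("l_test", lTest(set, seed = seed))

  laws <- candidateTwinLaws(set@cell, set@sg)
  twin <- lapply(laws, function(law) {
    res <- list(law = list(kind = law@kind,
                           description = law@description,
                           operator = unname(apply(law@operator, 1, c,
                                                   simplify = FALSE))))
    res$h_test <- tryCatch(hTest(set, law), error = function(e)
      list(error = conditionMessage(e)))
    res$britton <- tryCatch(
      britton(set, law)[c("alpha_estimate", "flag")],
      error = function(e) list(error = conditionMessage(e)))
    res$correlation <- tryCatch(twinCorrelation(set, law),
                                error = function(e)
                                  list(error = conditionMessage(e)))
    res$r_merge_augmented <- tryCatch(
      augmentedRmerge(set, law), error = function(e) NA_real_)
    res
  })

  tncs <- tryStage("tncs", {
    grid <- nativePatterson(set, grid_factor = config$grid_factor)
    findTncsPeaks(grid, min_distance = config$tncs_min_distance,
                  threshold_pct = 5)  # report small peaks; verdict uses cut
  })

  anom <- NULL
  if (set@anomalous &&
      all(c("Iplus", "Iminus") %in% names(set@data))) {
    anom <- tryStage("anomalous", measurability(bijvoetPairs(set)))
  } else skipped[["anomalous"]] <- "no Bijvoet-separated data"

  verdicts <- buildVerdicts(config, ltest, mom, twin, tncs, ice, aniso,
                            screws, comp, ios, anom)
  structure(list(
    schema_version = "1.0",
    tool = list(name = "refltriage", version = toolVersion()),
    seed = seed,
    config = unclass(config),
    input = list(path = path, cell = cellAsList(set@cell),
                 spacegroup = sgAsList(set@sg), n_unique = nrow(set@data),
                 d_min = unname(dr["d_min"]), d_max = unname(dr["d_max"]),
                 anomalous = set@anomalous),
    merge_stats = merge_stats,
    completeness = comp, i_over_sigma = ios, wilson = wilson,
    moments = if (!is.null(mom)) unclass(mom) else NULL,
    nz = nz, ice_rings = ice,
    anisotropy = if (!is.null(aniso)) unclass(aniso) else NULL,
    screw_axes = screws,
    l_test = if (!is.null(ltest)) ltest[c("mean_abs_L", "mean_L2",
                                          "n_pairs")] else NULL,
    twin_laws = twin,
    tncs_peaks = tncs,
    anomalous = if (!is.null(anom)) unclass(anom) else NULL,
    skipped = skipped,
    verdicts = verdicts), class = "TriageReport")
}

# Merging R that would result if the twin operator were a symmetry
# operator: near-zero values mean the assigned symmetry is too low.
augmentedRmerge <- function(set, law) {
  rot <- c(set@sg@rotations, list(lawMatrix(law)))
  tr <- rbind(set@sg@translations, c(0L, 0L, 0L))
  closed <- closeGroup(rot, tr)
  sgAug <- new("SpaceGroup", symbol = "", rotations = closed$rotations,
               translations = closed$translations,
               family = inferFamily(closed$rotations))
  df <- set@data
  df$sigI[is.na(df$sigI)] <- 1
  m <- mergeEquivalents(reflectionSet(set@cell, sgAug,
                                      df[, c("h", "k", "l", "I", "sigI")],
                                      merged = FALSE))
  m$stats$r_merge
}

alphaEstimates <- function(twin) {
  unlist(lapply(twin, function(tw) {
    c(if (is.null(tw$h_test$error)) tw$h_test$alpha_mean,
      if (is.null(tw$britton$error) && identical(tw$britton$flag, "ok"))
        tw$britton$alpha_estimate)
  }))
}

buildVerdicts <- function(config, ltest, mom, twin, tncs, ice, aniso,
                          screws, comp, ios, anom) {
  v <- list()
  verdict <- function(topic, status, evidence, thresholds)
    list(topic = topic, status = status, evidence = evidence,
         thresholds = thresholds)

  # twinning
  if (!is.null(ltest) || !is.null(mom)) {
    lmean <- if (!is.null(ltest)) ltest$mean_abs_L else NA_real_
    i2 <- if (!is.null(mom)) mom$acentric$i2_over_i_sq else NA_real_
    alphas <- alphaEstimates(twin)
    suspicious <- (is.finite(lmean) && lmean < config$l_mean_warn) ||
      (is.finite(i2) && i2 < config$i2_ratio_warn)
    status <- if (!suspicious) "ok"
      else if (length(alphas) && max(alphas) > config$alpha_severe)
        "severe" else "warning"
    v$twinning <- verdict("twinning", status,
      list(mean_abs_L = lmean, acentric_i2_over_i_sq = i2,
           alpha_estimates = if (length(alphas)) alphas else NA_real_),
      list(l_mean_warn = config$l_mean_warn,
           i2_ratio_warn = config$i2_ratio_warn,
           alpha_severe = config$alpha_severe))
  }

  # tNCS
  if (!is.null(tncs)) {
    big <- tncs[tncs$height_pct >= config$tncs_threshold_pct, ,
                drop = FALSE]
    v$tncs <- verdict("tncs",
      if (nrow(big)) "warning" else "ok",
      list(n_peaks = nrow(big),
           top_peak = if (nrow(tncs)) as.list(tncs[1, ]) else NULL),
      list(threshold_pct = config$tncs_threshold_pct,
           min_distance = config$tncs_min_distance))
  }

  # ice rings
  if (!is.null(ice) && !isTRUE(ice$skipped)) {
    v$ice_rings <- verdict("ice_rings",
      if (nrow(ice$ice)) "warning" else "ok",
      list(n_flagged = nrow(ice$ice),
           d_flagged = if (nrow(ice$ice)) ice$ice$d else NA_real_,
           n_other_anomalies = nrow(ice$anomalies)),
      list(z_cut = config$ice_z_cut))
  }

  # screw axes (informational: detected screws are reported, not warned)
  if (!is.null(screws)) {
    found <- screws[screws$verdict == "screw present", , drop = FALSE]
    v$screw_axes <- verdict("screw_axes", "ok",
      list(detected = if (nrow(found))
        paste(found$screw, "along", found$axis) else "none"),
      list(absent_max = config$screw_absent_max,
           present_min = config$screw_present_min))
  }

  # anisotropy
  if (!is.null(aniso)) {
    v$anisotropy <- verdict("anisotropy",
      if (aniso$delta_B > config$aniso_delta_warn &&
          aniso$ratio > config$aniso_ratio_warn) "warning" else "ok",
      list(delta_B = aniso$delta_B, ratio = aniso$ratio,
           eigenvalues = aniso$eigenvalues),
      list(aniso_delta_warn = config$aniso_delta_warn,
           aniso_ratio_warn = config$aniso_ratio_warn))
  }

  # anomalous signal
  if (!is.null(anom)) {
    v$anomalous_signal <- verdict("anomalous_signal",
      "ok",
      list(measurability = anom$measurability,
           useful = anom$measurability >= config$anom_useful),
      list(anom_useful = config$anom_useful))
  }

  # data quality
  if (!is.null(comp) || !is.null(ios)) {
    cv <- if (!is.null(comp)) comp$overall else NA_real_
    iv <- if (!is.null(ios)) ios$overall else NA_real_
    bad <- (is.finite(cv) && cv < config$completeness_warn) ||
      (is.finite(iv) && iv < config$i_over_sigma_warn)
    v$data_quality <- verdict("data_quality",
      if (bad) "warning" else "ok",
      list(completeness = cv, i_over_sigma = iv),
      list(completeness_warn = config$completeness_warn,
           i_over_sigma_warn = config$i_over_sigma_warn))
  }

  # symmetry too low
  if (length(twin)) {
    corr <- vapply(twin, function(tw)
      if (is.null(tw$correlation$error))
        tw$correlation$correlation else NA_real_, numeric(1))
    raug <- vapply(twin, function(tw)
      if (is.numeric(tw$r_merge_augmented)) tw$r_merge_augmented
      else NA_real_, numeric(1))
    hit <- which(is.finite(corr) & corr > config$sym_corr_min &
                 is.finite(raug) & raug < config$sym_rmerge_max)
    v$symmetry_too_low <- verdict("symmetry_too_low",
      if (length(hit)) "warning" else "ok",
      list(max_correlation = if (any(is.finite(corr)))
             max(corr, na.rm = TRUE) else NA_real_,
           min_r_merge_augmented = if (any(is.finite(raug)))
             min(raug, na.rm = TRUE) else NA_real_),
      list(sym_corr_min = config$sym_corr_min,
           sym_rmerge_max = config$sym_rmerge_max))
  }
  unname(v)
}

#' Worst verdict status of a report
#' @param report a `"TriageReport"`
#' @return 0 (all ok), 1 (warning) or 2 (severe) - the CLI exit code
#' @export
worstStatus <- function(report) {
  st <- vapply(report$verdicts, `[[`, character(1), "status")
  if (any(st == "severe")) 2L else if (any(st == "warning")) 1L else 0L
}

#' Render a triage report
#'
#' `"json"` produces a schema-versioned, lossless document (parse it back
#' with [jsonlite::fromJSON]); `"text"` a human-readable summary with one
#' verdict line per topic first, then the headline statistics, then any
#' stages that were not performed and why.
#'
#' @param report a `"TriageReport"` from [runTriage()]
#' @param format `"text"` or `"json"`
#' @return a character scalar (JSON) or vector of lines (text)
#' @export
renderReport <- function(report, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json")
    return(as.character(jsonlite::toJSON(
      unclass(report), auto_unbox = TRUE, digits = NA, null = "null",
      dataframe = "columns")))
  ln <- c(sprintf("refltriage %s triage report", report$tool$version),
          sprintf("input: %s (%d unique, %.2f-%.2f A, %s)",
                  report$input$path, report$input$n_unique,
                  report$input$d_max, report$input$d_min,
                  report$input$spacegroup$symbol),
          "", "verdicts:")
  for (v in report$verdicts) {
    ev <- v$evidence
    evtxt <- paste(vapply(names(ev), function(nm) {
      val <- ev[[nm]]
      if (is.numeric(val) && length(val) <= 3)
        paste0(nm, "=", paste(signif(val, 4), collapse = "/"))
      else if (is.character(val) || is.logical(val))
        paste0(nm, "=", paste(val, collapse = ","))
      else nm
    }, character(1)), collapse = "  ")
    ln <- c(ln, sprintf("  [%-7s] %-17s %s", v$status, v$topic, evtxt))
  }
  ln <- c(ln, "")
  if (!is.null(report$wilson))
    ln <- c(ln, sprintf("Wilson: B = %.1f A^2, K = %.3g",
                        report$wilson$B_iso, report$wilson$K))
  if (!is.null(report$l_test))
    ln <- c(ln, sprintf("L-test: <|L|> = %.3f, <L^2> = %.3f (%d pairs)",
                        report$l_test$mean_abs_L, report$l_test$mean_L2,
                        report$l_test$n_pairs))
  if (!is.null(report$completeness))
    ln <- c(ln, sprintf("completeness: %.1f%%",
                        100 * report$completeness$overall))
  if (!is.null(report$i_over_sigma))
    ln <- c(ln, sprintf("mean I/sigma: %.1f",
                        report$i_over_sigma$overall))
  if (length(report$skipped)) {
    ln <- c(ln, "", "not performed:")
    for (nm in names(report$skipped))
      ln <- c(ln, sprintf("  %s: %s", nm, report$skipped[[nm]]))
  }
  ln
}

#' @export
print.TriageReport <- function(x, ...) {
  cat(renderReport(x, "text"), sep = "\n")
  invisible(x)
}
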