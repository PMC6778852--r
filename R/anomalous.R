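#' Match Bijvoet pairs
#'
#' Collects, for every acentric unique reflection of an anomalous set, the
#' Bijvoet-separated intensity pair (I+, sigma+, I-, sigma-). Centric
#' reflections are excluded (their true anomalous difference is zero by
#' symmetry); entries with only one mate measured are counted as singles.
#'
#' @param set an anomalous [ReflectionSet-class] with Bijvoet columns
#' @return list: `pairs` data.frame (h, k, l, d, Iplus, sigIplus, Iminus,
#'   sigIminus), `n_singles`, `n_centric_excluded`,
#'   `anom_completeness` = fraction of acentric uniques with both mates
#' @export
bijvoetPairs <- function(set) {
  df <- set@data
  if (!all(c("Iplus", "Iminus") %in% names(df)) ||
      (all(is.na(df$Iplus)) && all(is.na(df$Iminus))))
    stop("no anomalous data: Bijvoet columns missing or empty")
  cen <- isCentric(hklMatrix(set), set@sg)
  acen <- df[!cen, , drop = FALSE]
  both <- !is.na(acen$Iplus) & !is.na(acen$Iminus)
  pairs <- acen[both, c("h", "k", "l", "d", "Iplus", "sigIplus",
                        "Iminus", "sigIminus")]
  rownames(pairs) <- NULL
  single <- xor(!is.na(acen$Iplus), !is.na(acen$Iminus))
  list(pairs = pairs, n_singles = sum(single),
       n_centric_excluded = sum(cen),
       anom_completeness = sum(both) / max(nrow(acen), 1L))
}

#' Anomalous measurability
#'
#' Fraction of Bijvoet pairs whose intensity difference is statistically
#' significant: |I+ - I-| / sqrt(sigma+^2 + sigma-^2) > `sigma_cut`,
#' reported overall and per resolution shell, together with the mean
#' significance ratio. Under pure noise the expected fraction is the
#' two-sided normal tail (0.27% at 3 sigma); values well above that
#' indicate achieved anomalous signal usable for phasing.
#'
#' @param pairs output of [bijvoetPairs()] (or its `pairs` data.frame)
#' @param sigma_cut significance threshold in sigmas (default 3)
#' @param n_shells resolution shells for the per-shell table (default 10)
#' @return list of class `"AnomalousReport"`: measurability,
#'   mean_dI_over_sig, shells data.frame, anom_completeness (NA when a
#'   bare data.frame was supplied), sigma_cut, n_pairs
#' @export
measurability <- function(pairs, sigma_cut = 3.0, n_shells = 10) {
  comp <- NA_real_
  if (is.list(pairs) && !is.data.frame(pairs)) {
    comp <- pairs$anom_completeness
    pairs <- pairs$pairs
  }
  if (nrow(pairs) == 0L) stop("empty Bijvoet pair set")
  ratio <- abs(pairs$Iplus - pairs$Iminus) /
    sqrt(pairs$sigIplus^2 + pairs$sigIminus^2)
  sig <- ratio > sigma_cut
  # equal-count resolution bins for the per-shell table
  ns <- max(1L, min(n_shells, floor(nrow(pairs) / 50)))
  qs <- unique(quantile(pairs$d, probs = seq(1, 0, length.out = ns + 1)))
  bin <- cut(pairs$d, breaks = rev(qs), include.lowest = TRUE)
  shells <- data.frame(
    d_mid = as.numeric(tapply(pairs$d, bin, median)),
    n = as.integer(table(bin)),
    measurability = as.numeric(tapply(sig, bin, mean)),
    mean_dI_over_sig = as.numeric(tapply(ratio, bin, mean)))
  shells <- shells[order(-shells$d_mid), ]
  rownames(shells) <- NULL
  structure(list(measurability = mean(sig),
                 mean_dI_over_sig = mean(ratio), shells = shells,
                 anom_completeness = comp, sigma_cut = sigma_cut,
                 n_pairs = nrow(pairs)),
            class = "AnomalousReport")
}
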