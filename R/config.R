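#' Pipeline configuration
#'
#' Bundles the thresholds of the filter cascade. Defaults follow the
#' processing rules the pipeline implements: a 20,000-count noise floor, a
#' limit of detection (LOD) of three times the median blank signal, a 60%
#' replicate detection rule, median +/- 2.5 * MAD whole-sample outlier
#' bounds with at least 4 of 5 replicates retained, a discard rule for
#' compound/condition cells with fewer than 3 surviving values, a 15% RSD
#' repeatability threshold and a 0.05 significance level.
#'
#' @param noise_floor Minimum LOD in counts (cps).
#' @param lod_blank_multiplier LOD = max(multiplier * median blank, floor).
#' @param detection_fraction Minimum fraction of replicates in which a
#'   compound must be detected in a condition (normally 3 of 5).
#' @param outlier_mad_multiplier Half-width of the outlier bounds in unscaled
#'   MAD units.
#' @param min_values_per_condition Cells with fewer surviving values are
#'   discarded.
#' @param min_retained_replicates Outlier removal never reduces a condition
#'   below this many replicates.
#' @param rsd_threshold_pct Repeatability acceptance threshold (percent,
#'   strict `<`).
#' @param alpha Significance level for condition comparisons.
#' @param redetect_after_outliers Re-run the detection rule on the replicate
#'   set that survives outlier removal (so the 60% rule uses the retained
#'   denominator).
#' @param seed Optional integer seed recorded alongside results.
#' @return A `qc_config` list.
#' @export
qc_config <- function(noise_floor = 20000,
                      lod_blank_multiplier = 3,
                      detection_fraction = 0.60,
                      outlier_mad_multiplier = 2.5,
                      min_values_per_condition = 3L,
                      min_retained_replicates = 4L,
                      rsd_threshold_pct = 15,
                      alpha = 0.05,
                      redetect_after_outliers = TRUE,
                      seed = NULL) {
  cfg <- list(
    noise_floor = noise_floor,
    lod_blank_multiplier = lod_blank_multiplier,
    detection_fraction = detection_fraction,
    outlier_mad_multiplier = outlier_mad_multiplier,
    min_values_per_condition = as.integer(min_values_per_condition),
    min_retained_replicates = as.integer(min_retained_replicates),
    rsd_threshold_pct = rsd_threshold_pct,
    alpha = alpha,
    redetect_after_outliers = isTRUE(redetect_after_outliers),
    seed = seed
  )
  num <- c("noise_floor", "lod_blank_multiplier", "detection_fraction",
           "outlier_mad_multiplier", "min_values_per_condition",
           "min_retained_replicates", "rsd_threshold_pct", "alpha")
  for (nm in num) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("config field '%s' must be a single positive number", nm))
    }
  }
  if (cfg$detection_fraction > 1) {
    abort("detection_fraction must lie in (0, 1]")
  }
  if (cfg$alpha >= 1) {
    abort("alpha must lie in (0, 1)")
  }
  structure(cfg, class = "qc_config")
}

#' @export
print.qc_config <- function(x, ...) {
  cat("<qc_config>\n")
  for (nm in setdiff(names(x), "seed")) {
    cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  }
  if (!is.null(x$seed)) cat(sprintf("  %-26s %s\n", "seed", x$seed))
  invisible(x)
}
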