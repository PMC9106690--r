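#' Relative concentration ladder of a serial dilution design
#'
#' @param factors Dilution factors, `>= 1` and strictly increasing; the
#'   default is the fourteen-point ladder 1:1.2 ... 1:100.
#' @return A tibble with `level`, `dilution_factor` and `rel_conc`
#'   (`1 / factor`), ordered from the least diluted level.
#' @export
#' @examples
#' dilution_design()           # 14 levels
#' dilution_design(c(2, 100))  # rel_conc 0.5, 0.01
dilution_design <- function(factors = default_dilution_factors) {
  if (length(factors) == 0 || any(factors < 1) || any(diff(factors) <= 0)) {
    abort("dilution factors must be >= 1 and strictly increasing")
  }
  tibble(level = seq_along(factors), dilution_factor = factors,
         rel_conc = 1 / factors)
}

#' Assess the relative-quantification range over a dilution series
#'
#' Judges, per compound, whether the measured response tracks a serial
#' dilution well enough for relative quantification. Individual injections
#' are first subjected to the LOD filter (strictly above the compound's
#' LOD); a dilution level survives only if at least `min_replicates_per_level`
#' of its injections do, and its response is the mean of the surviving
#' injections. Over the surviving levels the assessment computes the
#' Spearman correlation of level response versus relative concentration and
#' the linear range: the longest contiguous run of levels, anchored at the
#' least-diluted surviving level, over which responses strictly increase
#' with concentration and a least-squares fit of response on relative
#' concentration reaches `R^2 >= r2_min`. The verdict is
#' `QUANTIFIABLE_RELATIVE` when the linear range spans every level of the
#' design, `PARTIAL_RANGE` when it covers fewer (whether levels were lost to
#' the LOD filter or to non-linearity), and `EXCLUDED_BELOW_LOD` when all
#' levels fail the LOD filter or fewer than `min_levels` survive.
#'
#' @param records DILUTION injection records: a tibble with columns
#'   `compound`, `dilution_factor`, `value` (e.g. from
#'   [simulate_dilution_series()] or the DILUTION rows of a read plate).
#' @param lods LOD table from [compute_lod()] (columns `compound`, `lod`),
#'   or a single number applied to every compound.
#' @param config A [qc_config()] (currently unused beyond defaults; kept so
#'   assessments and QC runs share one configuration object).
#' @param r2_min Minimum R^2 of the linear fit over the range.
#' @param min_levels Minimum surviving levels for an assessable compound.
#' @param min_replicates_per_level Minimum surviving injections per level.
#' @return A `dilution_assessment` object: `assessments` has one row per
#'   compound (`compound`, `n_levels`, `n_levels_surviving`, `spearman_rho`,
#'   `linear_range_levels`, `range_min_factor`, `range_max_factor`,
#'   `verdict`, `excluded_reason`), `levels` holds the per-level responses.
#' @export
assess_dilution <- function(records, lods, config = qc_config(),
                            r2_min = 0.9, min_levels = 4,
                            min_replicates_per_level = 2) {
  records <- as_tibble(records)
  stopifnot(all(c("compound", "dilution_factor", "value") %in%
                  names(records)))
  if (is.numeric(lods) && is.null(dim(lods))) {
    lods <- tibble(compound = unique(records$compound), lod = lods)
  }
  factors <- sort(unique(records$dilution_factor))
  design <- dilution_design(factors)

  lvl <- records %>%
    left_join(select(as_tibble(lods), "compound", "lod"), by = "compound") %>%
    mutate(above_lod = !is.na(.data$value) & .data$value > .data$lod) %>%
    group_by(.data$compound, .data$dilution_factor) %>%
    summarise(
      n_injections = n(),
      n_above_lod = sum(.data$above_lod),
      mean_response = if (sum(.data$above_lod) >= !!min_replicates_per_level)
        mean(.data$value[.data$above_lod]) else NA_real_,
      .groups = "drop"
    ) %>%
    left_join(design, by = "dilution_factor") %>%
    mutate(surviving = !is.na(.data$mean_response)) %>%
    arrange(.data$compound, .data$level)

  assess_one <- function(d) {
    surv <- filter(d, .data$surviving)
    if (sum(d$n_above_lod) == 0) {
      return(tibble(
        n_levels = nrow(d), n_levels_surviving = 0L,
        spearman_rho = NA_real_, linear_range_levels = 0L,
        range_min_factor = NA_real_, range_max_factor = NA_real_,
        verdict = "EXCLUDED_BELOW_LOD",
        excluded_reason = "all injections below LOD"
      ))
    }
    if (nrow(surv) < min_levels) {
      return(tibble(
        n_levels = nrow(d), n_levels_surviving = nrow(surv),
        spearman_rho = NA_real_, linear_range_levels = 0L,
        range_min_factor = NA_real_, range_max_factor = NA_real_,
        verdict = "EXCLUDED_BELOW_LOD",
        excluded_reason = "insufficient levels"
      ))
    }
    rho <- suppressWarnings(
      cor(surv$mean_response, surv$rel_conc, method = "spearman"))
    # linear range: anchored at the least-diluted surviving level
    m <- surv$mean_response
    best <- 0L
    for (j in 2:nrow(surv)) {
      if (!all(diff(m[1:j]) < 0)) break   # strictly increasing with conc
      # R^2 of the simple least-squares fit response ~ rel_conc
      r2 <- suppressWarnings(cor(m[1:j], surv$rel_conc[1:j]))^2
      if (is.na(r2) || r2 < r2_min) break
      best <- j
    }
    tibble(
      n_levels = nrow(d), n_levels_surviving = nrow(surv),
      spearman_rho = rho,
      linear_range_levels = best,
      range_min_factor = if (best > 0) surv$dilution_factor[1] else NA_real_,
      range_max_factor = if (best > 0) surv$dilution_factor[best] else NA_real_,
      verdict = if (best == nrow(d)) "QUANTIFIABLE_RELATIVE"
                else "PARTIAL_RANGE",
      excluded_reason = NA_character_
    )
  }

  assessments <- lvl %>%
    group_by(.data$compound) %>%
    dplyr::group_modify(~ assess_one(.x)) %>%
    ungroup()

  structure(list(assessments = assessments, levels = lvl,
                 r2_min = r2_min, min_levels = min_levels),
            class = "dilution_assessment")
}

#' @export
print.dilution_assessment <- function(x, ...) {
  tt <- table(x$assessments$verdict)
  cat(sprintf("<dilution_assessment: %d compounds (%s)>\n",
              nrow(x$assessments),
              paste(sprintf("%s %d", names(tt), tt), collapse = ", ")))
  invisible(x)
}

#' @method tidy dilution_assessment
#' @export
tidy.dilution_assessment <- function(x, ...) x$assessments

#' @method glance dilution_assessment
#' @export
glance.dilution_assessment <- function(x, ...) {
  a <- x$assessments
  tibble(
    n_compounds = nrow(a),
    n_quantifiable = sum(a$verdict == "QUANTIFIABLE_RELATIVE"),
    n_partial = sum(a$verdict == "PARTIAL_RANGE"),
    n_excluded = sum(a$verdict == "EXCLUDED_BELOW_LOD"),
    median_rho = median(a$spearman_rho, na.rm = TRUE)
  )
}
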