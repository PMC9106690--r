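default_dilution_factors <- c(1.2, 1.4, 1.6, 1.8, 2, 3, 5, 7.5, 10, 15, 20,
                              30, 50, 100)

default_conditions <- c("5mg_10uL", "15mg_10uL", "25mg_10uL",
                        "5mg_20uL", "15mg_20uL", "25mg_20uL")

#' Scenario configuration for the synthetic plate generator
#'
#' Describes one emulated kit plate: the panel, the experimental conditions
#' (default: six cell-mass x loading-volume combinations with five
#' biological replicates each), PBS blank and pooled-QC injections, the
#' per-compound signal model, planted pathologies (whole-sample outliers,
#' compounds sitting below the noise floor), and the serial dilution ladder
#' (fourteen factors from 1:1.2 to 1:100, three replicate injections each).
#'
#' Signals are log-normal, parameterized so the arithmetic coefficient of
#' variation equals `cv` (`sdlog^2 = log(1 + cv^2)`); intensities are
#' strictly positive and the configured CV is recoverable from the data.
#'
#' @param panel A panel from [load_panel()].
#' @param conditions Character vector of condition labels.
#' @param replicates_per_condition Biological replicates per condition.
#' @param blank_count Number of PBS blank injections (>= 3).
#' @param pooled_qc_count Number of pooled QC injections.
#' @param true_mean Expected signal in counts. A single number, or a tibble
#'   with a `true_mean` column plus any of `compound`, `class`, `condition`
#'   key columns; more specific rows override less specific ones.
#' @param cv Coefficient of variation (proportion, in (0, 2)). Scalar or
#'   tibble with a `cv` column, keyed as for `true_mean`.
#' @param below_floor_compounds Compounds whose true mean is forced to
#'   `below_floor_mean`, i.e. planted under the noise floor.
#' @param below_floor_mean Mean signal assigned to below-floor compounds.
#' @param outlier_samples Tibble with columns `condition`, `replicate`,
#'   `scale_factor` (`!= 1`): whole-sample outliers whose every compound
#'   signal is scaled.
#' @param istd_mean,istd_cv Internal-standard signal model.
#' @param blank_median,blank_cv Blank signal model: log-normal with the given
#'   median, so the 3x-median LOD rule and the 20,000-count floor can each be
#'   made binding.
#' @param sensitivity Global plate sensitivity multiplier applied to every
#'   measured signal (emulates instrument sensitivity drift between runs).
#' @param dilution_factors Serial dilution factors, strictly increasing.
#' @param dilution_replicates Injections per dilution level.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(panel = load_panel("p400"),
                            conditions = default_conditions,
                            replicates_per_condition = 5L,
                            blank_count = 3L,
                            pooled_qc_count = 5L,
                            true_mean = 2e5,
                            cv = 0.10,
                            below_floor_compounds = character(0),
                            below_floor_mean = 5000,
                            outlier_samples = NULL,
                            istd_mean = 1e5,
                            istd_cv = 0.05,
                            blank_median = 2000,
                            blank_cv = 0.5,
                            sensitivity = 1,
                            dilution_factors = default_dilution_factors,
                            dilution_replicates = 3L,
                            seed = NULL) {
  if (replicates_per_condition < 3) {
    abort(paste("replicates_per_condition must be at least 3;",
                "the detection and sparse-cell rules could never retain anything"))
  }
  if (blank_count < 3) abort("blank_count must be at least 3")
  cv_values <- if (is.data.frame(cv)) cv$cv else cv
  if (any(cv_values <= 0 | cv_values >= 2)) {
    abort("cv values must lie in (0, 2)")
  }
  if (!is.null(outlier_samples)) {
    outlier_samples <- as_tibble(outlier_samples)
    stopifnot(all(c("condition", "replicate", "scale_factor") %in%
                    names(outlier_samples)))
    if (any(outlier_samples$scale_factor == 1)) {
      abort("planted outliers must have scale_factor != 1")
    }
  } else {
    outlier_samples <- tibble(condition = character(0),
                              replicate = integer(0),
                              scale_factor = numeric(0))
  }
  if (any(diff(dilution_factors) <= 0) || any(dilution_factors < 1)) {
    abort("dilution_factors must be >= 1 and strictly increasing")
  }
  bad <- setdiff(below_floor_compounds, panel$compound)
  if (length(bad) > 0) {
    abort(sprintf("below_floor_compounds not in panel: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  structure(list(
    panel = panel, conditions = conditions,
    replicates_per_condition = as.integer(replicates_per_condition),
    blank_count = as.integer(blank_count),
    pooled_qc_count = as.integer(pooled_qc_count),
    true_mean = true_mean, cv = cv,
    below_floor_compounds = below_floor_compounds,
    below_floor_mean = below_floor_mean,
    outlier_samples = outlier_samples,
    istd_mean = istd_mean, istd_cv = istd_cv,
    blank_median = blank_median, blank_cv = blank_cv,
    sensitivity = sensitivity,
    dilution_factors = dilution_factors,
    dilution_replicates = as.integer(dilution_replicates),
    seed = seed
  ), class = "scenario_config")
}

# Resolve a scalar-or-tibble parameter spec onto the compound x condition
# grid; rows with more key columns filled override less specific ones.
resolve_param <- function(grid, spec, value_col, default) {
  grid[[value_col]] <- default
  if (is.null(spec)) return(grid)
  if (is.numeric(spec) && length(spec) == 1) {
    grid[[value_col]] <- spec
    return(grid)
  }
  spec <- as_tibble(spec)
  stopifnot(value_col %in% names(spec))
  keys <- intersect(c("compound", "class", "condition"), names(spec))
  spec$.n_keys <- rowSums(!is.na(spec[, keys, drop = FALSE]))
  spec <- arrange(spec, .data$.n_keys)
  for (i in seq_len(nrow(spec))) {
    match_rows <- rep(TRUE, nrow(grid))
    for (k in keys) {
      if (!is.na(spec[[k]][i])) {
        match_rows <- match_rows & grid[[k]] == spec[[k]][i]
      }
    }
    grid[[value_col]][match_rows] <- spec[[value_col]][i]
  }
  grid
}

# CV-faithful log-normal draws: arithmetic mean = mean, arithmetic CV = cv.
rlnorm_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

signal_grid <- function(config) {
  grid <- tidyr::expand_grid(
    as_tibble(config$panel)[, c("compound", "class", "measurement_type",
                                "istd")],
    condition = config$conditions
  ) %>%
    resolve_param(config$true_mean, "true_mean", 2e5) %>%
    resolve_param(config$cv, "cv", 0.10)
  grid$true_mean[grid$compound %in% config$below_floor_compounds] <-
    config$below_floor_mean
  grid
}

#' Simulate a plate with known ground truth
#'
#' Generates a full [plate_dataset()] -- PBS blanks, condition/replicate
#' sample injections, pooled QC injections and per-injection
#' internal-standard signals -- under the scenario's signal model, plus the
#' ground truth needed to verify every downstream pipeline stage. All
#' randomness flows from one stream seeded once, drawn in plate order
#' (blanks, then samples by condition and replicate, then pooled QC; within
#' an injection, compounds in panel order, then internal standards), so a
#' given seed yields a bit-identical dataset.
#'
#' @param config A [scenario_config()].
#' @return A list of class `plateqc_simulation` with elements `plate` (a
#'   [plate_dataset()]) and `truth` (planted outliers, below-floor
#'   compounds, and the per-compound/condition true means and CVs).
#' @export
#' @examples
#' sim <- simulate_plate(scenario_config(seed = 1))
#' sim$plate
simulate_plate <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  panel <- as_tibble(config$panel)
  grid <- signal_grid(config)
  istd_ids <- unique(panel$istd)

  # --- blanks ---------------------------------------------------------------
  blank_ids <- sprintf("BLANK_%02d", seq_len(config$blank_count))
  blanks <- tidyr::expand_grid(sample_id = blank_ids,
                               compound = panel$compound) %>%
    mutate(value = config$sensitivity *
             rlnorm(n(), meanlog = log(config$blank_median),
                    sdlog = sqrt(log(1 + config$blank_cv^2))))
  blank_istd <- tidyr::expand_grid(sample_id = blank_ids, istd = istd_ids) %>%
    mutate(value = config$sensitivity *
             rlnorm_cv(n(), config$istd_mean, config$istd_cv))

  # --- samples --------------------------------------------------------------
  inj <- tidyr::expand_grid(condition = config$conditions,
                            replicate = seq_len(config$replicates_per_condition)) %>%
    mutate(sample_id = sprintf("S_%s_R%d", .data$condition, .data$replicate)) %>%
    left_join(config$outlier_samples, by = c("condition", "replicate")) %>%
    mutate(scale_factor = if_else(is.na(.data$scale_factor), 1,
                                  .data$scale_factor))
  values <- inj %>%
    left_join(grid, by = "condition",
              relationship = "many-to-many") %>%
    arrange(match(.data$sample_id, inj$sample_id),
            match(.data$compound, panel$compound)) %>%
    mutate(value = config$sensitivity * .data$scale_factor *
             rlnorm_cv(n(), .data$true_mean, .data$cv)) %>%
    select("sample_id", "compound", "value")
  sample_istd <- tidyr::expand_grid(sample_id = inj$sample_id,
                                    istd = istd_ids) %>%
    mutate(value = config$sensitivity *
             rlnorm_cv(n(), config$istd_mean, config$istd_cv))

  # --- pooled QC ------------------------------------------------------------
  qc_means <- grid %>%
    group_by(.data$compound) %>%
    summarise(true_mean = mean(.data$true_mean), cv = mean(.data$cv),
              .groups = "drop")
  qc_ids <- sprintf("POOL_%02d", seq_len(config$pooled_qc_count))
  qc_values <- tidyr::expand_grid(sample_id = qc_ids,
                                  compound = panel$compound) %>%
    left_join(qc_means, by = "compound") %>%
    mutate(value = config$sensitivity *
             rlnorm_cv(n(), .data$true_mean, .data$cv)) %>%
    select("sample_id", "compound", "value")
  qc_istd <- tidyr::expand_grid(sample_id = qc_ids, istd = istd_ids) %>%
    mutate(value = config$sensitivity *
             rlnorm_cv(n(), config$istd_mean, config$istd_cv))

  samples <- bind_rows(
    tibble(sample_id = blank_ids, sample_type = "BLANK_PBS",
           condition = NA_character_,
           replicate = seq_along(blank_ids)),
    tibble(sample_id = inj$sample_id, sample_type = "SAMPLE",
           condition = inj$condition, replicate = inj$replicate),
    tibble(sample_id = qc_ids, sample_type = "POOLED_QC",
           condition = NA_character_, replicate = seq_along(qc_ids))
  ) %>%
    mutate(dilution_factor = NA_real_)

  plate <- plate_dataset(
    samples = samples,
    values = bind_rows(blanks, values, qc_values),
    istd = bind_rows(blank_istd, sample_istd, qc_istd),
    panel = config$panel,
    metadata = list(generator = "plateqc::simulate_plate",
                    seed = config$seed %||% NA)
  )
  truth <- list(
    outliers = config$outlier_samples,
    below_floor = config$below_floor_compounds,
    params = grid,
    sensitivity = config$sensitivity
  )
  structure(list(plate = plate, truth = truth),
            class = "plateqc_simulation")
}

#' @export
print.plateqc_simulation <- function(x, ...) {
  cat("<plateqc_simulation>\n  plate: ")
  print(x$plate)
  cat(sprintf("  truth: %d planted outlier(s), %d below-floor compound(s)\n",
              nrow(x$truth$outliers), length(x$truth$below_floor)))
  invisible(x)
}

#' Simulate a serial dilution series
#'
#' Emulates injecting serial dilutions of the least-diluted calibration
#' standard: for each dilution factor `f` the expected signal is `base / f`,
#' observed through the log-normal noise model and clipped below by a blank
#' noise-floor draw (an instrument never reports less than its background),
#' with `dilution_replicates` injections per level.
#'
#' @param config A [scenario_config()]; uses its `dilution_factors`,
#'   `dilution_replicates`, noise model and seed.
#' @param base_concentration_scale Multiplier on each compound's undiluted
#'   base signal (the resolved `true_mean` of the first condition).
#' @return A tibble of DILUTION injection records: `sample_id`,
#'   `sample_type`, `dilution_factor`, `replicate`, `compound`, `value`.
#' @export
simulate_dilution_series <- function(config, base_concentration_scale = 1) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(config$dilution_factors) == 0) {
    abort("dilution_factors must be non-empty")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  panel <- as_tibble(config$panel)
  base <- signal_grid(config) %>%
    filter(.data$condition == config$conditions[[1]]) %>%
    mutate(base = .data$true_mean * base_concentration_scale) %>%
    select("compound", "base", "cv")
  recs <- tidyr::expand_grid(
    dilution_factor = config$dilution_factors,
    replicate = seq_len(config$dilution_replicates),
    compound = panel$compound
  ) %>%
    left_join(base, by = "compound") %>%
    mutate(
      signal = config$sensitivity *
        rlnorm_cv(n(), .data$base / .data$dilution_factor, .data$cv),
      floor_draw = config$sensitivity *
        rlnorm(n(), meanlog = log(config$blank_median),
               sdlog = sqrt(log(1 + config$blank_cv^2))),
      value = pmax(.data$signal, .data$floor_draw),
      sample_id = sprintf("DIL_%g_R%d", .data$dilution_factor,
                          .data$replicate),
      sample_type = "DILUTION"
    ) %>%
    select("sample_id", "sample_type", "dilution_factor", "replicate",
           "compound", "value")
  recs
}
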