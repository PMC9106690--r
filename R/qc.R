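qc_statuses <- c("retained", "missing", "lod", "detection_60pct",
                 "istd_missing", "outlier_mad", "sparse_lt3")

#' Compute per-compound limits of detection from blank injections
#'
#' The LOD of a compound is `lod_blank_multiplier` times the median signal of
#' the PBS blank injections, but never less than the configured noise floor
#' (`max(3 * median(blanks), 20000)` with the defaults). Compounds without
#' any blank value fall back to the floor alone and are marked so in the
#' `source` column.
#'
#' @param x A [plate_dataset()] (its `BLANK_PBS` injections are used) or a
#'   data frame with columns `compound` and `value` holding blank signals.
#' @param config A [qc_config()].
#' @return A tibble with columns `compound`, `n_blanks`, `blank_median`,
#'   `lod`, `source` (`"blank"` when the blank-derived value exceeds the
#'   floor, `"floor"` when the floor binds, `"floor_only"` when no blank
#'   value exists).
#' @export
#' @examples
#' blanks <- tibble::tibble(compound = "Ala", value = c(10000, 20000, 30000))
#' compute_lod(blanks, qc_config())   # 3 * 20000 = 60000
compute_lod <- function(x, config = qc_config()) {
  if (inherits(x, "plate_dataset")) {
    blanks <- tidy(x) %>%
      filter(.data$sample_type == "BLANK_PBS") %>%
      select("compound", "value")
    all_compounds <- x$panel$compound
  } else {
    blanks <- as_tibble(x)
    stopifnot(all(c("compound", "value") %in% names(blanks)))
    all_compounds <- unique(blanks$compound)
  }
  per <- blanks %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$compound) %>%
    summarise(n_blanks = n(), blank_median = median(.data$value),
              .groups = "drop")
  tibble(compound = all_compounds) %>%
    left_join(per, by = "compound") %>%
    mutate(
      n_blanks = if_else(is.na(.data$n_blanks), 0L, .data$n_blanks),
      lod_blank = config$lod_blank_multiplier * .data$blank_median,
      lod = pmax(if_else(is.na(.data$lod_blank), -Inf, .data$lod_blank),
                 config$noise_floor),
      source = case_when(
        .data$n_blanks == 0L ~ "floor_only",
        .data$lod_blank > config$noise_floor ~ "blank",
        TRUE ~ "floor"
      )
    ) %>%
    select("compound", "n_blanks", "blank_median", "lod", "source")
}

qc_table <- function(plate) {
  tidy(plate) %>%
    filter(.data$sample_type == "SAMPLE") %>%
    mutate(
      status = if_else(is.na(.data$value), "missing", "retained"),
      lod = NA_real_, istd_value = NA_real_, value_norm = NA_real_
    ) %>%
    select(-"sample_type", -"dilution_factor")
}

#' Reject values at or below the limit of detection
#'
#' A value survives only if it strictly exceeds its compound's LOD; rejected
#' values become missing (status `"lod"`), never zero.
#'
#' @param data A QC table as produced by [run_qc()] internals: one row per
#'   injection x compound with at least `compound`, `value` and `status`
#'   columns. Most users call [run_qc()] instead.
#' @param lods LOD table from [compute_lod()]; must cover every compound
#'   present.
#' @return `data` with the `lod` column filled and sub-LOD rows re-marked.
#' @export
apply_lod_filter <- function(data, lods) {
  miss <- setdiff(unique(data$compound), lods$compound)
  if (length(miss) > 0) {
    abort(sprintf("no LOD available for compound(s): %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  data %>%
    select(-"lod") %>%
    left_join(select(lods, "compound", "lod"), by = "compound") %>%
    mutate(status = if_else(
      .data$status == "retained" & !is.na(.data$value) &
        .data$value <= .data$lod,
      "lod", .data$status
    ))
}

#' Apply the replicate detection rule
#'
#' Within each condition a compound is valid only if it was detected (i.e.
#' survived the preceding filters) in at least `detection_fraction` of the
#' replicates still present -- normally three out of five. Values of invalid
#' compound/condition cells are removed with status `"detection_60pct"`.
#' Replicates whose rows were removed as whole-sample outliers drop out of
#' the denominator, so a re-run after outlier rejection uses the retained
#' replicate count.
#'
#' @inheritParams apply_lod_filter
#' @param config A [qc_config()].
#' @return `data` with invalid cells re-marked.
#' @export
detection_filter <- function(data, config = qc_config()) {
  cell <- data %>%
    group_by(.data$compound, .data$condition) %>%
    summarise(
      n_detected = sum(.data$status == "retained"),
      n_replicates = n_distinct(.data$replicate[.data$status != "outlier_mad"]),
      .groups = "drop"
    ) %>%
    filter(.data$n_replicates > 0,
           .data$n_detected / .data$n_replicates < config$detection_fraction)
  data %>%
    left_join(mutate(cell, .invalid = TRUE),
              by = c("compound", "condition")) %>%
    mutate(status = if_else(
      !is.na(.data$.invalid) & .data$status == "retained",
      "detection_60pct", .data$status
    )) %>%
    select(-".invalid", -"n_detected", -"n_replicates")
}

#' Normalize compound signals to their internal standards
#'
#' Divides each compound value by the internal-standard signal of the same
#' injection (the standard mapped to the compound in the panel). Injections
#' with a missing or non-positive internal-standard signal have the affected
#' compound values removed with status `"istd_missing"`.
#'
#' @inheritParams apply_lod_filter
#' @param istd Long tibble of internal-standard signals (`sample_id`,
#'   `istd`, `value`), typically `plate$istd`.
#' @return `data` with `istd_value` and `value_norm` filled.
#' @export
normalize_to_istd <- function(data, istd) {
  data %>%
    select(-"istd_value") %>%
    left_join(rename(as_tibble(istd), istd_value = "value"),
              by = c("sample_id", "istd")) %>%
    mutate(
      istd_ok = !is.na(.data$istd_value) & .data$istd_value > 0,
      value_norm = if_else(.data$istd_ok, .data$value / .data$istd_value,
                           NA_real_),
      status = if_else(.data$status == "retained" & !.data$istd_ok,
                       "istd_missing", .data$status)
    ) %>%
    select(-"istd_ok")
}

#' Flag and remove whole-sample outlier replicates
#'
#' For each condition, and separately for the LC and FIA compound blocks,
#' the normalized values of each replicate are summed (missing values are
#' absent from the sum). Replicates whose sum falls strictly outside
#' `median +/- outlier_mad_multiplier * MAD` are flagged, with the MAD taken
#' unscaled (`median(|s - median(s)|)`, no normality constant). At most
#' `replicates - min_retained_replicates` flagged replicates are removed per
#' condition and block -- the most extreme first -- so a 5-replicate
#' condition never drops below 4; additional flags are recorded but not
#' removed. Conditions with fewer than 3 replicates in a block are skipped.
#'
#' @inheritParams detection_filter
#' @return A list of class `outlier_scan`: `data` (rows of removed
#'   replicates re-marked `"outlier_mad"`), `flags` (one row per
#'   condition/block/replicate with the sum, bounds, and `flagged` /
#'   `removed` indicators) and `skipped` (conditions with too few
#'   replicates).
#' @export
detect_sample_outliers <- function(data, config = qc_config()) {
  sums <- data %>%
    filter(.data$status == "retained", !is.na(.data$value_norm)) %>%
    group_by(.data$condition, .data$measurement_type, .data$replicate) %>%
    summarise(sum_norm = sum(.data$value_norm), .groups = "drop_last")

  skipped <- sums %>%
    summarise(n_replicates = n(), .groups = "drop") %>%
    filter(.data$n_replicates < 3) %>%
    mutate(note = "fewer than 3 replicates; outlier scan skipped")

  flags <- sums %>%
    filter(n() >= 3) %>%
    mutate(
      center = median(.data$sum_norm),
      mad = median(abs(.data$sum_norm - .data$center)),
      lower = .data$center - config$outlier_mad_multiplier * .data$mad,
      upper = .data$center + config$outlier_mad_multiplier * .data$mad,
      flagged = .data$sum_norm < .data$lower | .data$sum_norm > .data$upper,
      cap = pmax(0L, n() - config$min_retained_replicates)
    ) %>%
    arrange(dplyr::desc(abs(.data$sum_norm - .data$center)),
            .by_group = TRUE) %>%
    mutate(removed = .data$flagged & cumsum(.data$flagged) <= .data$cap) %>%
    ungroup() %>%
    arrange(.data$condition, .data$measurement_type, .data$replicate) %>%
    select("condition", "measurement_type", "replicate", "sum_norm",
           "center", "mad", "lower", "upper", "flagged", "removed")

  removed <- flags %>%
    filter(.data$removed) %>%
    select("condition", "measurement_type", "replicate") %>%
    mutate(.out = TRUE)

  data <- data %>%
    left_join(removed, by = c("condition", "measurement_type", "replicate")) %>%
    mutate(status = if_else(!is.na(.data$.out) & .data$status == "retained",
                            "outlier_mad", .data$status)) %>%
    select(-".out")

  structure(list(data = data, flags = flags, skipped = skipped),
            class = "outlier_scan")
}

#' Discard sparse compound/condition cells
#'
#' Cells with fewer than `min_values_per_condition` surviving values (default
#' 3) are dropped from downstream analysis with status `"sparse_lt3"`.
#'
#' @inheritParams detection_filter
#' @return `data` with sparse cells re-marked.
#' @export
discard_sparse <- function(data, config = qc_config()) {
  sparse <- data %>%
    group_by(.data$compound, .data$condition) %>%
    summarise(n_retained = sum(.data$status == "retained"), .groups = "drop") %>%
    filter(.data$n_retained > 0,
           .data$n_retained < config$min_values_per_condition) %>%
    mutate(.sparse = TRUE) %>%
    select(-"n_retained")
  data %>%
    left_join(sparse, by = c("compound", "condition")) %>%
    mutate(status = if_else(!is.na(.data$.sparse) & .data$status == "retained",
                            "sparse_lt3", .data$status)) %>%
    select(-".sparse")
}

#' Run the full QC filter cascade on a plate
#'
#' Executes, in order: blank-based LOD computation, LOD filtering, the 60%
#' replicate detection rule, internal-standard normalization, median/MAD
#' whole-sample outlier rejection (per condition, separately for the LC and
#' FIA blocks), a re-run of the detection rule on the surviving replicates,
#' and the discard of compound/condition cells with fewer than 3 values.
#' Every removed value is recorded exactly once in the audit trail together
#' with the rule that removed it.
#'
#' @param plate A [plate_dataset()] containing at least one `BLANK_PBS`
#'   injection.
#' @param config A [qc_config()].
#' @return A `qc_result` object; see [tidy.qc_result()], [qc_audit()],
#'   [glance.qc_result()].
#' @export
#' @examples
#' sim <- simulate_plate(scenario_config(panel = load_panel("p400"), seed = 1))
#' qc <- run_qc(sim$plate)
#' glance(qc)
run_qc <- function(plate, config = qc_config()) {
  stopifnot(inherits(plate, "plate_dataset"))
  if (!any(plate$samples$sample_type == "BLANK_PBS")) {
    abort("plate has no BLANK_PBS injections; cannot compute LODs")
  }
  lods <- compute_lod(plate, config)
  dat <- qc_table(plate) %>%
    apply_lod_filter(lods) %>%
    detection_filter(config) %>%
    normalize_to_istd(plate$istd)
  scan <- detect_sample_outliers(dat, config)
  dat <- scan$data
  if (config$redetect_after_outliers) {
    dat <- detection_filter(dat, config)
  }
  dat <- discard_sparse(dat, config)
  structure(
    list(data = dat, lods = lods, outlier_flags = scan$flags,
         outlier_skipped = scan$skipped, config = config,
         panel = plate$panel, samples = plate$samples,
         metadata = plate$metadata),
    class = "qc_result"
  )
}

#' Retained, normalized values of a QC run
#'
#' @param x A `qc_result` from [run_qc()].
#' @param ... Unused.
#' @return A tibble of the surviving measurements with their normalized
#'   values: `sample_id`, `condition`, `replicate`, `compound`, `class`,
#'   `measurement_type`, `value`, `value_norm`.
#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) {
  x$data %>%
    filter(.data$status == "retained") %>%
    select("sample_id", "condition", "replicate", "compound", "class",
           "measurement_type", "value", "value_norm")
}

#' Audit trail of a QC run
#'
#' One row per removed value, with the rule that removed it: `lod`,
#' `detection_60pct`, `istd_missing`, `outlier_mad` or `sparse_lt3`.
#'
#' @param qc A `qc_result` from [run_qc()].
#' @return A tibble with columns `compound`, `condition`, `replicate`,
#'   `sample_id`, `rule`, `detail`.
#' @export
qc_audit <- function(qc) {
  stopifnot(inherits(qc, "qc_result"))
  qc$data %>%
    filter(!.data$status %in% c("retained", "missing")) %>%
    mutate(rule = .data$status, detail = case_when(
      .data$rule == "lod" ~ sprintf("value %.6g <= LOD %.6g",
                                    .data$value, .data$lod),
      .data$rule == "detection_60pct" ~ "detected in < 60% of replicates",
      .data$rule == "istd_missing" ~ "internal standard missing or non-positive",
      .data$rule == "outlier_mad" ~ "replicate removed as whole-sample outlier",
      .data$rule == "sparse_lt3" ~ "fewer than 3 surviving values in condition",
      TRUE ~ .data$rule
    )) %>%
    select("compound", "condition", "replicate", "sample_id", "rule",
           "detail") %>%
    arrange(.data$compound, .data$condition, .data$replicate)
}

#' @method glance qc_result
#' @export
glance.qc_result <- function(x, ...) {
  st <- x$data$status
  retained_cells <- x$data %>%
    filter(.data$status == "retained") %>%
    distinct(.data$compound, .data$condition)
  tibble(
    n_values_in = sum(st != "missing"),
    n_retained = sum(st == "retained"),
    n_rejected = sum(!st %in% c("retained", "missing")),
    n_outlier_injections = sum(x$outlier_flags$removed),
    n_cells_detected = nrow(retained_cells),
    n_compounds_detected = n_distinct(retained_cells$compound)
  )
}

#' @export
print.qc_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<qc_result: %d of %d values retained; %d rejected ",
           "(%d outlier injections); %d compounds detected>\n"),
    g$n_retained, g$n_values_in, g$n_rejected, g$n_outlier_injections,
    g$n_compounds_detected
  ))
  invisible(x)
}
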