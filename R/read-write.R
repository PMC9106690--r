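#' Render an "n/N (pct%)" table cell
#'
#' Percentages are rounded to the nearest integer with halves away from
#' zero (so 22/27 renders as "22/27 (81%)" and 158/366 as "158/366 (43%)").
#'
#' @param n,total Integer counts, `n <= total`.
#' @return Character vector of rendered cells; `"0/0 (0%)"` when `total` is 0.
#' @export
#' @examples
#' format_fraction(183, 408)   # "183/408 (45%)"
format_fraction <- function(n, total) {
  pct <- ifelse(total > 0, round_half_up(100 * n / total), 0)
  sprintf("%d/%d (%d%%)", as.integer(n), as.integer(total), as.integer(pct))
}

# round half away from zero (base round() goes to even)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

meta_cols <- c("sample_id", "sample_type", "condition", "replicate",
               "dilution_factor")

#' Read a wide plate export table
#'
#' Reads a wide CSV or TSV plate table: one row per injection, metadata
#' columns `sample_id`, `sample_type`, `condition`, `replicate` (and
#' optionally `dilution_factor`), and one column per compound or
#' internal-standard signal. The delimiter is auto-detected from the header
#' line. Empty cells become missing values, never zeros. Columns matching
#' neither the panel nor the metadata are reported and ignored, as are
#' vendor-style `*_status` annotation columns.
#'
#' @param path Path to the file.
#' @param panel The panel the columns are matched against.
#' @return A [plate_dataset()].
#' @export
read_plate <- function(path, panel) {
  if (!file.exists(path)) abort(sprintf("plate file not found: %s", path))
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  header_cols <- strsplit(header, delim, fixed = TRUE)[[1]]
  required <- setdiff(meta_cols, "dilution_factor")
  missing_cols <- setdiff(required, header_cols)
  if (length(missing_cols) > 0) {
    abort(sprintf("plate file is missing mandatory metadata column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  raw <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                           col_types = readr::cols(
                             sample_id = "c", sample_type = "c",
                             condition = "c", .default = "d"
                           ),
                           progress = FALSE, show_col_types = FALSE)
  if (!"dilution_factor" %in% names(raw)) raw$dilution_factor <- NA_real_

  signal_cols <- setdiff(names(raw), meta_cols)
  compound_cols <- intersect(signal_cols, panel$compound)
  istd_cols <- intersect(signal_cols, unique(panel$istd))
  status_cols <- signal_cols[endsWith(signal_cols, "_status")]
  unknown <- setdiff(signal_cols, c(compound_cols, istd_cols, status_cols))
  if (length(unknown) > 0) {
    warn(sprintf("ignoring %d column(s) not in the panel: %s",
                 length(unknown), paste(head(unknown, 10), collapse = ", ")))
  }

  check_cols <- c(compound_cols, istd_cols)
  for (cc in check_cols) {
    neg <- which(!is.na(raw[[cc]]) & raw[[cc]] < 0)
    if (length(neg) > 0) {
      abort(sprintf("negative signal value at row %d, column '%s'",
                    neg[1], cc))
    }
  }

  to_long <- function(cols, id_name) {
    raw %>%
      select("sample_id", all_of(cols)) %>%
      tidyr::pivot_longer(all_of(cols), names_to = id_name,
                          values_to = "value")
  }
  values <- to_long(compound_cols, "compound")
  istd <- to_long(istd_cols, "istd")

  samples <- raw %>%
    select(all_of(meta_cols)) %>%
    mutate(replicate = as.integer(.data$replicate))

  plate <- plate_dataset(samples = samples, values = values, istd = istd,
                         panel = panel,
                         metadata = list(source = path))
  attr(plate, "ignored_columns") <- unknown
  plate
}

#' Write a plate dataset as a wide CSV
#'
#' The inverse of [read_plate()]: one row per injection, metadata columns
#' first, then compound columns in panel order and internal-standard
#' columns. Missing values are written as empty cells.
#'
#' @param plate A [plate_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "plate_dataset"))
  wide_values <- plate$values %>%
    tidyr::pivot_wider(names_from = "compound", values_from = "value")
  wide_istd <- plate$istd %>%
    tidyr::pivot_wider(names_from = "istd", values_from = "value")
  out <- plate$samples %>%
    left_join(wide_values, by = "sample_id") %>%
    left_join(wide_istd, by = "sample_id")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write the report file set of a pipeline run
#'
#' Emits, into `path`: the filtered normalized matrix
#' (`normalized_matrix.csv`, injections x compounds, missing where a value
#' was removed), the per-class detected-compound count table
#' (`detected_counts.csv`, classes x conditions with LC/FIA/total sum rows),
#' the RSD summary (`rsd_summary.csv`: median RSD per measurement type and
#' condition plus `"n/N (pct%)"` below-threshold cells), and a
#' machine-readable audit trail (`audit.json`) with every filter decision
#' and its triggering rule.
#'
#' @param qc A `qc_result` from [run_qc()].
#' @param summary A `repeatability_summary` from [summarize_repeatability()];
#'   computed from `qc` when omitted.
#' @param path Output directory (created if needed).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_report <- function(qc, summary = NULL, path) {
  stopifnot(inherits(qc, "qc_result"))
  summary <- summary %||% summarize_repeatability(qc)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create report directory: %s", path))
  }
  conditions <- summary$conditions

  f_matrix <- file.path(path, "normalized_matrix.csv")
  mat <- tidy(qc) %>%
    select("sample_id", "condition", "replicate", "compound", "value_norm")
  wide <- if (nrow(mat) > 0) {
    tidyr::pivot_wider(mat, names_from = "compound",
                       values_from = "value_norm")
  } else {
    tibble(sample_id = character(0), condition = character(0),
           replicate = integer(0))
  }
  readr::write_csv(wide, f_matrix, na = "")

  f_counts <- file.path(path, "detected_counts.csv")
  counts_wide <- summary$detected_counts %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "n_detected")
  sum_row <- function(d, label, type) {
    vals <- summarise(d, across(all_of(conditions), \(x) sum(x, na.rm = TRUE)))
    dplyr::bind_cols(tibble(class = label, measurement_type = type), vals)
  }
  if (nrow(counts_wide) > 0) {
    lc <- filter(counts_wide, .data$measurement_type == "LC")
    fia <- filter(counts_wide, .data$measurement_type == "FIA")
    counts_wide <- bind_rows(
      lc,
      if (nrow(lc) > 0) sum_row(lc, "Sum", "LC"),
      fia,
      if (nrow(fia) > 0) sum_row(fia, "Sum", "FIA"),
      sum_row(counts_wide, "Total", "LC+FIA")
    )
  }
  readr::write_csv(counts_wide, f_counts, na = "")

  f_rsd <- file.path(path, "rsd_summary.csv")
  med <- summary$median_rsd %>%
    mutate(criteria = "Median RSD [%]",
           cell = sprintf("%.3g", .data$median_rsd_pct)) %>%
    select("measurement_type", "criteria", "condition", "cell")
  below <- summary$below_threshold %>%
    mutate(criteria = sprintf("Compounds with RSD < %g%%", summary$threshold),
           cell = .data$label) %>%
    select("measurement_type", "criteria", "condition", "cell")
  rsd_tbl <- bind_rows(med, below)
  rsd_wide <- if (nrow(rsd_tbl) > 0) {
    tidyr::pivot_wider(rsd_tbl, names_from = "condition",
                       values_from = "cell")
  } else {
    tibble(measurement_type = character(0), criteria = character(0))
  }
  readr::write_csv(rsd_wide, f_rsd, na = "")

  f_audit <- file.path(path, "audit.json")
  audit <- list(
    config = unclass(qc$config)[!vapply(unclass(qc$config), is.null,
                                        logical(1))],
    lods = qc$lods,
    outlier_flags = qc$outlier_flags,
    outlier_skipped = qc$outlier_skipped,
    decisions = qc_audit(qc)
  )
  jsonlite::write_json(audit, f_audit, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  invisible(c(f_matrix, f_counts, f_rsd, f_audit))
}
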