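sample_types <- c("SAMPLE", "BLANK_PBS", "POOLED_QC", "CALIBRATION", "DILUTION")

#' Construct a plate dataset
#'
#' A plate dataset holds everything one kit plate produced: per-injection
#' metadata (sample type, condition, replicate, dilution factor), the
#' injection x compound measurement values (peak areas for LC compounds,
#' peak intensities for FIA compounds) and the internal-standard signals of
#' every injection.
#'
#' @param samples Tibble of injection metadata with columns `sample_id`,
#'   `sample_type` (one of SAMPLE, BLANK_PBS, POOLED_QC, CALIBRATION,
#'   DILUTION), `condition`, `replicate` and `dilution_factor` (non-missing
#'   for DILUTION injections only).
#' @param values Long tibble of measurements: `sample_id`, `compound`,
#'   `value`. Missing measurements are `NA`, never zero; zeros are measured
#'   zeros and stay subject to the LOD filter.
#' @param istd Long tibble of internal-standard signals: `sample_id`,
#'   `istd`, `value`.
#' @param panel The panel the compounds belong to, from [load_panel()].
#' @param metadata Optional named list of free-form run annotations.
#' @return A `plate_dataset` object.
#' @export
plate_dataset <- function(samples, values, istd, panel,
                          metadata = list()) {
  samples <- as_tibble(samples)
  values <- as_tibble(values)
  istd <- as_tibble(istd)
  need <- setdiff(c("sample_id", "sample_type", "condition", "replicate"),
                  names(samples))
  if (length(need) > 0) {
    abort(sprintf("samples is missing column(s): %s",
                  paste(need, collapse = ", ")))
  }
  if (!"dilution_factor" %in% names(samples)) {
    samples$dilution_factor <- NA_real_
  }
  bad_type <- setdiff(unique(samples$sample_type), sample_types)
  if (length(bad_type) > 0) {
    abort(sprintf("unknown sample_type(s): %s",
                  paste(bad_type, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("sample_id values must be unique")
  }
  dil <- samples$sample_type == "DILUTION"
  if (any(dil & !is.finite(samples$dilution_factor))) {
    abort("DILUTION injections must carry a dilution_factor")
  }
  if (any(!dil & !is.na(samples$dilution_factor))) {
    abort("only DILUTION injections may carry a dilution_factor")
  }
  smp <- samples[samples$sample_type == "SAMPLE", c("condition", "replicate")]
  if (anyDuplicated(smp)) {
    abort("(condition, replicate) pairs must be unique among SAMPLE injections")
  }
  unknown <- setdiff(unique(values$compound), panel$compound)
  if (length(unknown) > 0) {
    abort(sprintf("measurements for compound(s) not in the panel: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  structure(
    list(samples = samples, values = values, istd = istd, panel = panel,
         metadata = metadata),
    class = "plate_dataset"
  )
}

#' @export
print.plate_dataset <- function(x, ...) {
  tt <- table(factor(x$samples$sample_type, levels = sample_types))
  cat(sprintf(
    "<plate_dataset: %d injections (%s), %d panel compounds>\n",
    nrow(x$samples),
    paste(sprintf("%s %d", names(tt[tt > 0]), tt[tt > 0]), collapse = ", "),
    nrow(x$panel)
  ))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Long (tidy) view of a plate dataset
#'
#' One row per injection x compound, with injection metadata and panel
#' annotation joined in.
#'
#' @param x A [plate_dataset()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `sample_type`, `condition`,
#'   `replicate`, `dilution_factor`, `compound`, `class`,
#'   `measurement_type`, `istd`, `value`.
#' @method tidy plate_dataset
#' @export
tidy.plate_dataset <- function(x, ...) {
  x$values %>%
    left_join(x$samples, by = "sample_id") %>%
    left_join(as_tibble(x$panel), by = "compound") %>%
    select("sample_id", "sample_type", "condition", "replicate",
           "dilution_factor", "compound", "class", "measurement_type",
           "istd", "value")
}

#' @method glance plate_dataset
#' @export
glance.plate_dataset <- function(x, ...) {
  tibble(
    n_injections = nrow(x$samples),
    n_samples = sum(x$samples$sample_type == "SAMPLE"),
    n_blanks = sum(x$samples$sample_type == "BLANK_PBS"),
    n_conditions = n_distinct(x$samples$condition[
      x$samples$sample_type == "SAMPLE"]),
    n_compounds = n_distinct(x$values$compound),
    n_missing = sum(is.na(x$values$value))
  )
}
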