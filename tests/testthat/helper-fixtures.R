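# Shared fixture builders. Everything is generated in code; the only files
# are the committed hand-derived toy plate under inst/extdata.

toy_panel_path <- function() {
  system.file("extdata", "toy_panel.csv", package = "plateqc",
              mustWork = TRUE)
}

toy_plate_path <- function() {
  system.file("extdata", "toy_plate.csv", package = "plateqc",
              mustWork = TRUE)
}

read_toy_qc <- function(config = qc_config()) {
  panel <- load_panel(toy_panel_path())
  plate <- read_plate(toy_plate_path(), panel)
  run_qc(plate, config)
}

# a small mixed LC/FIA panel for simulation-heavy tests
small_panel <- function(n_lc = 5, n_fia = 5) {
  structure(
    tibble::tibble(
      compound = c(sprintf("aa%02d", seq_len(n_lc)),
                   sprintf("pc%02d", seq_len(n_fia))),
      class = rep(c("amino acids", "phosphatidylcholines"),
                  c(n_lc, n_fia)),
      measurement_type = rep(c("LC", "FIA"), c(n_lc, n_fia)),
      istd = rep(c("IS_A", "IS_P"), c(n_lc, n_fia))
    ),
    class = c("plateqc_panel", class(tibble::tibble()))
  )
}

# Minimal QC-stage table (the long format the cascade stages operate on),
# for exercising single stages in isolation.
make_qc_tbl <- function(condition, replicate, compound, value_norm,
                        measurement_type = "LC", status = "retained") {
  tibble::tibble(
    sample_id = sprintf("S_%s_R%d", condition, replicate),
    condition = condition, replicate = replicate, compound = compound,
    class = "amino acids", measurement_type = measurement_type,
    istd = "IS", value = value_norm, lod = 0, istd_value = 1,
    value_norm = value_norm, status = status
  )
}

# Independent brute-force Kruskal-Wallis oracle: enumerates every
# permutation of the pooled values over the positions (all N! orderings,
# which over-counts each distinct group assignment uniformly) and computes H
# directly from the definition, without tie correction shortcuts shared with
# the package (the tie factor is permutation-invariant, so comparing raw H
# is equivalent).
kw_perm_oracle_p <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  n_total <- length(values)
  gi_obs <- rep(seq_along(groups), sizes)
  h_of <- function(vals, gi) {
    r <- rank(vals, ties.method = "average")
    rb <- tapply(r, gi, mean)
    ns <- tabulate(gi)
    12 / (n_total * (n_total + 1)) *
      sum(ns * (rb - (n_total + 1) / 2)^2)
  }
  h_obs <- h_of(values, gi_obs)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_orders <- perms(seq_len(n_total))
  hs <- vapply(all_orders,
               function(ord) h_of(values[ord], gi_obs), numeric(1))
  mean(hs >= h_obs - 1e-10)
}

# Direct Monte-Carlo oracle for the sampling distribution of the sample RSD
# under the generator's log-normal model (independent of the generator code).
rsd_mc_oracle_median <- function(cv, n = 5, n_conditions = 2000,
                                 seed = 1234) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  rsds <- replicate(n_conditions, {
    x <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    100 * stats::sd(x) / mean(x)
  })
  stats::median(rsds)
}

# Hand-assembled qc_result containing only retained cells, for driving the
# summary layer with exactly controlled RSDs.
fake_qc <- function(cells, config = qc_config()) {
  data <- tidyr::unnest(cells, "values")
  data <- dplyr::mutate(
    data,
    replicate = as.integer(stats::ave(seq_len(nrow(data)), data$compound,
                                      data$condition, FUN = seq_along)),
    sample_id = sprintf("S_%s_R%d", condition, replicate),
    istd = "IS", value = values, value_norm = values, lod = 0,
    istd_value = 1, status = "retained"
  )
  samples <- dplyr::distinct(data, condition, replicate)
  samples <- dplyr::mutate(samples,
                           sample_id = sprintf("S_%s_R%d", condition,
                                               replicate),
                           sample_type = "SAMPLE",
                           dilution_factor = NA_real_)
  panel <- dplyr::distinct(data, compound, class, measurement_type)
  panel$istd <- "IS"
  structure(
    list(data = dplyr::select(data, -"values"), samples = samples,
         panel = panel, config = config,
         outlier_flags = tibble::tibble(removed = logical(0)),
         outlier_skipped = tibble::tibble(), metadata = list()),
    class = "qc_result"
  )
}

# exact serial-dilution responses: value = base / factor, no noise
noiseless_ladder <- function(base = 1e6,
                             factors = dilution_design()$dilution_factor,
                             reps = 3, compound = "Ala") {
  tidyr::expand_grid(dilution_factor = factors, replicate = seq_len(reps)) |>
    dplyr::mutate(compound = compound, value = base / dilution_factor)
}
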