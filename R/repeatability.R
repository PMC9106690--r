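#' Relative standard deviation of a set of replicate values
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation; the
#' repeatability metric, conventionally accepted below a 15% threshold.
#' Missing values are dropped; a non-positive mean gives `NA`.
#'
#' @param x Numeric vector of retained (normalized) replicate values.
#' @return RSD in percent, or `NA` when undefined.
#' @export
#' @examples
#' compound_rsd(c(8, 10, 12))   # 20
compound_rsd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  100 * sd(x) / m
}

#' Summarize repeatability and detection of a QC run
#'
#' Builds the reporting surface of the pipeline: per-compound/condition RSDs
#' of the retained normalized values, detected-compound counts per class and
#' condition, median RSDs per measurement type and per class, and the count
#' of detected compounds with RSD strictly below the repeatability threshold
#' (rendered as `"n/N (pct%)"`).
#'
#' @param qc A `qc_result` from [run_qc()].
#' @param config A [qc_config()]; defaults to the one the QC run used.
#' @return A `repeatability_summary` object with tibbles `rsd`,
#'   `detected_counts`, `median_rsd`, `class_median_rsd` and
#'   `below_threshold`.
#' @export
summarize_repeatability <- function(qc, config = NULL) {
  stopifnot(inherits(qc, "qc_result"))
  config <- config %||% qc$config
  conditions <- unique(qc$samples$condition[qc$samples$sample_type == "SAMPLE"])
  retained <- tidy(qc)

  rsd <- retained %>%
    group_by(.data$compound, .data$class, .data$measurement_type,
             .data$condition) %>%
    summarise(n = n(), mean_norm = mean(.data$value_norm),
              rsd_pct = compound_rsd(.data$value_norm), .groups = "drop")

  class_grid <- tidyr::expand_grid(
    distinct(as_tibble(qc$panel), .data$class, .data$measurement_type),
    condition = conditions
  )
  detected_counts <- rsd %>%
    count(.data$class, .data$measurement_type, .data$condition,
          name = "n_detected") %>%
    full_join(class_grid, by = c("class", "measurement_type", "condition")) %>%
    mutate(n_detected = if_else(is.na(.data$n_detected), 0L,
                                .data$n_detected)) %>%
    arrange(match(.data$class, panel_classes()$class),
            match(.data$condition, conditions))

  median_rsd <- rsd %>%
    group_by(.data$measurement_type, .data$condition) %>%
    summarise(n_detected = n(),
              median_rsd_pct = median(.data$rsd_pct, na.rm = TRUE),
              .groups = "drop")

  class_median_rsd <- rsd %>%
    group_by(.data$class, .data$measurement_type, .data$condition) %>%
    summarise(n_detected = n(),
              median_rsd_pct = median(.data$rsd_pct, na.rm = TRUE),
              .groups = "drop")

  below_threshold <- rsd %>%
    group_by(.data$measurement_type, .data$condition) %>%
    summarise(
      n_below = sum(.data$rsd_pct < config$rsd_threshold_pct, na.rm = TRUE),
      n_detected = n(),
      .groups = "drop"
    ) %>%
    mutate(label = format_fraction(.data$n_below, .data$n_detected))

  structure(
    list(rsd = rsd, detected_counts = detected_counts,
         median_rsd = median_rsd, class_median_rsd = class_median_rsd,
         below_threshold = below_threshold,
         threshold = config$rsd_threshold_pct, conditions = conditions),
    class = "repeatability_summary"
  )
}

#' @export
print.repeatability_summary <- function(x, ...) {
  cat(sprintf("<repeatability_summary: %d compound/condition cells, %d conditions, RSD threshold %g%%>\n",
              nrow(x$rsd), length(x$conditions), x$threshold))
  print(x$below_threshold)
  invisible(x)
}

#' @method tidy repeatability_summary
#' @export
tidy.repeatability_summary <- function(x, ...) x$rsd

#' @method glance repeatability_summary
#' @export
glance.repeatability_summary <- function(x, ...) {
  tibble(
    n_cells = nrow(x$rsd),
    n_compounds_detected = n_distinct(x$rsd$compound),
    n_conditions = length(x$conditions),
    median_rsd_pct = median(x$rsd$rsd_pct, na.rm = TRUE),
    threshold_pct = x$threshold
  )
}

#' Rank conditions per compound
#'
#' For each compound, the conditions are ranked by the metric from lowest
#' (rank 1) to highest (rank `n`), with ties averaged. Conditions in which
#' the compound is missing receive no rank by default (`missing =
#' "ignore"`); with `missing = "worst_rank"` they are assigned the
#' worst-rank category `n_conditions` instead, a sensitivity variant that
#' penalizes non-detection.
#'
#' @param data Tibble with columns `compound`, `condition` and the metric.
#' @param metric Name of the metric column (default `"rsd_pct"`).
#' @param missing `"ignore"` or `"worst_rank"`.
#' @param n_conditions Total number of conditions (defaults to those present
#'   in `data`); defines the worst-rank category.
#' @return A tibble `compound`, `condition`, `rank`; compounds missing
#'   everywhere are excluded.
#' @export
#' @examples
#' d <- tibble::tibble(compound = "x",
#'                     condition = c("a", "b", "c"),
#'                     rsd_pct = c(5, 5, 10))
#' rank_conditions(d)$rank   # 1.5 1.5 3
rank_conditions <- function(data, metric = "rsd_pct",
                            missing = c("ignore", "worst_rank"),
                            n_conditions = NULL) {
  missing <- match.arg(missing)
  data <- as_tibble(data)
  stopifnot(all(c("compound", "condition", metric) %in% names(data)))
  n_conditions <- n_conditions %||% n_distinct(data$condition)
  if (n_conditions < 2) abort("ranking needs at least 2 conditions")
  out <- data %>%
    group_by(.data$compound) %>%
    filter(any(!is.na(.data[[!!metric]]))) %>%
    mutate(rank = rank(.data[[!!metric]], ties.method = "average",
                       na.last = "keep")) %>%
    ungroup()
  if (missing == "worst_rank") {
    out <- mutate(out, rank = if_else(is.na(.data$rank),
                                      as.numeric(!!n_conditions), .data$rank))
  } else {
    out <- filter(out, !is.na(.data$rank))
  }
  select(out, "compound", "condition", "rank")
}

as_groups <- function(x, g = NULL) {
  if (is.list(x) && is.null(g)) {
    groups <- lapply(x, function(v) v[!is.na(v)])
    if (is.null(names(groups))) {
      names(groups) <- sprintf("group%d", seq_along(groups))
    }
  } else {
    stopifnot(length(x) == length(g))
    keep <- !is.na(x)
    groups <- split(x[keep], g[keep])
  }
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) abort("need at least 2 non-empty groups")
  groups
}

kw_h_from_ranks <- function(r, gi, k) {
  n_total <- length(r)
  sizes <- tabulate(gi, k)
  rbar <- vapply(seq_len(k), function(i) mean(r[gi == i]), numeric(1))
  12 / (n_total * (n_total + 1)) *
    sum(sizes * (rbar - (n_total + 1) / 2)^2)
}

#' Kruskal-Wallis test
#'
#' Rank-based comparison of two or more groups. Values are pooled and ranked
#' with average ties; the statistic is
#' `H = 12/(N(N+1)) * sum(n_i * (Rbar_i - (N+1)/2)^2)` divided by the tie
#' correction `1 - sum(t^3 - t)/(N^3 - N)`. The p-value comes from the
#' chi-squared distribution with `k - 1` degrees of freedom
#' (`p_method = "asymptotic"`, the default) or from exhaustive enumeration of
#' all assignments of the pooled values to groups of the observed sizes
#' (`p_method = "exact"`, feasible for small pooled sizes). When every pooled
#' value is identical the statistic is 0 and p is 1 by convention.
#'
#' @param x A list of numeric vectors (one per group), or a value vector.
#' @param g Group labels when `x` is a vector.
#' @param p_method `"asymptotic"` or `"exact"`.
#' @return A `kw_test` object with elements `statistic`, `df`, `p.value`,
#'   `method`, `n`, `k`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))$statistic  # 32/7
kruskal_wallis <- function(x, g = NULL,
                           p_method = c("asymptotic", "exact")) {
  p_method <- match.arg(p_method)
  groups <- as_groups(x, g)
  k <- length(groups)
  values <- unlist(groups, use.names = FALSE)
  gi <- rep(seq_len(k), lengths(groups))
  n_total <- length(values)
  r <- rank(values, ties.method = "average")
  ties <- table(values)
  tie_c <- 1 - sum(ties^3 - ties) / (n_total^3 - n_total)
  if (tie_c <= 0) {
    h <- 0
    p <- 1
  } else {
    h <- kw_h_from_ranks(r, gi, k) / tie_c
    p <- if (p_method == "asymptotic") {
      pchisq(h, df = k - 1, lower.tail = FALSE)
    } else {
      kw_exact_p(r, lengths(groups), h / 1, tie_c)
    }
  }
  structure(
    list(statistic = h, df = k - 1L, p.value = p,
         method = paste("Kruskal-Wallis,", p_method, "p"),
         n = lengths(groups), k = k),
    class = "kw_test"
  )
}

# Exact permutation p: enumerate all distinct assignments of the pooled
# ranks to groups of the given sizes and count H >= observed.
kw_exact_p <- function(r, sizes, h_obs, tie_c) {
  n_total <- length(r)
  if (n_total > 12) {
    abort("exact enumeration is limited to pooled sizes <= 12")
  }
  k <- length(sizes)
  count <- 0L
  total <- 0L
  recurse <- function(remaining, which_group, assignment) {
    if (which_group == k) {
      assignment[remaining] <- k
      h <- kw_h_from_ranks(r, assignment, k) / tie_c
      total <<- total + 1L
      if (h >= h_obs - 1e-10) count <<- count + 1L
      return(invisible())
    }
    picks <- combn(remaining, sizes[which_group], simplify = FALSE)
    for (p in picks) {
      a <- assignment
      a[p] <- which_group
      recurse(setdiff(remaining, p), which_group + 1L, a)
    }
  }
  recurse(seq_len(n_total), 1L, integer(n_total))
  count / total
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("%s: H = %.4f, df = %d, p = %.4g (groups n = %s)\n",
              x$method, x$statistic, x$df, x$p.value,
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' @method tidy kw_test
#' @export
tidy.kw_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         method = x$method)
}

#' @method glance kw_test
#' @export
glance.kw_test <- function(x, ...) tidy(x)

#' Tukey-Kramer all-pairs comparison on pooled ranks
#'
#' Post-hoc companion to [kruskal_wallis()]: values are pooled and ranked,
#' and each pair of groups is compared through the difference of mean ranks
#' against the studentized-range distribution with infinite degrees of
#' freedom. The pair statistic is
#' `q = |Rbar_i - Rbar_j| / sqrt((N(N+1)/12) * (1/n_i + 1/n_j) / 2)`,
#' accommodating unequal group sizes; the family-wise two-sided p-value is
#' `ptukey(q, k, Inf, lower.tail = FALSE)`. With two groups this reduces to
#' the large-sample rank-sum comparison (`q[alpha, 2, Inf] = sqrt(2) *
#' z[alpha/2]`).
#'
#' @inheritParams kruskal_wallis
#' @param alpha Family-wise significance level.
#' @return A `tukey_kramer` object whose `pairs` tibble has one row per
#'   group pair: `group1`, `group2`, `mean_rank_diff`, `q`, `p.value`,
#'   `significant`.
#' @export
tukey_kramer <- function(x, g = NULL, alpha = 0.05) {
  groups <- as_groups(x, g)
  k <- length(groups)
  if (k < 2) abort("need at least 2 groups")
  values <- unlist(groups, use.names = FALSE)
  gi <- rep(seq_len(k), lengths(groups))
  n_total <- length(values)
  r <- rank(values, ties.method = "average")
  sizes <- lengths(groups)
  rbar <- vapply(seq_len(k), function(i) mean(r[gi == i]), numeric(1))
  var_pool <- n_total * (n_total + 1) / 12
  idx <- combn(k, 2)
  pairs <- tibble(
    group1 = names(groups)[idx[1, ]],
    group2 = names(groups)[idx[2, ]],
    n1 = unname(sizes[idx[1, ]]), n2 = unname(sizes[idx[2, ]]),
    mean_rank_diff = unname(rbar[idx[1, ]] - rbar[idx[2, ]])
  ) %>%
    mutate(
      se = sqrt(var_pool * (1 / .data$n1 + 1 / .data$n2) / 2),
      q = if_else(.data$se > 0, abs(.data$mean_rank_diff) / .data$se, 0),
      p.value = ptukey(.data$q, nmeans = !!k, df = Inf, lower.tail = FALSE),
      significant = .data$p.value <= !!alpha
    ) %>%
    select("group1", "group2", "n1", "n2", "mean_rank_diff", "q",
           "p.value", "significant")
  structure(list(pairs = pairs, alpha = alpha, k = k, n = n_total),
            class = "tukey_kramer")
}

#' @export
print.tukey_kramer <- function(x, ...) {
  cat(sprintf("<Tukey-Kramer on ranks: %d groups, N = %d, alpha = %g>\n",
              x$k, x$n, x$alpha))
  print(x$pairs)
  invisible(x)
}

#' @method tidy tukey_kramer
#' @export
tidy.tukey_kramer <- function(x, ...) x$pairs

#' Compare conditions by ranked repeatability (or any per-compound metric)
#'
#' The condition-comparison procedure of the pipeline: for each compound the
#' conditions are ranked by the metric (so compounds with large absolute
#' RSDs cannot dominate), then the per-condition rank samples are compared
#' with a Kruskal-Wallis test followed by a Tukey-Kramer all-pairs test on
#' the pooled ranks. `rank_based = FALSE` runs the same tests on the raw
#' metric values for comparison.
#'
#' @param data A `repeatability_summary` or a tibble with `compound`,
#'   `condition` and the metric column.
#' @param metric Metric column name (default `"rsd_pct"`).
#' @param missing Missing-cell handling passed to [rank_conditions()].
#' @param alpha Significance level.
#' @param rank_based Rank per compound before testing (the default).
#' @return A `condition_comparison` object with elements `ranks`, `kw`
#'   (a `kw_test`) and `posthoc` (a `tukey_kramer`).
#' @export
compare_conditions <- function(data, metric = "rsd_pct",
                               missing = c("ignore", "worst_rank"),
                               alpha = 0.05, rank_based = TRUE) {
  missing <- match.arg(missing)
  if (inherits(data, "repeatability_summary")) data <- data$rsd
  data <- as_tibble(data)
  if (rank_based) {
    ranks <- rank_conditions(data, metric = metric, missing = missing)
    score <- "rank"
  } else {
    ranks <- filter(data, !is.na(.data[[!!metric]]))
    score <- metric
  }
  kw <- kruskal_wallis(ranks[[score]], ranks$condition)
  tk <- tukey_kramer(ranks[[score]], ranks$condition, alpha = alpha)
  structure(
    list(ranks = ranks, kw = kw, posthoc = tk, metric = metric,
         missing = missing, alpha = alpha, rank_based = rank_based),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison on %s (%s)>\n", x$metric,
              if (x$rank_based) "per-compound ranks" else "raw values"))
  print(x$kw)
  print(x$posthoc)
  invisible(x)
}

#' @method tidy condition_comparison
#' @export
tidy.condition_comparison <- function(x, ...) tidy(x$posthoc)

#' @method glance condition_comparison
#' @export
glance.condition_comparison <- function(x, ...) {
  tibble(statistic = x$kw$statistic, df = x$kw$df, p.value = x$kw$p.value,
         n_pairs_significant = sum(x$posthoc$pairs$significant),
         alpha = x$alpha)
}
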