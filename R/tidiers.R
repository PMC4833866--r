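#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn optimal_cutoff `tidy()` returns the full candidate-grid
#'   evaluation (one row per candidate cutoff).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.gcr_cutoff <- function(x, ...) x$grid

#' @describeIn optimal_cutoff `glance()` returns a one-row summary with the
#'   optimum, its confusion counts, SENS/SPEC, cost and ROC AUC.
#' @export
glance.gcr_cutoff <- function(x, ...) {
  dplyr::bind_cols(
    x$evaluation,
    tibble::tibble(auc = x$auc, n = x$n, w1 = x$w1, w2 = x$w2,
                   rate_fold_threshold = x$rate_fold_threshold)
  )
}

#' @describeIn ks_discrete_test `tidy()` returns a one-row tibble with the
#'   statistic and p-value.
#' @param x A `ks_discrete` object.
#' @param ... Unused.
#' @export
tidy.ks_discrete <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 n_mc = x$n_mc, n_a = x$n_a, n_b = x$n_b)
}

#' @describeIn ks_discrete_test `glance()` is identical to `tidy()` (the
#'   result is already one row).
#' @export
glance.ks_discrete <- function(x, ...) tidy.ks_discrete(x)

#' @describeIn sscore_set_enrichment `tidy()`/`glance()` return a one-row
#'   tibble with the observed statistic, permutation count and p-value.
#' @param x A `perm_enrichment` object.
#' @param ... Unused.
#' @export
tidy.perm_enrichment <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, observed = x$observed,
    n_as_or_more_extreme = x$n_as_or_more_extreme,
    p.value = x$p.value, n_perm = x$n_perm,
    set_size = x$set_size, pool_size = x$pool_size,
    mean_overshoot = x$mean_overshoot %||% NA_real_
  )
}

#' @describeIn sscore_set_enrichment See `tidy()`.
#' @export
glance.perm_enrichment <- function(x, ...) tidy.perm_enrichment(x)

#' @describeIn reciprocal_consistency `tidy()` returns one row per
#'   reciprocal pair.
#' @param x A `gcr_reciprocal` object.
#' @param ... Unused.
#' @export
tidy.gcr_reciprocal <- function(x, ...) x$pairs

#' @describeIn reciprocal_consistency `glance()` returns the summary row.
#' @export
glance.gcr_reciprocal <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, mean_abs_diff = x$mean_abs_diff,
                 agreement_rate = x$agreement_rate)
}

#' @describeIn summarize_samples `tidy()` returns the combination-fraction
#'   table; `glance()` the percent of samples with any defect per mutation
#'   definition.
#' @param x An `alteration_summary` object.
#' @param ... Unused.
#' @export
tidy.alteration_summary <- function(x, ...) x$fractions

#' @describeIn summarize_samples See `tidy()`.
#' @export
glance.alteration_summary <- function(x, ...) {
  x$pct_any |>
    tidyr::pivot_wider(names_from = "definition", values_from = "pct_any",
                       names_prefix = "pct_any_") |>
    dplyr::mutate(n_samples = x$n_samples)
}
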