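#' Call GIS genes per assay from strain scores, rates and prior knowledge
#'
#' A gene is flagged as suppressing GCRs in an assay when its single-mutant
#' GCR strain score is at least `delta` (default 0.4) above the wild-type
#' control score for that assay. Quantitative rate measurements then
#' override the score evidence in both directions: genes with a measured
#' rate fold below `fold_threshold` (default 3) are removed even if their
#' score passed, and genes with a measured rate fold at or above the
#' threshold are included regardless of score. Previously published GIS
#' genes supplied through `prior_genes` are added with their own evidence
#' tag. Genes with undefined scores (all patches failed to grow) are marked
#' untested.
#'
#' @param strain_scores Data frame of single-mutant scores with columns
#'   `gene`, `assay`, `score` (`NA` score = untested).
#' @param wt_scores Wild-type control score per assay: either a data frame
#'   with columns `assay` and `wt_score` or a named numeric vector. Every
#'   assay present in `strain_scores` must be covered.
#' @param rates Optional data frame of measured rate folds with columns
#'   `gene`, `rate_fold` and optionally `assay` (without an `assay` column
#'   the measurement is applied to every assay).
#' @param prior_genes Optional data frame with columns `gene`, `assay` of
#'   previously published suppressors (or a character vector applied to all
#'   assays).
#' @param delta Score differential above wild type required to flag a gene.
#' @param fold_threshold Rate fold for inclusion/exclusion by rates.
#' @return A tibble with one row per gene-by-assay: `gene`, `assay`,
#'   `score`, `suppresses` (logical, `NA` = untested) and `evidence`
#'   (`"score_cutoff"`, `"rate_threefold"`, `"prior_literature"`,
#'   `"rate_below_threshold"` for score hits removed by rates, or `NA`).
#' @examples
#' scores <- tibble::tibble(gene = c("a", "b"), assay = "dGCR",
#'                          score = c(1.45, 1.0))
#' call_gis(scores, wt_scores = c(dGCR = 1.0))
#' @export
call_gis <- function(strain_scores, wt_scores, rates = NULL,
                     prior_genes = NULL, delta = 0.4, fold_threshold = 3) {
  stopifnot(is.data.frame(strain_scores),
            all(c("gene", "assay", "score") %in% names(strain_scores)))
  if (is.numeric(wt_scores)) {
    wt_scores <- tibble::tibble(assay = names(wt_scores),
                                wt_score = unname(wt_scores))
  }
  stopifnot(all(c("assay", "wt_score") %in% names(wt_scores)))
  missing_wt <- setdiff(unique(strain_scores$assay), wt_scores$assay)
  if (length(missing_wt) > 0) {
    stop("no wild-type score for assay(s): ", paste(missing_wt, collapse = ", "),
         call. = FALSE)
  }
  assays <- unique(strain_scores$assay)

  if (!is.null(rates)) {
    stopifnot(is.data.frame(rates), all(c("gene", "rate_fold") %in% names(rates)))
    if (!"assay" %in% names(rates)) {
      rates <- tidyr::expand_grid(rates, assay = assays)
    }
  } else {
    rates <- tibble::tibble(gene = character(), assay = character(),
                            rate_fold = numeric())
  }
  if (!is.null(prior_genes)) {
    if (is.character(prior_genes)) {
      prior_genes <- tidyr::expand_grid(gene = prior_genes, assay = assays)
    }
    stopifnot(all(c("gene", "assay") %in% names(prior_genes)))
    prior_genes$prior <- TRUE
  } else {
    prior_genes <- tibble::tibble(gene = character(), assay = character(),
                                  prior = logical())
  }

  strain_scores |>
    dplyr::left_join(wt_scores, by = "assay") |>
    dplyr::left_join(rates[, c("gene", "assay", "rate_fold")],
                     by = c("gene", "assay")) |>
    dplyr::full_join(prior_genes, by = c("gene", "assay")) |>
    dplyr::mutate(
      score_hit = !is.na(.data$score) & .data$score >= .data$wt_score + delta,
      rate_hit = !is.na(.data$rate_fold) & .data$rate_fold >= fold_threshold,
      rate_veto = !is.na(.data$rate_fold) & .data$rate_fold < fold_threshold,
      prior = !is.na(.data$prior) & .data$prior,
      # order of precedence: rates override score in both directions,
      # and the prior-literature union is applied last
      suppresses = dplyr::case_when(
        .data$prior ~ TRUE,
        .data$rate_hit ~ TRUE,
        .data$rate_veto ~ FALSE,
        .data$score_hit ~ TRUE,
        is.na(.data$score) ~ NA,
        TRUE ~ FALSE
      ),
      evidence = dplyr::case_when(
        .data$rate_hit ~ "rate_threefold",
        .data$score_hit & .data$rate_veto ~ "rate_below_threshold",
        .data$score_hit ~ "score_cutoff",
        .data$prior ~ "prior_literature",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("gene", "assay", "score", "suppresses", "evidence") |>
    dplyr::arrange(.data$gene, .data$assay)
}

#' Cross-assay overlap of GIS calls
#'
#' Counts, for every non-empty combination of assays, the genes that
#' suppress GCRs in exactly that combination (the cells of a Venn diagram;
#' marginal per-assay totals are recoverable by summing the cells
#' containing an assay).
#'
#' @param calls A [call_gis()] result (columns `gene`, `assay`,
#'   `suppresses`).
#' @return Tibble with `assays` (sorted, `+`-separated combination label),
#'   `n_assays`, and `n_genes`.
#' @examples
#' calls <- tibble::tibble(gene = c("a", "a", "b"),
#'                         assay = c("dGCR", "tyGCR", "dGCR"),
#'                         suppresses = TRUE)
#' assay_overlap(calls)
#' @export
assay_overlap <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("gene", "assay", "suppresses") %in% names(calls)))
  if (length(unique(calls$assay)) < 1) stop("no assays in `calls`", call. = FALSE)
  calls |>
    dplyr::filter(!is.na(.data$suppresses) & .data$suppresses) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      assays = paste(sort(unique(.data$assay)), collapse = "+"),
      n_assays = length(unique(.data$assay)),
      .groups = "drop"
    ) |>
    dplyr::count(.data$assays, .data$n_assays, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_assays), .data$assays)
}

#' Extrapolate screen completeness from a random-sample re-screen
#'
#' Estimates how many suppressor genes a candidate-preselected screen
#' missed by re-screening a random sample of the whole deletion collection:
#' the hit rate among `n_random_screened` randomly chosen untargeted
#' strains is extrapolated to the untested remainder of the pool, and the
#' identified fraction follows.
#'
#' @param hits_in_random_sample New hits found in the random sample.
#' @param n_random_screened Number of randomly sampled strains screened.
#' @param total_pool Size of the whole pool (e.g. all non-essential ORFs).
#' @param n_tested Number of strains covered by the targeted screen.
#' @param n_identified Number of suppressor genes the screen identified.
#' @return One-row tibble: `estimated_missed` =
#'   `(total_pool - n_tested) * hits_in_random_sample / n_random_screened`
#'   and `estimated_pct_identified` =
#'   `100 * n_identified / (n_identified + estimated_missed)`.
#' @examples
#' screen_completeness(1, 463, 4848, 1058, 182)
#' @export
screen_completeness <- function(hits_in_random_sample, n_random_screened,
                                total_pool, n_tested, n_identified) {
  if (n_random_screened <= 0) stop("`n_random_screened` must be > 0", call. = FALSE)
  if (total_pool < n_tested) stop("`total_pool` must be >= `n_tested`", call. = FALSE)
  missed <- (total_pool - n_tested) * hits_in_random_sample / n_random_screened
  if (n_identified + missed <= 0) stop("zero denominator", call. = FALSE)
  tibble::tibble(
    estimated_missed = missed,
    estimated_pct_identified = 100 * n_identified / (n_identified + missed)
  )
}
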