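#' Variant classes counted as loss of function
#'
#' Nonsense, frameshift insertions/deletions, in-frame insertions/deletions
#' and splice-site mutations.
#'
#' @return Character vector of variant-class labels.
#' @export
lof_classes <- function() {
  c("nonsense", "frameshift_insertion", "frameshift_deletion",
    "inframe_insertion", "inframe_deletion", "splice_site")
}

#' Classify mutations as LOF, predicted deleterious missense, or other
#'
#' Loss-of-function (LOF) classes are those in [lof_classes()]. A missense
#' mutation is "predicted deleterious" when at least `ndamage_threshold`
#' (default 5) of the six missense-effect predictors called it deleterious
#' (the `ndamage` score). Everything else -- silent mutations, missense
#' below the threshold, and unknown classes -- is `"other"`.
#'
#' @param mutations Data frame with columns `variant_class` and `ndamage`
#'   (0--6, missense only).
#' @param ndamage_threshold Minimum `ndamage` for a deleterious call.
#' @return The input with an added `category` column
#'   (`"lof"`, `"deleterious_missense"`, `"other"`).
#' @examples
#' m <- tibble::tibble(variant_class = c("nonsense", "missense", "missense"),
#'                     ndamage = c(NA, 5, 4))
#' classify_mutations(m)
#' @export
classify_mutations <- function(mutations, ndamage_threshold = 5) {
  stopifnot(is.data.frame(mutations),
            all(c("variant_class", "ndamage") %in% names(mutations)))
  known <- c(lof_classes(), "missense", "silent", "other")
  unknown <- setdiff(unique(mutations$variant_class), known)
  if (length(unknown) > 0) {
    message("unknown variant class(es) treated as 'other': ",
            paste(unknown, collapse = ", "))
  }
  dplyr::mutate(
    mutations,
    category = dplyr::case_when(
      .data$variant_class %in% lof_classes() ~ "lof",
      .data$variant_class == "missense" & !is.na(.data$ndamage) &
        .data$ndamage >= ndamage_threshold ~ "deleterious_missense",
      TRUE ~ "other"
    )
  )
}

#' Select candidate tumour-suppressor (or proto-oncogene) genes by S-score
#'
#' The S-score integrates copy-number, expression, methylation and mutation
#' evidence per gene over a cohort; strongly negative scores are consistent
#' with tumour suppressors, strongly positive ones with proto-oncogenes.
#' Genes at or below `threshold` (default -2) form the strict set, and
#' genes between `threshold` and `borderline` (default -1.95) form a
#' borderline band that is included but reported distinctly.
#'
#' @param annotations Data frame with columns `gene` and `s_score`.
#' @param threshold Strict threshold (default -2).
#' @param borderline Borderline threshold (default -1.95); must be no
#'   stricter than `threshold`.
#' @param direction `"suppressor"` selects low scores, `"oncogene"` flips
#'   the signs and selects high scores.
#' @return Tibble with `gene`, `s_score`, `band` (`"strict"` or
#'   `"borderline"`), containing only the selected genes.
#' @examples
#' ann <- tibble::tibble(gene = c("a", "b", "c"),
#'                       s_score = c(-2.3, -1.97, -1.5))
#' select_ts_candidates(ann)
#' @export
select_ts_candidates <- function(annotations, threshold = -2,
                                 borderline = -1.95,
                                 direction = c("suppressor", "oncogene")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(annotations),
            all(c("gene", "s_score") %in% names(annotations)))
  s <- annotations$s_score
  if (direction == "oncogene") {
    s <- -s
    threshold <- -abs(threshold)
    borderline <- -abs(borderline)
  }
  if (borderline < threshold) {
    stop("`borderline` must not be stricter than `threshold`", call. = FALSE)
  }
  annotations |>
    dplyr::mutate(.s = s) |>
    dplyr::filter(.data$.s <= borderline) |>
    dplyr::mutate(band = ifelse(.data$.s <= threshold, "strict", "borderline")) |>
    dplyr::select("gene", "s_score", "band") |>
    dplyr::arrange(.data$s_score * ifelse(direction == "oncogene", -1, 1))
}

#' Classify per-sample defects in candidate genes
#'
#' For every sample-by-candidate-gene combination, assigns the defect
#' categories:
#'
#' * `lof_mutation` -- any loss-of-function mutation ([lof_classes()]);
#' * `deleterious_missense` -- missense with `ndamage >= ndamage_threshold`;
#' * `cn_reduced_low_expression` -- GISTIC call of -1 or -2 together with
#'   an expression Z-score below `z_threshold` (default -2);
#' * `silenced` -- promoter hypermethylation with a Z-score below
#'   `z_threshold` and no copy-number loss (GISTIC >= 0), isolating
#'   epigenetic loss from copy-number-driven loss.
#'
#' Categories that need a platform the sample was not profiled on are `NA`
#' (unassessed), never `FALSE`. Samples absent from every platform are
#' excluded with a message.
#'
#' @param mutations,cnv,expression,methylation Long-format tibbles as in
#'   [simulate_cancer()] (or from [read_maf()] / [read_matrix_tsv()]).
#' @param genes Character vector of candidate genes to assess.
#' @param availability Optional tibble (`sample`, `platform`, `available`).
#'   When `NULL`, a sample counts as profiled on a platform iff it appears
#'   in that platform's table.
#' @param z_threshold Expression Z-score threshold (default -2).
#' @param ndamage_threshold Missense predictor threshold (default 5).
#' @return Tibble with one row per sample-by-gene: `sample`, `gene`, the
#'   four logical category columns, and `any_defect` (under the LOF-only
#'   mutation definition together with CN/expression and silencing).
#' @export
call_alterations <- function(mutations, cnv, expression, methylation,
                             genes, availability = NULL,
                             z_threshold = -2, ndamage_threshold = 5) {
  stopifnot(length(genes) > 0)
  if (is.null(availability)) {
    availability <- dplyr::bind_rows(
      tibble::tibble(sample = unique(mutations$sample), platform = "mutation"),
      tibble::tibble(sample = unique(cnv$sample), platform = "cnv"),
      tibble::tibble(sample = unique(expression$sample), platform = "expression"),
      tibble::tibble(sample = unique(methylation$sample), platform = "methylation")
    ) |>
      dplyr::mutate(available = TRUE)
  }
  avail <- availability |>
    tidyr::pivot_wider(names_from = "platform", values_from = "available",
                       values_fill = FALSE)
  for (p in c("mutation", "cnv", "expression", "methylation")) {
    if (!p %in% names(avail)) avail[[p]] <- FALSE
  }
  no_data <- avail$sample[!(avail$mutation | avail$cnv | avail$expression |
                              avail$methylation)]
  if (length(no_data) > 0) {
    message(length(no_data), " sample(s) with no platform data excluded")
    avail <- dplyr::filter(avail, !.data$sample %in% no_data)
  }

  mut_calls <- classify_mutations(
    dplyr::filter(mutations, .data$gene %in% genes), ndamage_threshold
  ) |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::summarise(has_lof = any(.data$category == "lof"),
                     has_del_mis = any(.data$category == "deleterious_missense"),
                     .groups = "drop")

  tidyr::expand_grid(sample = avail$sample, gene = genes) |>
    dplyr::left_join(avail, by = "sample") |>
    dplyr::left_join(mut_calls, by = c("sample", "gene")) |>
    dplyr::left_join(dplyr::filter(cnv, .data$gene %in% genes),
                     by = c("sample", "gene")) |>
    dplyr::left_join(dplyr::filter(expression, .data$gene %in% genes),
                     by = c("sample", "gene")) |>
    dplyr::left_join(dplyr::filter(methylation, .data$gene %in% genes),
                     by = c("sample", "gene")) |>
    dplyr::mutate(
      lof_mutation = ifelse(.data$mutation,
                            !is.na(.data$has_lof) & .data$has_lof, NA),
      deleterious_missense = ifelse(.data$mutation,
                                    !is.na(.data$has_del_mis) & .data$has_del_mis,
                                    NA),
      cn_reduced_low_expression = ifelse(
        .data$cnv & .data$expression,
        !is.na(.data$gistic) & .data$gistic < 0 &
          !is.na(.data$z) & .data$z < z_threshold,
        NA
      ),
      silenced = ifelse(
        .data$methylation & .data$expression & .data$cnv,
        !is.na(.data$hypermethylated) & .data$hypermethylated &
          !is.na(.data$z) & .data$z < z_threshold &
          !is.na(.data$gistic) & .data$gistic >= 0,
        NA
      ),
      any_defect = (!is.na(.data$lof_mutation) & .data$lof_mutation) |
        (!is.na(.data$cn_reduced_low_expression) &
           .data$cn_reduced_low_expression) |
        (!is.na(.data$silenced) & .data$silenced)
    ) |>
    dplyr::select("sample", "gene", "lof_mutation", "deleterious_missense",
                  "cn_reduced_low_expression", "silenced", "any_defect")
}

#' Per-sample summary of combined defect classes
#'
#' Collapses an alteration table to per-sample defect signatures and counts
#' the mutually exclusive combinations of the three evidence classes
#' (mutation, reduced copy number with reduced expression, silencing),
#' separately for the LOF-only and the LOF-plus-predicted-deleterious-
#' missense mutation definitions.
#'
#' @param calls A [call_alterations()] result.
#' @param denominator `"any"` (default) counts every sample with any
#'   platform data; `"complete"` restricts to samples assessed on all
#'   three evidence classes.
#' @param mmr_exclude Optional character vector of samples to drop before
#'   summarising (e.g. mismatch-repair-defective hypermutators).
#' @return Object of class `alteration_summary`: `fractions` (tibble with
#'   `definition`, `combination`, `n`, `fraction`), `per_sample` (tibble
#'   with `sample`, `definition`, `n_genes_altered`), `n_samples`, and
#'   `pct_any` (tibble: percent of samples with >= 1 defect per
#'   definition). Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
summarize_samples <- function(calls, denominator = c("any", "complete"),
                              mmr_exclude = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0) stop("`calls` must be non-empty", call. = FALSE)
  if (!is.null(mmr_exclude)) {
    calls <- dplyr::filter(calls, !.data$sample %in% mmr_exclude)
  }
  per_def <- function(include_missense) {
    mut <- if (include_missense) {
      (!is.na(calls$lof_mutation) & calls$lof_mutation) |
        (!is.na(calls$deleterious_missense) & calls$deleterious_missense)
    } else {
      !is.na(calls$lof_mutation) & calls$lof_mutation
    }
    df <- calls |>
      dplyr::mutate(.mut = mut) |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(
        mutation = any(.data$.mut),
        cn_expression = any(!is.na(.data$cn_reduced_low_expression) &
                              .data$cn_reduced_low_expression),
        silencing = any(!is.na(.data$silenced) & .data$silenced),
        assessed_all = all(!is.na(.data$lof_mutation)) &&
          all(!is.na(.data$cn_reduced_low_expression)) &&
          all(!is.na(.data$silenced)),
        n_genes_altered = sum(
          .data$.mut |
            (!is.na(.data$cn_reduced_low_expression) &
               .data$cn_reduced_low_expression) |
            (!is.na(.data$silenced) & .data$silenced)
        ),
        .groups = "drop"
      )
    if (denominator == "complete") df <- dplyr::filter(df, .data$assessed_all)
    df
  }
  defs <- list(lof_only = per_def(FALSE),
               lof_plus_missense = per_def(TRUE))
  combo_label <- function(m, c, s) {
    lab <- c("mutation", "cn_expression", "silencing")[c(m, c, s)]
    if (length(lab) == 0) "none" else paste(lab, collapse = "+")
  }
  fractions <- purrr::imap_dfr(defs, function(df, def) {
    df |>
      dplyr::mutate(combination = purrr::pmap_chr(
        list(.data$mutation, .data$cn_expression, .data$silencing),
        combo_label
      )) |>
      dplyr::count(.data$combination, name = "n") |>
      dplyr::mutate(definition = def, fraction = .data$n / sum(.data$n)) |>
      dplyr::select("definition", "combination", "n", "fraction")
  })
  per_sample <- purrr::imap_dfr(defs, function(df, def) {
    tibble::tibble(sample = df$sample, definition = def,
                   n_genes_altered = df$n_genes_altered)
  })
  pct_any <- fractions |>
    dplyr::group_by(.data$definition) |>
    dplyr::summarise(pct_any = 100 * sum(.data$fraction[.data$combination != "none"]),
                     .groups = "drop")
  structure(
    list(fractions = fractions, per_sample = per_sample,
         n_samples = nrow(defs$lof_only), pct_any = pct_any),
    class = "alteration_summary"
  )
}

#' @export
print.alteration_summary <- function(x, ...) {
  cat(sprintf("Defect summary over %d samples\n", x$n_samples))
  for (i in seq_len(nrow(x$pct_any))) {
    cat(sprintf("  %% with >= 1 defective gene (%s): %.1f%%\n",
                x$pct_any$definition[i], x$pct_any$pct_any[i]))
  }
  invisible(x)
}
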