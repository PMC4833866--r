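#' Convert papillae counts to categorical patch scores
#'
#' Assigns the semi-quantitative 0--5 score used to read out gross
#' chromosomal rearrangement (GCR) patch tests. Each patch of a strain is
#' replica-plated onto double-selective medium and the papillae (CanR 5FOAR
#' colonies, each reflecting an independent GCR event) are counted; the
#' count is then binned:
#'
#' * 0 -- no papillae
#' * 1 -- 1 to 5 papillae (the typical control-strain patch)
#' * 2 -- 6 to 15 papillae
#' * 3 -- 16 up to a countable number of papillae (~150)
#' * 4 -- too many or too close together to count (up to `lawn_threshold`)
#' * 5 -- a lawn of papillae covering the patch
#'
#' Patches that failed to grow carry no information about the GCR rate and
#' are returned as `NA`, the no-growth sentinel; downstream averaging skips
#' them rather than treating them as zeros.
#'
#' @param papillae_count Integer vector of papillae counts (`NA` allowed for
#'   patches that did not grow).
#' @param grew Logical vector (recycled); `FALSE` marks patches that failed
#'   to grow.
#' @param lawn Logical vector (recycled); `TRUE` forces score 5 regardless
#'   of the recorded count.
#' @param countable_max Upper bound of the score-3 band (default 150).
#' @param lawn_threshold Counts above this are scored 5 (default 1000).
#' @return Integer vector of patch scores in `0:5`, `NA` for no-growth
#'   patches.
#' @examples
#' score_patch(c(0, 3, 10, 40, 500, 2000))
#' score_patch(7, grew = FALSE)
#' @export
score_patch <- function(papillae_count, grew = TRUE, lawn = FALSE,
                        countable_max = 150, lawn_threshold = 1000) {
  n <- max(length(papillae_count), length(grew), length(lawn))
  papillae_count <- rep_len(papillae_count, n)
  grew <- rep_len(grew, n)
  lawn <- rep_len(lawn, n)
  if (any(papillae_count[grew & !is.na(papillae_count)] < 0)) {
    stop("`papillae_count` must be non-negative for grown patches", call. = FALSE)
  }
  sc <- rep(NA_integer_, n)
  idx <- grew & !is.na(grew)
  cnt <- papillae_count[idx]
  sc[idx] <- dplyr::case_when(
    lawn[idx] | cnt > lawn_threshold ~ 5L,
    cnt > countable_max ~ 4L,
    cnt >= 16 ~ 3L,
    cnt >= 6 ~ 2L,
    cnt >= 1 ~ 1L,
    TRUE ~ 0L
  )
  sc
}

#' Average patch scores into a GCR strain score
#'
#' The GCR strain score of one genotype in one assay is the arithmetic mean
#' of all of its valid (grown) patch scores. No-growth sentinels (`NA`) are
#' excluded from the mean; a strain whose patches all failed to grow has an
#' undefined score and is flagged so it can be ignored downstream.
#'
#' @param scores Numeric vector of patch scores (0--5), `NA` marking
#'   no-growth patches. Must be non-empty.
#' @param min_patches Minimum number of valid patches expected (default 3,
#'   the usual number of independent spore clones); fewer triggers the
#'   `low_n` flag but not an error.
#' @return A one-row tibble with columns `score` (mean, `NA` if no valid
#'   patch), `n_valid`, `n_no_growth`, and `low_n`.
#' @examples
#' strain_score(c(1, 1, 2))
#' strain_score(c(2, NA, 2, 2))
#' @export
strain_score <- function(scores, min_patches = 3) {
  if (length(scores) == 0) stop("`scores` must be non-empty", call. = FALSE)
  valid <- scores[!is.na(scores)]
  if (length(valid) > 0 && (min(valid) < 0 || max(valid) > 5)) {
    stop("patch scores must lie in [0, 5]", call. = FALSE)
  }
  tibble::tibble(
    score = if (length(valid) == 0) NA_real_ else mean(valid),
    n_valid = length(valid),
    n_no_growth = sum(is.na(scores)),
    low_n = length(valid) < min_patches
  )
}

#' Score every strain in a papillae table
#'
#' Applies [score_patch()] to each patch record and [strain_score()] to each
#' genotype-by-assay group of a patch table such as the one produced by
#' [simulate_screen()].
#'
#' @param patches A data frame with one row per patch, containing
#'   `papillae_count` and `grew` columns (and optionally `lawn`) plus the
#'   grouping columns in `by`.
#' @param by Character vector of columns identifying a strain
#'   (default `c("query_gene", "bait_gene", "assay")`).
#' @param min_patches Passed to [strain_score()].
#' @inheritParams score_patch
#' @return A tibble with one row per strain: the `by` columns plus `score`,
#'   `n_valid`, `n_no_growth`, `low_n`.
#' @examples
#' sim <- simulate_screen(screen_config(n_baits = 5, n_queries = 2, seed = 1))
#' score_strains(sim$patches)
#' @export
score_strains <- function(patches, by = c("query_gene", "bait_gene", "assay"),
                          min_patches = 3, countable_max = 150,
                          lawn_threshold = 1000) {
  stopifnot(is.data.frame(patches))
  missing_cols <- setdiff(c(by, "papillae_count", "grew"), names(patches))
  if (length(missing_cols) > 0) {
    stop("`patches` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  lawn <- if ("lawn" %in% names(patches)) patches$lawn else FALSE
  patches |>
    dplyr::mutate(.patch_score = score_patch(.data$papillae_count, .data$grew,
                                             lawn, countable_max, lawn_threshold)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      score = if (all(is.na(.data$.patch_score))) NA_real_ else
        mean(.data$.patch_score, na.rm = TRUE),
      n_valid = sum(!is.na(.data$.patch_score)),
      n_no_growth = sum(is.na(.data$.patch_score)),
      low_n = sum(!is.na(.data$.patch_score)) < min_patches,
      .groups = "drop"
    )
}
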