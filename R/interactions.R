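#' Call a genetic interaction from double- and single-mutant scores
#'
#' A query-by-bait double mutant is called as interacting when its GCR
#' strain score exceeds the higher of the two single-mutant strain scores
#' by at least `delta` (default 0.4, the single-mutant strain differential
#' score). High scores come close to saturating the 0--5 scale, so calls
#' where any input score reaches `saturation` (default 4.5) are retained
#' but flagged. If either single-mutant score is undefined the pair is
#' untestable and never called.
#'
#' All arguments are vectorised.
#'
#' @param double_score Score of the double mutant (0--5).
#' @param single_score_query,single_score_bait Scores of the two single
#'   mutants (`NA` = undefined).
#' @param delta Required score differential.
#' @param saturation Score at or above which the saturation flag is set.
#' @return Tibble with `double_score`, `single_score_query`,
#'   `single_score_bait`, `differential`, `called`, `untestable`,
#'   `saturated`.
#' @examples
#' call_interaction(2.0, 1.0, 1.2)
#' call_interaction(4.8, 4.0, 1.0)
#' @export
call_interaction <- function(double_score, single_score_query,
                             single_score_bait, delta = 0.4,
                             saturation = 4.5) {
  n <- max(length(double_score), length(single_score_query),
           length(single_score_bait))
  double_score <- rep_len(double_score, n)
  single_score_query <- rep_len(single_score_query, n)
  single_score_bait <- rep_len(single_score_bait, n)
  all_scores <- c(double_score, single_score_query, single_score_bait)
  if (any(all_scores < 0 | all_scores > 5, na.rm = TRUE)) {
    stop("scores must lie in [0, 5]", call. = FALSE)
  }
  max_single <- pmax(single_score_query, single_score_bait)
  differential <- double_score - max_single
  untestable <- is.na(double_score) | is.na(single_score_query) |
    is.na(single_score_bait)
  tibble::tibble(
    double_score, single_score_query, single_score_bait,
    differential = differential,
    called = !untestable & differential >= delta,
    untestable = untestable,
    saturated = !untestable &
      (double_score >= saturation | max_single >= saturation)
  )
}

#' Call all query-by-bait interactions in a strain-score table
#'
#' Joins double-mutant scores with the corresponding single-mutant scores
#' (the bait crossed to the wild-type query and the query crossed to the
#' control bait) and applies [call_interaction()] to every pair.
#'
#' @param strain_scores A [score_strains()] result: columns `query_gene`,
#'   `bait_gene`, `assay`, `score`.
#' @param wt_query Label of the wild-type query (default `"WT"`); rows with
#'   this query are the bait single mutants.
#' @param control_bait Label of the control bait (default `"control"`);
#'   rows with this bait are the query single mutants.
#' @inheritParams call_interaction
#' @return Tibble with one row per double mutant: `query_gene`,
#'   `bait_gene`, `assay` plus the [call_interaction()] columns.
#' @examples
#' sim <- simulate_screen(screen_config(n_baits = 20, n_queries = 3, seed = 2))
#' calls <- call_interactions(score_strains(sim$patches))
#' head(calls)
#' @export
call_interactions <- function(strain_scores, delta = 0.4, saturation = 4.5,
                              wt_query = "WT", control_bait = "control") {
  stopifnot(is.data.frame(strain_scores),
            all(c("query_gene", "bait_gene", "assay", "score") %in%
                  names(strain_scores)))
  bait_singles <- strain_scores |>
    dplyr::filter(.data$query_gene == wt_query,
                  .data$bait_gene != control_bait) |>
    dplyr::select("bait_gene", "assay", single_score_bait = "score")
  query_singles <- strain_scores |>
    dplyr::filter(.data$bait_gene == control_bait,
                  .data$query_gene != wt_query) |>
    dplyr::select("query_gene", "assay", single_score_query = "score")
  doubles <- strain_scores |>
    dplyr::filter(.data$query_gene != wt_query,
                  .data$bait_gene != control_bait)
  if (nrow(doubles) == 0) stop("no double-mutant scores found", call. = FALSE)
  doubles |>
    dplyr::left_join(query_singles, by = c("query_gene", "assay")) |>
    dplyr::left_join(bait_singles, by = c("bait_gene", "assay")) |>
    dplyr::mutate(call_interaction(.data$score, .data$single_score_query,
                                   .data$single_score_bait, delta,
                                   saturation)) |>
    dplyr::select("query_gene", "bait_gene", "assay", "double_score",
                  "single_score_query", "single_score_bait", "differential",
                  "called", "untestable", "saturated")
}

#' Number of unordered query pairs
#'
#' @param n_queries Number of query mutations (>= 0); vectorised.
#' @return `n * (n - 1) / 2`, the number of distinct unordered pairs.
#' @examples
#' possible_pairs(43)
#' @export
possible_pairs <- function(n_queries) {
  if (any(n_queries < 0)) stop("`n_queries` must be >= 0", call. = FALSE)
  choose(n_queries, 2)
}

#' Consistency of reciprocal query-by-bait crosses
#'
#' When the same gene pair was screened in both orientations (a as query
#' with b as bait, and b as query with a as bait), the two double-mutant
#' scores should agree. Reports the absolute score difference and the
#' agreement of the called flags for every reciprocal pair, together with
#' summary statistics.
#'
#' @param calls A [call_interactions()] result.
#' @return Object of class `gcr_reciprocal`: `pairs` (one row per
#'   reciprocal pair and assay with both scores, `abs_diff`, `agree`),
#'   `mean_abs_diff`, and `agreement_rate` (over pairs where both
#'   orientations were testable). Supports [tidy()] and [glance()]. The
#'   `pairs` tibble is empty when no reciprocal crosses exist.
#' @export
reciprocal_consistency <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("query_gene", "bait_gene", "assay", "double_score",
                  "called", "untestable") %in% names(calls)))
  ab <- calls |>
    dplyr::mutate(
      gene_a = pmin(.data$query_gene, .data$bait_gene),
      gene_b = pmax(.data$query_gene, .data$bait_gene),
      orientation = ifelse(.data$query_gene == .data$gene_a, "ab", "ba")
    )
  pairs <- ab |>
    dplyr::filter(.data$orientation == "ab") |>
    dplyr::inner_join(
      ab |> dplyr::filter(.data$orientation == "ba"),
      by = c("gene_a", "gene_b", "assay"), suffix = c("_ab", "_ba")
    ) |>
    dplyr::transmute(
      gene_a = .data$gene_a, gene_b = .data$gene_b, assay = .data$assay,
      score_ab = .data$double_score_ab, score_ba = .data$double_score_ba,
      abs_diff = abs(.data$score_ab - .data$score_ba),
      both_testable = !.data$untestable_ab & !.data$untestable_ba,
      agree = .data$called_ab == .data$called_ba
    )
  testable <- dplyr::filter(pairs, .data$both_testable)
  structure(
    list(
      pairs = pairs,
      n_pairs = nrow(pairs),
      mean_abs_diff = if (nrow(testable) > 0) mean(testable$abs_diff) else NA_real_,
      agreement_rate = if (nrow(testable) > 0) mean(testable$agree) else NA_real_
    ),
    class = "gcr_reciprocal"
  )
}

#' @export
print.gcr_reciprocal <- function(x, ...) {
  cat(sprintf(
    "Reciprocal crosses: %d pairs, mean |score diff| = %.3f, call agreement = %.3f\n",
    x$n_pairs, x$mean_abs_diff, x$agreement_rate))
  invisible(x)
}

#' Identify cooperating GIS (cGIS) genes
#'
#' cGIS genes elevate GCR rates only in combination with a query mutation:
#' they appear as the bait in at least one called interaction but are not
#' themselves GIS genes.
#'
#' @param calls A [call_interactions()] result.
#' @param gis_genes Character vector of GIS genes to exclude.
#' @return Tibble with `gene` and `n_queries` (number of distinct query
#'   mutations the gene interacts with).
#' @examples
#' calls <- tibble::tibble(query_gene = "q", bait_gene = c("a", "b"),
#'                         assay = "dGCR", called = c(TRUE, FALSE))
#' identify_cgis(calls, gis_genes = character())
#' @export
identify_cgis <- function(calls, gis_genes = character()) {
  stopifnot(is.data.frame(calls),
            all(c("query_gene", "bait_gene", "called") %in% names(calls)))
  if (nrow(calls) == 0) stop("`calls` must be non-empty", call. = FALSE)
  calls |>
    dplyr::filter(.data$called, !.data$bait_gene %in% gis_genes) |>
    dplyr::group_by(gene = .data$bait_gene) |>
    dplyr::summarise(n_queries = length(unique(.data$query_gene)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_queries), .data$gene)
}

#' Classify gene modules by shared interacting queries
#'
#' Modules (annotated complexes or pathways) are split into two groups:
#' group 1 modules contain at least two member genes with called
#' interactions that share at least one common interacting query mutation;
#' group 2 modules have interactions that are not shared (including modules
#' where only a single gene interacts). Modules with no tested member are
#' marked untested (`NA` group).
#'
#' @param modules Data frame with columns `module` and `gene` (one row per
#'   member), e.g. from [read_gmt()].
#' @param calls A [call_interactions()] result.
#' @return Tibble with one row per module: `module`, `n_members`,
#'   `n_tested`, `n_interacting`, `group` (1, 2 or `NA`), and
#'   `shared_queries` (comma-separated queries common to >= 2 interacting
#'   members, `""` if none).
#' @examples
#' modules <- tibble::tibble(module = "M1", gene = c("a", "b"))
#' calls <- tibble::tibble(query_gene = c("q1", "q2", "q2", "q3"),
#'                         bait_gene = c("a", "a", "b", "b"),
#'                         assay = "dGCR", called = TRUE, untestable = FALSE)
#' classify_modules(modules, calls)
#' @export
classify_modules <- function(modules, calls) {
  stopifnot(is.data.frame(modules), all(c("module", "gene") %in% names(modules)))
  if (nrow(modules) == 0) stop("`modules` must be non-empty", call. = FALSE)
  tested_genes <- unique(calls$bait_gene[!calls$untestable])
  interactions <- calls |>
    dplyr::filter(.data$called) |>
    dplyr::distinct(gene = .data$bait_gene, query = .data$query_gene)
  modules |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      n_members = length(unique(.data$gene)),
      n_tested = sum(unique(.data$gene) %in% tested_genes),
      members = list(unique(.data$gene)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      info = purrr::map(.data$members, function(gs) {
        qsets <- interactions |>
          dplyr::filter(.data$gene %in% gs) |>
          dplyr::group_by(.data$gene) |>
          dplyr::summarise(qs = list(unique(.data$query)), .groups = "drop")
        shared <- character(0)
        if (nrow(qsets) >= 2) {
          all_q <- unlist(qsets$qs)
          shared <- unique(all_q[duplicated(all_q)])
        }
        tibble::tibble(n_interacting = nrow(qsets),
                       shared_queries = paste(sort(shared), collapse = ","))
      })
    ) |>
    tidyr::unnest("info") |>
    dplyr::mutate(
      group = dplyr::case_when(
        .data$n_tested == 0 ~ NA_integer_,
        .data$n_interacting >= 2 & .data$shared_queries != "" ~ 1L,
        TRUE ~ 2L
      )
    ) |>
    dplyr::select("module", "n_members", "n_tested", "n_interacting",
                  "group", "shared_queries")
}

#' Interaction degree per query and per bait
#'
#' Counts called interactions for each query mutation and each bait gene.
#'
#' @param calls A [call_interactions()] result.
#' @return List of two tibbles, `per_query` (`query_gene`, `degree`) and
#'   `per_bait` (`bait_gene`, `degree`).
#' @export
interaction_degrees <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("query_gene", "bait_gene", "called") %in% names(calls)))
  called <- dplyr::filter(calls, .data$called)
  list(
    per_query = dplyr::count(called, .data$query_gene, name = "degree") |>
      dplyr::arrange(dplyr::desc(.data$degree)),
    per_bait = dplyr::count(called, .data$bait_gene, name = "degree") |>
      dplyr::arrange(dplyr::desc(.data$degree))
  )
}

#' Rate-based confirmation of a synergistic interaction
#'
#' Optional follow-up on called interactions when fluctuation-assay rate
#' folds are available for the double mutant and both singles. Under the
#' default additive null a pair is synergistic when the double-mutant rate
#' fold exceeds the sum of the single-mutant folds; the multiplicative null
#' requires it to exceed their product. Vectorised.
#'
#' @param double_fold,fold_a,fold_b Rate folds relative to wild type.
#' @param null `"additive"` (default) or `"multiplicative"`.
#' @return Logical vector: synergistic under the chosen null.
#' @examples
#' rate_synergy(12, 3, 4)                          # 12 > 3 + 4
#' rate_synergy(12, 3, 4, null = "multiplicative") # 12 > 12 is FALSE
#' @export
rate_synergy <- function(double_fold, fold_a, fold_b,
                         null = c("additive", "multiplicative")) {
  null <- match.arg(null)
  expected <- if (null == "additive") fold_a + fold_b else fold_a * fold_b
  double_fold > expected
}
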