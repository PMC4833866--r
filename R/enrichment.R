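#' Gene-set enrichment for extreme S-scores by randomisation
#'
#' Tests whether a query gene set contains more genes with extreme S-scores
#' than expected by chance. The observed statistic is the number of query
#' genes satisfying the extreme rule (`s_score <= threshold` for
#' tumour-suppressor signatures, `>=` for proto-oncogene signatures). Each
#' of `n_perm` permutations draws a uniform random gene set of the same
#' size, without replacement, from all scored genes and recomputes the
#' count; the one-sided enrichment p-value is the add-one rank
#' `p = (#{perm >= obs} + 1) / (n_perm + 1)`.
#'
#' @param gene_scores Data frame with columns `gene` and `s_score`.
#' @param query_set Character vector of genes (must all be scored).
#' @param threshold Extreme-score threshold (default -2).
#' @param direction `"le"` counts scores `<= threshold` (tumour
#'   suppressors); `"ge"` counts scores `>= threshold`.
#' @param n_perm Number of random sets (default 10000).
#' @param seed Optional integer seed.
#' @return Object of class `perm_enrichment` with `observed`, `p.value`,
#'   `n_as_or_more_extreme`, `n_perm`, `perm_stats` (the null draws) and
#'   bookkeeping fields. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' scores <- tibble::tibble(gene = letters[1:20],
#'                          s_score = c(rep(-3, 5), rnorm(15)))
#' sscore_set_enrichment(scores, letters[1:6], n_perm = 999, seed = 1)
#' @export
sscore_set_enrichment <- function(gene_scores, query_set, threshold = -2,
                                  direction = c("le", "ge"),
                                  n_perm = 10000, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(gene_scores),
            all(c("gene", "s_score") %in% names(gene_scores)))
  if (!all(query_set %in% gene_scores$gene)) {
    stop("all `query_set` genes must be present in `gene_scores`", call. = FALSE)
  }
  if (length(query_set) > nrow(gene_scores)) {
    stop("`query_set` larger than the gene pool", call. = FALSE)
  }
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  extreme <- if (direction == "le") gene_scores$s_score <= threshold
             else gene_scores$s_score >= threshold
  k <- length(query_set)
  n <- nrow(gene_scores)
  observed <- sum(extreme[gene_scores$gene %in% query_set])
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    sum(extreme[sample.int(n, k)])
  }, numeric(1))
  exceed <- sum(perm_stats >= observed)
  structure(
    list(statistic = "n_extreme", observed = observed,
         n_as_or_more_extreme = exceed,
         p.value = (exceed + 1) / (n_perm + 1),
         n_perm = n_perm, set_size = k, pool_size = n,
         perm_stats = perm_stats, seed = seed),
    class = "perm_enrichment"
  )
}

#' @export
print.perm_enrichment <- function(x, ...) {
  cat(sprintf(
    "Permutation enrichment (%s): observed = %g, p = %.4g (%d permutations)\n",
    x$statistic, x$observed, x$p.value, x$n_perm))
  invisible(x)
}

# Preset variant-class filters used in per-class mutation enrichment.
mutation_class_presets <- function() {
  list(
    lof = lof_classes(),
    deletions = c("frameshift_deletion", "inframe_deletion"),
    insertions = c("frameshift_insertion", "inframe_insertion"),
    frameshifts = c("frameshift_deletion", "frameshift_insertion"),
    nonsense = "nonsense",
    splice_site = "splice_site",
    missense = "missense"
  )
}

#' Amino-acid-length-normalised mutation enrichment by randomisation
#'
#' Tests whether a query gene set carries more mutations of the chosen
#' classes than random gene sets of matched total protein length. Long
#' genes accumulate more background mutations, so matching random sets by
#' gene count alone is biased in favour of long-gene sets; matching by
#' total amino-acid length removes that bias. Each permutation samples
#' genes uniformly without replacement until the cumulative protein length
#' reaches the query set's total (the last gene may overshoot; the mean
#' overshoot fraction is reported) and counts the qualifying mutations in
#' the sampled set. The p-value is the add-one one-sided rank as in
#' [sscore_set_enrichment()].
#'
#' @param mutations Data frame with columns `sample`, `gene`,
#'   `variant_class` and optionally `in_mononucleotide_repeat`.
#' @param annotations Data frame with columns `gene` and `length_aa`; every
#'   gene in the pool needs a length.
#' @param query_set Character vector of genes (all annotated).
#' @param classes Variant classes to count: a character vector of class
#'   labels or the name of a preset (`"lof"`, `"deletions"`,
#'   `"insertions"`, `"frameshifts"`, `"nonsense"`, `"splice_site"`,
#'   `"missense"`). Must be non-empty.
#' @param mono_repeat_only If `TRUE`, count only mutations flagged as lying
#'   in a mononucleotide repeat.
#' @param match_by `"length"` (default) samples random sets to matched
#'   total amino-acid length; `"count"` is the naive same-size-set test,
#'   exposed for comparison.
#' @param n_perm Number of random sets (default 10000).
#' @param seed Optional integer seed.
#' @return Object of class `perm_enrichment`; for `match_by = "length"`
#'   the element `mean_overshoot` gives the mean fractional length
#'   overshoot of the random sets.
#' @examples
#' cohort <- simulate_cancer(cancer_config(n_samples = 40, n_genes = 30,
#'                                         planted_ts_genes = 5, seed = 3))
#' length_normalized_mutation_enrichment(
#'   cohort$mutations, cohort$annotations,
#'   cohort$truth$planted_genes, classes = "lof", n_perm = 999, seed = 1)
#' @export
length_normalized_mutation_enrichment <- function(mutations, annotations,
                                                  query_set, classes = "lof",
                                                  mono_repeat_only = FALSE,
                                                  match_by = c("length", "count"),
                                                  n_perm = 10000, seed = NULL) {
  match_by <- match.arg(match_by)
  stopifnot(is.data.frame(mutations), is.data.frame(annotations),
            all(c("gene", "length_aa") %in% names(annotations)))
  if (length(classes) == 0) stop("`classes` must be non-empty", call. = FALSE)
  if (length(classes) == 1 && classes %in% names(mutation_class_presets())) {
    classes <- mutation_class_presets()[[classes]]
  }
  if (!all(query_set %in% annotations$gene)) {
    stop("all `query_set` genes must be annotated", call. = FALSE)
  }
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  qualifying <- mutations$variant_class %in% classes
  if (mono_repeat_only) {
    if (!"in_mononucleotide_repeat" %in% names(mutations)) {
      stop("`mutations` lacks the `in_mononucleotide_repeat` flag", call. = FALSE)
    }
    qualifying <- qualifying & mutations$in_mononucleotide_repeat
  }
  counts <- stats::setNames(rep(0, nrow(annotations)), annotations$gene)
  tab <- table(mutations$gene[qualifying])
  counts[names(tab)] <- as.numeric(tab)
  lengths <- stats::setNames(annotations$length_aa, annotations$gene)

  observed <- sum(counts[query_set])
  target_length <- sum(lengths[query_set])
  k <- length(query_set)
  n <- nrow(annotations)
  len_vec <- unname(lengths)
  cnt_vec <- unname(counts)

  overshoot <- numeric(n_perm)
  perm_stats <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    ord <- sample.int(n)
    if (match_by == "count") {
      take <- ord[seq_len(k)]
      overshoot[i] <- 0
    } else {
      cum <- cumsum(len_vec[ord])
      n_take <- which(cum >= target_length)[1]
      if (is.na(n_take)) n_take <- n
      take <- ord[seq_len(n_take)]
      overshoot[i] <- (cum[n_take] - target_length) / target_length
    }
    perm_stats[i] <- sum(cnt_vec[take])
  }
  exceed <- sum(perm_stats >= observed)
  structure(
    list(statistic = "n_mutations", observed = observed,
         n_as_or_more_extreme = exceed,
         p.value = (exceed + 1) / (n_perm + 1),
         n_perm = n_perm, set_size = k, pool_size = n,
         target_length = target_length,
         mean_overshoot = mean(overshoot),
         match_by = match_by,
         perm_stats = perm_stats, seed = seed),
    class = "perm_enrichment"
  )
}
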