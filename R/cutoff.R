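#' Confusion counts and cost at one candidate score cutoff
#'
#' Given paired GCR rate folds (relative to wild type, from fluctuation
#' assays) and GCR strain scores, evaluates one candidate cutoff `c`.
#' Mutants with a rate fold at least `rate_fold_threshold` (default 3)
#' above wild type form the positive class. A single consistent decision
#' rule is used: a mutant is called positive iff its score is `>= c`, so
#' the four counts partition the data. Then
#' `SENS = TP / (TP + FN)`, `SPEC = TN / (TN + FP)`, and the cost to be
#' maximised is `w1 * SENS + w2 * SPEC`.
#'
#' @param pairs Data frame with columns `rate_fold` (> 0) and `score`.
#' @param cutoff Candidate cutoff in score units.
#' @param rate_fold_threshold Rate fold defining the positive class.
#' @param w1,w2 Non-negative weights on sensitivity and specificity
#'   (defaults 2 and 1: false negatives are costlier because false
#'   positives can be removed by follow-up rate measurements).
#' @return One-row tibble: `cutoff`, `tp`, `fn`, `tn`, `fp`, `sens`,
#'   `spec`, `cost`. `sens` (or `spec`) is `NA` when the pairs contain no
#'   positives (or no negatives), and a warning is raised.
#' @examples
#' pairs <- tibble::tibble(rate_fold = c(5, 4, 1), score = c(2, 0.5, 0.5))
#' confusion_at_cutoff(pairs, cutoff = 1)
#' @export
confusion_at_cutoff <- function(pairs, cutoff, rate_fold_threshold = 3,
                                w1 = 2, w2 = 1) {
  check_pairs(pairs)
  check_weights(w1, w2)
  pos <- pairs$rate_fold >= rate_fold_threshold
  called <- pairs$score >= cutoff
  tp <- sum(pos & called); fn <- sum(pos & !called)
  tn <- sum(!pos & !called); fp <- sum(!pos & called)
  if (tp + fn == 0) warning("no positive pairs: sensitivity undefined", call. = FALSE)
  if (tn + fp == 0) warning("no negative pairs: specificity undefined", call. = FALSE)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble::tibble(cutoff = cutoff, tp = tp, fn = fn, tn = tn, fp = fp,
                 sens = sens, spec = spec, cost = w1 * sens + w2 * spec)
}

check_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0) stop("`pairs` must be non-empty", call. = FALSE)
  if (!all(c("rate_fold", "score") %in% names(pairs))) {
    stop("`pairs` needs columns `rate_fold` and `score`", call. = FALSE)
  }
  if (any(pairs$rate_fold <= 0)) stop("`rate_fold` must be > 0", call. = FALSE)
  invisible(pairs)
}

check_weights <- function(w1, w2) {
  if (w1 < 0 || w2 < 0 || w1 + w2 <= 0) {
    stop("weights must be non-negative with w1 + w2 > 0", call. = FALSE)
  }
  invisible(NULL)
}

# Candidate cutoffs: midpoints between consecutive distinct observed
# scores, plus sentinels below the minimum and above the maximum.
cutoff_candidates <- function(scores) {
  s <- sort(unique(scores))
  mids <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  c(s[1] - 0.5, mids, s[length(s)] + 0.5)
}

#' Optimal score cutoff by weighted sensitivity/specificity cost
#'
#' Evaluates `w1 * SENS + w2 * SPEC` on the candidate-cutoff grid (the
#' midpoints between consecutive distinct observed scores, plus sentinels
#' below the minimum and above the maximum score) and returns the lowest
#' candidate attaining the maximal cost; breaking ties toward the lowest
#' cutoff favours sensitivity, consistent with the default weighting.
#'
#' @inheritParams confusion_at_cutoff
#' @return An object of class `gcr_cutoff` with elements `cutoff` (the
#'   optimum), `evaluation` (its one-row [confusion_at_cutoff()] result),
#'   `grid` (evaluations at every candidate), `auc` (trapezoidal area under
#'   the ROC curve), and the parameters. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' pairs <- tibble::tibble(rate_fold = c(10, 8, 6, 1, 1.2, 0.9),
#'                         score = c(3.0, 2.5, 2.2, 1.0, 0.8, 0.6))
#' fit <- optimal_cutoff(pairs)
#' glance(fit)
#' @export
optimal_cutoff <- function(pairs, rate_fold_threshold = 3, w1 = 2, w2 = 1) {
  check_pairs(pairs)
  check_weights(w1, w2)
  pos <- pairs$rate_fold >= rate_fold_threshold
  if (!any(pos) || all(pos)) {
    stop("`pairs` must contain at least one positive and one negative mutant",
         call. = FALSE)
  }
  grid <- purrr::map_dfr(
    cutoff_candidates(pairs$score),
    function(ci) confusion_at_cutoff(pairs, ci, rate_fold_threshold, w1, w2)
  )
  best <- which(grid$cost == max(grid$cost))[1]  # ties -> lowest cutoff
  roc <- roc_points(grid)
  structure(
    list(
      cutoff = grid$cutoff[best],
      evaluation = grid[best, ],
      grid = grid,
      auc = roc_auc(roc),
      n = nrow(pairs),
      rate_fold_threshold = rate_fold_threshold, w1 = w1, w2 = w2
    ),
    class = "gcr_cutoff"
  )
}

#' @export
print.gcr_cutoff <- function(x, ...) {
  cat(sprintf(
    "Optimal GCR score cutoff: %.3f (w1 = %g, w2 = %g, >= %g-fold positives)\n",
    x$cutoff, x$w1, x$w2, x$rate_fold_threshold))
  cat(sprintf("  SENS = %.3f, SPEC = %.3f, cost = %.3f, AUC = %.3f, n = %d\n",
              x$evaluation$sens, x$evaluation$spec, x$evaluation$cost,
              x$auc, x$n))
  invisible(x)
}

roc_points <- function(grid) {
  grid |>
    dplyr::transmute(cutoff = .data$cutoff, fpr = 1 - .data$spec,
                     tpr = .data$sens) |>
    dplyr::arrange(dplyr::desc(.data$cutoff))
}

roc_auc <- function(roc) {
  ord <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[ord]; y <- roc$tpr[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Receiver-operator characteristic over the candidate cutoff grid
#'
#' @inheritParams confusion_at_cutoff
#' @return Tibble with `cutoff`, `fpr` (1 - SPEC) and `tpr` (SENS), ordered
#'   from the highest cutoff (0, 0) to the lowest (1, 1).
#' @examples
#' pairs <- tibble::tibble(rate_fold = c(10, 8, 1, 1.2),
#'                         score = c(3.0, 2.5, 1.0, 0.8))
#' roc_curve(pairs)
#' @export
roc_curve <- function(pairs, rate_fold_threshold = 3) {
  fit <- optimal_cutoff(pairs, rate_fold_threshold, w1 = 1, w2 = 1)
  roc_points(fit$grid)
}

#' Discrete two-sample Kolmogorov-Smirnov test with Monte-Carlo p-value
#'
#' Patch scores take a handful of discrete values, so the classical
#' Kolmogorov-Smirnov null distribution does not apply. The statistic
#' `D` is the supremum distance between the two empirical cumulative
#' distributions over the pooled support; the p-value is obtained by
#' permuting the pooled sample `n_mc` times and using the add-one rank
#' estimator `p = (#{D_perm >= D_obs} + 1) / (n_mc + 1)`, which is never
#' exactly zero.
#'
#' @param a,b Numeric vectors of discrete values (e.g. patch scores 0--5).
#' @param n_mc Number of Monte-Carlo permutations (>= 1).
#' @param seed Optional integer seed.
#' @return Object of class `ks_discrete` with `statistic` (D), `p.value`,
#'   `n_mc`, and sample sizes. Supports [tidy()] and [glance()].
#' @examples
#' ks_discrete_test(c(0, 1, 1, 2), c(2, 3, 3, 4), n_mc = 999, seed = 1)
#' @export
ks_discrete_test <- function(a, b, n_mc = 10000, seed = NULL) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (n_mc < 1) stop("`n_mc` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pooled <- c(a, b)
  support <- sort(unique(pooled))
  na <- length(a); nb <- length(b)
  d_stat <- function(xa, xb) {
    Fa <- cumsum(tabulate(match(xa, support), length(support))) / na
    Fb <- cumsum(tabulate(match(xb, support), length(support))) / nb
    max(abs(Fa - Fb))
  }
  d_obs <- d_stat(a, b)
  exceed <- 0L
  for (i in seq_len(n_mc)) {
    idx <- sample.int(na + nb, na)
    if (d_stat(pooled[idx], pooled[-idx]) >= d_obs - 1e-12) exceed <- exceed + 1L
  }
  structure(
    list(statistic = d_obs, p.value = (exceed + 1) / (n_mc + 1),
         n_mc = n_mc, n_a = na, n_b = nb),
    class = "ks_discrete"
  )
}

#' @export
print.ks_discrete <- function(x, ...) {
  cat(sprintf("Discrete two-sample KS test: D = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p.value, x$n_mc))
  invisible(x)
}
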