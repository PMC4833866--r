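# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

# Exhaustive confusion tally at one cutoff.
oracle_confusion <- function(rate_fold, score, cutoff, fold_threshold = 3) {
  tp <- fn <- tn <- fp <- 0L
  for (i in seq_along(rate_fold)) {
    positive <- rate_fold[i] >= fold_threshold
    called <- score[i] >= cutoff
    if (positive && called) tp <- tp + 1L
    if (positive && !called) fn <- fn + 1L
    if (!positive && !called) tn <- tn + 1L
    if (!positive && called) fp <- fp + 1L
  }
  c(tp = tp, fn = fn, tn = tn, fp = fp)
}

# Exhaustive per-assay-combination tally of a gene/assay/suppresses table.
oracle_overlap <- function(genes, assays, suppresses) {
  combos <- list()
  for (g in unique(genes)) {
    hit <- c()
    for (i in seq_along(genes)) {
      if (genes[i] == g && isTRUE(suppresses[i])) hit <- c(hit, assays[i])
    }
    if (length(hit) > 0) {
      key <- paste(sort(unique(hit)), collapse = "+")
      combos[[key]] <- (combos[[key]] %||% 0L) + 1L
    }
  }
  combos
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Enumerated unordered pairs.
oracle_pair_count <- function(n) {
  if (n < 2) return(0)
  cnt <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) cnt <- cnt + 1L
  cnt
}

# Precision/recall of interaction calls against generator truth,
# over testable pairs.
interaction_performance <- function(sim, calls) {
  calls <- calls[!calls$untestable, ]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  truth_keys <- key(sim$truth$synergy_pairs$gene_a, sim$truth$synergy_pairs$gene_b)
  is_true <- key(calls$query_gene, calls$bait_gene) %in% truth_keys
  tp <- sum(calls$called & is_true)
  fp <- sum(calls$called & !is_true)
  fn <- sum(!calls$called & is_true)
  c(precision = tp / (tp + fp), recall = tp / (tp + fn),
    fp_rate = fp / sum(!is_true))
}
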