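test_that("classify_mutations applies the LOF and ndamage rules", {
  m <- tibble::tibble(
    variant_class = c("nonsense", "frameshift_insertion", "frameshift_deletion",
                      "inframe_insertion", "inframe_deletion", "splice_site",
                      "missense", "missense", "missense", "silent"),
    ndamage = c(NA, NA, NA, NA, NA, NA, 5, 6, 4, NA)
  )
  out <- classify_mutations(m)
  expect_equal(out$category,
               c(rep("lof", 6), "deleterious_missense", "deleterious_missense",
                 "other", "other"))
  expect_message(
    odd <- classify_mutations(tibble::tibble(variant_class = "weird",
                                             ndamage = NA)),
    "unknown variant class")
  expect_equal(odd$category, "other")
})

test_that("select_ts_candidates separates strict and borderline bands", {
  ann <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        s_score = c(-2.3, -1.97, -1.5, 2.4))
  sel <- select_ts_candidates(ann)
  expect_setequal(sel$gene, c("a", "b"))
  expect_equal(sel$band[sel$gene == "a"], "strict")
  expect_equal(sel$band[sel$gene == "b"], "borderline")
  onc <- select_ts_candidates(ann, direction = "oncogene")
  expect_equal(onc$gene, "d")
  expect_error(select_ts_candidates(ann, threshold = -2, borderline = -2.5),
               "borderline")
})

fixture_cohort <- function() {
  list(
    mutations = tibble::tibble(
      sample = c("s1", "s2"), gene = c("g1", "g1"),
      variant_class = c("nonsense", "missense"), ndamage = c(NA, 6),
      in_mononucleotide_repeat = FALSE
    ),
    # row order: (s1,g1), (s1,g2), (s2,g1), (s2,g2), (s3,g1), (s3,g2)
    cnv = tidyr::expand_grid(sample = c("s1", "s2", "s3"),
                             gene = c("g1", "g2")) |>
      dplyr::mutate(gistic = c(0L, 0L, -1L, 0L, 0L, -1L)),
    expression = tidyr::expand_grid(sample = c("s1", "s2", "s3"),
                                    gene = c("g1", "g2")) |>
      dplyr::mutate(z = c(0, 0, -2.5, 0, -2.5, -1)),
    methylation = tidyr::expand_grid(sample = c("s1", "s2", "s3"),
                                     gene = c("g1", "g2")) |>
      dplyr::mutate(hypermethylated = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  )
}

test_that("call_alterations applies the category rules", {
  fx <- fixture_cohort()
  calls <- call_alterations(fx$mutations, fx$cnv, fx$expression,
                            fx$methylation, genes = c("g1", "g2"))
  get <- function(s, g) calls[calls$sample == s & calls$gene == g, ]
  # LOF mutation
  expect_true(get("s1", "g1")$lof_mutation)
  # deleterious missense (ndamage 6)
  expect_true(get("s2", "g1")$deleterious_missense)
  # GISTIC -1 with Z -2.5
  expect_true(get("s2", "g1")$cn_reduced_low_expression)
  # hypermethylated, Z -2.5, GISTIC 0 -> silenced
  expect_true(get("s3", "g1")$silenced)
  # GISTIC -1 with Z -1.0: no copy-number category
  expect_false(get("s3", "g2")$cn_reduced_low_expression)
  # silencing requires hypermethylation
  expect_false(get("s2", "g1")$silenced)
})

test_that("unavailable platforms leave categories unassessed rather than negative", {
  fx <- fixture_cohort()
  availability <- tidyr::expand_grid(
    sample = c("s1", "s2", "s3"),
    platform = c("mutation", "cnv", "expression", "methylation")
  ) |>
    dplyr::mutate(available = !(sample == "s1" & platform == "mutation"))
  calls <- call_alterations(fx$mutations, fx$cnv, fx$expression,
                            fx$methylation, genes = c("g1", "g2"),
                            availability = availability)
  s1 <- calls[calls$sample == "s1" & calls$gene == "g1", ]
  expect_true(is.na(s1$lof_mutation))
  expect_false(is.na(s1$cn_reduced_low_expression))
})

test_that("samples with no platform data are excluded with a message", {
  fx <- fixture_cohort()
  availability <- tidyr::expand_grid(
    sample = c("s1", "s2", "s3"),
    platform = c("mutation", "cnv", "expression", "methylation")
  ) |>
    dplyr::mutate(available = sample != "s3")
  expect_message(
    calls <- call_alterations(fx$mutations, fx$cnv, fx$expression,
                              fx$methylation, genes = "g1",
                              availability = availability),
    "no platform data")
  expect_false("s3" %in% calls$sample)
})

test_that("tightening thresholds never increases the number of calls", {
  set.seed(50)
  cohort <- simulate_cancer(cancer_config(n_samples = 120, n_genes = 40,
                                          planted_ts_genes = 8, seed = 50))
  count_calls <- function(z_threshold, ndamage_threshold) {
    calls <- call_alterations(cohort$mutations, cohort$cnv, cohort$expression,
                              cohort$methylation,
                              genes = cohort$annotations$gene,
                              availability = cohort$availability,
                              z_threshold = z_threshold,
                              ndamage_threshold = ndamage_threshold)
    sum(calls$lof_mutation, na.rm = TRUE) +
      sum(calls$deleterious_missense, na.rm = TRUE) +
      sum(calls$cn_reduced_low_expression, na.rm = TRUE) +
      sum(calls$silenced, na.rm = TRUE)
  }
  expect_gte(count_calls(-2, 5), count_calls(-3, 5))
  expect_gte(count_calls(-2, 5), count_calls(-2, 6))
})

test_that("summarize_samples computes combination fractions", {
  # 10 samples: 4 mutation-only, 3 cn-only, 1 both, 2 none
  calls <- tibble::tibble(
    sample = sprintf("s%02d", 1:10), gene = "g1",
    lof_mutation = c(rep(TRUE, 4), rep(FALSE, 3), TRUE, FALSE, FALSE),
    deleterious_missense = FALSE,
    cn_reduced_low_expression = c(rep(FALSE, 4), rep(TRUE, 3), TRUE, FALSE,
                                  FALSE),
    silenced = FALSE,
    any_defect = NA
  )
  summ <- summarize_samples(calls)
  fr <- summ$fractions[summ$fractions$definition == "lof_only", ]
  expect_equal(fr$fraction[fr$combination == "mutation"], 0.4)
  expect_equal(fr$fraction[fr$combination == "cn_expression"], 0.3)
  expect_equal(fr$fraction[fr$combination == "mutation+cn_expression"], 0.1)
  expect_equal(fr$fraction[fr$combination == "none"], 0.2)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(summ$pct_any$pct_any[summ$pct_any$definition == "lof_only"], 80)
})

test_that("summarize_samples separates the two mutation definitions", {
  calls <- tibble::tibble(
    sample = c("s1", "s2"), gene = "g1",
    lof_mutation = c(FALSE, FALSE),
    deleterious_missense = c(TRUE, FALSE),
    cn_reduced_low_expression = FALSE, silenced = FALSE, any_defect = NA
  )
  summ <- summarize_samples(calls)
  expect_equal(summ$pct_any$pct_any[summ$pct_any$definition == "lof_only"], 0)
  expect_equal(
    summ$pct_any$pct_any[summ$pct_any$definition == "lof_plus_missense"], 50)
  g <- glance(summ)
  expect_equal(g$n_samples, 2)
})

test_that("a planted defect prevalence of 0.7 is recovered at n = 1000", {
  set.seed(51)
  n <- 1000
  defect <- stats::runif(n) < 0.7
  calls <- tibble::tibble(
    sample = sprintf("s%04d", 1:n), gene = "g1",
    lof_mutation = defect, deleterious_missense = FALSE,
    cn_reduced_low_expression = FALSE, silenced = FALSE, any_defect = defect
  )
  summ <- summarize_samples(calls)
  frac <- summ$pct_any$pct_any[summ$pct_any$definition == "lof_only"] / 100
  expect_lt(abs(frac - 0.7), 0.05)
})

test_that("mmr exclusion removes samples before summarisation", {
  calls <- tibble::tibble(
    sample = c("s1", "s2"), gene = "g1",
    lof_mutation = TRUE, deleterious_missense = FALSE,
    cn_reduced_low_expression = FALSE, silenced = FALSE, any_defect = TRUE
  )
  summ <- summarize_samples(calls, mmr_exclude = "s2")
  expect_equal(summ$n_samples, 1)
})

test_that("planted genes are altered more often than background genes", {
  set.seed(52)
  wins <- replicate(20, {
    cohort <- simulate_cancer(cancer_config(n_samples = 80, n_genes = 30,
                                            planted_ts_genes = 6))
    calls <- call_alterations(cohort$mutations, cohort$cnv, cohort$expression,
                              cohort$methylation,
                              genes = cohort$annotations$gene,
                              availability = cohort$availability)
    freq <- tapply(calls$any_defect, calls$gene, mean)
    planted <- cohort$truth$planted_genes
    mean(freq[planted]) > mean(freq[setdiff(names(freq), planted)])
  })
  expect_lt(stats::binom.test(sum(wins), 20, alternative = "greater")$p.value,
            0.001)
})
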