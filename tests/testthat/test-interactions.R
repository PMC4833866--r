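test_that("call_interaction applies the 0.4 differential rule", {
  a <- call_interaction(2.0, 1.0, 1.2)
  expect_equal(a$differential, 0.8)
  expect_true(a$called)
  expect_false(a$saturated)
  b <- call_interaction(1.5, 1.0, 1.2)
  expect_equal(b$differential, 0.3)
  expect_false(b$called)
  # saturating single mutants are called but flagged
  s <- call_interaction(4.8, 4.0, 1.0)
  expect_equal(s$differential, 0.8)
  expect_true(s$called)
  expect_true(s$saturated)
  # undefined single: untestable, never called
  u <- call_interaction(3.0, NA, 1.0)
  expect_true(u$untestable)
  expect_false(u$called)
  expect_error(call_interaction(6, 1, 1), "0, 5")
})

test_that("call_interaction is symmetric in the two single scores", {
  set.seed(40)
  for (i in 1:25) {
    d <- stats::runif(1, 0, 5)
    s1 <- stats::runif(1, 0, 5); s2 <- stats::runif(1, 0, 5)
    x <- call_interaction(d, s1, s2)
    y <- call_interaction(d, s2, s1)
    expect_equal(x$differential, y$differential)
    expect_equal(x$called, y$called)
    expect_equal(x$saturated, y$saturated)
  }
})

test_that("possible_pairs counts unordered pairs", {
  expect_equal(possible_pairs(43), 903)
  expect_equal(possible_pairs(1), 0)
  expect_equal(possible_pairs(10), 45)
  expect_error(possible_pairs(-1), ">= 0")
  for (n in c(0, 1, 2, 5, 17, 50, 100)) {
    expect_equal(possible_pairs(n), oracle_pair_count(n))
  }
})

test_that("call_interactions joins singles onto doubles correctly", {
  scores <- tibble::tibble(
    query_gene = c("WT", "WT", "q1", "q1", "q1"),
    bait_gene = c("a", "b", "control", "a", "b"),
    assay = "dGCR",
    score = c(1.0, 1.2, 0.9, 2.0, 1.4)
  )
  calls <- call_interactions(scores)
  expect_equal(nrow(calls), 2)
  a <- calls[calls$bait_gene == "a", ]
  expect_equal(a$single_score_bait, 1.0)
  expect_equal(a$single_score_query, 0.9)
  expect_equal(a$differential, 1.0)
  expect_true(a$called)
  b <- calls[calls$bait_gene == "b", ]
  expect_equal(b$differential, 1.4 - 1.2)
  expect_false(b$called)
})

test_that("reciprocal crosses with identical scores agree perfectly", {
  calls <- tibble::tibble(
    query_gene = c("a", "b"), bait_gene = c("b", "a"), assay = "dGCR",
    double_score = c(2.5, 2.5), single_score_query = 1, single_score_bait = 1,
    differential = 1.5, called = TRUE, untestable = FALSE, saturated = FALSE
  )
  rec <- reciprocal_consistency(calls)
  expect_equal(rec$n_pairs, 1)
  expect_equal(rec$mean_abs_diff, 0)
  expect_equal(rec$agreement_rate, 1)
})

test_that("borderline reciprocal scores can disagree and are counted as such", {
  # 2.0 vs 2.5 with max single 1.9 and delta 0.4: differentials 0.1 and 0.6
  calls <- tibble::tibble(
    query_gene = c("a", "b"), bait_gene = c("b", "a"), assay = "dGCR",
    double_score = c(2.0, 2.5), single_score_query = 1.9,
    single_score_bait = 1.5, differential = c(0.1, 0.6),
    called = c(FALSE, TRUE), untestable = FALSE, saturated = FALSE
  )
  rec <- reciprocal_consistency(calls)
  expect_equal(rec$agreement_rate, 0)
  expect_equal(rec$mean_abs_diff, 0.5)
  g <- glance(rec)
  expect_equal(g$n_pairs, 1)
})

test_that("reciprocal_consistency returns an empty summary without reciprocals", {
  calls <- tibble::tibble(
    query_gene = "a", bait_gene = "b", assay = "dGCR", double_score = 2,
    single_score_query = 1, single_score_bait = 1, differential = 1,
    called = TRUE, untestable = FALSE, saturated = FALSE
  )
  rec <- reciprocal_consistency(calls)
  expect_equal(rec$n_pairs, 0)
  expect_true(is.na(rec$agreement_rate))
})

test_that("simulated screens give consistent reciprocal scores at strong synergy", {
  sim <- simulate_screen(screen_config(n_baits = 60, n_queries = 15,
                                       patches_per_strain = 6,
                                       synergy_fold = 10, seed = 41))
  rec <- reciprocal_consistency(call_interactions(score_strains(sim$patches)))
  expect_equal(rec$n_pairs, possible_pairs(15))
  expect_gte(rec$agreement_rate, 0.9)
})

test_that("identify_cgis returns called baits outside the GIS list", {
  calls <- tibble::tibble(
    query_gene = c("q1", "q1", "q2", "q2"),
    bait_gene = c("a", "b", "a", "c"),
    assay = "dGCR",
    called = c(TRUE, TRUE, TRUE, FALSE)
  )
  cgis <- identify_cgis(calls, gis_genes = "b")
  expect_equal(cgis$gene, "a")
  expect_equal(cgis$n_queries, 2)
  # cGIS and GIS are disjoint by construction
  expect_length(intersect(cgis$gene, "b"), 0)
  # every cGIS gene has at least one called interaction
  expect_true(all(cgis$gene %in% calls$bait_gene[calls$called]))
  expect_error(identify_cgis(calls[0, ]), "non-empty")
})

test_that("classify_modules separates shared from unshared interactions", {
  modules <- tibble::tibble(
    module = c("M1", "M1", "M2", "M2", "M3", "M4"),
    gene = c("a", "b", "c", "d", "e", "x")
  )
  calls <- tibble::tibble(
    query_gene = c("q1", "q2", "q2", "q3", "q1", "q4"),
    bait_gene = c("a", "a", "b", "b", "c", "d"),
    assay = "dGCR", called = TRUE, untestable = FALSE
  )
  calls <- dplyr::bind_rows(
    calls,
    tibble::tibble(query_gene = "q1", bait_gene = "e", assay = "dGCR",
                   called = TRUE, untestable = FALSE)
  )
  out <- classify_modules(modules, calls)
  # a interacts with {q1,q2}, b with {q2,q3}: shared q2 -> group 1
  expect_equal(out$group[out$module == "M1"], 1L)
  expect_equal(out$shared_queries[out$module == "M1"], "q2")
  # c with {q1}, d with {q4}: no shared query -> group 2
  expect_equal(out$group[out$module == "M2"], 2L)
  # single interacting gene -> group 2
  expect_equal(out$group[out$module == "M3"], 2L)
  # no tested member -> untested
  expect_true(is.na(out$group[out$module == "M4"]))
  expect_error(classify_modules(modules[0, ], calls), "non-empty")
})

test_that("interaction_degrees counts called interactions per query and bait", {
  calls <- tibble::tibble(
    query_gene = c("q1", "q1", "q2"),
    bait_gene = c("a", "b", "a"),
    called = c(TRUE, TRUE, FALSE)
  )
  deg <- interaction_degrees(calls)
  expect_equal(deg$per_query$degree[deg$per_query$query_gene == "q1"], 2)
  expect_equal(deg$per_bait$degree[deg$per_bait$bait_gene == "a"], 1)
})

test_that("rate_synergy distinguishes additive from multiplicative nulls", {
  expect_true(rate_synergy(12, 3, 4))
  expect_false(rate_synergy(12, 3, 4, null = "multiplicative"))
  expect_true(rate_synergy(13, 3, 4, null = "multiplicative"))
  expect_equal(rate_synergy(c(8, 6), c(3, 3), c(4, 4)), c(TRUE, FALSE))
})

test_that("simulated screens recover planted synergies", {
  sim <- simulate_screen(screen_config(n_baits = 120, n_queries = 8,
                                       patches_per_strain = 6,
                                       synergy_fold = 10, seed = 42))
  calls <- call_interactions(score_strains(sim$patches))
  perf <- interaction_performance(sim, calls)
  expect_gte(perf["precision"], 0.8)
  expect_gte(perf["recall"], 0.8)
  expect_lte(perf["fp_rate"], 0.05)
})
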