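#' Run the full synthetic screen-to-cancer pipeline
#'
#' Executes every stage in dependency order on synthetic data with known
#' ground truth: simulate the yeast screen, score patches into strain
#' scores, optimise the rate/score cutoff, call GIS genes and cross-assay
#' overlap, call interactions and cGIS genes, classify modules, simulate a
#' tumour cohort, classify per-sample alterations, and run both
#' randomisation enrichment tests. Stage outputs are written as TSV files
#' under `out_dir` together with a machine-readable JSON manifest recording
#' the package version, seed, parameters, and per-file MD5 checksums.
#' Rerunning with an identical configuration and seed reproduces every
#' output byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed controlling all randomness.
#' @param screen Optional [screen_config()] (its `seed` is overridden by
#'   `seed`).
#' @param cancer Optional [cancer_config()] (likewise).
#' @param modules Optional module definition tibble (`module`, `gene`);
#'   defaults to consecutive non-overlapping triples of bait genes, a
#'   stand-in for annotated complexes.
#' @param delta Score differential for GIS and interaction calls.
#' @param fold_threshold Rate fold threshold for GIS calls.
#' @param w1,w2 Cost-function weights for the cutoff optimisation.
#' @param z_threshold Expression Z-score threshold.
#' @param s_threshold,s_borderline S-score thresholds.
#' @param ndamage_threshold Missense predictor threshold.
#' @param n_perm Permutations for the enrichment tests.
#' @return Invisibly, a named list with all stage results and the manifest.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         screen = NULL, cancer = NULL, modules = NULL,
                         delta = 0.4, fold_threshold = 3, w1 = 2, w2 = 1,
                         z_threshold = -2, s_threshold = -2,
                         s_borderline = -1.95, ndamage_threshold = 5,
                         n_perm = 10000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(screen)) screen <- screen_config()
  if (is.null(cancer)) cancer <- cancer_config()
  screen$seed <- seed
  cancer$seed <- seed + 1L
  params <- list(seed = seed, delta = delta, fold_threshold = fold_threshold,
                 w1 = w1, w2 = w2, z_threshold = z_threshold,
                 s_threshold = s_threshold, s_borderline = s_borderline,
                 ndamage_threshold = ndamage_threshold, n_perm = n_perm)
  stages <- character(0)
  files <- character(0)
  emit <- function(stage, name, df) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, path)
    stages <<- union(stages, stage)
    files <<- c(files, path)
    path
  }

  # 1. simulate screen
  sim <- simulate_screen(screen)
  emit("simulate_screen", "patches", sim$patches)
  emit("simulate_screen", "truth_bait_folds", sim$truth$bait_folds)

  # 2. score
  scores <- score_strains(sim$patches)
  emit("score", "strain_scores", scores)

  # 3. cutoff optimisation on truth rates vs observed single-mutant scores
  singles <- scores |>
    dplyr::filter(.data$query_gene == "WT", .data$bait_gene != "control",
                  .data$assay == screen$double_assay, !is.na(.data$score)) |>
    dplyr::inner_join(
      sim$truth$bait_folds |>
        dplyr::filter(.data$assay == screen$double_assay),
      by = c("bait_gene" = "bait", "assay")
    ) |>
    dplyr::transmute(gene = .data$bait_gene, rate_fold = .data$fold,
                     score = .data$score)
  cutoff_fit <- optimal_cutoff(singles, fold_threshold, w1, w2)
  emit("cutoff", "cutoff_grid", cutoff_fit$grid)
  emit("cutoff", "cutoff_optimum", glance(cutoff_fit))

  # 4. GIS calls
  wt <- scores |>
    dplyr::filter(.data$query_gene == "WT", .data$bait_gene == "control") |>
    dplyr::select("assay", wt_score = "score")
  single_scores <- scores |>
    dplyr::filter(.data$query_gene == "WT", .data$bait_gene != "control") |>
    dplyr::select(gene = "bait_gene", "assay", "score")
  rates <- sim$truth$bait_folds |>
    dplyr::filter(.data$assay == screen$double_assay) |>
    dplyr::select(gene = "bait", "assay", rate_fold = "fold")
  gis <- call_gis(single_scores, wt, rates = rates, delta = delta,
                  fold_threshold = fold_threshold)
  emit("call_gis", "gis_calls", gis)
  emit("call_gis", "assay_overlap", assay_overlap(gis))
  gis_genes <- unique(gis$gene[!is.na(gis$suppresses) & gis$suppresses])

  # 5. interactions and cGIS genes
  inter <- call_interactions(scores, delta = delta)
  emit("interactions", "interaction_calls", inter)
  cgis <- identify_cgis(inter, gis_genes)
  emit("interactions", "cgis_genes", cgis)

  # 6. modules
  if (is.null(modules)) {
    baits <- sort(unique(sim$patches$bait_gene[sim$patches$bait_gene != "control"]))
    n_mod <- length(baits) %/% 3
    modules <- tibble::tibble(
      module = rep(sprintf("module%02d", seq_len(n_mod)), each = 3),
      gene = baits[seq_len(3 * n_mod)]
    )
  }
  mods <- classify_modules(modules, inter)
  emit("modules", "module_groups", mods)

  # 7. cancer classification
  cohort <- simulate_cancer(cancer)
  candidates <- select_ts_candidates(cohort$annotations, s_threshold,
                                     s_borderline)
  alts <- call_alterations(cohort$mutations, cohort$cnv, cohort$expression,
                           cohort$methylation, candidates$gene,
                           cohort$availability, z_threshold,
                           ndamage_threshold)
  summ <- summarize_samples(alts)
  emit("cancer_classify", "ts_candidates", candidates)
  emit("cancer_classify", "alteration_calls", alts)
  emit("cancer_classify", "alteration_summary", summ$fractions)

  # 8. cancer enrichment
  set.seed(seed + 2L)
  enr_s <- sscore_set_enrichment(cohort$annotations,
                                 cohort$truth$planted_genes,
                                 threshold = s_threshold, n_perm = n_perm)
  enr_m <- length_normalized_mutation_enrichment(
    cohort$mutations, cohort$annotations, cohort$truth$planted_genes,
    classes = "lof", n_perm = n_perm)
  enr <- dplyr::bind_rows(glance(enr_s), glance(enr_m))
  emit("cancer_enrich", "enrichment", enr)

  manifest <- list(
    package = "gisscreen",
    version = as.character(utils::packageVersion("gisscreen")),
    r_version = as.character(getRversion()),
    seed = seed,
    parameters = params,
    stages = stages,
    outputs = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    screen_sim = sim, scores = scores, cutoff = cutoff_fit, gis = gis,
    interactions = inter, cgis = cgis, modules = mods, cohort = cohort,
    candidates = candidates, alterations = alts, summary = summ,
    enrichment = list(s_score = enr_s, mutation = enr_m),
    manifest = manifest
  ))
}
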