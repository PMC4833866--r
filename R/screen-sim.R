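#' Configuration for a synthetic GCR patch screen
#'
#' Builds the parameter set for [simulate_screen()]. The defaults emulate a
#' desk-scale version of a systematic GCR screen: a collection of bait
#' deletion strains crossed against wild-type query strains carrying one of
#' several GCR assays, plus double-mutant crosses against a panel of query
#' mutations in one of the assays. A fraction of baits are planted genome
#' instability suppressing (GIS) genes whose deletion raises the GCR rate;
#' a fraction of query-by-bait pairs carry a planted synergy on top of the
#' multiplicative double-mutant null.
#'
#' The wild-type per-assay rates (events per cell division) together with
#' `cells_per_patch` set the expected number of pre-plating GCR events per
#' patch, `m = rate * cells_per_patch`. The defaults are calibrated so the
#' control strain reproduces typical control strain scores in the three
#' assay flavours (about 0.1, 0.9 and 2.7 for the sGCR-, dGCR- and
#' tyGCR-like assays).
#'
#' @param n_baits Number of bait genes (the first `n_queries` of which are
#'   also used as query mutations, so reciprocal crosses exist).
#' @param n_queries Number of mutant query strains crossed for double
#'   mutants.
#' @param assays Data frame with columns `assay` and `wt_rate` (wild-type
#'   GCR rate, events per cell division, > 0).
#' @param double_assay Which assay carries the double-mutant crosses
#'   (default `"dGCR"`).
#' @param fraction_gis Fraction of non-query baits planted as GIS genes.
#' @param gis_fold_meanlog,gis_fold_sdlog Log-normal parameters of the GCR
#'   rate fold-increase of planted GIS baits (default median 10-fold).
#' @param query_fold_meanlog,query_fold_sdlog Log-normal parameters of the
#'   single-mutant fold of query genes. The default (median 1, sdlog 0.4,
#'   so folds roughly 0.5--2.5) models a query panel chosen to sensitise
#'   without saturating the assay: cooperating mutations often cause no
#'   rate increase on their own, and strains with high single-mutant
#'   scores yield few detectable interactions.
#' @param assay_penetrance Probability that a planted GIS bait expresses its
#'   fold increase in any given assay (< 1 yields imperfect cross-assay
#'   overlap, as real mutants show).
#' @param fraction_synergy Fraction of query-by-bait pairs with a planted
#'   synergy.
#' @param synergy_fold Multiplier applied on top of the multiplicative
#'   double-mutant null for synergistic pairs.
#' @param cells_per_patch Effective number of cell divisions assayed per
#'   patch.
#' @param patches_per_strain Number of independent spore-clone patches per
#'   strain (>= 1; screens use at least 3).
#' @param control_patches Number of patches for the wild-type control strain
#'   (default 12): the control is replicated across plates in real screens,
#'   and its score anchors the per-assay cutoff, so it is scored from more
#'   patches than ordinary strains.
#' @param no_growth_prob Probability that a strain fails to grow (applied at
#'   the strain level: all of its patches are flagged as not grown).
#' @param lawn_threshold Papillae counts above this are recorded as a lawn.
#' @param model `"poisson"` (default) draws the papillae count as the
#'   Poisson number of independent pre-plating GCR events; `"jackpot"`
#'   additionally expands each event into a Lea-Coulson style clone of size
#'   `floor(1/U)` and reports total mutant cells, which produces classic
#'   fluctuation-assay jackpots.
#' @param seed Integer seed; fixing it fixes every output.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(n_baits = 200,
                          n_queries = 10,
                          assays = data.frame(
                            assay = c("sGCR", "dGCR", "tyGCR"),
                            wt_rate = c(6e-11, 1e-9, 8e-9)
                          ),
                          double_assay = "dGCR",
                          fraction_gis = 0.15,
                          gis_fold_meanlog = log(10),
                          gis_fold_sdlog = 0.5,
                          query_fold_meanlog = 0,
                          query_fold_sdlog = 0.4,
                          assay_penetrance = 0.7,
                          fraction_synergy = 0.1,
                          synergy_fold = 10,
                          cells_per_patch = 2e9,
                          patches_per_strain = 4,
                          control_patches = 12,
                          no_growth_prob = 0.05,
                          lawn_threshold = 1000,
                          model = c("poisson", "jackpot"),
                          seed = NULL) {
  model <- match.arg(model)
  cfg <- list(
    n_baits = n_baits, n_queries = n_queries,
    assays = tibble::as_tibble(assays), double_assay = double_assay,
    fraction_gis = fraction_gis,
    gis_fold_meanlog = gis_fold_meanlog, gis_fold_sdlog = gis_fold_sdlog,
    query_fold_meanlog = query_fold_meanlog, query_fold_sdlog = query_fold_sdlog,
    assay_penetrance = assay_penetrance,
    fraction_synergy = fraction_synergy, synergy_fold = synergy_fold,
    cells_per_patch = cells_per_patch, patches_per_strain = patches_per_strain,
    control_patches = control_patches,
    no_growth_prob = no_growth_prob, lawn_threshold = lawn_threshold,
    model = model, seed = seed
  )
  validate_screen_config(cfg)
  structure(cfg, class = "screen_config")
}

validate_screen_config <- function(cfg) {
  stopifnot(
    is.data.frame(cfg$assays),
    all(c("assay", "wt_rate") %in% names(cfg$assays))
  )
  if (any(cfg$assays$wt_rate < 0)) {
    stop("assay wild-type rates must be non-negative", call. = FALSE)
  }
  props <- c(cfg$fraction_gis, cfg$fraction_synergy, cfg$no_growth_prob,
             cfg$assay_penetrance)
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$patches_per_strain < 1) stop("patches_per_strain must be >= 1", call. = FALSE)
  if (cfg$control_patches < 1) stop("control_patches must be >= 1", call. = FALSE)
  if (cfg$n_queries > cfg$n_baits) stop("n_queries must be <= n_baits", call. = FALSE)
  if (cfg$cells_per_patch <= 0) stop("cells_per_patch must be > 0", call. = FALSE)
  if (cfg$synergy_fold < 1) stop("synergy_fold must be >= 1", call. = FALSE)
  if (!cfg$double_assay %in% cfg$assays$assay) {
    stop("double_assay must be one of the configured assays", call. = FALSE)
  }
  invisible(cfg)
}

# Draw papillae counts for one vector of expected event numbers m.
draw_papillae <- function(m, model, lawn_threshold) {
  n_events <- stats::rpois(length(m), m)
  if (model == "poisson") {
    counts <- n_events
  } else {
    # Lea-Coulson style jackpots: each pre-plating event expands into a
    # clone of size floor(1/U) (P(size >= k) = 1/k), capped at the lawn.
    counts <- vapply(n_events, function(k) {
      if (k == 0) return(0)
      sum(pmin(floor(1 / stats::runif(k)), lawn_threshold + 1))
    }, numeric(1))
  }
  counts
}

#' Simulate a GCR patch screen with known ground truth
#'
#' Generates per-patch papillae counts for single-mutant strains in every
#' configured assay, for query single mutants (query crossed to the control
#' deletion), and for query-by-bait double mutants in the double-mutant
#' assay. A control strain (`query = "WT"`, `bait = "control"`) is included
#' per assay. Rates follow a multiplicative model:
#' `rate = wt_rate * fold_query * fold_bait * synergy_fold`, with
#' `synergy_fold = 1` for non-synergistic pairs, and the papillae count per
#' patch is drawn from the configured rare-event model with expectation
#' `m = rate * cells_per_patch`.
#'
#' @param config A [screen_config()] object.
#' @return A list with elements:
#' * `patches`: tibble with one row per patch -- `strain_id`, `query_gene`,
#'   `bait_gene`, `assay`, `patch_index`, `papillae_count`, `lawn`, `grew`.
#' * `strains`: tibble with one row per strain including its true GCR
#'   `rate` (events per cell division).
#' * `truth`: list with `bait_folds` (bait, assay, fold), `query_folds`,
#'   `gis_baits` (planted GIS genes), `synergy_pairs` (`gene_a`, `gene_b`,
#'   unordered), and `dropped_strains` (strains lost to cross failure).
#' @examples
#' sim <- simulate_screen(screen_config(n_baits = 20, n_queries = 3, seed = 7))
#' head(sim$patches)
#' sim$truth$gis_baits
#' @export
simulate_screen <- function(config) {
  validate_screen_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  baits <- sprintf("g%03d", seq_len(config$n_baits))
  queries <- baits[seq_len(config$n_queries)]
  non_query_baits <- setdiff(baits, queries)

  # planted GIS baits and per-assay fold realisation
  is_gis <- stats::runif(length(non_query_baits)) < config$fraction_gis
  gis_baits <- non_query_baits[is_gis]
  base_fold <- stats::setNames(rep(1, config$n_baits), baits)
  base_fold[gis_baits] <- stats::rlnorm(length(gis_baits),
                                        config$gis_fold_meanlog,
                                        config$gis_fold_sdlog)
  base_fold[queries] <- stats::rlnorm(length(queries),
                                      config$query_fold_meanlog,
                                      config$query_fold_sdlog)
  assays <- config$assays$assay
  bait_folds <- tidyr::expand_grid(bait = baits, assay = assays) |>
    dplyr::mutate(
      active = .data$bait %in% queries |
        !(.data$bait %in% gis_baits) |
        stats::runif(dplyr::n()) < config$assay_penetrance,
      fold = ifelse(.data$active, base_fold[.data$bait], 1)
    ) |>
    dplyr::select("bait", "assay", "fold")

  # planted synergies on unordered pairs
  pair_grid <- tidyr::expand_grid(query = queries, bait = baits) |>
    dplyr::filter(.data$query != .data$bait)
  unordered <- unique(t(apply(pair_grid[, c("query", "bait")], 1, sort)))
  keys <- paste(unordered[, 1], unordered[, 2])
  syn_keys <- keys[stats::runif(length(keys)) < config$fraction_synergy]
  synergy_pairs <- tibble::tibble(
    gene_a = unordered[keys %in% syn_keys, 1],
    gene_b = unordered[keys %in% syn_keys, 2]
  )

  wt_rate <- stats::setNames(config$assays$wt_rate, config$assays$assay)
  fold_of <- function(gene, assay) {
    idx <- match(paste(gene, assay), paste(bait_folds$bait, bait_folds$assay))
    out <- bait_folds$fold[idx]
    out[gene == "control"] <- 1
    out[gene == "WT"] <- 1
    out
  }

  # strain table: control + singles per assay; query singles + doubles in
  # the double-mutant assay
  singles <- tidyr::expand_grid(query_gene = "WT", bait_gene = c("control", baits),
                                assay = assays)
  q_singles <- tidyr::expand_grid(query_gene = queries, bait_gene = "control",
                                  assay = config$double_assay)
  doubles <- tidyr::expand_grid(query_gene = queries, bait_gene = baits,
                                assay = config$double_assay) |>
    dplyr::filter(.data$query_gene != .data$bait_gene)
  strains <- dplyr::bind_rows(singles, q_singles, doubles) |>
    dplyr::mutate(
      strain_id = sprintf("s%05d", dplyr::row_number()),
      fold_q = fold_of(.data$query_gene, .data$assay),
      fold_b = fold_of(.data$bait_gene, .data$assay),
      key = paste(pmin(.data$query_gene, .data$bait_gene),
                  pmax(.data$query_gene, .data$bait_gene)),
      synergy = ifelse(.data$query_gene != "WT" & .data$bait_gene != "control" &
                         .data$key %in% syn_keys, config$synergy_fold, 1),
      rate = unname(wt_rate[.data$assay]) * .data$fold_q * .data$fold_b *
        .data$synergy,
      grew = stats::runif(dplyr::n()) >= config$no_growth_prob
    )
  # the control strain always grows (it anchors the wild-type score)
  strains$grew[strains$bait_gene == "control" & strains$query_gene == "WT"] <- TRUE

  patches <- strains |>
    dplyr::select("strain_id", "query_gene", "bait_gene", "assay", "rate", "grew") |>
    dplyr::mutate(n_patches = ifelse(
      .data$query_gene == "WT" & .data$bait_gene == "control",
      config$control_patches, config$patches_per_strain)) |>
    tidyr::uncount(weights = .data$n_patches, .id = "patch_index") |>
    dplyr::mutate(
      m = .data$rate * config$cells_per_patch,
      papillae_count = ifelse(
        .data$grew,
        draw_papillae(.data$m, config$model, config$lawn_threshold),
        NA_real_
      ),
      lawn = !is.na(.data$papillae_count) &
        .data$papillae_count > config$lawn_threshold
    ) |>
    dplyr::select("strain_id", "query_gene", "bait_gene", "assay",
                  "patch_index", "papillae_count", "lawn", "grew")

  truth <- list(
    bait_folds = bait_folds,
    query_folds = tibble::tibble(query = queries, fold = base_fold[queries]),
    gis_baits = gis_baits,
    synergy_pairs = synergy_pairs,
    dropped_strains = strains |>
      dplyr::filter(!.data$grew) |>
      dplyr::select("strain_id", "query_gene", "bait_gene", "assay")
  )
  list(
    patches = patches,
    strains = dplyr::select(strains, "strain_id", "query_gene", "bait_gene",
                            "assay", "rate", "grew"),
    truth = truth
  )
}
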