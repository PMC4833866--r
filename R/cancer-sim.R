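#' Configuration for a synthetic tumour cohort
#'
#' Builds the parameter set for [simulate_cancer()]. The generator emulates
#' the genomics data types used to classify per-sample defects in candidate
#' genome-stability genes: somatic mutations (MAF-like records with variant
#' class and a 0--6 `ndamage` missense-predictor count), GISTIC-style
#' thresholded copy-number calls, expression Z-scores coupled to copy loss,
#' sporadic promoter hypermethylation, and per-gene annotations (protein
#' length in amino acids and a precomputed tumour-suppressor S-score).
#' A planted set of defective tumour-suppressor genes carries excess
#' loss-of-function mutations, copy loss with depressed expression, and
#' S-scores drawn below -2; background mutation counts scale with protein
#' length.
#'
#' @param n_samples Number of tumour samples.
#' @param n_genes Number of genes.
#' @param planted_ts_genes Number of planted defective tumour-suppressor
#'   genes (must be <= `n_genes`).
#' @param length_meanlog,length_sdlog Log-normal parameters of protein
#'   length in amino acids (default median 500 aa).
#' @param background_mut_rate Background mutation probability per amino
#'   acid per sample (all classes combined).
#' @param planted_lof_rate Per-sample probability of an extra
#'   loss-of-function mutation in each planted gene.
#' @param cnv_loss_prob,homdel_prob Background per-sample probabilities of
#'   heterozygous loss (GISTIC -1) and homozygous deletion (-2).
#' @param planted_cnv_loss_prob,planted_homdel_prob The same probabilities
#'   for planted genes.
#' @param gain_prob,amp_prob Probabilities of GISTIC +1 and +2 calls.
#' @param expr_shift_on_loss Mean expression Z-score shift applied when a
#'   gene's copy number is reduced (and when it is hypermethylated);
#'   default -2.5 so copy-reduced planted genes average below Z = -2.
#' @param silencing_prob,planted_silencing_prob Per-sample probability of
#'   promoter hypermethylation for background and planted genes.
#' @param ndamage_probs,planted_ndamage_probs Probability vectors over
#'   `ndamage` values 0--6 for background and planted missense mutations.
#' @param availability_probs Named vector of per-platform probabilities
#'   that a sample was profiled (`mutation`, `cnv`, `expression`,
#'   `methylation`); not every sample is analysed on every platform.
#' @param mono_repeat_prob Probability that a frameshift lies in a
#'   mononucleotide repeat.
#' @param seed Integer seed.
#' @return A list of class `cancer_config`.
#' @export
cancer_config <- function(n_samples = 500,
                          n_genes = 200,
                          planted_ts_genes = 20,
                          length_meanlog = log(500),
                          length_sdlog = 0.6,
                          background_mut_rate = 1e-5,
                          planted_lof_rate = 0.02,
                          cnv_loss_prob = 0.05,
                          homdel_prob = 0.002,
                          planted_cnv_loss_prob = 0.3,
                          planted_homdel_prob = 0.02,
                          gain_prob = 0.05,
                          amp_prob = 0.01,
                          expr_shift_on_loss = -2.5,
                          silencing_prob = 0.002,
                          planted_silencing_prob = 0.02,
                          ndamage_probs = c(0.30, 0.25, 0.15, 0.10, 0.08, 0.07, 0.05),
                          planted_ndamage_probs = c(0.02, 0.03, 0.05, 0.10, 0.15, 0.30, 0.35),
                          availability_probs = c(mutation = 0.9, cnv = 0.95,
                                                 expression = 0.9, methylation = 0.85),
                          mono_repeat_prob = 0.2,
                          seed = NULL) {
  cfg <- as.list(environment())
  validate_cancer_config(cfg)
  structure(cfg, class = "cancer_config")
}

validate_cancer_config <- function(cfg) {
  if (cfg$planted_ts_genes > cfg$n_genes) {
    stop("planted_ts_genes must be <= n_genes", call. = FALSE)
  }
  probs <- c(cfg$planted_lof_rate, cfg$cnv_loss_prob, cfg$homdel_prob,
             cfg$planted_cnv_loss_prob, cfg$planted_homdel_prob,
             cfg$gain_prob, cfg$amp_prob, cfg$silencing_prob,
             cfg$planted_silencing_prob, cfg$mono_repeat_prob,
             cfg$availability_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$background_mut_rate < 0) stop("background_mut_rate must be >= 0", call. = FALSE)
  if (length(cfg$ndamage_probs) != 7 || length(cfg$planted_ndamage_probs) != 7) {
    stop("ndamage probability vectors must have 7 entries (scores 0-6)", call. = FALSE)
  }
  required <- c("mutation", "cnv", "expression", "methylation")
  if (!all(required %in% names(cfg$availability_probs))) {
    stop("availability_probs must name all four platforms", call. = FALSE)
  }
  invisible(cfg)
}

variant_class_probs <- c(
  missense = 0.60, silent = 0.15, nonsense = 0.05,
  frameshift_deletion = 0.05, frameshift_insertion = 0.03,
  inframe_deletion = 0.02, inframe_insertion = 0.01,
  splice_site = 0.04, other = 0.05
)

#' Simulate a tumour cohort with planted defective genes
#'
#' @param config A [cancer_config()] object.
#' @return A list of tibbles:
#' * `mutations`: `sample`, `gene`, `variant_class`, `ndamage` (missense
#'   only, `NA` otherwise), `in_mononucleotide_repeat`.
#' * `cnv`: `sample`, `gene`, `gistic` (integer -2..2).
#' * `expression`: `sample`, `gene`, `z`.
#' * `methylation`: `sample`, `gene`, `hypermethylated`.
#' * `annotations`: `gene`, `length_aa`, `s_score`.
#' * `availability`: `sample`, `platform`, `available`; platform tables
#'   only contain rows for available sample-platform combinations.
#' * `truth`: list with `planted_genes`.
#' @examples
#' cohort <- simulate_cancer(cancer_config(n_samples = 50, n_genes = 30,
#'                                         planted_ts_genes = 5, seed = 1))
#' head(cohort$mutations)
#' @export
simulate_cancer <- function(config) {
  validate_cancer_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  samples <- sprintf("TCGA-%04d", seq_len(config$n_samples))
  planted <- sample(genes, config$planted_ts_genes)

  len <- pmax(50L, as.integer(round(stats::rlnorm(config$n_genes,
                                                  config$length_meanlog,
                                                  config$length_sdlog))))
  names(len) <- genes
  s_score <- stats::rnorm(config$n_genes)
  s_score[genes %in% planted] <- stats::rnorm(length(planted), -3, 0.5)
  annotations <- tibble::tibble(gene = genes, length_aa = unname(len),
                                s_score = s_score)

  availability <- tidyr::expand_grid(
    sample = samples,
    platform = c("mutation", "cnv", "expression", "methylation")
  ) |>
    dplyr::mutate(available = stats::runif(dplyr::n()) <
                    config$availability_probs[.data$platform])

  avail_samples <- function(platform) {
    availability$sample[availability$platform == platform & availability$available]
  }

  lof_classes_sim <- c("nonsense", "frameshift_deletion", "frameshift_insertion",
                       "inframe_deletion", "inframe_insertion", "splice_site")

  # background mutations: counts per sample x gene ~ Poisson(length * rate)
  mut_samples <- avail_samples("mutation")
  bg <- tidyr::expand_grid(sample = mut_samples, gene = genes) |>
    dplyr::mutate(n_mut = stats::rpois(dplyr::n(),
                                       len[.data$gene] * config$background_mut_rate)) |>
    dplyr::filter(.data$n_mut > 0) |>
    tidyr::uncount(weights = .data$n_mut) |>
    dplyr::mutate(
      variant_class = sample(names(variant_class_probs), dplyr::n(),
                             replace = TRUE, prob = variant_class_probs),
      planted_gene = .data$gene %in% planted
    )
  # planted genes: extra LOF mutations
  extra <- tidyr::expand_grid(sample = mut_samples, gene = planted) |>
    dplyr::filter(stats::runif(dplyr::n()) < config$planted_lof_rate) |>
    dplyr::mutate(
      variant_class = sample(lof_classes_sim, dplyr::n(), replace = TRUE),
      planted_gene = TRUE
    )
  mutations <- dplyr::bind_rows(bg, extra) |>
    dplyr::mutate(
      ndamage = ifelse(
        .data$variant_class == "missense",
        ifelse(.data$planted_gene,
               sample(0:6, dplyr::n(), replace = TRUE,
                      prob = config$planted_ndamage_probs),
               sample(0:6, dplyr::n(), replace = TRUE,
                      prob = config$ndamage_probs)),
        NA_integer_
      ),
      in_mononucleotide_repeat =
        .data$variant_class %in% c("frameshift_deletion", "frameshift_insertion") &
        stats::runif(dplyr::n()) < config$mono_repeat_prob
    ) |>
    dplyr::select("sample", "gene", "variant_class", "ndamage",
                  "in_mononucleotide_repeat") |>
    dplyr::arrange(.data$sample, .data$gene)

  # copy number
  cnv <- tidyr::expand_grid(sample = avail_samples("cnv"), gene = genes) |>
    dplyr::mutate(
      p_loss = ifelse(.data$gene %in% planted, config$planted_cnv_loss_prob,
                      config$cnv_loss_prob),
      p_homdel = ifelse(.data$gene %in% planted, config$planted_homdel_prob,
                        config$homdel_prob),
      u = stats::runif(dplyr::n()),
      gistic = dplyr::case_when(
        .data$u < .data$p_homdel ~ -2L,
        .data$u < .data$p_homdel + .data$p_loss ~ -1L,
        .data$u < .data$p_homdel + .data$p_loss + config$amp_prob ~ 2L,
        .data$u < .data$p_homdel + .data$p_loss + config$amp_prob +
          config$gain_prob ~ 1L,
        TRUE ~ 0L
      )
    ) |>
    dplyr::select("sample", "gene", "gistic")

  # methylation
  methylation <- tidyr::expand_grid(sample = avail_samples("methylation"),
                                    gene = genes) |>
    dplyr::mutate(
      p = ifelse(.data$gene %in% planted, config$planted_silencing_prob,
                 config$silencing_prob),
      hypermethylated = stats::runif(dplyr::n()) < .data$p
    ) |>
    dplyr::select("sample", "gene", "hypermethylated")

  # expression: baseline noise shifted down on copy loss or hypermethylation
  expression <- tidyr::expand_grid(sample = avail_samples("expression"),
                                   gene = genes) |>
    dplyr::left_join(cnv, by = c("sample", "gene")) |>
    dplyr::left_join(methylation, by = c("sample", "gene")) |>
    dplyr::mutate(
      z = stats::rnorm(dplyr::n()) +
        config$expr_shift_on_loss *
          ((!is.na(.data$gistic) & .data$gistic < 0) |
             (!is.na(.data$hypermethylated) & .data$hypermethylated))
    ) |>
    dplyr::select("sample", "gene", "z")

  list(
    mutations = mutations, cnv = cnv, expression = expression,
    methylation = methylation, annotations = annotations,
    availability = availability,
    truth = list(planted_genes = sort(planted))
  )
}
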