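#' Configuration for the synthetic TLDA cohort generator
#'
#' Defaults are the published summaries of the real cohort: endogenous
#' reference-gene Cq means/SDs (UBC 17.1±0.7 ... TBP 24±0.6),
#' olfactory-epithelium reference genes anchored at ADCY3 21.3±0.8 and
#' OBP 30.6±1.1 with the unprinted four spaced evenly between, OR Cq
#' baselines in 25.8–39.8, 62±29 undetermined OR reactions per sample,
#' genomic-DNA card at 24.5±0.8, plasmid card at 25.4±1.1 (specific) /
#' 32.5±1.8 (negligible cross) / 25.0±0.8 (indistinguishable partner), and
#' RT-minus detection in 10% of reactions at 34.1±1.1.
#'
#' @param n_samples cohort size (default 26).
#' @param calibrator_cq delta-Cq calibrator (default 32.7).
#' @param endogenous_ref_params named list `gene = c(mean, sd)` of Cq.
#' @param oe_ref_params named list `gene = c(mean, sd)` of Cq.
#' @param or_cq_range range OR baselines are drawn from (default 25.8–39.8).
#' @param undetermined_rate_params `c(mean, sd)` of undetermined OR
#'   reactions per sample (default 62, 29).
#' @param neuron_fraction_sd SD (cycles) of the per-sample latent
#'   olfactory-neuron-content shift, applied to OR and OE-reference genes
#'   only — the biological variability the second normalization stage is
#'   designed to remove.
#' @param technical_loading_sd SD (cycles) of the per-sample latent loading
#'   shift applied to every gene.
#' @param or_noise_sd per-cell residual SD for OR genes (cycles).
#' @param run_offsets named numeric of additive per-run Cq offsets.
#' @param age_effect_genes named numeric: gene -> slope (cycles/year, applied
#'   to age centered at the cohort mean).
#' @param binary_effect_genes list of `list(gene=, covariate=, level=,
#'   delta=)` additive Cq shifts for samples at `level` of `covariate`.
#' @param gdna_cq_params,plasmid_specific_params,plasmid_cross_params,plasmid_indist_params
#'   `c(mean, sd)` for the calibration cards.
#' @param rtminus_detect_rate,rtminus_cq_params RT-minus contamination model.
#' @param max_cycles cycle ceiling; true Cq beyond it is undetermined.
#' @return list of class `generator_config`
#' @export
generator_config <- function(
    n_samples = 26,
    calibrator_cq = 32.7,
    endogenous_ref_params = list(
      UBC = c(17.1, 0.7), GAPDH = c(17.6, 0.5), PPIA = c(18.0, 0.6),
      CDKN1B = c(20.0, 0.6), CASC3 = c(20.4, 0.6), PSMC4 = c(21.5, 0.7),
      POLR2A = c(21.7, 0.6), YWHAZ = c(22.1, 0.8), RPL30 = c(22.6, 0.9),
      MRPL19 = c(22.8, 3.6), TBP = c(24.0, 0.6)),
    oe_ref_params = NULL,
    or_cq_range = c(25.8, 39.8),
    undetermined_rate_params = c(62, 29),
    neuron_fraction_sd = 0.6,
    technical_loading_sd = 0.3,
    or_noise_sd = 1.0,
    run_offsets = c(run1 = 0, run2 = 0, run3 = 0),
    age_effect_genes = numeric(0),
    binary_effect_genes = list(),
    gdna_cq_params = c(24.5, 0.8),
    plasmid_specific_params = c(25.4, 1.1),
    plasmid_cross_params = c(32.5, 1.8),
    plasmid_indist_params = c(25.0, 0.8),
    rtminus_detect_rate = 0.10,
    rtminus_cq_params = c(34.1, 1.1),
    max_cycles = 40) {
  if (is.null(oe_ref_params)) {
    # only the endpoints are printed; space the rest evenly between them
    genes <- c("ADCY3", "GNAL", "RIC8B", "RTP1", "CNGA2", "OBP2A_2B")
    mu <- seq(21.3, 30.6, length.out = 6)
    sd <- seq(0.8, 1.1, length.out = 6)
    oe_ref_params <- stats::setNames(lapply(seq_along(genes),
                                            function(i) c(mu[i], sd[i])), genes)
  }
  cfg <- list(n_samples = n_samples, calibrator_cq = calibrator_cq,
              endogenous_ref_params = endogenous_ref_params,
              oe_ref_params = oe_ref_params, or_cq_range = or_cq_range,
              undetermined_rate_params = undetermined_rate_params,
              neuron_fraction_sd = neuron_fraction_sd,
              technical_loading_sd = technical_loading_sd,
              or_noise_sd = or_noise_sd, run_offsets = run_offsets,
              age_effect_genes = age_effect_genes,
              binary_effect_genes = binary_effect_genes,
              gdna_cq_params = gdna_cq_params,
              plasmid_specific_params = plasmid_specific_params,
              plasmid_cross_params = plasmid_cross_params,
              plasmid_indist_params = plasmid_indist_params,
              rtminus_detect_rate = rtminus_detect_rate,
              rtminus_cq_params = rtminus_cq_params,
              max_cycles = max_cycles)
  sds <- c(neuron_fraction_sd, technical_loading_sd, or_noise_sd,
           undetermined_rate_params[2],
           vapply(endogenous_ref_params, `[`, 0, 2),
           vapply(oe_ref_params, `[`, 0, 2))
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  if (or_cq_range[1] >= or_cq_range[2]) stop("or_cq_range must be increasing")
  class(cfg) <- "generator_config"
  cfg
}

# residual per-cell SD so that total per-gene SD approximates the stated one
resid_sd <- function(total_sd, ...) sqrt(pmax(total_sd^2 - sum(c(...)^2), 0))

#' Generate a synthetic whole-olfactory-mucosa cohort
#'
#' Cell model:
#' `Cq = baseline_gene + covariate effects + technical_loading_s (all genes)
#'  + neuron_shift_s (OR and OE-reference genes only) + run_offset + noise`.
#' OR cells become undetermined when the true Cq exceeds `max_cycles` or the
#' cell is sampled as a dropout; the per-sample dropout count targets the
#' published 62±29 undetermined OR reactions per sample.
#'
#' @param config a [generator_config()]
#' @param seed integer seed; identical `(config, seed)` give identical output.
#' @param panel an [assay_panel()] (default [default_panel()]).
#' @return list with elements `cq` (a [cq_matrix()]), `samples` (data.frame
#'   of donor covariates) and `truth` (latent factors, baselines, planted
#'   effects and the true expressed status of every OR cell).
#' @export
generate_cohort <- function(config = generator_config(), seed = 1,
                            panel = default_panel()) {
  if (config$n_samples < 2)
    stop("n_samples must be >= 2 (association stages undefined below that)")
  set.seed(seed)
  n <- config$n_samples
  samples <- sprintf("S%02d", seq_len(n))
  runs <- names(config$run_offsets)
  run_id <- sort(rep(runs, length.out = n))  # contiguous blocks per run

  age <- round(stats::runif(n, 39, 81))
  sex <- rep(c("F", "M"), length.out = n)
  smoking <- sample(smoking_levels, n, replace = TRUE,
                    prob = c(12, 2, 8, 4) / 26)
  rin <- round(pmin(10, pmax(1, stats::rnorm(n, 7.3, 0.8))), 1)
  delay <- round(pmax(2, stats::rnorm(n, 27, 12)))
  smpl <- data.frame(sample_id = samples, age = age, sex = sex, rin = rin,
                     smoking = smoking, delay_hours = delay,
                     origin = "synthetic", stringsAsFactors = FALSE)

  assays <- panel$assay_id
  is_or <- panel$role == "or_target"
  is_oe <- panel$role == "oe_ref"
  is_endo <- panel$role %in% c("endogenous_ref", "internal_control")

  baseline <- numeric(length(assays))
  noise_sd <- numeric(length(assays))
  tech <- stats::rnorm(n, 0, config$technical_loading_sd)
  neuron <- stats::rnorm(n, 0, config$neuron_fraction_sd)

  for (i in seq_along(assays)) {
    g <- panel$gene_symbol[i]
    aid <- assays[i]
    if (is_endo[i]) {
      p <- config$endogenous_ref_params[[g]] %||%
        config$endogenous_ref_params[[aid]] %||% c(20, 0.6)
      baseline[i] <- p[1]
      noise_sd[i] <- resid_sd(p[2], config$technical_loading_sd)
    } else if (is_oe[i]) {
      p <- config$oe_ref_params[[aid]] %||% config$oe_ref_params[[g]] %||%
        c(25, 1)
      baseline[i] <- p[1]
      noise_sd[i] <- resid_sd(p[2], config$technical_loading_sd,
                              config$neuron_fraction_sd)
    }
  }
  baseline[is_or] <- stats::runif(sum(is_or), config$or_cq_range[1],
                                  config$or_cq_range[2])
  noise_sd[is_or] <- config$or_noise_sd

  effect <- matrix(0, n, length(assays), dimnames = list(samples, assays))
  if (length(config$age_effect_genes)) {
    for (g in names(config$age_effect_genes)) {
      j <- match(g, assays)
      if (is.na(j)) stop("age effect gene not in panel: ", g)
      effect[, j] <- effect[, j] + config$age_effect_genes[[g]] * (age - mean(age))
    }
  }
  for (be in config$binary_effect_genes) {
    j <- match(be$gene, assays)
    if (is.na(j)) stop("binary effect gene not in panel: ", be$gene)
    effect[, j] <- effect[, j] + be$delta * (smpl[[be$covariate]] == be$level)
  }

  noise <- matrix(stats::rnorm(n * length(assays), 0,
                               rep(noise_sd, each = n)),
                  n, length(assays), dimnames = list(samples, assays))
  latent <- outer(tech, rep(1, length(assays))) +
    outer(neuron, as.numeric(is_or | is_oe))
  cq_true <- matrix(baseline, n, length(assays), byrow = TRUE,
                    dimnames = list(samples, assays)) +
    effect + latent + config$run_offsets[run_id] + noise

  values <- cq_true
  # dropouts: OR cells only. Undetermined wells arise where template sits
  # near the detection limit, so drop probability rises logistically with
  # the cell's true Cq, centered at the quantile that makes the expected
  # per-sample count hit its target (drawn from the stated 62±29).
  n_or <- sum(is_or)
  target <- round(pmin(pmax(stats::rnorm(
    n, config$undetermined_rate_params[1],
    config$undetermined_rate_params[2]), 0), n_or))
  drop <- matrix(FALSE, n, length(assays))
  or_idx <- which(is_or)
  for (s in seq_len(n)) {
    if (target[s] > 0) {
      cqs <- cq_true[s, or_idx]
      center <- sort(cqs, decreasing = TRUE)[target[s]]
      p <- stats::plogis((cqs - center) / 0.7)
      drop[s, or_idx] <- stats::runif(n_or) < p
    }
  }
  values[drop | values > config$max_cycles] <- NA_real_
  values[!is.na(values)] <- pmax(values[!is.na(values)], 0.01)

  cutoff_cq <- 35.3   # true expressed status at the 5-copy equivalent Cq
  truth <- list(
    sample_factors = data.frame(sample_id = samples, technical_loading = tech,
                                neuron_shift = neuron, run_id = run_id,
                                undetermined_target = target,
                                stringsAsFactors = FALSE),
    baseline = stats::setNames(baseline, assays),
    effects = effect,
    true_cq = cq_true,
    true_expressed = cq_true[, is_or, drop = FALSE] <= cutoff_cq)

  list(cq = cq_matrix(values, run_id = run_id, condition = "whom",
                      max_cycles = config$max_cycles),
       samples = smpl, truth = truth)
}

#' Generate a genomic-DNA calibration card
#'
#' One pseudo-sample: every intronless assay draws from the genomic-DNA Cq
#' distribution (all genes have the same genomic copy number, so similar
#' Cq); intron-spanning assays stay undetermined. An anomalous assay (such
#' as a primer pair hitting a repeated region) can be planted at a stated
#' low Cq.
#'
#' @param config a [generator_config()]
#' @param seed integer seed
#' @param panel an [assay_panel()]
#' @param anomaly optional `list(assay_id=, cq=)` planted anomaly
#' @return a [cq_matrix()] with one row, condition `"gdna"`
#' @export
generate_gdna_card <- function(config = generator_config(), seed = 1,
                               panel = default_panel(), anomaly = NULL) {
  set.seed(seed)
  v <- rep(NA_real_, nrow(panel))
  intronless <- !panel$intron_spanning
  v[intronless] <- stats::rnorm(sum(intronless), config$gdna_cq_params[1],
                                config$gdna_cq_params[2])
  if (!is.null(anomaly)) {
    j <- match(anomaly$assay_id, panel$assay_id)
    if (is.na(j)) stop("anomaly assay not in panel: ", anomaly$assay_id)
    v[j] <- anomaly$cq
  }
  m <- matrix(v, 1, dimnames = list("gdna_pool", panel$assay_id))
  cq_matrix(m, run_id = "gdna_run", condition = "gdna",
            max_cycles = config$max_cycles)
}

#' Generate a plasmid-pool specificity card
#'
#' Pool members amplify at the specific Cq; assays declared negligible
#' cross-reactors or indistinguishable close paralogs in `cross_map` amplify
#' at their published offsets; everything else is undetermined.
#'
#' @param pool_members assay ids of the pooled OR plasmids
#' @param config a [generator_config()]
#' @param seed integer seed
#' @param panel an [assay_panel()]
#' @param cross_map optional `list(negligible = chr, indistinguishable = chr)`
#' @return a [cq_matrix()] with one row, condition `"plasmid"`
#' @export
generate_plasmid_card <- function(pool_members, config = generator_config(),
                                  seed = 1, panel = default_panel(),
                                  cross_map = NULL) {
  missing <- setdiff(pool_members, panel$assay_id)
  if (length(missing))
    stop("pool member not in panel: ", paste(missing, collapse = ", "))
  set.seed(seed)
  v <- rep(NA_real_, nrow(panel))
  names(v) <- panel$assay_id
  v[pool_members] <- stats::rnorm(length(pool_members),
                                  config$plasmid_specific_params[1],
                                  config$plasmid_specific_params[2])
  if (!is.null(cross_map)) {
    ng <- setdiff(cross_map$negligible %||% character(0), pool_members)
    ind <- setdiff(cross_map$indistinguishable %||% character(0), pool_members)
    v[ng] <- stats::rnorm(length(ng), config$plasmid_cross_params[1],
                          config$plasmid_cross_params[2])
    v[ind] <- stats::rnorm(length(ind), config$plasmid_indist_params[1],
                           config$plasmid_indist_params[2])
  }
  m <- matrix(v, 1, dimnames = list("plasmid_pool", panel$assay_id))
  cq_matrix(m, run_id = "plasmid_run", condition = "plasmid",
            max_cycles = config$max_cycles)
}

#' Generate RT-minus control ports
#'
#' Each assay is detected (residual genomic-DNA amplification) with
#' probability `rtminus_detect_rate`, at `rtminus_cq_params`; otherwise it
#' stays undetermined.
#'
#' @param config a [generator_config()]
#' @param seed integer seed
#' @param panel an [assay_panel()]
#' @param n_samples number of RT-minus pseudo-samples (default 1)
#' @return a [cq_matrix()], condition `"rt_minus"`
#' @export
generate_rt_minus <- function(config = generator_config(), seed = 1,
                              panel = default_panel(), n_samples = 1) {
  set.seed(seed)
  k <- nrow(panel)
  m <- matrix(NA_real_, n_samples, k,
              dimnames = list(sprintf("RTminus%02d", seq_len(n_samples)),
                              panel$assay_id))
  det <- matrix(stats::runif(n_samples * k), n_samples, k) <
    config$rtminus_detect_rate
  m[det] <- stats::rnorm(sum(det), config$rtminus_cq_params[1],
                         config$rtminus_cq_params[2])
  m[!is.na(m)] <- pmin(pmax(m[!is.na(m)], 0.01), config$max_cycles)
  cq_matrix(m, run_id = "rtminus_run", condition = "rt_minus",
            max_cycles = config$max_cycles)
}
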