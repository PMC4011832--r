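#' Pipeline configuration
#'
#' Validates and fills a configuration for [run_pipeline()]. Exactly one of
#' the file-input block (`cq_path`, `panel_path`, `metadata_path`) and the
#' `generator` block (a [generator_config()] or list of its arguments) must
#' be present.
#'
#' @param config named list or path to a JSON file
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  has_files <- !is.null(config$cq_path)
  has_gen <- !is.null(config$generator)
  if (has_files == has_gen)
    stop("validation error: exactly one of file inputs (cq_path/panel_path) ",
         "and a generator block must be given")
  if (has_files && is.null(config$panel_path))
    stop("validation error: file inputs need a panel_path")
  defaults <- list(detect_threshold = 35, copy_cutoff = 5,
                   cutoff_cq = 35.3, ratio_threshold = 2,
                   q_threshold = 0.05, calibrator_cq = 32.7,
                   calibration_mode = "configured",
                   sam_B = 1000, global_B = 10000, seed = 1,
                   tech_refs = NULL,   # NULL: pick top genes by geNorm
                   n_tech_refs = 3,
                   bio_refs = c("CNGA2", "GNAL", "ADCY3", "RIC8B", "RTP1",
                                "OBP2A_2B"))
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  thr <- c(config$detect_threshold, config$copy_cutoff, config$ratio_threshold,
           config$q_threshold)
  if (any(thr <= 0)) stop("validation error: thresholds must be positive")
  class(config) <- "pipeline_config"
  config
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  x <- unclass(config)
  x$out_dir <- NULL
  x <- x[order(names(x))]
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stage order: inputs (read files or generate a synthetic cohort) -> QC
#' (RT-minus, genomic-DNA screen, plasmid specificity, when cards are
#' available) -> two-stage normalization (geNorm selection of technical
#' references) -> copy-number calling and repertoire summaries ->
#' per-covariate association (SAM FDR + global permutation test) ->
#' deorphanized / potentially-non-functional enrichment. Every stage writes
#' TSV artifacts plus a JSON summary stamped with the configuration hash
#' and seed; identical configuration and seed give byte-identical bundles.
#'
#' @param config a [pipeline_config()] (or list / JSON path accepted by it)
#' @param out_dir output directory (created if needed)
#' @param seed overrides `config$seed` when given
#' @param quiet suppress progress messages
#' @return invisibly, a list with the stage results and `out_dir`
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  config <- pipeline_config(if (inherits(config, "pipeline_config"))
    unclass(config) else config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message("[orqprofiler] ", msg)
  }
  stage <- "inputs"
  result <- tryCatch({
    # ---- inputs ----
    if (!is.null(config$generator)) {
      gen_args <- config$generator
      gcfg <- if (inherits(gen_args, "generator_config")) gen_args
              else do.call(generator_config, gen_args)
      panel <- default_panel()
      cohort <- generate_cohort(gcfg, seed = config$seed, panel = panel)
      cqm <- cohort$cq
      meta <- cohort$samples
      rt <- generate_rt_minus(gcfg, seed = config$seed + 1, panel = panel)
      gdna <- generate_gdna_card(gcfg, seed = config$seed + 2, panel = panel)
      note("generated synthetic cohort: ", nrow(meta), " samples")
    } else {
      panel <- read_assay_panel(config$panel_path)
      cqm <- read_cq_table(config$cq_path)
      meta <- if (!is.null(config$metadata_path))
        read_tsv_plain(config$metadata_path) else NULL
      rt <- if (!is.null(config$rtminus_path)) read_cq_table(config$rtminus_path)
      gdna <- if (!is.null(config$gdna_path)) read_cq_table(config$gdna_path)
      note("read inputs: ", nrow(cqm$values), " samples x ",
           ncol(cqm$values), " assays")
    }

    # ---- qc ----
    stage <- "qc"
    qc <- list()
    excluded <- character(0)
    if (!is.null(rt)) {
      qc$rt_minus <- assess_rt_minus(rt, config$detect_threshold)
      write_tsv_plain(qc$rt_minus$per_sample, file.path(out_dir, "qc_rtminus.tsv"))
    }
    if (!is.null(gdna)) {
      qc$gdna <- screen_gdna_assays(gdna, panel)
      excluded <- qc$gdna$excluded
      write_tsv_plain(qc$gdna$report, file.path(out_dir, "qc_gdna.tsv"))
    }
    note("qc done; ", length(excluded), " assay(s) excluded")

    # ---- normalize ----
    stage <- "normalize"
    endo <- panel$assay_id[panel$role == "endogenous_ref"]
    rq_endo <- cq_to_rq(cqm, config$calibrator_cq)
    gn <- genorm_stability(rq_endo$values[, endo, drop = FALSE])
    tech_refs <- config$tech_refs %||% gn$ranking[seq_len(config$n_tech_refs)]
    norm <- normalize_two_stage(cqm, tech_refs = tech_refs,
                                bio_refs = config$bio_refs,
                                calibrator_cq = config$calibrator_cq)
    write_tsv_plain(data.frame(sample_id = rownames(norm$values),
                               nf_tech = norm$nf_tech, nf_bio = norm$nf_bio),
                    file.path(out_dir, "normalization_factors.tsv"))
    nrq_df <- data.frame(assay_id = colnames(norm$values),
                         t(norm$values), check.names = FALSE)
    write_tsv_plain(nrq_df, file.path(out_dir, "nrq.tsv"))
    note("normalized with tech refs: ", paste(tech_refs, collapse = ", "))

    # ---- call ----
    stage <- "call"
    # normalization factors are deliberately unscaled (keeps NRQ exactly
    # invariant to per-sample Cq shifts), so the effective Cq of a cell is
    # its raw Cq plus the sample's log2 total factor; anchor the configured
    # calibration at the raw-Cq cutoff translated onto that scale
    eff_cutoff <- config$cutoff_cq + mean(log2(norm$nf_tech * norm$nf_bio))
    cal <- fit_calibration(config$calibration_mode,
                           copy_cutoff = config$copy_cutoff,
                           cutoff_cq = if (config$calibration_mode ==
                                           "configured") eff_cutoff
                                       else config$cutoff_cq)
    ors <- setdiff(panel$assay_id[panel$role == "or_target"], excluded)
    nrq_or <- norm$values[, intersect(colnames(norm$values), ors), drop = FALSE]
    copies <- estimate_copies(nrq_or, cal, calibrator_cq = norm$calibrator_cq)
    calls <- call_expression(copies, cutoff = config$copy_cutoff)
    rep_sum <- repertoire_summary(calls, sex = meta$sex)
    copies_df <- data.frame(assay_id = colnames(copies$values),
                            t(copies$values), check.names = FALSE)
    write_tsv_plain(copies_df, file.path(out_dir, "copies.tsv"))
    write_tsv_plain(rep_sum$per_sample, file.path(out_dir, "repertoire_per_sample.tsv"))
    note("called expression: ", sum(calls$overall, na.rm = TRUE),
         " of ", length(ors), " ORs expressed overall")

    # ---- associate ----
    stage <- "associate"
    assoc <- list()
    if (!is.null(meta)) {
      expr <- log_expression(copies)
      covs <- list(age = meta$age,
                   sex = factor(meta$sex),
                   smoking = encode_smoking(meta$smoking))
      for (cv in names(covs)) {
        ok <- tryCatch({
          res <- sam_fdr(expr, covs[[cv]], B = config$sam_B,
                         seed = config$seed, q_threshold = config$q_threshold)
          glob <- global_association(expr, covs[[cv]], B = config$global_B,
                                     seed = config$seed)
          assoc[[cv]] <- list(sam = res, global = glob)
          write_tsv_plain(res$table,
                          file.path(out_dir, paste0("association_", cv, ".tsv")))
          TRUE
        }, error = function(e) {
          note("association for ", cv, " skipped: ", conditionMessage(e))
          FALSE
        })
      }
      note("association done for: ", paste(names(assoc), collapse = ", "))
    }

    # ---- enrich ----
    stage <- "enrich"
    copies_mean <- stats::setNames(copies$per_assay$mean, copies$per_assay$assay_id)
    enrich <- list()
    for (ann in c("deorphanized", "potentially_nonfunctional")) {
      e <- tryCatch(annotation_enrichment(calls, panel, ann, copies_mean),
                    error = function(err) {
                      note("enrichment for ", ann, " skipped: ",
                           conditionMessage(err))
                      NULL
                    })
      if (!is.null(e)) enrich[[ann]] <- e
    }
    comp <- class_composition(calls, panel)
    note("enrichment done")

    # ---- summary ----
    summary <- list(
      config_hash = hash, seed = config$seed,
      n_samples = nrow(cqm$values),
      n_or_analyzed = length(ors),
      excluded_assays = as.list(excluded),
      tech_refs = as.list(tech_refs),
      n_expressed_overall = sum(calls$overall, na.rm = TRUE),
      freq_class_sizes = as.list(rep_sum$freq_class_sizes),
      by_sex = if (!is.null(rep_sum$by_sex)) rep_sum$by_sex,
      class_composition = list(pct_tested = comp$pct_class1_tested,
                               pct_expressed = comp$pct_class1_expressed,
                               fisher_p = comp$fisher$p),
      enrichment = lapply(enrich, function(e) list(
        table = unclass(e$table), fisher_p = e$fisher$p,
        pct_expressed = e$pct_annotated_expressed,
        pct_not = e$pct_annotated_not,
        welch_p = if (!is.null(e$welch)) e$welch$p)),
      association = lapply(assoc, function(a) list(
        n_up = length(a$sam$significant_up),
        n_down = length(a$sam$significant_down),
        global_p = a$global$p, B = a$sam$B)))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    list(panel = panel, cq = cqm, qc = qc, genorm = gn, norm = norm,
         copies = copies, calls = calls, repertoire = rep_sum,
         association = assoc, enrichment = enrich, composition = comp,
         summary = summary, out_dir = out_dir)
  }, error = function(e) {
    writeLines(c(log_lines, paste0("FAILED at stage ", stage, ": ",
                                   conditionMessage(e))),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Command-line entry point
#'
#' `orqprofiler <subcommand> --config cfg.json [--seed N] [--out DIR]`.
#' The pipeline communicates between stages through files and every run
#' writes all stage artifacts, so the stage subcommands (`qc`, `normalize`,
#' `call`, `associate`, `enrich`) execute the same end-to-end flow as
#' `run`; they exist so shell scripts can name the stage they are after.
#' Configuration is JSON (fields of [pipeline_config()]).
#'
#' @param args character vector, defaults to the command line
#' @return invisibly, the [run_pipeline()] result
#' @export
orq_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: orqprofiler qc|normalize|call|associate|enrich|run --config cfg.json [--seed N] [--out DIR]"
  if (length(args) < 1) stop(usage, call. = FALSE)
  sub <- args[1]
  if (!sub %in% c("qc", "normalize", "call", "associate", "enrich", "run"))
    stop("unknown subcommand '", sub, "'\n", usage, call. = FALSE)
  cfg_path <- NULL; seed <- NULL; out <- "orqprofiler_out"
  i <- 2
  while (i <= length(args)) {
    if (args[i] == "--config") { cfg_path <- args[i + 1]; i <- i + 2 }
    else if (args[i] == "--seed") { seed <- as.integer(args[i + 1]); i <- i + 2 }
    else if (args[i] == "--out") { out <- args[i + 1]; i <- i + 2 }
    else stop("unknown argument '", args[i], "'\n", usage, call. = FALSE)
  }
  if (is.null(cfg_path)) stop("--config is required\n", usage, call. = FALSE)
  run_pipeline(cfg_path, out_dir = out, seed = seed)
}
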