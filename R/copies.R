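#' Fit the Cq-to-copies calibration model
#'
#' Anchors the exponential copies curve `copies(cq) = anchor_copies *
#' 2^(anchor_cq − cq)` in one of three ways: `"configured"` (default)
#' chooses the anchor so that the expression cutoff (5 copies / 20 ng RNA)
#' falls exactly at its published Cq equivalent (35.3 cycles); `"plasmid"`
#' anchors at ~3000 plasmid molecules per reaction at the card's mean
#' specific Cq; `"gdna"` anchors at the haploid genome count implied by the
#' reaction mass (one target locus per haploid genome, 0.0033 ng each) at
#' the card's mean intronless Cq. The naive mass anchors land within about
#' an order of magnitude of the published scale; the configured mode
#' reproduces it exactly.
#'
#' @param mode `"configured"`, `"plasmid"` or `"gdna"`
#' @param plasmid_card,gdna_card [cq_matrix()] calibration cards (for the
#'   respective modes)
#' @param pool_members plasmid pool assay ids (plasmid mode)
#' @param panel an [assay_panel()] (gdna mode)
#' @param copy_cutoff expression cutoff in copies (default 5)
#' @param cutoff_cq Cq the cutoff corresponds to (default 35.3)
#' @param anchor_cq optional explicit anchor Cq for configured mode (the
#'   anchor copies are then `copy_cutoff * 2^(cutoff_cq - anchor_cq)`)
#' @param plasmid_molecules molecules of each plasmid per reaction (3000)
#' @param reaction_mass_ng genomic DNA per reaction (150 ng per port feeds
#'   48 reactions: 3.125 ng each)
#' @return list of class `calibration_model`: `anchor_copies`, `anchor_cq`,
#'   `source`, `copies_at_cutoff_cq` diagnostic
#' @export
fit_calibration <- function(mode = c("configured", "plasmid", "gdna"),
                            plasmid_card = NULL, gdna_card = NULL,
                            pool_members = NULL, panel = NULL,
                            copy_cutoff = 5, cutoff_cq = 35.3,
                            anchor_cq = NULL, plasmid_molecules = 3000,
                            reaction_mass_ng = 3.125) {
  mode <- match.arg(mode)
  if (mode == "configured") {
    a_cq <- anchor_cq %||% cutoff_cq
    a_copies <- copy_cutoff * 2^(cutoff_cq - a_cq)
  } else if (mode == "plasmid") {
    if (is.null(plasmid_card) || is.null(pool_members))
      stop("plasmid mode needs plasmid_card and pool_members")
    cqs <- plasmid_card$values[1, pool_members]
    a_cq <- mean(cqs[!is.na(cqs)])
    a_copies <- plasmid_molecules
  } else {
    if (is.null(gdna_card) || is.null(panel))
      stop("gdna mode needs gdna_card and panel")
    x <- gdna_card$values[1, panel$assay_id]
    x <- x[!panel$intron_spanning & !is.na(x)]
    if (!length(x)) stop("no anchor derivable from the gDNA card")
    a_cq <- mean(x)
    a_copies <- reaction_mass_ng / 0.0033   # ng per haploid human genome
  }
  structure(list(anchor_copies = a_copies, anchor_cq = a_cq, source = mode,
                 copy_cutoff = copy_cutoff, cutoff_cq = cutoff_cq,
                 copies_at_cutoff_cq = a_copies * 2^(a_cq - cutoff_cq)),
            class = "calibration_model")
}

#' Convert normalized relative quantities to copies per 20 ng RNA
#'
#' The normalization-adjusted Cq of a cell is
#' `effective_cq = calibrator_cq − log2(NRQ)`; copies follow the anchored
#' exponential `anchor_copies * 2^(anchor_cq − effective_cq)` and halve
#' exactly per added cycle.
#'
#' @param nrq an `nrq_table` from [normalize_two_stage()] (or a positive
#'   matrix plus explicit `calibrator_cq`)
#' @param calibration a [fit_calibration()] model
#' @param calibrator_cq needed only when `nrq` is a bare matrix
#' @return list of class `copy_table`: `values` (samples x assays copies),
#'   `per_assay` (data.frame: mean, sd across samples), `calibration`
#' @export
estimate_copies <- function(nrq, calibration, calibrator_cq = NULL) {
  v <- if (inherits(nrq, "nrq_table")) nrq$values else nrq
  cal_cq <- if (inherits(nrq, "nrq_table")) nrq$calibrator_cq
            else calibrator_cq %||% stop("calibrator_cq required")
  eff_cq <- cal_cq - log2(v)
  copies <- calibration$anchor_copies * 2^(calibration$anchor_cq - eff_cq)
  per <- data.frame(assay_id = colnames(copies),
                    mean = apply(copies, 2, mean),
                    sd = apply(copies, 2, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(values = copies, per_assay = per, calibration = calibration),
            class = "copy_table")
}

#' Call expression at the copy cutoff
#'
#' A cell is expressed when its copies strictly exceed `cutoff` (boundary
#' cells at exactly the cutoff are not expressed); a gene's overall call
#' uses its across-sample mean. Assays excluded by QC are masked (`NA`
#' calls, dropped from margins).
#'
#' @param copies a `copy_table` from [estimate_copies()] or a samples x
#'   assays matrix
#' @param cutoff copies per 20 ng RNA (default 5)
#' @param excluded assay ids to mask
#' @return list of class `call_matrix`: `calls` (logical samples x assays,
#'   NA = masked), `n_expressing` (per assay), `n_expressed` (per sample),
#'   `overall` (per-assay logical, mean > cutoff), `cutoff`, `masked`
#' @export
call_expression <- function(copies, cutoff = 5, excluded = character(0)) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  v <- if (inherits(copies, "copy_table")) copies$values else copies
  calls <- v > cutoff
  mask <- colnames(calls) %in% excluded
  calls[, mask] <- NA
  overall <- colMeans(v) > cutoff
  overall[mask] <- NA
  structure(list(calls = calls,
                 n_expressing = colSums(calls),
                 n_expressed = rowSums(calls, na.rm = TRUE),
                 overall = overall, cutoff = cutoff,
                 masked = colnames(calls)[mask]),
            class = "call_matrix")
}

#' Frequency classes of expressing-individual counts
#'
#' Partition genes by how many of `n_individuals` express them: in all,
#' in the majority (at least half, rounded up, but not all), or rarely
#' (fewer than half).
#'
#' @param n_expressing integer vector per gene
#' @param n_individuals cohort size
#' @return factor with levels `all`, `majority`, `rare`
#' @export
frequency_classes <- function(n_expressing, n_individuals) {
  half <- ceiling(n_individuals / 2)
  cls <- ifelse(n_expressing == n_individuals, "all",
                ifelse(n_expressing >= half, "majority", "rare"))
  factor(cls, levels = c("all", "majority", "rare"))
}

#' Summarize the expressed OR repertoire
#'
#' @param calls a `call_matrix` from [call_expression()]
#' @param sex optional character vector per sample (`"F"`/`"M"`) for
#'   sex-stratified means
#' @return list: `per_sample` (data.frame of expressed counts),
#'   `by_sex` (mean ± sd of counts per sex, when given),
#'   `freq_class_sizes` (table over all/majority/rare among unmasked
#'   assays), `n_individuals`
#' @export
repertoire_summary <- function(calls, sex = NULL) {
  counts <- calls$n_expressed
  if (length(counts) < 1) stop("no samples")
  per_sample <- data.frame(sample_id = names(counts), n_expressed = counts,
                           row.names = NULL, stringsAsFactors = FALSE)
  by_sex <- NULL
  if (!is.null(sex)) {
    by_sex <- do.call(rbind, lapply(split(counts, sex), function(x)
      data.frame(n = length(x), mean = mean(x), sd = stats::sd(x))))
    by_sex <- cbind(sex = rownames(by_sex), by_sex)
    rownames(by_sex) <- NULL
  }
  ne <- calls$n_expressing[!colnames(calls$calls) %in% calls$masked]
  fc <- table(frequency_classes(ne, nrow(calls$calls)))
  list(per_sample = per_sample, by_sex = by_sex, freq_class_sizes = fc,
       n_individuals = nrow(calls$calls))
}

#' Class I composition of the tested and expressed OR sets
#'
#' @param calls a `call_matrix` restricted to OR assays (or a named logical
#'   vector of per-OR overall calls)
#' @param panel an [assay_panel()]
#' @return list: `pct_class1_tested`, `pct_class1_expressed`, counts, and a
#'   two-sided Fisher comparison of class I membership vs expression
#' @export
class_composition <- function(calls, panel) {
  overall <- if (inherits(calls, "call_matrix")) calls$overall else calls
  keep <- names(overall)[!is.na(overall)]
  cls <- panel$or_class[match(keep, panel$assay_id)]
  expressed <- overall[keep]
  n_tested <- length(keep)
  n_c1 <- sum(cls == "class_I")
  n_expr <- sum(expressed)
  n_c1_expr <- sum(expressed & cls == "class_I")
  tab <- contingency_2x2(n_c1_expr, n_expr - n_c1_expr,
                         n_c1 - n_c1_expr,
                         (n_tested - n_c1) - (n_expr - n_c1_expr))
  list(pct_class1_tested = 100 * n_c1 / n_tested,
       pct_class1_expressed = if (n_expr) 100 * n_c1_expr / n_expr else 0,
       n_tested = n_tested, n_class1 = n_c1, n_expressed = n_expr,
       n_class1_expressed = n_c1_expr,
       fisher = fisher_exact_2x2(tab))
}

#' Tissue expression ratios (olfactory mucosa vs inferior turbinate)
#'
#' Ratio of the cohort-mean olfactory-mucosa quantity to the single
#' inferior-turbinate quantity per OR; both inputs must carry technical
#' normalization only (the neuron-content factor is undefined for
#' respiratory mucosa).
#'
#' @param whom_quantities samples x OR matrix of technically normalized
#'   quantities
#' @param it_quantities named numeric per OR (single IT sample)
#' @param enrich_threshold enrichment cut on the ratio, inclusive (default 2)
#' @return data.frame of class `tissue_ratio_table`: assay_id, whom_mean,
#'   it, ratio, enriched; ORs missing from either side get NA ratios and
#'   are counted in `attr(, "n_missing")`
#' @export
tissue_ratio <- function(whom_quantities, it_quantities,
                         enrich_threshold = 2) {
  whom_mean <- colMeans(whom_quantities)
  all_ids <- union(names(whom_mean), names(it_quantities))
  wm <- whom_mean[all_ids]
  it <- it_quantities[all_ids]
  ratio <- unname(wm / it)
  out <- data.frame(assay_id = all_ids, whom_mean = unname(wm),
                    it = unname(it), ratio = ratio,
                    enriched = ratio >= enrich_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "n_missing") <- sum(is.na(ratio))
  attr(out, "n_enriched") <- sum(out$enriched, na.rm = TRUE)
  class(out) <- c("tissue_ratio_table", "data.frame")
  out
}
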