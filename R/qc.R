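#' Assess RT-minus contamination
#'
#' A reaction is "clean" when it is undetermined or crosses the threshold
#' only after `detect_threshold` cycles; detected reactions (numeric Cq at
#' or below the threshold) point at residual genomic DNA.
#'
#' @param rtminus a [cq_matrix()] of RT-minus ports
#' @param detect_threshold reliability threshold in cycles (default 35)
#' @param clean_bound minimum fraction_clean for a clean verdict (default 0.85)
#' @return list with `per_sample` (data.frame: fraction_clean, n_detected,
#'   mean_detected_cq, sd_detected_cq, verdict) and the thresholds used
#' @export
assess_rt_minus <- function(rtminus, detect_threshold = 35,
                            clean_bound = 0.85) {
  v <- rtminus$values
  if (length(v) == 0) stop("empty RT-minus matrix")
  per <- lapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    clean <- is.na(x) | x > detect_threshold
    det <- x[!clean]
    data.frame(sample_id = rownames(v)[i],
               fraction_clean = mean(clean),
               n_detected = length(det),
               mean_detected_cq = if (length(det)) mean(det) else NA_real_,
               sd_detected_cq = if (length(det) > 1) stats::sd(det) else NA_real_,
               verdict = if (mean(clean) >= clean_bound) "clean" else "contaminated",
               stringsAsFactors = FALSE)
  })
  list(per_sample = do.call(rbind, per),
       detect_threshold = detect_threshold, clean_bound = clean_bound)
}

#' Screen assays on a genomic-DNA card
#'
#' All genes share one copy number in genomic DNA, so intronless assays
#' should cluster tightly; an assay far below the cluster (center − k·SD,
#' robust center/spread: median and scaled MAD) amplifies something other
#' than a single locus and is excluded from downstream analysis.
#' Intron-spanning assays are expected undetermined; a detected one is
#' reported but tolerated.
#'
#' @param gdna a one-sample [cq_matrix()] from [generate_gdna_card()] or a
#'   real card
#' @param panel an [assay_panel()]
#' @param k_sd exclusion threshold in robust SD units (default 3)
#' @return list with `report` (per-assay data.frame: gdna_cq, status),
#'   `center`, `spread`, `excluded` (assay ids)
#' @export
screen_gdna_assays <- function(gdna, panel, k_sd = 3) {
  x <- gdna$values[1, panel$assay_id]
  intronless <- !panel$intron_spanning
  num <- x[intronless & !is.na(x)]
  if (length(num) == 0) stop("no numeric intronless Cq on the gDNA card")
  center <- stats::median(num)
  spread <- stats::mad(num)
  status <- character(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    cq <- x[i]
    if (panel$intron_spanning[i]) {
      status[i] <- if (is.na(cq)) "expected_undetermined_ok" else "unexpected_detected"
    } else if (is.na(cq)) {
      status[i] <- "not_detected"
    } else if (cq < center - k_sd * spread) {
      status[i] <- "anomalous_low"
    } else {
      status[i] <- "ok"
    }
  }
  report <- data.frame(assay_id = panel$assay_id, gdna_cq = unname(x),
                       status = status, stringsAsFactors = FALSE)
  list(report = report, center = center, spread = spread,
       excluded = panel$assay_id[status == "anomalous_low"])
}

#' Classify assay specificity on a plasmid-pool card
#'
#' Pool members define the specific amplification level; a non-member with
#' signal within `indistinct_delta` cycles of it cannot be discriminated
#' from its pooled paralog, one at `negligible_delta` or more above it
#' cross-reacts only negligibly, anything between is flagged intermediate.
#'
#' @param plasmid a one-sample [cq_matrix()]
#' @param pool_members assay ids of the pooled plasmids
#' @param indistinct_delta,negligible_delta cycle thresholds (defaults 3, 6)
#' @param partner_map optional named character: indistinguishable assay ->
#'   pooled paralog id (sequence identity is not derivable from Cq)
#' @return list with `report` (assay_id, cq, delta_cq, class, partner),
#'   `specific_mean`, class counts
#' @export
assess_plasmid_specificity <- function(plasmid, pool_members,
                                       indistinct_delta = 3,
                                       negligible_delta = 6,
                                       partner_map = NULL) {
  if (length(pool_members) == 0) stop("pool_members must be nonempty")
  x <- plasmid$values[1, ]
  mem_cq <- x[pool_members]
  if (anyNA(mem_cq)) {
    warning("pool member(s) undetermined, excluded from specific mean: ",
            paste(pool_members[is.na(mem_cq)], collapse = ", "))
    mem_cq <- mem_cq[!is.na(mem_cq)]
  }
  specific_mean <- mean(mem_cq)
  cls <- character(length(x))
  for (i in seq_along(x)) {
    a <- names(x)[i]
    if (a %in% pool_members) cls[i] <- "specific"
    else if (is.na(x[i])) cls[i] <- "silent"
    else if (x[i] <= specific_mean + indistinct_delta) cls[i] <- "indistinguishable"
    else if (x[i] >= specific_mean + negligible_delta) cls[i] <- "negligible_cross"
    else cls[i] <- "intermediate"
  }
  partner <- rep(NA_character_, length(x))
  if (!is.null(partner_map))
    partner[match(names(partner_map), names(x))] <- unname(partner_map)
  report <- data.frame(assay_id = names(x), cq = unname(x),
                       delta_cq = unname(x) - specific_mean, class = cls,
                       partner = partner, stringsAsFactors = FALSE)
  list(report = report, specific_mean = specific_mean,
       counts = table(factor(cls, levels = c("specific", "indistinguishable",
                                             "intermediate", "negligible_cross",
                                             "silent"))))
}

#' Inter-run calibration on a shared sample
#'
#' A shared sample measured in every run lets run-to-run shifts be
#' estimated: for each run pair, ordinary least squares of run-B on run-A Cq
#' over assays detected (numeric, below `detect_threshold`) in both, with r²
#' reported overall and per assay-role group; additive per-run offsets are
#' the mean paired difference against the reference (first) run, and can be
#' subtracted from the Cq matrix with [apply_run_offsets()].
#'
#' @param runs a [cq_matrix()] holding the shared sample's replicate rows
#'   (one per run, distinct `run_id`); other rows are ignored
#' @param shared_sample_id sample identifier prefix common to the replicate
#'   rows, or a character vector of the replicate row names
#' @param detect_threshold reliability threshold (default 35)
#' @param panel optional [assay_panel()] for per-role r²
#' @return list with `pairs` (data.frame: run_a, run_b, slope, intercept,
#'   r_squared, n plus per-role r² columns when a panel is given),
#'   `offsets` (named numeric per run, reference run 0)
#' @export
interrun_calibrate <- function(runs, shared_sample_id, detect_threshold = 35,
                               panel = NULL) {
  rows <- if (all(shared_sample_id %in% rownames(runs$values)))
    which(rownames(runs$values) %in% shared_sample_id)
  else grep(paste0("^", shared_sample_id), rownames(runs$values))
  if (length(rows) < 2) stop("shared sample must be measured in >= 2 runs")
  v <- runs$values[rows, , drop = FALSE]
  run_of <- runs$run_id[rows]
  if (anyDuplicated(run_of)) stop("one replicate per run expected")
  ref <- run_of[1]
  pairs <- list()
  role_groups <- NULL
  if (!is.null(panel)) {
    role <- panel$role[match(colnames(v), panel$assay_id)]
    role_groups <- list(or = role == "or_target",
                        oe_ref = role == "oe_ref",
                        endogenous = role %in% c("endogenous_ref",
                                                 "internal_control"))
  }
  for (i in 1:(length(rows) - 1)) for (j in (i + 1):length(rows)) {
    a <- v[i, ]; b <- v[j, ]
    use <- !is.na(a) & !is.na(b) & a < detect_threshold & b < detect_threshold
    if (sum(use) < 3)
      stop("fewer than 3 shared detected assays between runs ",
           run_of[i], " and ", run_of[j], "; fit undefined")
    fit <- stats::lm(b[use] ~ a[use])
    row <- data.frame(run_a = run_of[i], run_b = run_of[j],
                      slope = unname(stats::coef(fit)[2]),
                      intercept = unname(stats::coef(fit)[1]),
                      r_squared = summary(fit)$r.squared,
                      n = sum(use), stringsAsFactors = FALSE)
    if (!is.null(role_groups)) for (g in names(role_groups)) {
      u <- use & role_groups[[g]]
      row[[paste0("r_squared_", g)]] <-
        if (sum(u) >= 3) stats::cor(a[u], b[u])^2 else NA_real_
    }
    pairs[[length(pairs) + 1]] <- row
  }
  offsets <- vapply(seq_along(rows), function(i) {
    a <- v[1, ]; b <- v[i, ]
    use <- !is.na(a) & !is.na(b) & a < detect_threshold & b < detect_threshold
    mean(b[use] - a[use])
  }, 0)
  names(offsets) <- run_of
  list(pairs = do.call(rbind, pairs), offsets = offsets, reference_run = ref,
       detect_threshold = detect_threshold)
}

#' Subtract per-run calibration offsets from a Cq matrix
#'
#' @param cq a [cq_matrix()]
#' @param offsets named numeric per run, as returned by
#'   [interrun_calibrate()]; runs absent from `offsets` are left unchanged
#' @return a [cq_matrix()]
#' @export
apply_run_offsets <- function(cq, offsets) {
  v <- cq$values
  for (r in names(offsets)) {
    rows <- cq$run_id == r
    v[rows, ] <- v[rows, ] - offsets[[r]]
  }
  v[!is.na(v)] <- pmin(pmax(v[!is.na(v)], 0.01), cq$max_cycles)
  cq_matrix(v, cq$run_id, cq$condition, cq$max_cycles)
}
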