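#' Transform Cq values into relative quantities
#'
#' Delta-Cq quantification with constant efficiency: each cycle doubles the
#' template (E = 2), so `RQ = E^(calibrator − Cq)`. Undetermined cells are
#' substituted with `undetermined_substitute` cycles (default 40) *at this
#' stage only*; upstream the sentinel is kept lossless.
#'
#' @param cq a [cq_matrix()]
#' @param calibrator_cq calibrator in cycles (default 32.7, the mean OR Cq
#'   of the original cohort) or `"auto"` to recompute it as the mean of all
#'   OR Cq after substitution (requires `panel`)
#' @param efficiency amplification efficiency per cycle (> 1, default 2)
#' @param undetermined_substitute cycles substituted for undetermined cells
#' @param panel an [assay_panel()], needed only for `calibrator_cq = "auto"`
#' @return list of class `rq_table`: `values` (samples x assays, all > 0),
#'   `calibrator_cq`, `efficiency`, `undetermined_substitute`
#' @export
cq_to_rq <- function(cq, calibrator_cq = 32.7, efficiency = 2,
                     undetermined_substitute = 40, panel = NULL) {
  if (efficiency <= 1) stop("efficiency must be > 1")
  v <- cq$values
  v[is.na(v)] <- undetermined_substitute
  if (identical(calibrator_cq, "auto")) {
    if (is.null(panel)) stop("calibrator_cq = 'auto' needs a panel")
    ors <- intersect(panel$assay_id[panel$role == "or_target" & !panel$excluded],
                     colnames(v))
    calibrator_cq <- mean(v[, ors])
  }
  if (calibrator_cq <= 0) stop("calibrator_cq must be > 0")
  structure(list(values = efficiency^(calibrator_cq - v),
                 calibrator_cq = calibrator_cq, efficiency = efficiency,
                 undetermined_substitute = undetermined_substitute),
            class = "rq_table")
}

rq_values <- function(q) if (inherits(q, "rq_table")) q$values else q

#' geNorm reference-gene stability analysis
#'
#' For candidate genes j, k the pairwise variation `V_jk` is the standard
#' deviation across samples of `log2(q_j / q_k)`; the stability measure
#' `M_j` is the mean of `V_jk` over all k ≠ j. The least stable gene
#' (highest M) is removed and M recomputed until two genes remain; the
#' pairwise variation `V(n/n+1)` between normalization factors built from
#' the n and n+1 most stable genes indicates how many references suffice
#' (first n with V below `v_threshold`).
#'
#' @param quantities positive samples x genes matrix of relative quantities
#'   (or an `rq_table` restricted to the candidates)
#' @param v_threshold cut for V(n/n+1) (default 0.15, the conventional one)
#' @param na_action `"omit_samples"` drops samples with any missing
#'   candidate quantity (undetermined reference reactions are rare)
#' @return list of class `genorm_ranking`: `M` (initial M per candidate),
#'   `ranking` (most stable first; final tie broken by input order),
#'   `exclusion` (data.frame of step, gene, M at removal), `V` (named
#'   V(n/n+1) values), `recommended_n`
#' @export
genorm_stability <- function(quantities, v_threshold = 0.15,
                             na_action = c("omit_samples", "fail")) {
  na_action <- match.arg(na_action)
  q <- rq_values(quantities)
  if (anyNA(q)) {
    if (na_action == "fail") stop("missing quantities")
    q <- q[stats::complete.cases(q), , drop = FALSE]
  }
  if (ncol(q) < 3) stop("geNorm needs >= 3 candidate genes")
  if (nrow(q) < 2) stop("geNorm needs >= 2 samples")
  if (any(q <= 0)) stop("quantities must be positive")
  lq <- log2(q)
  genes <- colnames(lq)

  m_values <- function(cols) {
    vapply(cols, function(j) {
      mean(vapply(setdiff(cols, j),
                  function(k) stats::sd(lq[, j] - lq[, k]), 0))
    }, 0)
  }

  M0 <- m_values(genes)
  active <- genes
  excl <- data.frame(step = integer(0), gene = character(0), M = numeric(0),
                     stringsAsFactors = FALSE)
  step <- 0L
  while (length(active) > 2) {
    step <- step + 1L
    M <- m_values(active)
    worst <- active[which.max(M)]    # ties: first in panel order
    excl <- rbind(excl, data.frame(step = step, gene = worst,
                                   M = max(M), stringsAsFactors = FALSE))
    active <- setdiff(active, worst)
  }
  ranking <- c(active, rev(excl$gene))

  K <- length(genes)
  V <- numeric(0)
  if (K >= 3) {
    nf <- function(n) apply(lq[, ranking[seq_len(n)], drop = FALSE], 1, mean)
    V <- vapply(2:(K - 1), function(n) stats::sd(nf(n) - nf(n + 1)), 0)
    names(V) <- paste0("V", 2:(K - 1), "/", 3:K)
  }
  rec <- if (length(V) && any(V < v_threshold))
    (2:(K - 1))[which(V < v_threshold)[1]] else K
  structure(list(M = M0, ranking = ranking, exclusion = excl, V = V,
                 recommended_n = rec, v_threshold = v_threshold),
            class = "genorm_ranking")
}

#' @export
print.genorm_ranking <- function(x, ...) {
  cat("geNorm ranking (most stable first):",
      paste(x$ranking, collapse = " > "), "\n")
  cat("recommended n =", x$recommended_n, "\n")
  invisible(x)
}

#' Per-sample normalization factor
#'
#' Geometric mean of the listed reference genes' quantities, per sample.
#'
#' @param quantities samples x genes matrix (or `rq_table`)
#' @param reference_genes nonempty character vector of gene columns
#' @return named numeric, one factor per sample
#' @export
normalization_factor <- function(quantities, reference_genes) {
  q <- rq_values(quantities)
  if (length(reference_genes) == 0) stop("reference gene list is empty")
  missing <- setdiff(reference_genes, colnames(q))
  if (length(missing))
    stop("reference gene absent: ", paste(missing, collapse = ", "))
  apply(q[, reference_genes, drop = FALSE], 1, geomean)
}

#' Two-stage normalization of Cq data
#'
#' Stage 1 divides relative quantities by the geometric mean of stably
#' expressed endogenous reference genes (technical factor: loading, RT
#' efficiency). Stage 2 divides the result by the geometric mean of the
#' olfactory-epithelium-specific reference genes, computed from the
#' stage-1-normalized quantities (biological factor: the variable fraction
#' of olfactory neurons in patchy mucosa). The NRQ of an OR gene is thus
#' invariant both to global per-sample Cq shifts and to joint shifts of the
#' OR + OE-reference genes.
#'
#' @param cq a [cq_matrix()]
#' @param tech_refs endogenous reference assay ids (default: the three the
#'   geNorm analysis of the original cohort selected)
#' @param bio_refs OE-specific reference assay ids
#' @param calibrator_cq,efficiency,undetermined_substitute passed to
#'   [cq_to_rq()]
#' @param panel optional [assay_panel()] (for `calibrator_cq = "auto"`)
#' @return list of class `nrq_table`: `values` (samples x assays NRQ),
#'   `nf_tech`, `nf_bio` (per-sample factors), `rq` (the underlying
#'   `rq_table`), `tech_refs`, `bio_refs`
#' @export
normalize_two_stage <- function(cq,
                                tech_refs = c("CASC3", "PSMC4", "CDKN1B"),
                                bio_refs = c("CNGA2", "GNAL", "ADCY3",
                                             "RIC8B", "RTP1", "OBP2A_2B"),
                                calibrator_cq = 32.7, efficiency = 2,
                                undetermined_substitute = 40, panel = NULL) {
  rq <- cq_to_rq(cq, calibrator_cq, efficiency, undetermined_substitute, panel)
  nf_tech <- normalization_factor(rq, tech_refs)
  q1 <- rq$values / nf_tech
  nf_bio <- normalization_factor(q1, bio_refs)
  nrq <- q1 / nf_bio
  structure(list(values = nrq, nf_tech = nf_tech, nf_bio = nf_bio, rq = rq,
                 tech_refs = tech_refs, bio_refs = bio_refs,
                 calibrator_cq = rq$calibrator_cq),
            class = "nrq_table")
}
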