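#' Quantification-cycle (Cq) matrix
#'
#' A `cq_matrix` stores a rectangular grid of quantification-cycle values for
#' a set of samples (rows) against a set of assays (columns), together with
#' the run each sample was measured in and a condition tag (`rt_plus`,
#' `rt_minus`, `gdna`, `plasmid`, `whom`, `inferior_turbinate`, ...).
#' Undetermined reactions — wells that never crossed the fluorescence
#' threshold — are held as `NA` and are never silently replaced: the
#' 40-cycle substitution happens only in [cq_to_rq()].
#'
#' @param values numeric matrix, samples x assays, with dimnames; `NA` marks
#'   an undetermined Cq.
#' @param run_id character vector of run labels, one per sample (recycled if
#'   length 1).
#' @param condition character vector of condition tags, one per sample
#'   (recycled if length 1).
#' @param max_cycles maximum plausible cycle number; numeric cells must lie
#'   in (0, max_cycles].
#' @return an object of class `cq_matrix`: a list with elements `values`,
#'   `run_id`, `condition`, `max_cycles`.
#' @export
cq_matrix <- function(values, run_id = "run1", condition = "rt_plus",
                      max_cycles = 40) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("values must carry sample (row) and assay (column) names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("sample and assay names must be unique")
  n <- nrow(values)
  if (length(run_id) == 1) run_id <- rep(run_id, n)
  if (length(condition) == 1) condition <- rep(condition, n)
  if (length(run_id) != n || length(condition) != n)
    stop("run_id and condition must have one entry per sample")
  if (any(!nzchar(run_id))) stop("run_id entries must be non-empty")
  v <- values[!is.na(values)]
  if (any(v <= 0 | v > max_cycles))
    stop("numeric Cq values must lie in (0, ", max_cycles, "]")
  structure(list(values = values,
                 run_id = stats::setNames(as.character(run_id), rownames(values)),
                 condition = stats::setNames(as.character(condition), rownames(values)),
                 max_cycles = max_cycles),
            class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("cq_matrix: %d samples x %d assays, %d undetermined, runs: %s\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              paste(unique(x$run_id), collapse = ", ")))
  invisible(x)
}

#' @export
dim.cq_matrix <- function(x) dim(x$values)

#' Sample and assay identifiers of a cq_matrix
#' @param x a [cq_matrix()]
#' @return character vector
#' @export
cq_samples <- function(x) rownames(x$values)

#' @rdname cq_samples
#' @export
cq_assays <- function(x) colnames(x$values)

#' Subset a cq_matrix by samples and/or assays
#' @param x a [cq_matrix()]
#' @param samples,assays identifiers (or logical/integer indices) to keep
#' @return a [cq_matrix()]
#' @export
cq_subset <- function(x, samples = NULL, assays = NULL) {
  s <- samples %||% rownames(x$values)
  a <- assays %||% colnames(x$values)
  cq_matrix(x$values[s, a, drop = FALSE], x$run_id[s], x$condition[s],
            x$max_cycles)
}

default_undetermined_tokens <- c("Undetermined", "NA", "")

#' Read a Cq table from CSV/TSV
#'
#' Accepts the two layouts instrument exports come in: *long*
#' (`sample_id, assay_id, cq` plus optional `run_id`, `condition`) and *wide*
#' (one row per sample, one column per assay, optional `run_id`/`condition`
#' columns). Tokens in `undetermined_tokens` map to the undetermined
#' sentinel; any other non-numeric cell is a parse error naming the cell.
#'
#' @param path file path.
#' @param format `"auto"`, `"long"` or `"wide"`; auto-detection keys on the
#'   presence of `assay_id` + `cq` columns.
#' @param sep field separator; `NULL` guesses from the file extension
#'   (`.csv` is comma, otherwise tab).
#' @param undetermined_tokens strings mapped to undetermined.
#' @param max_cycles passed to [cq_matrix()].
#' @return a [cq_matrix()] with attribute `dialect` recording the layout,
#'   separator and undetermined tokens used.
#' @export
read_cq_table <- function(path, format = c("auto", "long", "wide"), sep = NULL,
                          undetermined_tokens = default_undetermined_tokens,
                          max_cycles = 40) {
  format <- match.arg(format)
  sep <- sep %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = NULL,
                          quote = "\"", comment.char = "")
  if (!"sample_id" %in% names(df))
    stop("format error: no 'sample_id' column in ", path)
  if (format == "auto")
    format <- if (all(c("assay_id", "cq") %in% names(df))) "long" else "wide"

  parse_cell <- function(txt, where) {
    if (txt %in% undetermined_tokens) return(NA_real_)
    v <- suppressWarnings(as.numeric(txt))
    if (is.na(v))
      stop("parse error: non-numeric Cq '", txt, "' at ", where)
    v
  }

  if (format == "long") {
    if (!all(c("assay_id", "cq") %in% names(df)))
      stop("format error: long layout needs 'assay_id' and 'cq' columns")
    samples <- unique(df$sample_id)
    assays <- unique(df$assay_id)
    m <- matrix(NA_real_, length(samples), length(assays),
                dimnames = list(samples, assays))
    seen <- matrix(FALSE, length(samples), length(assays),
                   dimnames = list(samples, assays))
    for (i in seq_len(nrow(df))) {
      m[df$sample_id[i], df$assay_id[i]] <-
        parse_cell(df$cq[i], paste0("row ", i, " (", df$sample_id[i], ", ",
                                    df$assay_id[i], ")"))
      seen[df$sample_id[i], df$assay_id[i]] <- TRUE
    }
    if (!all(seen))
      stop("format error: long table is not rectangular (missing cells)")
    run_id <- if ("run_id" %in% names(df))
      vapply(samples, function(s) df$run_id[df$sample_id == s][1], "") else "run1"
    condition <- if ("condition" %in% names(df))
      vapply(samples, function(s) df$condition[df$sample_id == s][1], "") else "rt_plus"
    out <- cq_matrix(m, run_id, condition, max_cycles)
  } else {
    meta_cols <- intersect(c("sample_id", "run_id", "condition"), names(df))
    assay_cols <- setdiff(names(df), meta_cols)
    if (length(assay_cols) == 0) stop("format error: wide table has no assay columns")
    if (anyDuplicated(df$sample_id)) stop("format error: duplicated sample_id")
    m <- matrix(NA_real_, nrow(df), length(assay_cols),
                dimnames = list(df$sample_id, assay_cols))
    for (j in seq_along(assay_cols)) for (i in seq_len(nrow(df)))
      m[i, j] <- parse_cell(df[[assay_cols[j]]][i],
                            paste0("row ", i, ", column '", assay_cols[j], "'"))
    out <- cq_matrix(m,
                     if ("run_id" %in% meta_cols) df$run_id else "run1",
                     if ("condition" %in% meta_cols) df$condition else "rt_plus",
                     max_cycles)
  }
  attr(out, "dialect") <- list(format = format, sep = sep,
                               undetermined_tokens = undetermined_tokens)
  out
}

#' Write a cq_matrix to disk (canonical long TSV)
#'
#' Undetermined cells are written as `"Undetermined"`; a write/read
#' round-trip reproduces the object exactly, including run labels and
#' condition tags.
#'
#' @param x a [cq_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cq_table <- function(x, path) {
  samples <- rownames(x$values)
  assays <- colnames(x$values)
  long <- data.frame(
    sample_id = rep(samples, each = length(assays)),
    assay_id = rep(assays, times = length(samples)),
    cq = as.vector(t(x$values)),
    run_id = rep(x$run_id, each = length(assays)),
    condition = rep(x$condition, each = length(assays)),
    stringsAsFactors = FALSE)
  long$cq <- ifelse(is.na(long$cq), "Undetermined", format(long$cq, digits = 15))
  write_tsv_plain(long, path)
}
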