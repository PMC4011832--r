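#' Geometric mean
#'
#' @param x positive numeric vector
#' @param na.rm drop missing values
#' @return exp(mean(log(x)))
#' @export
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0, na.rm = TRUE)) stop("geometric mean requires positive values")
  exp(mean(log(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @keywords internal
read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' @keywords internal
extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "orqprofiler")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}

# log(sum(exp(lx))) without overflow
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}
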