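#' 2x2 contingency table
#'
#' Rows: annotation in/out; columns: expressed/not.
#'
#' @param a,b,c,d nonnegative integer counts (`a` = annotated & expressed)
#' @return matrix of class `contingency_2x2` with margins as attributes
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  m <- matrix(as.integer(counts), 2, 2, byrow = TRUE,
              dimnames = list(c("in", "out"), c("expressed", "not")))
  class(m) <- c("contingency_2x2", class(m))
  m
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric summation with fixed margins. The two-sided p-value
#' uses the minimum-likelihood rule: the sum of point probabilities of all
#' tables no more probable than the observed one.
#'
#' @param table a [contingency_2x2()] or plain 2x2 matrix
#' @param alternative `"two_sided_min_likelihood"` (default), `"greater"`
#'   or `"less"` (tail in the `a` cell)
#' @return list: `p`, `odds_ratio` (sample odds ratio `ad/bc`; 0/0 -> NaN,
#'   x/0 -> Inf), `alternative`
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two_sided_min_likelihood",
                                             "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  m <- a + b            # annotated
  n <- c + d            # not annotated
  k <- a + c            # expressed
  support <- max(0, k - n):min(k, m)
  lp <- stats::dhyper(support, m, n, k, log = TRUE)
  p_obs <- lp[match(a, support)]
  p <- switch(alternative,
    two_sided_min_likelihood = sum(exp(lp[lp <= p_obs + 1e-7])),
    greater = sum(exp(lp[support >= a])),
    less = sum(exp(lp[support <= a])))
  or <- (a * d) / (b * c)
  list(p = min(p, 1), odds_ratio = or, alternative = alternative)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of an overlap at least as large as observed between a set of
#' size `K` and an independent draw of size `n` from a universe of size `N`:
#' inclusive tail `P(X >= x)` under Hypergeometric(N, K, n), summed in log
#' space for stability.
#'
#' @param N universe size
#' @param K size of the first set
#' @param n size of the second set
#' @param x observed overlap
#' @return p-value
#' @export
hypergeom_overlap <- function(N, K, n, x) {
  if (any(c(N, K, n, x) < 0) || K > N || n > N)
    stop("infeasible overlap specification")
  lo <- max(0, n + K - N); hi <- min(K, n)
  if (x < lo || x > hi)
    stop("infeasible overlap x = ", x, " (feasible ", lo, "..", hi, ")")
  i <- x:hi
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(exp(logsumexp(lp)), 1)
}

#' Welch's t-test from summary statistics
#'
#' Two-sample unequal-variance t with Welch–Satterthwaite degrees of
#' freedom and a two-tailed p-value, computed from group means, SDs and
#' sizes only.
#'
#' @param mean1,sd1,n1 first group
#' @param mean2,sd2,n2 second group
#' @return list: `t`, `df`, `p`
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 < 0 || sd2 < 0) stop("sd must be >= 0")
  se2 <- sd1^2 / n1 + sd2^2 / n2
  if (se2 == 0)
    return(list(t = 0, df = n1 + n2 - 2, p = if (mean1 == mean2) 1 else 0))
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Spearman rank correlation
#'
#' Average ranks on ties; two-sided p by exact permutation enumeration for
#' n <= 9, t-approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return list: `rho`, `p`, `method`; a constant vector gives `rho = NA`
#'   with `method = "undefined"`
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need length >= 3")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p = NA_real_, method = "undefined"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, method = method)
}

# all n! permutations of 1..n as a matrix (rows); n kept small by callers
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' Annotation enrichment in the expressed OR set
#'
#' Builds the expressed/not x annotated/not table over unmasked OR assays,
#' tests it with [fisher_exact_2x2()], and optionally compares mean copy
#' numbers between the annotated and unannotated groups with a Welch t-test
#' from group summaries.
#'
#' @param calls a `call_matrix` from [call_expression()] (per-OR overall
#'   calls) or a named logical vector
#' @param panel an [assay_panel()]
#' @param annotation `"deorphanized"` or `"potentially_nonfunctional"`
#' @param copies_mean optional named numeric of per-OR mean copies for the
#'   group comparison
#' @return list: `table` ([contingency_2x2()]), `fisher`, percentages, and
#'   `welch` when `copies_mean` is given
#' @export
annotation_enrichment <- function(calls, panel, annotation,
                                  copies_mean = NULL) {
  if (!annotation %in% names(panel))
    stop("annotation absent from panel: ", annotation)
  overall <- if (inherits(calls, "call_matrix")) calls$overall else calls
  keep <- names(overall)[!is.na(overall)]
  ann <- panel[[annotation]][match(keep, panel$assay_id)]
  if (!any(ann)) stop("annotation has zero members among called assays")
  expressed <- overall[keep]
  # rows: expressed / not expressed; columns: annotated / not annotated
  tab <- contingency_2x2(sum(ann & expressed), sum(!ann & expressed),
                         sum(ann & !expressed), sum(!ann & !expressed))
  dimnames(tab) <- list(c("expressed", "not_expressed"),
                        c("annotated", "not_annotated"))
  out <- list(table = tab, fisher = fisher_exact_2x2(tab),
              pct_annotated_expressed = 100 * tab[1, 1] / sum(tab[1, ]),
              pct_annotated_not = 100 * tab[2, 1] / sum(tab[2, ]))
  if (!is.null(copies_mean)) {
    g1 <- copies_mean[keep][ann]
    g2 <- copies_mean[keep][!ann]
    out$welch <- welch_from_summary(mean(g1), stats::sd(g1), length(g1),
                                    mean(g2), stats::sd(g2), length(g2))
  }
  out
}
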