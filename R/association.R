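# centered, unit-variance columns; zero-variance columns -> all zeros
standardize_cols <- function(E) {
  Ec <- sweep(E, 2, colMeans(E))
  s <- sqrt(colSums(Ec^2) / (nrow(E) - 1))
  zero <- s == 0
  s[zero] <- 1
  Es <- sweep(Ec, 2, s, "/")
  Es[, zero] <- 0
  Es
}

#' Per-gene association scores
#'
#' Continuous covariates score each gene by the Pearson correlation of its
#' (log-scale) expression with the covariate; two-class covariates use a
#' two-sample t-score with pooled variance and an exchangeability constant
#' `s0` added to the denominator (the SAM moderation that keeps
#' low-variance genes from dominating).
#'
#' @param expr samples x genes numeric matrix (log2 copies or log2 NRQ)
#' @param covariate numeric vector (continuous) or a two-level
#'   factor/character/logical (binary), one entry per sample; samples with
#'   `NA` covariate are dropped
#' @param s0 for binary covariates: `"median"` (default, the median of
#'   gene-wise standard errors), another percentile in `[0,1]` given as
#'   `list(quantile = q)`, or an explicit nonnegative number (0 recovers
#'   the plain pooled t)
#' @return named numeric of per-gene scores; attribute `type` is
#'   `"pearson"` or `"t"`, attribute `s0` the constant used
#' @export
gene_scores <- function(expr, covariate, s0 = "median") {
  keep <- !is.na(covariate)
  expr <- expr[keep, , drop = FALSE]
  covariate <- covariate[keep]
  n <- nrow(expr)
  if (length(unique(covariate)) == 1) stop("constant covariate")
  if (is.numeric(covariate) && length(unique(covariate)) > 2) {
    Es <- standardize_cols(expr)
    xs <- (covariate - mean(covariate)) / stats::sd(covariate)
    r <- drop(crossprod(Es, xs)) / (n - 1)
    return(structure(r, type = "pearson", s0 = 0))
  }
  g <- as.factor(covariate)
  if (nlevels(g) != 2) stop("binary covariate must have exactly 2 levels")
  if (min(table(g)) < 3) stop("need >= 3 samples per class")
  grp <- g == levels(g)[2]
  st <- t_score_stats(expr, grp)
  s0v <- resolve_s0(s0, st$se)
  d <- (st$m2 - st$m1) / (st$se + s0v)
  d[st$se + s0v == 0] <- 0
  structure(stats::setNames(d, colnames(expr)), type = "t", s0 = s0v)
}

# group means and pooled-variance standard error per gene (columns)
t_score_stats <- function(E, grp) {
  n1 <- sum(!grp); n2 <- sum(grp)
  m1 <- colMeans(E[!grp, , drop = FALSE])
  m2 <- colMeans(E[grp, , drop = FALSE])
  ss1 <- colSums(E[!grp, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(E[grp, , drop = FALSE]^2) - n2 * m2^2
  vp <- (ss1 + ss2) / (n1 + n2 - 2)
  vp[vp < 0] <- 0
  list(m1 = m1, m2 = m2, se = sqrt(vp * (1 / n1 + 1 / n2)))
}

resolve_s0 <- function(s0, se) {
  if (is.numeric(s0)) {
    if (s0 < 0) stop("s0 must be >= 0")
    return(s0)
  }
  if (identical(s0, "median")) return(stats::median(se))
  if (is.list(s0)) return(unname(stats::quantile(se, s0$quantile)))
  stop("unrecognized s0 specification")
}

# permutation index matrix (n x B); exhaustive when the permutation space
# is at most `limit`, otherwise B seeded draws. For binary covariates the
# space is the set of group assignments, enumerated via combinations.
permutation_indices <- function(covariate, B, seed, limit = 10000) {
  n <- length(covariate)
  binary <- !(is.numeric(covariate) && length(unique(covariate)) > 2)
  if (binary) {
    g <- as.factor(covariate)
    n2 <- sum(g == levels(g)[2])
    if (choose(n, n2) <= limit) {
      combos <- utils::combn(n, n2)
      # index permutations realizing every distinct group assignment
      lev2 <- which(g == levels(g)[2]); lev1 <- which(g != levels(g)[2])
      perms <- apply(combos, 2, function(pos) {
        out <- integer(n)
        out[pos] <- lev2[seq_along(pos)]
        out[-pos] <- lev1[seq_len(n - length(pos))]
        out
      })
      return(list(idx = perms, exhaustive = TRUE))
    }
  } else if (n <= 7 && factorial(n) <= limit) {
    return(list(idx = t(all_permutations(n)), exhaustive = TRUE))
  }
  set.seed(seed)
  list(idx = vapply(seq_len(B), function(b) sample.int(n), integer(n)),
       exhaustive = FALSE)
}

# per-permutation scores, one column per permutation, same s0 as observed
permuted_scores <- function(expr, covariate, idx, type, s0v) {
  n <- nrow(expr)
  if (type == "pearson") {
    Es <- standardize_cols(expr)
    xs <- (covariate - mean(covariate)) / stats::sd(covariate)
    X <- matrix(xs[idx], n, ncol(idx))
    crossprod(Es, X) / (n - 1)
  } else {
    g <- as.factor(covariate)
    grp <- g == levels(g)[2]
    n2 <- sum(grp); n1 <- n - n2
    G <- matrix(grp[idx], n, ncol(idx)) * 1
    S1 <- crossprod(expr, 1 - G)      # genes x B group sums
    S2 <- crossprod(expr, G)
    Q1 <- crossprod(expr^2, 1 - G)
    Q2 <- crossprod(expr^2, G)
    M1 <- S1 / n1; M2 <- S2 / n2
    vp <- (Q1 - n1 * M1^2 + Q2 - n2 * M2^2) / (n1 + n2 - 2)
    vp[vp < 0] <- 0
    se <- sqrt(vp * (1 / n1 + 1 / n2))
    d <- (M2 - M1) / (se + s0v)
    d[se + s0v == 0] <- 0
    d
  }
}

#' SAM-style permutation FDR
#'
#' Observed per-gene d-statistics (Pearson r for continuous covariates,
#' moderated t for binary ones) are compared to a null built by permuting
#' the covariate labels. The q-value of a gene is the median, across
#' permutations, of the number of null scores at least as extreme as its
#' own |d|, divided by the number of genes observed at least that extreme —
#' capped at 1 and made monotone non-decreasing as |d| decreases. The
#' permutation space is enumerated exhaustively when it has at most 10,000
#' elements; otherwise `B` seeded draws are used.
#'
#' @param expr samples x genes matrix (log scale)
#' @param covariate per-sample covariate; `NA` samples are dropped
#' @param B number of sampled permutations (>= 100)
#' @param seed integer seed for the permutation stream
#' @param q_threshold significance cut (default 0.05)
#' @param s0 moderation constant, see [gene_scores()]
#' @return list of class `association_result`: `table` (gene, score, d, q,
#'   direction), `significant_up` / `significant_down`, `B`,
#'   `exhaustive`, `seed`
#' @export
sam_fdr <- function(expr, covariate, B = 1000, seed = 1, q_threshold = 0.05,
                    s0 = "median") {
  if (B < 100) stop("B must be >= 100 (FDR unstable below)")
  keep <- !is.na(covariate)
  expr <- expr[keep, , drop = FALSE]
  covariate <- covariate[keep]
  d_obs <- gene_scores(expr, covariate, s0)
  type <- attr(d_obs, "type"); s0v <- attr(d_obs, "s0")
  pm <- permutation_indices(covariate, B, seed)
  dperm <- permuted_scores(expr, covariate, pm$idx, type, s0v)
  nperm <- ncol(dperm)

  abs_obs <- abs(d_obs)
  ord <- order(abs_obs, decreasing = TRUE)
  thresholds <- abs_obs[ord]
  G <- length(d_obs)
  rank_count <- vapply(thresholds, function(th) sum(abs_obs >= th - 1e-12), 0L)
  # exceedance counts per permutation at each gene's threshold
  counts <- matrix(0, G, nperm)
  for (b in seq_len(nperm)) {
    sorted <- sort(abs(dperm[, b]))
    counts[, b] <- G - findInterval(thresholds - 1e-12, sorted)
  }
  q_raw <- pmin(apply(counts, 1, stats::median) / rank_count, 1)
  q_mono <- rev(cummin(rev(q_raw)))   # non-decreasing as |d| decreases
  q <- numeric(G)
  q[ord] <- q_mono

  tab <- data.frame(gene = names(d_obs), score = unname(d_obs),
                    d = unname(d_obs), q = q,
                    direction = ifelse(d_obs > 0, "up",
                                       ifelse(d_obs < 0, "down", "none")),
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 significant_up = tab$gene[tab$q < q_threshold & tab$d > 0],
                 significant_down = tab$gene[tab$q < q_threshold & tab$d < 0],
                 B = nperm, exhaustive = pm$exhaustive, seed = seed,
                 s0 = s0v, type = type, q_threshold = q_threshold),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("SAM-style association (%s scores, %s%d permutations): %d up, %d down at q < %g\n",
              x$type, if (x$exhaustive) "exhaustive " else "", x$B,
              length(x$significant_up), length(x$significant_down),
              x$q_threshold))
  invisible(x)
}

#' Global permutation test of repertoire-wide association
#'
#' The observed statistic is the sum of squared per-gene association scores
#' (Pearson r or t); its null distribution comes from permuting the
#' patient labels. With an exhaustive permutation space the p-value is the
#' exact fraction of permutations reaching the observed statistic;
#' otherwise the add-one convention `p = (1 + #{T* >= T}) / (B + 1)` keeps
#' it in `[1/(B+1), 1]`.
#'
#' @inheritParams sam_fdr
#' @param B number of sampled permutations (default 10000)
#' @return list of class `global_test_result`: `T_obs`, `p`, `B`,
#'   `exhaustive`, `seed`
#' @export
global_association <- function(expr, covariate, B = 10000, seed = 1,
                               s0 = "median") {
  keep <- !is.na(covariate)
  expr <- expr[keep, , drop = FALSE]
  covariate <- covariate[keep]
  d_obs <- gene_scores(expr, covariate, s0)
  type <- attr(d_obs, "type"); s0v <- attr(d_obs, "s0")
  T_obs <- sum(d_obs^2)
  pm <- permutation_indices(covariate, B, seed)
  dperm <- permuted_scores(expr, covariate, pm$idx, type, s0v)
  T_perm <- colSums(dperm^2)
  p <- if (pm$exhaustive) mean(T_perm >= T_obs - 1e-12)
       else (1 + sum(T_perm >= T_obs - 1e-12)) / (ncol(dperm) + 1)
  structure(list(T_obs = T_obs, p = p, B = ncol(dperm),
                 exhaustive = pm$exhaustive, seed = seed, type = type),
            class = "global_test_result")
}

#' Binary smoking contrast
#'
#' Encodes smoking status as current vs never; past and unknown become
#' `NA` and are excluded from the smoking analysis.
#'
#' @param smoking character vector with levels never/past/current/unknown
#' @return factor with levels `never`, `current` (and `NA` elsewhere)
#' @export
encode_smoking <- function(smoking) {
  out <- ifelse(smoking %in% c("never", "current"), smoking, NA)
  factor(out, levels = c("never", "current"))
}

#' Log-scale expression for association testing
#'
#' @param copies a `copy_table` or samples x genes copies matrix
#' @param pseudo pseudo-count guarding zeros (default 0.5)
#' @return samples x genes matrix of `log2(copies + pseudo)`
#' @export
log_expression <- function(copies, pseudo = 0.5) {
  v <- if (inherits(copies, "copy_table")) copies$values else copies
  log2(v + pseudo)
}
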