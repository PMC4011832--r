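# Independent oracles and tiny fixture builders used across the suite.
# Oracles are deliberately naive (explicit loops, full enumeration) and
# share no code with the implementation they check.

# geNorm M and V by direct evaluation of the definitions
brute_genorm_M <- function(q) {
  genes <- colnames(q)
  sapply(genes, function(j) {
    vs <- c()
    for (k in setdiff(genes, j))
      vs <- c(vs, sd(log2(q[, j] / q[, k])))
    mean(vs)
  })
}

brute_genorm_V <- function(q, ranking) {
  K <- ncol(q)
  out <- c()
  for (n in 2:(K - 1)) {
    nf_n <- apply(q[, ranking[1:n], drop = FALSE], 1,
                  function(x) prod(x)^(1 / n))
    nf_n1 <- apply(q[, ranking[1:(n + 1)], drop = FALSE], 1,
                   function(x) prod(x)^(1 / (n + 1)))
    out <- c(out, sd(log2(nf_n / nf_n1)))
  }
  out
}

# Fisher two-sided (minimum-likelihood rule) by full enumeration of all
# tables with the observed margins
brute_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- sapply(support, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1))
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by direct summation of binomial coefficients
brute_hyper_upper <- function(N, K, n, x) {
  xs <- x:min(K, n)
  sum(sapply(xs, function(i) choose(K, i) * choose(N - K, n - i))) / choose(N, n)
}

# small mixed panel for fast synthetic tests
mk_small_panel <- function(n_or = 10) {
  endo <- c("CASC3", "PSMC4", "CDKN1B", "UBC")
  oe <- c("ADCY3", "CNGA2")
  ors <- sprintf("OR%dT1", seq_len(n_or))
  assay_panel(data.frame(
    assay_id = c(endo, oe, ors),
    gene_symbol = c(endo, oe, ors),
    role = c(rep("endogenous_ref", length(endo)), rep("oe_ref", length(oe)),
             rep("or_target", n_or)),
    or_class = c(rep("not_applicable", length(endo) + length(oe)),
                 rep("class_II", n_or)),
    stringsAsFactors = FALSE))
}

# generator config with small reference lists matching mk_small_panel
mk_small_config <- function(...) {
  args <- list(
    endogenous_ref_params = list(CASC3 = c(20.4, 0.6), PSMC4 = c(21.5, 0.7),
                                 CDKN1B = c(20.0, 0.6), UBC = c(17.1, 0.7)),
    oe_ref_params = list(ADCY3 = c(21.3, 0.8), CNGA2 = c(28.7, 1.0)),
    undetermined_rate_params = c(2, 1))
  args <- utils::modifyList(args, list(...))
  do.call(generator_config, args)
}

# sample one integer from lo..hi (sample(lo:hi, 1) misbehaves when lo == hi)
sample_int <- function(lo, hi) if (lo == hi) lo else sample(lo:hi, 1)

# cq_matrix from a plain matrix with default metadata
mk_cq <- function(m, ...) cq_matrix(m, ...)
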