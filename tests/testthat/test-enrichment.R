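test_that("Fisher exact reproduces the printed enrichment p-values", {
  # deorphanized x expressed margins reconstructed from the printed counts
  deor <- fisher_exact_2x2(contingency_2x2(43, 230, 4, 78))
  expect_equal(round(deor$p, 3), 0.009)
  expect_equal(deor$p, 0.009008204, tolerance = 1e-6)
  # potentially non-functional split
  nf <- fisher_exact_2x2(contingency_2x2(31, 242, 21, 61))
  expect_equal(round(nf$p, 3), 0.002)

  # degenerate margin
  expect_equal(fisher_exact_2x2(contingency_2x2(0, 10, 0, 10))$p, 1)
  # tiny table against full enumeration
  expect_equal(fisher_exact_2x2(contingency_2x2(2, 1, 1, 2))$p,
               brute_fisher_two_sided(2, 1, 1, 2), tolerance = 1e-12)
  expect_error(contingency_2x2(-1, 1, 1, 1), "nonnegative")
})

test_that("Fisher matches enumeration and transposition on random tables", {
  set.seed(31)
  for (rep in 1:40) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    p <- fisher_exact_2x2(contingency_2x2(a, b, c, d))$p
    expect_equal(p, brute_fisher_two_sided(a, b, c, d), tolerance = 1e-10)
    # transposing leaves p unchanged
    expect_equal(fisher_exact_2x2(contingency_2x2(a, c, b, d))$p, p,
                 tolerance = 1e-10)
    # one-sided tails against the stats oracle
    expect_equal(fisher_exact_2x2(contingency_2x2(a, b, c, d), "greater")$p,
                 fisher.test(matrix(c(a, c, b, d), 2), alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("hypergeometric overlap reproduces the printed study comparison", {
  expect_equal(hypergeom_overlap(261, 174, 202, 145), 0.0012, tolerance = 0.05)
  expect_equal(hypergeom_overlap(261, 174, 202, 145), 0.00120929,
               tolerance = 1e-6)
  expect_equal(hypergeom_overlap(10, 5, 4, 3), 55 / 210, tolerance = 1e-12)
  # minimum feasible overlap -> certain event
  expect_equal(hypergeom_overlap(20, 15, 10, 5), 1)
  expect_equal(hypergeom_overlap(10, 10, 7, 7), 1)
  expect_error(hypergeom_overlap(10, 5, 4, 5), "infeasible")
})

test_that("hypergeometric matches enumeration on random specifications", {
  set.seed(17)
  for (rep in 1:30) {
    N <- sample(5:30, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    lo <- max(0, n + K - N); hi <- min(K, n)
    x <- sample_int(lo, hi)
    expect_equal(hypergeom_overlap(N, K, n, x), brute_hyper_upper(N, K, n, x),
                 tolerance = 1e-10)
  }
})

test_that("Welch from summaries reproduces the copy-number comparison", {
  w <- welch_from_summary(174, 247, 47, 48, 115, 52)
  expect_equal(round(w$p, 3), 0.002)
  expect_equal(w$t, 3.197938, tolerance = 1e-6)
  expect_equal(w$df, 63.58947, tolerance = 1e-5)

  same <- welch_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(welch_from_summary(3, 0, 5, 3, 0, 5)$p, 1)

  # equal variances and sizes reduce to the pooled t
  pooled <- t.test(extra ~ group, data = sleep, var.equal = TRUE)
  g1 <- sleep$extra[sleep$group == 1]; g2 <- sleep$extra[sleep$group == 2]
  s <- sqrt((var(g1) + var(g2)) / 2)
  w2 <- welch_from_summary(mean(g1), s, 10, mean(g2), s, 10)
  expect_equal(w2$p, pooled$p.value, tolerance = 1e-6)
})

test_that("Spearman handles ties, perfect orders and exact enumeration", {
  x <- 1:6
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  # identity and full reversal both reach |rho| = 1 under enumeration
  expect_equal(spearman_cor(x, x)$p, 2 / factorial(6), tolerance = 1e-12)

  # 5-point toy with one tie against the brute-force rank formula
  xt <- c(1, 2, 3, 4, 5); yt <- c(2, 2, 1, 5, 4)
  got <- spearman_cor(xt, yt)
  expect_equal(got$rho, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_equal(got$method, "exact")
  expect_equal(spearman_cor(c(1, 1, 1), c(1, 2, 3))$method, "undefined")

  # t-approximation path agrees with cor.test for larger n
  set.seed(2)
  xl <- rnorm(30); yl <- xl + rnorm(30)
  ct <- cor.test(xl, yl, method = "spearman")
  got2 <- spearman_cor(xl, yl)
  expect_equal(got2$rho, unname(ct$estimate), tolerance = 1e-12)
})

test_that("annotation enrichment reconstructs the published tables", {
  p <- default_panel()
  ors <- setdiff(p$assay_id[p$role == "or_target"], "OR2A14")
  deor <- p$deorphanized[match(ors, p$assay_id)]
  nonf <- p$potentially_nonfunctional[match(ors, p$assay_id)]

  # expressed set hitting both printed margins: 43/4 deorphanized,
  # 31/21 non-functional, 273 expressed of 355
  expressed <- setNames(logical(355), ors)
  expressed[which(deor)[1:43]] <- TRUE
  expressed[which(nonf)[1:31]] <- TRUE
  expressed[which(!deor & !nonf)[1:199]] <- TRUE
  expect_equal(sum(expressed), 273L)

  ed <- annotation_enrichment(expressed, p, "deorphanized")
  expect_equal(unname(unclass(ed$table)), matrix(c(43, 4, 230, 78), 2))
  expect_equal(round(ed$fisher$p, 3), 0.009)
  expect_equal(round(ed$pct_annotated_expressed), 16)    # 43/273
  expect_equal(round(ed$pct_annotated_not, 1), 4.9)      # 4/82

  en <- annotation_enrichment(expressed, p, "potentially_nonfunctional")
  expect_equal(unname(unclass(en$table)), matrix(c(31, 21, 242, 61), 2))
  expect_equal(round(en$fisher$p, 3), 0.002)
  expect_equal(round(en$pct_annotated_expressed, 1), 11.4)  # 31/273
  expect_equal(round(en$pct_annotated_not, 1), 25.6)        # 21/82

  # copy-number group comparison wiring
  cm <- setNames(ifelse(deor, 174, 48), ors)
  ed2 <- annotation_enrichment(expressed, p, "deorphanized", copies_mean = cm)
  expect_true(!is.null(ed2$welch))

  expect_error(annotation_enrichment(expressed, p, "no_such_flag"), "absent")
  pz <- p; pz$deorphanized <- FALSE
  expect_error(annotation_enrichment(expressed, pz, "deorphanized"),
               "zero members")
})
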