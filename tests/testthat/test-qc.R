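mk_rt <- function(vals) {
  nm <- if (length(vals)) paste0("A", seq_along(vals)) else character(0)
  cq_matrix(matrix(vals, 1, length(vals), dimnames = list("RT1", nm)),
            condition = "rt_minus")
}

test_that("RT-minus contamination summary matches hand computations", {
  all_un <- mk_rt(rep(NA_real_, 10))
  r <- assess_rt_minus(all_un)$per_sample
  expect_equal(r$fraction_clean, 1)
  expect_true(is.na(r$mean_detected_cq))

  one_det <- mk_rt(c(rep(NA_real_, 9), 34.1))
  r2 <- assess_rt_minus(one_det)$per_sample
  expect_equal(r2$fraction_clean, 0.9)
  expect_equal(r2$mean_detected_cq, 34.1)
  expect_equal(r2$verdict, "clean")

  hand <- mk_rt(c(30, 36, NA, 34))
  r3 <- assess_rt_minus(hand)$per_sample
  expect_equal(r3$fraction_clean, 0.5)
  expect_equal(r3$mean_detected_cq, 32.0)
  expect_equal(r3$verdict, "contaminated")
  # clean + detected fractions always partition the assays
  expect_equal(r3$fraction_clean + r3$n_detected / 4, 1)

  expect_error(assess_rt_minus(mk_rt(numeric(0))), "empty")
})

test_that("RT-minus summary is invariant under assay permutation", {
  set.seed(1)
  v <- c(rnorm(5, 34, 1), rep(NA, 12), 36, 37)
  a <- assess_rt_minus(mk_rt(v))$per_sample
  b <- assess_rt_minus(mk_rt(sample(v)))$per_sample
  expect_equal(a[-1], b[-1])
})

gdna_panel <- default_panel()

test_that("gDNA screen flags the anomalous assay and tolerates detected _m", {
  cfg <- generator_config()
  card <- generate_gdna_card(cfg, seed = 4, panel = gdna_panel,
                             anomaly = list(assay_id = "OR2A14", cq = 12.4))
  # plant a detected intron-spanning reference (PPIA at 27, as seen on RNA-free DNA)
  card$values[1, "PPIA"] <- 27
  scr <- screen_gdna_assays(card, gdna_panel)
  rep <- scr$report
  expect_equal(rep$status[rep$assay_id == "OR2A14"], "anomalous_low")
  expect_true("OR2A14" %in% scr$excluded)
  expect_equal(rep$status[rep$assay_id == "PPIA"], "unexpected_detected")
  expect_false("PPIA" %in% scr$excluded)
  expect_equal(rep$status[rep$assay_id == "CASC3"], "expected_undetermined_ok")
  expect_lt(abs(scr$center - 24.5), 0.3)
})

test_that("gDNA screen statuses are invariant to a constant Cq shift", {
  card <- generate_gdna_card(generator_config(), seed = 4, panel = gdna_panel,
                             anomaly = list(assay_id = "OR2A14", cq = 12.4))
  a <- screen_gdna_assays(card, gdna_panel)
  shifted <- card
  shifted$values <- card$values + 3
  b <- screen_gdna_assays(shifted, gdna_panel)
  expect_equal(a$report$status, b$report$status)
  expect_equal(b$center, a$center + 3)
})

test_that("plasmid specificity classes follow the stated deltas", {
  p <- gdna_panel
  ors <- p$assay_id[p$role == "or_target"]
  v <- rep(NA_real_, nrow(p))
  names(v) <- p$assay_id
  members <- ors[1:3]
  v[members] <- 25.4
  v[ors[4]] <- 32.5   # negligible cross-reaction, delta ~ 7
  v[ors[5]] <- 25.0   # indistinguishable close paralog
  card <- cq_matrix(matrix(v, 1, dimnames = list("pl", names(v))),
                    condition = "plasmid")
  sp <- assess_plasmid_specificity(card, members)
  rep <- sp$report
  expect_equal(rep$class[rep$assay_id == ors[4]], "negligible_cross")
  expect_equal(rep$delta_cq[rep$assay_id == ors[4]], 7.1)
  expect_equal(rep$class[rep$assay_id == ors[5]], "indistinguishable")
  expect_equal(rep$class[rep$assay_id == ors[6]], "silent")
  expect_true(all(rep$class[rep$assay_id %in% members] == "specific"))
  # member dropping out of the pool triggers a warning, not an error
  v2 <- v; v2[members[1]] <- NA
  card2 <- cq_matrix(matrix(v2, 1, dimnames = list("pl", names(v2))),
                     condition = "plasmid")
  expect_warning(assess_plasmid_specificity(card2, members), "undetermined")
})

test_that("inter-run calibration recovers exact shifts and identity", {
  set.seed(2)
  assays <- paste0("G", 1:40)
  base <- runif(40, 20, 34)
  m <- rbind(CAL_r1 = base, CAL_r2 = base)
  colnames(m) <- assays
  runs <- cq_matrix(m, run_id = c("r1", "r2"))
  ir <- interrun_calibrate(runs, "CAL")
  expect_equal(ir$pairs$slope, 1, tolerance = 1e-12)
  expect_equal(ir$pairs$intercept, 0, tolerance = 1e-10)
  expect_equal(ir$pairs$r_squared, 1)
  expect_equal(unname(ir$offsets), c(0, 0))

  m2 <- rbind(CAL_r1 = base, CAL_r2 = base + 0.5)
  colnames(m2) <- assays
  ir2 <- interrun_calibrate(cq_matrix(m2, run_id = c("r1", "r2")), "CAL")
  expect_equal(unname(ir2$offsets["r2"]), 0.5)
  expect_equal(ir2$pairs$r_squared, 1)

  # applying offsets recenters the shared-sample paired difference to zero
  corrected <- apply_run_offsets(cq_matrix(m2, run_id = c("r1", "r2")),
                                 ir2$offsets)
  expect_equal(mean(corrected$values[2, ] - corrected$values[1, ]), 0,
               tolerance = 1e-12)
  expect_error(interrun_calibrate(cq_matrix(
    matrix(c(36, 37, 36.5, 37.5), 2, 2,
           dimnames = list(c("CAL_a", "CAL_b"), c("G1", "G2"))),
    run_id = c("r1", "r2")), "CAL"), "fewer than 3")
})

test_that("OR genes show lower inter-run reproducibility than references", {
  p <- gdna_panel
  set.seed(3)
  base <- numeric(nrow(p))
  base[p$role != "or_target"] <- runif(sum(p$role != "or_target"), 17, 30)
  base[p$role == "or_target"] <- runif(sum(p$role == "or_target"), 26, 34)
  runA <- base + rnorm(nrow(p), 0, ifelse(p$role == "or_target", 0.8, 0.1))
  runB <- base + rnorm(nrow(p), 0, ifelse(p$role == "or_target", 0.8, 0.1))
  m <- rbind(CAL_r1 = runA, CAL_r2 = runB)
  colnames(m) <- p$assay_id
  ir <- interrun_calibrate(cq_matrix(m, run_id = c("r1", "r2")), "CAL",
                           panel = p)
  expect_lt(ir$pairs$r_squared_or, ir$pairs$r_squared_endogenous)
  expect_lt(ir$pairs$r_squared_or, ir$pairs$r_squared_oe_ref)
})
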