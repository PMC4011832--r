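small_panel <- mk_small_panel()

test_that("identical (config, seed) gives identical output; seeds differ", {
  cfg <- mk_small_config()
  a <- generate_cohort(cfg, seed = 11, panel = small_panel)
  b <- generate_cohort(cfg, seed = 11, panel = small_panel)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 12, panel = small_panel)
  expect_false(identical(a$cq$values, c$cq$values))
  expect_error(generate_cohort(generator_config(n_samples = 1), seed = 1),
               "n_samples")
})

test_that("degenerate noise gives Cq equal to baselines exactly", {
  cfg <- generator_config(
    n_samples = 4,
    endogenous_ref_params = list(CASC3 = c(20.4, 0), PSMC4 = c(21.5, 0),
                                 CDKN1B = c(20.0, 0), UBC = c(17.1, 0)),
    oe_ref_params = list(ADCY3 = c(21.3, 0), CNGA2 = c(28.7, 0)),
    undetermined_rate_params = c(0, 0),
    neuron_fraction_sd = 0, technical_loading_sd = 0, or_noise_sd = 0)
  out <- generate_cohort(cfg, seed = 5, panel = small_panel)
  for (s in 1:4)
    expect_equal(unname(out$cq$values[s, ]), unname(out$truth$baseline))
})

test_that("default cohort reproduces the stated UBC mean Cq", {
  out <- generate_cohort(generator_config(), seed = 42)
  ubc <- out$cq$values[, "UBC"]
  expect_lt(abs(mean(ubc) - 17.1), 3 * 0.7 / sqrt(26))
})

test_that("undetermined counts per sample track the stated 62±29", {
  counts <- unlist(lapply(1:8, function(s) {
    out <- generate_cohort(generator_config(), seed = 100 + s)
    rowSums(is.na(out$cq$values))
  }))
  # dropout targets 62 plus the over-40-cycle overflow; allow generous play
  expect_gt(mean(counts), 40)
  expect_lt(mean(counts), 100)
  expect_gt(sd(counts), 15)
})

test_that("a planted age slope yields positive Cq-age correlation", {
  hits <- vapply(1:100, function(s) {
    cfg <- mk_small_config(age_effect_genes = c(OR1T1 = 0.05))
    out <- generate_cohort(cfg, seed = s, panel = small_panel)
    cq <- out$cq$values[, "OR1T1"]
    ok <- !is.na(cq)
    cor(cq[ok], out$samples$age[ok]) > 0
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("latent-factor structure matches the two-stage normalization model", {
  cfg <- mk_small_config(n_samples = 200)
  out <- generate_cohort(cfg, seed = 7, panel = small_panel)
  tech <- out$truth$sample_factors$technical_loading
  neuron <- out$truth$sample_factors$neuron_shift
  # endogenous references load on the technical factor with slope ~ 1
  slope_endo <- coef(lm(out$cq$values[, "CASC3"] ~ tech))[2]
  expect_lt(abs(slope_endo - 1), 0.2)
  # OE references load on technical + neuron with slope ~ 1 on each
  fit_oe <- coef(lm(out$cq$values[, "ADCY3"] ~ tech + neuron))
  expect_lt(abs(fit_oe[2] - 1), 0.2)
  expect_lt(abs(fit_oe[3] - 1), 0.2)
})

test_that("after two-stage normalization null OR NRQ is decoupled from latents", {
  # six OE references, as on the real card: averaging them keeps the
  # biological factor's own noise from leaking into the normalized values
  oe6 <- c("ADCY3", "GNAL", "RIC8B", "RTP1", "CNGA2", "OBP2A_2B")
  endo <- c("CASC3", "PSMC4", "CDKN1B")
  ors <- sprintf("OR%dT1", 1:5)
  panel6 <- assay_panel(data.frame(
    assay_id = c(endo, oe6, ors), gene_symbol = c(endo, oe6, ors),
    role = c(rep("endogenous_ref", 3), rep("oe_ref", 6),
             rep("or_target", 5)),
    or_class = c(rep("not_applicable", 9), rep("class_II", 5))))
  cfg <- generator_config(
    endogenous_ref_params = list(CASC3 = c(20.4, 0.6), PSMC4 = c(21.5, 0.7),
                                 CDKN1B = c(20.0, 0.6)),
    n_samples = 200, undetermined_rate_params = c(0, 0),
    or_cq_range = c(26, 32))  # keep cells determined
  out <- generate_cohort(cfg, seed = 8, panel = panel6)
  norm <- normalize_two_stage(out$cq, tech_refs = endo, bio_refs = oe6)
  lnrq <- log2(norm$values[, "OR5T1"])
  expect_lt(abs(cor(lnrq, out$truth$sample_factors$technical_loading)), 0.1)
  expect_lt(abs(cor(lnrq, out$truth$sample_factors$neuron_shift)), 0.1)
})

test_that("gDNA card: intron-spanning undetermined, anomaly planted, sd=0 exact", {
  p <- default_panel()
  card <- generate_gdna_card(generator_config(), seed = 3, panel = p,
                             anomaly = list(assay_id = "OR2A14", cq = 12.4))
  isp <- p$intron_spanning
  expect_true(all(is.na(card$values[1, isp])))
  expect_equal(card$values[1, "OR2A14"], 12.4)

  card0 <- generate_gdna_card(generator_config(gdna_cq_params = c(24.5, 0)),
                              seed = 3, panel = p)
  expect_true(all(card0$values[1, !isp] == 24.5))
})

test_that("plasmid card: members, cross-reactors and silence behave as stated", {
  p <- default_panel()
  ors <- p$assay_id[p$role == "or_target"]
  members <- ors[1:30]
  cfg0 <- generator_config(plasmid_specific_params = c(25.4, 0))
  card <- generate_plasmid_card(members, cfg0, seed = 2, panel = p)
  expect_equal(sum(!is.na(card$values)), 30L)
  expect_true(all(card$values[1, members] == 25.4))

  cm <- list(negligible = ors[31:41], indistinguishable = ors[42:45])
  card2 <- generate_plasmid_card(members, generator_config(), seed = 2,
                                 panel = p, cross_map = cm)
  expect_true(all(!is.na(card2$values[1, cm$indistinguishable])))
  # negligible cross-reactors sit ~7 cycles above the specific mean
  delta <- mean(card2$values[1, cm$negligible]) -
    mean(card2$values[1, members])
  expect_lt(abs(delta - 7.1), 2)
  expect_error(generate_plasmid_card("NOT_AN_ASSAY", panel = p),
               "not in panel")
})

test_that("RT-minus detection rate follows its configuration", {
  p <- default_panel()
  all_na <- generate_rt_minus(generator_config(rtminus_detect_rate = 0),
                              seed = 1, panel = p)
  expect_true(all(is.na(all_na$values)))
  all_det <- generate_rt_minus(
    generator_config(rtminus_detect_rate = 1, rtminus_cq_params = c(34.1, 0)),
    seed = 1, panel = p)
  expect_true(all(all_det$values == 34.1))
  # default 10% within binomial 99% bounds on the 373-assay panel
  rt <- generate_rt_minus(generator_config(), seed = 9, panel = p)
  frac <- mean(!is.na(rt$values))
  expect_lt(abs(frac - 0.10), 2.58 * sqrt(0.1 * 0.9 / 373))
})
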