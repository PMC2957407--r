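test_that("cohort composition, determinism and invalid requests", {
  co <- make_cohort(22, 7, 9, 6, seed = 1)
  expect_equal(nrow(co), 22)
  expect_equal(sum(co$egfr == "mutant"), 7)
  expect_equal(sum(co$ras != "wt"), 9)
  expect_equal(sum(co$met_activation == "positive"), 6)
  expect_false(anyDuplicated(co$line_id) > 0)
  expect_true(all(co$true_ic50 > 0))
  expect_identical(co, make_cohort(22, 7, 9, 6, seed = 1))
  expect_false(identical(co$true_ic50,
                         make_cohort(22, 7, 9, 6, seed = 2)$true_ic50))
  expect_error(make_cohort(3, 2, 2, 0, seed = 1), "invalid composition")
  co2 <- make_cohort(3, 2, 2, 0, seed = 1, allow_cooccur = TRUE)
  expect_equal(sum(co2$ras != "wt"), 2)
})

test_that("genotype-driven IC50 distributions point the right way", {
  co <- make_cohort(22, 7, 9, 6, seed = 3)
  expect_lt(median(co$true_ic50[co$egfr == "mutant"]),
            median(co$true_ic50[co$ras != "wt"]))
})

test_that("rosette signal recovers injected effects exactly when noiseless", {
  fx <- fixture_rosette_exact()
  av <- average_replicates(fx$rosette)
  m <- binding_as_matrix(av[, names(av) != "pos_control" &
                              names(av) != "neg_control"])
  co <- fx$cohort
  # compare lines free of confounding labels (MET-negative throughout)
  mut <- co$line_id[co$egfr == "mutant" & co$met_activation == "negative"]
  wt <- co$line_id[co$egfr == "wt" & co$ras == "wt" &
                     co$met_activation == "negative"]
  ras <- co$line_id[co$ras != "wt" & co$met_activation == "negative"]
  # Grb2 effect +2 log2 for EGFR mutants -> ratio exactly 4 vs plain wt
  expect_equal(unname(m["Grb2", mut[1]] / m["Grb2", wt[1]]), 4)
  # a probe carrying only the global RAS effect: flat across plain wt lines,
  # depressed exactly 2-fold in RAS mutants
  eff <- fx$truth$effects
  probe0 <- setdiff(
    eff$probe[eff$label == "ras_mutant"],
    eff$probe[eff$label %in% c("egfr_mutant", "met_positive")]
  )[1]
  expect_true(diff(range(m[probe0, wt])) == 0)
  expect_equal(unname(m[probe0, wt[1]] / m[probe0, ras[1]]), 2)
})

test_that("control columns bracket the samples for pTyr-dependent probes", {
  panel <- fixture_panel()
  co <- fixture_cohort()
  truth <- binding_truth(panel)
  ro <- simulate_rosette(panel, co, truth, seed = 11)
  av <- average_replicates(ro)
  m <- binding_as_matrix(av)
  dep <- setdiff(
    panel$probe[!panel$probe_class %in% c("GST_control", "actin_antibody")],
    truth$low_signal
  )
  samples <- co$line_id
  # positive control dominates every sample in expectation (log-mean gap
  # >= positive_boost); allow a small noise margin on realised means
  expect_true(all(m[dep, "pos_control"] >=
                    apply(m[dep, samples], 1, max) * 0.8))
  # negative control sits at background
  expect_lt(median(m[dep, "neg_control"]),
            median(m[dep, samples]) / 8)
})

test_that("replicate CV matches the log-normal closed form", {
  panel <- fixture_panel()
  co <- fixture_cohort()
  sd_log2 <- 0.3
  truth <- binding_truth(panel, noise_sd = sd_log2, line_sd = 0)
  ro <- simulate_rosette(panel, co, truth, n_replicates = 4, seed = 7)
  qc <- qc_replicates(ro)
  # CV of a log-normal with log2-sd s: sqrt(exp(ln(2)^2 s^2) - 1)
  cv_expected <- sqrt(exp(log(2)^2 * sd_log2^2) - 1)
  got <- mean(qc$line_cv$mean_cv)
  expect_gt(got, cv_expected * 0.7)
  expect_lt(got, cv_expected * 1.3)
})

test_that("seeded lanes are reproducible and flat without bands", {
  panel <- fixture_panel()
  co <- make_cohort(4, 1, 1, 1, seed = 2)
  truth <- binding_truth(panel)
  l1 <- simulate_lanes(panel, co, truth, probes = "Grb2", seed = 9)
  l2 <- simulate_lanes(panel, co, truth, probes = "Grb2", seed = 9)
  expect_identical(l1$profiles, l2$profiles)
  # zero bands and zero baseline noise -> flat zero profile
  truth0 <- binding_truth(panel)
  truth0$bands <- truth0$bands[0, ]
  l0 <- simulate_lanes(panel, co, truth0, probes = "Grb2", seed = 9,
                       baseline_noise = 0)
  expect_true(all(l0$profiles$intensity == 0))
})

test_that("MET band amplitude ratio equals the configured effect", {
  panel <- fixture_panel()
  co <- make_cohort(6, 0, 0, 3, seed = 4)
  truth <- binding_truth(panel, noise_sd = 0, line_sd = 0)
  l <- simulate_lanes(panel, co, truth, probes = "p85A", seed = 3,
                      baseline_noise = 0)
  pos_line <- co$line_id[co$met_activation == "positive"][1]
  neg_line <- co$line_id[co$met_activation == "negative"][1]
  prof_pos <- l$profiles[l$profiles$sample == pos_line, ]
  prof_neg <- l$profiles[l$profiles$sample == neg_line, ]
  mw <- calibrate_mw(prof_pos$position, l$ladder)
  at145 <- which.min(abs(mw - 145))
  met_delta <- truth$bands$delta[truth$bands$probe == "p85A" &
                                   truth$bands$label %in% "met_positive"][1]
  expect_equal(prof_pos$intensity[at145] / prof_neg$intensity[at145],
               2^met_delta, tolerance = 1e-6)
})

test_that("treatment with zero shifts is the identity and shifts recover", {
  fx <- fixture_rosette_exact()
  truth0 <- fx$truth
  truth0$inhibition$shift <- 0
  same <- simulate_treatment(fx$rosette, truth0, fx$cohort, "erlotinib",
                             seed = 2)
  expect_equal(same$intensity, fx$rosette$intensity)

  treated <- simulate_treatment(fx$rosette, fx$truth, fx$cohort,
                                "erlotinib", seed = 2)
  av_u <- average_replicates(fx$rosette)
  av_t <- average_replicates(treated)
  keep <- !names(av_u) %in% c("pos_control", "neg_control")
  fc <- log2_fc(av_t[, keep], av_u[, keep], floor = 1e-9)
  gs <- group_summary(fc, fx$panel)
  sens <- fx$cohort$line_id[fx$cohort$erlotinib_class == "sensitive"][1]
  g <- gs[gs$condition == sens, ]
  expect_equal(g$mean_fc[g$family == "RAS_activator"], -3.1)
  expect_equal(g$mean_fc[g$family == "Nck"], 1.0)
})

test_that("dose-response generator sits on the curve when noiseless", {
  doses <- 10^seq(0, 3, length.out = 8)
  tab <- simulate_dose_response(50, hill = 1, top = 1, bottom = 0,
                                doses = doses, noise_sd = 0,
                                n_replicates = 2, seed = 1)
  expect_equal(tab$viability, four_pl(tab$dose, 1, 0, 1, 50))
  at_ic50 <- simulate_dose_response(50, doses = c(1, 10, 50, 1000),
                                    noise_sd = 0, n_replicates = 1, seed = 1)
  expect_equal(at_ic50$viability[at_ic50$dose == 50], 0.5)
  expect_identical(simulate_dose_response(50, seed = 4),
                   simulate_dose_response(50, seed = 4))
})
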