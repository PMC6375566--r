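test_that("adult gate captures adults and excludes L4 on separable runs", {
  set.seed(301)
  ev <- simulate_biosort_run(strain_preset("col-121"), exposure_preset("DMSO"),
                             6000)
  gate <- fit_adult_gate(ev)
  adults <- ev$tof[ev$true_stage == "adult"]
  l4 <- ev$tof[ev$true_stage == "L4"]
  expect_true(gate$separable)
  expect_gte(mean(adults >= gate$tof_min & adults <= gate$tof_max), 0.98)
  expect_lte(mean(l4 >= gate$tof_min & l4 <= gate$tof_max), 0.01)
  expect_lt(gate$tof_min, gate$tof_max)

  expect_error(fit_adult_gate(data.frame(tof = 1:100)), "true_stage")
  few <- data.frame(tof = rlnorm(60), true_stage = rep(c("adult", "L4"),
                                                       c(10, 50)))
  expect_error(fit_adult_gate(few), "50 labelled adult")
})

test_that("identical adult and L4 distributions trip the inseparability flag", {
  set.seed(302)
  tof <- rlnorm(2000, log(300), 0.2)
  ev <- data.frame(tof = tof, true_stage = rep(c("adult", "L4"), 1000))
  gate <- fit_adult_gate(ev)
  expect_false(gate$separable)
  expect_true(is.finite(gate$l4_contamination))
})

test_that("threshold fitting minimises FPR + FNR and matches the scan oracle", {
  # fully separated values: midpoint convention
  thr <- fit_gfp_threshold(c(1, 4, 7, 10), c(20, 25, 30))
  expect_equal(thr$tau, 15)
  expect_identical(thr$fpr_neg, 0)
  expect_identical(thr$fnr_pos, 0)

  set.seed(303)
  for (i in 1:10) {
    neg <- rnorm(120, 10, 3)
    pos <- rnorm(150, 16, 4)
    thr <- fit_gfp_threshold(neg, pos)
    expect_equal(thr$tau, brute_force_threshold(neg, pos))
  }

  # positive run drawn from the negative distribution: unusable
  neg <- rnorm(400, 10, 1)
  pos <- rnorm(400, 10, 1)
  expect_error(fit_gfp_threshold(neg, pos), "unusable calibration")
  expect_error(fit_gfp_threshold(numeric(0), pos), "non-empty")
})

test_that("classification follows the gate, strict threshold, and order invariance", {
  gate <- structure(list(tof_min = 100, tof_max = 200), class = "adult_gate")
  thr <- structure(list(tau = 15), class = "gfp_threshold")
  ev <- data.frame(tof = c(50, 150, 150, 150, 250),
                   gfp_peak = c(100, 15, 15.001, 3, 100))
  cls <- classify_events(ev, gate, thr)
  expect_equal(as.character(cls),
               c("out_of_gate", "adult_gfp_neg", "adult_gfp_pos",
                 "adult_gfp_neg", "out_of_gate"))

  set.seed(304)
  ev2 <- simulate_biosort_run(strain_preset("him-8"), exposure_preset("DMSO"),
                              800)
  perm <- sample(nrow(ev2))
  expect_identical(classify_events(ev2, gate, thr)[perm],
                   classify_events(ev2[perm, ], gate, thr))

  # raising tau never increases the positive count
  taus <- seq(0, 100, by = 5)
  counts <- vapply(taus, function(t) {
    sum(classify_events(ev2, gate,
                        structure(list(tau = t), class = "gfp_threshold")) ==
          "adult_gfp_pos")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("him-8 calibration runs classify overwhelmingly positive", {
  set.seed(305)
  cal <- make_calibration(4000)
  ev <- simulate_biosort_run(strain_preset("him-8"), exposure_preset("DMSO"),
                             5000)
  cls <- classify_events(ev, cal$gate, cal$threshold)
  gated <- cls[cls != "out_of_gate"]
  expect_gte(mean(gated == "adult_gfp_pos"), 0.95)
})

test_that("classified GFP+ fraction recovers the Poisson-thinned closed form", {
  set.seed(306)
  cal <- make_calibration(4000)
  veh <- exposure_preset("DMSO")
  for (p in c(0.01, 0.1, 0.367)) {
    s <- strain_params("probe", p_male = p)
    ev <- simulate_biosort_run(s, veh, 10000)
    cls <- classify_events(ev, cal$gate, cal$threshold)
    gated <- cls[cls != "out_of_gate"]
    expected <- 1 - exp(-12 * p)
    se <- sqrt(expected * (1 - expected) / length(gated))
    expect_lt(abs(mean(gated == "adult_gfp_pos") - expected), 3 * se + 0.01)
  }
})

test_that("calibrations survive a serialization round trip", {
  set.seed(307)
  cal <- make_calibration(2000)
  path <- withr::local_tempfile(fileext = ".yml")
  write_calibration(cal$gate, cal$threshold, path)
  back <- read_calibration(path)
  expect_equal(back$gate$tof_min, cal$gate$tof_min)
  expect_equal(back$gate$tof_max, cal$gate$tof_max)
  expect_equal(back$threshold$tau, cal$threshold$tau)
  bad <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(a = 1), bad)
  expect_error(read_calibration(bad), "not a calibration")
})
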