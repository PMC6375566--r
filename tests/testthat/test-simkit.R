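test_that("Hill effect honours its anchor points and monotonicity", {
  hp <- hill_params(ec50 = 50, n = 2, emax = 0.8)
  expect_identical(hill_effect(0, hp), 0)
  expect_equal(hill_effect(50, hp), 0.4)
  expect_equal(hill_effect(1e9, hp), 0.8, tolerance = 1e-8)
  doses <- seq(0, 1000, by = 5)
  expect_true(all(diff(hill_effect(doses, hp)) >= 0))
  # degenerate ec50 = 0 acts as a step at 0+
  step <- hill_params(ec50 = 0, n = 1, emax = 0.3)
  expect_equal(hill_effect(c(0, 1e-9, 10), step), c(0, 0.3, 0.3))
})

test_that("brood records nest males <= adults <= hatched <= eggs everywhere", {
  set.seed(201)
  strains <- list(strain_preset("col-121"), strain_preset("him-8"))
  exposures <- list(exposure_preset("DMSO"), exposure_preset("DBP", 500),
                    exposure_preset("TCMTB", 100))
  for (s in strains) for (ex in exposures) {
    b <- simulate_brood(s, ex, 50)
    expect_true(all(b$males <= b$adults))
    expect_true(all(b$adults <= b$hatched))
    expect_true(all(b$hatched <= b$eggs))
  }
  zero <- strain_params("none", p_male = 0)
  b0 <- simulate_brood(zero, exposure_preset("DMSO"), 50)
  expect_identical(sum(b0$males), 0L)
})

test_that("male fraction is recovered across the preset range", {
  set.seed(202)
  veh <- exposure_preset("DMSO")
  for (p in c(0.001, 0.05, 0.367)) {
    s <- strain_params("probe", p_male = p)
    b <- simulate_brood(s, veh, 450)  # ~1e5 progeny
    n <- sum(b$adults)
    expect_gt(n, 5e4)
    p_hat <- sum(b$males) / n
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(p_hat - p), 3 * se)
  }
})

test_that("simulation is reproducible and null exposure equals vehicle", {
  wt <- strain_preset("col-121")
  veh <- exposure_preset("DMSO")
  null_dbp <- exposure_preset("DBP", dose = 0)  # all effects vanish at dose 0

  set.seed(203); a <- simulate_brood(wt, veh, 40)
  set.seed(203); b <- simulate_brood(wt, null_dbp, 40)
  expect_identical(a, b)

  set.seed(203); e1 <- simulate_biosort_run(wt, veh, 500)
  set.seed(203); e2 <- simulate_biosort_run(wt, null_dbp, 500)
  expect_identical(e1, e2)

  set.seed(203); g1 <- simulate_germline(wt, veh, 20)
  set.seed(203); g2 <- simulate_germline(wt, null_dbp, 20)
  expect_identical(g1, g2)

  set.seed(204); r1 <- simulate_biosort_run(wt, veh, 300)
  set.seed(204); r2 <- simulate_biosort_run(wt, veh, 300)
  expect_identical(r1, r2)
})

test_that("sorter events respect composition and embryo-load physics", {
  wt <- strain_preset("col-121")
  veh <- exposure_preset("DMSO")
  expect_identical(nrow(simulate_biosort_run(wt, veh, 0)), 0L)
  set.seed(205)
  deb <- simulate_biosort_run(wt, veh, 200,
                              composition = c(debris = 1))
  expect_true(all(deb$true_stage == "debris"))
  expect_true(all(deb$n_embryos == 0))

  # him-8 adults carry >= 1 GFP+ embryo with Poisson-thinned probability
  # 1 - exp(-mu * p) = 0.9878 at mu = 12, p = 0.367
  him <- simulate_biosort_run(strain_preset("him-8"), veh, 17000)
  adults <- him[him$true_stage == "adult", ]
  expect_gt(nrow(adults), 1e4)
  frac <- mean(adults$n_gfp_embryos >= 1)
  expected <- 1 - exp(-12 * 0.367)
  se <- sqrt(expected * (1 - expected) / nrow(adults))
  expect_lt(abs(frac - expected), 3 * se)
  expect_true(all(him$n_gfp_embryos <= him$n_embryos))
  expect_true(all(him$n_embryos[him$true_stage != "adult"] == 0))
})

test_that("germline profiles reflect strain genetics", {
  set.seed(206)
  veh <- exposure_preset("DMSO")
  spo <- simulate_germline(strain_preset("spo-11-depleted"), veh, 50)
  expect_true(all(spo$diakinesis$n_dapi_bodies == 12))

  ctrl <- simulate_germline(strain_preset("col-121"), veh, 1000)
  expect_lt(mean(ctrl$corpses$corpse_count), 3)
  tal <- diakinesis_tally(ctrl$diakinesis)
  expect_identical(tal$modal_dapi, 6L)

  # rad-54 traps RAD-51: meiotic-zone rates are cumulative, non-decreasing
  rates <- germscreen:::.zone_rates(strain_preset("rad-54"),
                                    exposure_preset("DBP"))
  expect_true(all(diff(rates[3:7]) >= 0))
  # without SPO-11 the meiotic zones fall to the mitotic background
  rates0 <- germscreen:::.zone_rates(strain_preset("spo-11-depleted"),
                                     exposure_preset("DBP"))
  expect_true(all(rates0[3:7] == mean(rates0[1:2])))
})

test_that("qPCR simulation encodes tissue-resolved expression changes", {
  glp <- strain_preset("glp-1")
  veh <- exposure_preset("DMSO")
  expect_false(germline_present_at(glp, 25))
  expect_true(germline_present_at(glp, 15))
  expect_true(germline_present_at(strain_preset("col-121"), 25))

  # noise-free, germline log2FC = 1: fold is exactly 2 at 15 C
  ex1 <- exposure_params("probe", dose = 100,
                         expr = list("chk-1" = c(1, 0)))
  set.seed(207)
  ct <- rbind(simulate_qpcr(glp, ex1, 15, sigma_ct = 0),
              simulate_qpcr(glp, veh, 15, sigma_ct = 0))
  res <- qpcr_analysis(ct, treated = "probe")
  expect_equal(res$fold[res$gene == "chk-1"], 2, tolerance = 1e-9)
  # zero-effect genes sit at fold 1
  expect_equal(res$fold[res$gene == "rad-50"], 1, tolerance = 1e-9)

  expect_error(simulate_qpcr(glp, exposure_params("bad", 1,
                                                  expr = list(zzz = c(1, 0))),
                             15),
               "unknown gene")
})
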