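test_that("lethality fractions follow the nested-count arithmetic", {
  expect_equal(lethality_fractions(100, 100, 100),
               data.frame(emb_lethality = 0, larval_lethality = 0))
  r <- lethality_fractions(100, 0, 0)
  expect_equal(r$emb_lethality, 1)
  expect_true(is.na(r$larval_lethality))
  expect_equal(lethality_fractions(200, 150, 120),
               data.frame(emb_lethality = 0.25, larval_lethality = 0.2))
  expect_error(lethality_fractions(10, 20, 5), "nested")
  expect_error(lethality_fractions(-1, 0, 0), "non-negative")
})

test_that("exact Mann-Whitney equals full enumeration, ties included", {
  expect_equal(mann_whitney_two_tailed(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  r <- mann_whitney_two_tailed(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_identical(r$method, "exact")

  set.seed(501)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:4, n1, replace = TRUE)  # heavy ties on purpose
    y <- sample(1:4, n2, replace = TRUE)
    got <- mann_whitney_two_tailed(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, brute_force_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney p is invariant under monotone transforms and has a sane approximation", {
  set.seed(502)
  x <- rpois(10, 3); y <- rpois(12, 4)
  p1 <- mann_whitney_two_tailed(x, y)$p_value
  p2 <- mann_whitney_two_tailed(exp(x / 2), exp(y / 2))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)

  # forcing the normal approximation stays close to the exact answer
  approx <- mann_whitney_two_tailed(x, y, exact_limit = 1)
  expect_identical(approx$method, "normal_approx")
  expect_lt(abs(approx$p_value - p1), 0.05)
})

test_that("two-sided Fisher equals table enumeration and is transpose-invariant", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5)$p_value, 1)
  expect_equal(fisher_exact_two_sided(0, 10, 0, 12)$p_value, 1)

  # gonads with gaps: 16/53 exposed vs 6/55 vehicle is significant
  g <- fisher_exact_two_sided(16, 37, 6, 49)
  expect_lt(g$p_value, 0.05)
  expect_equal(g$p_value, brute_force_fisher_p(16, 37, 6, 49),
               tolerance = 1e-12)
  expect_equal(g$p_value,
               fisher.test(matrix(c(16, 6, 37, 49), 2))$p.value,
               tolerance = 1e-7)

  set.seed(503)
  for (i in 1:15) {
    tb <- sample(0:12, 4, replace = TRUE)
    p <- fisher_exact_two_sided(tb[1], tb[2], tb[3], tb[4])$p_value
    expect_equal(p, brute_force_fisher_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    # transposition of the 2x2 table
    expect_equal(p, fisher_exact_two_sided(tb[1], tb[3], tb[2], tb[4])$p_value,
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_two_sided(1.5, 2, 3, 4), "integers")
})

test_that("zone assignment bins the normalised gonad axis evenly", {
  expect_identical(zone_assign(0), 1L)
  expect_identical(zone_assign(0.999), 7L)
  expect_error(zone_assign(1), "\\[0, 1\\)")
  expect_error(zone_assign(-0.1), "\\[0, 1\\)")
  grid <- seq(0, 1 - 1e-9, length.out = 7000)
  expect_true(all(table(zone_assign(grid)) == 1000))
})

test_that("zone profiles separate meiotic elevation from the mitotic zone", {
  wt <- strain_preset("col-121")
  veh <- exposure_preset("DMSO")
  set.seed(504)
  a <- simulate_germline(wt, veh, 10)
  ident <- zone_profile_compare(a$foci, a$foci)
  expect_true(all(ident$p_value == 1))
  expect_equal(ident$mean_exposed, ident$mean_vehicle)

  b <- simulate_germline(wt, exposure_preset("DBP"), 10)
  v <- simulate_germline(wt, veh, 10)
  zp <- zone_profile_compare(b$foci, v$foci)
  # mitotic zones (z1-z2) indistinguishable; pachytene (z4-z6) elevated
  expect_true(all(zp$p_value[zp$zone %in% 1:2] > 0.05))
  expect_true(all(zp$p_value[zp$zone %in% 4:6] < 0.01))
  expect_true(all(zp$mean_exposed[4:6] > zp$mean_vehicle[4:6]))

  empty <- a$foci[a$foci$zone != 3, ]
  expect_error(zone_profile_compare(empty, v$foci), "zone 3")
})

test_that("corpse analysis detects CEP-1-dependent damage apoptosis", {
  wt <- strain_preset("col-121")
  cep <- strain_preset("cep-1")
  veh <- exposure_preset("DMSO")
  dbp <- exposure_preset("DBP")
  set.seed(505)
  corpses <- rbind(
    data.frame(condition = "DMSO", genotype = "col-121",
               count = simulate_germline(wt, veh, 35)$corpses$corpse_count),
    data.frame(condition = "DBP", genotype = "col-121",
               count = simulate_germline(wt, dbp, 35)$corpses$corpse_count),
    data.frame(condition = "DMSO", genotype = "cep-1",
               count = simulate_germline(cep, veh, 35)$corpses$corpse_count),
    data.frame(condition = "DBP", genotype = "cep-1",
               count = simulate_germline(cep, dbp, 35)$corpses$corpse_count))
  res <- corpse_analysis(corpses)
  s <- res$summary
  expect_equal(s$fold_vs_vehicle[s$condition == "DMSO"], c(1, 1))
  expect_gte(s$fold_vs_vehicle[s$condition == "DBP" & s$genotype == "col-121"],
             2)
  expect_identical(res$dependence$label[res$dependence$condition == "DBP"],
                   "cep-1-dependent")

  # vehicle-only arms: no elevation anywhere
  v2 <- corpses[corpses$condition == "DMSO", ]
  v2b <- v2; v2b$condition <- "mock"
  res2 <- corpse_analysis(rbind(v2, v2b))
  expect_true(all(res2$dependence$label == "no-elevation"))
  expect_error(corpse_analysis(corpses[corpses$condition != "DMSO", ]),
               "vehicle")
})

test_that("diakinesis tallies report class percentages and DAPI histograms", {
  toy <- data.frame(
    n_dapi_bodies = c(8, 9, 6, rep(6, 7)),
    defect_class = c("fragments", "fragments", "bridges", rep("normal", 7)))
  tal <- diakinesis_tally(toy)
  expect_equal(tal$classes$percent[tal$classes$defect_class == "fragments"], 20)
  expect_equal(tal$classes$percent[tal$classes$defect_class == "bridges"], 10)
  expect_equal(tal$classes$percent[tal$classes$defect_class == "normal"], 70)
  expect_equal(tal$n_total, 10)

  allnorm <- data.frame(n_dapi_bodies = rep(6, 20),
                        defect_class = rep("normal", 20))
  t2 <- diakinesis_tally(allnorm)
  expect_equal(t2$classes$percent, 100)
  expect_identical(t2$modal_dapi, 6L)
  expect_error(diakinesis_tally(allnorm[0, ]), "no diakinesis")
})

test_that("gonad defect comparison flags exposure-elevated categories", {
  wt <- strain_preset("col-121")
  set.seed(506)
  ex <- simulate_germline(wt, exposure_preset("TCMTB"), 60)
  v <- simulate_germline(wt, exposure_preset("DMSO"), 60)
  cmp <- gonad_defect_compare(ex$defects, v$defects)
  expect_identical(cmp$defect, c("gap", "aggregate", "lz_like"))
  expect_true(all(cmp$pct_exposed >= 0 & cmp$pct_exposed <= 100))
  expect_lt(cmp$p_value[cmp$defect == "lz_like"], 0.05)
})
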