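test_that("percent_change matches hand arithmetic", {
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(1, 5), -80)
  set.seed(3)
  a <- stats::runif(20, 0.1, 10)
  b <- stats::runif(20, 0.1, 10)
  expect_equal(percent_change(a, b), 100 * (a - b) / b)
  expect_error(percent_change(1, 0), "zero baseline")
})

test_that("protection runner reproduces the chronic/acute contrast", {
  fx <- default_fixture()
  pre <- run_ang1_protection(fx$model, fx$params, mode = "pre_25min")
  expect_gt(pre$pSrc_reduction_pct, 60)
  expect_gt(pre$pVEcad_reduction_pct, 60)
  expect_gt(pre$sequestration_at_pre_time, 0.7)
  sim <- run_ang1_protection(fx$model, fx$params, mode = "simultaneous",
                             ang1_dose = 500)
  expect_lt(sim$pSrc_reduction_pct, 15)
  only <- run_ang1_protection(fx$model, fx$params, mode = "ang1_only")
  expect_true(is.na(only$pSrc_reduction_pct))
  expect_error(run_ang1_protection(fx$model, fx$params, mode = "nope"))
  # protection monotone in pre-stimulation dose
  reds <- vapply(c(10, 50, 200), function(d)
    run_ang1_protection(fx$model, fx$params, mode = "pre_25min",
                        ang1_dose = d)$pSrc_reduction_pct, numeric(1))
  expect_true(all(diff(reds) > -1))
})

test_that("combination grids anchor at baseline and rescue ppAkt", {
  fx <- default_fixture()
  g <- run_combination_grid(fx$model, fx$params, "Src",
                            levels = c(0, 0.4, 0.8),
                            ang1_doses = c(0, 500))
  expect_equal(nrow(g), 6)
  base <- g[g$level == 0 & g$ang1_dose == 0, ]
  # level 0 / Ang1 0 equals the uninhibited VEGF baseline
  pr <- stimulus_protocol(list(list(time = 0, ligand = "VEGF",
                                    amount = 50)),
                          t_end = 15, output_grid = seq(0, 15, 0.5))
  ref <- simulate_protocol(fx$model, fx$params, pr, y0 = fx$y0)
  expect_equal(base$pSrc,
               unname(ref$observables[nrow(ref$observables), "pSrc"]),
               tolerance = 1e-8)
  # pSrc decreases with Src inhibition level
  noang <- g[g$ang1_dose == 0, ]
  expect_true(all(diff(noang$pSrc) < 0))
  # Ang1 rescue of ppAkt under high Src inhibition
  hi <- g[g$level == 0.8, ]
  expect_gt(hi$ppAkt[hi$ang1_dose == 500], hi$ppAkt[hi$ang1_dose == 0])
  # VEGFR2 inhibition: Erk suppression is not rescued by Ang1
  gv <- run_combination_grid(fx$model, fx$params, "VEGFR2",
                             levels = c(0, 0.9), ang1_doses = c(0, 500))
  v9 <- gv[gv$level == 0.9, ]
  v0 <- gv[gv$level == 0 & gv$ang1_dose == 0, ]
  expect_lt(max(v9$pErk), 0.9 * v0$pErk)
  expect_lt(abs(v9$pErk[v9$ang1_dose == 500] -
                  v9$pErk[v9$ang1_dose == 0]),
            0.05 * v0$pErk)
  expect_error(run_combination_grid(fx$model, fx$params, "Raf"),
               "unknown target")
})

test_that("crosstalk sweep anchors, saturates and stays monotone", {
  fx <- default_fixture()
  sw <- run_crosstalk_sweep(fx$model, fx$params,
                            doses = c(0, 1, 2, 4, 7, 10, 20))
  expect_equal(sw$shedding_fold$values[1], 1, tolerance = 1e-9)
  expect_equal(sw$ptie2_inhibition$values[1], 0, tolerance = 1e-9)
  expect_true(all(diff(sw$shedding_fold$values) > -1e-9))
  expect_true(all(diff(sw$ptie2_inhibition$values) > -0.5))
  expect_equal(sw$summary$shedding_fold_plateau, 2, tolerance = 0.25)
  expect_gt(sw$summary$ptie2_inhibition_plateau, 75)
})

test_that("scenario baselines are identical across runners", {
  fx <- default_fixture()
  a <- run_ang1_protection(fx$model, fx$params, mode = "pre_25min")
  b <- run_ang1_protection(fx$model, fx$params, mode = "simultaneous")
  expect_identical(a$baseline_hash, b$baseline_hash)
  expect_equal(a$baseline_max_pSrc, b$baseline_max_pSrc)
})
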