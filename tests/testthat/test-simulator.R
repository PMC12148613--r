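test_that("toy binding system equilibrates to the analytic Kd ratio", {
  tb <- toy_binding_model(kon = 2, koff = 0.5, A0 = 1, B0 = 0.7)
  y <- pre_equilibrate(tb$model, tb$params)
  # A + B <-> C with Kd = koff/kon: C/(A*B) = 1/Kd at equilibrium
  expect_equal(y[["C"]] / (y[["A"]] * y[["B"]]), 2 / 0.5,
               tolerance = 1e-6)
  # conservation of the totals
  expect_equal(y[["A"]] + y[["C"]], 1, tolerance = 1e-9)
  # idempotence: re-equilibrating from the equilibrium changes nothing
  tb2 <- tb
  y2 <- pre_equilibrate(tb$model, tb$params)
  expect_equal(y, y2, tolerance = 1e-9)
})

test_that("constitutive shedding is at flux balance after pre-equilibration", {
  fx <- default_fixture()
  cm <- compile_rhs(fx$model, fx$params)
  rates <- cm$rates(fx$y0)
  # sTie2 production (shedding) equals clearance at steady state
  shed <- rates[["tie2_shed_const"]] + rates[["tie2_shed_vegf"]]
  clear <- rates[["stie2_clear"]]
  expect_equal(shed, clear, tolerance = 1e-6)
  # shedding flux equals rate constant x surface Tie2
  expect_equal(shed,
               fx$params$values[["kshedtie2"]] * fx$y0[["Tie2"]],
               tolerance = 1e-6)
})

test_that("zero-ligand protocol stays flat after pre-equilibration", {
  fx <- default_fixture()
  pr <- stimulus_protocol(list(), t_end = 120,
                          output_grid = seq(0, 120, 5))
  res <- simulate_protocol(fx$model, fx$params, pr, y0 = fx$y0)
  phospho <- c("pVEGFR2", "pTie2", "pSrc", "ppAkt", "pErk", "pVEcad")
  for (ob in phospho) {
    v <- res$observables[, ob]
    expect_lt(max(v) - min(v), 1e-3 * max(max(abs(v)), 1e-9) + 1e-9)
  }
})

test_that("ligand events raise the species by exactly the added amount", {
  fx <- default_fixture()
  m <- fx$model; p <- fx$params
  pr <- stimulus_protocol(list(list(time = 10, ligand = "VEGF",
                                    amount = 50)),
                          t_end = 20, output_grid = c(0, 9.5, 10, 20))
  res <- simulate_protocol(m, p, pr, y0 = fx$y0)
  pre <- res$states[res$times == 9.5, "VEGF"]
  post <- res$states[res$times == 10, "VEGF"]
  expect_equal(unname(post - pre), 50 / p$values[["mw_vegf"]],
               tolerance = 1e-6)
  # state before the event is unperturbed relative to a no-event run
  pr0 <- stimulus_protocol(list(), t_end = 20,
                           output_grid = c(0, 9.5, 10, 20))
  res0 <- simulate_protocol(m, p, pr0, y0 = fx$y0)
  expect_equal(res$states[res$times == 9.5, ],
               res0$states[res0$times == 9.5, ], tolerance = 1e-8)
  expect_error(stimulus_protocol(list(list(time = 0, ligand = "VEGF",
                                           amount = -1))),
               "negative dose")
})

test_that("Ang2 doses split into the configured multimer mixture", {
  p <- default_parameters()
  add <- ligand_addition("Ang2", 500, p)
  mono <- 500 / p$values[["mw_ang2_monomer"]]
  expect_equal(sum(add * c(2, 3, 4)), mono, tolerance = 1e-12)
  expect_equal(unname(add["A2d"] / add["A2t"]), 0.4 / 0.3,
               tolerance = 1e-12)
})

test_that("simulation is deterministic and tolerance-stable", {
  fx <- default_fixture()
  pr <- stimulus_protocol(list(list(time = 0, ligand = "VEGF",
                                    amount = 50)),
                          t_end = 30, output_grid = seq(0, 30, 1))
  r1 <- simulate_protocol(fx$model, fx$params, pr, y0 = fx$y0)
  r2 <- simulate_protocol(fx$model, fx$params, pr, y0 = fx$y0)
  expect_identical(r1$observables, r2$observables)
  # tightening rtol 10x moves observables by < 0.1% relative
  r3 <- simulate_protocol(fx$model, fx$params, pr, y0 = fx$y0,
                          rtol = 1e-9, atol = 1e-11)
  scale <- pmax(abs(r1$observables), 1e-6)
  expect_lt(max(abs(r1$observables - r3$observables) / scale), 1e-3)
})

test_that("peak summaries handle degenerate and analytic cases", {
  expect_error(summarize_peak(1:3, c(NA, NA, NA)), "NaN")
  cst <- summarize_peak(c(0, 1, 2), c(2, 2, 2))
  expect_equal(cst$t_peak, 0)
  mono <- summarize_peak(0:10, 0:10)
  expect_equal(mono$t_peak, 10)
  # grid peak of a known pulse t*exp(-t): max at t = 1
  tt <- seq(0, 5, 0.1)
  pk <- summarize_peak(tt, tt * exp(-tt))
  expect_equal(pk$t_peak, 1, tolerance = 0.11)
})

test_that("refined peaks are stable under grid halving", {
  fx <- default_fixture()
  pr <- stimulus_protocol(list(list(time = 0, ligand = "VEGF",
                                    amount = 50)),
                          t_end = 20, output_grid = seq(0, 20, 1))
  pk1 <- peak_refined(fx$model, fx$params, pr, "pSrc", y0 = fx$y0)
  pr$output_grid <- seq(0, 20, 0.5)
  pk2 <- peak_refined(fx$model, fx$params, pr, "pSrc", y0 = fx$y0)
  expect_lt(abs(pk1$peak - pk2$peak) / pk2$peak, 0.005)
  expect_lt(abs(pk1$t_peak - pk2$t_peak), 0.2 + 1e-9)
})

test_that("dose-response anchors at baseline and finds saturation", {
  fx <- default_fixture()
  dr <- dose_response(fx$model, fx$params, "VEGF",
                      c(0, 2, 5, 10, 20), "shed_fold",
                      summary = "peak", t_end = 30, y0 = fx$y0)
  expect_equal(dr$values[1], 1, tolerance = 1e-9)
  expect_true(all(diff(dr$values) > -1e-9))
  expect_true(dr$saturation_dose %in% dr$doses)
  expect_error(dose_response(fx$model, fx$params, "VEGF", c(0, 5),
                             "not_an_observable"),
               "unknown readout")
})

test_that("positivity: states stay essentially non-negative on protocols", {
  fx <- default_fixture()
  prs <- list(
    stimulus_protocol(list(list(time = 0, ligand = "VEGF", amount = 50)),
                      t_end = 60, output_grid = seq(0, 60, 2)),
    stimulus_protocol(list(list(time = 0, ligand = "Ang1", amount = 500),
                           list(time = 0, ligand = "Ang2", amount = 500)),
                      t_end = 60, output_grid = seq(0, 60, 2)))
  for (pr in prs) {
    res <- simulate_protocol(fx$model, fx$params, pr, y0 = fx$y0)
    expect_gt(min(res$states), -1e-9)
  }
})
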