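test_that("noise-free datasets equal the normalized simulation exactly", {
  fx <- default_fixture()
  pr <- stimulus_protocol(list(list(time = 0, ligand = "VEGF",
                                    amount = 50)), t_end = 30)
  d <- generate_timecourse_dataset(fx$model, fx$params, pr, "pSrc",
                                   c(0, 2, 5, 10, 30), noise = NULL,
                                   id = "nf", y0 = fx$y0)
  pred <- predict_dataset(fx$model, fx$params, d, y0 = fx$y0)
  expect_equal(d$points$value, unname(pred), tolerance = 1e-8)
  expect_equal(max(d$points$value), 100)
})

test_that("multiplicative noise has the configured CV and is seeded", {
  set.seed(0)
  base <- rep(10, 1000)
  noisy <- endonet:::.apply_noise(base, noise_model(scale = 0.05))
  cv <- stats::sd(noisy) / mean(noisy)
  expect_gt(cv, 0.04)
  expect_lt(cv, 0.06)
  fx <- default_fixture()
  pr <- stimulus_protocol(list(list(time = 0, ligand = "VEGF",
                                    amount = 50)), t_end = 20)
  mk <- function(seed) {
    set.seed(seed)
    generate_timecourse_dataset(fx$model, fx$params, pr, "pSrc",
                                c(2, 5, 10), id = "x", y0 = fx$y0)
  }
  expect_identical(mk(1)$points$value, mk(1)$points$value)
  expect_false(identical(mk(1)$points$value, mk(2)$points$value))
})

test_that("dose-response datasets are monotone up to small noise", {
  fx <- default_fixture()
  set.seed(0)
  d <- generate_dose_response_dataset(
    fx$model, fx$params, "Ang1", c(0, 12.5, 25, 50, 100, 200, 400, 800),
    "pTie2", at_time = 15, t_end = 15, y0 = fx$y0)
  # isotonic fit explains almost all dataset variance
  iso <- stats::isoreg(d$points$abscissa, d$points$value)
  r2 <- 1 - sum((iso$yf - d$points$value)^2) /
    sum((d$points$value - mean(d$points$value))^2)
  expect_gt(r2, 0.9)
  expect_equal(d$points$abscissa[1], 0)
})

test_that("fixture suite is complete, parseable and self-consistent", {
  suite <- make_fixture_suite(seed = 0)
  expect_gte(length(suite$datasets), 16)
  expect_true(all(vapply(suite$datasets, inherits, logical(1),
                         "calibration_dataset")))
  # percent-of-max datasets peak at exactly 100
  for (d in suite$datasets)
    if (d$normalization == "percent_of_max")
      expect_equal(max(d$points$value), 100, tolerance = 1e-9)
  # two seeds: identical protocols, different draws
  s2 <- make_fixture_suite(seed = 1)
  expect_identical(names(suite$datasets), names(s2$datasets))
  expect_identical(suite$datasets[[1]]$points$abscissa,
                   s2$datasets[[1]]$points$abscissa)
  expect_false(identical(
    vapply(suite$datasets, function(d) d$points$value[2], numeric(1)),
    vapply(s2$datasets, function(d) d$points$value[2], numeric(1))))
  # noise-free suite evaluates to (numerically) zero objective at truth
  fx <- default_fixture()
  s0 <- make_fixture_suite(seed = 0, cv = 0)
  expect_lt(objective_sse(fx$params, s0$datasets, fx$model), 1e-6)
})
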