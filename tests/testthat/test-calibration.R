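test_that("normalization modes behave as documented", {
  d_pct <- list(normalization = "percent_of_max")
  expect_equal(normalize_prediction(c(2, 2, 2), d_pct), c(100, 100, 100))
  # scale invariance
  x <- c(1, 3, 2)
  expect_equal(normalize_prediction(x, d_pct),
               normalize_prediction(2 * x, d_pct))
  expect_equal(normalize_prediction(x, d_pct), 100 * x / 3)
  d_fold <- list(normalization = "fold_of_baseline")
  expect_equal(normalize_prediction(c(1, 2, 4), d_fold, baseline = 2),
               c(0.5, 1, 2))
  expect_error(normalize_prediction(c(1, 2), d_fold, baseline = 0),
               "zero baseline")
  expect_equal(normalize_prediction(x, list(normalization = "absolute")),
               x)
})

test_that("objective is zero at truth, positive off-truth, and additive", {
  tb <- toy_binding_model()
  pr <- stimulus_protocol(list(list(time = 0, ligand = "A", amount = 0.5,
                                    unit = "nM")),
                          t_end = 10, output_grid = seq(0, 10, 1))
  d1 <- generate_timecourse_dataset(tb$model, tb$params, pr, "C",
                                    c(1, 2, 5, 10), noise = NULL,
                                    normalization = "absolute", id = "d1")
  d2 <- generate_timecourse_dataset(tb$model, tb$params, pr, "C",
                                    c(0.5, 3, 8), noise = NULL,
                                    normalization = "absolute", id = "d2")
  expect_lt(objective_sse(tb$params, list(d1, d2), tb$model), 1e-10)
  p2 <- update_params(tb$params, c(kon = 2))
  expect_gt(objective_sse(p2, list(d1, d2), tb$model), 0)
  # additivity across datasets
  o12 <- objective_sse(p2, list(d1, d2), tb$model)
  o1 <- objective_sse(p2, list(d1), tb$model)
  o2 <- objective_sse(p2, list(d2), tb$model)
  expect_equal(o12, o1 + o2, tolerance = 1e-6)
  # doubling weights doubles the objective
  d1w <- d1; d1w$points$weight <- 2 * d1w$points$weight
  d2w <- d2; d2w$points$weight <- 2 * d2w$points$weight
  expect_equal(objective_sse(p2, list(d1w, d2w), tb$model), 2 * o12,
               tolerance = 1e-10)
  expect_error(objective_sse(tb$params, list(), tb$model), "empty")
})

test_that("pattern search solves convex and benchmark problems", {
  # 2-D quadratic bowl
  quad <- function(x) sum((x - c(0.3, -0.2))^2)
  r <- pattern_search(quad, lower = c(-2, -2), upper = c(2, 2),
                      init = c(1, 1))
  expect_true(r$converged)
  expect_lt(r$objective, 1e-4)
  expect_equal(r$par, c(0.3, -0.2), tolerance = 1e-2)
  # Rosenbrock from the standard start
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  rb <- pattern_search(rosen, lower = c(-5, -5), upper = c(5, 5),
                       init = c(-1.2, 1),
                       control = list(max_eval = 5000))
  expect_lt(rb$objective, 1e-3)
  # incumbent objective never increases along the trace
  expect_true(all(diff(rb$trace$objective) <= 1e-15))
  # starting at the optimum returns immediately converged
  r0 <- pattern_search(quad, c(-2, -2), c(2, 2), init = c(0.3, -0.2),
                       control = list(step0 = 1e-7))
  expect_true(r0$converged)
  expect_equal(r0$par, c(0.3, -0.2))
  expect_error(pattern_search(quad, c(0, 0), c(-1, -1), c(0, 0)),
               "invalid bounds")
})

test_that("pattern search respects bounds at every evaluated point", {
  seen <- list()
  obj <- function(x) {
    seen[[length(seen) + 1]] <<- x
    sum(x^2)
  }
  r <- pattern_search(obj, lower = c(0.5, -1), upper = c(2, 0.2),
                      init = c(1, 0), control = list(max_eval = 200))
  pts <- do.call(rbind, seen)
  expect_true(all(pts[, 1] >= 0.5 - 1e-12 & pts[, 1] <= 2 + 1e-12))
  expect_true(all(pts[, 2] >= -1 - 1e-12 & pts[, 2] <= 0.2 + 1e-12))
  expect_equal(r$par[1], 0.5, tolerance = 1e-5)
})

test_that("fitting zero parameters returns the initial objective", {
  tb <- toy_binding_model()
  pr <- stimulus_protocol(list(list(time = 0, ligand = "A", amount = 0.5,
                                    unit = "nM")),
                          t_end = 10, output_grid = seq(0, 10, 1))
  d <- generate_timecourse_dataset(tb$model, tb$params, pr, "C",
                                   c(1, 5, 10), noise = NULL,
                                   normalization = "absolute", id = "d")
  r <- fit(tb$model, list(d), tb$params, character(0))
  expect_equal(r$objective,
               objective_sse(tb$params, list(d), tb$model))
  expect_true(r$converged)
  expect_equal(r$n_eval, 1L)
})

test_that("fit recovers a perturbed binding constant on the toy model", {
  tb <- toy_binding_model(kon = 2, koff = 0.5)
  pr <- stimulus_protocol(list(list(time = 0, ligand = "A", amount = 0.5,
                                    unit = "nM")),
                          t_end = 10, output_grid = seq(0, 10, 0.5))
  d <- generate_timecourse_dataset(tb$model, tb$params, pr, "C",
                                   c(0.5, 1, 2, 3, 5, 8, 10),
                                   noise = NULL,
                                   normalization = "absolute", id = "d")
  start <- update_params(tb$params, c(kon = 0.4, koff = 2))
  r <- fit(tb$model, list(d), start, c("kon", "koff"),
           control = list(max_eval = 1500))
  expect_lt(r$objective, 1e-6)
  expect_equal(r$best_params$values[["kon"]] /
                 r$best_params$values[["koff"]],
               2 / 0.5, tolerance = 0.05)
  # audit trail files
  out <- tempfile()
  r2 <- fit(tb$model, list(d), start, c("kon"), out_dir = out,
            control = list(max_eval = 50))
  expect_true(file.exists(file.path(out, "trace.csv")))
  expect_true(file.exists(file.path(out, "fitted_params.json")))
})
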