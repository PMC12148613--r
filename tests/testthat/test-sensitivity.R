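test_that("LHS sampling is stratified and seed-reproducible", {
  cfg <- sensitivity_config(keys = "x", n_base = 10, sampler = "lhs",
                            seed = 1, ranges = list(x = c(0, 1)))
  s1 <- sample_parameter_space(cfg, c(x = 1))
  # one sample per decile in each column
  expect_equal(sort(floor(s1$A[, 1] * 10)), 0:9)
  s2 <- sample_parameter_space(cfg, c(x = 1))
  expect_identical(s1$A, s2$A)
  cfg$seed <- 2
  s3 <- sample_parameter_space(cfg, c(x = 1))
  expect_false(identical(s1$A, s3$A))
})

test_that("Sobol sequence matches the reference first points and leaps", {
  pts <- sobol_sequence(8, 2)
  # classical unscrambled base-2 sequence
  expect_equal(pts[, 1],
               c(0, 0.5, 0.75, 0.25, 0.375, 0.875, 0.625, 0.125))
  expect_equal(pts[, 2],
               c(0, 0.5, 0.25, 0.75, 0.375, 0.875, 0.125, 0.625))
  expect_error(sobol_sequence(4, 50), "capacity")
  # skip/leap discrepancy stays below i.i.d. uniform sampling
  dq <- l2_star_discrepancy(sobol_sequence(1024, 2, skip = 1000,
                                           leap = 100))
  set.seed(42)
  dr <- mean(replicate(10,
                       l2_star_discrepancy(matrix(stats::runif(2048),
                                                  1024, 2))))
  expect_lt(dq, dr)
})

test_that("first-order indices recover the Ishigami analytic values", {
  cfg <- sensitivity_config(keys = c("x1", "x2", "x3"),
                            sampler = "sobol_sequence", n_base = 4096,
                            leap = 0, outputs = "y", boot = 200,
                            ranges = list(x1 = c(-pi, pi),
                                          x2 = c(-pi, pi),
                                          x3 = c(-pi, pi)))
  r <- sobol_first_order(ishigami_fn, cfg, c(x1 = 1, x2 = 1, x3 = 1))
  expect_equal(r$n_runs, 4096 * 5)
  est <- r$main_effect[, "index", "y"]
  expect_lt(max(abs(est - ishigami_analytic())), 0.03)
  # bootstrap CIs contain the point estimates
  expect_true(all(r$main_effect[, "ci_lo", "y"] <= est + 1e-9))
  expect_true(all(r$main_effect[, "ci_hi", "y"] >= est - 1e-9))
  # estimator consistency: error shrinks from n_base 512 to 4096
  cfg$n_base <- 512
  r512 <- sobol_first_order(ishigami_fn, cfg,
                            c(x1 = 1, x2 = 1, x3 = 1))
  e512 <- abs(r512$main_effect[, "index", "y"] - ishigami_analytic())
  e4096 <- abs(est - ishigami_analytic())
  # allow one inversion among the three indices
  expect_gte(sum(e4096 <= e512 + 1e-9), 2)
})

test_that("additive model: first order sums to one, no interactions", {
  f <- function(M) matrix(M[, 1] + 2 * M[, 2] + 0.5 * M[, 3], ncol = 1,
                          dimnames = list(NULL, "y"))
  cfg <- sensitivity_config(keys = c("a", "b", "c"),
                            sampler = "sobol_sequence", n_base = 2048,
                            leap = 0, outputs = "y", boot = 50,
                            ranges = list(a = c(0, 1), b = c(0, 1),
                                          c = c(0, 1)))
  r1 <- sobol_first_order(f, cfg, c(a = 1, b = 1, c = 1))
  S <- r1$main_effect[, "index", "y"]
  # analytic: S_i proportional to c_i^2 (equal uniform variances)
  w <- c(1, 4, 0.25) / sum(c(1, 4, 0.25))
  expect_lt(max(abs(S - w)), 0.02)
  expect_lt(abs(sum(S) - 1), 0.02)
  r2 <- sobol_second_order(f, cfg, c(a = 1, b = 1, c = 1))
  expect_equal(r2$n_runs, 2048 * (2 * 3 + 2))
  M <- r2$second_order$y
  expect_lt(max(abs(M)), 0.02)
  expect_identical(M, t(M))
  expect_equal(diag(M), stats::setNames(rep(0, 3), c("a", "b", "c")))
})

test_that("pure interaction lands on the second-order index", {
  f <- function(M) matrix(M[, 1] * M[, 2], ncol = 1,
                          dimnames = list(NULL, "y"))
  cfg <- sensitivity_config(keys = c("a", "b"),
                            sampler = "sobol_sequence", n_base = 4096,
                            leap = 0, outputs = "y", boot = 50,
                            ranges = list(a = c(-1, 1), b = c(-1, 1)))
  r1 <- sobol_first_order(f, cfg, c(a = 1, b = 1))
  expect_lt(max(abs(r1$main_effect[, "index", "y"])), 0.05)
  r2 <- sobol_second_order(f, cfg, c(a = 1, b = 1))
  expect_equal(r2$second_order$y["a", "b"], 1, tolerance = 0.05)
})

test_that("degenerate outputs are flagged undefined", {
  f <- function(M) matrix(1, nrow = nrow(M), ncol = 1,
                          dimnames = list(NULL, "y"))
  cfg <- sensitivity_config(keys = c("a", "b"), n_base = 64,
                            outputs = "y", boot = 10,
                            ranges = list(a = c(0, 1), b = c(0, 1)))
  r <- sobol_first_order(f, cfg, c(a = 1, b = 1))
  expect_true("y" %in% r$undefined)
  expect_true(all(is.na(r$main_effect[, "index", "y"])))
})

test_that("rank_top orders by index with lexicographic ties", {
  r <- list(main_effect = array(
    c(0.5, 0.2, 0.5, 0.4, 0.4, 0.1, 0.4, 0.3, 0.6, 0.3, 0.6, 0.5),
    dim = c(4, 3, 1),
    dimnames = list(c("zeta", "alpha", "mid", "beta"),
                    c("index", "ci_lo", "ci_hi"), "y")),
    outputs = "y")
  class(r) <- "sobol_result"
  top <- rank_top(r, "y", 3)
  # 0.5 tie between zeta and mid broken lexicographically
  expect_equal(top$parameter, c("mid", "zeta", "beta"))
  expect_equal(nrow(rank_top(r, "y", 0)), 0)
  expect_equal(nrow(rank_top(r, "y", 99)), 4)
  expect_error(rank_top(r, "nope"), "does not contain")
})

test_that("model evaluator is deterministic and bookkeeping is exact", {
  fx <- default_fixture()
  keys <- c("kactivesrc", "Tie2_0", "kcatPI3KAkt")
  cfg <- sensitivity_config(keys = keys, n_base = 8, boot = 20,
                            outputs = c("pSrc", "ppAkt"))
  ev <- sensitivity_evaluator(fx$model, fx$params, cfg)
  r <- sobol_first_order(ev, cfg, fx$params$values)
  expect_equal(r$n_runs, 8 * (3 + 2))
  expect_true(all(is.finite(r$main_effect[, "index", ])))
  # identical config gives identical indices (fixed seed)
  r2 <- sobol_first_order(ev, cfg, fx$params$values)
  expect_identical(r$main_effect, r2$main_effect)
  # tidy export
  td <- sobol_tidy(r)
  expect_setequal(names(td),
                  c("parameter", "output", "index", "ci_lo", "ci_hi"))
  expect_equal(nrow(td), 3 * 2)
})
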