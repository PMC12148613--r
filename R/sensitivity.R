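#' Configuration for variance-based global sensitivity analysis
#'
#' Parameters are varied uniformly on \code{[lo x baseline, hi x baseline]}
#' (default 0.2-fold to 5-fold).  Model outputs are the configured
#' observables at \code{readout_time} minutes after a simultaneous
#' multi-ligand stimulus applied to the pre-equilibrated model.
#'
#' @param keys Parameter keys to vary.
#' @param lo,hi Range factors relative to baseline (0 < lo < hi).
#' @param sampler \code{"lhs"} (Latin hypercube) or \code{"sobol_sequence"}.
#' @param skip,leap Sobol-sequence skip (default 1e3) and leap (default 1e2).
#' @param n_base Base sample size N; the first-order design evaluates
#'   N(d+2) points, the second-order design N(2d+2).
#' @param outputs Observable names to analyze.
#' @param readout_time Minutes post-stimulus (default 5).
#' @param stimulus Named vector of ligand doses in ng/mL applied at t = 0
#'   (default VEGF 10, Ang1 200, Ang2 500).
#' @param seed RNG seed for the LHS sampler and bootstrap (default 0).
#' @param boot Bootstrap resamples for confidence intervals (default 1000).
#' @param ci Confidence level (default 0.95).
#' @param ranges Optional named list of absolute \code{c(lo, hi)} ranges per
#'   key, overriding the fold-range construction (used for analytic test
#'   functions whose factors are not positive parameters).
#' @return A config list.
#' @export
sensitivity_config <- function(keys, lo = 0.2, hi = 5,
                               sampler = c("lhs", "sobol_sequence"),
                               skip = 1000, leap = 100, n_base = 256,
                               outputs = c("pVEGFR2", "pTie2", "pSrc",
                                           "ppAkt"),
                               readout_time = 5,
                               stimulus = c(VEGF = 10, Ang1 = 200,
                                            Ang2 = 500),
                               seed = 0, boot = 1000, ci = 0.95,
                               ranges = NULL) {
  stopifnot(lo > 0, hi > lo, n_base >= 2, ci > 0, ci < 1)
  list(keys = keys, lo = lo, hi = hi, sampler = match.arg(sampler),
       skip = skip, leap = leap, n_base = n_base, outputs = outputs,
       readout_time = readout_time, stimulus = stimulus, seed = seed,
       boot = boot, ci = ci, ranges = ranges)
}

#' Sample the parameter space for Saltelli-type Sobol estimation
#'
#' Draws the base matrices A and B (each \code{n_base x d}) plus the
#' cross matrices AB_i (A with column i from B) and BA_i needed by the
#' first- and second-order estimators.  LHS sampling is stratified uniform
#' per dimension and seeded; the Sobol-sequence sampler uses the configured
#' skip and leap on a 2d-dimensional sequence.
#'
#' @param config A [sensitivity_config()].
#' @param baseline Named numeric baseline parameter values for the keys.
#' @param second_order Also return the BA_i matrices.
#' @return List with \code{A}, \code{B}, \code{AB} (list over i), optionally
#'   \code{BA}, and \code{u01} (the raw uniform design).
#' @export
sample_parameter_space <- function(config, baseline,
                                   second_order = FALSE) {
  d <- length(config$keys)
  n <- config$n_base
  if (config$sampler == "lhs") {
    set.seed(config$seed)
    u <- lhs::randomLHS(n, 2 * d)
  } else {
    u <- sobol_sequence(n, 2 * d, skip = config$skip, leap = config$leap)
  }
  if (!is.null(config$ranges)) {
    lo <- vapply(config$ranges[config$keys], `[[`, numeric(1), 1)
    hi <- vapply(config$ranges[config$keys], `[[`, numeric(1), 2)
  } else {
    base <- baseline[config$keys]
    lo <- config$lo * base
    hi <- config$hi * base
  }
  scale_block <- function(ublock) {
    m <- sweep(ublock, 2, hi - lo, `*`)
    m <- sweep(m, 2, lo, `+`)
    colnames(m) <- config$keys
    m
  }
  A <- scale_block(u[, seq_len(d), drop = FALSE])
  B <- scale_block(u[, d + seq_len(d), drop = FALSE])
  AB <- lapply(seq_len(d), function(i) { M <- A; M[, i] <- B[, i]; M })
  out <- list(A = A, B = B, AB = AB, u01 = u)
  if (second_order)
    out$BA <- lapply(seq_len(d), function(i) { M <- B; M[, i] <- A[, i]; M })
  out
}

#' Model evaluator for sensitivity analysis
#'
#' Returns a vectorized evaluator mapping a matrix of parameter rows to a
#' matrix of outputs: each row is substituted into the baseline parameter
#' set, the ligand-free model is re-equilibrated (fixed horizon), the
#' configured stimulus is applied at t = 0, and the configured observables
#' are read out at \code{readout_time} minutes.
#'
#' @param model A [network_model()].
#' @param params Baseline [parameter_set()].
#' @param config A [sensitivity_config()].
#' @param eq_time Pre-equilibration horizon in minutes (default 500).
#' @param rtol,atol Integrator tolerances (relaxed relative to the
#'   simulator defaults because tens of thousands of runs are integrated;
#'   the BDF integrator is used for the same reason).
#' @return Function \code{(theta_matrix) -> output_matrix}.
#' @export
sensitivity_evaluator <- function(model, params, config, eq_time = 800,
                                  rtol = 1e-4, atol = 1e-6) {
  doses <- config$stimulus
  doses <- doses[doses > 0]
  # encoding template: species/stoichiometry/observable structure is fixed
  # across samples; only the resolved rate constants change
  template <- compile_rhs(model, params)
  vals0 <- params$values
  key_pos <- match(config$keys, names(vals0))
  k_idx <- lapply(model$rules, function(r) match(r$k, names(vals0)))
  km_idx <- vapply(model$rules, function(r)
    if (is.null(r$Km)) NA_integer_ else match(r$Km, names(vals0)),
    integer(1))
  s1_idx <- vapply(model$rules, function(r) {
    ss <- r$sat %||% list()
    if (length(ss) >= 1) match(ss[[1]][2], names(vals0)) else NA_integer_
  }, integer(1))
  s2_idx <- vapply(model$rules, function(r) {
    ss <- r$sat %||% list()
    if (length(ss) >= 2) match(ss[[2]][2], names(vals0)) else NA_integer_
  }, integer(1))
  scales <- vapply(model$rules, `[[`, numeric(1), "scale")
  init_idx <- vapply(model$species, function(s)
    if (is.na(s$init_key)) NA_integer_ else match(s$init_key, names(vals0)),
    integer(1))
  ow <- lapply(config$outputs, function(o) model$observables[[o]])
  oidx <- lapply(ow, function(w) match(names(w), model$species_names))
  # stimulus: named ligand doses resolved to species increments per sample
  function(theta) {
    if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1,
                                             dimnames = list(NULL,
                                                             config$keys))
    out <- matrix(NA_real_, nrow = nrow(theta),
                  ncol = length(config$outputs),
                  dimnames = list(NULL, config$outputs))
    pp <- params
    times <- c(0, eq_time, eq_time + config$readout_time)
    for (r in seq_len(nrow(theta))) {
      vals <- vals0
      vals[key_pos] <- theta[r, ]
      pp$values <- vals
      res <- tryCatch({
        enc <- template$enc
        for (j in seq_along(k_idx)) enc$k[j] <- prod(vals[k_idx[[j]]]) *
            scales[j]
        ok <- !is.na(km_idx); enc$Km[ok] <- vals[km_idx[ok]]
        ok <- !is.na(s1_idx); enc$sat1K[ok] <- vals[s1_idx[ok]]
        ok <- !is.na(s2_idx); enc$sat2K[ok] <- vals[s2_idx[ok]]
        y0 <- numeric(length(init_idx))
        ok <- !is.na(init_idx)
        y0[ok] <- vals[init_idx[ok]]
        names(y0) <- model$species_names
        .Call(C_load_model, enc)
        eq <- deSolve::vode(y = y0, times = c(0, eq_time),
                            func = "C_derivs", parms = numeric(0),
                            dllname = "endonet", initfunc = "C_initmod",
                            rtol = rtol, atol = atol, maxsteps = 100000)
        if (attr(eq, "istate")[1] < 0 || anyNA(eq))
          stop("integration failure")
        y <- eq[nrow(eq), -1]
        names(y) <- model$species_names
        add <- unlist(lapply(names(doses), function(lg)
          ligand_addition(lg, unname(doses[[lg]]), pp)))
        y[names(add)] <- y[names(add)] + add
        sim <- deSolve::vode(y = y, times = c(0, config$readout_time),
                             func = "C_derivs", parms = numeric(0),
                             dllname = "endonet", initfunc = "C_initmod",
                             rtol = rtol, atol = atol, maxsteps = 100000)
        if (attr(sim, "istate")[1] < 0 || anyNA(sim))
          stop("integration failure")
        yT <- sim[nrow(sim), -1]
        vapply(seq_along(ow), function(k)
          sum(ow[[k]] * yT[oidx[[k]]]), numeric(1))
      }, error = function(e) rep(NA_real_, length(config$outputs)))
      out[r, ] <- res
    }
    out
  }
}

# product-moment (correlation-form) first-order estimator; used inside the
# second-order synergy scheme so that its quasi-random bias cancels against
# the product-moment V_ij term
.saltelli_first <- function(fA, fB, fABi) {
  V <- stats::var(c(fA, fB))
  if (V == 0) return(NA_real_)
  mean(fB * (fABi - fA)) / V
}

# Jansen difference-form first-order estimator; lower variance, used for the
# reported main-effect indices
.jansen_first <- function(fA, fB, fABi) {
  V <- stats::var(c(fA, fB))
  if (V == 0) return(NA_real_)
  1 - mean((fB - fABi)^2) / (2 * V)
}

#' First-order (main-effect) Sobol indices
#'
#' Jansen-type estimator \eqn{S_i = 1 - mean((f_B - f_{AB_i})^2) / (2 V(Y))}
#' from the (A, B, AB_i) design, with percentile bootstrap confidence
#' intervals over sample rows.  Total evaluations: \code{n_base * (d + 2)}.
#'
#' @param model_evaluator Function (matrix of parameter rows) -> matrix of
#'   outputs, e.g. from [sensitivity_evaluator()]; analytic test functions
#'   can be wrapped directly.
#' @param config A [sensitivity_config()].
#' @param baseline Named numeric baseline values for \code{config$keys}.
#' @return A \code{sobol_result}: \code{main_effect} (3-d array parameter x
#'   (index, ci_lo, ci_hi) x output), \code{n_runs}, \code{outputs},
#'   \code{undefined} (outputs with zero variance), \code{config}.
#' @export
sobol_first_order <- function(model_evaluator, config, baseline) {
  d <- length(config$keys)
  s <- sample_parameter_space(config, baseline)
  fA <- model_evaluator(s$A)
  fB <- model_evaluator(s$B)
  fAB <- lapply(s$AB, model_evaluator)
  n_runs <- as.integer(config$n_base * (d + 2))
  outs <- config$outputs
  main <- array(NA_real_, dim = c(d, 3, length(outs)),
                dimnames = list(config$keys, c("index", "ci_lo", "ci_hi"),
                                outs))
  undefined <- character(0)
  set.seed(config$seed + 1)
  boot_idx <- matrix(sample.int(config$n_base,
                                config$n_base * config$boot,
                                replace = TRUE),
                     nrow = config$boot)
  alpha <- (1 - config$ci) / 2
  for (o in outs) {
    a <- fA[, o]; b <- fB[, o]
    if (anyNA(c(a, b)) || stats::var(c(a, b)) == 0) {
      undefined <- c(undefined, o)
      next
    }
    for (i in seq_len(d)) {
      abi <- fAB[[i]][, o]
      main[i, "index", o] <- .jansen_first(a, b, abi)
      bs <- vapply(seq_len(config$boot), function(r) {
        ii <- boot_idx[r, ]
        .jansen_first(a[ii], b[ii], abi[ii])
      }, numeric(1))
      main[i, c("ci_lo", "ci_hi"), o] <-
        stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
    }
  }
  structure(list(main_effect = main, n_runs = n_runs, outputs = outs,
                 undefined = undefined, config = config,
                 second_order = NULL),
            class = "sobol_result")
}

#' Second-order (synergy) Sobol indices
#'
#' Estimates the pairwise interaction indices
#' \eqn{S_{ij} = V_{ij}/V - S_i - S_j} using the full Saltelli scheme with
#' the BA_i matrices: \eqn{V^{c}_{ij} = mean(f_{BA_i} f_{AB_j}) -
#' mean(f_A f_B)}.  The matrix is symmetric with a zero diagonal.  Total
#' evaluations: \code{n_base * (2d + 2)}.
#'
#' @inheritParams sobol_first_order
#' @return A \code{sobol_result} whose \code{second_order} is a list of
#'   symmetric d x d matrices, one per output.
#' @export
sobol_second_order <- function(model_evaluator, config, baseline) {
  d <- length(config$keys)
  s <- sample_parameter_space(config, baseline, second_order = TRUE)
  fA <- model_evaluator(s$A)
  fB <- model_evaluator(s$B)
  fAB <- lapply(s$AB, model_evaluator)
  fBA <- lapply(s$BA, model_evaluator)
  n_runs <- as.integer(config$n_base * (2 * d + 2))
  outs <- config$outputs
  second <- list()
  undefined <- character(0)
  for (o in outs) {
    a <- fA[, o]; b <- fB[, o]
    M <- matrix(0, d, d, dimnames = list(config$keys, config$keys))
    if (anyNA(c(a, b)) || stats::var(c(a, b)) == 0) {
      undefined <- c(undefined, o)
      M[] <- NA_real_
      second[[o]] <- M
      next
    }
    V <- stats::var(c(a, b))
    Si <- vapply(seq_len(d), function(i)
      .saltelli_first(a, b, fAB[[i]][, o]), numeric(1))
    f0sq <- mean(c(a, b))^2
    for (i in seq_len(d)) for (j in seq_len(d)) {
      if (j <= i) next
      Vij <- mean(fBA[[i]][, o] * fAB[[j]][, o]) - f0sq
      M[i, j] <- M[j, i] <- Vij / V - Si[i] - Si[j]
    }
    second[[o]] <- M
  }
  structure(list(main_effect = NULL, n_runs = n_runs, outputs = outs,
                 undefined = undefined, config = config,
                 second_order = second),
            class = "sobol_result")
}

#' Top-k parameters by main-effect index
#'
#' @param result A \code{sobol_result} from [sobol_first_order()].
#' @param output Output name.
#' @param k Number of parameters (k greater than the parameter count returns
#'   all; k = 0 returns an empty frame).
#' @return Data frame (parameter, index, ci_lo, ci_hi) in descending index
#'   order; ties broken lexicographically by key.
#' @export
rank_top <- function(result, output, k = 10) {
  if (is.null(result$main_effect) || !output %in% result$outputs)
    stop("result does not contain main-effect indices for '", output, "'")
  m <- result$main_effect[, , output, drop = FALSE]
  df <- data.frame(parameter = rownames(m), index = m[, "index", 1],
                   ci_lo = m[, "ci_lo", 1], ci_hi = m[, "ci_hi", 1],
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$index, df$parameter), ]
  utils::head(df, n = max(k, 0))
}

#' Export Sobol indices as a tidy data frame
#'
#' @param result A \code{sobol_result}.
#' @return Long-format data frame \code{(parameter, output, index, ci_lo,
#'   ci_hi)} for first-order results, or \code{(parameter_i, parameter_j,
#'   output, index)} for second-order results.
#' @export
sobol_tidy <- function(result) {
  if (!is.null(result$main_effect)) {
    do.call(rbind, lapply(result$outputs, function(o) {
      m <- result$main_effect[, , o, drop = FALSE]
      data.frame(parameter = rownames(m), output = o,
                 index = m[, "index", 1], ci_lo = m[, "ci_lo", 1],
                 ci_hi = m[, "ci_hi", 1], row.names = NULL)
    }))
  } else {
    do.call(rbind, lapply(names(result$second_order), function(o) {
      M <- result$second_order[[o]]
      ij <- which(upper.tri(M), arr.ind = TRUE)
      data.frame(parameter_i = rownames(M)[ij[, 1]],
                 parameter_j = colnames(M)[ij[, 2]], output = o,
                 index = M[ij], row.names = NULL)
    }))
  }
}

#' L2 star discrepancy of a point set
#'
#' Warnock's closed form; used to verify that the quasi-random sampler
#' covers the unit cube more uniformly than i.i.d. uniform draws.
#'
#' @param x Matrix of points in the unit hypercube.
#' @return Scalar discrepancy.
#' @export
l2_star_discrepancy <- function(x) {
  n <- nrow(x); d <- ncol(x)
  t1 <- 3^(-d)
  t2 <- (2 / n) * sum(apply((1 - x^2) / 2, 1, prod))
  cross <- matrix(1, n, n)
  for (j in seq_len(d))
    cross <- cross * (1 - outer(x[, j], x[, j], pmax))
  t3 <- sum(cross) / n^2
  sqrt(t1 - t2 + t3)
}
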