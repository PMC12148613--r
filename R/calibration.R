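#' Define a calibration dataset
#'
#' Normalized measurements (or synthetic emulations thereof) of one observable
#' under one stimulation protocol, as a function of time or of ligand dose.
#'
#' @param id Dataset identifier.
#' @param observable Model observable the data map to.
#' @param abscissa \code{"time"} (minutes) or \code{"dose"} (ng/mL).
#' @param points Data frame with columns \code{abscissa}, \code{value},
#'   \code{weight} (weights default to 1/n so each dataset contributes
#'   equally to the objective).
#' @param normalization \code{"percent_of_max"}, \code{"fold_of_baseline"} or
#'   \code{"absolute"}.
#' @param protocol For time datasets, a [stimulus_protocol()]; ignored for
#'   dose datasets.
#' @param ligand For dose datasets, the swept ligand.
#' @param summary,at_time,t_end For dose datasets, how each dose is summarized
#'   (see [dose_response()]).
#' @param source Provenance tag (\code{"synthetic"}, \code{"experimental"}).
#' @param truth Optional fingerprint of the generating parameter set.
#' @return A \code{calibration_dataset}.
#' @export
calibration_dataset <- function(id, observable, abscissa, points,
                                normalization, protocol = NULL,
                                ligand = NULL, summary = "at_time",
                                at_time = 15, t_end = 60,
                                source = "synthetic", truth = NULL) {
  stopifnot(abscissa %in% c("time", "dose"),
            normalization %in% c("percent_of_max", "fold_of_baseline",
                                 "absolute"))
  if (!all(c("abscissa", "value", "weight") %in% names(points)))
    stop("points must have columns abscissa, value, weight")
  if (nrow(points) < 2) stop("a dataset needs at least two points")
  if (any(points$weight <= 0)) stop("weights must be positive")
  if (abscissa == "time" && is.null(protocol))
    stop("time datasets need a protocol")
  if (abscissa == "dose" && is.null(ligand))
    stop("dose datasets need a ligand")
  structure(list(id = id, observable = observable, abscissa = abscissa,
                 points = points, normalization = normalization,
                 protocol = protocol, ligand = ligand, summary = summary,
                 at_time = at_time, t_end = t_end, source = source,
                 truth = truth),
            class = "calibration_dataset")
}

#' Normalize a simulated curve the way a dataset is normalized
#'
#' \code{percent_of_max} divides by the maximum of the prediction over the
#' dataset's abscissae and multiplies by 100 (scale-invariant);
#' \code{fold_of_baseline} divides by the pre-stimulus baseline value;
#' \code{absolute} passes through.
#'
#' @param pred Numeric vector of raw predictions at the dataset abscissae.
#' @param dataset A [calibration_dataset()].
#' @param baseline Pre-stimulus value of the observable (required for
#'   \code{fold_of_baseline}).
#' @return Normalized prediction vector.
#' @export
normalize_prediction <- function(pred, dataset, baseline = NULL) {
  switch(dataset$normalization,
    percent_of_max = {
      mx <- max(pred)
      if (mx == 0) rep(0, length(pred)) else 100 * pred / mx
    },
    fold_of_baseline = {
      if (is.null(baseline)) stop("fold_of_baseline needs a baseline value")
      if (baseline == 0) stop("zero baseline with fold normalization")
      pred / baseline
    },
    absolute = pred)
}

#' Predict a dataset from the model
#'
#' @param model,params As elsewhere.
#' @param dataset A [calibration_dataset()].
#' @param y0 Pre-equilibrated baseline state (computed if missing).
#' @return Normalized prediction vector at the dataset's abscissae.
#' @export
predict_dataset <- function(model, params, dataset, y0 = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  y0 <- y0 %||% pre_equilibrate(model, params)
  base_obs <- observe(model, y0)[1, dataset$observable]
  if (dataset$abscissa == "time") {
    tt <- dataset$points$abscissa
    pr <- dataset$protocol
    grid <- sort(unique(c(tt, pr$output_grid[1],
                          pr$output_grid[length(pr$output_grid)])))
    pr$output_grid <- grid
    res <- simulate_protocol(model, params, pr, y0 = y0, rtol = rtol,
                             atol = atol)
    pred <- res$observables[match(tt, res$times), dataset$observable]
  } else {
    dr <- dose_response(model, params, dataset$ligand,
                        dataset$points$abscissa, dataset$observable,
                        summary = dataset$summary, at_time = dataset$at_time,
                        t_end = dataset$t_end, y0 = y0, rtol = rtol,
                        atol = atol)
    pred <- dr$values
  }
  normalize_prediction(pred, dataset, baseline = base_obs)
}

#' Sum-of-squared-errors objective
#'
#' \eqn{\sum_{datasets} \sum_{points} w (normalized prediction - value)^2}.
#' A candidate for which the simulation fails (integration failure,
#' non-convergent pre-equilibration) contributes a large finite penalty.
#'
#' @param params A [parameter_set()] candidate.
#' @param datasets List of [calibration_dataset()] objects.
#' @param model A [network_model()].
#' @param penalty Value returned on simulation failure (default 1e9).
#' @param rtol,atol Integrator tolerances (relaxed defaults: the objective
#'   is evaluated thousands of times during a fit).
#' @return Non-negative scalar.
#' @export
objective_sse <- function(params, datasets, model, penalty = 1e9,
                          rtol = 1e-6, atol = 1e-9) {
  if (!length(datasets)) stop("empty dataset list")
  y0 <- tryCatch(pre_equilibrate(model, params, tol = 1e-7),
                 error = function(e) NULL)
  if (is.null(y0)) return(penalty)
  base_obs <- observe(model, y0)[1, ]
  total <- 0

  # time-course datasets sharing a protocol are simulated once on the union
  # of their sample grids
  is_tc <- vapply(datasets, function(d) d$abscissa == "time", logical(1))
  tc <- datasets[is_tc]
  if (length(tc)) {
    keyof <- function(d) {
      ev <- vapply(d$protocol$events, function(e)
        paste(e$time, e$ligand, e$amount, e$unit %||% "ng/mL"),
        character(1))
      paste(c(ev, d$protocol$t_end), collapse = "|")
    }
    groups <- split(tc, vapply(tc, keyof, character(1)))
    for (g in groups) {
      tt <- sort(unique(c(0, unlist(lapply(g, function(d)
        d$points$abscissa)))))
      pr <- g[[1]]$protocol
      pr$output_grid <- tt
      res <- tryCatch(simulate_protocol(model, params, pr, y0 = y0,
                                        rtol = rtol, atol = atol),
                      error = function(e) NULL)
      if (is.null(res)) return(penalty)
      for (d in g) {
        raw <- res$observables[match(d$points$abscissa, res$times),
                               d$observable]
        pred <- tryCatch(
          normalize_prediction(raw, d,
                               baseline = base_obs[[d$observable]]),
          error = function(e) NULL)
        if (is.null(pred) || anyNA(pred)) return(penalty)
        total <- total + sum(d$points$weight * (pred - d$points$value)^2)
      }
    }
  }
  for (d in datasets[!is_tc]) {
    pred <- tryCatch(predict_dataset(model, params, d, y0 = y0,
                                     rtol = rtol, atol = atol),
                     error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) return(penalty)
    total <- total + sum(d$points$weight * (pred - d$points$value)^2)
  }
  total
}

#' Generalized pattern search minimizer
#'
#' Derivative-free coordinate poll search: at mesh size \eqn{\Delta} the 2n
#' coordinate directions are polled in lexicographic parameter order (+ then
#' -), the first improving poll is accepted (opportunistic polling), the mesh
#' expands by 2 on success and contracts by 0.5 on failure, and the search
#' stops when the mesh falls below \code{mesh_tol} or the evaluation budget
#' is exhausted.  Deterministic given the initial point and poll ordering.
#'
#' @param objective Function of a numeric vector.
#' @param lower,upper Finite bound vectors; polls are projected onto them.
#' @param init Initial point within bounds.
#' @param control List: \code{step0} initial mesh (default 0.25; small
#'   enough that curved-valley objectives keep making progress within
#'   typical budgets), \code{expand}
#'   (2), \code{contract} (0.5), \code{mesh_tol} (1e-6), \code{max_eval}
#'   (5000), \code{poll} (\code{"restart"}, the strict scheme, or
#'   \code{"cyclic"}, which continues the lexicographic scan past an
#'   accepted poll and suits higher-dimensional fits).
#' @return List: \code{par}, \code{objective}, \code{trace} (data frame of
#'   iteration, mesh, objective), \code{n_eval}, \code{converged}.
#' @export
pattern_search <- function(objective, lower, upper, init,
                           control = list()) {
  ctl <- utils::modifyList(list(step0 = 0.25, expand = 2, contract = 0.5,
                                mesh_tol = 1e-6, max_eval = 5000,
                                poll = "restart"), control)
  n <- length(init)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower > upper)) stop("invalid bounds")
  if (any(init < lower - 1e-12) || any(init > upper + 1e-12))
    stop("init outside bounds")
  ord <- if (!is.null(names(init))) order(names(init)) else seq_len(n)
  x <- pmin(pmax(init, lower), upper)
  f <- objective(x)
  n_eval <- 1L
  mesh <- ctl$step0
  tr_it <- 0L; tr_mesh <- mesh; tr_f <- f
  iter <- 0L
  cyclic <- identical(ctl$poll, "cyclic")
  while (mesh >= ctl$mesh_tol && n_eval < ctl$max_eval) {
    improved <- FALSE
    for (i in ord) {
      # "restart": the poll round ends at the first improving direction and
      # a new round starts around the new incumbent (strict pattern search).
      # "cyclic": the scan continues with the next coordinate around the
      # updated incumbent, which avoids starving later coordinates on
      # higher-dimensional calibration problems.
      for (s in c(1, -1)) {
        cand <- x
        cand[i] <- min(max(x[i] + s * mesh, lower[i]), upper[i])
        if (cand[i] == x[i]) next
        fc <- objective(cand)
        n_eval <- n_eval + 1L
        if (fc < f) {
          x <- cand; f <- fc; improved <- TRUE
          break
        }
        if (n_eval >= ctl$max_eval) break
      }
      if ((improved && !cyclic) || n_eval >= ctl$max_eval) break
    }
    mesh <- mesh * (if (improved) ctl$expand else ctl$contract)
    iter <- iter + 1L
    tr_it <- c(tr_it, iter); tr_mesh <- c(tr_mesh, mesh); tr_f <- c(tr_f, f)
  }
  list(par = x, objective = f,
       trace = data.frame(iteration = tr_it, mesh = tr_mesh,
                          objective = tr_f),
       n_eval = n_eval, converged = mesh < ctl$mesh_tol)
}

#' Fit model parameters to calibration datasets
#'
#' Wraps [objective_sse()] and [pattern_search()].  The search runs in log10
#' parameter space; per-parameter bounds default to [0.01x, 100x] of the
#' initial estimate.
#'
#' @param model A [network_model()].
#' @param datasets List of [calibration_dataset()] objects.
#' @param params Starting [parameter_set()] (also supplies fixed values).
#' @param fitted_keys Character vector of keys to fit (empty vector returns
#'   the initial objective with no iterations).
#' @param bounds Optional named list of \code{c(lo, hi)} on the natural scale.
#' @param init Optional named numeric vector of initial values for the fitted
#'   keys (defaults to their values in \code{params}).
#' @param control Passed to [pattern_search()]; default initial mesh 0.5
#'   log10 units.
#' @param out_dir Optional directory: writes \code{trace.csv} and
#'   \code{fitted_params.json} audit files.
#' @return A \code{calibration_result}: \code{best_params},
#'   \code{objective}, \code{trace}, \code{fitted_keys}, \code{fixed_keys},
#'   \code{converged}, \code{n_eval}.
#' @export
fit <- function(model, datasets, params, fitted_keys, bounds = NULL,
                init = NULL, control = list(), out_dir = NULL) {
  if (!length(datasets)) stop("empty dataset list")
  bad <- setdiff(fitted_keys, names(params$values))
  if (length(bad)) stop("unknown fitted key(s): ", paste(bad, collapse = ", "))
  ctl <- utils::modifyList(list(step0 = 0.5, poll = "cyclic"), control)
  if (!length(fitted_keys)) {
    f0 <- objective_sse(params, datasets, model)
    return(structure(list(best_params = params, objective = f0,
                          trace = data.frame(iteration = 0L, mesh = NA_real_,
                                             objective = f0),
                          fitted_keys = character(0),
                          fixed_keys = names(params$values),
                          converged = TRUE, n_eval = 1L),
                     class = "calibration_result"))
  }
  init <- init %||% params$values[fitted_keys]
  init <- init[fitted_keys]
  bounds <- bounds %||% stats::setNames(
    lapply(fitted_keys, function(k) c(init[[k]] / 100, init[[k]] * 100)),
    fitted_keys)
  lo <- log10(vapply(bounds[fitted_keys], `[[`, numeric(1), 1))
  hi <- log10(vapply(bounds[fitted_keys], `[[`, numeric(1), 2))
  obj <- function(xlog) {
    cand <- update_params(params,
                          stats::setNames(10^xlog, fitted_keys))
    objective_sse(cand, datasets, model)
  }
  res <- pattern_search(obj, lo, hi,
                        stats::setNames(log10(unname(init)), fitted_keys),
                        control = ctl)
  best <- update_params(params, stats::setNames(10^res$par, fitted_keys))
  out <- structure(list(best_params = best, objective = res$objective,
                        trace = res$trace, fitted_keys = fitted_keys,
                        fixed_keys = setdiff(names(params$values),
                                             fitted_keys),
                        converged = res$converged, n_eval = res$n_eval),
                   class = "calibration_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$trace, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(best$values[fitted_keys]),
                         file.path(out_dir, "fitted_params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> objective ", signif(x$objective, 6),
      if (x$converged) " (converged)" else " (budget exhausted)", "; ",
      length(x$fitted_keys), " fitted keys; ", x$n_eval,
      " objective evaluations\n", sep = "")
  invisible(x)
}
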