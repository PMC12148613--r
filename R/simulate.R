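#' Convert a ligand dose to species additions
#'
#' Doses in ng/mL are converted to nM via the configured molecular weights
#' (VEGF-A dimer 45 kDa, Ang1 tetramer 280 kDa, Ang2 monomer 66 kDa).  An
#' Ang2 dose is split into the configured dimer/trimer/tetramer multimer
#' mixture (mole fractions of multimer species, default 0.4/0.3/0.3).
#'
#' @param ligand \code{"VEGF"}, \code{"Ang1"}, \code{"Ang2"} or any species
#'   name (then \code{amount} must already be in nM).
#' @param amount Dose.
#' @param params A [parameter_set()].
#' @param unit \code{"ng/mL"} (default for the named ligands) or \code{"nM"}.
#' @return Named numeric vector of species concentration increments (nM).
#' @export
ligand_addition <- function(ligand, amount, params, unit = "ng/mL") {
  if (amount < 0) stop("negative dose rejected")
  v <- params$values
  if (unit == "nM" || !ligand %in% c("VEGF", "Ang1", "Ang2"))
    return(stats::setNames(amount, ligand))
  switch(ligand,
    VEGF = c(VEGF = amount / v[["mw_vegf"]]),
    Ang1 = c(Ang1 = amount / v[["mw_ang1_tetramer"]]),
    Ang2 = {
      mono <- amount / v[["mw_ang2_monomer"]]
      f <- c(v[["ang2_frac_dimer"]], v[["ang2_frac_trimer"]],
             v[["ang2_frac_tetramer"]])
      nmult <- mono / sum(f * c(2, 3, 4))
      c(A2d = f[1] * nmult, A2t = f[2] * nmult, A2q = f[3] * nmult)
    })
}

#' Define a stimulation protocol
#'
#' @param events List of events, each \code{list(time =, ligand =, amount =,
#'   unit =)} with time in minutes and amount in ng/mL (default) or nM.
#'   Ligand additions are instantaneous concentration jumps.
#' @param inhibitors List of [inhibitor_spec()] objects.
#' @param t_end Simulation horizon in minutes.
#' @param output_grid Output times (minutes), sorted ascending; defaults to
#'   0 to \code{t_end} at 0.5-minute resolution.
#' @return A \code{stimulus_protocol} object.
#' @export
stimulus_protocol <- function(events = list(), inhibitors = list(),
                              t_end = 120,
                              output_grid = seq(0, t_end, by = 0.5)) {
  for (e in events) {
    if (e$time < 0 || e$time > t_end)
      stop("event time must lie in [0, t_end]")
    if (e$amount < 0) stop("negative dose rejected")
  }
  if (is.unsorted(output_grid)) stop("output_grid must be sorted ascending")
  for (i in inhibitors) stopifnot(inherits(i, "inhibitor_spec"))
  structure(list(events = events, inhibitors = inhibitors, t_end = t_end,
                 output_grid = output_grid), class = "stimulus_protocol")
}

.inhibitor_scales <- function(inhibitors, t) {
  sc <- c(Src = 1, Axl = 1, Akt = 1, VEGFR2 = 1)
  for (i in inhibitors)
    if (t >= i$apply_time) sc[i$target] <- sc[i$target] * (1 - i$fraction)
  sc
}

.integrate_segment <- function(enc, y0, times, rtol, atol) {
  .Call(C_load_model, enc)
  out <- deSolve::lsoda(y = y0, times = times, func = "C_derivs",
                        parms = numeric(0), dllname = "endonet",
                        initfunc = "C_initmod", rtol = rtol, atol = atol,
                        maxsteps = 100000)
  if (attr(out, "istate")[1] < 0 || anyNA(out))
    stop("integration failure near t = ",
         signif(out[nrow(out), 1], 6), " min; state snapshot: ",
         paste(signif(out[nrow(out), -1], 4), collapse = ", "))
  out
}

#' Run a stimulation protocol
#'
#' Integrates the model piecewise between protocol events with a stiff
#' adaptive solver (lsoda, rtol 1e-8 / atol 1e-10 by default).  Ligand
#' additions are instantaneous concentration jumps; inhibitors scale their
#' target's tagged rate constants by (1 - fraction) from their application
#' time onward.  Output at an event time reports the post-event state.
#'
#' @param model A [network_model()] (inhibitors registered on the model are
#'   honored in addition to those in the protocol).
#' @param params A [parameter_set()].
#' @param protocol A [stimulus_protocol()].
#' @param y0 Initial state (typically from [pre_equilibrate()]); defaults to
#'   [initial_state()].
#' @param rtol,atol Integrator tolerances.
#' @return A \code{simulation_result}: \code{times}, \code{states} (time x
#'   species), \code{observables} (time x observable), \code{protocol},
#'   \code{params_hash}.
#' @export
simulate_protocol <- function(model, params, protocol, y0 = NULL,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  inhibitors <- c(model$inhibitors, protocol$inhibitors)
  grid <- protocol$output_grid
  y <- y0 %||% initial_state(model, params)
  y <- y[model$species_names]

  breaks <- sort(unique(c(0, protocol$t_end,
                          vapply(protocol$events, `[[`, numeric(1), "time"),
                          vapply(inhibitors, `[[`, numeric(1),
                                 "apply_time"))))
  breaks <- breaks[breaks >= 0 & breaks <= protocol$t_end]
  states <- matrix(NA_real_, nrow = length(grid),
                   ncol = length(model$species_names),
                   dimnames = list(NULL, model$species_names))

  for (si in seq_len(length(breaks) - 1)) {
    t0 <- breaks[si]; t1 <- breaks[si + 1]
    # apply events scheduled at t0
    for (e in protocol$events)
      if (e$time == t0) {
        add <- ligand_addition(e$ligand, e$amount, params,
                               e$unit %||% "ng/mL")
        bad <- setdiff(names(add), model$species_names)
        if (length(bad)) stop("protocol adds unknown species: ",
                              paste(bad, collapse = ", "))
        y[names(add)] <- y[names(add)] + add
      }
    sc <- .inhibitor_scales(inhibitors, t0)
    cm <- compile_rhs(model, params, inhibitor_scale = sc)
    in_seg <- which(grid >= t0 & grid <= t1)
    seg_times <- sort(unique(c(t0, grid[in_seg], t1)))
    if (length(seg_times) < 2) seg_times <- c(t0, t1)
    out <- .integrate_segment(cm$enc, y, seg_times, rtol, atol)
    keep <- match(grid[in_seg], out[, 1])
    ok <- !is.na(keep)
    states[in_seg[ok], ] <- out[keep[ok], -1, drop = FALSE]
    y <- out[nrow(out), -1]
    names(y) <- model$species_names
  }
  # grid points at interior breaks get the post-event segment value; the final
  # loop iteration already wrote them (later segments overwrite earlier ones)
  obsm <- observe(model, states)
  structure(list(times = grid, states = states, observables = obsm,
                 protocol = protocol,
                 params_hash = params_fingerprint(params)),
            class = "simulation_result")
}

#' Pre-equilibrate the ligand-free model
#'
#' Integrates the ligand-free system until every component satisfies
#' \code{|dx/dt| / (|x| + eps) < tol}, so that constitutive processes
#' (receptor turnover, constitutive Tie2/Tie1 shedding against clearance) are
#' at flux balance before a stimulus is applied.
#'
#' @param model A [network_model()].
#' @param params A [parameter_set()].
#' @param tol Relative steady-state tolerance (default 1e-8).
#' @param max_time Maximum simulated time (minutes) before giving up.
#' @param chunk Integration chunk length between convergence checks.
#' @param eps Softening constant in the convergence criterion (nM).
#' @param rtol,atol Integrator tolerances.
#' @return Named steady-state vector.
#' @export
pre_equilibrate <- function(model, params, tol = 1e-8, max_time = 5000,
                            chunk = 250, eps = 1e-4, rtol = 1e-10,
                            atol = 1e-12) {
  cm <- compile_rhs(model, params)
  y <- initial_state(model, params)
  t <- 0
  repeat {
    dy <- cm$rhs(y)
    rel <- abs(dy) / (abs(y) + eps)
    if (max(rel) < tol) return(y)
    if (t >= max_time)
      stop("pre-equilibration did not converge within ", max_time,
           " min; worst species: ", names(which.max(rel)),
           " (relative rate ", signif(max(rel), 3), ")")
    out <- .integrate_segment(cm$enc, y, c(t, t + chunk), rtol, atol)
    y <- out[nrow(out), -1]
    names(y) <- model$species_names
    t <- t + chunk
  }
}

#' Peak of a time course
#'
#' @param times Numeric vector of times (minutes).
#' @param values Observable values on the same grid.
#' @return \code{list(peak =, t_peak =)}; for a constant series the time is
#'   the first grid point.
#' @export
summarize_peak <- function(times, values) {
  if (all(is.na(values))) stop("all-NaN time course")
  i <- which.max(values)
  if (length(unique(stats::na.omit(values))) == 1) i <- 1L
  list(peak = values[i], t_peak = times[i])
}

#' Refined peak of a simulated observable
#'
#' Finds the coarse-grid maximum, then re-simulates the protocol on a
#' 0.1-minute grid in a window around it and reports the refined peak.
#'
#' @param model,params,protocol,y0 As in [simulate_protocol()].
#' @param observable Observable name.
#' @param window Half-width (minutes) of the refinement window.
#' @param after Only consider times >= \code{after} (e.g. the stimulus time).
#' @return \code{list(peak =, t_peak =)}.
#' @export
peak_refined <- function(model, params, protocol, observable, y0 = NULL,
                         window = 1, after = 0) {
  res <- simulate_protocol(model, params, protocol, y0 = y0)
  sel <- res$times >= after
  coarse <- summarize_peak(res$times[sel], res$observables[sel, observable])
  lo <- max(after, coarse$t_peak - window)
  hi <- min(protocol$t_end, coarse$t_peak + window)
  fine <- protocol
  fine$output_grid <- seq(lo, hi, by = 0.1)
  resf <- simulate_protocol(model, params, fine, y0 = y0)
  summarize_peak(resf$times, resf$observables[, observable])
}

.derived_readout <- function(readout, model, params, result, idx) {
  v <- params$values
  if (readout == "shed_fold") {
    pr2 <- result$observables[idx, "pVEGFR2"]
    sat <- pr2 / (v[["kmshedvegf"]] + pr2)
    return(1 + v[["kshedvegf"]] * sat / v[["kshedtie2"]])
  }
  stop("unknown readout '", readout, "'")
}

#' Dose-response sweep
#'
#' Runs one simulation per dose from a shared pre-equilibrated baseline and
#' summarizes a readout per dose.  The plateau is the value at the largest
#' dose; the saturation dose is the smallest dose whose response covers 95%
#' of the baseline-to-plateau span.
#'
#' @param model,params As elsewhere.
#' @param ligand Ligand name for [ligand_addition()].
#' @param doses Numeric vector of doses (ng/mL), ascending.
#' @param readout An observable name or the derived readout
#'   \code{"shed_fold"} (instantaneous Tie2-shedding rate-constant fold over
#'   constitutive).
#' @param summary \code{"at_time"} (default, value at \code{at_time}),
#'   \code{"peak"}, or \code{"steady"} (value at \code{t_end}).
#' @param at_time Readout time for \code{summary = "at_time"}.
#' @param t_end Simulation horizon per dose.
#' @param costim Optional named list \code{list(ligand =, amount =)} added at
#'   t = 0 alongside the swept ligand (e.g. Ang1 co-stimulation).
#' @param y0 Optional pre-equilibrated baseline (computed if missing).
#' @return A \code{dose_response_curve}: doses, values, readout, plateau,
#'   saturation_dose.
#' @export
dose_response <- function(model, params, ligand, doses, readout,
                          summary = "at_time", at_time = 60, t_end = 60,
                          costim = NULL, y0 = NULL, rtol = 1e-8,
                          atol = 1e-10) {
  if (any(doses < 0)) stop("doses must be >= 0")
  if (is.unsorted(doses)) stop("doses must be ascending")
  known <- c(names(model$observables), "shed_fold")
  if (!readout %in% known) stop("unknown readout '", readout, "'")
  y0 <- y0 %||% pre_equilibrate(model, params)
  # peak summaries need a dense grid; point summaries do not
  grid <- if (summary == "peak") seq(0, t_end, by = 0.5) else
    sort(unique(c(0, at_time, t_end)))
  vals <- vapply(doses, function(d) {
    ev <- list(list(time = 0, ligand = ligand, amount = d))
    if (!is.null(costim))
      ev <- c(ev, list(list(time = 0, ligand = costim$ligand,
                            amount = costim$amount)))
    pr <- stimulus_protocol(ev, t_end = t_end, output_grid = grid)
    res <- simulate_protocol(model, params, pr, y0 = y0, rtol = rtol,
                             atol = atol)
    idx <- switch(summary,
                  at_time = which.min(abs(res$times - at_time)),
                  steady = length(res$times),
                  peak = NA_integer_,
                  stop("unknown summary mode"))
    if (summary == "peak") {
      if (readout == "shed_fold") {
        f <- vapply(seq_along(res$times), function(i)
          .derived_readout("shed_fold", model, params, res, i), numeric(1))
        max(f)
      } else summarize_peak(res$times, res$observables[, readout])$peak
    } else if (readout == "shed_fold") {
      .derived_readout("shed_fold", model, params, res, idx)
    } else {
      res$observables[idx, readout]
    }
  }, numeric(1))
  v0 <- vals[1]
  vp <- vals[length(vals)]
  target <- v0 + 0.95 * (vp - v0)
  sat <- if (vp >= v0) doses[which(vals >= target)[1]] else
    doses[which(vals <= target)[1]]
  structure(list(doses = doses, values = vals, readout = readout,
                 summary = summary, plateau = vp, baseline = v0,
                 saturation_dose = sat),
            class = "dose_response_curve")
}

#' Fingerprint of a parameter set
#' @param params A [parameter_set()].
#' @return Short hex digest string.
#' @export
params_fingerprint <- function(params) {
  s <- paste(names(params$values), signif(params$values, 12),
             collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
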