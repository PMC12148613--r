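#' Signed percent change
#'
#' @param perturbed,baseline Numeric summaries.
#' @return \code{100 * (perturbed - baseline) / baseline}.
#' @export
percent_change <- function(perturbed, baseline) {
  if (any(baseline == 0)) stop("zero baseline")
  100 * (perturbed - baseline) / baseline
}

.src_sequestration <- function(result) {
  1 - (result$observables[, "freeSrc"] + result$observables[, "pSrc"]) /
    result$observables[, "totalSrc"]
}

#' VEGF crosstalk dose sweep
#'
#' Sweeps VEGF and reports the three crosstalk readouts: (i) cumulative Ang2
#' released from Weibel-Palade bodies over the simulation window, (ii) the
#' Tie2-shedding rate fold over constitutive shedding (peak enhancement), and
#' (iii) percent inhibition of Ang1-induced Tie2 activation (steady pTie2
#' under Ang1 co-stimulation, relative to the VEGF = 0 case).  Each curve
#' carries its plateau and the smallest dose reaching 95% of the plateau.
#'
#' @param model,params As elsewhere.
#' @param doses VEGF doses in ng/mL (default 0-20, 41 points).
#' @param ang1_costim Ang1 co-stimulation dose for the pTie2-inhibition
#'   curve (ng/mL, default 200).
#' @param window Simulation window per dose (minutes, default 60).
#' @return List with \code{ang2_release}, \code{shedding_fold},
#'   \code{ptie2_inhibition} (each a \code{dose_response_curve}) and a
#'   \code{summary} list of plateaus and saturation doses.
#' @export
run_crosstalk_sweep <- function(model, params, doses = seq(0, 20, by = 0.5),
                                ang1_costim = 200, window = 60) {
  y0 <- pre_equilibrate(model, params)
  a2 <- dose_response(model, params, "VEGF", doses, "Ang2_released",
                      summary = "at_time", at_time = window,
                      t_end = window, y0 = y0)
  sh <- dose_response(model, params, "VEGF", doses, "shed_fold",
                      summary = "peak", t_end = window, y0 = y0)
  pt <- dose_response(model, params, "VEGF", doses, "pTie2",
                      summary = "at_time", at_time = window,
                      t_end = window,
                      costim = list(ligand = "Ang1", amount = ang1_costim),
                      y0 = y0)
  inhib <- percent_change(pt$values, pt$values[1]) * -1
  inhib_curve <- structure(list(doses = doses, values = inhib,
                                readout = "pTie2_inhibition",
                                summary = "at_time",
                                plateau = inhib[length(inhib)],
                                baseline = inhib[1],
                                saturation_dose = NA_real_),
                           class = "dose_response_curve")
  t95 <- 0.95 * inhib_curve$plateau
  inhib_curve$saturation_dose <- doses[which(inhib >= t95)[1]]
  list(ang2_release = a2, shedding_fold = sh,
       ptie2_inhibition = inhib_curve,
       summary = list(
         ang2_release_plateau = a2$plateau,
         ang2_release_saturation_dose = a2$saturation_dose,
         shedding_fold_plateau = sh$plateau,
         shedding_fold_saturation_dose = sh$saturation_dose,
         ptie2_inhibition_plateau = inhib_curve$plateau,
         ang1_costim = ang1_costim))
}

#' Chronic versus acute Ang1 protection
#'
#' Compares VEGF-induced Src and VE-cadherin activation with and without
#' Ang1 stimulation.  Modes: \code{"pre_25min"} (Ang1 at t = 0, VEGF added
#' after \code{pre_time} minutes), \code{"simultaneous"} (both at t = 0),
#' \code{"ang1_only"} (no VEGF).  Peaks of the transient readouts are taken
#' after the VEGF addition and compared to a VEGF-only baseline run.
#'
#' @param model,params As elsewhere.
#' @param mode One of \code{"pre_25min"}, \code{"simultaneous"},
#'   \code{"ang1_only"}.
#' @param ang1_dose,vegf_dose Doses in ng/mL (defaults 50/50).
#' @param pre_time Pre-stimulation duration for \code{"pre_25min"}
#'   (minutes).
#' @param horizon Post-VEGF simulation window (minutes).
#' @return A \code{protection_report} list: peak pSrc and pVEcad (and their
#'   percent reductions versus the VEGF-only baseline), the pTie2 and
#'   Src-sequestration trajectories, and the sequestration fraction at
#'   \code{pre_time}.
#' @export
run_ang1_protection <- function(model, params,
                                mode = c("pre_25min", "simultaneous",
                                         "ang1_only"),
                                ang1_dose = 50, vegf_dose = 50,
                                pre_time = 25, horizon = 60) {
  mode <- match.arg(mode)
  if (ang1_dose < 0 || vegf_dose < 0) stop("doses must be >= 0")
  y0 <- pre_equilibrate(model, params)
  grid_of <- function(t_end) seq(0, t_end, by = 0.5)

  base_pr <- stimulus_protocol(
    list(list(time = 0, ligand = "VEGF", amount = vegf_dose)),
    t_end = horizon, output_grid = grid_of(horizon))
  base <- simulate_protocol(model, params, base_pr, y0 = y0)
  base_psrc <- summarize_peak(base$times, base$observables[, "pSrc"])
  base_pvec <- summarize_peak(base$times, base$observables[, "pVEcad"])

  events <- switch(mode,
    pre_25min = list(list(time = 0, ligand = "Ang1", amount = ang1_dose),
                     list(time = pre_time, ligand = "VEGF",
                          amount = vegf_dose)),
    simultaneous = list(list(time = 0, ligand = "Ang1",
                             amount = ang1_dose),
                        list(time = 0, ligand = "VEGF",
                             amount = vegf_dose)),
    ang1_only = list(list(time = 0, ligand = "Ang1", amount = ang1_dose)))
  vegf_at <- if (mode == "pre_25min") pre_time else 0
  t_end <- vegf_at + horizon
  pr <- stimulus_protocol(events, t_end = t_end,
                          output_grid = grid_of(t_end))
  res <- simulate_protocol(model, params, pr, y0 = y0)
  sel <- res$times >= vegf_at
  psrc <- summarize_peak(res$times[sel], res$observables[sel, "pSrc"])
  pvec <- summarize_peak(res$times[sel], res$observables[sel, "pVEcad"])
  seq_frac <- .src_sequestration(res)
  structure(list(
    mode = mode, ang1_dose = ang1_dose, vegf_dose = vegf_dose,
    max_pSrc = psrc$peak, max_pVEcad = pvec$peak,
    baseline_max_pSrc = base_psrc$peak,
    baseline_max_pVEcad = base_pvec$peak,
    pSrc_reduction_pct = if (mode == "ang1_only") NA_real_ else
      -percent_change(psrc$peak, base_psrc$peak),
    pVEcad_reduction_pct = if (mode == "ang1_only") NA_real_ else
      -percent_change(pvec$peak, base_pvec$peak),
    pTie2_trajectory = data.frame(time = res$times,
                                  pTie2 = res$observables[, "pTie2"]),
    sequestration_trajectory = data.frame(time = res$times,
                                          fraction = seq_frac),
    sequestration_at_pre_time =
      seq_frac[which.min(abs(res$times - pre_time))],
    baseline_hash = base$params_hash),
    class = "protection_report")
}

#' Inhibitor x Ang1 combination grid
#'
#' For each (inhibition level, Ang1 dose) pair, simulates simultaneous Ang1
#' plus a background VEGF stimulus with the inhibitor applied at t = 0 and
#' reports pTie2, pSrc, ppAkt and pErk at the readout time.
#'
#' @param model,params As elsewhere.
#' @param target Inhibitor target: \code{"Src"}, \code{"Axl"}, \code{"Akt"}
#'   or \code{"VEGFR2"}.
#' @param levels Inhibition fractions (default 0, 0.2, ..., 1).
#' @param ang1_doses Ang1 doses in ng/mL (default 0, 50, 200, 500).
#' @param vegf_background Background VEGF dose in ng/mL (default 50; the
#'   grid is reported against this pro-permeability background).
#' @param readout_time Minutes post-stimulation (default 15).
#' @return Data frame with one row per grid point: target, level,
#'   ang1_dose, vegf_background, readout_time, pTie2, pSrc, ppAkt, pErk.
#' @export
run_combination_grid <- function(model, params, target,
                                 levels = seq(0, 1, by = 0.2),
                                 ang1_doses = c(0, 50, 200, 500),
                                 vegf_background = 50, readout_time = 15) {
  if (!target %in% c("Src", "Axl", "Akt", "VEGFR2"))
    stop("unknown target '", target, "'")
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  y0 <- pre_equilibrate(model, params)
  grid <- seq(0, readout_time, by = 0.5)
  rows <- list()
  for (lv in levels) for (a1 in ang1_doses) {
    events <- list(list(time = 0, ligand = "VEGF",
                        amount = vegf_background))
    if (a1 > 0)
      events <- c(events, list(list(time = 0, ligand = "Ang1",
                                    amount = a1)))
    inh <- if (lv > 0) list(inhibitor_spec(target, lv, 0)) else list()
    pr <- stimulus_protocol(events, inhibitors = inh,
                            t_end = readout_time, output_grid = grid)
    res <- simulate_protocol(model, params, pr, y0 = y0)
    i <- length(res$times)
    rows[[length(rows) + 1]] <- data.frame(
      target = target, level = lv, ang1_dose = a1,
      vegf_background = vegf_background, readout_time = readout_time,
      pTie2 = res$observables[i, "pTie2"],
      pSrc = res$observables[i, "pSrc"],
      ppAkt = res$observables[i, "ppAkt"],
      pErk = res$observables[i, "pErk"])
  }
  do.call(rbind, rows)
}
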