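#' Noise model for synthetic datasets
#'
#' @param kind \code{"multiplicative_lognormal"} (scale interpreted as a
#'   coefficient of variation) or \code{"additive_gaussian"} (scale is the
#'   standard deviation on the normalized scale).
#' @param scale Non-negative noise scale; 0 disables noise.
#' @param seed RNG seed.
#' @return A \code{noise_model} list.
#' @export
noise_model <- function(kind = c("multiplicative_lognormal",
                                 "additive_gaussian"),
                        scale = 0.05, seed = 0) {
  kind <- match.arg(kind)
  if (scale < 0) stop("noise scale must be >= 0")
  structure(list(kind = kind, scale = scale, seed = seed),
            class = "noise_model")
}

.apply_noise <- function(values, noise) {
  if (is.null(noise) || noise$scale == 0) return(values)
  if (noise$kind == "multiplicative_lognormal") {
    sdlog <- sqrt(log(1 + noise$scale^2))
    values * stats::rlnorm(length(values), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
  } else {
    values + stats::rnorm(length(values), sd = noise$scale)
  }
}

#' Generate a synthetic time-course calibration dataset
#'
#' Simulates the model at the truth parameters, samples the observable at
#' the requested times, applies the noise model to the raw signal and then
#' normalizes, so that declared normalizations hold exactly (a
#' percent-of-max dataset always has maximum 100).
#'
#' @param model,params Model and truth parameters.
#' @param protocol A [stimulus_protocol()].
#' @param observable Observable name.
#' @param sample_times Times (minutes) within the protocol horizon.
#' @param noise A [noise_model()] (or NULL for noise-free).
#' @param normalization Dataset normalization mode.
#' @param id Dataset id.
#' @param y0 Optional pre-equilibrated state.
#' @return A [calibration_dataset()] tagged with the truth fingerprint.
#' @export
generate_timecourse_dataset <- function(model, params, protocol, observable,
                                        sample_times, noise = noise_model(),
                                        normalization = "percent_of_max",
                                        id = observable, y0 = NULL) {
  if (!length(sample_times)) stop("empty sample times")
  if (any(sample_times < 0 | sample_times > protocol$t_end))
    stop("sample times outside protocol horizon")
  y0 <- y0 %||% pre_equilibrate(model, params)
  pr <- protocol
  pr$output_grid <- sort(unique(sample_times))
  res <- simulate_protocol(model, params, pr, y0 = y0)
  raw <- res$observables[match(sample_times, res$times), observable]
  base <- observe(model, y0)[1, observable]
  noisy <- .apply_noise(raw, noise)
  vals <- normalize_prediction(noisy, list(normalization = normalization),
                               baseline = if (normalization ==
                                              "fold_of_baseline")
                                 .apply_noise(base, noise) else base)
  calibration_dataset(
    id = id, observable = observable, abscissa = "time",
    points = data.frame(abscissa = sample_times, value = vals,
                        weight = 1 / length(sample_times)),
    normalization = normalization, protocol = protocol,
    source = "synthetic", truth = params_fingerprint(params))
}

#' Generate a synthetic dose-response calibration dataset
#'
#' @inheritParams generate_timecourse_dataset
#' @param ligand Swept ligand name.
#' @param doses Doses in ng/mL.
#' @param summary,at_time,t_end Per-dose summary (see [dose_response()]).
#' @return A [calibration_dataset()].
#' @export
generate_dose_response_dataset <- function(model, params, ligand, doses,
                                           observable,
                                           noise = noise_model(),
                                           normalization = "percent_of_max",
                                           summary = "at_time",
                                           at_time = 15, t_end = 60,
                                           id = paste0(observable, "_vs_",
                                                       ligand),
                                           y0 = NULL) {
  y0 <- y0 %||% pre_equilibrate(model, params)
  dr <- dose_response(model, params, ligand, doses, observable,
                      summary = summary, at_time = at_time, t_end = t_end,
                      y0 = y0)
  base <- observe(model, y0)[1, observable]
  noisy <- .apply_noise(dr$values, noise)
  vals <- normalize_prediction(noisy, list(normalization = normalization),
                               baseline = base)
  calibration_dataset(
    id = id, observable = observable, abscissa = "dose",
    points = data.frame(abscissa = doses, value = vals,
                        weight = 1 / length(doses)),
    normalization = normalization, ligand = ligand, summary = summary,
    at_time = at_time, t_end = t_end,
    source = "synthetic", truth = params_fingerprint(params))
}

#' Generate the packaged calibration fixture suite
#'
#' Emulates the statistical structure of the study's calibration surfaces:
#' VEGF-axis time courses (receptor dynamics and downstream signaling under
#' 50 ng/mL VEGF), Tie-axis time courses and Ang1/Ang2 dose responses, a
#' VEGF dose response of S1P activation, Ang2 release, and constitutive and
#' VEGF-enhanced soluble-Tie2 accumulation.  Truth parameters default to the
#' packaged calibrated set, so the suite doubles as a regression baseline.
#'
#' @param seed Seed controlling all noise draws.
#' @param model,params Model and truth parameters.
#' @param cv Noise coefficient of variation (multiplicative lognormal;
#'   default 0.05).
#' @param dir Optional directory: datasets are written as CSV + JSON sidecar
#'   pairs plus a manifest via [write_dataset_csv()].
#' @return Invisible list with \code{datasets} (named list of
#'   [calibration_dataset()]), \code{truth} fingerprint and \code{manifest}.
#' @export
make_fixture_suite <- function(seed = 0, model = NULL, params = NULL,
                               cv = 0.05, dir = NULL) {
  params <- params %||% default_parameters()
  model <- model %||% build_default_model(params = params)
  set.seed(seed)
  y0 <- pre_equilibrate(model, params)
  nm <- if (cv > 0) noise_model(scale = cv, seed = seed) else NULL

  tc_times <- c(0, 2, 5, 10, 15, 20, 30, 45, 60)
  vegf_pr <- stimulus_protocol(
    list(list(time = 0, ligand = "VEGF", amount = 50)), t_end = 60)
  ang1_pr <- stimulus_protocol(
    list(list(time = 0, ligand = "Ang1", amount = 50)), t_end = 60)
  none_pr <- stimulus_protocol(list(), t_end = 120)

  ds <- list()
  addtc <- function(obs, pr, id, times = tc_times,
                    normalization = "percent_of_max") {
    ds[[id]] <<- generate_timecourse_dataset(
      model, params, pr, obs, times, noise = nm,
      normalization = normalization, id = id, y0 = y0)
  }
  # VEGF-axis receptor and downstream panels
  for (obs in c("VEGFR2_total", "VEGFR2_surface", "pVEGFR2", "pSrc",
                "pAxl", "ppAkt", "peNOS", "pPLCg", "Ca_cyto", "pErk"))
    addtc(obs, vegf_pr, paste0("vegf_tc_", obs))
  # Tie-axis panels
  for (obs in c("pTie2", "ppAkt", "RhoA_GTP", "mDiaSrc_complex"))
    addtc(obs, ang1_pr, paste0("ang1_tc_", obs))
  # Tie2 activation dose responses
  ang_doses <- c(0, 12.5, 25, 50, 100, 200, 400, 800)
  ds$ang1_dr_pTie2 <- generate_dose_response_dataset(
    model, params, "Ang1", ang_doses, "pTie2", noise = nm,
    at_time = 15, t_end = 15, id = "ang1_dr_pTie2", y0 = y0)
  ds$ang2_dr_pTie2 <- generate_dose_response_dataset(
    model, params, "Ang2", ang_doses, "pTie2", noise = nm,
    at_time = 15, t_end = 15, id = "ang2_dr_pTie2", y0 = y0)
  # crosstalk calibration surfaces
  ds$vegf_dr_S1P <- generate_dose_response_dataset(
    model, params, "VEGF", c(0, 1, 2, 4, 6, 8, 10, 15, 20), "S1P",
    noise = nm, at_time = 30, t_end = 30, id = "vegf_dr_S1P", y0 = y0)
  addtc("Ang2_released", vegf_pr, "vegf_tc_Ang2_released")
  addtc("sTie2", none_pr, "constitutive_tc_sTie2",
        times = c(0, 15, 30, 60, 90, 120),
        normalization = "fold_of_baseline")
  vegf_pr_long <- stimulus_protocol(
    list(list(time = 0, ligand = "VEGF", amount = 50)), t_end = 120)
  ds$vegf_tc_sTie2 <- generate_timecourse_dataset(
    model, params, vegf_pr_long, "sTie2", c(0, 15, 30, 60, 90, 120),
    noise = nm, normalization = "fold_of_baseline", id = "vegf_tc_sTie2",
    y0 = y0)

  manifest <- list(seed = seed, cv = cv,
                   truth = params_fingerprint(params),
                   n_datasets = length(ds), ids = names(ds))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (d in ds) write_dataset_csv(d, dir)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(datasets = ds, truth = params_fingerprint(params),
                 manifest = manifest))
}

#' Designated identifiable parameter subset for recovery experiments
#'
#' Eight kinetic constants with direct leverage on the shapes of the fixture
#' suite's curves (receptor internalization, Src dephosphorylation,
#' junctional translocation, RhoA activation, Ang1/Ang2 binding, WPB
#' release, VE-PTP activity).
#'
#' @return Character vector of parameter keys.
#' @export
identifiable_subset <- function() {
  c("kintpvegfr2", "kdephossrc", "ktransloctie2", "kactrhoa",
    "konang1tie2", "koffang2tie2", "krelang2", "kcatveptp")
}
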