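.resolve_k <- function(rule, values) {
  prod(values[rule$k]) * rule$scale
}

#' Compile a network model into an ODE right-hand side
#'
#' Encodes the model into the flat representation consumed by the compiled
#' derivative routine.  The state ordering is the species order of the model
#' (\code{model$species_names}); this ordering is fixed and shared by all
#' simulation output.
#'
#' @param model A [network_model()].
#' @param params A [parameter_set()].
#' @param inhibitor_scale Optional named numeric vector mapping a target tag
#'   (e.g. \code{"Src"}) to a multiplicative activity factor applied to every
#'   rule carrying that tag (used by the simulator to realize inhibitors as
#'   piecewise-constant scalings).
#' @return A \code{compiled_model} object.  \code{$rhs} is a function
#'   \code{(state, t)} returning the derivative vector; \code{$rates} returns
#'   the per-reaction rate vector.
#' @export
compile_rhs <- function(model, params, inhibitor_scale = NULL) {
  stopifnot(inherits(model, "network_model"),
            inherits(params, "parameter_set"))
  spn <- model$species_names
  obn <- names(model$observables)
  sidx <- stats::setNames(seq_along(spn), spn)
  oidx <- stats::setNames(seq_along(obn), obn)
  code_of <- function(nm) {
    if (is.null(nm)) return(0L)
    if (nm %in% spn) return(sidx[[nm]])
    if (nm %in% obn) return(-oidx[[nm]])
    stop("unknown species/observable reference '", nm, "'")
  }
  vals <- params$values
  missing <- setdiff(unlist(lapply(model$rules, function(r)
    c(r$k, r$Km, vapply(r$sat %||% list(), `[[`, character(1), 2)))),
    names(vals))
  if (length(missing))
    stop("missing parameter key(s): ", paste(unique(missing), collapse = ", "))

  nr <- length(model$rules)
  law <- integer(nr); r1 <- integer(nr); r2 <- integer(nr)
  mod <- integer(nr); sat1 <- integer(nr); sat2 <- integer(nr)
  k <- numeric(nr); Km <- numeric(nr); sat1K <- numeric(nr)
  sat2K <- numeric(nr)
  st_ptr <- integer(nr + 1); st_idx <- integer(0); st_coef <- numeric(0)

  for (j in seq_len(nr)) {
    r <- model$rules[[j]]
    law[j] <- match(r$law, c("mass_action", "michaelis_menten",
                             "saturating_hill")) - 1L
    rs <- names(r$reactants)
    if (length(rs) >= 1) r1[j] <- sidx[[rs[1]]]
    if (length(rs) >= 2) r2[j] <- sidx[[rs[2]]]
    mod[j] <- code_of(r$modifier)
    kk <- .resolve_k(r, vals)
    if (!is.null(inhibitor_scale) && !is.na(r$tag) &&
        r$tag %in% names(inhibitor_scale))
      kk <- kk * inhibitor_scale[[r$tag]]
    k[j] <- kk
    Km[j] <- if (!is.null(r$Km)) vals[[r$Km]] else 0
    ss <- r$sat %||% list()
    if (length(ss) >= 1) { sat1[j] <- code_of(ss[[1]][1])
                           sat1K[j] <- vals[[ss[[1]][2]]] }
    if (length(ss) >= 2) { sat2[j] <- code_of(ss[[2]][1])
                           sat2K[j] <- vals[[ss[[2]][2]]] }
    net <- model$stoichiometry[, j]
    nz <- which(net != 0)
    st_ptr[j + 1] <- st_ptr[j] + length(nz)
    st_idx <- c(st_idx, as.integer(nz))
    st_coef <- c(st_coef, net[nz])
  }

  enc_obs_idx <- integer(0); enc_obs_w <- numeric(0)
  obs_ptr <- integer(length(obn) + 1)
  for (o in seq_along(obn)) {
    w <- model$observables[[o]]
    obs_ptr[o + 1] <- obs_ptr[o] + length(w)
    enc_obs_idx <- c(enc_obs_idx, sidx[names(w)])
    enc_obs_w <- c(enc_obs_w, unname(w))
  }

  enc <- list(n_sp = length(spn), n_obs = length(obn), n_rxn = nr,
              obs_ptr = obs_ptr, obs_idx = enc_obs_idx, obs_w = enc_obs_w,
              law = law, r1 = r1, r2 = r2, mod = mod,
              sat1 = sat1, sat2 = sat2, k = k, Km = Km,
              sat1K = sat1K, sat2K = sat2K,
              st_ptr = st_ptr, st_idx = st_idx, st_coef = st_coef)

  obj <- list(enc = enc, species = spn, observables = obn,
              rule_names = model$rule_names, model = model, params = params)
  obj$load <- function() invisible(.Call(C_load_model, enc))
  obj$rhs <- function(state, t = 0) {
    .Call(C_load_model, enc)
    stats::setNames(.Call(C_eval_rhs, as.numeric(t), as.numeric(state)), spn)
  }
  obj$rates <- function(state, t = 0) {
    .Call(C_load_model, enc)
    stats::setNames(.Call(C_eval_rates, as.numeric(t), as.numeric(state)),
                    model$rule_names)
  }
  class(obj) <- "compiled_model"
  obj
}

#' Initial state vector of a model
#'
#' @param model A [network_model()].
#' @param params A [parameter_set()].
#' @return Named numeric vector in the model's state ordering; species without
#'   an initial-value key start at zero.
#' @export
initial_state <- function(model, params) {
  y <- vapply(model$species, function(s) {
    if (is.na(s$init_key)) 0 else params$values[[s$init_key]]
  }, numeric(1))
  stats::setNames(y, model$species_names)
}

#' Observable values for a state matrix
#'
#' @param model A [network_model()].
#' @param states Matrix (time x species) or a single named state vector.
#' @return Matrix (time x observable).
#' @export
observe <- function(model, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1,
                                             dimnames = list(NULL,
                                                             names(states)))
  out <- sapply(model$observables, function(w)
    as.numeric(states[, names(w), drop = FALSE] %*% unname(w)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1, dimnames = list(NULL,
                                                 names(model$observables)))
  out
}
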