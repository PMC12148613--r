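# Shared fixtures: small analytic models and a cached default model.

# two-species reversible binding A + B <-> C
toy_binding_model <- function(kon = 1, koff = 1, A0 = 1, B0 = 1) {
  p <- parameter_set(c(kon = kon, koff = koff, A_0 = A0, B_0 = B0))
  sp <- list(
    species_def("A", "extracellular", c(A = 1), "A_0"),
    species_def("B", "surface", c(B = 1), "B_0"),
    species_def("C", "surface", c(A = 1, B = 1)))
  rx <- list(reaction_rule("bind", c(A = 1, B = 1), c(C = 1),
                           k = "kon", rev = "koff"))
  list(model = network_model(sp, rx, list(C = c(C = 1)), p), params = p)
}

# independent brute-force derivative: walks the rule list and sums terms,
# sharing no code with the compiled evaluator
naive_rhs <- function(model, params, state) {
  v <- params$values
  obsval <- function(nm) {
    if (nm %in% model$species_names) return(state[[nm]])
    w <- model$observables[[nm]]
    sum(w * state[names(w)])
  }
  dy <- stats::setNames(numeric(length(state)), names(state))
  for (r in model$rules) {
    k <- prod(v[r$k]) * r$scale
    rate <- switch(r$law,
      mass_action = {
        x <- k
        for (s in names(r$reactants)) x <- x * state[[s]]
        if (!is.null(r$modifier)) x <- x * max(obsval(r$modifier), 0)
        x
      },
      michaelis_menten = {
        S <- max(state[[names(r$reactants)[1]]], 0)
        k * max(obsval(r$modifier), 0) * S / (v[[r$Km]] + S)
      },
      saturating_hill = {
        S <- max(state[[names(r$reactants)[1]]], 0)
        k * S / (v[[r$Km]] + S)
      })
    for (s in r$sat %||% list()) {
      X <- max(obsval(s[[1]]), 0)
      rate <- rate * X / (v[[s[[2]]]] + X)
    }
    for (s in names(r$reactants)) dy[s] <- dy[s] - r$reactants[[s]] * rate
    for (s in names(r$products)) dy[s] <- dy[s] + r$products[[s]] * rate
  }
  dy
}

# random small mass-action/enzymatic network for oracle tests
random_small_model <- function(seed) {
  set.seed(seed)
  ns <- sample(3:6, 1)
  spn <- paste0("S", seq_len(ns))
  pvals <- c(stats::setNames(stats::runif(ns, 0.1, 2),
                             paste0(spn, "_0")),
             stats::setNames(stats::runif(8, 0.05, 3), paste0("k", 1:8)),
             Km1 = stats::runif(1, 0.1, 1))
  p <- parameter_set(pvals)
  sp <- lapply(spn, function(s)
    species_def(s, "cytosol", init_key = paste0(s, "_0")))
  rx <- list()
  for (j in 1:4) {
    ij <- sample(ns, 2)
    rx[[length(rx) + 1]] <- reaction_rule(
      paste0("ma", j),
      stats::setNames(c(1L, 1L), spn[ij]),
      stats::setNames(1L, spn[sample(ns, 1)]),
      k = paste0("k", j), non_conserving = TRUE)
  }
  ij <- sample(ns, 2)
  rx[[length(rx) + 1]] <- reaction_rule(
    "mm1", stats::setNames(1L, spn[ij[1]]),
    stats::setNames(1L, spn[ij[2]]), law = "michaelis_menten",
    k = "k5", Km = "Km1", modifier = spn[sample(ns, 1)],
    non_conserving = TRUE)
  rx[[length(rx) + 1]] <- reaction_rule(
    "sat1", stats::setNames(1L, spn[1]), stats::setNames(1L, spn[ns]),
    k = "k6", sat = list(c(spn[sample(ns, 1)], "Km1")),
    non_conserving = TRUE)
  list(model = network_model(sp, rx,
                             list(tot = stats::setNames(rep(1, ns), spn)),
                             p),
       params = p)
}

# cached default model and pre-equilibrated state (built once per test run)
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- default_parameters()
      m <- build_default_model(params = p)
      y0 <- pre_equilibrate(m, p)
      cache <<- list(model = m, params = p, y0 = y0)
    }
    cache
  }
})

ishigami_fn <- function(M)
  matrix(sin(M[, 1]) + 7 * sin(M[, 2])^2 + 0.1 * M[, 3]^4 * sin(M[, 1]),
         ncol = 1, dimnames = list(NULL, "y"))

ishigami_analytic <- function(a = 7, b = 0.1) {
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  c((b * pi^4 / 5 + b^2 * pi^8 / 50 + 0.5) / V, (a^2 / 8) / V, 0)
}
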