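// Reaction-network right-hand side for the endothelial signaling model.
//
// The R side encodes a compiled model (species, sparse observables, reaction
// rate laws and sparse stoichiometry) into flat integer/double vectors; this
// translation unit holds one such encoded model in a static context and
// exposes
//   - C_load_model(list):    install an encoded model,
//   - C_eval_rhs(t, y):      derivative vector (R-callable),
//   - C_eval_rates(t, y):    per-reaction rates (R-callable, diagnostics),
//   - C_derivs / C_initmod:  the deSolve compiled-function interface.
//
// Rate-law codes: 0 mass action  k * [r1] * [r2] * mod
//                 1 enzymatic    k * E * max(S,0) / (Km + max(S,0)), E = mod
//                 2 Vmax form    k * max(S,0) / (Km + max(S,0))
// Every law is additionally multiplied by up to two saturating factors
// X/(K+X).  Modifier / saturation codes: 0 none, +i species i, -j observable j
// (1-based).  Negative state values are tolerated: saturating and enzymatic
// terms clamp their argument at zero so the derivative stays finite.

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <vector>

namespace {

struct Net {
  int n_sp = 0, n_obs = 0, n_rxn = 0;
  std::vector<int> obs_ptr, obs_idx;
  std::vector<double> obs_w;
  std::vector<int> law, r1, r2, mod, sat1, sat2;
  std::vector<double> k, Km, sat1K, sat2K;
  std::vector<int> st_ptr, st_idx;
  std::vector<double> st_coef;
  // scratch
  std::vector<double> obsval, rate;
  bool loaded = false;
};

Net G;

inline double pos(double x) { return x > 0 ? x : 0; }

SEXP elt(SEXP lst, const char *name) {
  SEXP names = Rf_getAttrib(lst, R_NamesSymbol);
  for (int i = 0; i < Rf_length(lst); ++i)
    if (strcmp(CHAR(STRING_ELT(names, i)), name) == 0)
      return VECTOR_ELT(lst, i);
  Rf_error("encoded model is missing component '%s'", name);
  return R_NilValue;
}

void as_int(SEXP lst, const char *name, std::vector<int> &out) {
  SEXP x = PROTECT(Rf_coerceVector(elt(lst, name), INTSXP));
  out.assign(INTEGER(x), INTEGER(x) + Rf_length(x));
  UNPROTECT(1);
}

void as_dbl(SEXP lst, const char *name, std::vector<double> &out) {
  SEXP x = PROTECT(Rf_coerceVector(elt(lst, name), REALSXP));
  out.assign(REAL(x), REAL(x) + Rf_length(x));
  UNPROTECT(1);
}

void compute_obs(const double *y) {
  for (int o = 0; o < G.n_obs; ++o) {
    double s = 0;
    for (int p = G.obs_ptr[o]; p < G.obs_ptr[o + 1]; ++p)
      s += G.obs_w[p] * y[G.obs_idx[p] - 1];
    G.obsval[o] = s;
  }
}

inline double refval(int code, const double *y) {
  if (code > 0) return y[code - 1];
  if (code < 0) return G.obsval[-code - 1];
  return 1.0;
}

void compute_rates(const double *y) {
  compute_obs(y);
  for (int j = 0; j < G.n_rxn; ++j) {
    double r = G.k[j];
    switch (G.law[j]) {
    case 0:
      if (G.r1[j]) r *= y[G.r1[j] - 1];
      if (G.r2[j]) r *= y[G.r2[j] - 1];
      if (G.mod[j]) r *= pos(refval(G.mod[j], y));
      break;
    case 1: {
      double S = pos(y[G.r1[j] - 1]);
      double E = G.mod[j] ? pos(refval(G.mod[j], y)) : 1.0;
      r *= E * S / (G.Km[j] + S);
      break;
    }
    default: {
      double S = pos(y[G.r1[j] - 1]);
      r *= S / (G.Km[j] + S);
      break;
    }
    }
    if (G.sat1[j]) {
      double X = pos(refval(G.sat1[j], y));
      r *= X / (G.sat1K[j] + X);
    }
    if (G.sat2[j]) {
      double X = pos(refval(G.sat2[j], y));
      r *= X / (G.sat2K[j] + X);
    }
    G.rate[j] = r;
  }
}

void fill_dy(const double *y, double *dy) {
  compute_rates(y);
  for (int i = 0; i < G.n_sp; ++i) dy[i] = 0;
  for (int j = 0; j < G.n_rxn; ++j) {
    double r = G.rate[j];
    for (int p = G.st_ptr[j]; p < G.st_ptr[j + 1]; ++p)
      dy[G.st_idx[p] - 1] += G.st_coef[p] * r;
  }
}

}  // namespace

extern "C" {

SEXP C_load_model(SEXP enc) {
  G.n_sp = Rf_asInteger(elt(enc, "n_sp"));
  G.n_obs = Rf_asInteger(elt(enc, "n_obs"));
  G.n_rxn = Rf_asInteger(elt(enc, "n_rxn"));
  as_int(enc, "obs_ptr", G.obs_ptr);
  as_int(enc, "obs_idx", G.obs_idx);
  as_dbl(enc, "obs_w", G.obs_w);
  as_int(enc, "law", G.law);
  as_int(enc, "r1", G.r1);
  as_int(enc, "r2", G.r2);
  as_int(enc, "mod", G.mod);
  as_int(enc, "sat1", G.sat1);
  as_int(enc, "sat2", G.sat2);
  as_dbl(enc, "k", G.k);
  as_dbl(enc, "Km", G.Km);
  as_dbl(enc, "sat1K", G.sat1K);
  as_dbl(enc, "sat2K", G.sat2K);
  as_int(enc, "st_ptr", G.st_ptr);
  as_int(enc, "st_idx", G.st_idx);
  as_dbl(enc, "st_coef", G.st_coef);
  G.obsval.assign(G.n_obs, 0.0);
  G.rate.assign(G.n_rxn, 0.0);
  G.loaded = true;
  return R_NilValue;
}

SEXP C_eval_rhs(SEXP t, SEXP y) {
  (void)t;
  if (!G.loaded) Rf_error("no model loaded");
  if (Rf_length(y) != G.n_sp) Rf_error("state length mismatch");
  SEXP yy = PROTECT(Rf_coerceVector(y, REALSXP));
  SEXP dy = PROTECT(Rf_allocVector(REALSXP, G.n_sp));
  fill_dy(REAL(yy), REAL(dy));
  UNPROTECT(2);
  return dy;
}

SEXP C_eval_rates(SEXP t, SEXP y) {
  (void)t;
  if (!G.loaded) Rf_error("no model loaded");
  if (Rf_length(y) != G.n_sp) Rf_error("state length mismatch");
  SEXP yy = PROTECT(Rf_coerceVector(y, REALSXP));
  compute_rates(REAL(yy));
  SEXP out = PROTECT(Rf_allocVector(REALSXP, G.n_rxn));
  for (int j = 0; j < G.n_rxn; ++j) REAL(out)[j] = G.rate[j];
  UNPROTECT(2);
  return out;
}

// deSolve compiled-code interface
void C_initmod(void (*odeparms)(int *, double *)) {
  (void)odeparms;  // parameters are baked into the loaded model
}

void C_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
              int *ip) {
  (void)t;
  (void)yout;
  (void)ip;
  if (!G.loaded || *neq != G.n_sp)
    Rf_error("compiled model not loaded or state length mismatch");
  fill_dy(y, ydot);
}

static const R_CallMethodDef call_entries[] = {
    {"C_load_model", (DL_FUNC)&C_load_model, 1},
    {"C_eval_rhs", (DL_FUNC)&C_eval_rhs, 2},
    {"C_eval_rates", (DL_FUNC)&C_eval_rates, 2},
    {NULL, NULL, 0}};

void R_init_endonet(DllInfo *dll) {
  R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
  // keep OS-level symbol lookup available so deSolve can resolve C_derivs
  R_useDynamicSymbols(dll, TRUE);
}

}  // extern "C"
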