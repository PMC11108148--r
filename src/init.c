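#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* compiled model interface consumed by deSolve */
void edneg_initmod(void (*odeparms)(int *, double *));
void edneg_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);
void edneg_jac(int *neq, double *t, double *y, int *ml, int *mu,
               double *pd, int *nrowpd, double *yout, int *ip);

/* .Call interface (src/edneg.cpp) */
SEXP c_edneg_rhs(SEXP t, SEXP y, SEXP parms);
SEXP c_edneg_jacobian(SEXP t, SEXP y, SEXP parms);
SEXP c_edneg_gates(SEXP phi_s, SEXP phi_d, SEXP ca_dn, SEXP x, SEXP parms);
SEXP c_edneg_fluxes(SEXP y, SEXP parms, SEXP membrane);

static const R_CMethodDef CEntries[] = {
  {"edneg_initmod", (DL_FUNC) &edneg_initmod, 1},
  {"edneg_derivs",  (DL_FUNC) &edneg_derivs,  6},
  {"edneg_jac",     (DL_FUNC) &edneg_jac,     9},
  {NULL, NULL, 0}
};

static const R_CallMethodDef CallEntries[] = {
  {"c_edneg_rhs",      (DL_FUNC) &c_edneg_rhs,      3},
  {"c_edneg_jacobian", (DL_FUNC) &c_edneg_jacobian, 3},
  {"c_edneg_gates",    (DL_FUNC) &c_edneg_gates,    5},
  {"c_edneg_fluxes",   (DL_FUNC) &c_edneg_fluxes,   3},
  {NULL, NULL, 0}
};

void R_init_edneguq(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
  R_forceSymbols(dll, FALSE);
}
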