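#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void cycle_initmod(void (*odeparms)(int *, double *));
void cycle_initforc(void (*odeforcs)(int *, double *));
void cycle_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
  {"cycle_initmod",  (DL_FUNC) &cycle_initmod,  1},
  {"cycle_initforc", (DL_FUNC) &cycle_initforc, 1},
  {"cycle_derivs",   (DL_FUNC) &cycle_derivs,   6},
  {NULL, NULL, 0}
};

void R_init_ovucycle(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
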