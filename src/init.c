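#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP myo_vm_eval(SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP myo_vm_set_model(SEXP, SEXP, SEXP, SEXP);
extern void myo_vm_derivs(int *, double *, double *, double *, double *, int *);
extern void myo_vm_jac(int *, double *, double *, int *, int *, double *,
                       int *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
  {"myo_vm_eval", (DL_FUNC) &myo_vm_eval, 5},
  {"myo_vm_set_model", (DL_FUNC) &myo_vm_set_model, 4},
  {NULL, NULL, 0}
};

/* registered so deSolve can resolve them by name as compiled-model
 * derivative/Jacobian routines */
static const R_CMethodDef CEntries[] = {
  {"myo_vm_derivs", (DL_FUNC) &myo_vm_derivs, 6},
  {"myo_vm_jac", (DL_FUNC) &myo_vm_jac, 9},
  {NULL, NULL, 0}
};

void R_init_myocyte(DllInfo *dll)
{
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
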