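#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP bden_deriv_id(SEXP);
extern SEXP bden_deriv_eval(SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP bden_rk4_seg(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef call_entries[] = {
  {"bden_deriv_id", (DL_FUNC) &bden_deriv_id, 1},
  {"bden_deriv_eval", (DL_FUNC) &bden_deriv_eval, 5},
  {"bden_rk4_seg", (DL_FUNC) &bden_rk4_seg, 7},
  {NULL, NULL, 0}
};

void R_init_bden(DllInfo *dll)
{
  R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
  R_forceSymbols(dll, TRUE);
}
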