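/* Fixed-step RK4 over one measurement segment for packaged models whose
 * derivative functions were generated to C. The spline (W) and input (U)
 * values are tabulated at the 2*nsub+1 half-step times by the caller. */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>
#include "model_derivs.h"

SEXP bden_deriv_id(SEXP key_)
{
  const char *key = CHAR(STRING_ELT(key_, 0));
  for (int i = 0; bden_deriv_table[i].key; i++)
    if (strcmp(bden_deriv_table[i].key, key) == 0)
      return ScalarInteger(i);
  return ScalarInteger(NA_INTEGER);
}

/* evaluate one registered derivative (testing hook) */
SEXP bden_deriv_eval(SEXP id_, SEXP x_, SEXP u_, SEXP t_, SEXP p_)
{
  int id = INTEGER(id_)[0];
  const bden_deriv_entry *e = &bden_deriv_table[id];
  SEXP out = PROTECT(allocVector(REALSXP, e->n_states));
  e->fn(REAL(t_)[0], REAL(x_), LENGTH(u_) ? REAL(u_) : NULL,
        LENGTH(p_) ? REAL(p_) : NULL, REAL(out));
  UNPROTECT(1);
  return out;
}

SEXP bden_rk4_seg(SEXP id_, SEXP x0_, SEXP W_, SEXP U_, SEXP tt_, SEXP nsub_,
                  SEXP p_)
{
  const int id = INTEGER(id_)[0];
  const bden_deriv_entry *e = &bden_deriv_table[id];
  const int n = e->n_states;
  const int nsub = INTEGER(nsub_)[0];
  const double *W = REAL(W_);           /* n x (2 nsub + 1) */
  const double *U = LENGTH(U_) ? REAL(U_) : NULL;
  const int mu = LENGTH(U_) ? (int) (LENGTH(U_) / (2 * nsub + 1)) : 0;
  const double *tt = REAL(tt_);
  const double *p = LENGTH(p_) ? REAL(p_) : NULL;
  const double hs = (tt[2 * nsub] - tt[0]) / nsub;
  const double h2 = hs / 2.0, h6 = hs / 6.0;

  double x[64], xa[64], k1[64], k2[64], k3[64], k4[64];
  if (n > 64) error("state dimension too large for the C integrator");
  memcpy(x, REAL(x0_), n * sizeof(double));

  for (int s = 0; s < nsub; s++) {
    const int i0 = 2 * s;
    const double *w0 = W + (size_t) n * i0;
    const double *wm = w0 + n, *w1 = wm + n;
    const double *u0 = U ? U + (size_t) mu * i0 : NULL;
    const double *um = u0 ? u0 + mu : NULL, *u1 = um ? um + mu : NULL;
    const double t0 = tt[i0], tm = tt[i0 + 1], t1 = tt[i0 + 2];

    e->fn(t0, x, u0, p, k1);
    for (int i = 0; i < n; i++) { k1[i] += w0[i]; xa[i] = x[i] + h2 * k1[i]; }
    e->fn(tm, xa, um, p, k2);
    for (int i = 0; i < n; i++) { k2[i] += wm[i]; xa[i] = x[i] + h2 * k2[i]; }
    e->fn(tm, xa, um, p, k3);
    for (int i = 0; i < n; i++) { k3[i] += wm[i]; xa[i] = x[i] + hs * k3[i]; }
    e->fn(t1, xa, u1, p, k4);
    for (int i = 0; i < n; i++) {
      k4[i] += w1[i];
      x[i] += h6 * (k1[i] + 2.0 * (k2[i] + k3[i]) + k4[i]);
    }
  }
  for (int i = 0; i < n; i++)
    if (!R_FINITE(x[i])) return R_NilValue;

  SEXP out = PROTECT(allocVector(REALSXP, n));
  memcpy(REAL(out), x, n * sizeof(double));
  UNPROTECT(1);
  return out;
}
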