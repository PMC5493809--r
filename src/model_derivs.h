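#ifndef BDEN_MODEL_DERIVS_H
#define BDEN_MODEL_DERIVS_H

typedef void (*bden_deriv_fn)(double t, const double *x, const double *u,
                              const double *p, double *dx);

typedef struct {
  const char *key;
  int n_states;
  bden_deriv_fn fn;
} bden_deriv_entry;

extern const bden_deriv_entry bden_deriv_table[];

#endif
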