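/* Generated by scripts/gen_model_c.R from inst/extdata/models/ - do not edit. */
#include <math.h>
#include "model_derivs.h"

/* alpha-pinene */
static void deriv_0(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((-((p[0] + p[1]))) * x[0]);
  dx[1] = (p[0] * x[0]);
  dx[2] = (((p[1] * x[0]) - ((2.0 * p[2]) * pow(x[2], 2.0))) + ((2.0 * p[3]) * x[3]));
  dx[3] = ((p[2] * pow(x[2], 2.0)) - (p[3] * x[3]));
}

/* alpha-pinene:missing-dimerization */
static void deriv_1(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((-((p[0] + p[1]))) * x[0]);
  dx[1] = (p[0] * x[0]);
  dx[2] = ((p[1] * x[0]) - (p[4] * x[2]));
  dx[3] = ((p[4] * x[2]) - (p[3] * x[3]));
}

/* dream6 */
static void deriv_2(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((p[0] / ((1.0 + pow(((x[11] / p[1])), p[3])))) - (p[4] * x[0]));
  dx[1] = (((p[0] * pow(((x[6] / p[1])), p[3])) / ((1.0 + pow(((x[6] / p[1])), p[3])))) - (p[4] * x[1]));
  dx[2] = ((p[0] / ((1.0 + pow(((x[7] / p[1])), p[3])))) - (p[4] * x[2]));
  dx[3] = (((p[0] * pow(((x[8] / p[1])), p[3])) / ((1.0 + pow(((x[8] / p[1])), p[3])))) - (p[4] * x[3]));
  dx[4] = ((p[0] / ((1.0 + pow(((x[9] / p[1])), p[3])))) - (p[4] * x[4]));
  dx[5] = (((p[0] * pow(((x[10] / p[1])), p[3])) / ((1.0 + pow(((x[10] / p[1])), p[3])))) - (p[4] * x[5]));
  dx[6] = ((p[6] * x[0]) - (p[5] * x[6]));
  dx[7] = ((p[6] * x[1]) - (p[5] * x[7]));
  dx[8] = ((p[6] * x[2]) - (p[5] * x[8]));
  dx[9] = ((p[6] * x[3]) - (p[5] * x[9]));
  dx[10] = ((p[6] * x[4]) - (p[5] * x[10]));
  dx[11] = ((p[6] * x[5]) - (p[5] * x[11]));
}

/* dream6:wrong-repression */
static void deriv_3(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((p[0] / ((1.0 + pow(((x[11] / p[1])), p[3])))) - (p[4] * x[0]));
  dx[1] = (((p[0] * pow(((x[6] / p[1])), p[3])) / ((1.0 + pow(((x[6] / p[1])), p[3])))) - (p[4] * x[1]));
  dx[2] = ((p[0] / ((1.0 + pow(((x[7] / p[1])), p[3])))) - (p[4] * x[2]));
  dx[3] = ((((p[0] * pow(((x[8] / p[1])), p[3])) / ((1.0 + pow(((x[8] / p[1])), p[3])))) / ((1.0 + pow(((x[11] / p[2])), p[3])))) - (p[4] * x[3]));
  dx[4] = ((p[0] / ((1.0 + pow(((x[9] / p[1])), p[3])))) - (p[4] * x[4]));
  dx[5] = (((p[0] * pow(((x[10] / p[1])), p[3])) / ((1.0 + pow(((x[10] / p[1])), p[3])))) - (p[4] * x[5]));
  dx[6] = ((p[6] * x[0]) - (p[5] * x[6]));
  dx[7] = ((p[6] * x[1]) - (p[5] * x[7]));
  dx[8] = ((p[6] * x[2]) - (p[5] * x[8]));
  dx[9] = ((p[6] * x[3]) - (p[5] * x[9]));
  dx[10] = ((p[6] * x[4]) - (p[5] * x[10]));
  dx[11] = ((p[6] * x[5]) - (p[5] * x[11]));
}

/* epor */
static void deriv_4(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = (((((-p[0]) * x[0]) * x[1]) + (p[1] * x[2])) + (p[5] * x[3]));
  dx[1] = (((((p[2] * p[3]) - (p[2] * x[1])) - ((p[0] * x[0]) * x[1])) + (p[1] * x[2])) + (p[5] * x[3]));
  dx[2] = ((((p[0] * x[0]) * x[1]) - (p[1] * x[2])) - (p[4] * x[2]));
  dx[3] = ((((p[4] * x[2]) - (p[5] * x[3])) - (p[6] * x[3])) - (p[7] * x[3]));
  dx[4] = (p[6] * x[3]);
  dx[5] = (p[7] * x[3]);
}

/* epor:wrong-feedback */
static void deriv_5(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((((-p[0]) * x[0]) * x[1]) + (p[1] * x[2])) + (p[5] * x[3])) - ((p[8] * x[0]) * x[1]));
  dx[1] = ((((((p[2] * p[3]) - (p[2] * x[1])) - ((p[0] * x[0]) * x[1])) + (p[1] * x[2])) + (p[5] * x[3])) - ((p[8] * x[0]) * x[1]));
  dx[2] = ((((p[0] * x[0]) * x[1]) - (p[1] * x[2])) - (p[4] * x[2]));
  dx[3] = ((((p[4] * x[2]) - (p[5] * x[3])) - (p[6] * x[3])) - (p[7] * x[3]));
  dx[4] = (p[6] * x[3]);
  dx[5] = (p[7] * x[3]);
}

/* gprotein */
static void deriv_6(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = (((p[0] - (p[1] * x[0])) - (p[3] * x[0])) + (p[4] * x[1]));
  dx[1] = (((p[3] * x[0]) - (p[4] * x[1])) - (p[2] * x[1]));
  dx[2] = ((((-p[5]) * x[1]) * x[2]) + ((p[7] * x[4]) * x[5]));
  dx[3] = (((p[5] * x[1]) * x[2]) - (p[6] * x[3]));
  dx[4] = ((p[6] * x[3]) - ((p[7] * x[4]) * x[5]));
  dx[5] = (((p[5] * x[1]) * x[2]) - ((p[7] * x[4]) * x[5]));
}

/* gprotein:wrong-reactivation */
static void deriv_7(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = (((p[0] - (p[1] * x[0])) - (p[3] * x[0])) + (p[4] * x[1]));
  dx[1] = (((p[3] * x[0]) - (p[4] * x[1])) - (p[2] * x[1]));
  dx[2] = ((((-p[5]) * x[1]) * x[2]) + ((p[7] * x[4]) * x[5]));
  dx[3] = ((((p[5] * x[1]) * x[2]) - (p[6] * x[3])) + ((p[8] * x[1]) * x[4]));
  dx[4] = (((p[6] * x[3]) - ((p[7] * x[4]) * x[5])) - ((p[8] * x[1]) * x[4]));
  dx[5] = (((p[5] * x[1]) * x[2]) - ((p[7] * x[4]) * x[5]));
}

/* jak-stat */
static void deriv_8(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((-p[0]) * x[0]) * u[0]) + ((2.0 * p[3]) * x[3]));
  dx[1] = (((p[0] * x[0]) * u[0]) - (p[1] * pow(x[1], 2.0)));
  dx[2] = (((0.5 * p[1]) * pow(x[1], 2.0)) - (p[2] * x[2]));
  dx[3] = ((p[2] * x[2]) - (p[3] * x[3]));
}

/* jak-stat:no-nuclear-export */
static void deriv_9(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = (((-p[0]) * x[0]) * u[0]);
  dx[1] = (((p[0] * x[0]) * u[0]) - (p[1] * pow(x[1], 2.0)));
  dx[2] = (((0.5 * p[1]) * pow(x[1], 2.0)) - (p[2] * x[2]));
  dx[3] = (p[2] * x[2]);
}

/* jak-stat:missing-import */
static void deriv_10(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((-p[0]) * x[0]) * u[0]) + ((2.0 * p[3]) * x[3]));
  dx[1] = (((p[0] * x[0]) * u[0]) - (p[1] * pow(x[1], 2.0)));
  dx[2] = ((0.5 * p[1]) * pow(x[1], 2.0));
  dx[3] = ((-p[3]) * x[3]);
}

/* jak-stat:missing-dimerization */
static void deriv_11(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((-p[0]) * x[0]) * u[0]) + ((2.0 * p[3]) * x[3]));
  dx[1] = ((p[0] * x[0]) * u[0]);
  dx[2] = ((-p[2]) * x[2]);
  dx[3] = ((p[2] * x[2]) - (p[3] * x[3]));
}

/* jak-stat:spurious-recycling */
static void deriv_12(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((-p[0]) * x[0]) * u[0]) + ((2.0 * p[3]) * x[3]));
  dx[1] = ((((p[0] * x[0]) * u[0]) - (p[1] * pow(x[1], 2.0))) + (p[4] * x[3]));
  dx[2] = (((0.5 * p[1]) * pow(x[1], 2.0)) - (p[2] * x[2]));
  dx[3] = (((p[2] * x[2]) - (p[3] * x[3])) - (p[4] * x[3]));
}

/* jak-stat:spurious-dissociation */
static void deriv_13(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((-p[0]) * x[0]) * u[0]) + ((2.0 * p[3]) * x[3]));
  dx[1] = ((((p[0] * x[0]) * u[0]) - (p[1] * pow(x[1], 2.0))) + ((2.0 * p[5]) * x[2]));
  dx[2] = ((((0.5 * p[1]) * pow(x[1], 2.0)) - (p[2] * x[2])) - (p[5] * x[2]));
  dx[3] = ((p[2] * x[2]) - (p[3] * x[3]));
}

/* motif-cascade */
static void deriv_14(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = (((p[0] * u[0]) - (p[1] * x[0])) - (p[3] * x[0]));
  dx[1] = (((p[1] * x[0]) - (p[2] * x[1])) - (p[4] * x[1]));
  dx[2] = ((p[2] * x[1]) - (p[5] * x[2]));
}

/* motif-cascade:missing-conversion */
static void deriv_15(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((p[0] * u[0]) - (p[3] * x[0]));
  dx[1] = (((-p[2]) * x[1]) - (p[4] * x[1]));
  dx[2] = ((p[2] * x[1]) - (p[5] * x[2]));
}

/* motif-cascade:wrong-recycling */
static void deriv_16(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((p[0] * u[0]) - (p[1] * x[0])) - (p[3] * x[0])) + (p[6] * x[2]));
  dx[1] = (((p[1] * x[0]) - (p[2] * x[1])) - (p[4] * x[1]));
  dx[2] = (((p[2] * x[1]) - (p[5] * x[2])) - (p[6] * x[2]));
}

/* motif-coherent-ffl */
static void deriv_17(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((p[0] * u[0]) - (p[1] * x[0])) - (p[2] * x[0])) - (p[4] * x[0]));
  dx[1] = (((p[1] * x[0]) - (p[3] * x[1])) - (p[5] * x[1]));
  dx[2] = (((p[2] * x[0]) + (p[3] * x[1])) - (p[6] * x[2]));
}

/* motif-coherent-ffl:missing-shortcut */
static void deriv_18(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((p[0] * u[0]) - (p[1] * x[0])) - (p[2] * x[0])) - (p[4] * x[0]));
  dx[1] = ((p[1] * x[0]) - (p[5] * x[1]));
  dx[2] = ((p[2] * x[0]) - (p[6] * x[2]));
}

/* motif-fanout */
static void deriv_19(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = (((((p[0] * u[0]) - (p[1] * x[0])) - (p[2] * x[0])) - (p[3] * x[0])) - (p[4] * x[0]));
  dx[1] = ((p[1] * x[0]) - (p[5] * x[1]));
  dx[2] = ((p[2] * x[0]) - (p[6] * x[2]));
  dx[3] = ((p[3] * x[0]) - (p[7] * x[3]));
}

/* motif-fanout:missing-branch */
static void deriv_20(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((p[0] * u[0]) - (p[1] * x[0])) - (p[2] * x[0])) - (p[4] * x[0]));
  dx[1] = ((p[1] * x[0]) - (p[5] * x[1]));
  dx[2] = ((p[2] * x[0]) - (p[6] * x[2]));
  dx[3] = ((-p[7]) * x[3]);
}

/* motif-fanout:wrong-crosslink */
static void deriv_21(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = (((((p[0] * u[0]) - (p[1] * x[0])) - (p[2] * x[0])) - (p[3] * x[0])) - (p[4] * x[0]));
  dx[1] = (((p[1] * x[0]) - (p[5] * x[1])) - (p[8] * x[1]));
  dx[2] = (((p[2] * x[0]) + (p[8] * x[1])) - (p[6] * x[2]));
  dx[3] = ((p[3] * x[0]) - (p[7] * x[3]));
}

/* motif-incoherent-ffl */
static void deriv_22(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((p[0] * u[0]) - (p[1] * x[0])) - (p[2] * x[0])) - (p[3] * x[0]));
  dx[1] = (((p[1] * x[0]) - (p[4] * x[1])) - ((p[6] * x[1]) * x[2]));
  dx[2] = (((p[2] * x[0]) - (p[5] * x[2])) - ((p[6] * x[1]) * x[2]));
}

/* motif-incoherent-ffl:missing-repression */
static void deriv_23(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((p[0] * u[0]) - (p[1] * x[0])) - (p[2] * x[0])) - (p[3] * x[0]));
  dx[1] = ((p[1] * x[0]) - (p[4] * x[1]));
  dx[2] = ((p[2] * x[0]) - (p[5] * x[2]));
}

/* motif-negative-feedback */
static void deriv_24(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((p[0] * u[0]) - (p[1] * x[0])) - (p[3] * x[0])) - ((p[6] * x[0]) * x[2]));
  dx[1] = (((p[1] * x[0]) - (p[2] * x[1])) - (p[4] * x[1]));
  dx[2] = (((p[2] * x[1]) - (p[5] * x[2])) - ((p[6] * x[0]) * x[2]));
}

/* motif-negative-feedback:missing-feedback */
static void deriv_25(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = (((p[0] * u[0]) - (p[1] * x[0])) - (p[3] * x[0]));
  dx[1] = (((p[1] * x[0]) - (p[2] * x[1])) - (p[4] * x[1]));
  dx[2] = ((p[2] * x[1]) - (p[5] * x[2]));
}

/* uvb */
static void deriv_26(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((-p[0]) * u[0]) * x[0]) + (p[1] * pow(x[1], 2.0)));
  dx[1] = (((((((2.0 * p[0]) * u[0]) * x[0]) - ((2.0 * p[1]) * pow(x[1], 2.0))) - ((p[2] * x[1]) * x[2])) + (p[3] * x[3])) + ((p[4] * x[7]) * x[3]));
  dx[2] = (((((-p[2]) * x[1]) * x[2]) + (p[3] * x[3])) + ((p[4] * x[7]) * x[3]));
  dx[3] = ((((p[2] * x[1]) * x[2]) - (p[3] * x[3])) - ((p[4] * x[7]) * x[3]));
  dx[4] = (((p[5] * x[3]) / ((p[6] + x[3]))) - (p[7] * x[4]));
  dx[5] = ((p[8] * x[4]) - (p[9] * x[5]));
  dx[6] = (((p[10] * x[5]) / ((p[11] + x[5]))) - (p[12] * x[6]));
  dx[7] = (((p[13] * x[5]) / ((p[14] + x[5]))) - (p[15] * x[7]));
  dx[8] = ((((p[16] * x[5]) / ((p[17] + x[5]))) + ((p[18] * x[6]) / ((p[19] + x[6])))) - (p[20] * x[8]));
  dx[9] = ((p[21] * x[8]) - (p[22] * x[9]));
  dx[10] = (((p[23] * x[5]) / ((p[24] + x[5]))) - (p[25] * x[10]));
}

/* uvb:missing-rup-feedback */
static void deriv_27(double t, const double *x, const double *u, const double *p, double *dx)
{
  (void) t; (void) u; (void) p;
  dx[0] = ((((-p[0]) * u[0]) * x[0]) + (p[1] * pow(x[1], 2.0)));
  dx[1] = ((((((2.0 * p[0]) * u[0]) * x[0]) - ((2.0 * p[1]) * pow(x[1], 2.0))) - ((p[2] * x[1]) * x[2])) + (p[3] * x[3]));
  dx[2] = ((((-p[2]) * x[1]) * x[2]) + (p[3] * x[3]));
  dx[3] = (((p[2] * x[1]) * x[2]) - (p[3] * x[3]));
  dx[4] = (((p[5] * x[3]) / ((p[6] + x[3]))) - (p[7] * x[4]));
  dx[5] = ((p[8] * x[4]) - (p[9] * x[5]));
  dx[6] = (((p[10] * x[5]) / ((p[11] + x[5]))) - (p[12] * x[6]));
  dx[7] = (((p[13] * x[5]) / ((p[14] + x[5]))) - (p[15] * x[7]));
  dx[8] = ((((p[16] * x[5]) / ((p[17] + x[5]))) + ((p[18] * x[6]) / ((p[19] + x[6])))) - (p[20] * x[8]));
  dx[9] = ((p[21] * x[8]) - (p[22] * x[9]));
  dx[10] = (((p[23] * x[5]) / ((p[24] + x[5]))) - (p[25] * x[10]));
}

const bden_deriv_entry bden_deriv_table[] = {
  {"alpha-pinene", 4, deriv_0},
  {"alpha-pinene:missing-dimerization", 4, deriv_1},
  {"dream6", 12, deriv_2},
  {"dream6:wrong-repression", 12, deriv_3},
  {"epor", 6, deriv_4},
  {"epor:wrong-feedback", 6, deriv_5},
  {"gprotein", 6, deriv_6},
  {"gprotein:wrong-reactivation", 6, deriv_7},
  {"jak-stat", 4, deriv_8},
  {"jak-stat:no-nuclear-export", 4, deriv_9},
  {"jak-stat:missing-import", 4, deriv_10},
  {"jak-stat:missing-dimerization", 4, deriv_11},
  {"jak-stat:spurious-recycling", 4, deriv_12},
  {"jak-stat:spurious-dissociation", 4, deriv_13},
  {"motif-cascade", 3, deriv_14},
  {"motif-cascade:missing-conversion", 3, deriv_15},
  {"motif-cascade:wrong-recycling", 3, deriv_16},
  {"motif-coherent-ffl", 3, deriv_17},
  {"motif-coherent-ffl:missing-shortcut", 3, deriv_18},
  {"motif-fanout", 4, deriv_19},
  {"motif-fanout:missing-branch", 4, deriv_20},
  {"motif-fanout:wrong-crosslink", 4, deriv_21},
  {"motif-incoherent-ffl", 3, deriv_22},
  {"motif-incoherent-ffl:missing-repression", 3, deriv_23},
  {"motif-negative-feedback", 3, deriv_24},
  {"motif-negative-feedback:missing-feedback", 3, deriv_25},
  {"uvb", 11, deriv_26},
  {"uvb:missing-rup-feedback", 11, deriv_27},
  {0, 0, 0}
};
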