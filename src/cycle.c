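/* Compiled right-hand side of the 13-state menstrual cycle DDE model
 * for use with deSolve::dede.  Mirrors the reference R implementation
 * in R/model.R; the two must agree to solver precision (checked in the
 * test suite).
 *
 * State order: RP_LH, LH, RP_FSH, FSH, RcF, GrF, DomF, Sc1, Sc2,
 *              Lut1, Lut2, Lut3, Lut4.
 * Forcings: E2exo(t) (pg/mL), P4exo(t) (ng/mL), linearly interpolated
 * by the solver from a fine grid supplied on the R side.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 46

static double parms[NPAR];
static double forc[2];

/* parameters, canonical package order plus t0 and the (constant)
 * history inhibin appended */
#define V0_LH      parms[0]
#define V1_LH      parms[1]
#define Km_LH      parms[2]
#define Ki_LH_P    parms[3]
#define k_LH       parms[4]
#define c_LH_P     parms[5]
#define c_LH_E     parms[6]
#define alpha_LH   parms[7]
#define V_FSH      parms[8]
#define Ki_FSH_Inh parms[9]
#define tau        parms[10]
#define k_FSH      parms[11]
#define c_FSH_P    parms[12]
#define c_FSH_E    parms[13]
#define alpha_FSH  parms[14]
#define vol        parms[15]
#define w_scale    parms[16]
#define q_scale    parms[17]
#define b_rec      parms[18]
#define c1         parms[19]
#define c2         parms[20]
#define c3         parms[21]
#define c4         parms[22]
#define d1         parms[23]
#define d2         parms[24]
#define k1         parms[25]
#define k2         parms[26]
#define k3         parms[27]
#define k4         parms[28]
#define alpha_exp  parms[29]
#define gamma_exp  parms[30]
#define e0         parms[31]
#define e1         parms[32]
#define e2         parms[33]
#define e3         parms[34]
#define p0         parms[35]
#define p1         parms[36]
#define p2         parms[37]
#define h0         parms[38]
#define h1         parms[39]
#define h2         parms[40]
#define h3         parms[41]
#define b1_cpl     parms[42]
#define b2_cpl     parms[43]
#define t_origin   parms[44]
#define hist_inh   parms[45]

#define E2EXO forc[0]
#define P4EXO forc[1]

void cycle_initmod(void (*odeparms)(int *, double *)) {
  int n = NPAR;
  odeparms(&n, parms);
}

void cycle_initforc(void (*odeforcs)(int *, double *)) {
  int n = 2;
  odeforcs(&n, forc);
}

static void lagvalue(double T, int *nr, int N, double *ytau) {
  static void (*fun)(double, int *, int, double *) = NULL;
  if (fun == NULL)
    fun = (void (*)(double, int *, int, double *))
      R_GetCCallable("deSolve", "lagvalue");
  fun(T, nr, N, ytau);
}

void cycle_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip) {
  double s[13];
  for (int i = 0; i < 13; i++) s[i] = y[i] > 0 ? y[i] : 0;

  double RP_LH = s[0], LH = s[1], RP_FSH = s[2], FSH = s[3];
  double RcF = s[4], GrF = s[5], DomF = s[6], Sc1 = s[7], Sc2 = s[8];
  double Lut1 = s[9], Lut2 = s[10], Lut3 = s[11], Lut4 = s[12];

  double E2 = e0 + e1 * GrF + e2 * DomF + e3 * Lut4 + b1_cpl * E2EXO;
  double P4 = p0 + p1 * Lut3 + p2 * Lut4 + b2_cpl * P4EXO;

  double inh_lag;
  double T = *t - tau;
  if (tau <= 0) {
    inh_lag = h0 + h1 * DomF + h2 * Lut2 + h3 * Lut3;
  } else if (T <= t_origin) {
    inh_lag = hist_inh;
  } else {
    int nr[3] = {6, 10, 11};    /* DomF, Lut2, Lut3 */
    double ylag[3];
    lagvalue(T, nr, 3, ylag);
    for (int i = 0; i < 3; i++) if (ylag[i] < 0) ylag[i] = 0;
    inh_lag = h0 + h1 * ylag[0] + h2 * ylag[1] + h3 * ylag[2];
  }

  double r8 = E2 / Km_LH;
  double hill = pow(r8, 8.0);
  hill = hill / (1.0 + hill);

  double syn_LH = (V0_LH + V1_LH * hill) / (1.0 + P4 / Ki_LH_P);
  double rel_LH = k_LH * (1.0 + c_LH_P * P4) * RP_LH / (1.0 + c_LH_E * E2);

  double den_F = 1.0 + c_FSH_E * E2;
  double syn_FSH = V_FSH / (1.0 + inh_lag / Ki_FSH_Inh + P4 / w_scale);
  double rel_FSH = k_FSH * (1.0 + c_FSH_P * P4) * RP_FSH / (den_F * den_F);

  double recr = (b_rec + c1 * RcF) * FSH / (1.0 + P4 / q_scale);
  double f12 = c2 * pow(LH, alpha_exp) * RcF;
  double f23 = c3 * LH * GrF;
  double f34 = c4 * pow(LH, gamma_exp) * DomF;

  ydot[0] = syn_LH - rel_LH;
  ydot[1] = rel_LH / vol - alpha_LH * LH;
  ydot[2] = syn_FSH - rel_FSH;
  ydot[3] = rel_FSH / vol - alpha_FSH * FSH;
  ydot[4] = recr - f12;
  ydot[5] = f12 - f23;
  ydot[6] = f23 - f34;
  ydot[7] = f34 - d1 * Sc1;
  ydot[8] = d1 * Sc1 - d2 * Sc2;
  ydot[9] = d2 * Sc2 - k1 * Lut1;
  ydot[10] = k1 * Lut1 - k2 * Lut2;
  ydot[11] = k2 * Lut2 - k3 * Lut3;
  ydot[12] = k3 * Lut3 - k4 * Lut4;

  if (ip[0] >= 3) {
    yout[0] = E2;
    yout[1] = P4;
    yout[2] = inh_lag;
  }
}
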