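/* Coupled myofilament + reduced calcium-handling cell model.
 *
 * State vector (7):
 *   y[0] Cai     free cytosolic calcium, uM
 *   y[1] Ca_sr   SR calcium, uM
 *   y[2] g       release gate (dimensionless, decays with tau_rel)
 *   y[3] CaTRPN  fractional troponin C calcium occupancy
 *   y[4] B       blocked tropomyosin fraction
 *   y[5] W       weakly bound crossbridge fraction
 *   y[6] S       strongly bound crossbridge fraction
 * U = 1 - B - W - S is implicit.
 *
 * Parameter order must match .hcm_par_names in R/params.R.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 41

static double p[NPAR];

/* parameter indices */
enum {
  iCa50, iN_TRPN, iK_ON, iK_OFF, iN_TM, iK_BU, iK_UB, iTRPN_CAP,
  iK_UW, iK_WU, iK_WS, iK_SU, iT_REF, iRHO0, iR, iGAMMA_FB,
  iFB_MODE, iFB_LO, iFB_HI, iCTRL_WS, iR_ON_TREF,
  iG_AMP, iTAU_REL, iK_REL, iV_SERCA, iK_SERCA, iH_SERCA,
  iK_NCX, iCA_DIA, iA_IN, iD_IN, iVR, iB_CMDN, iK_CMDN, iTRPN_TOT,
  iLCC, iSERCA_SC, iNCX_SC, iINAL_BLOCK, iALPHA_NAL, iCL
};

void hcm_initparms(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, p);
}

static double clipd(double x, double lo, double hi)
{
  return x < lo ? lo : (x > hi ? hi : x);
}

/* DRX fraction at odds R*rho0, normalised to its control value */
static double avail_scale(double R, double rho0)
{
  double f  = R * rho0 / (1.0 + R * rho0);
  double f0 = rho0 / (1.0 + rho0);
  return f / f0;
}

void hcm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
  double Cai    = y[0] > 0.0 ? y[0] : 0.0;
  double Ca_sr  = y[1] > 0.0 ? y[1] : 0.0;
  double g      = y[2];
  double CaTRPN = clipd(y[3], 1e-12, 1.0);
  double B = y[4], W = y[5], S = y[6];
  double U = 1.0 - B - W - S;

  /* myosin availability and feedback on thin-filament sensitivity */
  double avail = avail_scale(p[iR], p[iRHO0]);
  double fb = 1.0;
  if (p[iFB_MODE] == 1.0) {          /* static: driven by R itself */
    fb = clipd(1.0 - p[iGAMMA_FB] * (p[iR] - 1.0), p[iFB_LO], p[iFB_HI]);
  } else if (p[iFB_MODE] == 2.0) {   /* dynamic: driven by crossbridge occupancy */
    fb = clipd(1.0 - p[iGAMMA_FB] * (W + S) / p[iCTRL_WS], p[iFB_LO], p[iFB_HI]);
  }
  double ca50_eff = p[iCa50] * fb;

  /* troponin calcium binding (Hill-type driving term) */
  double x = pow(Cai / ca50_eff, p[iN_TRPN]);
  double dCaTRPN = p[iK_ON] * x * (1.0 - CaTRPN) - p[iK_OFF] * CaTRPN;

  /* tropomyosin blocked <-> unblocked switching */
  double half_ntm = 0.5 * p[iN_TM];
  double gain = pow(CaTRPN, -half_ntm);
  if (gain > p[iTRPN_CAP]) gain = p[iTRPN_CAP];
  double dB = p[iK_UB] * gain * U - p[iK_BU] * pow(CaTRPN, half_ntm) * B;

  /* crossbridge cycling; availability scales attachment (or T_ref) */
  double k_uw_eff = p[iK_UW] * (p[iR_ON_TREF] == 1.0 ? 1.0 : avail);
  double dW = k_uw_eff * U - (p[iK_WU] + p[iK_WS]) * W;
  double dS = p[iK_WS] * W - p[iK_SU] * S;

  /* calcium fluxes, uM/ms */
  double J_trpn = p[iTRPN_TOT] * dCaTRPN;
  double J_rel  = p[iK_REL] * g * Ca_sr;
  double cah    = pow(Cai, p[iH_SERCA]);
  double J_serca = p[iSERCA_SC] * p[iV_SERCA] * cah /
                   (cah + pow(p[iK_SERCA], p[iH_SERCA]));
  double J_ncx  = p[iNCX_SC] * (1.0 + p[iALPHA_NAL] * p[iINAL_BLOCK]) *
                  p[iK_NCX] * (Cai - p[iCA_DIA]);
  double tmod   = p[iCL] > 0.0 ? fmod(*t, p[iCL]) : *t;
  double J_in   = (tmod < p[iD_IN]) ? p[iLCC] * p[iA_IN] : 0.0;

  double kc   = p[iK_CMDN] + Cai;
  double beta = 1.0 / (1.0 + p[iB_CMDN] * p[iK_CMDN] / (kc * kc));

  ydot[0] = beta * (J_in + J_rel - J_serca - J_ncx - J_trpn);
  ydot[1] = p[iVR] * (J_serca - J_rel);
  ydot[2] = -g / p[iTAU_REL];
  ydot[3] = dCaTRPN;
  ydot[4] = dB;
  ydot[5] = dW;
  ydot[6] = dS;

  if (ip[0] > 0) { /* active tension output */
    double tsc = p[iR_ON_TREF] == 1.0 ? avail : 1.0;
    yout[0] = p[iT_REF] * tsc * (S > 0.0 ? S : 0.0);
  }
}

static const R_CMethodDef cMethods[] = {
  {"hcm_initparms", (DL_FUNC) &hcm_initparms, 1},
  {"hcm_derivs",    (DL_FUNC) &hcm_derivs,    6},
  {NULL, NULL, 0}
};

void R_init_hcmtwitch(DllInfo *dll)
{
  R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
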