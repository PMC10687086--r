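/* Right-hand sides for the luciferase reaction models, called by deSolve.
 *
 * Units: concentrations in uM, time in s. Infinite dissociation constants
 * are passed as zero *inverse* constants (QSSA) or zero on-rates (mass
 * action), so the corresponding terms vanish exactly.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* ---- QSSA progress model: single state P (product, uM) ----------------- */

static double qssa_parms[6];
#define Q_KCAT  qssa_parms[0]
#define Q_KM    qssa_parms[1]
#define Q_INVKP qssa_parms[2]   /* 1/K_p, 0 when K_p = Inf */
#define Q_INVKS qssa_parms[3]   /* 1/K_s, 0 when K_s = Inf */
#define Q_E0    qssa_parms[4]
#define Q_S0    qssa_parms[5]

void lucifit_init_qssa(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, qssa_parms);
}

void lucifit_deriv_qssa(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    double P = y[0];
    double S = Q_S0 - P;
    if (S < 0.0) S = 0.0;
    if (P < 0.0) P = 0.0;
    double denom = Q_KM * (1.0 + P * Q_INVKP) + S * (1.0 + S * Q_INVKS);
    ydot[0] = (denom > 0.0) ? Q_KCAT * Q_E0 * S / denom : 0.0;
}

/* ---- Mass-action network: E, S, ES, ESS, EP, P (all uM) ---------------- */

static double ma_parms[7];
#define M_K1    ma_parms[0]   /* E + S association, 1/uM/s  */
#define M_KOFF  ma_parms[1]   /* ES dissociation, 1/s       */
#define M_KCAT  ma_parms[2]   /* ES -> E + P, 1/s           */
#define M_KONP  ma_parms[3]   /* E + P association, 1/uM/s  */
#define M_KOFFP ma_parms[4]   /* EP dissociation, 1/s       */
#define M_KONS  ma_parms[5]   /* ES + S association, 1/uM/s */
#define M_KOFFS ma_parms[6]   /* ESS dissociation, 1/s      */

void lucifit_init_ma(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, ma_parms);
}

void lucifit_deriv_ma(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double E = y[0], S = y[1], ES = y[2], ESS = y[3], EP = y[4], P = y[5];
    double bind   = M_K1   * E  * S;
    double unbind = M_KOFF * ES;
    double cat    = M_KCAT * ES;
    double bindP  = M_KONP * E  * P;
    double unbP   = M_KOFFP * EP;
    double bindS2 = M_KONS * ES * S;
    double unbS2  = M_KOFFS * ESS;

    ydot[0] = -bind + unbind + cat - bindP + unbP;        /* E   */
    ydot[1] = -bind + unbind - bindS2 + unbS2;            /* S   */
    ydot[2] =  bind - unbind - cat - bindS2 + unbS2;      /* ES  */
    ydot[3] =  bindS2 - unbS2;                            /* ESS */
    ydot[4] =  bindP - unbP;                              /* EP  */
    ydot[5] =  cat - bindP + unbP;                        /* P   */
}

static const R_CMethodDef cMethods[] = {
    {"lucifit_init_qssa",  (DL_FUNC) &lucifit_init_qssa,  1},
    {"lucifit_deriv_qssa", (DL_FUNC) &lucifit_deriv_qssa, 6},
    {"lucifit_init_ma",    (DL_FUNC) &lucifit_init_ma,    1},
    {"lucifit_deriv_ma",   (DL_FUNC) &lucifit_deriv_ma,   6},
    {NULL, NULL, 0}
};

void R_init_lucifit(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
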