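/* Compiled right-hand side of the 12-state regulation-structured
 * denitrification model, in deSolve's compiled-model interface.
 * Parameter order must match .param_names on the R side. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define NPAR 29
static double parms[NPAR];

#define f1      parms[0]
#define f2      parms[1]
#define k1      parms[2]
#define k2      parms[3]
#define Kd1     parms[4]
#define Kd2     parms[5]
#define Ka1     parms[6]
#define Ka2     parms[7]
#define kdeg    parms[8]
#define kR1     parms[9]
#define kR2     parms[10]
#define kT1     parms[11]
#define kT2     parms[12]
#define kE1     parms[13]
#define kE2     parms[14]
#define KT1     parms[15]
#define KT2     parms[16]
#define KET1    parms[17]
#define KET2    parms[18]
#define KER1    parms[19]
#define KER2    parms[20]
#define alphaR1 parms[21]
#define alphaR2 parms[22]
#define betaR1  parms[23]
#define betaR2  parms[24]
#define betaT1  parms[25]
#define betaT2  parms[26]
#define betaE1  parms[27]
#define betaE2  parms[28]

void rscm_initparms(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

static double monod(double x, double K)
{
    return x / (K + x);
}

static double clip0(double x)
{
    return x > 0.0 ? x : 0.0;
}

void rscm_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double DOC = clip0(y[0]), NO3 = clip0(y[1]), NO2 = clip0(y[2]);
    double BM = clip0(y[5]);
    double rho1 = clip0(y[6]), rho2 = clip0(y[7]);
    double tau1 = clip0(y[8]), tau2 = clip0(y[9]);
    double e1 = clip0(y[10]), e2 = clip0(y[11]);

    double r1kin = k1 * monod(DOC, Kd1) * monod(NO3, Ka1);
    double r2kin = k2 * monod(DOC, Kd2) * monod(NO2, Ka2);
    double r1 = e1 * r1kin;
    double r2 = e2 * r2kin;
    double s = r1 + r2;
    double u1 = s > 0.0 ? r1 / s : 0.0;
    double u2 = s > 0.0 ? r2 / s : 0.0;

    double rR1 = kR1 * monod(DOC, Kd1) * monod(NO3, Ka1);
    double rR2 = kR2 * monod(DOC, Kd2) * monod(NO2, Ka2);
    double rT1 = kT1 * monod(rho1, KT1);
    double rT2 = kT2 * monod(rho2, KT2);
    double rE1 = kE1 * monod(tau1, KET1) * monod(rho1, KER1);
    double rE2 = kE2 * monod(tau2, KET2) * monod(rho2, KER2);

    ydot[0] = -r1 - r2 + 5.0 * kdeg * BM;                 /* DOC  */
    ydot[1] = -2.0 * f1 * r1;                             /* NO3  */
    ydot[2] = 2.0 * f1 * r1 - (4.0 / 3.0) * f2 * r2;      /* NO2  */
    ydot[3] = (2.0 / 3.0) * f2 * r2;                      /* N2   */
    ydot[4] = f1 * r1 + f2 * r2;                          /* DIC  */
    ydot[5] = (1.0 - f1) / 5.0 * r1 + (1.0 - f2) / 5.0 * r2 - kdeg * BM;
    ydot[6] = alphaR1 + u1 * rR1 - betaR1 * rho1;         /* rho1 */
    ydot[7] = alphaR2 + u2 * rR2 - betaR2 * rho2;         /* rho2 */
    ydot[8] = rT1 - betaT1 * tau1;                        /* tau1 */
    ydot[9] = rT2 - betaT2 * tau2;                        /* tau2 */
    ydot[10] = rE1 - betaE1 * e1;                         /* e1   */
    ydot[11] = rE2 - betaE2 * e2;                         /* e2   */
}

static const R_CMethodDef cMethods[] = {
    {"rscm_initparms", (DL_FUNC) &rscm_initparms, 1},
    {"rscm_derivs",    (DL_FUNC) &rscm_derivs,    6},
    {NULL, NULL, 0}
};

void R_init_rscm(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
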