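/* Compiled right-hand side of the ten-state HIF-1alpha regulatory network,
 * in deSolve's compiled-model calling convention.  The parameter vector is
 * the 45 kinetic constants in the package's canonical order followed by the
 * five treatment scale factors (constant within one integration segment;
 * the R layer restarts the integrator at every protocol event).
 * Must mirror rhs_scaled() in R/model.R exactly. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 50

static double parms[NPARMS];

/* kinetic parameters, canonical order */
#define a1     parms[0]
#define a2     parms[1]
#define a3     parms[2]
#define a5     parms[3]
#define a7     parms[4]
#define a8     parms[5]
#define a9     parms[6]
#define a11    parms[7]
#define d1     parms[8]
#define d2     parms[9]
#define d3     parms[10]
#define d4     parms[11]
#define d5     parms[12]
#define d6     parms[13]
#define d7     parms[14]
#define d8     parms[15]
#define d9     parms[16]
#define d10    parms[17]
#define k1     parms[18]
#define k2     parms[19]
#define k3     parms[20]
#define k4     parms[21]
#define k5     parms[22]
#define k6     parms[23]
#define k7     parms[24]
#define k8     parms[25]
#define k9     parms[26]
#define k10    parms[27]
#define k11    parms[28]
#define k12    parms[29]
#define k13    parms[30]
#define k14    parms[31]
#define k15    parms[32]
#define kS     parms[33]
#define kalpha parms[34]
#define n2     parms[35]
#define xi28   parms[36]
#define xi4    parms[37]
#define xi44   parms[38]
#define xi10   parms[39]
#define Delta  parms[40]
#define phi    parms[41]
#define K_O2   parms[42]
#define alpha1 parms[43]
#define alpha2 parms[44]
/* treatment scale factors */
#define s_hydrox parms[45]
#define s_st3il  parms[46]
#define s_st3blk parms[47]
#define s_mtor   parms[48]
#define s_nfkb   parms[49]

void hifnk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void hifnk_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double y1 = y[0], y2 = y[1], y3 = y[2], y4 = y[3], y5 = y[4];
    double y6 = y[5], y7 = y[6], y8 = y[7], y9 = y[8], y10 = y[9];

    double hill = 0.0;
    if (!(y8 <= 0.0 && xi28 <= 0.0)) {
        double yp = pow(y8, n2);
        hill = kS * yp / (pow(xi28, n2) + yp);
    }
    double phd   = Delta * y6 + a11;
    double fih   = k10 * K_O2 * phi * y4 / (xi4 + y4);
    double phd4  = k13 * K_O2 * phd * y4 / (xi44 + y4);
    double phd10 = k12 * K_O2 * phd * y10 / (xi10 + y10);
    double bind  = k4 * y4 * y5;

    ydot[0] = a1 - d1 * y1;
    ydot[1] = a2 + k1 * y1 + hill - d2 * y2;
    ydot[2] = s_mtor * (a3 + k2 * y2) * alpha1 / (alpha2 + y6) - d3 * y3;
    ydot[3] = kalpha * y9 - d4 * y4 - bind + k5 * y6
              - s_hydrox * (phd4 + fih) + k11 * y10;
    ydot[4] = a5 - bind + k5 * y6 - d5 * y5;
    ydot[5] = bind - k5 * y6 - d6 * y6;
    ydot[6] = s_nfkb * (a7 + k7 * y1 + k14 * y6 + k15 * y3) - d7 * y7;
    ydot[7] = s_st3blk * (a8 + k8 * y3 + s_st3il * k6 * y1) - d8 * y8;
    ydot[8] = a9 + k9 * y7 + k3 * y8 - d9 * y9;
    ydot[9] = s_hydrox * (fih - phd10) - k11 * y10 - d10 * y10;
}

static const R_CMethodDef CEntries[] = {
    {"hifnk_initmod", (DL_FUNC) &hifnk_initmod, 1},
    {"hifnk_derivs",  (DL_FUNC) &hifnk_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_hifnk(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_forceSymbols(dll, FALSE);
}
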