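/* Compiled right-hand sides for deSolve.
 *
 * Parameter vector layout for the extended model (packed by the R side,
 * see .pack_parms): the 51 model parameters in canonical order, then three
 * knockout gates (gpcr, crhfb, grloop; 0/1) and the stress level, which is
 * constant within one integration segment (piecewise-constant protocols
 * are split at their breakpoints before integration).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NP_EXT 55
static double pe[NP_EXT];

void hpa_ext_init(void (*odeparms)(int *, double *))
{
    int n = NP_EXT;
    odeparms(&n, pe);
}

/* indices into pe[] following PARAM_NAMES */
#define V_in    pe[0]
#define V_ex    pe[1]
#define V_nu    pe[2]
#define kdiff1  pe[3]
#define k1ex    pe[4]
#define k2in    pe[5]
#define k2ex    pe[6]
#define k3in    pe[7]
#define k3ex    pe[8]
#define DD(i)   pe[9 + (i) - 1]   /* d1..d15 */
#define kGRC    pe[24]
#define kGRdim  pe[25]
#define kCRC    pe[26]
#define kGC2    pe[27]
#define K1      pe[28]
#define K3      pe[29]
#define K4      pe[30]
#define K5      pe[31]
#define K6      pe[32]
#define K7      pe[33]
#define K8      pe[34]
#define K9      pe[35]
#define VV(i)   pe[36 + (i) - 1]  /* v1..v8 */
#define ks      pe[44]
#define ksb     pe[45]
#define ktl1    pe[46]
#define ktl2    pe[47]
#define ktrs1   pe[48]
#define ktrs2   pe[49]
#define hill_h  pe[50]
#define KO_GPCR   pe[51]
#define KO_CRHFB  pe[52]
#define KO_GRLOOP pe[53]
#define STRESS    pe[54]

void hpa_ext_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double COR_ex = y[0], CRH = y[1], ACTH_ex = y[2], COR_in = y[3],
        ACTH_in = y[4], GPCR = y[5], CRHR = y[6], GR = y[7], D_nu = y[8],
        mPOMC = y[9], mGR = y[10], TFs_in = y[11], TFs_nu = y[12],
        pmPOMC = y[13], pmGR = y[14];

    const double vie = V_in / V_ex;
    const double vni = V_nu / V_in;
    const double kb  = V_nu / (2.0 * V_in);

    const double CC = CRHR * CRH / kCRC;
    const double GC = (KO_GPCR > 0.5) ? 0.0
        : GPCR * COR_ex * COR_ex / kGC2;

    const double kappa = kGRC * kGRC * kGRdim;
    const double D_cyt = COR_in * COR_in * GR * GR / kappa;
    const double FF = 2.0 * (kb * k2ex * D_nu - k2in * D_cyt) /
        (1.0 + 4.0 * COR_in * GR * (COR_in + GR) / kappa);

    const double release = k1ex * CC * ACTH_in /
        (K4 * (1.0 + GC / K5) + CC);

    double tf_prod = 0.0;
    if (KO_CRHFB < 0.5) {
        const double CCh = pow(CC, hill_h);
        tf_prod = VV(4) * CCh / (pow(K6, hill_h) + CCh);
    }

    const double gr_auto = (KO_GRLOOP > 0.5) ? 0.0
        : VV(8) * D_nu / (K9 + D_nu);

    ydot[0] = vie * kdiff1 * (COR_in - COR_ex) +
        VV(1) * ACTH_ex / (K1 + ACTH_ex) - DD(1) * COR_ex;
    ydot[1] = ks * (ksb + STRESS) / (1.0 + COR_ex / K3) - DD(2) * CRH;
    ydot[2] = vie * release - DD(3) * ACTH_ex;
    ydot[3] = kdiff1 * (COR_ex - COR_in) - DD(4) * COR_in + FF;
    ydot[4] = ktl1 * mPOMC - DD(5) * ACTH_in - release;
    ydot[5] = (KO_GPCR > 0.5) ? 0.0 : VV(2) - DD(6) * GPCR;
    ydot[6] = VV(3) - DD(7) * CRHR;
    ydot[7] = ktl2 * mGR + FF - DD(8) * GR;
    ydot[8] = k2in * D_cyt - k2ex * D_nu - DD(9) * D_nu;
    ydot[9] = vni * ktrs1 * pmPOMC - DD(10) * mPOMC;
    ydot[10] = vni * ktrs2 * pmGR - DD(11) * mGR;
    ydot[11] = vni * k3ex * TFs_nu - k3in * TFs_in - DD(12) * TFs_in + tf_prod;
    ydot[12] = k3in * TFs_in - k3ex * TFs_nu - DD(13) * TFs_nu;
    ydot[13] = -ktrs1 * pmPOMC + VV(5) - DD(14) * pmPOMC +
        VV(6) * TFs_nu / (K7 * (1.0 + D_nu / K8) + TFs_nu);
    ydot[14] = -ktrs2 * pmGR + VV(7) + gr_auto - DD(15) * pmGR;
}

/* parsimonious 4-state model: 12 parameters + stress */
#define NP_PARS 13
static double pp[NP_PARS];

void hpa_pars_init(void (*odeparms)(int *, double *))
{
    int n = NP_PARS;
    odeparms(&n, pp);
}

void hpa_pars_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double CRH = y[0], ACTH = y[1], GR = y[2], COR = y[3];
    const double kc = pp[0], ki1 = pp[1], kcd = pp[2], ka = pp[3],
        ki2 = pp[4], kad = pp[5], kr = pp[6], kk = pp[7], kcr = pp[8],
        krd = pp[9], ko = pp[10], kod = pp[11], stress = pp[12];
    const double CG = COR * GR;
    ydot[0] = (kc + stress) / (1.0 + COR / ki1) - kcd * CRH;
    ydot[1] = ka * CRH / (1.0 + CG / ki2) - kad * ACTH;
    ydot[2] = kr * CG * CG / (kk + CG * CG) + kcr - krd * GR;
    ydot[3] = ko * ACTH - kod * COR;
}

static const R_CMethodDef CEntries[] = {
    {NULL, NULL, 0}
};

void R_init_hpaxis(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
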