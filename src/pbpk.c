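/* Minimal PBPK model right-hand side for deSolve.
 *
 * States: y0 = C_sys (systemic blood, mg/L), y1 = C_pv (portal vein blood),
 * y2 = C_liver (liver tissue), y3 = C_sac (adjusting compartment),
 * y4 = cumulative plasma AUC (mg*h/L).
 *
 * Parameter vector (padded to NPARMS on the R side):
 *  0 V_sys  1 V_pv  2 V_liver  3 V_sac_abs (L; 0 disables the SAC)
 *  4 Q_HA   5 Q_pv  6 Kp_liver 7 BP  8 f_u  9 CL_R
 * 10 K_in  11 K_out 12 k_a
 * 13 inflow0 = f_a * k_a * F_g * Dose (mg/h at t = 0)
 * 14 CL_direct (L/h; used when mode = 0)
 * 15 mode (0 = direct intrinsic clearance, 1 = Michaelis-Menten)
 * 16 conv = 1000 / MW (mg/L -> uM)
 * 17 npath (number of flattened sub-pathway terms)
 * 18.. pairs (A*Vm in pmol/min, Km in uM) per sub-pathway
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 40
static double p[NPARMS];

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double V_sys = p[0], V_pv = p[1], V_liver = p[2], V_sac = p[3];
    double Q_HA = p[4], Q_pv = p[5], Kp = p[6], BP = p[7];
    double fu = p[8], CL_R = p[9], K_in = p[10], K_out = p[11];
    double ka = p[12], inflow0 = p[13];
    double QH = Q_HA + Q_pv;
    double KpBP = Kp / BP;
    double CL;

    if (p[15] > 0.5) {                      /* Michaelis-Menten */
        double Cu_uM = fu * y[2] / Kp * p[16];
        int npath = (int) p[17];
        CL = 0.0;
        for (int i = 0; i < npath; i++)
            CL += p[18 + 2 * i] / (p[19 + 2 * i] + Cu_uM);
        CL *= 6e-5;                         /* uL/min -> L/h */
    } else {
        CL = p[14];
    }

    ydot[0] = (QH * y[2] / KpBP - QH * y[0] - CL_R * y[0] / BP
               - K_in * V_sys * y[0] + K_out * V_sac * y[3]) / V_sys;
    ydot[1] = (Q_pv * y[0] - Q_pv * y[1] + inflow0 * exp(-ka * *t)) / V_pv;
    ydot[2] = (Q_pv * y[1] + Q_HA * y[0] - QH * y[2] / KpBP
               - CL * fu * y[2] / Kp) / V_liver;
    ydot[3] = (V_sac > 0.0)
        ? (K_in * V_sys * y[0] - K_out * V_sac * y[3]) / V_sac
        : 0.0;
    ydot[4] = y[0] / BP;                    /* plasma AUC state */
}

static const R_CMethodDef CEntries[] = {
    {"pbpk_init",   (DL_FUNC) &pbpk_init,   1},
    {"pbpk_derivs", (DL_FUNC) &pbpk_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_mpbpkgsa(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, FALSE);
}
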