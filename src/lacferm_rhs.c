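/* Compiled right-hand side for deSolve.
 *
 * State vector (12 entries): LAC_out, LAC_in, GLU, PYR, LA, M, LR, N, LS,
 * LZ, X, cumR5 (running time-integral of the LDH flux, used for
 * conversion-fraction bookkeeping).  Must stay in exact agreement with the
 * R reference implementation in R/model.R (ode_rhs); a test asserts this.
 */
#include <R.h>
#include <math.h>

#define NPAR 37
static double parms[NPAR];

#define Km_LP      parms[0]
#define Kcat_LP    parms[1]
#define Km_GAL     parms[2]
#define Kcat_GAL   parms[3]
#define Km_GLYC    parms[4]
#define Vmax_GLYC  parms[5]
#define Km_LDH     parms[6]
#define Vmax_LDH   parms[7]
#define K_LS       parms[8]
#define d_LS       parms[9]
#define K_LZ       parms[10]
#define d_LZ       parms[11]
#define K_LR       parms[12]
#define d_LR       parms[13]
#define d_M        parms[14]
#define d_N        parms[15]
#define GR         parms[16]
#define G          parms[17]
#define n_sw       parms[18]
#define Kb         parms[19]
#define V0         parms[20]
#define V1         parms[21]
#define V2         parms[22]
#define T_max      parms[23]
#define S_sens     parms[24]
#define Ks         parms[25]
#define K_LA       parms[26]
#define mu_max     parms[27]
#define pH_thr     parms[28]
#define c0         parms[29]
#define c1         parms[30]
#define c2         parms[31]
#define f_conv     parms[32]
#define pyr_glc    parms[33]
#define variant    parms[34]  /* 0 = wild_type, 1 = engineered */
#define floor_N    parms[35]  /* 1 = floor net lacSZ transcription at 0 */
#define rep_hill   parms[36]  /* 1 = hill repression form */

void lacferm_initmod(void (*odeparms)(int *, double *))
{
    int N = NPAR;
    odeparms(&N, parms);
}

void lacferm_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double s[11];
    int i;
    for (i = 0; i < 11; i++) s[i] = (y[i] > 0.0) ? y[i] : 0.0;

    double LAC_out = s[0], LAC_in = s[1], GLU = s[2], PYR = s[3],
           LA = s[4], M = s[5], LR = s[6], N = s[7], LS = s[8],
           LZ = s[9], X = s[10];

    int eng = (variant > 0.5);
    if (!eng) { M = 0.0; LR = 0.0; }

    double pH = c0 - c1 * LA + c2 * LA * LA;
    double mu = mu_max * LAC_out / (LAC_out + Ks) * (1.0 - LA / K_LA);
    double mu_d = (mu > 0.0) ? mu : 0.0;
    double F = 1.0 - tanh(n_sw * (pH - pH_thr));

    double R1  = Kcat_LP * LS * LAC_out / (LAC_out + Km_LP);
    double R2  = Kcat_LP * LS * LAC_in / (LAC_in + Km_LP);
    double R3  = Kcat_GAL * LZ * LAC_in / (LAC_in + Km_GAL);
    double R4  = Vmax_GLYC * GLU / (GLU + Km_GLYC);
    double R5  = Vmax_LDH * PYR / (PYR + Km_LDH);
    double R6  = V0 * GR;
    double R7  = V1 * F * GR;
    double R8  = (d_M + mu_d) * M;
    double R9  = K_LR * M;
    double R10 = Kb * LR * LAC_in;
    double R11 = (d_LR + mu_d) * LR;
    double R12 = V2 * G;
    double R13 = T_max * (S_sens * LR / (1.0 + S_sens * LR)) * G;
    double R14 = (d_N + mu_d) * N;
    double R15 = K_LS * N;
    double R16 = (d_LS + mu_d) * LS;
    double R17 = K_LZ * N;
    double R18 = (d_LZ + mu_d) * LZ;
    double R19 = mu_d * X;

    double prod_N;
    if (rep_hill > 0.5) {
        prod_N = eng ? T_max * G / (1.0 + S_sens * LR) : T_max * G;
    } else if (eng) {
        prod_N = R12 - R13;
        if (floor_N > 0.5 && prod_N < 0.0) prod_N = 0.0;
    } else {
        prod_N = R12;
    }

    ydot[0]  = -R1 + R2;
    ydot[1]  = eng ? (R1 - R2 - R3 - R10) : (R1 - R2 - R3);
    ydot[2]  = R3 - R4;
    ydot[3]  = pyr_glc * R4 - f_conv * R5;
    ydot[4]  = f_conv * R5;
    ydot[5]  = eng ? (R6 + R7 - R8) : 0.0;
    ydot[6]  = eng ? (R9 - R10 - R11) : 0.0;
    ydot[7]  = prod_N - R14;
    ydot[8]  = R15 - R16;
    ydot[9]  = R17 - R18;
    ydot[10] = R19;
    ydot[11] = R5;   /* cumulative LDH flux */
}
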