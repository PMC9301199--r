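/* Respiratory-tract semi-PBPK right-hand side for deSolve's compiled
 * model interface (func = "pbpk_derivs", dllname = "nasalpbpk").
 *
 * State vector (amounts, ng):
 *   0  ELF_Nose   4  TIS_Nose    8  GI        11 UNABS
 *   1  ELF_BB     5  TIS_BB      9  CENTRAL   12 DEPOT (pre-absorption hold)
 *   2  ELF_bb     6  TIS_bb     10  ELIM
 *   3  ELF_AL     7  TIS_AL
 *
 * Parameters (see R/simulate.R, same order):
 *   0-3   PS_Nose, PS_BB, PS_bb, PS_AL          [mL/h]
 *   4-7   V_ELF   (Nose, BB, bb, AL)            [mL]
 *   8-11  V_tissue(Nose, BB, bb, AL)            [mL]
 *   12-14 fu_ELF, fu_tissue, fu_p
 *   15    kmcc_bb   16 kmcc_BB                  [1/h]
 *   17    FA        18 ka                       [1/h]
 *   19    Vc [mL]   20 CL                       [mL/h]
 */
#include <R.h>

static double parms[21];
#define N_PARMS 21

#define PS(i)     parms[(i)]
#define VELF(i)   parms[4 + (i)]
#define VTIS(i)   parms[8 + (i)]
#define FU_ELF    parms[12]
#define FU_TIS    parms[13]
#define FU_P      parms[14]
#define KMCC_bb   parms[15]
#define KMCC_BB   parms[16]
#define FA        parms[17]
#define KA        parms[18]
#define VC        parms[19]
#define CL        parms[20]

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int x;
    double cp = y[9] / VC;
    double net_tissue_to_plasma = 0.0;

    /* ELF -> tissue permeation (one-way); mucociliary bb -> BB -> GI */
    for (x = 0; x < 4; x++) {
        double celf = y[x] / VELF(x);
        double ctis = y[4 + x] / VTIS(x);
        double perm_in  = PS(x) * FU_ELF * celf;           /* ELF -> tissue  */
        double perm_out = PS(x) * (FU_TIS * ctis - FU_P * cp); /* tissue <-> plasma */
        ydot[x]     = -perm_in;
        ydot[4 + x] =  perm_in - perm_out;
        net_tissue_to_plasma += perm_out;
    }
    ydot[2] += -KMCC_bb * y[2];                 /* bb-ELF swept to BB-ELF */
    ydot[1] +=  KMCC_bb * y[2] - KMCC_BB * y[1];
    /* BB-ELF swept to pharynx and swallowed */
    ydot[8]  = KMCC_BB * y[1] - KA * y[8];      /* GI depot */
    ydot[9]  = FA * KA * y[8] + net_tissue_to_plasma - CL * cp;
    ydot[10] = CL * cp;                         /* cumulative elimination */
    ydot[11] = (1.0 - FA) * KA * y[8];          /* cumulative (1-FA) loss */
    ydot[12] = 0.0;                             /* lag depot: moved by events */
}
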