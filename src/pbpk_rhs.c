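/* Whole-body perfusion-limited PBPK right-hand side for deSolve.
 *
 * States (0-based):
 *   0..11  tissue amounts (mg), order:
 *          adipose bone brain gut heart kidney liver lung muscle skin spleen rest
 *   12     arterial blood, 13 venous blood (mg)
 *   14     gut-lumen depot (mg)
 *   15..17 cumulative eliminated: NAT2, renal, other (mg)
 *
 * Parameters (45): V[0..13], Q[0..11], Kp[0..11], fu, Km, Vmax, CLr, CLother,
 * ka, inf_rate.  The lung slot of Q holds cardiac output; the liver slot holds
 * hepatic artery flow only (gut + spleen outflow drains through the liver).
 * Blood:plasma ratio is 1 so blood concentration == plasma concentration.
 */
#include <R.h>

static double parms[45];
#define V(i)   parms[(i)]
#define Q(i)   parms[14 + (i)]
#define KP(i)  parms[26 + (i)]
#define FU     parms[38]
#define KM     parms[39]
#define VMAX   parms[40]
#define CLR    parms[41]
#define CLOTH  parms[42]
#define KA     parms[43]
#define INF    parms[44]

#define GUT 3
#define LIV 6
#define LNG 7
#define SPL 10

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = 45;
    odeparms(&n, parms);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double cart = y[12] / V(12);
    double cven = y[13] / V(13);
    double cout[12];
    double ven_in = 0.0, qsys = 0.0;
    int i;

    for (i = 0; i < 12; i++)
        cout[i] = y[i] / (V(i) * KP(i));

    double co   = Q(LNG);
    double qliv = Q(LIV) + Q(GUT) + Q(SPL);

    /* unbound drug in the liver water driving saturable N-acetylation */
    double cu = FU * cout[LIV];
    if (cu < 0.0) cu = 0.0;
    double v = VMAX * cu / (KM + cu);

    for (i = 0; i < 12; i++) {
        if (i == LNG) continue;
        qsys += Q(i);
        if (i == GUT || i == SPL || i == LIV) continue;
        ydot[i] = Q(i) * (cart - cout[i]);
        ven_in += Q(i) * cout[i];
    }

    ydot[GUT] = Q(GUT) * (cart - cout[GUT]) + KA * y[14];
    ydot[SPL] = Q(SPL) * (cart - cout[SPL]);
    ydot[LIV] = Q(LIV) * cart + Q(GUT) * cout[GUT] + Q(SPL) * cout[SPL]
              - qliv * cout[LIV] - v;
    ven_in   += qliv * cout[LIV];

    ydot[LNG] = co * (cven - cout[LNG]);
    ydot[12]  = co * cout[LNG] - qsys * cart;
    ydot[13]  = ven_in - co * cven - (CLR + CLOTH) * cven + INF;
    ydot[14]  = -KA * y[14];
    ydot[15]  = v;
    ydot[16]  = CLR * cven;
    ydot[17]  = CLOTH * cven;
}
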