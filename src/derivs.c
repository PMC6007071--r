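/* Mass-action derivatives of the reduced (OO, PP, PO) system for deSolve.
 *
 * Parameter layout (21 values, set via initfunc):
 *   0..3   p0..p3      catalytic phosphorylation rates   (catalyst PP, x nt)
 *   4..7   d0..d3      catalytic dephosphorylation rates (catalyst OO, x nd)
 *   8..11  bp0..bp3    spontaneous phosphorylation rates (x nt)
 *   12..15 bd0..bd3    spontaneous dephosphorylation rates (x nd)
 *   16 nt, 17 nd, 18 tot
 *   19 mode_OO, 20 mode_PP  (0 linear, 1 log, 2 frozen at zero)
 *
 * OP is eliminated through the conservation OO + OP + PO + PP = tot.
 *
 * Log mode integrates u = log(concentration) and is only selected (on the R
 * side) for a species whose every inflow is proportional to itself — OO when
 * bd0 = bd1 = 0, PP when bp2 = bp3 = 0. Such species can pass through
 * concentrations far below any absolute tolerance during relaxation cycles;
 * in log coordinates the slope stays O(rates) and exp() underflows to zero
 * harmlessly inside the other equations. Frozen mode pins a multiplicative
 * species started at exactly zero, which exact dynamics keeps at zero.
 */
#include <R.h>
#include <math.h>
#include <R_ext/Rdynload.h>

static double parms[21];

#define P0 parms[0]
#define P1 parms[1]
#define P2 parms[2]
#define P3 parms[3]
#define D0 parms[4]
#define D1 parms[5]
#define D2 parms[6]
#define D3 parms[7]
#define BP0 parms[8]
#define BP1 parms[9]
#define BP2 parms[10]
#define BP3 parms[11]
#define BD0 parms[12]
#define BD1 parms[13]
#define BD2 parms[14]
#define BD3 parms[15]
#define NT parms[16]
#define ND parms[17]
#define TOT parms[18]
#define MODE_OO ((int) parms[19])
#define MODE_PP ((int) parms[20])

void sw_initmod(void (*odeparms)(int *, double *))
{
    int n = 21;
    odeparms(&n, parms);
}

void sw_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double OO, PP, PO, OP;

    OO = (MODE_OO == 1) ? exp(y[0]) : (MODE_OO == 2 ? 0.0 : y[0]);
    PP = (MODE_PP == 1) ? exp(y[1]) : (MODE_PP == 2 ? 0.0 : y[1]);
    PO = y[2];
    OP = TOT - OO - PP - PO;

    if (MODE_OO == 1)
        /* d log(OO)/dt; valid because bd0 = bd1 = 0 in this mode */
        ydot[0] = -(P0 + P1) * NT * PP
            + (D0 * OP + D1 * PO) * ND
            - (BP0 + BP1) * NT;
    else if (MODE_OO == 2)
        ydot[0] = 0.0;
    else
        ydot[0] = -(P0 + P1) * NT * PP * OO
            + D0 * ND * OO * OP + D1 * ND * OO * PO
            - (BP0 + BP1) * NT * OO
            + BD0 * ND * OP + BD1 * ND * PO;

    if (MODE_PP == 1)
        /* d log(PP)/dt; valid because bp2 = bp3 = 0 in this mode */
        ydot[1] = (P3 * OP + P2 * PO) * NT
            - (D2 + D3) * ND * OO
            - (BD2 + BD3) * ND;
    else if (MODE_PP == 2)
        ydot[1] = 0.0;
    else
        ydot[1] = P3 * NT * PP * OP + P2 * NT * PP * PO
            - (D2 + D3) * ND * OO * PP
            + BP3 * NT * OP + BP2 * NT * PO
            - (BD2 + BD3) * ND * PP;

    ydot[2] = P1 * NT * PP * OO - P2 * NT * PP * PO
        + D2 * ND * OO * PP - D1 * ND * OO * PO
        + BP1 * NT * OO - BP2 * NT * PO
        + BD2 * ND * PP - BD1 * ND * PO;

    if (ip[0] >= 1)
        yout[0] = OP;
}

static const R_CMethodDef cMethods[] = {
    {"sw_initmod", (DL_FUNC) &sw_initmod, 1},
    {"sw_derivs", (DL_FUNC) &sw_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_phosswitch(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
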