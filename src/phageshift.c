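/* Compiled core: ODE right-hand side / Jacobian / floor event in the deSolve
 * compiled-model convention, and the exact SSA loop on quantized populations.
 *
 * Parameter vector layout (shared with R/params.R, do not reorder):
 *   0 lambda1, 1 lambda2, 2 Y1, 3 Y2, 4 eta1, 5 eta2, 6 beta1, 7 beta2,
 *   8 deltaC, 9 deltaB, 10 deltaP, 11 phi, 12 floor (ODE event only)
 * State order: C, B1, B2, P.
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>

static double parms[13];

#define L1   parms[0]
#define L2   parms[1]
#define YY1  parms[2]
#define YY2  parms[3]
#define E1   parms[4]
#define E2   parms[5]
#define B_1  parms[6]
#define B_2  parms[7]
#define D_C  parms[8]
#define D_B  parms[9]
#define D_P  parms[10]
#define PHI  parms[11]
#define FLR  parms[12]

void ps_initmod(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, parms);
}

void ps_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double C = y[0], B1 = y[1], B2 = y[2], P = y[3];
    ydot[0] = PHI - D_C * C - C * (L1 * B1 / YY1 + L2 * B2 / YY2);
    ydot[1] = B1 * (L1 * C - E1 * P - D_B);
    ydot[2] = B2 * (L2 * C - E2 * P - D_B);
    ydot[3] = P * (B_1 * E1 * B1 + B_2 * E2 * B2 - D_P);
}

/* full analytic Jacobian, column-major in pd (nrowpd rows) */
void ps_jac(int *neq, double *t, double *y, int *ml, int *mu,
            double *pd, int *nrowpd, double *yout, int *ip)
{
    double C = y[0], B1 = y[1], B2 = y[2], P = y[3];
    int n = *nrowpd;

    pd[0 + n * 0] = -D_C - (L1 * B1 / YY1 + L2 * B2 / YY2);
    pd[1 + n * 0] = B1 * L1;
    pd[2 + n * 0] = B2 * L2;
    pd[3 + n * 0] = 0.0;

    pd[0 + n * 1] = -C * L1 / YY1;
    pd[1 + n * 1] = L1 * C - E1 * P - D_B;
    pd[2 + n * 1] = 0.0;
    pd[3 + n * 1] = P * B_1 * E1;

    pd[0 + n * 2] = -C * L2 / YY2;
    pd[1 + n * 2] = 0.0;
    pd[2 + n * 2] = L2 * C - E2 * P - D_B;
    pd[3 + n * 2] = P * B_2 * E2;

    pd[0 + n * 3] = 0.0;
    pd[1 + n * 3] = -B1 * E1;
    pd[2 + n * 3] = -B2 * E2;
    pd[3 + n * 3] = B_1 * E1 * B1 + B_2 * E2 * B2 - D_P;
}

/* clamp event: species held at the influx floor, nutrient at zero */
void ps_event(int *n, double *t, double *y)
{
    if (y[0] < 0.0) y[0] = 0.0;
    for (int i = 1; i < 4; i++)
        if (y[i] < FLR) y[i] = FLR;
}

/* ---------------------------------------------------------------------------
 * Exact SSA on quantized populations.  Nine elementary processes; each rate is
 * the corresponding deterministic flux divided by the population quantum, so
 * rate x quantum recovers the flux and the propensity-weighted drift equals
 * the ODE right-hand side exactly.
 */

SEXP ps_ssa(SEXP s_params, SEXP s_init, SEXP s_tend, SEXP s_quantum,
            SEXP s_floor, SEXP s_recdt)
{
    double *pp = REAL(s_params);
    double l1 = pp[0], l2 = pp[1], yy1 = pp[2], yy2 = pp[3];
    double e1 = pp[4], e2 = pp[5], b1 = pp[6], b2 = pp[7];
    double dc = pp[8], db = pp[9], dp = pp[10], phi = pp[11];
    double q = asReal(s_quantum), flr = asReal(s_floor);
    double tend = asReal(s_tend), recdt = asReal(s_recdt);

    double y[4];
    for (int i = 0; i < 4; i++) y[i] = REAL(s_init)[i];

    int nrec = (int) floor(tend / recdt + 1e-9) + 1;
    SEXP s_out = PROTECT(allocMatrix(REALSXP, nrec, 5));
    SEXP s_cnt = PROTECT(allocVector(REALSXP, 9));
    double *out = REAL(s_out), *cnt = REAL(s_cnt);
    for (int k = 0; k < 9; k++) cnt[k] = 0.0;

    double t = 0.0, a[9];
    int irec = 0, halted = 0;
    R_xlen_t nev = 0;

    GetRNGstate();
    for (;;) {
        a[0] = phi / q;
        a[1] = dc * y[0] / q;
        a[2] = l1 * y[0] * y[1] / q;
        a[3] = l2 * y[0] * y[2] / q;
        a[4] = e1 * y[1] * y[3] / q;
        a[5] = e2 * y[2] * y[3] / q;
        a[6] = db * y[1] / q;
        a[7] = db * y[2] / q;
        a[8] = dp * y[3] / q;
        double atot = 0.0;
        for (int k = 0; k < 9; k++) atot += a[k];
        if (atot <= 0.0) halted = 1;

        double tnext = (atot > 0.0) ? t + exp_rand() / atot : R_PosInf;

        while (irec < nrec && irec * recdt <= tnext) {
            out[irec] = irec * recdt;
            for (int i = 0; i < 4; i++) out[irec + nrec * (i + 1)] = y[i];
            irec++;
        }
        if (irec >= nrec || atot <= 0.0) break;

        t = tnext;
        double u = unif_rand() * atot, acc = 0.0;
        int k = 8;
        for (int j = 0; j < 9; j++) {
            acc += a[j];
            if (u <= acc) { k = j; break; }
        }
        switch (k) {
        case 0: y[0] += q; break;
        case 1: y[0] -= q; break;
        case 2: y[1] += q; y[0] -= q / yy1; break;
        case 3: y[2] += q; y[0] -= q / yy2; break;
        case 4: y[1] -= q; y[3] += b1 * q; break;
        case 5: y[2] -= q; y[3] += b2 * q; break;
        case 6: y[1] -= q; break;
        case 7: y[2] -= q; break;
        case 8: y[3] -= q; break;
        }
        cnt[k] += 1.0;
        if (y[0] < 0.0) y[0] = 0.0;
        for (int i = 1; i < 4; i++)
            if (y[i] < flr) y[i] = flr;

        if ((++nev & 0x3FFFFF) == 0) R_CheckUserInterrupt();
    }
    PutRNGstate();

    /* total propensity hit zero: state is frozen for the remaining records */
    if (halted) {
        while (irec < nrec) {
            out[irec] = irec * recdt;
            for (int i = 0; i < 4; i++) out[irec + nrec * (i + 1)] = y[i];
            irec++;
        }
    }

    SEXP s_res = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(s_res, 0, s_out);
    SET_VECTOR_ELT(s_res, 1, s_cnt);
    SET_VECTOR_ELT(s_res, 2, ScalarLogical(halted));
    SEXP s_nm = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(s_nm, 0, mkChar("trajectory"));
    SET_STRING_ELT(s_nm, 1, mkChar("event_counts"));
    SET_STRING_ELT(s_nm, 2, mkChar("halted"));
    setAttrib(s_res, R_NamesSymbol, s_nm);
    UNPROTECT(4);
    return s_res;
}
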