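#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Rolling minimum / maximum over a centered window of `half` points on each
   side, with edge truncation.  Used by the TopHat (morphological opening)
   baseline: opening = dilation(erosion(x)).  O(n * w) is fine at the sizes a
   linear-TOF profile has (~2e4 points, w ~ 150). */

static SEXP roll_extreme(SEXP x, SEXP half, int do_min)
{
    R_xlen_t n = XLENGTH(x);
    int h = asInteger(half);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    const double *xs = REAL(x);
    double *o = REAL(out);
    for (R_xlen_t i = 0; i < n; i++) {
        R_xlen_t lo = i - h, hi = i + h;
        if (lo < 0) lo = 0;
        if (hi > n - 1) hi = n - 1;
        double v = xs[lo];
        for (R_xlen_t j = lo + 1; j <= hi; j++) {
            if (do_min ? (xs[j] < v) : (xs[j] > v)) v = xs[j];
        }
        o[i] = v;
    }
    UNPROTECT(1);
    return out;
}

SEXP C_roll_min(SEXP x, SEXP half) { return roll_extreme(x, half, 1); }
SEXP C_roll_max(SEXP x, SEXP half) { return roll_extreme(x, half, 0); }

static const R_CallMethodDef callMethods[] = {
    {"C_roll_min", (DL_FUNC) &C_roll_min, 2},
    {"C_roll_max", (DL_FUNC) &C_roll_max, 2},
    {NULL, NULL, 0}
};

void R_init_phycoMS(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
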