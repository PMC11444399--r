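#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Cascade of biquad sections, direct form II transposed.
   sos: n_sections x 6 (column-major: b0 b1 b2 a0 a1 a2), a0 assumed 1.
   zi:  n_sections x 2 initial state per section. */
SEXP C_sosfilt(SEXP sosS, SEXP xS, SEXP ziS)
{
    int ns = Rf_nrows(sosS);
    R_xlen_t n = Rf_xlength(xS);
    SEXP yS = PROTECT(Rf_duplicate(xS));
    double *y = REAL(yS);
    double *sos = REAL(sosS);
    double *zi = REAL(ziS);
    for (int s = 0; s < ns; ++s) {
        double b0 = sos[s + 0 * ns], b1 = sos[s + 1 * ns], b2 = sos[s + 2 * ns];
        double a1 = sos[s + 4 * ns], a2 = sos[s + 5 * ns];
        double z1 = zi[s], z2 = zi[s + ns];
        for (R_xlen_t i = 0; i < n; ++i) {
            double xi = y[i];
            double yi = b0 * xi + z1;
            z1 = b1 * xi - a1 * yi + z2;
            z2 = b2 * xi - a2 * yi;
            y[i] = yi;
        }
    }
    UNPROTECT(1);
    return yS;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_sosfilt", (DL_FUNC) &C_sosfilt, 3},
    {NULL, NULL, 0}
};

void R_init_canicoh(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
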