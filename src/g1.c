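/* Per-voxel normalized temporal autocorrelation of a complex field series.
 *
 * g1(tau) = mean_t[ conj(R(t)) R(t+tau) ] / mean_t[ |R(t)|^2 ]
 *
 * The lag-tau numerator averages over the (nt - tau) available pairs; the
 * denominator is the full lag-0 power average, so g1(0) == 1 exactly for any
 * voxel with nonzero power.  Zero-power voxels get g1(0)=1, g1(tau>0)=0 and
 * are flagged.
 *
 * data: complex array, R dims (nz, nx, ny, nt); voxel index varies fastest.
 * Returns list(g1 = complex (nz, nx, ny, max_lag + 1), zero_power = logical).
 */

#include <R.h>
#include <Rinternals.h>

SEXP C_g1_autocorr(SEXP data, SEXP dim, SEXP max_lag_)
{
    const int *d = INTEGER(dim);
    const R_xlen_t nvox = (R_xlen_t) d[0] * d[1] * d[2];
    const int nt = d[3];
    const int max_lag = asInteger(max_lag_);
    if (max_lag < 1 || max_lag >= nt)
        error("max_lag must be in [1, n_repeats - 1]");

    const Rcomplex *x = COMPLEX(data);
    const int nlag = max_lag + 1;

    SEXP g1 = PROTECT(allocVector(CPLXSXP, nvox * nlag));
    SEXP flag = PROTECT(allocVector(LGLSXP, nvox));
    Rcomplex *g = COMPLEX(g1);
    int *zp = LOGICAL(flag);

    double *br = (double *) R_alloc(nt, sizeof(double));
    double *bi = (double *) R_alloc(nt, sizeof(double));

    for (R_xlen_t v = 0; v < nvox; v++) {
        double pow0 = 0.0;
        for (int t = 0; t < nt; t++) {
            const Rcomplex z = x[v + (R_xlen_t) t * nvox];
            br[t] = z.r; bi[t] = z.i;
            pow0 += z.r * z.r + z.i * z.i;
        }
        pow0 /= nt;
        zp[v] = (pow0 == 0.0);
        g[v].r = 1.0; g[v].i = 0.0; /* lag 0 */
        for (int tau = 1; tau <= max_lag; tau++) {
            double sr = 0.0, si = 0.0;
            const int np = nt - tau;
            if (!zp[v]) {
                for (int t = 0; t < np; t++) {
                    /* conj(R(t)) * R(t+tau) */
                    sr += br[t] * br[t + tau] + bi[t] * bi[t + tau];
                    si += br[t] * bi[t + tau] - bi[t] * br[t + tau];
                }
                sr /= (double) np * pow0;
                si /= (double) np * pow0;
            }
            g[v + (R_xlen_t) tau * nvox].r = sr;
            g[v + (R_xlen_t) tau * nvox].i = si;
        }
    }

    SEXP gdim = PROTECT(allocVector(INTSXP, 4));
    INTEGER(gdim)[0] = d[0]; INTEGER(gdim)[1] = d[1];
    INTEGER(gdim)[2] = d[2]; INTEGER(gdim)[3] = nlag;
    setAttrib(g1, R_DimSymbol, gdim);

    const char *nms[] = {"g1", "zero_power", ""};
    SEXP out = PROTECT(mkNamed(VECSXP, nms));
    SET_VECTOR_ELT(out, 0, g1);
    SET_VECTOR_ELT(out, 1, flag);
    UNPROTECT(4);
    return out;
}
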