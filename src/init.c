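#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_h5_write_field(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_h5_read_field(SEXP);
SEXP C_h5_del_attr(SEXP, SEXP);
SEXP C_g1_autocorr(SEXP, SEXP, SEXP);

static const R_CallMethodDef call_entries[] = {
    {"C_h5_write_field", (DL_FUNC) &C_h5_write_field, 7},
    {"C_h5_read_field",  (DL_FUNC) &C_h5_read_field,  1},
    {"C_h5_del_attr",    (DL_FUNC) &C_h5_del_attr,    2},
    {"C_g1_autocorr",    (DL_FUNC) &C_g1_autocorr,    3},
    {NULL, NULL, 0}
};

void R_init_dualocta(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
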