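/* HDF5 container I/O for complex OCT field series.
 *
 * On-disk layout (h5py compatible):
 *   dataset /field : 4-D compound {r, i} float32 (complex64), C-order dims
 *                    (t, y, x, z) == R column-major dims (z, x, y, t)
 *   root attributes: mode (string), n_repeats (int), dt_ms (double),
 *                    pitch_um (double[3], ordered z, x, y)
 *
 * In-memory type is compound {double r; double i}, binary-compatible with
 * Rcomplex; HDF5 converts float<->double on read/write.
 */

#include <R.h>
#include <Rinternals.h>
#include <string.h>
#include <hdf5.h>

static hid_t cplx_mem_type(void)
{
    hid_t t = H5Tcreate(H5T_COMPOUND, sizeof(Rcomplex));
    H5Tinsert(t, "r", 0, H5T_NATIVE_DOUBLE);
    H5Tinsert(t, "i", sizeof(double), H5T_NATIVE_DOUBLE);
    return t;
}

static hid_t cplx_file_type(void)
{
    hid_t t = H5Tcreate(H5T_COMPOUND, 8);
    H5Tinsert(t, "r", 0, H5T_IEEE_F32LE);
    H5Tinsert(t, "i", 4, H5T_IEEE_F32LE);
    return t;
}

static void write_str_attr(hid_t loc, const char *name, const char *value)
{
    hid_t atype = H5Tcopy(H5T_C_S1);
    H5Tset_size(atype, strlen(value) + 1);
    H5Tset_strpad(atype, H5T_STR_NULLTERM);
    hid_t aspace = H5Screate(H5S_SCALAR);
    hid_t attr = H5Acreate2(loc, name, atype, aspace, H5P_DEFAULT, H5P_DEFAULT);
    H5Awrite(attr, atype, value);
    H5Aclose(attr); H5Sclose(aspace); H5Tclose(atype);
}

SEXP C_h5_write_field(SEXP path, SEXP data, SEXP dim, SEXP mode,
                      SEXP n_repeats, SEXP dt_ms, SEXP pitch_um)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    const int *d = INTEGER(dim); /* (nz, nx, ny, nt), R column-major */
    hsize_t fdims[4] = { (hsize_t) d[3], (hsize_t) d[2],
                         (hsize_t) d[1], (hsize_t) d[0] };

    hid_t file = H5Fcreate(fname, H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
    if (file < 0) error("cannot create HDF5 file '%s'", fname);

    hid_t space = H5Screate_simple(4, fdims, NULL);
    hid_t ftype = cplx_file_type();
    hid_t mtype = cplx_mem_type();
    hid_t dset = H5Dcreate2(file, "field", ftype, space,
                            H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    herr_t st = H5Dwrite(dset, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                         COMPLEX(data));
    H5Dclose(dset); H5Tclose(mtype); H5Tclose(ftype); H5Sclose(space);
    if (st < 0) { H5Fclose(file); error("HDF5 write of /field failed"); }

    hid_t root = H5Gopen2(file, "/", H5P_DEFAULT);
    write_str_attr(root, "mode", CHAR(STRING_ELT(mode, 0)));
    {
        hid_t sp = H5Screate(H5S_SCALAR);
        hid_t a = H5Acreate2(root, "n_repeats", H5T_STD_I32LE, sp,
                             H5P_DEFAULT, H5P_DEFAULT);
        H5Awrite(a, H5T_NATIVE_INT, INTEGER(n_repeats));
        H5Aclose(a); H5Sclose(sp);

        sp = H5Screate(H5S_SCALAR);
        a = H5Acreate2(root, "dt_ms", H5T_IEEE_F64LE, sp,
                       H5P_DEFAULT, H5P_DEFAULT);
        H5Awrite(a, H5T_NATIVE_DOUBLE, REAL(dt_ms));
        H5Aclose(a); H5Sclose(sp);

        hsize_t three = 3;
        sp = H5Screate_simple(1, &three, NULL);
        a = H5Acreate2(root, "pitch_um", H5T_IEEE_F64LE, sp,
                       H5P_DEFAULT, H5P_DEFAULT);
        H5Awrite(a, H5T_NATIVE_DOUBLE, REAL(pitch_um));
        H5Aclose(a); H5Sclose(sp);
    }
    H5Gclose(root);
    H5Fclose(file);
    return R_NilValue;
}

/* drop a root attribute in place (used to exercise format-error paths) */
SEXP C_h5_del_attr(SEXP path, SEXP name)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fopen(fname, H5F_ACC_RDWR, H5P_DEFAULT);
    if (file < 0) error("cannot open HDF5 file '%s'", fname);
    hid_t root = H5Gopen2(file, "/", H5P_DEFAULT);
    H5Adelete(root, CHAR(STRING_ELT(name, 0)));
    H5Gclose(root);
    H5Fclose(file);
    return R_NilValue;
}

static void require_attr(hid_t root, const char *name, const char *fname)
{
    htri_t ok = H5Aexists(root, name);
    if (ok <= 0)
        error("invalid field-series container '%s': missing attribute '%s'",
              fname, name);
}

SEXP C_h5_read_field(SEXP path)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fopen(fname, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) error("cannot open HDF5 file '%s'", fname);

    if (H5Lexists(file, "field", H5P_DEFAULT) <= 0) {
        H5Fclose(file);
        error("invalid field-series container '%s': missing dataset 'field'",
              fname);
    }
    hid_t root = H5Gopen2(file, "/", H5P_DEFAULT);
    require_attr(root, "mode", fname);
    require_attr(root, "n_repeats", fname);
    require_attr(root, "dt_ms", fname);
    require_attr(root, "pitch_um", fname);

    hid_t dset = H5Dopen2(file, "field", H5P_DEFAULT);
    hid_t space = H5Dget_space(dset);
    int rank = H5Sget_simple_extent_ndims(space);
    if (rank != 4) {
        H5Sclose(space); H5Dclose(dset); H5Gclose(root); H5Fclose(file);
        error("invalid field-series container '%s': dataset 'field' must be 4-D",
              fname);
    }
    hsize_t fdims[4];
    H5Sget_simple_extent_dims(space, fdims, NULL);
    R_xlen_t n = (R_xlen_t)(fdims[0] * fdims[1] * fdims[2] * fdims[3]);

    SEXP data = PROTECT(allocVector(CPLXSXP, n));
    hid_t mtype = cplx_mem_type();
    herr_t st = H5Dread(dset, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                        COMPLEX(data));
    H5Tclose(mtype); H5Sclose(space); H5Dclose(dset);
    if (st < 0) { H5Gclose(root); H5Fclose(file); error("HDF5 read failed"); }

    SEXP dim = PROTECT(allocVector(INTSXP, 4));
    INTEGER(dim)[0] = (int) fdims[3]; /* z */
    INTEGER(dim)[1] = (int) fdims[2]; /* x */
    INTEGER(dim)[2] = (int) fdims[1]; /* y */
    INTEGER(dim)[3] = (int) fdims[0]; /* t */
    setAttrib(data, R_DimSymbol, dim);

    /* attributes */
    char modebuf[64] = {0};
    {
        hid_t a = H5Aopen(root, "mode", H5P_DEFAULT);
        hid_t atype = H5Aget_type(a);
        size_t sz = H5Tget_size(atype);
        if (sz > 63) sz = 63;
        hid_t rtype = H5Tcopy(H5T_C_S1);
        H5Tset_size(rtype, sz + 1 > 64 ? 64 : sz + 1);
        H5Aread(a, rtype, modebuf);
        H5Tclose(rtype); H5Tclose(atype); H5Aclose(a);
    }
    int nrep = 0; double dtms = 0; double pitch[3] = {0, 0, 0};
    {
        hid_t a = H5Aopen(root, "n_repeats", H5P_DEFAULT);
        H5Aread(a, H5T_NATIVE_INT, &nrep); H5Aclose(a);
        a = H5Aopen(root, "dt_ms", H5P_DEFAULT);
        H5Aread(a, H5T_NATIVE_DOUBLE, &dtms); H5Aclose(a);
        a = H5Aopen(root, "pitch_um", H5P_DEFAULT);
        H5Aread(a, H5T_NATIVE_DOUBLE, pitch); H5Aclose(a);
    }
    H5Gclose(root);
    H5Fclose(file);

    const char *nms[] = {"data", "mode", "n_repeats", "dt_ms", "pitch_um", ""};
    SEXP out = PROTECT(mkNamed(VECSXP, nms));
    SET_VECTOR_ELT(out, 0, data);
    SET_VECTOR_ELT(out, 1, mkString(modebuf));
    SET_VECTOR_ELT(out, 2, ScalarInteger(nrep));
    SET_VECTOR_ELT(out, 3, ScalarReal(dtms));
    SEXP p = PROTECT(allocVector(REALSXP, 3));
    memcpy(REAL(p), pitch, 3 * sizeof(double));
    SET_VECTOR_ELT(out, 4, p);
    UNPROTECT(4);
    return out;
}
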