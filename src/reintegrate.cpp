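#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Explicit-Euler gradient-descent reintegration of a target gradient field:
//   u <- clip( u + dt * div( D (grad u - G) ) )
// Forward-difference gradient with Neumann boundary; divergence is its exact
// negative adjoint (backward differences with boundary rows/columns).  The
// 2x2 diffusion tensor D is per-pixel, symmetric, frozen (shared across the
// three colour channels); identity D gives the isotropic scheme.
// Stops when max|du|/dt < tol or after max_iter steps.
// [[Rcpp::export]]
List reintegrate_cpp(NumericVector u_init,
                     NumericVector G1, NumericVector G2,
                     NumericVector D11, NumericVector D12, NumericVector D22,
                     int H, int W,
                     double dt, double tol, int max_iter,
                     bool clip, bool record_energy) {
    const int npix = H * W;
    const int n = npix * 3;
    NumericVector u = clone(u_init);
    std::vector<double> q1(n), q2(n);
    std::vector<double> energy;
    if (record_energy) energy.reserve(max_iter);

    int iters = 0;
    bool finite = true, converged = false;
    double max_delta = NA_REAL;

    for (int it = 0; it < max_iter; ++it) {
        double en = 0.0;
        // residual r = grad u - G, then q = D r (per pixel, per channel)
        for (int k = 0; k < 3; ++k) {
            const int ck = npix * k;
            for (int j = 0; j < W; ++j) {
                const int cj = ck + H * j;
                for (int i = 0; i < H; ++i) {
                    const int idx = cj + i;
                    double r1 = (i < H - 1) ? u[idx + 1] - u[idx] : 0.0;
                    double r2 = (j < W - 1) ? u[idx + H] - u[idx] : 0.0;
                    r1 -= G1[idx];
                    r2 -= G2[idx];
                    if (record_energy) en += r1 * r1 + r2 * r2;
                    const int p = idx - ck;  // pixel index into D fields
                    q1[idx] = D11[p] * r1 + D12[p] * r2;
                    q2[idx] = D12[p] * r1 + D22[p] * r2;
                }
            }
        }
        if (record_energy) energy.push_back(en);

        // u += dt * div q;  div q[i,j] = q1[i,j]-q1[i-1,j] (+ boundary rows)
        //                              + q2[i,j]-q2[i,j-1] (+ boundary cols)
        max_delta = 0.0;
        for (int k = 0; k < 3; ++k) {
            const int ck = npix * k;
            for (int j = 0; j < W; ++j) {
                const int cj = ck + H * j;
                for (int i = 0; i < H; ++i) {
                    const int idx = cj + i;
                    double div = 0.0;
                    if (i < H - 1) div += q1[idx];
                    if (i > 0)     div -= q1[idx - 1];
                    if (j < W - 1) div += q2[idx];
                    if (j > 0)     div -= q2[idx - H];
                    double v = u[idx] + dt * div;
                    if (!std::isfinite(v)) { finite = false; }
                    if (clip) v = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
                    double d = std::fabs(v - u[idx]);
                    if (d > max_delta) max_delta = d;
                    u[idx] = v;
                }
            }
        }
        iters = it + 1;
        if (!finite) break;
        if (max_delta / dt < tol) { converged = true; break; }
    }

    return List::create(
        _["u"] = u,
        _["iterations"] = iters,
        _["converged"] = converged,
        _["finite"] = finite,
        _["max_delta"] = max_delta,
        _["energy"] = record_energy ? wrap(energy) : R_NilValue);
}
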