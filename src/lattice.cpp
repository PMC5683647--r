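#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Occupancy weights for k rigid ligands of footprint n (bp) on an N-bp
// lattice with fugacity x = K * L_free and nearest-neighbour contact
// factor omega (one factor per pair of ligands in immediate contact).
//
// DP over lattice positions, split by the state of site i:
//   A[i][k] : site i is the last covered site of a ligand
//   B[i][k] : site i is free
// A ligand ending at i starts at i-n+1; the segment before it ends at
// i-n, either free (B) or the end of a contacting ligand (omega * A).
// Everything is linear and homogeneous, so a uniform rescale of all
// stored values keeps the final normalised distribution exact.
static std::vector<double> pk_weights(int N, int n, double x, double omega) {
    int kmax = N / n;
    std::vector<std::vector<double>> A(N + 1, std::vector<double>(kmax + 1, 0.0));
    std::vector<std::vector<double>> B(N + 1, std::vector<double>(kmax + 1, 0.0));
    B[0][0] = 1.0;
    for (int i = 1; i <= N; ++i) {
        for (int k = 0; k <= kmax; ++k) {
            B[i][k] = B[i - 1][k] + A[i - 1][k];
            if (k >= 1 && i >= n) {
                A[i][k] = x * (B[i - n][k - 1] + omega * A[i - n][k - 1]);
            }
        }
        double mx = 0.0;
        for (int k = 0; k <= kmax; ++k)
            mx = std::max(mx, std::max(A[i][k], B[i][k]));
        if (mx > 1e250) {
            const double c = 1e-250;
            for (int j = 0; j <= i; ++j)
                for (int k = 0; k <= kmax; ++k) { A[j][k] *= c; B[j][k] *= c; }
        }
    }
    std::vector<double> w(kmax + 1);
    double Z = 0.0;
    for (int k = 0; k <= kmax; ++k) {
        w[k] = A[N][k] + B[N][k];
        Z += w[k];
    }
    for (int k = 0; k <= kmax; ++k) w[k] /= Z;
    return w;
}

//' @noRd
// [[Rcpp::export(name = ".lattice_pk_cpp")]]
NumericVector lattice_pk_cpp(int N, int n, double x, double omega) {
    if (N < 1 || n < 1) stop("N and n must be >= 1");
    if (x < 0) stop("fugacity x must be >= 0");
    if (omega <= 0) stop("omega must be > 0");
    std::vector<double> w = pk_weights(N, n, x, omega);
    return NumericVector(w.begin(), w.end());
}

static double mean_k(int N, int n, double x, double omega) {
    std::vector<double> w = pk_weights(N, n, x, omega);
    double m = 0.0;
    for (size_t k = 1; k < w.size(); ++k) m += k * w[k];
    return m;
}

// Free-ligand concentration under mass conservation:
//   protein_total = L + dna_total * <k>(L)
// <k> is non-decreasing in L, so the conservation function is strictly
// increasing; plain bisection on [0, protein_total].
// [[Rcpp::export(name = ".solve_free_cpp")]]
double solve_free_cpp(int N, int n, double K, double omega,
                      double dna_total, double protein_total) {
    if (protein_total <= 0) return 0.0;
    if (dna_total <= 0 || K <= 0) return protein_total;
    double lo = 0.0, hi = protein_total;
    for (int it = 0; it < 200; ++it) {
        double mid = 0.5 * (lo + hi);
        double g = mid + dna_total * mean_k(N, n, K * mid, omega) - protein_total;
        if (g > 0) hi = mid; else lo = mid;
        if ((hi - lo) <= 1e-14 * protein_total) break;
    }
    return 0.5 * (lo + hi);
}

// Depletion-corrected band-fraction matrix: one row per protein total,
// columns k = 0..floor(N/n).
// [[Rcpp::export(name = ".titration_fractions_cpp")]]
NumericMatrix titration_fractions_cpp(int N, int n, double K, double omega,
                                      double dna_total,
                                      NumericVector protein_totals) {
    int kmax = N / n;
    int m = protein_totals.size();
    NumericMatrix out(m, kmax + 1);
    NumericVector lfree(m);
    for (int i = 0; i < m; ++i) {
        double L = solve_free_cpp(N, n, K, omega, dna_total, protein_totals[i]);
        lfree[i] = L;
        std::vector<double> w = pk_weights(N, n, K * L, omega);
        for (int k = 0; k <= kmax; ++k) out(i, k) = w[k];
    }
    out.attr("L_free") = lfree;
    return out;
}
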