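#include <Rcpp.h>
#include <algorithm>
#include <vector>
#ifdef _OPENMP
#include <omp.h>
#endif

using namespace Rcpp;

// Bases are encoded 0=A, 1=C, 2=G, 3=U by the R wrappers.
// Complementary pairs: AU, GC, GU (wobble), unordered.
static inline int sigma_code(int a, int b) {
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 1; // AU
    if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 1; // GC
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1; // GU
    return 0;
}

// Maximum-matching DP, original loop order: i descending, j ascending,
// all split instances (k ascending) before the pairing statement.
// [[Rcpp::export]]
IntegerMatrix nussinov_ref_cpp(IntegerVector seq) {
    const int N = seq.size();
    IntegerMatrix S(N, N);
    for (int i = N - 2; i >= 0; --i) {
        for (int j = i + 1; j < N; ++j) {
            int acc = S(i, j);
            for (int k = 0; k < j - i; ++k) {      // S1: split at i+k
                const int cand = S(i, i + k) + S(i + k + 1, j);
                if (cand > acc) acc = cand;
            }
            const int pair = S(i + 1, j - 1) + sigma_code(seq[i], seq[j]); // S2
            S(i, j) = std::max(acc, pair);
        }
    }
    return S;
}

// Transpose engine: the lower triangle mirrors the upper one as cells are
// finished, so the second operand of the split sum is read along row j
// (S(j, i+k+1) == S(i+k+1, j)) instead of down column j.
// [[Rcpp::export]]
IntegerMatrix nussinov_transpose_cpp(IntegerVector seq) {
    const int N = seq.size();
    IntegerMatrix S(N, N);
    for (int i = N - 2; i >= 0; --i) {
        for (int j = i + 1; j < N; ++j) {
            int acc = S(i, j);
            for (int k = 0; k < j - i; ++k) {
                const int cand = S(i, i + k) + S(j, i + k + 1);
                if (cand > acc) acc = cand;
            }
            const int pair = S(i + 1, j - 1) + sigma_code(seq[i], seq[j]);
            S(i, j) = std::max(acc, pair);
            S(j, i) = S(i, j);
        }
    }
    return S;
}

// Deterministic splitmix/LCG shuffle so that tile-order permutations are
// reproducible across platforms without touching R's RNG.
static inline uint32_t lcg_next(uint32_t &state) {
    state = state * 1664525u + 1013904223u;
    return state;
}

static void shuffle_ids(std::vector<int> &v, uint32_t &state) {
    for (int n = (int)v.size() - 1; n > 0; --n) {
        const int idx = (int)(lcg_next(state) % (uint32_t)(n + 1));
        std::swap(v[n], v[idx]);
    }
}

// Space-time tiled executor.  Tiles are identified by (ii, jj, i0, tt):
// ii  : band over the row index i, anchored at the top (ii = 0 covers
//       i in [N-ws, N-1]) because i descends in the original order;
// jj  : band over the anti-diagonal i0 = j - i, i0 in (ws*jj, ws*jj+ws];
// tt  : time slice, over k for the split statement and over j for the
//       pairing statement.
// Wavefronts w = ii + jj run serially; within a wavefront the (ii, jj)
// space tiles are independent and may run in any order (optionally
// shuffled, optionally on OpenMP threads); inside one space tile i0, tt,
// i, then (split k-chunk, pairing) run in schedule-tuple order.
// [[Rcpp::export]]
IntegerMatrix nussinov_tiled_cpp(IntegerVector seq, int ws, int wt,
                                 int threads = 1, bool shuffle = false,
                                 int seed = 1) {
    const int N = seq.size();
    IntegerMatrix S(N, N);
    if (N < 2) return S;
    const int iimax = (N - 1) / ws;
    const int jjmax = (N - 2) / ws;
    uint32_t rng = (uint32_t)seed * 2654435761u + 1u;

    for (int w = 0; w <= iimax + jjmax; ++w) {
        std::vector<int> jjs;
        for (int jj = std::max(0, w - iimax); jj <= std::min(w, jjmax); ++jj)
            jjs.push_back(jj);
        if (shuffle) shuffle_ids(jjs, rng);

        const int ntile = (int)jjs.size();
#ifdef _OPENMP
#pragma omp parallel for num_threads(threads) schedule(dynamic)
#endif
        for (int t = 0; t < ntile; ++t) {
            const int jj = jjs[t];
            const int ii = w - jj;
            const int iLo = std::max(0, N - ws * (ii + 1));
            const int iHi0 = std::min(N - ws * ii - 1, N - 2);
            if (iLo > iHi0) continue;
            const int d0 = ws * jj + 1;
            const int d1 = std::min(ws * jj + ws, N - 1);
            for (int i0 = d0; i0 <= d1; ++i0) {
                const int iHi = std::min(iHi0, N - 1 - i0);
                if (iLo > iHi) continue;
                const int ttmax = (i0 + iHi) / wt;
                for (int tt = 0; tt <= ttmax; ++tt) {
                    const int kLo = wt * tt;
                    const int kHi = std::min(wt * tt + wt - 1, i0 - 1);
                    for (int i = iLo; i <= iHi; ++i) {
                        const int j = i0 + i;
                        int acc = S(i, j);
                        for (int k = kLo; k <= kHi; ++k) {
                            const int cand = S(i, i + k) + S(i + k + 1, j);
                            if (cand > acc) acc = cand;
                        }
                        if (j / wt == tt) {
                            const int pair =
                                S(i + 1, j - 1) + sigma_code(seq[i], seq[j]);
                            if (pair > acc) acc = pair;
                        }
                        S(i, j) = acc;
                    }
                }
            }
        }
    }
    return S;
}

// [[Rcpp::export]]
bool has_openmp_cpp() {
#ifdef _OPENMP
    return true;
#else
    return false;
#endif
}
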