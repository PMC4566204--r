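#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

// Pair codes: 0 AU, 1 UA, 2 GC, 3 CG, 4 GU, 5 UG, -1 not pairable.
static inline int pair_code(char a, char b) {
    if (a == 'A' && b == 'U') return 0;
    if (a == 'U' && b == 'A') return 1;
    if (a == 'G' && b == 'C') return 2;
    if (a == 'C' && b == 'G') return 3;
    if (a == 'G' && b == 'U') return 4;
    if (a == 'U' && b == 'G') return 5;
    return -1;
}

// ---------------------------------------------------------------------------
// Nussinov base-pair maximization with a minimum hairpin loop.
// Traceback prefers pairing (i,j) over bifurcation on ties.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop) {
    const int n = (int)seq.size();
    std::string db(n, '.');
    if (n == 0) return List::create(_["pairs"] = 0, _["structure"] = db);
    std::vector<std::vector<int> > N(n, std::vector<int>(n, 0));
    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = N[i][j - 1]; // j unpaired
            for (int k = i; k <= j - min_loop - 1; ++k) {
                if (pair_code(seq[k], seq[j]) < 0) continue;
                int left = (k > i) ? N[i][k - 1] : 0;
                int inner = (k + 1 <= j - 1) ? N[k + 1][j - 1] : 0;
                int v = left + inner + 1;
                if (v > best) best = v;
            }
            N[i][j] = best;
        }
    }
    // deterministic traceback: prefer pairing (i,j) itself, then the smallest
    // pairing partner k, then leaving j unpaired
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j || N[i][j] == 0) continue;
        bool done = false;
        if (pair_code(seq[i], seq[j]) >= 0 && j - i - 1 >= min_loop) {
            int inner = (i + 1 <= j - 1) ? N[i + 1][j - 1] : 0;
            if (inner + 1 == N[i][j]) {
                db[i] = '('; db[j] = ')';
                stack.push_back(std::make_pair(i + 1, j - 1));
                done = true;
            }
        }
        if (!done) {
            for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
                if (pair_code(seq[k], seq[j]) < 0) continue;
                int left = (k > i) ? N[i][k - 1] : 0;
                int inner = (k + 1 <= j - 1) ? N[k + 1][j - 1] : 0;
                if (left + inner + 1 == N[i][j]) {
                    db[k] = '('; db[j] = ')';
                    if (k > i) stack.push_back(std::make_pair(i, k - 1));
                    if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
                    done = true;
                }
            }
        }
        if (!done) stack.push_back(std::make_pair(i, j - 1));
    }
    return List::create(_["pairs"] = N[0][n - 1], _["structure"] = db);
}

// ---------------------------------------------------------------------------
// Reduced nearest-neighbour minimum-free-energy folding (Zuker-style):
// stacking energies for the 36 ordered pair stacks, affine hairpin /
// bulge / internal-loop penalties, and a linear multiloop model.
// No dangling ends or coaxial stacking.
// ---------------------------------------------------------------------------

struct EP {
    double stack[6][6];
    double hairpin_a, hairpin_b;
    double bulge_a, bulge_b;
    double internal_a, internal_b;
    double multi_a, multi_b, multi_c;
    int min_loop, max_internal, hairpin_cap;
};

static const double INF = 1e9;

static inline double hairpinE(const EP &p, int size) {
    int s = size > p.hairpin_cap ? p.hairpin_cap : size;
    return p.hairpin_a + p.hairpin_b * s;
}

// [[Rcpp::export(name = ".zuker_cpp")]]
List zuker_cpp(std::string seq, NumericMatrix stack_mat,
               double hairpin_a, double hairpin_b,
               double bulge_a, double bulge_b,
               double internal_a, double internal_b,
               double multi_a, double multi_b, double multi_c,
               int min_loop, int max_internal, int hairpin_cap) {
    const int n = (int)seq.size();
    std::string db(n, '.');
    if (n == 0) return List::create(_["mfe"] = 0.0, _["structure"] = db);
    EP p;
    for (int a = 0; a < 6; ++a)
        for (int b = 0; b < 6; ++b) p.stack[a][b] = stack_mat(a, b);
    p.hairpin_a = hairpin_a; p.hairpin_b = hairpin_b;
    p.bulge_a = bulge_a; p.bulge_b = bulge_b;
    p.internal_a = internal_a; p.internal_b = internal_b;
    p.multi_a = multi_a; p.multi_b = multi_b; p.multi_c = multi_c;
    p.min_loop = min_loop; p.max_internal = max_internal; p.hairpin_cap = hairpin_cap;

    std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
    std::vector<std::vector<double> > WM(n, std::vector<double>(n, INF));
    std::vector<std::vector<double> > WM2(n, std::vector<double>(n, INF));

    for (int len = 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int pc = pair_code(seq[i], seq[j]);
            if (pc >= 0 && j - i - 1 >= p.min_loop) {
                double best = hairpinE(p, j - i - 1);
                // stacking + bulge/internal: inner pair (k,l)
                for (int k = i + 1; k < j; ++k) {
                    if (k - i - 1 > p.max_internal) break;
                    for (int l = j - 1; l > k; --l) {
                        int size1 = k - i - 1, size2 = j - l - 1;
                        if (size1 + size2 > p.max_internal) break; // size2 grows as l falls
                        if (V[k][l] >= INF) continue;
                        int pc2 = pair_code(seq[k], seq[l]);
                        if (pc2 < 0) continue;
                        double e;
                        if (size1 == 0 && size2 == 0)
                            e = p.stack[pc][pc2] + V[k][l];
                        else if (size1 == 0 || size2 == 0)
                            e = p.bulge_a + p.bulge_b * (size1 + size2) + V[k][l];
                        else
                            e = p.internal_a + p.internal_b * (size1 + size2) + V[k][l];
                        if (e < best) best = e;
                    }
                }
                // multiloop closed by (i,j)
                if (j - i - 1 >= 2 && WM2[i + 1][j - 1] < INF) {
                    double e = p.multi_a + p.multi_b + WM2[i + 1][j - 1];
                    if (e < best) best = e;
                }
                V[i][j] = best;
            }
            // WM: >= 1 branch inside a multiloop
            double wm = INF;
            if (V[i][j] < INF) wm = V[i][j] + p.multi_b;
            if (i + 1 <= j && WM[i + 1][j] < INF) wm = std::min(wm, WM[i + 1][j] + p.multi_c);
            if (i <= j - 1 && WM[i][j - 1] < INF) wm = std::min(wm, WM[i][j - 1] + p.multi_c);
            for (int k = i + 1; k <= j; ++k) {
                if (WM[i][k - 1] < INF && V[k][j] < INF)
                    wm = std::min(wm, WM[i][k - 1] + V[k][j] + p.multi_b);
            }
            WM[i][j] = wm;
            // WM2: >= 2 branches
            double wm2 = INF;
            if (i <= j - 1 && WM2[i][j - 1] < INF) wm2 = WM2[i][j - 1] + p.multi_c;
            for (int k = i + 1; k <= j; ++k) {
                if (WM[i][k - 1] < INF && V[k][j] < INF)
                    wm2 = std::min(wm2, WM[i][k - 1] + V[k][j] + p.multi_b);
            }
            WM2[i][j] = wm2;
        }
    }

    // external loop
    std::vector<double> W(n + 1, 0.0);
    for (int j = 1; j <= n; ++j) {
        double w = W[j - 1];
        for (int i = 1; i <= j; ++i) {
            if (V[i - 1][j - 1] < INF)
                w = std::min(w, W[i - 1] + V[i - 1][j - 1]);
        }
        W[j] = w;
    }

    // traceback
    const double eps = 1e-9;
    enum Kind { TRV, TRWM, TRWM2 };
    std::vector<std::pair<int, std::pair<int, int> > > st;
    {   // external
        int j = n;
        while (j > 0) {
            if (std::fabs(W[j] - W[j - 1]) < eps) { --j; continue; }
            bool found = false;
            for (int i = 1; i <= j && !found; ++i) {
                if (V[i - 1][j - 1] < INF &&
                    std::fabs(W[j] - (W[i - 1] + V[i - 1][j - 1])) < eps) {
                    st.push_back(std::make_pair((int)TRV, std::make_pair(i - 1, j - 1)));
                    j = i - 1; found = true;
                }
            }
            if (!found) --j; // numerical safety
        }
    }
    while (!st.empty()) {
        int kind = st.back().first;
        int i = st.back().second.first, j = st.back().second.second;
        st.pop_back();
        if (kind == TRV) {
            db[i] = '('; db[j] = ')';
            int pc = pair_code(seq[i], seq[j]);
            double v = V[i][j];
            if (std::fabs(v - hairpinE(p, j - i - 1)) < eps) continue;
            bool found = false;
            for (int k = i + 1; k < j && !found; ++k) {
                if (k - i - 1 > p.max_internal) break;
                for (int l = j - 1; l > k && !found; --l) {
                    int size1 = k - i - 1, size2 = j - l - 1;
                    if (size1 + size2 > p.max_internal) break;
                    if (V[k][l] >= INF) continue;
                    if (pair_code(seq[k], seq[l]) < 0) continue;
                    double e;
                    int pc2 = pair_code(seq[k], seq[l]);
                    if (size1 == 0 && size2 == 0) e = p.stack[pc][pc2] + V[k][l];
                    else if (size1 == 0 || size2 == 0)
                        e = p.bulge_a + p.bulge_b * (size1 + size2) + V[k][l];
                    else e = p.internal_a + p.internal_b * (size1 + size2) + V[k][l];
                    if (std::fabs(v - e) < eps) {
                        st.push_back(std::make_pair((int)TRV, std::make_pair(k, l)));
                        found = true;
                    }
                }
            }
            if (!found && j - i - 1 >= 2 && WM2[i + 1][j - 1] < INF &&
                std::fabs(v - (p.multi_a + p.multi_b + WM2[i + 1][j - 1])) < eps) {
                st.push_back(std::make_pair((int)TRWM2, std::make_pair(i + 1, j - 1)));
            }
        } else if (kind == TRWM2) {
            double v = WM2[i][j];
            if (i <= j - 1 && WM2[i][j - 1] < INF &&
                std::fabs(v - (WM2[i][j - 1] + p.multi_c)) < eps) {
                st.push_back(std::make_pair((int)TRWM2, std::make_pair(i, j - 1)));
                continue;
            }
            for (int k = i + 1; k <= j; ++k) {
                if (WM[i][k - 1] < INF && V[k][j] < INF &&
                    std::fabs(v - (WM[i][k - 1] + V[k][j] + p.multi_b)) < eps) {
                    st.push_back(std::make_pair((int)TRWM, std::make_pair(i, k - 1)));
                    st.push_back(std::make_pair((int)TRV, std::make_pair(k, j)));
                    break;
                }
            }
        } else { // TRWM
            double v = WM[i][j];
            if (V[i][j] < INF && std::fabs(v - (V[i][j] + p.multi_b)) < eps) {
                st.push_back(std::make_pair((int)TRV, std::make_pair(i, j)));
                continue;
            }
            if (i + 1 <= j && WM[i + 1][j] < INF &&
                std::fabs(v - (WM[i + 1][j] + p.multi_c)) < eps) {
                st.push_back(std::make_pair((int)TRWM, std::make_pair(i + 1, j)));
                continue;
            }
            if (i <= j - 1 && WM[i][j - 1] < INF &&
                std::fabs(v - (WM[i][j - 1] + p.multi_c)) < eps) {
                st.push_back(std::make_pair((int)TRWM, std::make_pair(i, j - 1)));
                continue;
            }
            for (int k = i + 1; k <= j; ++k) {
                if (WM[i][k - 1] < INF && V[k][j] < INF &&
                    std::fabs(v - (WM[i][k - 1] + V[k][j] + p.multi_b)) < eps) {
                    st.push_back(std::make_pair((int)TRWM, std::make_pair(i, k - 1)));
                    st.push_back(std::make_pair((int)TRV, std::make_pair(k, j)));
                    break;
                }
            }
        }
    }
    return List::create(_["mfe"] = W[n], _["structure"] = db);
}
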