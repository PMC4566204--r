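#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Affine-gap local alignment. A gap of length L costs gap_open + gap_ext * L
// (Biostrings convention), so the open transition costs gap_open + gap_ext.

struct AlnRes {
    int score, qs, qe, ss, se, nmatch, alen, ngap;
    AlnRes() : score(0), qs(0), qe(0), ss(0), se(0), nmatch(0), alen(0), ngap(0) {}
};

// Full Smith-Waterman with traceback; coordinates are 1-based inclusive,
// qs..qe on the query, ss..se on the subject. Returns score 0 when the best
// local alignment is empty. Rolling DP rows; one packed traceback byte per
// cell: bits 0-1 = H source (0 stop, 1 diag, 2 E, 3 F), bit 2 = E extends,
// bit 3 = F extends.
static AlnRes sw_affine(const std::string &q, const std::string &s,
                        int match, int mismatch, int go, int ge) {
    const int n = (int)q.size(), m = (int)s.size();
    const int NEG = -(1 << 28);
    std::vector<int> Hprev(m + 1, 0), Hrow(m + 1, 0), F(m + 1, NEG);
    std::vector<uint8_t> TB((size_t)n * m, 0);
    int best = 0, bi = 0, bj = 0;
    const int open_cost = go + ge;
    for (int i = 1; i <= n; ++i) {
        uint8_t *tb = &TB[(size_t)(i - 1) * m];
        const char qc = q[i - 1];
        int e = NEG;
        Hrow[0] = 0;
        int hdiag = Hprev[0]; // H[i-1][j-1] as j sweeps
        for (int j = 1; j <= m; ++j) {
            uint8_t t = 0;
            int e_open = Hrow[j - 1] - open_cost;
            int e_ext = e - ge;
            if (e_ext > e_open) { e = e_ext; t |= 4; } else e = e_open;
            int f_open = Hprev[j] - open_cost;
            int f_ext = F[j] - ge;
            int f;
            if (f_ext > f_open) { f = f_ext; t |= 8; } else f = f_open;
            F[j] = f;
            int diag = hdiag + ((qc == s[j - 1]) ? match : mismatch);
            hdiag = Hprev[j];
            int h = 0; uint8_t src = 0;
            if (diag > h) { h = diag; src = 1; }
            if (e > h) { h = e; src = 2; }
            if (f > h) { h = f; src = 3; }
            Hrow[j] = h;
            tb[j - 1] = t | src;
            if (h > best) { best = h; bi = i; bj = j; }
        }
        std::swap(Hprev, Hrow);
    }
    AlnRes r;
    if (best <= 0) return r;
    r.score = best; r.qe = bi; r.se = bj;
    int i = bi, j = bj;
    int state = 0; // 0 = in H, 2 = in E, 3 = in F
    while (i > 0 && j > 0) {
        uint8_t t = TB[(size_t)(i - 1) * m + (j - 1)];
        if (state == 0) {
            uint8_t src = t & 3;
            if (src == 0) break;
            if (src == 1) {
                r.alen++; if (q[i - 1] == s[j - 1]) r.nmatch++;
                --i; --j;
            } else state = src;
        } else if (state == 2) {
            r.alen++; r.ngap++;
            if (!(t & 4)) state = 0;
            --j;
        } else {
            r.alen++; r.ngap++;
            if (!(t & 8)) state = 0;
            --i;
        }
    }
    r.qs = i + 1; r.ss = j + 1;
    return r;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  int match, int mismatch, int gap_open, int gap_ext) {
    if ((double)query.size() * (double)subject.size() > 6.4e7)
        stop("exact Smith-Waterman restricted to <= 6.4e7 cells");
    AlnRes r = sw_affine(query, subject, match, mismatch, gap_open, gap_ext);
    return List::create(_["score"] = r.score, _["qstart"] = r.qs, _["qend"] = r.qe,
                        _["sstart"] = r.ss, _["send"] = r.se, _["nmatch"] = r.nmatch,
                        _["alnlen"] = r.alen, _["gaps"] = r.ngap);
}

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
    }
}

// k-mer seeded search of each query against a set of subjects.
// Seed hits are grouped into diagonal bands; a band qualifies when it holds
// at least min_seed_hits seeds at non-overlapping query offsets (two-hit
// style filtering), and is then resolved by an exact Smith-Waterman
// restricted to a subject window around the band, so a reported HSP is the
// optimal local alignment within its window.
// [[Rcpp::export(name = ".seed_search_cpp")]]
DataFrame seed_search_cpp(CharacterVector queries, CharacterVector subjects,
                          int word, int match, int mismatch,
                          int gap_open, int gap_ext,
                          int min_seed_hits, int band_pad, int min_score) {
    const int nq = queries.size(), ns = subjects.size();
    std::vector<std::string> subj(ns);
    size_t total = 0;
    for (int k = 0; k < ns; ++k) {
        subj[k] = as<std::string>(subjects[k]);
        total += subj[k].size();
    }

    // sorted flat index of (kmer, subject, position), binary-searched
    struct Entry { uint64_t key; int32_t sidx, pos; };
    std::vector<Entry> index;
    index.reserve(total);
    const uint64_t mask = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
    for (int k = 0; k < ns; ++k) {
        const std::string &s = subj[k];
        uint64_t key = 0; int run = 0;
        for (int p = 0; p < (int)s.size(); ++p) {
            int c = base_code(s[p]);
            if (c < 0) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t)c) & mask;
            if (++run >= word) {
                Entry e; e.key = key; e.sidx = k; e.pos = p - word + 1;
                index.push_back(e);
            }
        }
    }
    std::sort(index.begin(), index.end(),
              [](const Entry &a, const Entry &b) { return a.key < b.key; });

    std::vector<int> o_q, o_s, o_score, o_qs, o_qe, o_ss, o_se, o_nm, o_al, o_gap;

    for (int qi = 0; qi < nq; ++qi) {
        std::string q = as<std::string>(queries[qi]);
        const int qlen = (int)q.size();
        if (qlen < word) continue;
        // seed hits per subject: (diag, spos, qpos)
        struct Hit { int diag, spos, qpos; };
        std::vector<std::vector<Hit> > hits(ns);
        uint64_t key = 0; int run = 0;
        for (int p = 0; p < qlen; ++p) {
            int c = base_code(q[p]);
            if (c < 0) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t)c) & mask;
            if (++run >= word) {
                int qpos = p - word + 1;
                Entry probe; probe.key = key; probe.sidx = 0; probe.pos = 0;
                std::vector<Entry>::iterator lo = std::lower_bound(
                    index.begin(), index.end(), probe,
                    [](const Entry &a, const Entry &b) { return a.key < b.key; });
                size_t cnt = 0;
                for (std::vector<Entry>::iterator it = lo;
                     it != index.end() && it->key == key && cnt < 10000;
                     ++it, ++cnt) {
                    Hit h; h.diag = it->pos - qpos; h.spos = it->pos;
                    h.qpos = qpos;
                    hits[it->sidx].push_back(h);
                }
            }
        }
        for (int k = 0; k < ns; ++k) {
            if (hits[k].empty()) continue;
            std::vector<Hit> &hv = hits[k];
            std::sort(hv.begin(), hv.end(), [](const Hit &a, const Hit &b) {
                return a.diag != b.diag ? a.diag < b.diag : a.spos < b.spos;
            });
            // group seed hits whose diagonals lie within band_pad of each other
            std::vector<AlnRes> found;
            size_t g0 = 0;
            while (g0 < hv.size()) {
                size_t g1 = g0 + 1;
                int dmin = hv[g0].diag, dmax = hv[g0].diag;
                while (g1 < hv.size() && hv[g1].diag - dmax <= band_pad) {
                    dmax = hv[g1].diag; ++g1;
                }
                // effective seeds: non-overlapping query offsets
                int eff = 0, lastq = -word;
                {
                    std::vector<int> qp;
                    for (size_t h = g0; h < g1; ++h) qp.push_back(hv[h].qpos);
                    std::sort(qp.begin(), qp.end());
                    for (size_t h = 0; h < qp.size(); ++h)
                        if (qp[h] >= lastq + word) { ++eff; lastq = qp[h]; }
                }
                if (eff >= min_seed_hits) {
                    int w0 = dmin - band_pad;               // window start = diag range
                    int w1 = dmax + qlen + word + band_pad; // + query span + padding
                    if (w0 < 0) w0 = 0;
                    if (w1 > (int)subj[k].size()) w1 = (int)subj[k].size();
                    // keep each window DP tractable even for repeat-dense bands
                    if ((double)qlen * (double)(w1 - w0) > 6.4e7)
                        w1 = w0 + qlen + 2 * band_pad + word;
                    if (w1 > w0) {
                        std::string win = subj[k].substr(w0, w1 - w0);
                        AlnRes r = sw_affine(q, win, match, mismatch, gap_open, gap_ext);
                        if (r.score >= min_score) {
                            r.ss += w0; r.se += w0;
                            found.push_back(r);
                        }
                    }
                }
                g0 = g1;
            }
            // drop HSPs that mostly overlap a better HSP on the subject
            std::sort(found.begin(), found.end(),
                      [](const AlnRes &a, const AlnRes &b) { return a.score > b.score; });
            std::vector<AlnRes> kept;
            for (size_t a = 0; a < found.size(); ++a) {
                bool dup = false;
                for (size_t b = 0; b < kept.size(); ++b) {
                    int ov = std::min(found[a].se, kept[b].se) -
                             std::max(found[a].ss, kept[b].ss) + 1;
                    int len = found[a].se - found[a].ss + 1;
                    if (ov > 0 && 2 * ov >= len) { dup = true; break; }
                }
                if (!dup) kept.push_back(found[a]);
            }
            for (size_t a = 0; a < kept.size(); ++a) {
                const AlnRes &r = kept[a];
                o_q.push_back(qi + 1); o_s.push_back(k + 1);
                o_score.push_back(r.score);
                o_qs.push_back(r.qs); o_qe.push_back(r.qe);
                o_ss.push_back(r.ss); o_se.push_back(r.se);
                o_nm.push_back(r.nmatch); o_al.push_back(r.alen); o_gap.push_back(r.ngap);
            }
        }
    }
    return DataFrame::create(_["qidx"] = o_q, _["sidx"] = o_s, _["score"] = o_score,
                             _["qstart"] = o_qs, _["qend"] = o_qe,
                             _["sstart"] = o_ss, _["send"] = o_se,
                             _["nmatch"] = o_nm, _["alnlen"] = o_al, _["gaps"] = o_gap);
}
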