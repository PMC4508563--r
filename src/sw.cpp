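#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Affine-gap Smith-Waterman over integer-encoded residues (0-based indices
// into the substitution matrix). A gap of length k costs gap_open +
// k * gap_extend (BLAST convention). Alignments must start and end on a
// substitution column; scores are floored at zero.
//
// Traceback states: 0 = stop, 1 = diagonal (M), 2 = up/gap-in-subject (Ix),
// 3 = left/gap-in-query (Iy).

struct SWResult {
    double score;
    int q_start, q_end, s_start, s_end; // 1-based inclusive, 0 if no hit
    int aln_length, n_ident, n_pos;
};

// reusable DP workspace: avoids per-call allocation in batch mode
struct SWWork {
    std::vector<double> M, Ix, Iy;
    std::vector<uint8_t> tbM, tbX, tbY;
    void ensure(size_t cells) {
        if (M.size() < cells) {
            M.resize(cells); Ix.resize(cells); Iy.resize(cells);
            tbM.resize(cells); tbX.resize(cells); tbY.resize(cells);
        }
    }
};

static SWResult sw_core(const int *a, int m, const int *b, int n,
                        const double *S, int ns,
                        double gap_open, double gap_extend, SWWork &w) {
    const double NEG = -1e30;
    const double gi = gap_open + gap_extend; // cost of opening (length-1 gap)
    size_t cells = (size_t)(m + 1) * (n + 1);
    w.ensure(cells);
    std::vector<double> &M = w.M, &Ix = w.Ix, &Iy = w.Iy;
    std::vector<uint8_t> &tbM = w.tbM, &tbX = w.tbX, &tbY = w.tbY;
    // only the DP boundaries need initialization; inner cells are written
    // before they are read
    for (int j = 0; j <= n; ++j) { M[j] = 0.0; Ix[j] = NEG; Iy[j] = NEG; }
    for (int i = 1; i <= m; ++i) {
        size_t c = (size_t)i * (n + 1);
        M[c] = 0.0; Ix[c] = NEG; Iy[c] = NEG;
    }

    double best = 0.0;
    int bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
        const double *Srow = S + (size_t)a[i - 1] * ns;
        for (int j = 1; j <= n; ++j) {
            size_t c = (size_t)i * (n + 1) + j;
            size_t d = (size_t)(i - 1) * (n + 1) + (j - 1);
            size_t u = (size_t)(i - 1) * (n + 1) + j;
            size_t l = c - 1;
            double sub = Srow[b[j - 1]];
            // M: diagonal move from best of three states
            double vm = M[d], vx = Ix[d], vy = Iy[d];
            double pv = vm; uint8_t pt = 1;
            if (vx > pv) { pv = vx; pt = 2; }
            if (vy > pv) { pv = vy; pt = 3; }
            // starting fresh beats extending a non-positive prefix
            if (pv <= 0.0) { pv = 0.0; pt = 0; }
            double mv = pv + sub;
            if (mv < 0.0) { mv = 0.0; pt = 0; }
            M[c] = mv; tbM[c] = pt;
            // Ix: gap in subject (consume a[i])
            double xo = M[u] - gi, xe = Ix[u] - gap_extend;
            if (xo >= xe) { Ix[c] = xo; tbX[c] = 1; }
            else          { Ix[c] = xe; tbX[c] = 2; }
            // Iy: gap in query (consume b[j])
            double yo = M[l] - gi, ye = Iy[l] - gap_extend;
            if (yo >= ye) { Iy[c] = yo; tbY[c] = 1; }
            else          { Iy[c] = ye; tbY[c] = 3; }
            if (M[c] > best) { best = M[c]; bi = i; bj = j; }
        }
    }

    SWResult r;
    r.score = best;
    r.q_start = r.q_end = r.s_start = r.s_end = 0;
    r.aln_length = r.n_ident = r.n_pos = 0;
    if (best <= 0.0) return r;

    int i = bi, j = bj;
    uint8_t state = 1; // end on substitution column
    r.q_end = bi; r.s_end = bj;
    while (i > 0 && j > 0) {
        size_t c = (size_t)i * (n + 1) + j;
        if (state == 1) {
            r.aln_length++;
            if (a[i - 1] == b[j - 1]) r.n_ident++;
            if (S[(size_t)a[i - 1] * ns + b[j - 1]] > 0) r.n_pos++;
            uint8_t prev = tbM[c];
            r.q_start = i; r.s_start = j;
            --i; --j;
            if (prev == 0) break;
            state = prev;
        } else if (state == 2) {
            r.aln_length++;
            state = tbX[c];
            --i;
        } else {
            r.aln_length++;
            state = tbY[c];
            --j;
        }
    }
    return r;
}

// [[Rcpp::export(name = ".sw_pair")]]
List sw_pair(IntegerVector a, IntegerVector b, NumericMatrix S,
             double gap_open, double gap_extend) {
    SWWork w;
    SWResult r = sw_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                         REAL(S), S.nrow(), gap_open, gap_extend, w);
    return List::create(
        _["score"] = r.score,
        _["q_start"] = r.q_start, _["q_end"] = r.q_end,
        _["s_start"] = r.s_start, _["s_end"] = r.s_end,
        _["aln_length"] = r.aln_length,
        _["n_ident"] = r.n_ident, _["n_pos"] = r.n_pos);
}

// Batch alignment of index pairs (0-based rows into seqs_a / seqs_b lists of
// integer vectors). Hits with score < min_score are dropped.
// [[Rcpp::export(name = ".sw_batch")]]
DataFrame sw_batch(List seqs_a, List seqs_b, IntegerMatrix pairs,
                   NumericMatrix S, double gap_open, double gap_extend,
                   double min_score) {
    int np = pairs.nrow();
    std::vector<int> qi, si, qs, qe, ss, se, al, ni, npos;
    std::vector<double> sc;
    SWWork w;
    for (int p = 0; p < np; ++p) {
        int ia = pairs(p, 0), ib = pairs(p, 1);
        IntegerVector a = seqs_a[ia];
        IntegerVector b = seqs_b[ib];
        SWResult r = sw_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                             REAL(S), S.nrow(), gap_open, gap_extend, w);
        if (r.score < min_score) continue;
        qi.push_back(ia + 1); si.push_back(ib + 1);
        sc.push_back(r.score);
        qs.push_back(r.q_start); qe.push_back(r.q_end);
        ss.push_back(r.s_start); se.push_back(r.s_end);
        al.push_back(r.aln_length);
        ni.push_back(r.n_ident); npos.push_back(r.n_pos);
        if ((p & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    return DataFrame::create(
        _["query_idx"] = wrap(qi), _["subject_idx"] = wrap(si),
        _["score"] = wrap(sc),
        _["q_start"] = wrap(qs), _["q_end"] = wrap(qe),
        _["s_start"] = wrap(ss), _["s_end"] = wrap(se),
        _["aln_length"] = wrap(al),
        _["n_ident"] = wrap(ni), _["n_pos"] = wrap(npos));
}

static inline uint64_t kmer_key(const int *s, int t, int k, int base) {
    uint64_t h = 0;
    for (int q = 0; q < k; ++q) h = h * (uint64_t)base + (uint64_t)s[t + q];
    return h;
}

// Deterministic exact k-mer candidate screen: returns 0-based (query, subject)
// index pairs sharing at least min_shared k-mer occurrences. Residues are
// 0-based integer codes < base.
// [[Rcpp::export(name = ".kmer_candidates")]]
IntegerMatrix kmer_candidates(List seqs_a, List seqs_b, int k,
                              int min_shared, int base) {
    int na = seqs_a.size(), nb = seqs_b.size();
    std::unordered_map<uint64_t, std::vector<int> > idx;
    for (int j = 0; j < nb; ++j) {
        IntegerVector b = seqs_b[j];
        int n = b.size();
        for (int t = 0; t + k <= n; ++t)
            idx[kmer_key(INTEGER(b), t, k, base)].push_back(j);
    }
    std::vector<int> count(nb, 0);
    std::vector<int> touched;
    std::vector<int> out_a, out_b;
    for (int i = 0; i < na; ++i) {
        IntegerVector a = seqs_a[i];
        int n = a.size();
        touched.clear();
        for (int t = 0; t + k <= n; ++t) {
            std::unordered_map<uint64_t, std::vector<int> >::iterator it =
                idx.find(kmer_key(INTEGER(a), t, k, base));
            if (it == idx.end()) continue;
            const std::vector<int> &v = it->second;
            for (size_t q = 0; q < v.size(); ++q) {
                if (count[v[q]] == 0) touched.push_back(v[q]);
                count[v[q]]++;
            }
        }
        for (size_t q = 0; q < touched.size(); ++q) {
            int j = touched[q];
            if (count[j] >= min_shared) { out_a.push_back(i); out_b.push_back(j); }
            count[j] = 0;
        }
        if ((i & 255) == 0) Rcpp::checkUserInterrupt();
    }
    IntegerMatrix out(out_a.size(), 2);
    for (size_t q = 0; q < out_a.size(); ++q) {
        out(q, 0) = out_a[q];
        out(q, 1) = out_b[q];
    }
    return out;
}
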