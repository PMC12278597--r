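#include <Rcpp.h>
using namespace Rcpp;

// Count mismatches between two equal-length C strings.
static int mism(const char* a, const char* b, int n) {
    int m = 0;
    for (int i = 0; i < n; ++i) if (a[i] != b[i]) ++m;
    return m;
}

// Merge a forward read with the reverse-complemented mate by exhaustive
// ungapped overlap scan. The mate may start at any offset s within the
// forward read; the overlap is scored as matches - mismatches and the
// best-scoring placement with overlap >= min_overlap and mismatch rate
// <= max_mismatch_rate wins (ties: the placement found first, i.e. the
// longest overlap). Within the overlap the higher-quality base and its
// quality are kept. Returns NULL when no acceptable overlap exists.
// [[Rcpp::export]]
SEXP cpp_merge_overlap(std::string s1, std::string q1,
                       std::string s2, std::string q2,
                       int min_overlap, double max_mismatch_rate) {
    int L1 = s1.size(), L2 = s2.size();
    if ((int) q1.size() != L1 || (int) q2.size() != L2)
        stop("sequence/quality length mismatch");
    if (L1 < min_overlap || L2 < min_overlap) return R_NilValue;

    int best_s = -1, best_score = INT_MIN;
    for (int s = 0; s <= L1 - min_overlap; ++s) {
        int o = std::min(L1 - s, L2);
        if (o < min_overlap) break;
        int m = mism(s1.c_str() + s, s2.c_str(), o);
        if ((double) m > max_mismatch_rate * o) continue;
        int score = o - 2 * m;
        if (score > best_score) { best_score = score; best_s = s; }
    }
    if (best_s < 0) return R_NilValue;

    int s = best_s;
    int o = std::min(L1 - s, L2);
    int Lm = std::max(L1, s + L2);
    std::string seq(Lm, 'N'), qual(Lm, '!');
    for (int i = 0; i < s; ++i) { seq[i] = s1[i]; qual[i] = q1[i]; }
    for (int i = 0; i < o; ++i) {
        if (q1[s + i] >= q2[i]) { seq[s + i] = s1[s + i]; qual[s + i] = q1[s + i]; }
        else                    { seq[s + i] = s2[i];     qual[s + i] = q2[i]; }
    }
    if (s + L2 > L1)
        for (int i = o; i < L2; ++i) { seq[s + i] = s2[i]; qual[s + i] = q2[i]; }
    else
        for (int i = s + o; i < L1; ++i) { seq[i] = s1[i]; qual[i] = q1[i]; }
    return List::create(_["seq"] = seq, _["qual"] = qual,
                        _["overlap"] = o, _["mismatches"] = (o - best_score) / 2);
}

// Hamming distance; -1 when lengths differ (undefined).
// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
    if (a.size() != b.size()) return -1;
    return mism(a.c_str(), b.c_str(), a.size());
}

// Mismatch count of a fixed pattern against each string in x (all assumed
// the same length as the pattern; shorter strings count missing positions
// as mismatches).
// [[Rcpp::export]]
IntegerVector cpp_count_mismatches(CharacterVector x, std::string pat) {
    int n = x.size(), P = pat.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        if (x[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
        std::string xi = as<std::string>(x[i]);
        int L = std::min((int) xi.size(), P);
        out[i] = mism(xi.c_str(), pat.c_str(), L) + (P - L);
    }
    return out;
}
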