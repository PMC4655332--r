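#include <Rcpp.h>
using namespace Rcpp;

// Hamming distance between two equal-length strings, stopping early once
// the running count exceeds maxd (returns maxd + 1 in that case).
static int hamming_capped(const char *a, const char *b, int len, int maxd) {
    int d = 0;
    for (int i = 0; i < len; ++i) {
        if (a[i] != b[i] && ++d > maxd) return maxd + 1;
    }
    return d;
}

// [[Rcpp::export]]
IntegerMatrix hamming_pairs_cpp(CharacterVector x, CharacterVector y, int maxd) {
    // All (i, j) with hamming(x[i], y[j]) <= maxd; strings must share one length.
    std::vector<int> ii, jj, dd;
    int nx = x.size(), ny = y.size();
    std::vector<const char *> xp(nx), yp(ny);
    int len = nx ? LENGTH(STRING_ELT(x, 0)) : 0;
    for (int i = 0; i < nx; ++i) xp[i] = CHAR(STRING_ELT(x, i));
    for (int j = 0; j < ny; ++j) yp[j] = CHAR(STRING_ELT(y, j));
    for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) {
            int d = hamming_capped(xp[i], yp[j], len, maxd);
            if (d <= maxd) { ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(d); }
        }
    }
    IntegerMatrix out(ii.size(), 3);
    for (size_t k = 0; k < ii.size(); ++k) {
        out(k, 0) = ii[k]; out(k, 1) = jj[k]; out(k, 2) = dd[k];
    }
    colnames(out) = CharacterVector::create("i", "j", "dist");
    return out;
}

// [[Rcpp::export]]
IntegerVector hamming_dist_cpp(std::string a, CharacterVector y) {
    int n = y.size(), len = a.size();
    IntegerVector out(n);
    for (int j = 0; j < n; ++j) {
        const char *b = CHAR(STRING_ELT(y, j));
        int d = 0;
        for (int i = 0; i < len; ++i) if (a[i] != b[i]) ++d;
        out[j] = d;
    }
    return out;
}

// Matches between a and b when b is slid by `shift` relative to a:
// compare a[i + shift] with b[i] (shift may be negative). Denominator is
// the full read length, matching the shifted-overlap homology model.
static int shift_matches(const char *a, const char *b, int len, int shift) {
    int m = 0;
    int lo = shift > 0 ? 0 : -shift;
    int hi = shift > 0 ? len - shift : len;
    for (int i = lo; i < hi; ++i) if (a[i + shift] == b[i]) ++m;
    return m;
}

// [[Rcpp::export]]
double shifted_identity_cpp(std::string a, std::string b, int shift) {
    int len = a.size();
    if ((int) b.size() != len) stop("sequences must have equal length");
    if (shift <= -len || shift >= len) return 0.0;
    return shift_matches(a.c_str(), b.c_str(), len, shift) / (double) len;
}

// [[Rcpp::export]]
NumericMatrix max_shifted_identity_cpp(CharacterVector x, int max_shift,
                                       double threshold) {
    // For every unordered pair, the maximum full-length-denominator identity
    // over shifts strictly inside (-max_shift, max_shift); rows only for
    // pairs whose maximum exceeds `threshold`.
    int n = x.size();
    std::vector<const char *> xp(n);
    int len = n ? LENGTH(STRING_ELT(x, 0)) : 0;
    for (int i = 0; i < n; ++i) xp[i] = CHAR(STRING_ELT(x, i));
    std::vector<double> ii, jj, idv, shv;
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            int best = -1, best_shift = 0;
            for (int s = -(max_shift - 1); s <= max_shift - 1; ++s) {
                int m = shift_matches(xp[i], xp[j], len, s);
                if (m > best) { best = m; best_shift = s; }
            }
            double ident = best / (double) len;
            if (ident > threshold) {
                ii.push_back(i + 1); jj.push_back(j + 1);
                idv.push_back(ident); shv.push_back(best_shift);
            }
        }
    }
    NumericMatrix out(ii.size(), 4);
    for (size_t k = 0; k < ii.size(); ++k) {
        out(k, 0) = ii[k]; out(k, 1) = jj[k]; out(k, 2) = idv[k]; out(k, 3) = shv[k];
    }
    colnames(out) = CharacterVector::create("i", "j", "identity", "shift");
    return out;
}
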