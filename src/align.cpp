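#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh).
// Gap of length L costs gap_open + gap_extend * L (the Biostrings/EMBOSS
// "opening + per-base extension" convention), so the first gap base costs
// gap_open + gap_extend.
//
// States: M = a[i] aligned to b[j]; X = a[i] aligned to a gap (gap in b);
// Y = b[j] aligned to a gap (gap in a). Terminal gaps are penalized (true
// global alignment).
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 NumericMatrix submat, CharacterVector alphabet,
                 double gap_open, double gap_extend) {
    const int n = a.size(), m = b.size();
    if (n == 0 || m == 0) stop("sequences must be non-empty");
    const double NEG = -std::numeric_limits<double>::infinity();
    const double opencost = gap_open + gap_extend;

    // residue -> matrix index lookup
    std::vector<int> lut(256, -1);
    for (int i = 0; i < alphabet.size(); ++i)
        lut[(unsigned char)CHAR(STRING_ELT(alphabet, i))[0]] = i;
    std::vector<int> ai(n), bi(m);
    for (int i = 0; i < n; ++i) {
        ai[i] = lut[(unsigned char)a[i]];
        if (ai[i] < 0) stop("illegal residue in first sequence");
    }
    for (int j = 0; j < m; ++j) {
        bi[j] = lut[(unsigned char)b[j]];
        if (bi[j] < 0) stop("illegal residue in second sequence");
    }

    const int W = m + 1;
    std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
        Y((n + 1) * W, NEG);
    // traceback: which state each cell's maximum came from (0=M,1=X,2=Y)
    std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1),
        tY((n + 1) * W, -1);

    M[0] = 0.0;
    for (int i = 1; i <= n; ++i) {
        X[i * W] = -(gap_open + gap_extend * i);
        tX[i * W] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
        Y[j] = -(gap_open + gap_extend * j);
        tY[j] = (j == 1) ? 0 : 2;
    }

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const int c = i * W + j, d = (i - 1) * W + (j - 1),
                      u = (i - 1) * W + j, l = i * W + (j - 1);
            double s = submat(ai[i - 1], bi[j - 1]);
            // M
            double best = M[d]; signed char tb = 0;
            if (X[d] > best) { best = X[d]; tb = 1; }
            if (Y[d] > best) { best = Y[d]; tb = 2; }
            M[c] = (best == NEG) ? NEG : best + s;
            tM[c] = tb;
            // X: consume a[i-1] against a gap
            best = M[u] - opencost; tb = 0;
            if (X[u] - gap_extend > best) { best = X[u] - gap_extend; tb = 1; }
            if (Y[u] - opencost > best) { best = Y[u] - opencost; tb = 2; }
            X[c] = best; tX[c] = tb;
            // Y: consume b[j-1] against a gap
            best = M[l] - opencost; tb = 0;
            if (X[l] - opencost > best) { best = X[l] - opencost; tb = 1; }
            if (Y[l] - gap_extend > best) { best = Y[l] - gap_extend; tb = 2; }
            Y[c] = best; tY[c] = tb;
        }
    }

    const int end = n * W + m;
    double score = M[end]; int state = 0;
    if (X[end] > score) { score = X[end]; state = 1; }
    if (Y[end] > score) { score = Y[end]; state = 2; }

    std::string outa, outb;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        const int c = i * W + j;
        if (state == 0) {
            outa.push_back(a[i - 1]);
            outb.push_back(b[j - 1]);
            state = tM[c]; --i; --j;
        } else if (state == 1) {
            outa.push_back(a[i - 1]);
            outb.push_back('-');
            state = tX[c]; --i;
        } else {
            outa.push_back('-');
            outb.push_back(b[j - 1]);
            state = tY[c]; --j;
        }
    }
    std::reverse(outa.begin(), outa.end());
    std::reverse(outb.begin(), outb.end());
    return List::create(_["aligned_a"] = outa, _["aligned_b"] = outb,
                        _["score"] = score);
}
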