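#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Banded global (Needleman-Wunsch) alignment with affine gap penalties.
// Reads in this workflow are >99% identical to the guide, so the optimal
// path stays within a narrow band around the main diagonal; the band is
// widened by the length difference so the corner cell is always reachable.
//
// Gap of length L costs gapOpen + L * gapExt (first gapped base pays both).

static const double NEG = -std::numeric_limits<double>::infinity() / 4.0;

// traceback codes: which matrix the predecessor cell lives in
enum { FROM_M = 0, FROM_X = 1, FROM_Y = 2 };

// [[Rcpp::export]]
List banded_align_cpp(std::string p, std::string s, int band = 24,
                      double match = 2.0, double mismatch = -4.0,
                      double gapOpen = -12.0, double gapExt = -4.0) {
    const int lp = (int) p.size();
    const int ls = (int) s.size();
    if (lp == 0 || ls == 0)
        stop("empty sequence in banded_align_cpp");
    const int bandL = band + std::max(0, lp - ls);   // j >= i - bandL
    const int bandR = band + std::max(0, ls - lp);   // j <= i + bandR
    const int W = bandL + bandR + 1;                 // band width, k = j - i + bandL

    // score layers: M (diagonal), X (gap in subject, consumes p), Y (gap in p)
    std::vector<double> M((size_t)(lp + 1) * W, NEG);
    std::vector<double> X((size_t)(lp + 1) * W, NEG);
    std::vector<double> Y((size_t)(lp + 1) * W, NEG);
    std::vector<unsigned char> tbM((size_t)(lp + 1) * W, 0);
    std::vector<unsigned char> tbX((size_t)(lp + 1) * W, 0);
    std::vector<unsigned char> tbY((size_t)(lp + 1) * W, 0);

    #define IDX(i, k) ((size_t)(i) * W + (size_t)(k))

    // i = 0 row: only gaps in p (Y) along j
    M[IDX(0, bandL)] = 0.0;
    for (int j = 1; j <= std::min(ls, bandR); ++j) {
        int k = j + bandL;           // i = 0
        Y[IDX(0, k)] = gapOpen + gapExt * j;
        tbY[IDX(0, k)] = FROM_Y;
    }
    for (int i = 1; i <= lp; ++i) {
        int jlo = std::max(0, i - bandL);
        int jhi = std::min(ls, i + bandR);
        if (jlo > jhi) continue;
        for (int j = jlo; j <= jhi; ++j) {
            int k = j - i + bandL;
            size_t at = IDX(i, k);
            if (j == 0) {
                // column 0: only gaps in subject (X)
                X[at] = gapOpen + gapExt * i;
                tbX[at] = FROM_X;
                continue;
            }
            // M: diagonal move, same k at (i-1, j-1)
            {
                size_t d = IDX(i - 1, k);
                double sub = (p[i - 1] == s[j - 1]) ? match : mismatch;
                double bm = M[d], bx = X[d], by = Y[d];
                double best = bm; unsigned char who = FROM_M;
                if (bx > best) { best = bx; who = FROM_X; }
                if (by > best) { best = by; who = FROM_Y; }
                if (best > NEG / 2) { M[at] = best + sub; tbM[at] = who; }
            }
            // X: consume p[i-1], gap in subject; predecessor (i-1, j) -> k+1
            if (k + 1 < W) {
                size_t u = IDX(i - 1, k + 1);
                double open = std::max(M[u], Y[u]) + gapOpen + gapExt;
                double ext  = X[u] + gapExt;
                if (open >= ext) {
                    if (open > NEG / 2) { X[at] = open; tbX[at] = (M[u] >= Y[u]) ? FROM_M : FROM_Y; }
                } else {
                    X[at] = ext; tbX[at] = FROM_X;
                }
            }
            // Y: consume s[j-1], gap in pattern; predecessor (i, j-1) -> k-1
            if (k - 1 >= 0) {
                size_t l = IDX(i, k - 1);
                double open = std::max(M[l], X[l]) + gapOpen + gapExt;
                double ext  = Y[l] + gapExt;
                if (open >= ext) {
                    if (open > NEG / 2) { Y[at] = open; tbY[at] = (M[l] >= X[l]) ? FROM_M : FROM_X; }
                } else {
                    Y[at] = ext; tbY[at] = FROM_Y;
                }
            }
        }
    }

    int kEnd = ls - lp + bandL;
    size_t end = IDX(lp, kEnd);
    double best = M[end]; int layer = FROM_M;
    if (X[end] > best) { best = X[end]; layer = FROM_X; }
    if (Y[end] > best) { best = Y[end]; layer = FROM_Y; }
    if (!(best > NEG / 2))
        stop("band too narrow: no alignment path reached the end cell");

    // traceback
    std::string ap, as;
    ap.reserve(lp + 16); as.reserve(ls + 16);
    int i = lp, j = ls;
    while (i > 0 || j > 0) {
        int k = j - i + bandL;
        size_t at = IDX(i, k);
        if (layer == FROM_M) {
            unsigned char who = tbM[at];
            ap.push_back(p[i - 1]); as.push_back(s[j - 1]);
            --i; --j; layer = who;
        } else if (layer == FROM_X) {
            unsigned char who = tbX[at];
            ap.push_back(p[i - 1]); as.push_back('-');
            --i; layer = (i == 0 && j == 0) ? FROM_M : who;
        } else {
            unsigned char who = tbY[at];
            ap.push_back('-'); as.push_back(s[j - 1]);
            --j; layer = (i == 0 && j == 0) ? FROM_M : who;
        }
    }
    std::reverse(ap.begin(), ap.end());
    std::reverse(as.begin(), as.end());

    return List::create(_["score"] = best,
                        _["pattern"] = ap,
                        _["subject"] = as);
}
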