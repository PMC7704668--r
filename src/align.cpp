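#include <Rcpp.h>
#include <cctype>
#include <cstring>
#include <vector>
#include <string>
using namespace Rcpp;

// IUPAC bitmask: A=1, C=2, G=4, T=8; returns 0 for non-nucleotide characters.
static inline int iupac_code(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;
    case 'T': return 8;  case 'U': return 8;
    case 'R': return 5;  case 'Y': return 10; case 'S': return 6;
    case 'W': return 9;  case 'K': return 12; case 'M': return 3;
    case 'B': return 14; case 'D': return 13; case 'H': return 11;
    case 'V': return 7;  case 'N': return 15;
    default:  return 0;
  }
}

// [[Rcpp::export(name = ".iupac_codes")]]
IntegerVector iupac_codes(std::string s) {
  IntegerVector out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = iupac_code(s[i]);
  return out;
}

// Banded global pairwise alignment with affine gaps (gap of length k costs
// open + k * ext).  Ambiguity codes score as matches when their base sets
// intersect.  The band is centred on the main diagonal; it is widened
// automatically so the corner (n, m) is always reachable.
//
// Returns the aligned reference string, the aligned query string and the
// optimal score.  Gap placement within repeat runs is left to the traceback
// and canonicalised (3'-justified) by the R wrapper.
// [[Rcpp::export(name = ".banded_align")]]
List banded_align(std::string ref, std::string qry,
                  double match, double mismatch,
                  double gap_open, double gap_ext, int band) {
  const int n = ref.size(), m = qry.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (band < std::abs(n - m) + 8) band = std::abs(n - m) + 8;
  const int W = 2 * band + 1;
  const double NEG = -1e30;

  std::vector<int> rc(n), qc(m);
  for (int i = 0; i < n; ++i) rc[i] = iupac_code(ref[i]);
  for (int j = 0; j < m; ++j) qc[j] = iupac_code(qry[j]);

  // state matrices: M (diagonal), X (gap in query / deletion, consumes ref),
  // Y (gap in ref / insertion, consumes qry); banded storage col = j - i + band
  std::vector<double> Mrow(W, NEG), Xrow(W, NEG), Yrow(W, NEG);
  std::vector<double> Mprev(W, NEG), Xprev(W, NEG), Yprev(W, NEG);
  // traceback: 0 from M, 1 from X, 2 from Y (predecessor state)
  std::vector<unsigned char> tbM((size_t)(n + 1) * W, 255),
      tbX((size_t)(n + 1) * W, 255), tbY((size_t)(n + 1) * W, 255);

  // row i = number of ref chars consumed, col j = qry chars consumed
  for (int i = 0; i <= n; ++i) {
    std::fill(Mrow.begin(), Mrow.end(), NEG);
    std::fill(Xrow.begin(), Xrow.end(), NEG);
    std::fill(Yrow.begin(), Yrow.end(), NEG);
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i + band;
      if (i == 0 && j == 0) { Mrow[k] = 0.0; continue; }
      // X: gap in query (vertical), predecessor at (i-1, j) -> same k offset+1
      if (i > 0 && j - (i - 1) + band <= 2 * band) {
        int kp = j - (i - 1) + band;
        if (kp >= 0 && kp < W) {
          double fromM = Mprev[kp] - (gap_open + gap_ext);
          double fromX = Xprev[kp] - gap_ext;
          if (fromM >= fromX) { Xrow[k] = fromM; tbX[(size_t)i * W + k] = 0; }
          else                { Xrow[k] = fromX; tbX[(size_t)i * W + k] = 1; }
        }
      }
      // Y: gap in ref (horizontal), predecessor at (i, j-1) -> k-1
      if (j > 0 && k - 1 >= 0) {
        double fromM = Mrow[k - 1] - (gap_open + gap_ext);
        double fromY = Yrow[k - 1] - gap_ext;
        if (fromM >= fromY) { Yrow[k] = fromM; tbY[(size_t)i * W + k] = 0; }
        else                { Yrow[k] = fromY; tbY[(size_t)i * W + k] = 2; }
      }
      // M: diagonal, predecessor at (i-1, j-1) -> same k
      if (i > 0 && j > 0) {
        double s = (rc[i - 1] & qc[j - 1]) ? match : mismatch;
        double bM = Mprev[k], bX = Xprev[k], bY = Yprev[k];
        double best = bM; unsigned char st = 0;
        if (bX > best) { best = bX; st = 1; }
        if (bY > best) { best = bY; st = 2; }
        if (best > NEG / 2) { Mrow[k] = best + s; tbM[(size_t)i * W + k] = st; }
      }
    }
    std::swap(Mrow, Mprev); std::swap(Xrow, Xprev); std::swap(Yrow, Yprev);
  }

  int kend = m - n + band;
  double sM = Mprev[kend], sX = Xprev[kend], sY = Yprev[kend];
  double score = sM; int state = 0;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }
  if (score < NEG / 2)
    stop("alignment band too narrow; increase `band`");

  // traceback
  std::string ra, qa;
  ra.reserve(n + 16); qa.reserve(m + 16);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int k = j - i + band;
    unsigned char prev;
    if (state == 0) {
      prev = tbM[(size_t)i * W + k];
      ra.push_back(ref[i - 1]); qa.push_back(qry[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = tbX[(size_t)i * W + k];
      ra.push_back(ref[i - 1]); qa.push_back('-');
      --i;
    } else {
      prev = tbY[(size_t)i * W + k];
      ra.push_back('-'); qa.push_back(qry[j - 1]);
      --j;
    }
    if (prev == 255) stop("internal error: broken traceback");
    state = prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  return List::create(_["ref"] = ra, _["qry"] = qa, _["score"] = score);
}
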