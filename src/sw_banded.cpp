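#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Banded Smith-Waterman local alignment with linear gap penalty.
// The DP is restricted to diagonals j - i in [dlo, dhi] (j indexes b,
// i indexes a). Start coordinates, match count and alignment length are
// propagated through the DP so no traceback matrix is needed.
//
// Scores follow the +1 match / -1 mismatch / -2 gap convention used for
// consensus-vs-read screening; they are parameters so tests can vary them.

// [[Rcpp::export(name = ".sw_banded_cpp")]]
List sw_banded_cpp(std::string a, std::string b,
                   int match = 1, int mismatch = -1, int gap = -2,
                   int dlo = 0, int dhi = 0) {
  const int m = (int)a.size();
  const int n = (int)b.size();
  if (dlo > dhi) stop("dlo must be <= dhi");
  const int K = dhi - dlo + 1;
  const int NEG = -1000000000;

  // rows indexed by i (0..m); cell k stores j = i + dlo + k
  std::vector<int> Hprev(K, 0), Hcur(K, 0);
  std::vector<int> SIp(K, 0), SJp(K, 0), NMp(K, 0), ALp(K, 0);
  std::vector<int> SIc(K, 0), SJc(K, 0), NMc(K, 0), ALc(K, 0);

  int best = 0, bi = 0, bj = 0, bsi = 0, bsj = 0, bnm = 0, bal = 0;

  // initialise row i = 0: empty alignments
  for (int k = 0; k < K; ++k) { Hprev[k] = 0; }

  const char *pa = a.data(), *pb = b.data();
  for (int i = 1; i <= m; ++i) {
    int klo = 1 - (i + dlo); if (klo < 0) klo = 0;
    int khi = n - i - dlo; if (khi > K - 1) khi = K - 1;
    const char ac = pa[i - 1];
    int *Hp = Hprev.data(), *Hc = Hcur.data();
    int *sip = SIp.data(), *sjp = SJp.data();
    int *nmp = NMp.data(), *alp = ALp.data();
    int *sic = SIc.data(), *sjc = SJc.data();
    int *nmc = NMc.data(), *alc = ALc.data();
    const char *pbj = pb + (i + dlo - 1);
    for (int k = klo; k <= khi; ++k) {
      const int j = i + dlo + k;
      const bool eq = ac == pbj[k];
      const int s = eq ? match : mismatch;

      // diagonal: (i-1, j-1) is offset k in the previous row
      const int hp = Hp[k];
      int h = hp + s, si, sj, nm, al;
      if (hp > 0) { si = sip[k]; sj = sjp[k];
                    nm = nmp[k] + (eq ? 1 : 0); al = alp[k] + 1; }
      else { si = i - 1; sj = j - 1; nm = eq ? 1 : 0; al = 1; }
      // up: (i-1, j) -> offset k+1 in previous row (gap in b)
      if (k + 1 < K && Hp[k + 1] > 0 && Hp[k + 1] + gap > h) {
        h = Hp[k + 1] + gap; si = sip[k + 1]; sj = sjp[k + 1];
        nm = nmp[k + 1]; al = alp[k + 1] + 1;
      }
      // left: (i, j-1) -> offset k-1 in current row (gap in a)
      if (k - 1 >= 0 && Hc[k - 1] > 0 && Hc[k - 1] + gap > h) {
        h = Hc[k - 1] + gap; si = sic[k - 1]; sj = sjc[k - 1];
        nm = nmc[k - 1]; al = alc[k - 1] + 1;
      }
      if (h <= 0) { Hc[k] = 0; continue; }
      Hc[k] = h; sic[k] = si; sjc[k] = sj; nmc[k] = nm; alc[k] = al;
      if (h > best) {
        best = h; bi = i; bj = j; bsi = si; bsj = sj; bnm = nm; bal = al;
      }
    }
    if (klo > 0) Hcur[klo - 1] = 0;
    std::swap(Hprev, Hcur);
    std::swap(SIp, SIc); std::swap(SJp, SJc);
    std::swap(NMp, NMc); std::swap(ALp, ALc);
    std::fill(Hcur.begin(), Hcur.end(), 0);
  }

  return List::create(
    _["score"] = best,
    _["a_start"] = bsi, _["a_end"] = bi,
    _["b_start"] = bsj, _["b_end"] = bj,
    _["n_match"] = bnm, _["aln_len"] = bal);
}
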