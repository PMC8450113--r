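#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap Smith-Waterman with a hard cap on gap-run length.
//
// Sequences are integer-coded (A=1, C=2, G=3, T=4; anything else never
// matches).  A gap of length g costs gap_open + g * gap_extend.  Gap runs
// longer than max_gap are impossible by construction: extension of a run at
// the cap is forbidden, and a new gap may not open immediately after a gap
// on the same side (which would splice two runs into one).  Long indels
// therefore split the alignment into separate local fragments, which the
// caller recovers by masking and re-aligning (BLASTN-like HSP behaviour).
//
// Returns the single best local alignment (score, 1-based inclusive spans,
// and the gapped sequences as integer vectors with 0 marking a gap).

static const int NEG = -(1 << 28);

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s,
                  int match, int mismatch,
                  int gap_open, int gap_extend, int max_gap) {
  const int n = q.size(), m = s.size();
  // pointer codes for H: 0 stop, 1 diag, 2 from E (gap in query), 3 from F
  // (gap in subject); for E/F: 1 open, 2 extend
  std::vector<uint8_t> ptrH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> ptrE((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> ptrF((size_t)(n + 1) * (m + 1), 0);

  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Fcol(m + 1, NEG);      // vertical gap state per column
  std::vector<int> FrunCol(m + 1, 0);     // current vertical gap-run length

  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    int E = NEG, Erun = 0;
    Hcur[0] = 0;
    const int qi = q[i - 1];
    const size_t row = (size_t)i * (m + 1);
    const size_t prow = (size_t)(i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      // E: gap in query (consumes subject base j)
      int e_open = (ptrH[row + j - 1] == 2) ? NEG : Hcur[j - 1] - gap_open - gap_extend;
      int e_ext  = (Erun >= max_gap || Erun == 0) ? NEG : E - gap_extend;
      if (e_open >= e_ext) { E = e_open; Erun = (e_open > NEG) ? 1 : 0; ptrE[row + j] = 1; }
      else                 { E = e_ext;  Erun = Erun + 1;               ptrE[row + j] = 2; }
      if (E <= NEG) { E = NEG; Erun = 0; }

      // F: gap in subject (consumes query base i)
      int f_open = (ptrH[prow + j] == 3) ? NEG : Hprev[j] - gap_open - gap_extend;
      int f_ext  = (FrunCol[j] >= max_gap || FrunCol[j] == 0) ? NEG : Fcol[j] - gap_extend;
      int F;
      if (f_open >= f_ext) { F = f_open; FrunCol[j] = (f_open > NEG) ? 1 : 0; ptrF[row + j] = 1; }
      else                 { F = f_ext;  FrunCol[j] = FrunCol[j] + 1;         ptrF[row + j] = 2; }
      if (F <= NEG) { F = NEG; FrunCol[j] = 0; }
      Fcol[j] = F;

      const int sj = s[j - 1];
      const int sub = (qi >= 1 && qi <= 4 && qi == sj) ? match : mismatch;
      int diag = Hprev[j - 1] + sub;

      int h = 0; uint8_t p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (E > h)    { h = E;    p = 2; }
      if (F > h)    { h = F;    p = 3; }
      Hcur[j] = h; ptrH[row + j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  if (best <= 0) {
    return List::create(_["score"] = 0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["sstart"] = NA_INTEGER,
                        _["send"] = NA_INTEGER,
                        _["q_aln"] = IntegerVector(0), _["s_aln"] = IntegerVector(0));
  }

  // traceback (pointer matrices fully retained)
  std::vector<int> qa, sa;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    const size_t row = (size_t)i * (m + 1);
    uint8_t p = ptrH[row + j];
    if (p == 0) break;
    if (p == 1) { qa.push_back(q[i - 1]); sa.push_back(s[j - 1]); --i; --j; }
    else if (p == 2) {              // gap in query: walk the E run
      while (true) {
        uint8_t pe = ptrE[(size_t)i * (m + 1) + j];
        qa.push_back(0); sa.push_back(s[j - 1]); --j;
        if (pe == 1) break;
      }
    } else {                        // gap in subject: walk the F run
      while (true) {
        uint8_t pf = ptrF[(size_t)i * (m + 1) + j];
        qa.push_back(q[i - 1]); sa.push_back(0); --i;
        if (pf == 1) break;
      }
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  return List::create(_["score"] = best,
                      _["qstart"] = i + 1, _["qend"] = bi,
                      _["sstart"] = j + 1, _["send"] = bj,
                      _["q_aln"] = IntegerVector(qa.begin(), qa.end()),
                      _["s_aln"] = IntegerVector(sa.begin(), sa.end()));
}
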