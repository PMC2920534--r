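#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Residue indexing over the 20 standard amino acids. 'X' (when admitted at
// parse time) maps to -1 and never matches anything, including itself.
static inline int aa_index(char c) {
  switch (c) {
    case 'A': return 0;  case 'R': return 1;  case 'N': return 2;
    case 'D': return 3;  case 'C': return 4;  case 'Q': return 5;
    case 'E': return 6;  case 'G': return 7;  case 'H': return 8;
    case 'I': return 9;  case 'L': return 10; case 'K': return 11;
    case 'M': return 12; case 'F': return 13; case 'P': return 14;
    case 'S': return 15; case 'T': return 16; case 'W': return 17;
    case 'Y': return 18; case 'V': return 19;
    default:  return -1;
  }
}

struct HitRec {
  int pep_i;      // 1-based index into the peptide vector
  int prot_i;     // 1-based index into the protein vector
  int pep_off;    // 0-based offset of the window within the peptide
  int prot_start; // 0-based start of the window within the protein
  int len;        // window length
  int score;      // alignment score (scored mode) or window length (exact mode)
};

// Exact mode: report every maximal window of length >= wmin shared between
// peptide and protein with <= maxmm substitutions. Maximal: extending one
// residue left or right either leaves the sequences or exceeds the mismatch
// budget. Implemented as a two-pointer sweep along each alignment diagonal.
static void exact_pair(const std::vector<int>& pep, const std::vector<int>& prot,
                       int pi, int qi, int wmin, int maxmm,
                       std::vector<HitRec>& out) {
  const int lp = (int)pep.size(), Lq = (int)prot.size();
  if (lp < wmin || Lq < wmin) return;
  std::vector<int> mm(lp);
  for (int o = -(lp - 1); o <= Lq - 1; ++o) {
    int iLo = std::max(0, -o);
    int iHi = std::min(lp, Lq - o);
    if (iHi - iLo < wmin) continue;
    for (int i = iLo; i < iHi; ++i) {
      int a = pep[i], b = prot[i + o];
      mm[i] = (a >= 0 && a == b) ? 0 : 1;
    }
    int b = iLo, cnt = 0;
    for (int a = iLo; a < iHi; ++a) {
      if (b < a) { b = a; cnt = 0; }
      while (b < iHi && cnt + mm[b] <= maxmm) { cnt += mm[b]; ++b; }
      int len = b - a;
      if (len >= wmin) {
        bool leftmax = (a == iLo) || (cnt + mm[a - 1] > maxmm);
        if (leftmax) out.push_back({pi, qi, a, a + o, len, len});
      }
      if (b > a) cnt -= mm[a];
    }
  }
}

// Scored mode: every exact word of word_size seeds an ungapped extension to
// the score-maximal interval in each direction; reported iff score >= min_score.
// Identical extended intervals from overlapping seeds are deduplicated.
static void scored_pair(const std::vector<int>& pep, const std::vector<int>& prot,
                        int pi, int qi, const IntegerMatrix& smat,
                        int ws, int min_score, std::vector<HitRec>& out) {
  const int lp = (int)pep.size(), Lq = (int)prot.size();
  if (lp < ws || Lq < ws) return;
  size_t first = out.size();
  for (int i = 0; i + ws <= lp; ++i) {
    for (int j = 0; j + ws <= Lq; ++j) {
      bool word = true;
      int seed_sc = 0;
      for (int t = 0; t < ws; ++t) {
        int a = pep[i + t], b = prot[j + t];
        if (a < 0 || a != b) { word = false; break; }
        seed_sc += smat(a, b);
      }
      if (!word) continue;
      // extend left
      int best_l = 0, cur = 0, lext = 0;
      for (int t = 1; i - t >= 0 && j - t >= 0; ++t) {
        int a = pep[i - t], b = prot[j - t];
        cur += (a >= 0 && b >= 0) ? smat(a, b) : -1000000;
        if (cur > best_l) { best_l = cur; lext = t; }
      }
      // extend right
      int best_r = 0, rext = 0; cur = 0;
      for (int t = 0; i + ws + t < lp && j + ws + t < Lq; ++t) {
        int a = pep[i + ws + t], b = prot[j + ws + t];
        cur += (a >= 0 && b >= 0) ? smat(a, b) : -1000000;
        if (cur > best_r) { best_r = cur; rext = t + 1; }
      }
      int sc = seed_sc + best_l + best_r;
      if (sc >= min_score)
        out.push_back({pi, qi, i - lext, j - lext, ws + lext + rext, sc});
    }
  }
  // dedupe identical intervals (same peptide offset/protein start/length),
  // keeping the best score
  if (out.size() - first > 1) {
    std::vector<HitRec> kept;
    for (size_t u = first; u < out.size(); ++u) {
      bool dup = false;
      for (size_t v = 0; v < kept.size(); ++v) {
        if (kept[v].pep_off == out[u].pep_off &&
            kept[v].prot_start == out[u].prot_start &&
            kept[v].len == out[u].len) {
          if (out[u].score > kept[v].score) kept[v].score = out[u].score;
          dup = true; break;
        }
      }
      if (!dup) kept.push_back(out[u]);
    }
    out.resize(first);
    for (size_t v = 0; v < kept.size(); ++v) out.push_back(kept[v]);
  }
}

static std::vector<std::vector<int> > encode(const CharacterVector& x) {
  std::vector<std::vector<int> > enc(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    enc[i].resize(s.size());
    for (size_t t = 0; t < s.size(); ++t) enc[i][t] = aa_index(s[t]);
  }
  return enc;
}

static DataFrame hits_to_df(const std::vector<HitRec>& hits) {
  int n = (int)hits.size();
  IntegerVector pep_i(n), prot_i(n), pep_off(n), prot_start(n), len(n), score(n);
  for (int u = 0; u < n; ++u) {
    pep_i[u] = hits[u].pep_i;       prot_i[u] = hits[u].prot_i;
    pep_off[u] = hits[u].pep_off;   prot_start[u] = hits[u].prot_start;
    len[u] = hits[u].len;           score[u] = hits[u].score;
  }
  return DataFrame::create(_["pep_i"] = pep_i, _["prot_i"] = prot_i,
                           _["pep_off"] = pep_off, _["prot_start"] = prot_start,
                           _["len"] = len, _["score"] = score);
}

// [[Rcpp::export]]
DataFrame cpp_search_exact(CharacterVector peptides, CharacterVector proteins,
                           int wmin, int maxmm) {
  std::vector<std::vector<int> > pe = encode(peptides), pr = encode(proteins);
  std::vector<HitRec> hits;
  for (size_t i = 0; i < pe.size(); ++i)
    for (size_t j = 0; j < pr.size(); ++j)
      exact_pair(pe[i], pr[j], (int)i + 1, (int)j + 1, wmin, maxmm, hits);
  return hits_to_df(hits);
}

// [[Rcpp::export]]
DataFrame cpp_search_scored(CharacterVector peptides, CharacterVector proteins,
                            IntegerMatrix smat, int word_size, int min_score) {
  std::vector<std::vector<int> > pe = encode(peptides), pr = encode(proteins);
  std::vector<HitRec> hits;
  for (size_t i = 0; i < pe.size(); ++i)
    for (size_t j = 0; j < pr.size(); ++j)
      scored_pair(pe[i], pr[j], (int)i + 1, (int)j + 1, smat,
                  word_size, min_score, hits);
  return hits_to_df(hits);
}
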