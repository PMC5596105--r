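#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Duplex column states for the expectation score.
enum ColState { MATCH = 0, GU = 1, MISMATCH = 2 };

static inline int col_state(char m, char s) {
  // m: miRNA base 5'->3'; s: target (transcript) base; Watson-Crick = match,
  // G:U wobble (m G with target T, or m T with target G) = GU.
  if ((m == 'A' && s == 'T') || (m == 'T' && s == 'A') ||
      (m == 'C' && s == 'G') || (m == 'G' && s == 'C')) return MATCH;
  if ((m == 'G' && s == 'T') || (m == 'T' && s == 'G')) return GU;
  return MISMATCH;
}

// Penalties in half-units so E stays exact: match 0, G:U 1, mismatch 2, gap 4;
// doubled when the 1-based miRNA position lies in the seed region 2..13.
static inline int col_penalty_half(int state, int mir_pos1) {
  int p = (state == MATCH) ? 0 : (state == GU ? 1 : 2);
  if (mir_pos1 >= 2 && mir_pos1 <= 13) p *= 2;
  return p;
}

static inline int gap_penalty_half(int mir_pos1) {
  int p = 4;
  if (mir_pos1 >= 2 && mir_pos1 <= 13) p *= 2;
  return p;
}

struct Aln {
  int half_e;        // 2*E
  int site_len;      // window length on the transcript
  int n_mismatch, n_gu, n_gap;
  bool central_mismatch; // any miRNA position 9..11 not a Watson-Crick match
  std::string states;
  bool ok;
};

// Score one alignment variant at transcript anchor t (site 3' end fixed so that
// miRNA position 1 pairs transcript position t + site_len - 1).
// variant: 0 = ungapped; 1 = target bulge after miRNA position g (site one longer);
// 2 = miRNA position g unpaired (site one shorter). g is 1-based miRNA position.
static Aln score_variant(const std::string &m, const std::string &tx, int t,
                         int variant, int g, int half_cutoff) {
  int L = m.size();
  Aln a; a.ok = false; a.half_e = 0; a.n_mismatch = 0; a.n_gu = 0; a.n_gap = 0;
  a.central_mismatch = false;
  int site_len = L + (variant == 1 ? 1 : (variant == 2 ? -1 : 0));
  if (t < 0 || t + site_len > (int)tx.size()) return a;
  a.site_len = site_len;
  std::string st;
  st.reserve(site_len + 1);
  // site indexed from its 3' end: site3(j) = tx[t + site_len - 1 - j]
  auto site3 = [&](int j) { return tx[t + site_len - 1 - j]; };
  int j = 0; // next site position (from 3' end)
  for (int i = 0; i < L; ++i) {
    int pos1 = i + 1;
    if (variant == 2 && pos1 == g) {
      a.half_e += gap_penalty_half(pos1);
      a.n_gap++;
      st.push_back('-');
      if (pos1 >= 9 && pos1 <= 11) a.central_mismatch = true;
      if (a.half_e > half_cutoff) return a;
      continue;
    }
    if (variant == 1 && pos1 == g + 1 && j == i) {
      // bulged target base between miRNA positions g and g+1
      a.half_e += gap_penalty_half(pos1);
      a.n_gap++;
      st.push_back('^');
      ++j;
      if (a.half_e > half_cutoff) return a;
    }
    int s = col_state(m[i], site3(j));
    a.half_e += col_penalty_half(s, pos1);
    if (s == MISMATCH) a.n_mismatch++;
    if (s == GU) a.n_gu++;
    if (s != MATCH && pos1 >= 9 && pos1 <= 11) a.central_mismatch = true;
    st.push_back(s == MATCH ? ':' : (s == GU ? '.' : 'X'));
    ++j;
    if (a.half_e > half_cutoff) return a;
  }
  a.states = st;
  a.ok = (a.half_e <= half_cutoff);
  return a;
}

// Scan all transcripts for target sites of each miRNA with expectation E <= cutoff,
// allowing at most max_gaps (0 or 1) gaps. For each anchor the best variant is kept;
// the R wrapper resolves overlapping sites per miRNA-transcript pair.
// [[Rcpp::export]]
DataFrame scan_targets_cpp(CharacterVector mirnas, CharacterVector transcripts,
                           double cutoff = 3.0, int max_gaps = 1) {
  int half_cutoff = (int)std::lround(cutoff * 2);
  IntegerVector mi_v, tx_v, start_v, end_v, mm_v, gu_v, gap_v;
  NumericVector e_v;
  LogicalVector tr_v;
  CharacterVector st_v;
  int nm = mirnas.size(), ntx = transcripts.size();
  for (int mi = 0; mi < nm; ++mi) {
    std::string m = as<std::string>(mirnas[mi]);
    int L = m.size();
    for (int ti = 0; ti < ntx; ++ti) {
      std::string tx = as<std::string>(transcripts[ti]);
      int n = tx.size();
      for (int t = 0; t + L - 1 <= n; ++t) {
        // candidate variants at this anchor
        Aln best; best.ok = false;
        Aln a0 = score_variant(m, tx, t, 0, 0, half_cutoff);
        if (a0.ok) best = a0;
        if (max_gaps >= 1) {
          for (int g = 1; g <= L - 1; ++g) {
            Aln a1 = score_variant(m, tx, t, 1, g, half_cutoff);
            if (a1.ok && (!best.ok || a1.half_e < best.half_e)) best = a1;
            if (g >= 2 && g <= L - 1) {
              Aln a2 = score_variant(m, tx, t, 2, g, half_cutoff);
              if (a2.ok && (!best.ok || a2.half_e < best.half_e)) best = a2;
            }
          }
        }
        if (best.ok) {
          mi_v.push_back(mi + 1);
          tx_v.push_back(ti + 1);
          start_v.push_back(t);
          end_v.push_back(t + best.site_len);
          e_v.push_back(best.half_e / 2.0);
          mm_v.push_back(best.n_mismatch);
          gu_v.push_back(best.n_gu);
          gap_v.push_back(best.n_gap);
          tr_v.push_back(best.central_mismatch);
          st_v.push_back(best.states);
        }
      }
    }
  }
  return DataFrame::create(_["mirna_idx"] = mi_v, _["transcript_idx"] = tx_v,
                           _["start"] = start_v, _["end"] = end_v, _["E"] = e_v,
                           _["n_mismatch"] = mm_v, _["n_gu"] = gu_v,
                           _["n_gap"] = gap_v, _["translational"] = tr_v,
                           _["states"] = st_v, _["stringsAsFactors"] = false);
}
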