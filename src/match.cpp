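#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Sliding ungapped matcher for tags vs a reference mature set.
// Alignment: tag position 0 sits at reference position s; s ranges so that the 5' and
// 3' end offsets are both within max_off. off5 = -s (negative = 5' trimmed relative to
// the reference), off3 = (s + Lt) - Lr (positive = 3' extension). A hit needs
// overlap >= min_overlap and <= max_sub substitutions inside the overlap.
// Best hit: fewest substitutions, then smallest |off5|+|off3|, then lowest ref index
// (callers pass references sorted by id), then smallest s.
// [[Rcpp::export]]
DataFrame match_tags_cpp(CharacterVector tags, CharacterVector refs,
                         int max_sub = 2, int max_off = 4, int min_overlap = 17) {
  int nt = tags.size(), nr = refs.size();
  std::vector<std::string> rs(nr);
  for (int r = 0; r < nr; ++r) rs[r] = as<std::string>(refs[r]);
  IntegerVector tag_i, ref_i, nsub_v, off5_v, off3_v;
  for (int t = 0; t < nt; ++t) {
    std::string ts = as<std::string>(tags[t]);
    int Lt = ts.size();
    int b_sub = max_sub + 1, b_off = 1 << 20, b_ref = -1, b_s = 0, b5 = 0, b3 = 0;
    for (int r = 0; r < nr; ++r) {
      int Lr = rs[r].size();
      for (int s = -max_off; s <= max_off; ++s) {
        int off5 = -s;
        int off3 = (s + Lt) - Lr;
        if (off3 < -max_off || off3 > max_off) continue;
        int lo = s < 0 ? -s : 0;           // tag index where overlap starts
        int hi = (s + Lt > Lr ? Lr - s : Lt); // tag index past overlap end
        int ov = hi - lo;
        if (ov < min_overlap) continue;
        int sub = 0;
        for (int k = lo; k < hi && sub <= max_sub; ++k)
          if (ts[k] != rs[r][s + k]) ++sub;
        if (sub > max_sub) continue;
        int osum = std::abs(off5) + std::abs(off3);
        bool better = (sub < b_sub) ||
          (sub == b_sub && osum < b_off) ||
          (sub == b_sub && osum == b_off && b_ref >= 0 && r < b_ref) ||
          (sub == b_sub && osum == b_off && r == b_ref && s < b_s);
        if (b_ref < 0 && sub <= max_sub) better = true;
        if (better) {
          b_sub = sub; b_off = osum; b_ref = r; b_s = s; b5 = off5; b3 = off3;
        }
      }
    }
    if (b_ref >= 0) {
      tag_i.push_back(t + 1);
      ref_i.push_back(b_ref + 1);
      nsub_v.push_back(b_sub);
      off5_v.push_back(b5);
      off3_v.push_back(b3);
    }
  }
  return DataFrame::create(_["tag_idx"] = tag_i, _["ref_idx"] = ref_i,
                           _["n_sub"] = nsub_v, _["offset_5p"] = off5_v,
                           _["offset_3p"] = off3_v);
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    default: return 'N';
  }
}

static inline bool pack_kmer(const std::string &s, int pos, int k, uint32_t &key) {
  uint32_t v = 0;
  for (int i = 0; i < k; ++i) {
    char c = s[pos + i];
    int b;
    switch (c) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: return false;
    }
    v = (v << 2) | b;
  }
  key = v;
  return true;
}

// Ungapped tag-to-locus mapping with <= max_mm mismatches on both strands, via a
// pigeonhole 6-mer seed index: a tag split into three parts must have one part exact,
// so looking up the first 6-mer of each third finds every placement.
// Coordinates: 0-based start on the forward locus sequence; strand "-" means the
// reverse complement of the tag matches there.
// [[Rcpp::export]]
DataFrame map_tags_cpp(CharacterVector tags, CharacterVector loci, int max_mm = 2) {
  const int K = 6;
  int nl = loci.size();
  std::vector<std::string> ls(nl);
  // seed index: kmer -> vector of (locus, pos)
  std::unordered_map<uint32_t, std::vector<std::pair<int,int>>> idx;
  for (int l = 0; l < nl; ++l) {
    ls[l] = as<std::string>(loci[l]);
    int n = ls[l].size();
    for (int p = 0; p + K <= n; ++p) {
      uint32_t key;
      if (pack_kmer(ls[l], p, K, key)) idx[key].push_back({l, p});
    }
  }
  IntegerVector tag_i, locus_i, start_v, mm_v;
  CharacterVector strand_v;
  int nt = tags.size();
  for (int t = 0; t < nt; ++t) {
    std::string fw = as<std::string>(tags[t]);
    int L = fw.size();
    std::string rc(L, 'N');
    for (int i = 0; i < L; ++i) rc[L - 1 - i] = comp_base(fw[i]);
    for (int sidx = 0; sidx < 2; ++sidx) {
      const std::string &q = (sidx == 0 ? fw : rc);
      // seed offsets: starts of the three thirds
      int offs[3] = {0, L / 3, (2 * L) / 3};
      std::vector<std::pair<int,int>> seen; // (locus, start) already reported
      for (int c = 0; c < 3; ++c) {
        int o = offs[c];
        if (o + K > L) continue;
        uint32_t key;
        if (!pack_kmer(q, o, K, key)) continue;
        auto it = idx.find(key);
        if (it == idx.end()) continue;
        for (auto &hit : it->second) {
          int l = hit.first, start = hit.second - o;
          if (start < 0 || start + L > (int)ls[l].size()) continue;
          bool dup = false;
          for (auto &sv : seen)
            if (sv.first == l && sv.second == start) { dup = true; break; }
          if (dup) continue;
          int mm = 0;
          const std::string &S = ls[l];
          for (int k = 0; k < L && mm <= max_mm; ++k)
            if (q[k] != S[start + k]) ++mm;
          if (mm <= max_mm) {
            seen.push_back({l, start});
            tag_i.push_back(t + 1);
            locus_i.push_back(l + 1);
            start_v.push_back(start);
            mm_v.push_back(mm);
            strand_v.push_back(sidx == 0 ? "+" : "-");
          } else {
            seen.push_back({l, start}); // verified and rejected; skip re-checks
          }
        }
      }
    }
  }
  return DataFrame::create(_["tag_idx"] = tag_i, _["locus_idx"] = locus_i,
                           _["start"] = start_v, _["strand"] = strand_v,
                           _["n_mismatches"] = mm_v,
                           _["stringsAsFactors"] = false);
}
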