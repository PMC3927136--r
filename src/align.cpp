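// Core alignment and k-mer routines for pmoaclass.
//
// The nucleotide engine is seed-and-extend: exact shared words gate which
// read/reference pairs are aligned, then the extension computes the optimal
// local alignment (Gotoh affine-gap Smith-Waterman) with traceback.  The
// translated engine mirrors BLAST-style ungapped X-drop extension from exact
// amino-acid word seeds.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int NEG_INF = -100000000;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Distinct k-mer keys of a sequence (2-bit encoding, A=0 C=1 G=2 T=3).
// Words containing non-ACGT characters are skipped.  k must be <= 25 so the
// key is exactly representable as a double.
// [[Rcpp::export]]
NumericVector kmer_keys_cpp(std::string seq, int k) {
  std::vector<uint64_t> keys;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run >= k) keys.push_back(cur);
  }
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
  NumericVector out(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) out[i] = (double)keys[i];
  return out;
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string seq) {
  std::string out(seq.size(), 'N');
  for (size_t i = 0; i < seq.size(); ++i) {
    char c = seq[seq.size() - 1 - i];
    switch (c) {
    case 'A': out[i] = 'T'; break; case 'a': out[i] = 't'; break;
    case 'C': out[i] = 'G'; break; case 'c': out[i] = 'g'; break;
    case 'G': out[i] = 'C'; break; case 'g': out[i] = 'c'; break;
    case 'T': out[i] = 'A'; break; case 't': out[i] = 'a'; break;
    default:  out[i] = c;
    }
  }
  return out;
}

static void collect_words(const std::string& s, int w,
                          std::unordered_set<uint64_t>& set) {
  const uint64_t mask = (1ULL << (2 * w)) - 1;
  uint64_t cur = 0; int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run >= w) set.insert(cur);
  }
}

// For each reference, does it share an exact word of size w with the forward
// read and/or its reverse complement?  Returns an integer matrix [nref x 2]
// of 0/1 flags (columns: forward, reverse).  w must be <= 31.
// [[Rcpp::export]]
IntegerMatrix seed_strands_cpp(std::string fwd, std::string rc,
                               CharacterVector refs, int w) {
  std::unordered_set<uint64_t> fset, rset;
  collect_words(fwd, w, fset);
  collect_words(rc, w, rset);
  IntegerMatrix out(refs.size(), 2);
  const uint64_t mask = (1ULL << (2 * w)) - 1;
  for (int r = 0; r < refs.size(); ++r) {
    std::string ref = as<std::string>(refs[r]);
    uint64_t cur = 0; int run = 0;
    int hitf = 0, hitr = 0;
    for (size_t i = 0; i < ref.size() && !(hitf && hitr); ++i) {
      int c = base_code(ref[i]);
      if (c < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint64_t)c) & mask;
      if (++run >= w) {
        if (!hitf && fset.count(cur)) hitf = 1;
        if (!hitr && rset.count(cur)) hitr = 1;
      }
    }
    out(r, 0) = hitf;
    out(r, 1) = hitr;
  }
  return out;
}

// Optimal local alignment (Smith-Waterman with Gotoh affine gaps) with
// traceback.  `sub` is a 128 x 128 substitution matrix indexed by character
// code.  A gap of length L costs gap_open + L * gap_ext.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, NEG_INF),
      F((n + 1) * W, NEG_INF);
  // traceback codes: tbH 0=stop 1=diag 2=fromE 3=fromF; tbE/tbF 0=fromH 1=ext
  std::vector<uint8_t> tbH((n + 1) * W, 0), tbE((n + 1) * W, 0),
      tbF((n + 1) * W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int ai = (unsigned char)a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      // E: gap in a (consumes b[j])
      int e_open = H[idx - 1] - gap_open - gap_ext;
      int e_ext  = E[idx - 1] - gap_ext;
      if (e_ext > e_open) { E[idx] = e_ext; tbE[idx] = 1; }
      else                { E[idx] = e_open; tbE[idx] = 0; }
      // F: gap in b (consumes a[i])
      int f_open = H[idx - W] - gap_open - gap_ext;
      int f_ext  = F[idx - W] - gap_ext;
      if (f_ext > f_open) { F[idx] = f_ext; tbF[idx] = 1; }
      else                { F[idx] = f_open; tbF[idx] = 0; }
      int diag = H[idx - W - 1] + sub(ai, (unsigned char)b[j - 1]);
      int h = 0; uint8_t t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      H[idx] = h; tbH[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["qaln"] = "", _["saln"] = "",
                        _["qstart"] = 0, _["qend"] = 0, _["sstart"] = 0,
                        _["send"] = 0);
  }
  std::string qa, sa;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  while (true) {
    const int idx = i * W + j;
    if (state == 0) {
      uint8_t t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        qa.push_back(a[i - 1]); sa.push_back(b[j - 1]);
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      qa.push_back('-'); sa.push_back(b[j - 1]);
      uint8_t t = tbE[idx];
      --j;
      if (t == 0) state = 0;
    } else {
      qa.push_back(a[i - 1]); sa.push_back('-');
      uint8_t t = tbF[idx];
      --i;
      if (t == 0) state = 0;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(_["score"] = best, _["qaln"] = qa, _["saln"] = sa,
                      _["qstart"] = i + 1, _["qend"] = bi,
                      _["sstart"] = j + 1, _["send"] = bj);
}

// Best ungapped HSP between any pair of translation frames, seeded on exact
// shared amino-acid words of size w and extended with X-drop.  Frames are
// amino-acid strings ('*' marks stops; give it a strongly negative score in
// `sub` so extensions truncate there).  Returns c(score, qframe, sframe,
// qstart, qend, sstart, send) with 1-based frame coordinates, or score 0 if
// no seed exists.
// [[Rcpp::export]]
NumericVector tx_best_hsp_cpp(CharacterVector qframes, CharacterVector sframes,
                              IntegerMatrix sub, int w, int xdrop) {
  int best = 0, bqf = 0, bsf = 0, bqs = 0, bqe = 0, bss = 0, bse = 0;
  for (int sf = 0; sf < sframes.size(); ++sf) {
    std::string s = as<std::string>(sframes[sf]);
    if ((int)s.size() < w) continue;
    std::unordered_multimap<uint32_t, int> index;
    for (size_t j = 0; j + w <= s.size(); ++j) {
      bool ok = true;
      uint32_t key = 0;
      for (int t = 0; t < w; ++t) {
        char c = s[j + t];
        if (c == '*') { ok = false; break; }
        key = (key << 8) | (uint32_t)(unsigned char)c;
      }
      if (ok) index.insert({key, (int)j});
    }
    if (index.empty()) continue;
    for (int qf = 0; qf < qframes.size(); ++qf) {
      std::string q = as<std::string>(qframes[qf]);
      if ((int)q.size() < w) continue;
      std::unordered_map<int, int> diag_done;  // diagonal -> last covered qend
      for (size_t i = 0; i + w <= q.size(); ++i) {
        bool ok = true;
        uint32_t key = 0;
        for (int t = 0; t < w; ++t) {
          char c = q[i + t];
          if (c == '*') { ok = false; break; }
          key = (key << 8) | (uint32_t)(unsigned char)c;
        }
        if (!ok) continue;
        auto range = index.equal_range(key);
        for (auto it = range.first; it != range.second; ++it) {
          int j = it->second;
          int d = (int)i - j;
          auto dd = diag_done.find(d);
          if (dd != diag_done.end() && dd->second >= (int)i) continue;
          int word = 0;
          for (int t = 0; t < w; ++t)
            word += sub((unsigned char)q[i + t], (unsigned char)s[j + t]);
          // extend left
          int cur = 0, best_l = 0, off_l = 0;
          for (int qi = (int)i - 1, sj = j - 1; qi >= 0 && sj >= 0; --qi, --sj) {
            cur += sub((unsigned char)q[qi], (unsigned char)s[sj]);
            if (cur > best_l) { best_l = cur; off_l = (int)i - qi; }
            if (cur < best_l - xdrop) break;
          }
          // extend right
          cur = 0; int best_r = 0, off_r = 0;
          for (int qi = (int)i + w, sj = j + w;
               qi < (int)q.size() && sj < (int)s.size(); ++qi, ++sj) {
            cur += sub((unsigned char)q[qi], (unsigned char)s[sj]);
            if (cur > best_r) { best_r = cur; off_r = qi - (int)i - w + 1; }
            if (cur < best_r - xdrop) break;
          }
          int total = word + best_l + best_r;
          int qe = (int)i + w - 1 + off_r;
          diag_done[d] = qe;
          if (total > best) {
            best = total;
            bqf = qf + 1; bsf = sf + 1;
            bqs = (int)i - off_l + 1; bqe = qe + 1;
            bss = j - off_l + 1; bse = j + w - 1 + off_r + 1;
          }
        }
      }
    }
  }
  return NumericVector::create(best, bqf, bsf, bqs, bqe, bss, bse);
}
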