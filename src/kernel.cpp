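#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

const char BASES[4] = {'A', 'C', 'G', 'T'};

char complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (std::size_t i = 0; i < r.size(); ++i) r[i] = complement(r[i]);
  return r;
}

struct Aln {
  int score, start, end, matches;
  std::vector<int> map;  // subject position (1-based) per pattern position, 0 = gap
};

// Semi-global alignment of the WHOLE pattern against a substring of the
// subject (free subject overhangs at both ends). With anchor_start = true the
// aligned subject region must begin at subject position 1 (prefix alignment;
// the end stays free) — used for greedy tandem unit consumption.
// Linear gap penalty; scores fixed (match +1 / mismatch -1 / gap -2): the
// callers threshold on identity (matches / pattern length), not on score.
Aln align_core(const std::string& p, const std::string& s,
               bool anchor_start, bool want_map) {
  const int m = (int)p.size(), n = (int)s.size();
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  std::vector<int> prev(n + 1), cur(n + 1);
  // traceback moves: 0 stop (free start), 1 diag, 2 up (pattern vs gap),
  // 3 left (subject vs gap)
  std::vector<unsigned char> tb((std::size_t)(m + 1) * (n + 1), 0);
  for (int j = 0; j <= n; ++j) prev[j] = anchor_start ? j * GAP : 0;
  if (anchor_start) for (int j = 1; j <= n; ++j) tb[j] = 3;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i * GAP;
    tb[(std::size_t)i * (n + 1)] = 2;
    const char pc = p[i - 1];
    for (int j = 1; j <= n; ++j) {
      int d = prev[j - 1] + (pc == s[j - 1] ? MATCH : MISMATCH);
      int u = prev[j] + GAP;
      int l = cur[j - 1] + GAP;
      int best = d; unsigned char mv = 1;
      if (u > best) { best = u; mv = 2; }
      if (l > best) { best = l; mv = 3; }
      cur[j] = best;
      tb[(std::size_t)i * (n + 1) + j] = mv;
    }
    std::swap(prev, cur);
  }
  int jend = 0, bestScore = prev[0];
  for (int j = 1; j <= n; ++j) if (prev[j] > bestScore) { bestScore = prev[j]; jend = j; }

  Aln r; r.score = bestScore; r.end = jend; r.matches = 0;
  if (want_map) r.map.assign(m, 0);
  int i = m, j = jend;
  while (i > 0 || (anchor_start && j > 0)) {
    unsigned char mv = tb[(std::size_t)i * (n + 1) + j];
    if (mv == 1)      { if (p[i - 1] == s[j - 1]) ++r.matches;
                        if (want_map) r.map[i - 1] = j; --i; --j; }
    else if (mv == 2) { --i; }
    else if (mv == 3) { --j; }
    else break;  // free start reached
  }
  r.start = j + 1;
  return r;
}

}  // namespace

// [[Rcpp::export]]
List cpp_align(std::string pattern, std::string subject,
               bool anchor_start = false, bool want_map = false) {
  if (pattern.empty() || subject.empty())
    stop("pattern and subject must be non-empty");
  Aln a = align_core(pattern, subject, anchor_start, want_map);
  List out = List::create(
    _["score"] = a.score, _["start"] = a.start, _["end"] = a.end,
    _["matches"] = a.matches,
    _["identity"] = (double)a.matches / (double)pattern.size());
  if (want_map) out["map"] = IntegerVector(a.map.begin(), a.map.end());
  return out;
}

// Greedy tandem unit counting: repeatedly align the unit consensus to the
// front of the remaining segment (prefix-anchored, free end) and accept the
// unit if identity >= min_identity; advance past the aligned footprint.
// Returns c(count, consumed bases).
// [[Rcpp::export]]
IntegerVector cpp_count_tandem(std::string segment, std::string unit,
                               double min_identity) {
  const int ulen = (int)unit.size();
  if (ulen < 1) stop("unit must be non-empty");
  int pos = 0, count = 0;
  const int n = (int)segment.size();
  const int min_rem = std::max(1, (int)std::ceil(0.65 * ulen));
  while (n - pos >= min_rem) {
    int wlen = std::min(n - pos, ulen + 8);
    std::string window = segment.substr(pos, wlen);
    Aln a = align_core(unit, window, true, false);
    double id = (double)a.matches / (double)ulen;
    if (id >= min_identity) {
      ++count;
      pos += std::max(1, a.end);
    } else {
      pos += ulen;  // skip an unrecognizable stretch
    }
  }
  IntegerVector out(2);
  out[0] = count; out[1] = pos > n ? n : pos;
  return out;
}

// All 1-based start positions where pattern matches subject with at most
// max_mm mismatches (no indels).
// [[Rcpp::export]]
IntegerVector cpp_scan(std::string subject, std::string pattern, int max_mm) {
  const int n = (int)subject.size(), m = (int)pattern.size();
  std::vector<int> hits;
  for (int i = 0; i + m <= n; ++i) {
    int mm = 0;
    for (int j = 0; j < m; ++j) {
      if (subject[i + j] != pattern[j] && ++mm > max_mm) break;
    }
    if (mm <= max_mm) hits.push_back(i + 1);
  }
  return IntegerVector(hits.begin(), hits.end());
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming distance requires equal lengths");
  int d = 0;
  for (std::size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// Per-base error injection using R's RNG (reproducible under set.seed).
// For each template base: one draw decides deletion / substitution / intact,
// then one draw decides whether a random base is inserted after it. The two
// draws are always consumed so the RNG stream length is fixed per base.
// [[Rcpp::export]]
CharacterVector cpp_mutate(CharacterVector seqs, double p_sub, double p_ins,
                           double p_del) {
  const int nseq = seqs.size();
  CharacterVector out(nseq);
  for (int k = 0; k < nseq; ++k) {
    std::string s = as<std::string>(seqs[k]);
    std::string r;
    r.reserve(s.size() + 16);
    for (std::size_t i = 0; i < s.size(); ++i) {
      double u = unif_rand();
      if (u >= p_del) {
        char c = s[i];
        if (u < p_del + p_sub) {
          // substitute with one of the three other bases
          int b0 = 0;
          switch (c) { case 'A': b0 = 0; break; case 'C': b0 = 1; break;
                       case 'G': b0 = 2; break; case 'T': b0 = 3; break;
                       default: b0 = -1; }
          int pick = (int)(unif_rand() * 3.0); if (pick > 2) pick = 2;
          c = (b0 < 0) ? BASES[pick] : BASES[(b0 + 1 + pick) % 4];
        }
        r += c;
      }
      if (unif_rand() < p_ins) {
        int pick = (int)(unif_rand() * 4.0); if (pick > 3) pick = 3;
        r += BASES[pick];
      }
    }
    out[k] = r;
  }
  return out;
}

// Batch dual-barcode matcher. For each read, both orientations are tried:
// the forward barcode is read at positions [1, bc_len] and the reverse
// barcode (as reverse complement) at [L - rtag_len - bc_len + 1, L - rtag_len].
// A read is assigned iff exactly one (sample, orientation) pair matches both
// barcodes within max_mm mismatches.
// Returns sample index (1-based; 0 unmatched, -1 ambiguous) and orientation
// (1 forward, 2 reverse, 0 none).
// [[Rcpp::export]]
List cpp_demux(CharacterVector reads, CharacterVector bc_fwd,
               CharacterVector bc_rev_rc, int bc_len, int rtag_len,
               int max_mm) {
  const int nr = reads.size(), ns = bc_fwd.size();
  std::vector<std::string> bf(ns), br(ns);
  for (int s = 0; s < ns; ++s) {
    bf[s] = as<std::string>(bc_fwd[s]);
    br[s] = as<std::string>(bc_rev_rc[s]);
  }
  IntegerVector sample(nr), orient(nr);
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const int L = (int)rd.size();
    int nhit = 0, hit_s = 0, hit_o = 0;
    if (L >= 2 * bc_len + rtag_len) {
      for (int o = 1; o <= 2; ++o) {
        std::string view = (o == 1) ? rd : revcomp(rd);
        std::string f_obs = view.substr(0, bc_len);
        std::string r_obs = view.substr(L - rtag_len - bc_len, bc_len);
        for (int s = 0; s < ns; ++s) {
          int d1 = 0, d2 = 0;
          for (int j = 0; j < bc_len; ++j) {
            if (f_obs[j] != bf[s][j]) ++d1;
            if (r_obs[j] != br[s][j]) ++d2;
          }
          if (d1 <= max_mm && d2 <= max_mm) {
            ++nhit; hit_s = s + 1; hit_o = o;
          }
        }
      }
    }
    if (nhit == 1)      { sample[i] = hit_s; orient[i] = hit_o; }
    else if (nhit == 0) { sample[i] = 0;  orient[i] = 0; }
    else                { sample[i] = -1; orient[i] = 0; }
  }
  return List::create(_["sample"] = sample, _["orientation"] = orient);
}
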