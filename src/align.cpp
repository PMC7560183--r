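#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Gap of length L costs gap_open + L * gap_ext,
// matching the gapOpening/gapExtension convention of the common pairwise aligners.
// Traceback records aligned (match/mismatch) column pairs only; gap columns are
// counted in ncols but carry no coordinate pair.

struct AlnResult {
  double score;
  int qstart, qend, sstart, send; // 1-based, inclusive; 0 if empty
  int matches, ncols;
  std::vector<int> qmap, smap;    // aligned (non-gap) columns, 1-based
};

static AlnResult sw_core(const std::string &q, const std::string &s,
                         double match, double mismatch,
                         double gap_open, double gap_ext) {
  const int n = (int)q.size(), m = (int)s.size();
  AlnResult res; res.score = 0; res.qstart = res.qend = res.sstart = res.send = 0;
  res.matches = 0; res.ncols = 0;
  if (n == 0 || m == 0) return res;
  if ((double)(n + 1) * (double)(m + 1) > 2.5e8)
    stop("alignment matrix too large (%d x %d); use the seeded search", n, m);

  const double NEG = -1e30;
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<double> E((size_t)(n + 1) * (m + 1), NEG); // gap in query (consumes subject)
  std::vector<double> F((size_t)(n + 1) * (m + 1), NEG); // gap in subject (consumes query)
  // traceback: 0 stop, 1 diag, 2 from E, 3 from F; for E/F: open (1) vs extend (0)
  std::vector<unsigned char> TH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> TE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> TF((size_t)(n + 1) * (m + 1), 0);

  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * (m + 1), prow = (size_t)(i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      double eo = H[row + j - 1] - gap_open - gap_ext;
      double ee = E[row + j - 1] - gap_ext;
      if (eo >= ee) { E[row + j] = eo; TE[row + j] = 1; }
      else          { E[row + j] = ee; TE[row + j] = 0; }
      double fo = H[prow + j] - gap_open - gap_ext;
      double fe = F[prow + j] - gap_ext;
      if (fo >= fe) { F[row + j] = fo; TF[row + j] = 1; }
      else          { F[row + j] = fe; TF[row + j] = 0; }
      double sc = (q[i - 1] == s[j - 1] && q[i - 1] != 'N') ? match : mismatch;
      double d = H[prow + j - 1] + sc;
      double h = 0; unsigned char t = 0;
      if (d > h) { h = d; t = 1; }
      if (E[row + j] > h) { h = E[row + j]; t = 2; }
      if (F[row + j] > h) { h = F[row + j]; t = 3; }
      H[row + j] = h; TH[row + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  res.score = best;
  if (best <= 0) return res;
  // traceback from (bi, bj)
  int i = bi, j = bj; int state = 0; // 0 = H, 2 = E, 3 = F
  std::vector<int> qm, sm; int matches = 0, ncols = 0;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = TH[idx];
      if (t == 0) break;
      if (t == 1) {
        qm.push_back(i); sm.push_back(j); ++ncols;
        if (q[i - 1] == s[j - 1] && q[i - 1] != 'N') ++matches;
        --i; --j;
      } else state = t;
    } else if (state == 2) {
      ++ncols;
      unsigned char t = TE[idx];
      --j;
      if (t == 1) state = 0;
    } else {
      ++ncols;
      unsigned char t = TF[idx];
      --i;
      if (t == 1) state = 0;
    }
  }
  std::reverse(qm.begin(), qm.end());
  std::reverse(sm.begin(), sm.end());
  res.qstart = qm.empty() ? 0 : qm.front();
  res.qend   = qm.empty() ? 0 : qm.back();
  res.sstart = sm.empty() ? 0 : sm.front();
  res.send   = sm.empty() ? 0 : sm.back();
  res.matches = matches; res.ncols = ncols;
  res.qmap = qm; res.smap = sm;
  return res;
}

static List aln_to_list(const AlnResult &r) {
  return List::create(_["score"] = r.score,
                      _["qstart"] = r.qstart, _["qend"] = r.qend,
                      _["sstart"] = r.sstart, _["send"] = r.send,
                      _["matches"] = r.matches, _["ncols"] = r.ncols,
                      _["qmap"] = IntegerVector(r.qmap.begin(), r.qmap.end()),
                      _["smap"] = IntegerVector(r.smap.begin(), r.smap.end()));
}

// [[Rcpp::export]]
List cpp_sw_align(std::string query, std::string subject,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  return aln_to_list(sw_core(query, subject, match, mismatch, gap_open, gap_ext));
}

static inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

// k-mer seeded local search: hash query k-mers, scan the subject, cluster seeds
// by diagonal and position, align each candidate window with the full DP above.
// [[Rcpp::export]]
List cpp_seeded_hits(std::string query, std::string subject, int k,
                     double match, double mismatch,
                     double gap_open, double gap_ext,
                     int band, int max_hits) {
  const int n = (int)query.size(), m = (int)subject.size();
  List out;
  if (n < k || m < k) return out;

  std::unordered_map<uint64_t, std::vector<int> > idx;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(query[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask; ++run;
    if (run >= k) idx[h].push_back(i - k + 1); // 0-based query start
  }
  if (idx.empty()) return out;

  struct Seed { int q, s; };
  std::vector<Seed> seeds;
  h = 0; run = 0;
  for (int j = 0; j < m; ++j) {
    int c = base_code(subject[j]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask; ++run;
    if (run >= k) {
      auto it = idx.find(h);
      if (it != idx.end())
        for (int qp : it->second) seeds.push_back({qp, j - k + 1});
    }
  }
  if (seeds.empty()) return out;

  std::sort(seeds.begin(), seeds.end(), [](const Seed &a, const Seed &b) {
    int da = a.s - a.q, db = b.s - b.q;
    if (da != db) return da < db;
    return a.s < b.s;
  });

  // cluster seeds -> candidate subject windows
  std::vector<std::pair<int, int> > wins;
  int cs_lo = seeds[0].s, cs_hi = seeds[0].s;
  int prev_d = seeds[0].s - seeds[0].q, prev_s = seeds[0].s;
  auto flush = [&](int lo, int hi) {
    int a = std::max(0, lo - n - band);
    int b = std::min(m, hi + k + n + band);
    wins.push_back(std::make_pair(a, b));
  };
  for (size_t t = 1; t < seeds.size(); ++t) {
    int d = seeds[t].s - seeds[t].q;
    bool same = (d - prev_d) <= band && std::abs(seeds[t].s - prev_s) <= 2 * n + band;
    if (same) {
      cs_lo = std::min(cs_lo, seeds[t].s);
      cs_hi = std::max(cs_hi, seeds[t].s);
    } else {
      flush(cs_lo, cs_hi);
      cs_lo = cs_hi = seeds[t].s;
    }
    prev_d = d; prev_s = seeds[t].s;
  }
  flush(cs_lo, cs_hi);

  // merge overlapping windows
  std::sort(wins.begin(), wins.end());
  std::vector<std::pair<int, int> > merged;
  for (auto &w : wins) {
    if (!merged.empty() && w.first <= merged.back().second)
      merged.back().second = std::max(merged.back().second, w.second);
    else merged.push_back(w);
  }

  std::vector<AlnResult> hits;
  std::vector<int> offsets;
  for (auto &w : merged) {
    std::string sub = subject.substr(w.first, w.second - w.first);
    AlnResult r = sw_core(query, sub, match, mismatch, gap_open, gap_ext);
    if (r.score > 0 && r.ncols > 0) { hits.push_back(r); offsets.push_back(w.first); }
  }
  // sort by score descending
  std::vector<int> ord(hits.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return hits[a].score > hits[b].score;
  });
  int nh = std::min((int)ord.size(), max_hits);
  List res(nh);
  for (int t = 0; t < nh; ++t) {
    AlnResult r = hits[ord[t]];
    int off = offsets[ord[t]];
    r.sstart += off; r.send += off;
    for (auto &v : r.smap) v += off;
    res[t] = aln_to_list(r);
  }
  return res;
}
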