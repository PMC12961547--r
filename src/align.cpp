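#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3, anything else (N etc.) = -1.
// A base coded -1 never matches, is never indexed in k-mer seeds.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': case 'a': c = 'T'; break;
      case 'C': case 'c': c = 'G'; break;
      case 'G': case 'g': c = 'C'; break;
      case 'T': case 't': c = 'A'; break;
      default: c = 'N'; break;
    }
  }
  return r;
}

// ---- k-mer index over a set of chromosome sequences -------------------------

struct KmerIndex {
  int k;
  // packed position: (chrom << 40) | pos ; supports chrom < 2^24, pos < 2^40
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;
};

static void build_index(KmerIndex& idx, const std::vector<std::string>& seqs, int k) {
  idx.k = k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t ci = 0; ci < seqs.size(); ++ci) {
    const std::string& s = seqs[ci];
    if ((int)s.size() < k) continue;
    uint64_t key = 0;
    int valid = 0;  // number of consecutive valid bases ending here
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t pos = i + 1 - k;
        idx.map[key].push_back(((uint64_t)ci << 40) | pos);
      }
    }
  }
}

// k-mer key of query starting at qpos, or false if it contains a non-ACGT base
static bool query_kmer(const std::string& q, int qpos, int k, uint64_t& key) {
  key = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(q[qpos + i]);
    if (b < 0) return false;
    key = (key << 2) | (uint64_t)b;
  }
  return true;
}

// ---- fitting alignment ------------------------------------------------------
// Align the whole query against any substring of target[t_lo, t_hi)
// minimising unit-cost edit distance (Levenshtein); free end gaps on the
// target only.  Traceback prefers diagonal moves so that match/gap counts are
// reported for one canonical optimal path.

struct FitAln {
  int edit;        // minimum edit distance
  int matches;     // identically aligned bases
  int mismatches;  // aligned but different
  int gap_opens;   // maximal runs of gaps (either sequence)
  int gapped;      // total gapped columns
  long t_start;    // target coordinates of the aligned span (absolute)
  long t_end;      // exclusive
  bool ok;
};

static FitAln fit_align(const std::string& q, const std::string& t,
                        long t_lo, long t_hi) {
  FitAln res; res.ok = false;
  const int m = (int)q.size();
  if (t_lo < 0) t_lo = 0;
  if (t_hi > (long)t.size()) t_hi = (long)t.size();
  const int n = (int)(t_hi - t_lo);
  if (m == 0 || n <= 0) return res;

  // D has (m+1) x (n+1) cells; dir: 0 diag, 1 up (gap in target), 2 left (gap in query)
  std::vector<int> D((size_t)(m + 1) * (n + 1));
  std::vector<uint8_t> dir((size_t)(m + 1) * (n + 1));
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  for (int j = 0; j <= n; ++j) { D[at(0, j)] = 0; dir[at(0, j)] = 2; }
  for (int i = 1; i <= m; ++i) { D[at(i, 0)] = i; dir[at(i, 0)] = 1; }

  std::vector<int> qc(m), tc(n);
  for (int i = 0; i < m; ++i) qc[i] = base_code(q[i]);
  for (int j = 0; j < n; ++j) tc[j] = base_code(t[t_lo + j]);

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int sub = (qc[i - 1] >= 0 && qc[i - 1] == tc[j - 1]) ? 0 : 1;
      int best = D[at(i - 1, j - 1)] + sub; uint8_t d = 0;
      int up = D[at(i - 1, j)] + 1;
      if (up < best) { best = up; d = 1; }
      int left = D[at(i, j - 1)] + 1;
      if (left < best) { best = left; d = 2; }
      D[at(i, j)] = best; dir[at(i, j)] = d;
    }
  }

  int best_j = 0, best_e = D[at(m, 0)];
  for (int j = 1; j <= n; ++j)
    if (D[at(m, j)] < best_e) { best_e = D[at(m, j)]; best_j = j; }

  // traceback
  int i = m, j = best_j;
  int matches = 0, mism = 0, gaps = 0, gap_opens = 0;
  uint8_t prev = 0;
  while (i > 0) {
    uint8_t d = dir[at(i, j)];
    if (d == 0) {
      if (qc[i - 1] >= 0 && qc[i - 1] == tc[j - 1]) ++matches; else ++mism;
      --i; --j;
    } else if (d == 1) {
      ++gaps; if (prev != 1) ++gap_opens;
      --i;
    } else {
      ++gaps; if (prev != 2) ++gap_opens;
      --j;
    }
    prev = d;
  }
  res.edit = best_e;
  res.matches = matches;
  res.mismatches = mism;
  res.gap_opens = gap_opens;
  res.gapped = gaps;
  res.t_start = t_lo + j;
  res.t_end = t_lo + best_j;
  res.ok = true;
  return res;
}

// ---- local alignment --------------------------------------------------------
// Smith-Waterman (+1 match, -2 mismatch, -2 per gapped column) of the query
// against target[t_lo, t_hi).  The -2 penalties keep random sequence in the
// logarithmic score regime while 70%-identity homology still extends
// (expected drift 0.7 - 0.6 > 0 per column).  Only the best-scoring local
// segment is reported, so partially homologous queries yield partial aligned
// fractions.  Traceback prefers diagonal moves.

static FitAln sw_align(const std::string& q, const std::string& t,
                       long t_lo, long t_hi) {
  FitAln res; res.ok = false;
  const int m = (int)q.size();
  if (t_lo < 0) t_lo = 0;
  if (t_hi > (long)t.size()) t_hi = (long)t.size();
  const int n = (int)(t_hi - t_lo);
  if (m == 0 || n <= 0) return res;

  std::vector<int> S((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> dir((size_t)(m + 1) * (n + 1), 3);  // 3 = stop
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  std::vector<int> qc(m), tc(n);
  for (int i = 0; i < m; ++i) qc[i] = base_code(q[i]);
  for (int j = 0; j < n; ++j) tc[j] = base_code(t[t_lo + j]);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int sub = (qc[i - 1] >= 0 && qc[i - 1] == tc[j - 1]) ? 1 : -2;
      int sc = S[at(i - 1, j - 1)] + sub; uint8_t d = 0;
      int up = S[at(i - 1, j)] - 2;
      if (up > sc) { sc = up; d = 1; }
      int left = S[at(i, j - 1)] - 2;
      if (left > sc) { sc = left; d = 2; }
      if (sc <= 0) { sc = 0; d = 3; }
      S[at(i, j)] = sc; dir[at(i, j)] = d;
      if (sc > best) { best = sc; bi = i; bj = j; }
    }
  }
  if (best == 0) return res;

  int i = bi, j = bj;
  int matches = 0, mism = 0, gaps = 0, gap_opens = 0;
  uint8_t prev = 0;
  while (i > 0 && j > 0 && dir[at(i, j)] != 3 && S[at(i, j)] > 0) {
    uint8_t d = dir[at(i, j)];
    if (d == 0) {
      if (qc[i - 1] >= 0 && qc[i - 1] == tc[j - 1]) ++matches; else ++mism;
      --i; --j;
    } else if (d == 1) {
      ++gaps; if (prev != 1) ++gap_opens;
      --i;
    } else {
      ++gaps; if (prev != 2) ++gap_opens;
      --j;
    }
    prev = d;
  }
  res.edit = mism + gaps;
  res.matches = matches;
  res.mismatches = mism;
  res.gap_opens = gap_opens;
  res.gapped = gaps;
  res.t_start = t_lo + j;
  res.t_end = t_lo + bj;
  res.ok = true;
  return res;
}

static std::vector<std::string> as_strings(const CharacterVector& x) {
  std::vector<std::string> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = as<std::string>(x[i]);
  return out;
}

// ---- read mapping -----------------------------------------------------------
// Seed with non-overlapping k-mers, verify every candidate locus with a
// fitting alignment of the full read, keep the hit with minimal edit distance
// <= max_edit.  Ties between loci are broken by lowest chromosome index, then
// leftmost start; plus strand wins a cross-strand tie.

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector chrom_seqs,
                        int k, int max_edit, int max_occ) {
  std::vector<std::string> seqs = as_strings(chrom_seqs);
  KmerIndex idx;
  build_index(idx, seqs, k);

  const R_xlen_t nr = reads.size();
  IntegerVector out_chrom(nr, NA_INTEGER), out_start(nr, NA_INTEGER),
      out_end(nr, NA_INTEGER), out_edit(nr, NA_INTEGER), out_match(nr, NA_INTEGER);
  CharacterVector out_strand(nr, NA_STRING);

  for (R_xlen_t r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int m = (int)fwd.size();
    if (m < k) continue;  // degenerate read: unmapped
    bool have = false;
    int b_chrom = 0, b_edit = 0, b_match = 0; long b_start = 0, b_end = 0;
    char b_strand = '+';

    for (int st = 0; st < 2; ++st) {
      std::string q = (st == 0) ? fwd : revcomp(fwd);
      // candidate start positions, from seed diagonals
      std::vector<std::pair<int, long>> cands;  // (chrom, implied start)
      for (int qpos = 0; qpos + k <= m; qpos += k) {
        uint64_t key;
        if (!query_kmer(q, qpos, k, key)) continue;
        auto it = idx.map.find(key);
        if (it == idx.map.end()) continue;
        if ((int)it->second.size() > max_occ) continue;
        for (uint64_t packed : it->second) {
          int ci = (int)(packed >> 40);
          long pos = (long)(packed & ((1ULL << 40) - 1));
          cands.push_back({ci, pos - qpos});
        }
      }
      if (cands.empty()) continue;
      std::sort(cands.begin(), cands.end());
      // collapse candidates whose implied starts fall within max_edit of the
      // previous representative on the same chromosome
      std::vector<std::pair<int, long>> reps;
      for (auto& c : cands) {
        if (!reps.empty() && reps.back().first == c.first &&
            c.second - reps.back().second <= (long)max_edit)
          continue;
        reps.push_back(c);
      }
      for (auto& c : reps) {
        const std::string& t = seqs[c.first];
        FitAln a = fit_align(q, t, c.second - max_edit, c.second + m + max_edit);
        if (!a.ok || a.edit > max_edit) continue;
        bool better = !have || a.edit < b_edit ||
          (a.edit == b_edit && (c.first < b_chrom ||
                                (c.first == b_chrom && a.t_start < b_start)));
        // a cross-strand tie at equal locus keeps the earlier (plus) strand
        if (have && st == 1 && a.edit == b_edit && c.first == b_chrom &&
            a.t_start == b_start) better = false;
        if (better) {
          have = true; b_chrom = c.first; b_edit = a.edit; b_match = a.matches;
          b_start = a.t_start; b_end = a.t_end; b_strand = (st == 0) ? '+' : '-';
        }
      }
    }
    if (have) {
      out_chrom[r] = b_chrom + 1;
      out_start[r] = (int)b_start;
      out_end[r] = (int)b_end;
      out_edit[r] = b_edit;
      out_match[r] = b_match;
      out_strand[r] = std::string(1, b_strand);
    }
  }
  return DataFrame::create(_["chrom_idx"] = out_chrom, _["start"] = out_start,
                           _["end"] = out_end, _["edit_distance"] = out_edit,
                           _["n_matches"] = out_match, _["strand"] = out_strand,
                           _["stringsAsFactors"] = false);
}

// ---- seeded projection (blat-like) ------------------------------------------
// Exact seed matches on both strands are grouped by (chromosome, strand,
// diagonal); each group's spanned target region is aligned to the full query
// by fitting alignment.  Per-hit match/mismatch/gap counts are returned; score
// and identity filters are applied by the caller.

struct Cluster { int chrom; long t_lo, t_hi; int n_seeds; };

// [[Rcpp::export]]
DataFrame cpp_project_queries(CharacterVector queries, CharacterVector chrom_seqs,
                              int seed_len, int max_occ, int min_seeds,
                              int diag_tol) {
  std::vector<std::string> seqs = as_strings(chrom_seqs);
  KmerIndex idx;
  build_index(idx, seqs, seed_len);

  std::vector<int> o_query, o_chrom, o_matches, o_mism, o_gapopen, o_gapped;
  std::vector<long> o_tstart, o_tend;
  std::vector<char> o_strand;

  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    std::string fwd = as<std::string>(queries[qi]);
    int m = (int)fwd.size();
    if (m < seed_len) continue;
    for (int st = 0; st < 2; ++st) {
      std::string q = (st == 0) ? fwd : revcomp(fwd);
      // seeds: (chrom, diag, tpos)
      std::vector<std::tuple<int, long, long>> seeds;
      for (int qpos = 0; qpos + seed_len <= m; ++qpos) {
        uint64_t key;
        if (!query_kmer(q, qpos, seed_len, key)) continue;
        auto it = idx.map.find(key);
        if (it == idx.map.end()) continue;
        if ((int)it->second.size() > max_occ) continue;  // ooc-style masking
        for (uint64_t packed : it->second) {
          int ci = (int)(packed >> 40);
          long pos = (long)(packed & ((1ULL << 40) - 1));
          seeds.push_back({ci, pos - qpos, pos});
        }
      }
      if (seeds.empty()) continue;
      std::sort(seeds.begin(), seeds.end());
      // cluster seeds along nearby diagonals
      std::vector<Cluster> clusters;
      int cur_chrom = -1; long cur_diag = 0;
      long lo = 0, hi = 0; int nseed = 0;
      auto flush = [&]() {
        if (nseed >= min_seeds)
          clusters.push_back({cur_chrom, lo, hi, nseed});
        nseed = 0;
      };
      for (auto& s : seeds) {
        int ci = std::get<0>(s); long dg = std::get<1>(s), tp = std::get<2>(s);
        // span implied by the seed's diagonal: the query projected there
        if (nseed == 0 || ci != cur_chrom || dg - cur_diag > diag_tol) {
          flush();
          cur_chrom = ci; cur_diag = dg; lo = dg; hi = dg + m; nseed = 1;
        } else {
          cur_diag = dg;
          lo = std::min(lo, dg); hi = std::max(hi, dg + (long)m); ++nseed;
        }
      }
      flush();
      if (clusters.empty()) continue;
      // indel slack, then merge overlapping spans
      for (auto& c : clusters) {
        c.t_lo = c.t_lo - diag_tol;
        c.t_hi = c.t_hi + diag_tol;
      }
      std::sort(clusters.begin(), clusters.end(),
                [](const Cluster& a, const Cluster& b) {
                  return a.chrom < b.chrom ||
                         (a.chrom == b.chrom && a.t_lo < b.t_lo);
                });
      std::vector<Cluster> merged;
      for (auto& c : clusters) {
        if (!merged.empty() && merged.back().chrom == c.chrom &&
            c.t_lo <= merged.back().t_hi) {
          merged.back().t_hi = std::max(merged.back().t_hi, c.t_hi);
          merged.back().n_seeds += c.n_seeds;
        } else merged.push_back(c);
      }
      for (auto& c : merged) {
        FitAln a = sw_align(q, seqs[c.chrom], c.t_lo, c.t_hi);
        if (!a.ok) continue;
        o_query.push_back((int)qi + 1);
        o_chrom.push_back(c.chrom + 1);
        o_matches.push_back(a.matches);
        o_mism.push_back(a.mismatches);
        o_gapopen.push_back(a.gap_opens);
        o_gapped.push_back(a.gapped);
        o_tstart.push_back(a.t_start);
        o_tend.push_back(a.t_end);
        o_strand.push_back(st == 0 ? '+' : '-');
      }
    }
  }
  int nh = (int)o_query.size();
  IntegerVector qv(nh), cv(nh), mv(nh), xv(nh), gv(nh), gp(nh), ts(nh), te(nh);
  CharacterVector sv(nh);
  for (int i = 0; i < nh; ++i) {
    qv[i] = o_query[i]; cv[i] = o_chrom[i]; mv[i] = o_matches[i];
    xv[i] = o_mism[i]; gv[i] = o_gapopen[i]; gp[i] = o_gapped[i];
    ts[i] = (int)o_tstart[i]; te[i] = (int)o_tend[i];
    sv[i] = std::string(1, o_strand[i]);
  }
  return DataFrame::create(_["query_idx"] = qv, _["chrom_idx"] = cv,
                           _["t_start"] = ts, _["t_end"] = te,
                           _["strand"] = sv, _["matches"] = mv,
                           _["mismatches"] = xv, _["gap_opens"] = gv,
                           _["gapped"] = gp, _["stringsAsFactors"] = false);
}
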