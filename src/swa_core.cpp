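// Core kernels for the sliding-window assembler: unique-read table construction,
// quaternary-keyword hash lookup, overlap profiling, window filtering and the
// greedy seed-extension loop. Kept in C++ so that genome-scale runs (10^6+
// unique reads) stay within interactive time; the R level exposes each
// operation and mirrors the small-scale semantics for testing.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char base_comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 0;
}

static std::string revcomp_one(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = base_comp(s[s.size() - 1 - i]);
    if (!c) stop("non-ACGT character in sequence");
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    out[i] = revcomp_one(s);
  }
  return out;
}

// Per-read minimum and mean Phred score (Sanger +33 encoding).
// [[Rcpp::export]]
List cpp_quality_stats(CharacterVector quals) {
  R_xlen_t n = quals.size();
  IntegerVector qmin(n);
  NumericVector qmean(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    int len = (int)LENGTH(STRING_ELT(quals, i));
    if (len == 0) { qmin[i] = NA_INTEGER; qmean[i] = NA_REAL; continue; }
    int mn = 1000; double sum = 0;
    for (int k = 0; k < len; ++k) {
      int ph = (int)(unsigned char)q[k] - 33;
      if (ph < mn) mn = ph;
      sum += ph;
    }
    qmin[i] = mn;
    qmean[i] = sum / len;
  }
  return List::create(_["min"] = qmin, _["mean"] = qmean);
}

// Collapse reads plus their reverse complements into the sorted unique-read
// table: one row per distinct sequence with its multiplicity and the mean of
// the contributing reads' mean qualities (a reverse-complement copy carries
// the same mean quality, the base-wise string being reversed).
// [[Rcpp::export]]
List cpp_unique_table(CharacterVector seqs, NumericVector mean_quals) {
  R_xlen_t n = seqs.size();
  if (mean_quals.size() != n) stop("sequence/quality length mismatch");
  std::vector<std::pair<std::string, double> > pool;
  pool.reserve(2 * (size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    pool.push_back(std::make_pair(s, mean_quals[i]));
    pool.push_back(std::make_pair(revcomp_one(s), mean_quals[i]));
  }
  std::sort(pool.begin(), pool.end(),
            [](const std::pair<std::string, double>& a,
               const std::pair<std::string, double>& b) { return a.first < b.first; });
  std::vector<std::string> useq;
  std::vector<int> ufreq;
  std::vector<double> uq;
  size_t i = 0, m = pool.size();
  while (i < m) {
    size_t j = i;
    double qsum = 0;
    while (j < m && pool[j].first == pool[i].first) { qsum += pool[j].second; ++j; }
    useq.push_back(pool[i].first);
    ufreq.push_back((int)(j - i));
    uq.push_back(qsum / (double)(j - i));
    i = j;
  }
  size_t k = useq.size();
  CharacterVector rs(k);
  IntegerVector rf(k);
  NumericVector rq(k);
  for (size_t t = 0; t < k; ++t) { rs[t] = useq[t]; rf[t] = ufreq[t]; rq[t] = uq[t]; }
  return List::create(_["sequence"] = rs, _["frequency"] = rf, _["mean_quality"] = rq);
}

// Rectangular sliding-window SUM with edge replication, applied N_f times.
static void smooth_vec(std::vector<double>& y, int L_w, int N_f) {
  int n = (int)y.size();
  int hw = (L_w - 1) / 2;
  std::vector<double> tmp(n);
  for (int pass = 0; pass < N_f; ++pass) {
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int d = -hw; d <= hw; ++d) {
        int idx = i + d;
        if (idx < 0) idx = 0;
        if (idx >= n) idx = n - 1;
        s += y[idx];
      }
      tmp[i] = s;
    }
    y.swap(tmp);
  }
}

// [[Rcpp::export]]
NumericVector cpp_smooth(NumericVector x, int L_w, int N_f) {
  if (L_w < 1 || L_w % 2 == 0) stop("L_w must be odd and positive");
  if (L_w > x.size()) stop("L_w exceeds profile length");
  std::vector<double> y(x.begin(), x.end());
  smooth_vec(y, L_w, N_f);
  return NumericVector(y.begin(), y.end());
}

struct Params {
  int L_r, max_ov, min_ov, L_d, L_w, N_f, L_k, count_floor;
  double S_d, S_fd, H_p, L_p, T1, T2, h;
  int strategy;   // 0 = longest_overlap, 1 = nearest_depth
  int stop_rule;  // 0 = confidence (CUSUM + trim-back), 1 = per-step threshold
};

static Params read_params(const List& p) {
  Params P;
  P.L_r = as<int>(p["L_r"]);
  P.max_ov = as<int>(p["max_ov"]);
  P.min_ov = as<int>(p["min_ov"]);
  P.L_d = P.max_ov - P.min_ov;
  P.L_w = as<int>(p["L_w"]);
  P.N_f = as<int>(p["N_f"]);
  P.L_k = as<int>(p["L_k"]);
  P.count_floor = as<int>(p["count_floor"]);
  P.S_d = as<double>(p["S_d"]);
  P.S_fd = as<double>(p["S_fd"]);
  P.H_p = as<double>(p["H_p"]);
  P.L_p = as<double>(p["L_p"]);
  P.T1 = as<double>(p["T_1"]);
  P.T2 = as<double>(p["T_2"]);
  P.h = as<double>(p["h"]);
  std::string strat = as<std::string>(p["strategy"]);
  P.strategy = (strat == "nearest_depth") ? 1 : 0;
  std::string sr = as<std::string>(p["stop_rule"]);
  P.stop_rule = (sr == "threshold") ? 1 : 0;
  if (P.L_k < 1 || P.L_k > 31) stop("L_k out of range [1, 31]");
  if (P.min_ov < P.L_k) stop("min_ov must be >= L_k for complete hash lookup");
  return P;
}

struct Engine {
  std::vector<std::string> seqs;  // sorted lexicographically (table invariant)
  std::vector<int> freq;
  std::vector<double> mq;
  std::vector<char> used;
  Params P;
  std::unordered_map<uint64_t, std::vector<int> > fwd;

  uint64_t key_at(const char* p) const {
    uint64_t k = 0;
    for (int i = 0; i < P.L_k; ++i) {
      int c = base_code(p[i]);
      if (c < 0) return UINT64_MAX;
      k = (k << 2) | (uint64_t)c;
    }
    return k;
  }

  void build_index() {
    fwd.clear();
    fwd.reserve(seqs.size() * 2);
    for (size_t i = 0; i < seqs.size(); ++i) {
      uint64_t k = key_at(seqs[i].data());
      if (k != UINT64_MAX) fwd[k].push_back((int)i);
    }
  }

  // x[j-1] for j = 1..L_d with overlap t = max_ov - j + 1; exact verification
  // after hash lookup. cand[j-1] holds the matching unassembled entry ids.
  void profile(const std::string& contig, std::vector<double>& x,
               std::vector<std::vector<int> >& cand) const {
    x.assign(P.L_d, 0.0);
    cand.assign(P.L_d, std::vector<int>());
    int clen = (int)contig.size();
    int tmax = std::min(P.max_ov, clen);
    for (int t = tmax; t > P.min_ov; --t) {
      int j = P.max_ov - t + 1;
      if (j < 1 || j > P.L_d) continue;
      const char* suf = contig.data() + (clen - t);
      uint64_t k = key_at(suf);
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it = fwd.find(k);
      if (it == fwd.end()) continue;
      for (size_t q = 0; q < it->second.size(); ++q) {
        int id = it->second[q];
        if (used[id]) continue;
        if (std::memcmp(seqs[id].data(), suf, (size_t)t) == 0) {
          x[j - 1] += freq[id];
          cand[j - 1].push_back(id);
        }
      }
    }
  }

  // A read is extendable when its own 3' end overlaps at least one other
  // unassembled entry by >= min_ov bases.
  bool extendable(int id) const {
    const std::string& r = seqs[id];
    for (int t = P.max_ov; t >= P.min_ov; --t) {
      const char* suf = r.data() + (P.L_r - t);
      uint64_t k = key_at(suf);
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it = fwd.find(k);
      if (it == fwd.end()) continue;
      for (size_t q = 0; q < it->second.size(); ++q) {
        int id2 = it->second[q];
        if (id2 == id || used[id2]) continue;
        if (std::memcmp(seqs[id2].data(), suf, (size_t)t) == 0) return true;
      }
    }
    return false;
  }

  // Optimal-read choice; returns entry id (or -1) and writes its j.
  int choose(const std::vector<double>& x, std::vector<std::vector<int> >& cand,
             int* j_out) const {
    if (P.strategy == 0) {
      for (int j = 1; j <= P.L_d; ++j) {
        std::vector<int>& v = cand[j - 1];
        if (v.empty()) continue;
        std::sort(v.begin(), v.end(), [this](int a, int b) {
          if (freq[a] != freq[b]) return freq[a] > freq[b];
          return a < b;  // seqs sorted, so id order is lexicographic order
        });
        for (size_t q = 0; q < v.size(); ++q)
          if (extendable(v[q])) { *j_out = j; return v[q]; }
      }
      return -1;
    }
    // nearest_depth: candidate whose profile count is closest to S_d,
    // ties broken by longer overlap (smaller j), then frequency, then order.
    std::vector<std::pair<double, std::pair<int, int> > > all;  // (dist, (j, id))
    for (int j = 1; j <= P.L_d; ++j)
      for (size_t q = 0; q < cand[j - 1].size(); ++q)
        all.push_back(std::make_pair(std::fabs(x[j - 1] - P.S_d),
                                     std::make_pair(j, cand[j - 1][q])));
    std::sort(all.begin(), all.end(), [this](
        const std::pair<double, std::pair<int, int> >& a,
        const std::pair<double, std::pair<int, int> >& b) {
      if (a.first != b.first) return a.first < b.first;
      if (a.second.first != b.second.first) return a.second.first < b.second.first;
      int ia = a.second.second, ib = b.second.second;
      if (freq[ia] != freq[ib]) return freq[ia] > freq[ib];
      return ia < ib;
    });
    for (size_t q = 0; q < all.size(); ++q)
      if (extendable(all[q].second.second)) {
        *j_out = all[q].second.first;
        return all[q].second.second;
      }
    return -1;
  }

  // Extend one end of the working contig. Under the confidence stop rule a
  // one-sided CUSUM accumulates evidence against the pool hypothesis; on
  // detection the contig is trimmed back to the last in-control checkpoint
  // (the change-point estimate) and reads consumed past it are released.
  void extend_end(std::string& contig, bool is_repeat, std::vector<double>& mn,
                  std::vector<int>& consumed, std::string& reason) {
    double S = 0;
    size_t cp_len = contig.size(), cp_mn = mn.size(), cp_con = consumed.size();
    std::vector<double> x;
    std::vector<std::vector<int> > cand;
    long guard = 0, guard_max = (long)seqs.size() + 16;
    for (;;) {
      if (++guard > guard_max) { reason = "step_limit"; return; }
      profile(contig, x, cand);
      bool any = false;
      for (size_t q = 0; q < cand.size(); ++q)
        if (!cand[q].empty()) { any = true; break; }
      if (!any) { reason = "no_overlap"; return; }
      std::vector<double> y(x);
      smooth_vec(y, P.L_w, P.N_f);
      double m_y = 0;
      for (size_t q = 0; q < y.size(); ++q) m_y += y[q];
      m_y /= (double)y.size();
      if (P.stop_rule == 1) {
        bool go = is_repeat ? (m_y > P.T2) : (m_y < P.T1);
        if (!go) { reason = "boundary"; return; }
      } else {
        double dev = is_repeat ? (P.T2 - m_y) : (m_y - P.T1);
        S += dev;
        if (S < 0) S = 0;
        if (S > P.h) {
          contig.resize(cp_len);
          mn.resize(cp_mn);
          while (consumed.size() > cp_con) {
            used[consumed.back()] = 0;
            consumed.pop_back();
          }
          reason = "boundary";
          return;
        }
      }
      int j = 0;
      int id = choose(x, cand, &j);
      if (id < 0) { reason = "no_extendable"; return; }
      int t = P.max_ov - j + 1;
      contig.append(seqs[id], (size_t)t, (size_t)(P.L_r - t));
      mn.push_back(m_y);
      used[id] = 1;
      consumed.push_back(id);
      if (P.stop_rule == 0 && S == 0) {
        cp_len = contig.size();
        cp_mn = mn.size();
        cp_con = consumed.size();
      }
    }
  }

  // 3' extension, then 5' extension via reverse complement of the working
  // contig (single extension code path).
  void extend_full(int seed_id, bool is_repeat, std::string& contig,
                   std::vector<double>& mn, std::string& r3, std::string& r5) {
    used[seed_id] = 1;
    contig = seqs[seed_id];
    std::vector<int> consumed;
    extend_end(contig, is_repeat, mn, consumed, r3);
    contig = revcomp_one(contig);
    extend_end(contig, is_repeat, mn, consumed, r5);
    contig = revcomp_one(contig);
  }

  // After a contig is finished, every unique entry occurring as an L_r
  // substring of the contig (either orientation) is marked assembled so the
  // region cannot re-seed; other copies of an assembled repeat share these
  // entries and are retired with it.
  void consume_substrings(const std::string& contig) {
    int n = (int)contig.size();
    if (n < P.L_r) return;
    for (int o = 0; o < 2; ++o) {
      std::string s = o ? revcomp_one(contig) : contig;
      std::string w;
      for (int i = 0; i + P.L_r <= n; ++i) {
        w.assign(s, (size_t)i, (size_t)P.L_r);
        std::vector<std::string>::const_iterator it =
            std::lower_bound(seqs.begin(), seqs.end(), w);
        if (it != seqs.end() && *it == w) used[it - seqs.begin()] = 1;
      }
    }
  }
};

static Engine make_engine(CharacterVector sequences, IntegerVector frequency,
                          NumericVector mean_quality, LogicalVector assembled,
                          List params) {
  Engine E;
  E.P = read_params(params);
  R_xlen_t n = sequences.size();
  if (frequency.size() != n || assembled.size() != n || mean_quality.size() != n)
    stop("table column lengths differ");
  E.seqs.reserve(n);
  E.freq.assign(frequency.begin(), frequency.end());
  E.mq.assign(mean_quality.begin(), mean_quality.end());
  E.used.resize(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    E.seqs.push_back(as<std::string>(sequences[i]));
    if ((int)E.seqs.back().size() != E.P.L_r) stop("entry length differs from L_r");
    if (i > 0 && E.seqs[i] < E.seqs[i - 1]) stop("unique-read table must be sorted");
    E.used[i] = assembled[i] ? 1 : 0;
  }
  E.build_index();
  return E;
}

// [[Rcpp::export]]
NumericVector cpp_overlap_profile(CharacterVector sequences, IntegerVector frequency,
                                  NumericVector mean_quality, LogicalVector assembled,
                                  std::string contig, List params) {
  Engine E = make_engine(sequences, frequency, mean_quality, assembled, params);
  std::vector<double> x;
  std::vector<std::vector<int> > cand;
  E.profile(contig, x, cand);
  return NumericVector(x.begin(), x.end());
}

// [[Rcpp::export]]
List cpp_extend_contig(CharacterVector sequences, IntegerVector frequency,
                       NumericVector mean_quality, LogicalVector assembled,
                       int seed_index, bool is_repeat, List params) {
  Engine E = make_engine(sequences, frequency, mean_quality, assembled, params);
  if (seed_index < 1 || seed_index > (int)E.seqs.size()) stop("seed index out of range");
  std::string contig, r3, r5;
  std::vector<double> mn;
  E.extend_full(seed_index - 1, is_repeat, contig, mn, r3, r5);
  LogicalVector out_used(E.used.size());
  for (size_t i = 0; i < E.used.size(); ++i) out_used[i] = (E.used[i] != 0);
  return List::create(_["sequence"] = contig,
                      _["mn"] = NumericVector(mn.begin(), mn.end()),
                      _["stop3"] = r3, _["stop5"] = r5,
                      _["assembled"] = out_used);
}

// Full serial assembly: repeat pass (seeds with frequency > H_p, highest
// first) then nonrepeat pass (count_floor <= frequency <= L_p, lowest first);
// equal counts resolved by higher mean quality, then table order.
// [[Rcpp::export]]
List cpp_assemble(CharacterVector sequences, IntegerVector frequency,
                  NumericVector mean_quality, LogicalVector assembled,
                  List params) {
  Engine E = make_engine(sequences, frequency, mean_quality, assembled, params);
  int n = (int)E.seqs.size();
  std::vector<std::string> out_seq, out_class, out_seed, out_r3, out_r5;
  std::vector<std::vector<double> > out_mn;

  for (int pass = 0; pass < 2; ++pass) {
    bool is_repeat = (pass == 0);
    std::vector<int> order;
    for (int i = 0; i < n; ++i) {
      if (E.used[i]) continue;
      if (is_repeat) {
        if ((double)E.freq[i] > E.P.H_p) order.push_back(i);
      } else {
        if (E.freq[i] >= E.P.count_floor && (double)E.freq[i] <= E.P.L_p)
          order.push_back(i);
      }
    }
    std::stable_sort(order.begin(), order.end(), [&E, is_repeat](int a, int b) {
      if (E.freq[a] != E.freq[b])
        return is_repeat ? (E.freq[a] > E.freq[b]) : (E.freq[a] < E.freq[b]);
      if (E.mq[a] != E.mq[b]) return E.mq[a] > E.mq[b];
      return a < b;
    });
    for (size_t k = 0; k < order.size(); ++k) {
      int sid = order[k];
      if (E.used[sid]) continue;
      std::string contig, r3, r5;
      std::vector<double> mn;
      E.extend_full(sid, is_repeat, contig, mn, r3, r5);
      E.consume_substrings(contig);
      out_seq.push_back(contig);
      out_class.push_back(is_repeat ? "repeat" : "nonrepeat");
      out_seed.push_back(E.seqs[sid]);
      out_r3.push_back(r3);
      out_r5.push_back(r5);
      out_mn.push_back(mn);
      if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
    }
  }

  size_t m = out_seq.size();
  CharacterVector rs(m), rc(m), rseed(m), rr3(m), rr5(m);
  List rmn(m);
  for (size_t i = 0; i < m; ++i) {
    rs[i] = out_seq[i];
    rc[i] = out_class[i];
    rseed[i] = out_seed[i];
    rr3[i] = out_r3[i];
    rr5[i] = out_r5[i];
    rmn[i] = NumericVector(out_mn[i].begin(), out_mn[i].end());
  }
  LogicalVector out_used(n);
  for (int i = 0; i < n; ++i) out_used[i] = (E.used[i] != 0);
  return List::create(_["sequence"] = rs, _["contig_class"] = rc,
                      _["seed"] = rseed, _["stop3"] = rr3, _["stop5"] = rr5,
                      _["mn"] = rmn, _["assembled"] = out_used);
}
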