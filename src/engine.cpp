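// Core engines: gap-free overlap scan with ratio scoring and acceptance
// gates, Phred-aware consensus, canonical k-mer counting with greedy tail
// extension, and simulator inner loops. All randomness goes through R's RNG
// so results are reproducible from set.seed().

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <string>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- utilities

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'N': return 'N';
    default: return 0; // signals illegal character
  }
}

static std::string revcomp_str(const std::string& s) {
  const size_t n = s.size();
  std::string out(n, 'N');
  for (size_t i = 0; i < n; ++i) {
    char c = comp_base(s[n - 1 - i]);
    if (c == 0)
      stop("illegal base '%s' at position %d", std::string(1, s[n - 1 - i]),
           (int)(n - i));
    out[i] = c;
  }
  return out;
}

// Phred -> error probability lookup
static double phred_p(int q) {
  if (q < 0) q = 0;
  if (q > 93) q = 93;
  static double tab[94];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 94; ++i) tab[i] = std::pow(10.0, -i / 10.0);
    init = true;
  }
  return tab[q];
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = revcomp_str(std::string(seqs[i]));
  return out;
}

// ------------------------------------------------------------- profile

struct Prof {
  double c0, c1, c2, c3, c5, c6_prob;
  int c4, c6_insert;
  bool flat_confirm, flat_rescue, ouq;
  int qcap;
  double v_max, h_thresh, adapter_frac;
};

static Prof parse_profile(const List& p) {
  Prof pr;
  pr.c0 = as<double>(p["c0"]);
  pr.c1 = as<double>(p["c1"]);
  pr.c2 = as<double>(p["c2"]);
  pr.c3 = as<double>(p["c3"]);
  pr.c4 = as<int>(p["c4"]);
  pr.c5 = as<double>(p["c5"]);
  pr.c6_insert = as<int>(p["c6_insert"]);
  pr.c6_prob = as<double>(p["c6_prob"]);
  pr.flat_confirm = as<bool>(p["use_flat_confirm"]);
  pr.flat_rescue = as<bool>(p["use_flat_rescue"]);
  pr.ouq = as<bool>(p["ouq"]);
  pr.qcap = as<int>(p["qcap"]);
  pr.v_max = as<double>(p["v_max"]);
  pr.h_thresh = as<double>(p["h_thresh"]);
  pr.adapter_frac = as<double>(p["adapter_mismatch_frac"]);
  return pr;
}

// ------------------------------------------------- sequence complexity gate

// Shannon entropy (bits) of the dinucleotide composition of a pair;
// invariant under reverse complement.
static double dinuc_entropy(const std::string& a, const std::string& b) {
  int counts[16] = {0};
  long total = 0;
  const std::string* seqs[2] = {&a, &b};
  for (int s = 0; s < 2; ++s) {
    const std::string& x = *seqs[s];
    int prev = -1;
    for (size_t i = 0; i < x.size(); ++i) {
      int code;
      switch (x[i]) {
        case 'A': code = 0; break; case 'C': code = 1; break;
        case 'G': code = 2; break; case 'T': code = 3; break;
        default: code = -1;
      }
      if (prev >= 0 && code >= 0) { counts[prev * 4 + code]++; total++; }
      prev = code;
    }
  }
  if (total == 0) return 0.0;
  double h = 0.0;
  for (int i = 0; i < 16; ++i) {
    if (counts[i] > 0) {
      double f = (double)counts[i] / (double)total;
      h -= f * std::log2(f);
    }
  }
  return h;
}

static int complexity_v(const std::string& a, const std::string& b,
                        double v_max, double h_thresh) {
  double h = dinuc_entropy(a, b);
  return (int)std::floor(v_max * std::max(0.0, 1.0 - h / h_thresh));
}

// [[Rcpp::export]]
int cpp_complexity_v(std::string s1, std::string s2, double v_max,
                     double h_thresh) {
  return complexity_v(s1, s2, v_max, h_thresh);
}

// ----------------------------------------------------------- overlap scan

// Match/mismatch counts for one candidate insert size. Positions involving N
// contribute to neither count. With ouq, counts become quality-derived
// weights (match: 1 - p1 - p2; mismatch: 1 - p1*p2; both floored at 0.1).
static inline void count_overlap(const std::string& s1, const int* q1, int L1,
                                 const std::string& s2rc, const int* q2rc,
                                 int L2, int S, bool ouq, double& G,
                                 double& B) {
  G = 0.0; B = 0.0;
  const int off = S - L2;
  int j0 = off > 0 ? off : 0;
  int j1 = S < L1 ? S : L1;
  for (int j = j0; j < j1; ++j) {
    const char c1 = s1[j], c2 = s2rc[j - off];
    if (c1 == 'N' || c2 == 'N') continue;
    if (ouq) {
      const double p1 = phred_p(q1[j]), p2 = phred_p(q2rc[j - off]);
      if (c1 == c2) G += std::max(0.1, 1.0 - p1 - p2);
      else          B += std::max(0.1, 1.0 - p1 * p2);
    } else {
      if (c1 == c2) G += 1.0; else B += 1.0;
    }
  }
}

// Expected mismatches in the overlap at insert size S:
//   E = sum over compared positions of p1 + p2 - (4/3) p1 p2.
static double expected_mismatches(const int* q1, int L1, const int* q2rc,
                                  int L2, int S, const std::string& s1,
                                  const std::string& s2rc) {
  const int off = S - L2;
  int j0 = off > 0 ? off : 0;
  int j1 = S < L1 ? S : L1;
  double e = 0.0;
  for (int j = j0; j < j1; ++j) {
    if (s1[j] == 'N' || s2rc[j - off] == 'N') continue;
    const double p1 = phred_p(q1[j]), p2 = phred_p(q2rc[j - off]);
    e += p1 + p2 - (4.0 / 3.0) * p1 * p2;
  }
  return e;
}

// Binomial upper tail P(X >= b), X ~ Bin(w, r), in log space.
static double binom_upper_tail(int w, int b, double r) {
  if (b <= 0) return 1.0;
  if (b > w) return 0.0;
  if (r < 1e-12) r = 1e-12;
  if (r > 1.0 - 1e-12) r = 1.0 - 1e-12;
  const double lr = std::log(r), lq = std::log1p(-r);
  double p = 0.0;
  for (int k = b; k <= w; ++k)
    p += std::exp(R::lchoose((double)w, (double)k) + k * lr + (w - k) * lq);
  return p > 1.0 ? 1.0 : p;
}

// Status codes (kept in step with status_levels() on the R side)
enum Status {
  ST_MERGED = 0, ST_NO_OVERLAP = 1, ST_AMBIGUOUS = 2, ST_TOO_SHORT_OVERLAP = 3,
  ST_TOO_SHORT_INSERT = 4, ST_ADAPTER_MISMATCH = 5, ST_TOO_MANY_MISMATCHES = 6,
  ST_IMPROBABLE_PATTERN = 7, ST_KFILTER_FAIL = 8
};

struct OvlResult {
  int status;
  int S, W;             // accepted candidate (valid when S > 0)
  double G, B, R1, R2, E, P;
  int V;
  bool from_flat;
};

// Full decision for one pair: candidate scan, ratio gates, flat-mode
// confirm/rescue, adapter gate, expected-mismatch gate, pattern-probability
// gate — first failure wins.
static OvlResult find_overlap_one(const std::string& s1,
                                  const std::vector<int>& q1,
                                  const std::string& s2rc,
                                  const std::vector<int>& q2rc,
                                  const std::string& s2orig,
                                  const Prof& pr, const std::string& a1,
                                  const std::string& a2, bool use_adapters) {
  OvlResult res;
  res.status = ST_NO_OVERLAP;
  res.S = NA_INTEGER; res.W = 0;
  res.G = res.B = 0.0;
  res.R1 = res.R2 = res.E = res.P = NA_REAL;
  res.from_flat = false;

  const int L1 = (int)s1.size(), L2 = (int)s2rc.size();
  res.V = complexity_v(s1, s2rc, pr.v_max, pr.h_thresh);
  const double gmin = std::max((double)pr.c4, (double)res.V);

  int bestS = -1;
  double bestG = 0, bestB = 0, R1 = R_PosInf, R2 = R_PosInf;
  int flatS = -1;
  double flatG = 0, flatB = R_PosInf;

  for (int S = pr.c6_insert; S <= L1 + L2 - 1; ++S) {
    double G, B;
    count_overlap(s1, q1.data(), L1, s2rc, q2rc.data(), L2, S, pr.ouq, G, B);
    if (G + B <= 0.0) continue;
    const double R = (B + pr.c0) / (B + G);
    if (R < R1) {           // strict <: ties keep the smaller S seen first
      R2 = R1; R1 = R; bestS = S; bestG = G; bestB = B;
    } else if (R < R2) {
      R2 = R;
    }
    if (G >= gmin && B < flatB) { flatB = B; flatS = S; flatG = G; }
  }

  if (bestS < 0) return res;  // no candidate at all
  res.R1 = R1; res.R2 = R2;

  // ratio-mode gates, in order
  int status = ST_MERGED;
  if (R1 > pr.c1) status = ST_NO_OVERLAP;
  else if (R1 * pr.c2 > R2) status = ST_AMBIGUOUS;
  else if (R2 < pr.c3) status = ST_AMBIGUOUS;
  else if (bestG < gmin) status = ST_TOO_SHORT_OVERLAP;
  else if (bestS < pr.c6_insert) status = ST_TOO_SHORT_INSERT;

  // flat-mode confirmation (xstrict/ustrict) and rescue (xloose)
  if (status == ST_MERGED && pr.flat_confirm &&
      (flatS < 0 || flatS != bestS)) {
    status = ST_AMBIGUOUS;
  }
  int accS = bestS;
  double accG = bestG, accB = bestB;
  if (status != ST_MERGED && pr.flat_rescue && flatS >= 0) {
    accS = flatS; accG = flatG; accB = flatB;
    res.from_flat = true;
    status = ST_MERGED;
  }

  res.S = accS;
  res.W = std::min(L1, accS) + std::min(L2, accS) - accS;
  res.G = accG; res.B = accB;

  if (status != ST_MERGED) { res.status = status; return res; }

  // 7a: adapter check on read-through overhangs
  if (use_adapters && accS < std::max(L1, L2)) {
    const std::string* reads[2] = {&s1, &s2orig};
    const std::string* adps[2] = {&a1, &a2};
    for (int side = 0; side < 2; ++side) {
      const std::string& rd = *reads[side];
      const std::string& ad = *adps[side];
      if (ad.empty()) continue;
      const int over = (int)rd.size() - accS;
      const int n = std::min(over, (int)ad.size());
      if (n <= 0) continue;
      int mm = 0;
      for (int t = 0; t < n; ++t) {
        const char c = rd[accS + t], a = ad[t];
        if (c != 'N' && a != 'N' && c != a) mm++;
      }
      if ((double)mm / (double)n > pr.adapter_frac) {
        res.status = ST_ADAPTER_MISMATCH;
        return res;
      }
    }
  }

  // 7b: expected-mismatch gate
  res.E = expected_mismatches(q1.data(), L1, q2rc.data(), L2, accS, s1, s2rc);
  if (accB > res.E * pr.c5) { res.status = ST_TOO_MANY_MISMATCHES; return res; }

  // 7c: pattern-probability gate (binomial upper tail at rate E/W)
  {
    const double r = res.W > 0 ? res.E / (double)res.W : 0.0;
    const int b_int = (int)std::ceil(accB - 1e-9);
    res.P = binom_upper_tail(res.W, b_int, r);
    if (res.P < pr.c6_prob) { res.status = ST_IMPROBABLE_PATTERN; return res; }
  }

  res.status = ST_MERGED;
  return res;
}

// ------------------------------------------------------------- consensus

static inline void consensus_base_cpp(char b1, int q1, char b2, int q2,
                                      int qcap, char& b, int& q) {
  if (b1 == 'N' && b2 == 'N') { b = 'N'; q = 0; return; }
  if (b1 == 'N') { b = b2; q = q2; return; }
  if (b2 == 'N') { b = b1; q = q1; return; }
  if (b1 == b2) { b = b1; q = std::min(q1 + q2, qcap); return; }
  if (q1 == q2) { b = 'N'; q = 0; return; }
  if (q1 > q2) { b = b1; q = q1 - q2; } else { b = b2; q = q2 - q1; }
}

// Build the merged read of length S. Positions covered by both reads get the
// consensus; by one read, that read's base; by neither (REM rescue with
// S > L1+L2), the k-mer-extension base at quality qext, else N/0.
static void build_merged(const std::string& s1, const std::vector<int>& q1,
                         const std::string& s2rc, const std::vector<int>& q2rc,
                         int S, int qcap, const std::string& ext1,
                         const std::string& ext2rc, int qext,
                         std::string& mseq, std::vector<int>& mqual) {
  const int L1 = (int)s1.size(), L2 = (int)s2rc.size();
  mseq.assign(S, 'N');
  mqual.assign(S, 0);
  const int off = S - L2;              // start of r2rc in merged coordinates
  const int e2 = (int)ext2rc.size();   // rc'd r2 extension sits at off-e2..off-1
  for (int i = 0; i < S; ++i) {
    const bool has1 = i < L1;
    const bool has2 = i >= off;
    if (has1 && has2) {
      char b; int q;
      consensus_base_cpp(s1[i], q1[i], s2rc[i - off], q2rc[i - off], qcap, b, q);
      mseq[i] = b; mqual[i] = q;
    } else if (has1) {
      mseq[i] = s1[i]; mqual[i] = q1[i];
    } else if (has2) {
      mseq[i] = s2rc[i - off]; mqual[i] = q2rc[i - off];
    } else if (i - L1 < (int)ext1.size()) {
      mseq[i] = ext1[i - L1]; mqual[i] = qext;
    } else if (i >= off - e2) {
      mseq[i] = ext2rc[i - (off - e2)]; mqual[i] = qext;
    }
  }
}

// [[Rcpp::export]]
List cpp_consensus_merge(std::string s1, IntegerVector q1, std::string s2rc,
                         IntegerVector q2rc, int S, int qcap) {
  const int L1 = (int)s1.size(), L2 = (int)s2rc.size();
  if (S < 1 || S > L1 + L2 - 1)
    stop("insert size %d outside [1, %d]", S, L1 + L2 - 1);
  std::vector<int> v1(q1.begin(), q1.end()), v2(q2rc.begin(), q2rc.end());
  std::string mseq;
  std::vector<int> mqual;
  build_merged(s1, v1, s2rc, v2, S, qcap, "", "", 0, mseq, mqual);
  return List::create(_["seq"] = mseq, _["qual"] = wrap(mqual));
}

// ------------------------------------------------------- exported overlap API

// [[Rcpp::export]]
DataFrame cpp_enumerate_candidates(std::string s1, IntegerVector q1,
                                   std::string s2rc, IntegerVector q2rc,
                                   double c0, int min_insert, bool ouq) {
  const int L1 = (int)s1.size(), L2 = (int)s2rc.size();
  std::vector<int> v1(q1.begin(), q1.end()), v2(q2rc.begin(), q2rc.end());
  std::vector<int> Ss, Ws;
  std::vector<double> Gs, Bs, Rs;
  for (int S = min_insert; S <= L1 + L2 - 1; ++S) {
    double G, B;
    count_overlap(s1, v1.data(), L1, s2rc, v2.data(), L2, S, ouq, G, B);
    if (G + B <= 0.0) continue;
    Ss.push_back(S);
    Ws.push_back(std::min(L1, S) + std::min(L2, S) - S);
    Gs.push_back(G); Bs.push_back(B);
    Rs.push_back((B + c0) / (B + G));
  }
  return DataFrame::create(_["S"] = Ss, _["W"] = Ws, _["G"] = Gs,
                           _["B"] = Bs, _["R"] = Rs);
}

static List ovl_to_list(const OvlResult& r) {
  return List::create(
      _["status"] = r.status, _["S"] = r.S, _["W"] = r.W, _["G"] = r.G,
      _["B"] = r.B, _["R1"] = r.R1, _["R2"] = r.R2, _["E"] = r.E,
      _["P"] = r.P, _["V"] = r.V, _["from_flat"] = r.from_flat);
}

// [[Rcpp::export]]
List cpp_find_overlap(std::string s1, IntegerVector q1, std::string s2,
                      IntegerVector q2, List profile, std::string adapter1,
                      std::string adapter2, bool use_adapters) {
  Prof pr = parse_profile(profile);
  std::string s2rc = revcomp_str(s2);
  std::vector<int> v1(q1.begin(), q1.end());
  std::vector<int> v2(q2.begin(), q2.end());
  std::reverse(v2.begin(), v2.end());
  OvlResult r = find_overlap_one(s1, v1, s2rc, v2, s2, pr, adapter1, adapter2,
                                 use_adapters);
  return ovl_to_list(r);
}

// ----------------------------------------------------------- k-mer table

struct KmerTable {
  int k;
  std::unordered_map<uint64_t, int32_t> counts;
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// encode fwd/rc rolling k-mers; returns false if any N in window
static bool encode_kmer(const std::string& s, int pos, int k, uint64_t& fwd,
                        uint64_t& rc) {
  fwd = 0; rc = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    fwd = (fwd << 2) | (uint64_t)c;
    rc |= ((uint64_t)(3 - c)) << (2 * i);
  }
  return true;
}

static inline uint64_t canonical(uint64_t fwd, uint64_t rc) {
  return fwd < rc ? fwd : rc;
}

static int32_t table_get(const KmerTable& t, uint64_t key) {
  auto it = t.counts.find(key);
  return it == t.counts.end() ? 0 : it->second;
}

static void count_seq(KmerTable& t, const std::string& s) {
  const int k = t.k;
  const int L = (int)s.size();
  if (L < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;  // number of consecutive non-N bases ending here
  for (int i = 0; i < L; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
    valid++;
    if (valid >= k) t.counts[canonical(fwd, rc)]++;
  }
}

// [[Rcpp::export]]
SEXP cpp_kmer_build(CharacterVector seqs, int k) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be odd and in [3, 31]");
  XPtr<KmerTable> ptr(new KmerTable(), true);
  ptr->k = k;
  for (int i = 0; i < seqs.size(); ++i)
    count_seq(*ptr, std::string(seqs[i]));
  return ptr;
}

// [[Rcpp::export]]
void cpp_kmer_accumulate(SEXP tab, CharacterVector seqs) {
  XPtr<KmerTable> t(tab);
  for (int i = 0; i < seqs.size(); ++i)
    count_seq(*t, std::string(seqs[i]));
}

// [[Rcpp::export]]
List cpp_kmer_stats(SEXP tab) {
  XPtr<KmerTable> t(tab);
  double total = 0;
  for (auto& kv : t->counts) total += kv.second;
  return List::create(_["k"] = t->k,
                      _["n_distinct"] = (double)t->counts.size(),
                      _["total"] = total);
}

// [[Rcpp::export]]
double cpp_kmer_get(SEXP tab, std::string kmer) {
  XPtr<KmerTable> t(tab);
  if ((int)kmer.size() != t->k) stop("k-mer length must equal table k");
  uint64_t fwd, rc;
  if (!encode_kmer(kmer, 0, t->k, fwd, rc)) return 0;
  return table_get(*t, canonical(fwd, rc));
}

// Stop reasons (kept in step with extend_tail() on the R side)
enum StopReason { SR_MAX_LENGTH = 0, SR_BRANCH = 1, SR_LOW_DEPTH = 2,
                  SR_NO_SEED = 3 };

// Greedy tail extension: from the terminal k-mer, append the unique
// sufficiently-deep successor base; stop at branches, depth dropouts, or
// the requested length.
static void extend_tail_core(const KmerTable& t, const std::string& seq,
                             int max_ext, int min_depth, std::string& added,
                             int& reason) {
  added.clear();
  const int k = t.k;
  const int L = (int)seq.size();
  if (L < k) { reason = SR_NO_SEED; return; }
  uint64_t fwd, rc;
  if (!encode_kmer(seq, L - k, k, fwd, rc)) { reason = SR_NO_SEED; return; }
  if (table_get(t, canonical(fwd, rc)) == 0) { reason = SR_NO_SEED; return; }
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  reason = SR_MAX_LENGTH;
  for (int e = 0; e < max_ext; ++e) {
    int32_t cnt[4];
    int best = -1, second = -1;
    for (int b = 0; b < 4; ++b) {
      uint64_t nf = ((fwd << 2) | (uint64_t)b) & mask;
      uint64_t nr = (rc >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
      cnt[b] = table_get(t, canonical(nf, nr));
      if (best < 0 || cnt[b] > cnt[best]) { second = best; best = b; }
      else if (second < 0 || cnt[b] > cnt[second]) second = b;
    }
    if (cnt[best] < min_depth) { reason = SR_LOW_DEPTH; return; }
    if ((double)cnt[second] >= std::max(2.0, (double)cnt[best] / 8.0)) {
      reason = SR_BRANCH; return;
    }
    added.push_back(bases[best]);
    fwd = ((fwd << 2) | (uint64_t)best) & mask;
    rc = (rc >> 2) | (((uint64_t)(3 - best)) << (2 * (k - 1)));
  }
}

// [[Rcpp::export]]
List cpp_extend_tail(SEXP tab, std::string seq, int max_ext, int min_depth) {
  XPtr<KmerTable> t(tab);
  std::string added;
  int reason;
  extend_tail_core(*t, seq, max_ext, min_depth, added, reason);
  return List::create(_["added"] = added, _["stop_reason"] = reason);
}

// [[Rcpp::export]]
LogicalVector cpp_kfilter(SEXP tab, CharacterVector seqs, int min_depth) {
  XPtr<KmerTable> t(tab);
  const int k = t->k;
  LogicalVector pass(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = std::string(seqs[i]);
    bool ok = true;
    const int L = (int)s.size();
    if (L >= k) {
      const uint64_t mask = (1ULL << (2 * k)) - 1;
      uint64_t fwd = 0, rc = 0;
      int valid = 0;
      for (int j = 0; j < L && ok; ++j) {
        int c = base_code(s[j]);
        if (c < 0) { valid = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rc = (rc >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
        valid++;
        if (valid >= k && table_get(*t, canonical(fwd, rc)) < min_depth)
          ok = false;
      }
    }
    pass[i] = ok;
  }
  return pass;
}

// --------------------------------------------------------------- batch merge

// Merge a batch of pairs. mode: 0 = overlap only, 1 = REM, 2 = RSEM.
// For REM/RSEM, `tab` must be a k-mer table built from the same reads.
// [[Rcpp::export]]
List cpp_merge_batch(CharacterVector s1v, List q1v, CharacterVector s2v,
                     List q2v, List profile, std::string adapter1,
                     std::string adapter2, int mode, SEXP tab, int max_ext,
                     int min_depth, int kfilter_depth, int qext,
                     bool build_reads) {
  Prof pr = parse_profile(profile);
  const bool use_adapters = !adapter1.empty() || !adapter2.empty();
  const int n = s1v.size();
  const bool kmer_mode = mode > 0;
  KmerTable* t = NULL;
  if ((kmer_mode || kfilter_depth > 0)) {
    if (Rf_isNull(tab)) stop("k-mer table required for this mode");
    XPtr<KmerTable> tp(tab);
    t = tp.get();
  }

  IntegerVector status(n), insert(n, NA_INTEGER);
  NumericVector R1(n, NA_REAL);
  CharacterVector mseq(n);
  List mqual(n);

  for (int i = 0; i < n; ++i) {
    std::string s1 = std::string(s1v[i]);
    std::string s2 = std::string(s2v[i]);
    IntegerVector q1r = q1v[i], q2r = q2v[i];
    std::vector<int> q1(q1r.begin(), q1r.end());
    std::vector<int> q2rc(q2r.begin(), q2r.end());
    std::reverse(q2rc.begin(), q2rc.end());
    std::string s2rc = revcomp_str(s2);

    OvlResult d0 = find_overlap_one(s1, q1, s2rc, q2rc, s2, pr, adapter1,
                                    adapter2, use_adapters);
    OvlResult acc = d0;
    std::string ext1, ext2;

    if (kmer_mode) {
      int reason1, reason2;
      extend_tail_core(*t, s1, max_ext, min_depth, ext1, reason1);
      extend_tail_core(*t, s2, max_ext, min_depth, ext2, reason2);
      if (!ext1.empty() || !ext2.empty()) {
        // evaluate the extended pair; tail extensions keep read starts fixed,
        // so its insert size is directly comparable to d0's
        std::string s1x = s1 + ext1;
        std::string s2x = s2 + ext2;
        std::vector<int> q1x(q1);
        q1x.insert(q1x.end(), ext1.size(), qext);
        std::vector<int> q2x(q2r.begin(), q2r.end());
        q2x.insert(q2x.end(), ext2.size(), qext);
        std::vector<int> q2xrc(q2x.begin(), q2x.end());
        std::reverse(q2xrc.begin(), q2xrc.end());
        std::string s2xrc = revcomp_str(s2x);
        OvlResult d1 = find_overlap_one(s1x, q1x, s2xrc, q2xrc, s2x, pr,
                                        "", "", false);
        const bool ok0 = d0.status == ST_MERGED;
        const bool ok1 = d1.status == ST_MERGED;
        if (mode == 1) {                       // REM
          if (!ok1) acc = d0;
          else if (ok0 && d0.S == d1.S) acc = d0;
          else if (!ok0) acc = d1;
          else { acc = d0; acc.status = ST_AMBIGUOUS; }  // S0 != S1
        } else {                               // RSEM
          if (ok0 && ok1 && d0.S == d1.S) acc = d0;
          else if (ok0) { acc = d0; acc.status = ST_AMBIGUOUS; }
          else acc = d0;
        }
      }
    }

    if (acc.status == ST_MERGED) {
      std::string ms;
      std::vector<int> mq;
      build_merged(s1, q1, s2rc, q2rc, acc.S, pr.qcap, ext1,
                   ext2.empty() ? std::string() : revcomp_str(ext2), qext,
                   ms, mq);
      if (kfilter_depth > 0) {
        // reject merges containing k-mers unseen at the required depth
        bool ok = true;
        const int k = t->k;
        const int L = (int)ms.size();
        if (L >= k) {
          const uint64_t mask = (1ULL << (2 * k)) - 1;
          uint64_t fwd = 0, rc = 0;
          int valid = 0;
          for (int j = 0; j < L && ok; ++j) {
            int c = base_code(ms[j]);
            if (c < 0) { valid = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)c) & mask;
            rc = (rc >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
            valid++;
            if (valid >= k && table_get(*t, canonical(fwd, rc)) < kfilter_depth)
              ok = false;
          }
        }
        if (!ok) acc.status = ST_KFILTER_FAIL;
      }
      if (acc.status == ST_MERGED && build_reads) {
        mseq[i] = ms;
        mqual[i] = wrap(mq);
      }
    }

    status[i] = acc.status;
    if (acc.status == ST_MERGED) insert[i] = acc.S;
    R1[i] = acc.R1;
  }

  return List::create(_["status"] = status, _["insert"] = insert,
                      _["R1"] = R1, _["seq"] = mseq, _["qual"] = mqual);
}

// ------------------------------------------------------------ quality codec

// [[Rcpp::export]]
List cpp_decode_qual(CharacterVector lines, int offset, int qmax) {
  const int n = lines.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = std::string(lines[i]);
    IntegerVector q(s.size());
    for (size_t j = 0; j < s.size(); ++j) {
      int v = (int)(unsigned char)s[j] - offset;
      if (v < 0) v = 0;
      if (v > qmax) v = qmax;
      q[j] = v;
    }
    out[i] = q;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_encode_qual(List quals, int offset) {
  const int n = quals.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector q = quals[i];
    std::string s(q.size(), '!');
    for (int j = 0; j < q.size(); ++j) {
      int v = q[j] + offset;
      if (v < 33 || v > 126)
        stop("quality %d not encodable at offset %d", (int)q[j], offset);
      s[j] = (char)v;
    }
    out[i] = s;
  }
  return out;
}

// ------------------------------------------------------------- simulator

// [[Rcpp::export]]
std::string cpp_random_genome(int n, double gc) {
  std::string s(n, 'A');
  const double half_gc = gc / 2.0, half_at = (1.0 - gc) / 2.0;
  for (int i = 0; i < n; ++i) {
    const double u = R::unif_rand();
    if (u < half_gc) s[i] = 'G';
    else if (u < gc) s[i] = 'C';
    else if (u < gc + half_at) s[i] = 'A';
    else s[i] = 'T';
  }
  return s;
}

// Substitute each base with probability 10^(-Q/10), uniformly among the
// other three bases; N bases are left untouched.
// [[Rcpp::export]]
CharacterVector cpp_apply_errors(CharacterVector seqs, List quals) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = std::string(seqs[i]);
    IntegerVector q = quals[i];
    if ((int)s.size() != q.size())
      stop("sequence/quality length mismatch in read %d", i + 1);
    for (size_t j = 0; j < s.size(); ++j) {
      if (s[j] == 'N') continue;
      if (R::unif_rand() < phred_p(q[j])) {
        const int cur = base_code(s[j]);
        int sub = (int)(R::unif_rand() * 3.0);
        if (sub > 2) sub = 2;
        sub = (cur + 1 + sub) % 4;  // uniform over the other three
        s[j] = bases[sub];
      }
    }
    out[i] = s;
  }
  return out;
}
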