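#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Low-level sequence kernels. Sequences arrive as upper-case character
// strings over {A,C,G,T,N}; anything other than A/C/G/T is treated as
// ambiguous and excluded from k-mer space.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j)
      r[s.size() - 1 - j] = comp_base(s[j]);
    out[i] = r;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}

static inline std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t j = 0; j < s.size(); ++j)
    r[s.size() - 1 - j] = comp_base(s[j]);
  return r;
}

// canonical form: lexicographic min of a k-mer and its reverse complement
static inline std::string canonical_kmer(const std::string& km) {
  std::string rc = revcomp_str(km);
  return (rc < km) ? rc : km;
}

static bool kmer_clean(const char* p, int k) {
  for (int j = 0; j < k; ++j)
    if (base2bits(p[j]) < 0) return false;
  return true;
}

// Canonical k-mer counts over a set of sequences. K-mers containing
// non-ACGT characters are skipped entirely.
// [[Rcpp::export]]
DataFrame cpp_kmer_counts(CharacterVector seqs, int k) {
  std::unordered_map<std::string, double> counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + (size_t)k <= s.size(); ++p) {
      if (!kmer_clean(s.c_str() + p, k)) continue;
      counts[canonical_kmer(s.substr(p, k))] += 1.0;
    }
  }
  CharacterVector kmers(counts.size());
  NumericVector cnt(counts.size());
  R_xlen_t i = 0;
  for (auto& kv : counts) {
    kmers[i] = kv.first;
    cnt[i] = kv.second;
    ++i;
  }
  return DataFrame::create(_["kmer"] = kmers, _["count"] = cnt,
                           _["stringsAsFactors"] = false);
}

// Positions covered by at least one genome-wide-unique k-mer window
// (canonical counting). Returns covered and the non-N denominator;
// records shorter than k contribute to neither.
// [[Rcpp::export]]
List cpp_unique_coverage(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> counts;  // capped at 2
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + (size_t)k <= s.size(); ++p) {
      if (!kmer_clean(s.c_str() + p, k)) continue;
      auto it = counts.find(canonical_kmer(s.substr(p, k)));
      if (it == counts.end())
        counts[canonical_kmer(s.substr(p, k))] = 1;
      else if (it->second < 2)
        it->second = 2;
    }
  }
  double covered = 0.0, denom = 0.0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    size_t L = s.size();
    if ((int)L < k) continue;
    std::vector<int> cov(L, 0);
    for (size_t p = 0; p + (size_t)k <= L; ++p) {
      if (!kmer_clean(s.c_str() + p, k)) continue;
      auto it = counts.find(canonical_kmer(s.substr(p, k)));
      if (it != counts.end() && it->second == 1) {
        // mark window via difference trick
        cov[p] += 1;
        if (p + k < L) cov[p + k] -= 1;
      }
    }
    int open = 0;
    for (size_t p = 0; p < L; ++p) {
      open += cov[p];
      if (base2bits(s[p]) >= 0) {
        denom += 1.0;
        if (open > 0) covered += 1.0;
      }
    }
  }
  return List::create(_["covered"] = covered, _["denom"] = denom);
}

// Exact k-mer anchor hits between query and reference assemblies.
// The reference is indexed by forward-strand packed k-mers (k <= 32);
// k-mers whose occurrence count exceeds max_occ are masked, mimicking
// aligner repeat masking. Returned positions are 0-based; strand is
// +1 / -1 relative to the forward reference strand, with q_pos given
// on the (possibly reverse-complemented) query frame used for chaining.
// [[Rcpp::export]]
DataFrame cpp_anchor_hits(CharacterVector qseqs, CharacterVector rseqs,
                          int k, int max_occ, bool skip_same_idx) {
  if (k < 1 || k > 32) stop("anchor k must be in 1..32");
  typedef std::pair<int, int> RefPos;  // (record idx, pos)
  std::unordered_map<uint64_t, std::vector<RefPos> > index;
  std::unordered_map<uint64_t, bool> masked;

  for (R_xlen_t ri = 0; ri < rseqs.size(); ++ri) {
    std::string s = as<std::string>(rseqs[ri]);
    if ((int)s.size() < k) continue;
    uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base2bits(s[p]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run < k) continue;
      uint64_t kk = key;
      if (masked.count(kk)) continue;
      auto& v = index[kk];
      if ((int)v.size() >= max_occ) {
        masked[kk] = true;
        std::vector<RefPos>().swap(v);
        index.erase(kk);
        continue;
      }
      v.push_back(RefPos((int)ri, (int)(p - k + 1)));
    }
  }

  std::vector<int> q_idx, q_pos, r_idx, r_pos, strand;
  for (R_xlen_t qi = 0; qi < qseqs.size(); ++qi) {
    std::string s = as<std::string>(qseqs[qi]);
    if ((int)s.size() < k) continue;
    std::string rc = revcomp_str(s);
    for (int pass = 0; pass < 2; ++pass) {
      const std::string& q = (pass == 0) ? s : rc;
      int str = (pass == 0) ? 1 : -1;
      uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
      int run = 0;
      for (size_t p = 0; p < q.size(); ++p) {
        int b = base2bits(q[p]);
        if (b < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run < k) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        int qp = (int)(p - k + 1);
        for (auto& rp : it->second) {
          if (skip_same_idx && rp.first == (int)qi) continue;
          q_idx.push_back((int)qi);
          q_pos.push_back(qp);
          r_idx.push_back(rp.first);
          r_pos.push_back(rp.second);
          strand.push_back(str);
        }
      }
    }
  }
  return DataFrame::create(_["q_idx"] = q_idx, _["q_pos"] = q_pos,
                           _["r_idx"] = r_idx, _["r_pos"] = r_pos,
                           _["strand"] = strand);
}

// Mismatch count between equal-length strings.
// [[Rcpp::export]]
int cpp_count_mismatches(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) ++mm;
  return mm;
}

// Greedy exact extension: number of consecutive matching characters
// starting at (q_from, r_from) (0-based) moving in direction dir (+1/-1).
// [[Rcpp::export]]
int cpp_extend_match(std::string q, std::string r, int q_from, int r_from,
                     int dir) {
  int n = 0;
  int qi = q_from, ri = r_from;
  while (qi >= 0 && ri >= 0 && qi < (int)q.size() && ri < (int)r.size() &&
         q[qi] == r[ri] && q[qi] != 'N') {
    ++n;
    qi += dir;
    ri += dir;
  }
  return n;
}

// Batch chain finalisation for one (query record, reference record, strand)
// group: optional greedy exact end extension, mismatch recount over the
// full span for equal-length chains, and span/identity filtering.
// Unequal-length chains (from indel stitching) are passed back with
// needs_dp = true for a dynamic-programming recount in R.
// [[Rcpp::export]]
List cpp_finalize_chains(std::string qstr, std::string rstr,
                         IntegerVector qs, IntegerVector qe,
                         IntegerVector rs, IntegerVector re,
                         bool extend, int min_cluster, double min_identity) {
  int n = qs.size();
  std::vector<int> oqs, oqe, ors, ore, mat, col;
  std::vector<int> needs_dp;
  oqs.reserve(n); oqe.reserve(n); ors.reserve(n); ore.reserve(n);
  for (int i = 0; i < n; ++i) {
    int a = qs[i], b = qe[i], c = rs[i], d = re[i];
    if (extend) {
      int qi = a - 1, ri = c - 1;
      while (qi >= 0 && ri >= 0 && qstr[qi] == rstr[ri] && qstr[qi] != 'N') {
        --qi; --ri;
      }
      a = qi + 1; c = ri + 1;
      qi = b; ri = d;
      while (qi < (int)qstr.size() && ri < (int)rstr.size() &&
             qstr[qi] == rstr[ri] && qstr[qi] != 'N') {
        ++qi; ++ri;
      }
      b = qi; d = ri;
    }
    int spanq = b - a, spanr = d - c;
    if (std::max(spanq, spanr) < min_cluster) continue;
    if (spanq == spanr) {
      int mm = 0;
      for (int j = 0; j < spanq; ++j)
        if (qstr[a + j] != rstr[c + j]) ++mm;
      double ident = 100.0 * (spanq - mm) / spanq;
      if (ident < min_identity) continue;
      oqs.push_back(a); oqe.push_back(b); ors.push_back(c); ore.push_back(d);
      mat.push_back(spanq - mm); col.push_back(spanq); needs_dp.push_back(0);
    } else {
      oqs.push_back(a); oqe.push_back(b); ors.push_back(c); ore.push_back(d);
      mat.push_back(0); col.push_back(0); needs_dp.push_back(1);
    }
  }
  return List::create(_["qs"] = oqs, _["qe"] = oqe, _["rs"] = ors,
                      _["re"] = ore, _["matches"] = mat, _["columns"] = col,
                      _["needs_dp"] = needs_dp);
}
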