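// 2-bit k-mer kernels: encoding, windowed extraction with the singleton
// filter, heap-based multiway merge for the cohort recurrency index, and the
// exact multi-pattern read scan used for traceback.
//
// Encoded k-mers travel through R as doubles: 4^k exceeds R's 32-bit integer
// range already at k = 16, and doubles are exact up to 2^53 (k <= 26).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <queue>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

static const int MAX_K = 26; // 4^26 < 2^53, exact in a double

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static void check_k(int k) {
  if (k < 1 || k > MAX_K)
    stop("k must be between 1 and %d", MAX_K);
}

// [[Rcpp::export]]
NumericVector encode_kmers_cpp(CharacterVector seqs, int k) {
  check_k(k);
  R_xlen_t n = seqs.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    R_xlen_t len = LENGTH(STRING_ELT(seqs, i));
    if (len != k)
      stop("sequence %d has length %d, expected k = %d", (int)(i + 1), (int)len, k);
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(s[j]);
      if (b < 0)
        stop("sequence %d contains a non-ACGT character ('%c') at position %d",
             (int)(i + 1), s[j], j + 1);
      code = (code << 2) | (uint64_t)b;
    }
    out[i] = (double)code;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector decode_kmers_cpp(NumericVector codes, int k) {
  check_k(k);
  R_xlen_t n = codes.size();
  double maxcode = std::ldexp(1.0, 2 * k); // 4^k
  CharacterVector out(n);
  std::vector<char> buf(k + 1, '\0');
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = codes[i];
    if (ISNAN(v) || v < 0 || v >= maxcode || v != std::floor(v))
      stop("code %d (%.0f) is not a valid encoded %d-mer", (int)(i + 1), v, k);
    uint64_t code = (uint64_t)v;
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = BITS2BASE[code & 3];
      code >>= 2;
    }
    out[i] = std::string(buf.data(), k);
  }
  return out;
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// [[Rcpp::export]]
NumericVector revcomp_codes_cpp(NumericVector codes, int k) {
  check_k(k);
  NumericVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = (double)revcomp_code((uint64_t)codes[i], k);
  return out;
}

// Distinct k-mers with within-sample occurrence count >= min_count, summed
// over all reads (sliding windows, step 1; windows touching a non-ACGT base
// are skipped). Returns codes sorted ascending.
// [[Rcpp::export]]
NumericVector extract_kmers_cpp(CharacterVector reads, int k, int min_count,
                                bool canonical) {
  check_k(k);
  if (min_count < 1) stop("min_count must be >= 1");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    R_xlen_t len = LENGTH(STRING_ELT(reads, i));
    uint64_t code = 0;
    int valid = 0; // length of current run of ACGT bases ending here
    for (R_xlen_t j = 0; j < len; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) {
        valid = 0;
        code = 0;
        continue;
      }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t key = code;
        if (canonical) {
          uint64_t rc = revcomp_code(code, k);
          if (rc < key) key = rc;
        }
        ++counts[key];
      }
    }
  }
  std::vector<uint64_t> keep;
  keep.reserve(counts.size());
  for (const auto &kv : counts)
    if (kv.second >= min_count) keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());
  NumericVector out(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) out[i] = (double)keep[i];
  return out;
}

// Cohort recurrency index: heap-based multiway merge over per-sample sorted,
// duplicate-free k-mer vectors. Each element of `ksets` is one sample;
// is_patient flags its cohort. Emits, for every k-mer seen in any sample, the
// number of distinct control and patient samples containing it, in ascending
// k-mer order.
// [[Rcpp::export]]
List cohort_index_cpp(List ksets, LogicalVector is_patient) {
  int n = ksets.size();
  if (n != is_patient.size())
    stop("ksets and is_patient must have the same length");
  std::vector<NumericVector> streams;
  streams.reserve(n);
  for (int i = 0; i < n; ++i) streams.push_back(as<NumericVector>(ksets[i]));

  typedef std::pair<double, int> Item; // (k-mer code, stream index)
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > heap;
  std::vector<R_xlen_t> pos(n, 0);
  for (int i = 0; i < n; ++i)
    if (streams[i].size() > 0) heap.push(Item(streams[i][0], i));

  std::vector<double> kmer;
  std::vector<int> nc, np;
  while (!heap.empty()) {
    double cur = heap.top().first;
    int n_control = 0, n_patient = 0;
    while (!heap.empty() && heap.top().first == cur) {
      int s = heap.top().second;
      heap.pop();
      if (is_patient[s]) ++n_patient; else ++n_control;
      if (++pos[s] < streams[s].size()) {
        double nxt = streams[s][pos[s]];
        if (nxt <= cur)
          stop("k-mer set for sample %d is not strictly ascending", s + 1);
        heap.push(Item(nxt, s));
      }
    }
    kmer.push_back(cur);
    nc.push_back(n_control);
    np.push_back(n_patient);
  }
  return List::create(_["kmer"] = NumericVector(kmer.begin(), kmer.end()),
                      _["n_control"] = IntegerVector(nc.begin(), nc.end()),
                      _["n_patient"] = IntegerVector(np.begin(), np.end()));
}

// Exact multi-pattern scan: for every read, which of the (sorted) query
// k-mers occur in it as an exact forward-orientation substring. Windows
// containing non-ACGT bases never match. Returns per-read matched query
// indices (1-based, unique, ascending) and per-query read counts (a read
// counts once per query it contains, however many times).
// [[Rcpp::export]]
List scan_reads_cpp(CharacterVector reads, NumericVector queries, int k) {
  check_k(k);
  R_xlen_t nq = queries.size();
  std::vector<uint64_t> q(nq);
  for (R_xlen_t i = 0; i < nq; ++i) q[i] = (uint64_t)queries[i];
  if (!std::is_sorted(q.begin(), q.end()))
    stop("queries must be sorted ascending");

  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  List per_read(reads.size());
  IntegerVector query_read_counts(nq);
  std::vector<int> hit; // scratch: matched query indices for current read
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    R_xlen_t len = LENGTH(STRING_ELT(reads, i));
    hit.clear();
    uint64_t code = 0;
    int valid = 0;
    for (R_xlen_t j = 0; j < len; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        std::vector<uint64_t>::iterator it =
          std::lower_bound(q.begin(), q.end(), code);
        if (it != q.end() && *it == code)
          hit.push_back((int)(it - q.begin()) + 1);
      }
    }
    std::sort(hit.begin(), hit.end());
    hit.erase(std::unique(hit.begin(), hit.end()), hit.end());
    for (size_t h = 0; h < hit.size(); ++h) ++query_read_counts[hit[h] - 1];
    per_read[i] = IntegerVector(hit.begin(), hit.end());
  }
  return List::create(_["per_read"] = per_read,
                      _["query_read_counts"] = query_read_counts);
}
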