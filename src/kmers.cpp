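#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default: stop("non-ACGT character in sequence");
    }
  }
  return r;
}

// k-mer -> integer code, lexicographic over A<C<G<T (A=0 .. T=3),
// first base most significant. Requires k <= 15 so codes fit in int.
static void window_codes(const std::string& s, int k, int stride,
                         std::vector<int>& out) {
  out.clear();
  int n = (int)s.size();
  if (n < k) return;
  for (int start = 0; start + k <= n; start += stride) {
    int code = 0;
    for (int j = 0; j < k; ++j) {
      int b = base_code(s[start + j]);
      if (b < 0) stop("non-ACGT character in sequence");
      code = code * 4 + b;
    }
    out.push_back(code);
  }
}

// [[Rcpp::export(name = ".tokenize_codes_cpp")]]
List tokenize_codes_cpp(CharacterVector seqs, int k, int stride) {
  if (k < 1 || k > 15) stop("k must be in 1..15");
  if (stride < 1) stop("stride must be >= 1");
  int n = seqs.size();
  List fwd(n), rev(n);
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k)
      stop("sequence %d is shorter than k = %d", i + 1, k);
    window_codes(s, k, stride, buf);
    fwd[i] = IntegerVector(buf.begin(), buf.end());
    std::string rc = revcomp_str(s);
    window_codes(rc, k, stride, buf);
    rev[i] = IntegerVector(buf.begin(), buf.end());
  }
  return List::create(_["forward"] = fwd, _["reverse"] = rev);
}

// [[Rcpp::export(name = ".codes_to_kmers_cpp")]]
CharacterVector codes_to_kmers_cpp(IntegerVector codes, int k) {
  static const char* bases = "ACGT";
  int n = codes.size();
  CharacterVector out(n);
  std::string buf(k, 'A');
  for (int i = 0; i < n; ++i) {
    int code = codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = bases[code & 3];
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export(name = ".kfv_counts_cpp")]]
IntegerVector kfv_counts_cpp(std::string seq, int k, int stride) {
  if (k < 1 || k > 12) stop("kfv supports k in 1..12");
  if (stride < 1) stop("stride must be >= 1");
  if ((int)seq.size() < k) stop("sequence shorter than k");
  size_t m = (size_t)1 << (2 * k);
  IntegerVector counts((R_xlen_t)m);
  std::vector<int> codes;
  window_codes(seq, k, stride, codes);
  for (size_t i = 0; i < codes.size(); ++i) counts[codes[i]]++;
  return counts;
}
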