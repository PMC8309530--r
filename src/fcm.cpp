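#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Sparse order-k context-count table over a single-character alphabet.
// Each stored context maps to a vector of length |A|+1: per-symbol counts
// followed by the context total. Contexts are plain strings; with k = 20
// over |A| = 20 a dense table is impossible, but the number of distinct
// contexts is bounded by the training length.
struct FCMTable {
  int k;
  std::string alphabet;
  int sym_index[256];
  std::unordered_map<std::string, std::vector<uint32_t>> tab;
  long long n_train;

  FCMTable(int k_, const std::string& alpha_) : k(k_), alphabet(alpha_), n_train(0) {
    std::fill(sym_index, sym_index + 256, -1);
    for (size_t i = 0; i < alphabet.size(); ++i)
      sym_index[(unsigned char)alphabet[i]] = (int)i;
  }

  int index_of(char c) const { return sym_index[(unsigned char)c]; }
};

// Circular extension: the k symbols preceding position 0 are the last k
// symbols of the sequence itself (wrapping more than once when k > n).
static std::string circular_prefix(const std::string& s, int k) {
  const long long n = (long long)s.size();
  std::string pre(k, ' ');
  for (int j = 0; j < k; ++j) {
    long long idx = ((long long)(-k + j) % n + n) % n;
    pre[j] = s[idx];
  }
  return pre;
}

static void check_symbols(const FCMTable& m, const std::string& s) {
  for (char c : s)
    if (m.index_of(c) < 0)
      stop("symbol '%s' not in model alphabet", std::string(1, c).c_str());
}

// [[Rcpp::export]]
SEXP fcm_train_cpp(std::string seq, int k, std::string alphabet) {
  if (k < 1) stop("context order k must be >= 1");
  if (seq.empty()) stop("training sequence is empty");
  XPtr<FCMTable> ptr(new FCMTable(k, alphabet), true);
  FCMTable& m = *ptr;
  check_symbols(m, seq);

  const long long n = (long long)seq.size();
  const int A = (int)alphabet.size();
  std::string ext = circular_prefix(seq, k) + seq;
  std::string ctx = ext.substr(0, k);
  for (long long i = 0; i < n; ++i) {
    int s = m.index_of(ext[i + k]);
    auto it = m.tab.find(ctx);
    if (it == m.tab.end())
      it = m.tab.emplace(ctx, std::vector<uint32_t>(A + 1, 0u)).first;
    it->second[s] += 1u;
    it->second[A] += 1u;
    // roll the context window one symbol forward
    ctx.erase(0, 1);
    ctx.push_back(ext[i + k]);
  }
  m.n_train = n;
  return ptr;
}

// Per-position lookup of (v(s|ctx), total(ctx)) for coding x against a
// frozen model; contexts wrap circularly within x itself.
// [[Rcpp::export]]
List fcm_lookup_cpp(SEXP model, std::string x) {
  XPtr<FCMTable> ptr(model);
  FCMTable& m = *ptr;
  check_symbols(m, x);
  const long long n = (long long)x.size();
  const int A = (int)m.alphabet.size();
  NumericVector v(n), tot(n);
  std::string ext = circular_prefix(x, m.k) + x;
  std::string ctx = ext.substr(0, m.k);
  for (long long i = 0; i < n; ++i) {
    int s = m.index_of(ext[i + m.k]);
    auto it = m.tab.find(ctx);
    if (it == m.tab.end()) {
      v[i] = 0.0; tot[i] = 0.0;
    } else {
      v[i] = (double)it->second[s];
      tot[i] = (double)it->second[A];
    }
    ctx.erase(0, 1);
    ctx.push_back(ext[i + m.k]);
  }
  return List::create(_["v"] = v, _["tot"] = tot);
}

// Total code length in bits for each of several sequences against one
// frozen model. Accumulation is in extended precision, matching R's
// sum() over the per-position terms, so this agrees bit-for-bit with
// the vectorised R path.
// [[Rcpp::export]]
NumericVector fcm_bits_batch_cpp(SEXP model, CharacterVector xs, double alpha) {
  XPtr<FCMTable> ptr(model);
  FCMTable& m = *ptr;
  const int A = (int)m.alphabet.size();
  NumericVector out(xs.size());
  for (R_xlen_t si = 0; si < xs.size(); ++si) {
    std::string x = as<std::string>(xs[si]);
    check_symbols(m, x);
    long double acc = 0.0L;
    std::string ext = circular_prefix(x, m.k) + x;
    std::string ctx = ext.substr(0, m.k);
    for (long long i = 0; i < (long long)x.size(); ++i) {
      int s = m.index_of(ext[i + m.k]);
      double v = 0.0, tot = 0.0;
      auto it = m.tab.find(ctx);
      if (it != m.tab.end()) {
        v = (double)it->second[s];
        tot = (double)it->second[A];
      }
      acc += -std::log2((v + alpha) / (tot + alpha * A));
      ctx.erase(0, 1);
      ctx.push_back(ext[i + m.k]);
    }
    out[si] = (double)acc;
  }
  return out;
}

// Raw counts for one context (zeros if never seen); last element is the total.
// [[Rcpp::export]]
NumericVector fcm_context_counts_cpp(SEXP model, std::string context) {
  XPtr<FCMTable> ptr(model);
  FCMTable& m = *ptr;
  const int A = (int)m.alphabet.size();
  if ((int)context.size() != m.k) stop("context length must equal k");
  check_symbols(m, context);
  NumericVector out(A + 1);
  auto it = m.tab.find(context);
  if (it != m.tab.end())
    for (int j = 0; j <= A; ++j) out[j] = (double)it->second[j];
  return out;
}

// [[Rcpp::export]]
List fcm_export_cpp(SEXP model) {
  XPtr<FCMTable> ptr(model);
  FCMTable& m = *ptr;
  const int A = (int)m.alphabet.size();
  std::vector<std::string> keys;
  keys.reserve(m.tab.size());
  for (auto& kv : m.tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector contexts(keys.size());
  IntegerMatrix counts((int)keys.size(), A);
  for (size_t i = 0; i < keys.size(); ++i) {
    contexts[i] = keys[i];
    const std::vector<uint32_t>& row = m.tab[keys[i]];
    for (int j = 0; j < A; ++j) counts(i, j) = (int)row[j];
  }
  return List::create(_["context"] = contexts, _["counts"] = counts,
                      _["k"] = m.k, _["alphabet"] = m.alphabet,
                      _["n_train"] = (double)m.n_train);
}

// [[Rcpp::export]]
SEXP fcm_import_cpp(CharacterVector contexts, IntegerMatrix counts,
                    int k, std::string alphabet, double n_train) {
  const int A = (int)alphabet.size();
  if (counts.ncol() != A) stop("counts must have one column per alphabet symbol");
  XPtr<FCMTable> ptr(new FCMTable(k, alphabet), true);
  FCMTable& m = *ptr;
  for (int i = 0; i < contexts.size(); ++i) {
    std::string ctx = as<std::string>(contexts[i]);
    if ((int)ctx.size() != k) stop("context length must equal k");
    std::vector<uint32_t> row(A + 1, 0u);
    uint32_t total = 0u;
    for (int j = 0; j < A; ++j) {
      if (counts(i, j) < 0) stop("counts must be nonnegative");
      row[j] = (uint32_t)counts(i, j);
      total += row[j];
    }
    row[A] = total;
    m.tab[ctx] = row;
  }
  m.n_train = (long long)n_train;
  return ptr;
}

// [[Rcpp::export]]
double fcm_mass_cpp(SEXP model) {
  XPtr<FCMTable> ptr(model);
  double mass = 0.0;
  const int A = (int)ptr->alphabet.size();
  for (auto& kv : ptr->tab) mass += (double)kv.second[A];
  return mass;
}
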