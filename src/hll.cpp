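#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// 64-bit FNV-1a over bytes, finalized with a splitmix64 mix.
// Fixed constants => identical hashes on every platform and run.
static inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline uint64_t hash_bytes(const char* s, size_t n) {
  uint64_t h = 0xcbf29ce484222325ULL;
  for (size_t i = 0; i < n; i++) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 0x100000001b3ULL;
  }
  return mix64(h);
}

struct Hll {
  int p;
  std::vector<uint8_t> reg;
  Hll(int p_) : p(p_), reg((size_t)1 << p_, 0) {}
  void add_hash(uint64_t h) {
    uint64_t idx = h >> (64 - p);
    uint64_t rest = h << p;
    // rank = leading zeros of remaining bits + 1, capped
    uint8_t rho = 1;
    if (rest == 0) {
      rho = (uint8_t)(64 - p + 1);
    } else {
      while (!(rest & 0x8000000000000000ULL)) { rho++; rest <<= 1; }
    }
    if (rho > reg[idx]) reg[idx] = rho;
  }
  double estimate() const {
    size_t m = reg.size();
    double sum = 0.0;
    size_t zeros = 0;
    for (size_t i = 0; i < m; i++) {
      sum += std::ldexp(1.0, -(int)reg[i]);
      if (reg[i] == 0) zeros++;
    }
    double alpha;
    if (m == 16) alpha = 0.673;
    else if (m == 32) alpha = 0.697;
    else if (m == 64) alpha = 0.709;
    else alpha = 0.7213 / (1.0 + 1.079 / (double)m);
    double e = alpha * (double)m * (double)m / sum;
    if (e <= 2.5 * (double)m && zeros > 0)
      e = (double)m * std::log((double)m / (double)zeros);
    return e;
  }
};

// [[Rcpp::export(name = ".hll_create")]]
SEXP hll_create(int p) {
  if (p < 4 || p > 18) stop("HLL precision exponent must be in [4,18]");
  XPtr<Hll> ptr(new Hll(p), true);
  return ptr;
}

// [[Rcpp::export(name = ".hll_insert")]]
void hll_insert(SEXP sk, CharacterVector keys) {
  XPtr<Hll> ptr(sk);
  for (R_xlen_t i = 0; i < keys.size(); i++) {
    const char* s = CHAR(STRING_ELT(keys, i));
    ptr->add_hash(hash_bytes(s, strlen(s)));
  }
}

// [[Rcpp::export(name = ".hll_estimate")]]
double hll_estimate(SEXP sk) {
  XPtr<Hll> ptr(sk);
  return ptr->estimate();
}

// [[Rcpp::export(name = ".hll_precision")]]
int hll_precision(SEXP sk) {
  XPtr<Hll> ptr(sk);
  return ptr->p;
}

// [[Rcpp::export(name = ".hll_merge_into")]]
void hll_merge_into(SEXP dst, SEXP src) {
  XPtr<Hll> a(dst); XPtr<Hll> b(src);
  if (a->p != b->p) stop("cannot merge HLL sketches of different precision");
  for (size_t i = 0; i < a->reg.size(); i++)
    if (b->reg[i] > a->reg[i]) a->reg[i] = b->reg[i];
}

// [[Rcpp::export(name = ".hll_registers")]]
RawVector hll_registers(SEXP sk) {
  XPtr<Hll> ptr(sk);
  RawVector out(ptr->reg.size());
  for (size_t i = 0; i < ptr->reg.size(); i++) out[i] = ptr->reg[i];
  return out;
}

// [[Rcpp::export(name = ".hll_restore")]]
SEXP hll_restore(RawVector regs) {
  size_t m = regs.size();
  int p = 0;
  while (((size_t)1 << p) < m) p++;
  if (((size_t)1 << p) != m) stop("register vector length is not a power of two");
  XPtr<Hll> ptr(new Hll(p), true);
  for (size_t i = 0; i < m; i++) ptr->reg[i] = regs[i];
  return ptr;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    case 'N': return 'N'; case 'n': return 'n';
    default: return 'N';
  }
}

// [[Rcpp::export(name = ".revcomp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); i++) {
    std::string s(CHAR(STRING_ELT(seqs, i)));
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); j++) r[j] = comp_base(s[s.size() - 1 - j]);
    out[i] = r;
  }
  return out;
}

// Canonical k-mers of one sequence: for each window, the lexicographic min of
// the window and its reverse complement; windows with non-ACGT bases skipped.
// [[Rcpp::export(name = ".canonical_kmers")]]
CharacterVector canonical_kmers_cpp(std::string seq, int k) {
  std::vector<std::string> out;
  int n = (int)seq.size();
  if (k < 1 || n < k) return CharacterVector(0);
  for (int i = 0; i + k <= n; i++) {
    bool ok = true;
    for (int j = 0; j < k; j++) {
      char c = seq[i + j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
    }
    if (!ok) continue;
    std::string fwd = seq.substr(i, k);
    std::string rev(k, 'N');
    for (int j = 0; j < k; j++) rev[j] = comp_base(fwd[k - 1 - j]);
    out.push_back(fwd <= rev ? fwd : rev);
  }
  return wrap(out);
}

// Insert all canonical k-mers of seq into a sketch; returns how many windows
// were inserted (the read's total-k-mer contribution).
// [[Rcpp::export(name = ".hll_insert_kmers")]]
int hll_insert_kmers(SEXP sk, std::string seq, int k) {
  XPtr<Hll> ptr(sk);
  int n = (int)seq.size();
  int added = 0;
  if (k < 1 || n < k) return 0;
  for (int i = 0; i + k <= n; i++) {
    bool ok = true;
    for (int j = 0; j < k; j++) {
      char c = seq[i + j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
    }
    if (!ok) continue;
    std::string fwd = seq.substr(i, k);
    std::string rev(k, 'N');
    for (int j = 0; j < k; j++) rev[j] = comp_base(fwd[k - 1 - j]);
    const std::string& can = (fwd <= rev) ? fwd : rev;
    ptr->add_hash(hash_bytes(can.c_str(), can.size()));
    added++;
  }
  return added;
}
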