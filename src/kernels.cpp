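#ifndef _GNU_SOURCE
#define _GNU_SOURCE
#endif
#include <cstring>
#ifdef __SSE2__
#include <emmintrin.h>
#endif
#include <Rcpp.h>
using namespace Rcpp;

// Exact substring scan over a byte range [from, to) of the sequence;
// returns 0-based start positions relative to `from` (overlapping matches
// included).  Operates on the CHARSXP bytes directly: no copy, no locale
// scanning.
// [[Rcpp::export]]
IntegerVector scan_motif_cpp(CharacterVector seq, std::string pat,
                             int from = 0, int to = -1) {
  const char* s = CHAR(STRING_ELT(seq, 0));
  int n = LENGTH(STRING_ELT(seq, 0));
  if (to < 0 || to > n) to = n;
  int m = static_cast<int>(pat.size());
  std::vector<int> hits;
  if (m == 0 || to - from < m) return IntegerVector(0);
  const char* p = pat.c_str();
  const char* base = s + from;
  const char* cur = base;
  const char* end = s + to;
  while (cur + m <= end) {
    const char* hit = static_cast<const char*>(
      memmem(cur, end - cur, p, m));
    if (hit == nullptr) break;
    hits.push_back(static_cast<int>(hit - base));
    cur = hit + 1;
  }
  return wrap(hits);
}

// One pass over [from, to) matching four patterns simultaneously (the two
// motifs and their reverse complements); returns a list of four 0-based
// hit-position vectors relative to `from`.  A 2-byte prefilter keeps the
// inner loop branch-cheap.
// [[Rcpp::export]]
List scan_motifs4_cpp(CharacterVector seq, CharacterVector pats,
                      int from, int to) {
  const char* s = CHAR(STRING_ELT(seq, 0));
  int n = LENGTH(STRING_ELT(seq, 0));
  if (to < 0 || to > n) to = n;
  std::vector<std::vector<int> > hits(4);
  const char* p[4];
  int m[4];
  uint16_t key[4];
  for (int k = 0; k < 4; ++k) {
    p[k] = CHAR(STRING_ELT(pats, k));
    m[k] = LENGTH(STRING_ELT(pats, k));
    if (m[k] < 2) stop("patterns must have length >= 2");
    memcpy(&key[k], p[k], 2);
  }
  // per pattern: vectorized two-byte prefilter (both bytes must match,
  // ~1/16 pass rate on DNA), full compare only on surviving candidates
  for (int k = 0; k < 4; ++k) {
    const char* pk = p[k];
    const int mk = m[k];
    const char c0 = pk[0], c1 = pk[1];
    int last = to - mk;              // last valid start (absolute)
    int i = from;
#ifdef __SSE2__
    const __m128i v0 = _mm_set1_epi8(c0);
    const __m128i v1 = _mm_set1_epi8(c1);
    for (; i + 16 <= last + 1 && i + 17 <= n; i += 16) {
      __m128i a = _mm_loadu_si128(reinterpret_cast<const __m128i*>(s + i));
      __m128i b = _mm_loadu_si128(
        reinterpret_cast<const __m128i*>(s + i + 1));
      int mask = _mm_movemask_epi8(
        _mm_and_si128(_mm_cmpeq_epi8(a, v0), _mm_cmpeq_epi8(b, v1)));
      while (mask) {
        int bpos = __builtin_ctz(mask);
        mask &= mask - 1;
        int pos = i + bpos;
        if (pos <= last && memcmp(s + pos + 2, pk + 2, mk - 2) == 0)
          hits[k].push_back(pos - from);
      }
    }
#endif
    for (; i <= last; ++i) {
      if (s[i] == c0 && s[i + 1] == c1 &&
          memcmp(s + i + 2, pk + 2, mk - 2) == 0)
        hits[k].push_back(i - from);
    }
  }
  return List::create(wrap(hits[0]), wrap(hits[1]), wrap(hits[2]),
                      wrap(hits[3]));
}

static inline unsigned char comp_base(unsigned char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    case 'a': return 't'; case 't': return 'a';
    case 'c': return 'g'; case 'g': return 'c';
    default: return c;
  }
}

// Assemble a sequence from pieces in one allocation.  Piece k is either a
// byte range [from[k], to[k]) of seqs[[seq_idx[k]]] (1-based index) or, when
// seq_idx[k] == 0, the literal string literal[k]; rc[k] reverse-complements
// that piece.
// [[Rcpp::export]]
CharacterVector splice_cpp(List seqs, IntegerVector seq_idx,
                           NumericVector from, NumericVector to,
                           LogicalVector rc, CharacterVector literal) {
  int K = seq_idx.size();
  std::vector<const char*> ptr(K);
  std::vector<long> len(K);
  long total = 0;
  for (int k = 0; k < K; ++k) {
    if (seq_idx[k] == 0) {
      SEXP lit = STRING_ELT(literal, k);
      ptr[k] = CHAR(lit);
      len[k] = LENGTH(lit);
    } else {
      CharacterVector sv = seqs[seq_idx[k] - 1];
      SEXP cs = STRING_ELT(sv, 0);
      long n = LENGTH(cs);
      long a = static_cast<long>(from[k]), b = static_cast<long>(to[k]);
      if (a < 0 || b > n || b < a) stop("splice piece out of range");
      ptr[k] = CHAR(cs) + a;
      len[k] = b - a;
    }
    total += len[k];
  }
  std::string out;
  out.resize(total);
  long off = 0;
  for (int k = 0; k < K; ++k) {
    if (rc[k]) {
      for (long i = 0; i < len[k]; ++i)
        out[off + i] = static_cast<char>(comp_base(
          static_cast<unsigned char>(ptr[k][len[k] - 1 - i])));
    } else {
      memcpy(&out[off], ptr[k], len[k]);
    }
    off += len[k];
  }
  return CharacterVector::create(Rf_mkCharLen(out.data(), total));
}

// Byte-range substring [start0, end0), 0-based half-open; O(window), not
// O(position) as R's substr is under multi-byte locales.
// [[Rcpp::export]]
CharacterVector subseq_cpp(CharacterVector seq, double start0, double end0) {
  const char* s = CHAR(STRING_ELT(seq, 0));
  int n = LENGTH(STRING_ELT(seq, 0));
  int a = static_cast<int>(start0), b = static_cast<int>(end0);
  if (a < 0 || b > n || b < a) stop("substring out of range");
  return CharacterVector::create(Rf_mkCharLen(s + a, b - a));
}

// Reverse complement over A/C/G/T/N (case preserved for lower-case input).
// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seq) {
  const char* s = CHAR(STRING_ELT(seq, 0));
  int n = LENGTH(STRING_ELT(seq, 0));
  static unsigned char comp[256];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 256; ++i) comp[i] = static_cast<unsigned char>(i);
    comp[(int)'A'] = 'T'; comp[(int)'T'] = 'A';
    comp[(int)'C'] = 'G'; comp[(int)'G'] = 'C';
    comp[(int)'a'] = 't'; comp[(int)'t'] = 'a';
    comp[(int)'c'] = 'g'; comp[(int)'g'] = 'c';
    init = true;
  }
  std::string out(n, 'N');
  for (int i = 0; i < n; ++i)
    out[i] = static_cast<char>(comp[static_cast<unsigned char>(s[n - 1 - i])]);
  return CharacterVector::create(Rf_mkCharLen(out.data(), n));
}

// count occurrences of a single byte
// [[Rcpp::export]]
double count_char_cpp(CharacterVector seq, std::string ch) {
  const char* s = CHAR(STRING_ELT(seq, 0));
  int n = LENGTH(STRING_ELT(seq, 0));
  char c = ch[0];
  double cnt = 0;
  for (int i = 0; i < n; ++i) if (s[i] == c) cnt += 1;
  return cnt;
}

// byte length (O(1))
// [[Rcpp::export]]
double seq_len_cpp(CharacterVector seq) {
  return static_cast<double>(LENGTH(STRING_ELT(seq, 0)));
}

// Mechanistic toy contact map: distance decay + block elevation between
// consecutive boundary bins + loop bonus for convergent anchor pairs.
// All bin vectors are 0-based. Cells with |i-j| < diag_min are set to 0.
// [[Rcpp::export]]
NumericMatrix toy_map_cpp(int n, IntegerVector boundary,
                          IntegerVector anchor_f, IntegerVector anchor_r,
                          double gamma, double c_in, double c_out,
                          double loop_bonus, int loop_max, int diag_min) {
  std::vector<bool> isb(n, false), af(n, false), ar(n, false);
  for (int k = 0; k < boundary.size(); ++k) {
    int b = boundary[k];
    if (b >= 0 && b < n) isb[b] = true;
  }
  for (int k = 0; k < anchor_f.size(); ++k) {
    int b = anchor_f[k];
    if (b >= 0 && b < n) af[b] = true;
  }
  for (int k = 0; k < anchor_r.size(); ++k) {
    int b = anchor_r[k];
    if (b >= 0 && b < n) ar[b] = true;
  }
  // boundary bins delimit blocks but belong to none (a unique sentinel id):
  // this keeps the block relation exactly symmetric under strand reversal.
  // A window with no boundary at all has no block structure (pure decay),
  // not one window-wide elevated block.
  std::vector<int> block(n);
  bool any_boundary = false;
  for (int i = 0; i < n; ++i) if (isb[i]) { any_boundary = true; break; }
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    if (isb[i]) {
      ++cur;
      block[i] = -(i + 1);
    } else {
      block[i] = any_boundary ? cur : -(n + i + 1);
    }
  }
  std::vector<double> decay(n);
  for (int d = 0; d < n; ++d)
    decay[d] = -gamma * std::log10(static_cast<double>(d) + 1.0);
  NumericMatrix m(n, n);
  double* md = REAL(m);
  for (int i = 0; i < n; ++i) {
    const int bi = block[i];
    const bool fi = af[i];
    for (int j = i + diag_min; j < n; ++j) {
      double v = decay[j - i] + (block[j] == bi ? c_in : c_out);
      if (fi && ar[j] && (j - i) <= loop_max) v += loop_bonus;
      md[i + static_cast<long>(n) * j] = v;
      md[j + static_cast<long>(n) * i] = v;
    }
  }
  return m;
}

// Masked upper-triangle comparison of two symmetric maps.
// Evaluation cells: i + min_sep <= j, neither bin masked, and at least one
// bin in the required ("req") set (req is all-true for non-breakend SVs).
// Returns MSE, 1 - Pearson r, the cell count, and a zero-variance flag.
// [[Rcpp::export]]
List compare_maps_cpp(NumericMatrix ref, NumericMatrix alt,
                      LogicalVector mask, LogicalVector req, int min_sep) {
  int n = ref.nrow();
  double sd2 = 0, sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  double cnt = 0;
  for (int i = 0; i < n; ++i) {
    if (mask[i]) continue;
    for (int j = i + min_sep; j < n; ++j) {
      if (mask[j]) continue;
      if (!(req[i] || req[j])) continue;
      double x = ref(i, j), y = alt(i, j), d = x - y;
      sd2 += d * d;
      sx += x; sy += y;
      sxx += x * x; syy += y * y; sxy += x * y;
      cnt += 1;
    }
  }
  if (cnt < 1) {
    return List::create(_["mse"] = NA_REAL, _["corr"] = NA_REAL,
                        _["n_cells"] = 0.0, _["zero_variance"] = false);
  }
  double mse = sd2 / cnt;
  double vx = sxx - sx * sx / cnt;
  double vy = syy - sy * sy / cnt;
  double corr;
  bool zv = false;
  if (vx <= 1e-12 || vy <= 1e-12) {
    corr = 0.0;
    zv = true;
  } else {
    double r = (sxy - sx * sy / cnt) / std::sqrt(vx * vy);
    corr = 1.0 - r;
  }
  return List::create(_["mse"] = mse, _["corr"] = corr,
                      _["n_cells"] = cnt, _["zero_variance"] = zv);
}

// Per-bin MSE track: track[i] = mean over unmasked j with |i-j| >= min_sep
// of (ref[i,j]-alt[i,j])^2; masked bins get 0.
// [[Rcpp::export]]
NumericVector disruption_track_cpp(NumericMatrix ref, NumericMatrix alt,
                                   LogicalVector mask, int min_sep) {
  int n = ref.nrow();
  NumericVector track(n);
  for (int i = 0; i < n; ++i) {
    if (mask[i]) { track[i] = 0.0; continue; }
    double s = 0; double cnt = 0;
    for (int j = 0; j < n; ++j) {
      int d = j - i; if (d < 0) d = -d;
      if (d < min_sep) continue;
      if (mask[j]) continue;
      double dd = ref(i, j) - alt(i, j);
      s += dd * dd;
      cnt += 1;
    }
    track[i] = (cnt > 0) ? s / cnt : 0.0;
  }
  return track;
}
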