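#include <Rcpp.h>
using namespace Rcpp;

// Bit-code conventions shared with the R side (see census.R):
// for a k-subset {v1 < v2 < ... < vk} of node indices, pair bits come
// first in combn(k, 2) column order, then one loop bit per member node.
// k = 4: pairs (1,2)(1,3)(1,4)(2,3)(2,4)(3,4) -> bits 0..5, loops bits 6..9.
// k = 3: pairs (1,2)(1,3)(2,3) -> bits 0..2, loops bits 3..5.
// k = 2: pair (1,2) -> bit 0, loops bits 1..2.

// [[Rcpp::export]]
IntegerVector cpp_code_census(const IntegerMatrix& A, int k) {
  int n = A.nrow();
  if (k < 2 || k > 4) stop("k must be 2, 3 or 4");
  int nbits = k * (k - 1) / 2 + k;
  IntegerVector counts(1 << nbits);
  if (n < k) return counts;
  if (k == 2) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        int code = A(i, j) | (A(i, i) << 1) | (A(j, j) << 2);
        counts[code]++;
      }
  } else if (k == 3) {
    for (int i = 0; i < n - 2; ++i)
      for (int j = i + 1; j < n - 1; ++j)
        for (int l = j + 1; l < n; ++l) {
          int code = A(i, j) | (A(i, l) << 1) | (A(j, l) << 2) |
                     (A(i, i) << 3) | (A(j, j) << 4) | (A(l, l) << 5);
          counts[code]++;
        }
  } else {
    for (int i = 0; i < n - 3; ++i)
      for (int j = i + 1; j < n - 2; ++j) {
        int aij = A(i, j);
        for (int l = j + 1; l < n - 1; ++l) {
          int ail = A(i, l), ajl = A(j, l);
          for (int m = l + 1; m < n; ++m) {
            int code = aij | (ail << 1) | (A(i, m) << 2) |
                       (ajl << 3) | (A(j, m) << 4) | (A(l, m) << 5) |
                       (A(i, i) << 6) | (A(j, j) << 7) |
                       (A(l, l) << 8) | (A(m, m) << 9);
            counts[code]++;
          }
        }
      }
  }
  return counts;
}

// Number of 4-subsets whose induced loop-free subgraph contains a
// 4-cycle through all four nodes. On 4 vertices this holds iff the
// induced simple graph has >= 5 edges, or exactly 4 edges with every
// vertex of internal degree 2 (the plain 4-cycle).
// [[Rcpp::export]]
int cpp_count_c4sets(const IntegerMatrix& A) {
  int n = A.nrow();
  long long count = 0;
  for (int i = 0; i < n - 3; ++i)
    for (int j = i + 1; j < n - 2; ++j) {
      int aij = A(i, j);
      for (int l = j + 1; l < n - 1; ++l) {
        int ail = A(i, l), ajl = A(j, l);
        for (int m = l + 1; m < n; ++m) {
          int aim = A(i, m), ajm = A(j, m), alm = A(l, m);
          int e = aij + ail + aim + ajl + ajm + alm;
          if (e >= 5) { count++; continue; }
          if (e == 4) {
            int di = aij + ail + aim;
            int dj = aij + ajl + ajm;
            int dl = ail + ajl + alm;
            int dm = aim + ajm + alm;
            if (di == 2 && dj == 2 && dl == 2 && dm == 2) count++;
          }
        }
      }
    }
  return (int)count;
}

// Enumerate 4-subsets whose bit code satisfies keep[code]; returns a
// matrix with columns v1..v4 (1-based) and the code.
// [[Rcpp::export]]
IntegerMatrix cpp_foursets(const IntegerMatrix& A, const LogicalVector& keep) {
  int n = A.nrow();
  if (keep.size() != 1024) stop("keep must have length 1024");
  std::vector<int> rows;
  for (int i = 0; i < n - 3; ++i)
    for (int j = i + 1; j < n - 2; ++j)
      for (int l = j + 1; l < n - 1; ++l)
        for (int m = l + 1; m < n; ++m) {
          int code = A(i, j) | (A(i, l) << 1) | (A(i, m) << 2) |
                     (A(j, l) << 3) | (A(j, m) << 4) | (A(l, m) << 5) |
                     (A(i, i) << 6) | (A(j, j) << 7) |
                     (A(l, l) << 8) | (A(m, m) << 9);
          if (keep[code]) {
            rows.push_back(i + 1); rows.push_back(j + 1);
            rows.push_back(l + 1); rows.push_back(m + 1);
            rows.push_back(code);
          }
        }
  int S = rows.size() / 5;
  IntegerMatrix out(S, 5);
  for (int r = 0; r < S; ++r)
    for (int c = 0; c < 5; ++c) out(r, c) = rows[5 * r + c];
  return out;
}

static inline int rand_int(int n) {
  int v;
  do { v = (int)(unif_rand() * n); } while (v >= n);
  return v;
}

// Degree-preserving switching randomization. `edges` is an E x 2
// 0-based matrix; a row (a, a) is a self-loop carrying two stubs.
// Performs `s` successful double-edge swaps; proposals that would
// duplicate an existing edge, merely recreate the removed pair, or (in
// preserve mode) create or destroy a self-loop are rejected and do not
// count toward s. Attempts are capped so graphs admitting no legal swap
// (e.g. a triangle) return unchanged. Uses the R RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_switch_randomize(const IntegerMatrix& edges, int n, int s,
                                   bool preserve_loops, double max_attempts) {
  int E = edges.nrow();
  if (E < 2) stop("switching requires at least 2 edges");
  std::vector<int> ea(E), eb(E);
  std::vector<char> adj((size_t)n * n, 0);
  for (int e = 0; e < E; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    if (a < 0 || b < 0 || a >= n || b >= n) stop("edge endpoint out of range");
    if (a > b) std::swap(a, b);
    ea[e] = a; eb[e] = b;
    adj[(size_t)a * n + b] = 1;
    adj[(size_t)b * n + a] = 1;
  }
  long long done = 0, attempts = 0;
  long long cap = (long long)max_attempts;
  GetRNGstate();
  while (done < s && attempts < cap) {
    attempts++;
    int e1 = rand_int(E), e2 = rand_int(E);
    if (e1 == e2) continue;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    int x1, y1, x2, y2;
    if (unif_rand() < 0.5) { x1 = a; y1 = d; x2 = c; y2 = b; }
    else                   { x1 = a; y1 = c; x2 = b; y2 = d; }
    if (x1 > y1) std::swap(x1, y1);
    if (x2 > y2) std::swap(x2, y2);
    // identical proposals would duplicate each other
    if (x1 == x2 && y1 == y2) continue;
    // no-op: proposal set equals removed set
    bool p1_is_r1 = (x1 == a && y1 == b), p1_is_r2 = (x1 == c && y1 == d);
    bool p2_is_r1 = (x2 == a && y2 == b), p2_is_r2 = (x2 == c && y2 == d);
    if ((p1_is_r1 && p2_is_r2) || (p1_is_r2 && p2_is_r1)) continue;
    if (preserve_loops &&
        (a == b || c == d || x1 == y1 || x2 == y2)) continue;
    // duplicate check against edges other than the two being removed
    if (!p1_is_r1 && !p1_is_r2 && adj[(size_t)x1 * n + y1]) continue;
    if (!p2_is_r1 && !p2_is_r2 && adj[(size_t)x2 * n + y2]) continue;
    adj[(size_t)a * n + b] = 0; adj[(size_t)b * n + a] = 0;
    adj[(size_t)c * n + d] = 0; adj[(size_t)d * n + c] = 0;
    adj[(size_t)x1 * n + y1] = 1; adj[(size_t)y1 * n + x1] = 1;
    adj[(size_t)x2 * n + y2] = 1; adj[(size_t)y2 * n + x2] = 1;
    ea[e1] = x1; eb[e1] = y1;
    ea[e2] = x2; eb[e2] = y2;
    done++;
  }
  PutRNGstate();
  IntegerMatrix out(E, 2);
  for (int e = 0; e < E; ++e) { out(e, 0) = ea[e]; out(e, 1) = eb[e]; }
  out.attr("switches_done") = (double)done;
  out.attr("attempts") = (double)attempts;
  return out;
}
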