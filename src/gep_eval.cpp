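#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Symbol coding shared with the R side:
//   1 '+'  2 '-'  3 '*'  4 '/'  5 sin  6 cos  7 square  8 cube  9 power
//   11..19 inputs X1..X9
//   20 numeric constant (value in the parallel consts matrix)
static const double CLAMP = 1e10;

static inline double clampv(double v) {
  if (std::isnan(v)) return CLAMP;
  if (v > CLAMP) return CLAMP;
  if (v < -CLAMP) return -CLAMP;
  return v;
}

static inline int arity(int code) {
  if (code == 5 || code == 6 || code == 7 || code == 8) return 1;
  if (code >= 1 && code <= 4) return 2;
  if (code == 9) return 2;
  return 0;
}

static inline double pdiv(double a, double b) {
  return b == 0.0 ? 1.0 : a / b;
}

static inline double ppow(double a, double b) {
  // negative base with non-integer exponent uses |base|
  if (a < 0.0 && b != std::floor(b)) a = -a;
  return std::pow(a, b);
}

// Evaluate one multigenic chromosome over all rows of X.
// codes/consts: (gene length) x (number of genes); sub-trees are linked by
// addition. Every intermediate is clamped to +/-1e10 (NaN -> 1e10).
// [[Rcpp::export]]
NumericVector gep_eval_cpp(IntegerMatrix codes, NumericMatrix consts,
                           NumericMatrix X) {
  const int glen = codes.nrow(), ngenes = codes.ncol();
  const int n = X.nrow();
  NumericVector out(n, 0.0);
  std::vector<double> vals((size_t)glen * n);
  std::vector<int> child1(glen), child2(glen);

  for (int g = 0; g < ngenes; ++g) {
    // Karva (level-order) decode: how many symbols are expressed
    int required = 1;
    for (int i = 0; i < required && i < glen; ++i) {
      int a = arity(codes(i, g));
      required += a;
    }
    if (required > glen) stop("illegal chromosome: tail contains a function");
    // children follow in reading order
    int next = 1;
    for (int i = 0; i < required; ++i) {
      int a = arity(codes(i, g));
      child1[i] = (a >= 1) ? next : -1;
      child2[i] = (a == 2) ? next + 1 : -1;
      next += a;
    }
    // evaluate bottom-up (children always have larger index)
    for (int i = required - 1; i >= 0; --i) {
      int code = codes(i, g);
      double *vi = &vals[(size_t)i * n];
      if (code >= 11 && code <= 19) {
        int col = code - 11;
        for (int r = 0; r < n; ++r) vi[r] = X(r, col);
      } else if (code == 20) {
        double c = consts(i, g);
        for (int r = 0; r < n; ++r) vi[r] = c;
      } else {
        const double *a = &vals[(size_t)child1[i] * n];
        const double *b = (child2[i] >= 0) ? &vals[(size_t)child2[i] * n]
                                           : (const double *)0;
        switch (code) {
        case 1: for (int r = 0; r < n; ++r) vi[r] = clampv(a[r] + b[r]); break;
        case 2: for (int r = 0; r < n; ++r) vi[r] = clampv(a[r] - b[r]); break;
        case 3: for (int r = 0; r < n; ++r) vi[r] = clampv(a[r] * b[r]); break;
        case 4: for (int r = 0; r < n; ++r) vi[r] = clampv(pdiv(a[r], b[r])); break;
        case 5: for (int r = 0; r < n; ++r) vi[r] = clampv(std::sin(a[r])); break;
        case 6: for (int r = 0; r < n; ++r) vi[r] = clampv(std::cos(a[r])); break;
        case 7: for (int r = 0; r < n; ++r) vi[r] = clampv(a[r] * a[r]); break;
        case 8: for (int r = 0; r < n; ++r) vi[r] = clampv(a[r] * a[r] * a[r]); break;
        case 9: for (int r = 0; r < n; ++r) vi[r] = clampv(ppow(a[r], b[r])); break;
        default: stop("unknown symbol code");
        }
      }
    }
    for (int r = 0; r < n; ++r) out[r] = clampv(out[r] + vals[r]);
  }
  return out;
}
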