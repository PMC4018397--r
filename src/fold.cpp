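// Minimum-free-energy folding by dynamic programming under a
// simplified nearest-neighbour model: stacking energies for
// Watson-Crick and G.U pairs, hairpin/bulge/internal loop penalties
// by length, no dangles, no multibranch loops (each closed pair
// encloses at most one helix; the exterior may hold several
// stem-loops). Energy tables are supplied from R so the R-side
// enumeration oracle and this engine share one parameter set.
//
// Traceback is deterministic: pairing is preferred over leaving a
// base unpaired on energy ties; inner pairs are scanned at the
// smallest 5' position first, then the largest 3' position.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-9;

// codes: A=0, C=1, G=2, T/U=3; pair index AU=0 UA=1 CG=2 GC=3 GU=4 UG=5
static inline int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct FoldCtx {
  const std::vector<int>& s;
  const NumericMatrix& stack;
  const NumericVector& hairpinE;   // 1-based by loop length (R vector)
  const NumericVector& bulgeE;
  const NumericVector& internalE;
  int min_hairpin, max_loop, n;
  std::vector<double> V;           // n x n, row-major
  std::vector<double> ext;         // suffix energies, size n + 1

  FoldCtx(const std::vector<int>& s_, const NumericMatrix& st,
          const NumericVector& h, const NumericVector& b,
          const NumericVector& in, int mh, int ml)
    : s(s_), stack(st), hairpinE(h), bulgeE(b), internalE(in),
      min_hairpin(mh), max_loop(ml), n((int)s_.size()),
      V((size_t)s_.size() * s_.size(), INF), ext(s_.size() + 1, 0.0) {}

  double& v(int i, int j) { return V[(size_t)i * n + j]; }

  double loop_energy(int pc_out, int l1, int l2, int pc_in) {
    if (l1 == 0 && l2 == 0) return stack(pc_out, pc_in);
    int lt = l1 + l2;
    if (lt > max_loop) return INF;
    if (l1 == 0 || l2 == 0) return bulgeE[lt - 1];
    return internalE[lt - 1];
  }

  void fill() {
    for (int span = min_hairpin + 2; span <= n; ++span) {
      for (int i = 0; i + span - 1 < n; ++i) {
        int j = i + span - 1;
        int pc = pair_code(s[i], s[j]);
        if (pc < 0) continue;
        double best = hairpinE[j - i - 1 - 1];  // loop length j-i-1, 1-based
        for (int p = i + 1; p <= j - 2; ++p) {
          int l1 = p - i - 1;
          if (l1 > max_loop) break;
          for (int q = j - 1; q >= p + 1; --q) {
            int l2 = j - q - 1;
            if (l1 + l2 > max_loop) break;
            double vin = v(p, q);
            if (vin >= INF / 2) continue;
            double e = loop_energy(pc, l1, l2, pair_code(s[p], s[q]));
            if (vin + e < best) best = vin + e;
          }
        }
        v(i, j) = best;
      }
    }
    // exterior: ext[i] = min energy of suffix i..n-1
    for (int i = n - 1; i >= 0; --i) {
      double best = ext[i + 1];
      for (int j = i + min_hairpin + 1; j < n; ++j) {
        double vi = v(i, j);
        if (vi < INF / 2 && vi + ext[j + 1] < best) best = vi + ext[j + 1];
      }
      ext[i] = best;
    }
  }

  void trace_v(int i, int j, std::string& db) {
    db[i] = '(';
    db[j] = ')';
    int pc = pair_code(s[i], s[j]);
    double target = v(i, j);
    for (int p = i + 1; p <= j - 2; ++p) {
      int l1 = p - i - 1;
      if (l1 > max_loop) break;
      for (int q = j - 1; q >= p + 1; --q) {
        int l2 = j - q - 1;
        if (l1 + l2 > max_loop) break;
        double vin = v(p, q);
        if (vin >= INF / 2) continue;
        double e = loop_energy(pc, l1, l2, pair_code(s[p], s[q]));
        if (vin + e <= target + EPS) {
          trace_v(p, q, db);
          return;
        }
      }
    }
    // hairpin loop: nothing more to mark
  }

  std::string trace() {
    std::string db(n, '.');
    int i = 0;
    while (i < n) {
      bool paired = false;
      for (int j = i + min_hairpin + 1; j < n; ++j) {
        double vi = v(i, j);
        if (vi < INF / 2 && vi + ext[j + 1] <= ext[i] + EPS) {
          trace_v(i, j, db);
          i = j + 1;
          paired = true;
          break;
        }
      }
      if (!paired) i += 1;  // ext[i] == ext[i+1]
    }
    return db;
  }
};

// [[Rcpp::export]]
List c_fold_mfe(IntegerVector seq_codes, NumericMatrix stack,
                NumericVector hairpinE, NumericVector bulgeE,
                NumericVector internalE, int min_hairpin, int max_loop) {
  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  FoldCtx ctx(s, stack, hairpinE, bulgeE, internalE, min_hairpin, max_loop);
  ctx.fill();
  double mfe = ctx.ext[0];
  std::string db = ctx.trace();
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
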