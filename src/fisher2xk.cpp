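#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact two-sided p-value for a 2 x k contingency table with fixed margins,
// under the probability-mass ordering: p = sum of multivariate-hypergeometric
// probabilities of all tables (same column totals, same alt-allele total)
// whose probability is <= that of the observed table, with a small relative
// tolerance so exact ties are always included.
//
// The search runs column by column over the alt-allele composition. Two
// dynamic-programming tables give, for every (column, remaining alt count),
// the maximum and minimum achievable sum of log-binomial terms over the
// remaining columns. A subtree whose maximum is below the threshold is wholly
// extreme and its total mass collapses to a single binomial coefficient
// (Vandermonde identity); a subtree whose minimum is above the threshold
// contributes nothing. Only subtrees straddling the threshold are expanded.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lchoose_(double n, double k) {
  if (k < 0 || k > n) return NEG_INF;
  return std::lgamma(n + 1.0) - std::lgamma(k + 1.0) - std::lgamma(n - k + 1.0);
}

struct FisherCtx {
  int k;
  std::vector<int> tot;      // column totals
  std::vector<int> sufTot;   // sufTot[j] = sum of tot[j..k-1]
  int A;                     // total alt alleles
  double logDenom;           // lchoose(N, A)
  double thresh;             // logPobs + tie tolerance
  std::vector<std::vector<double>> maxS, minS; // [j][s]
  long double acc;           // accumulated extreme probability
  long double excluded;      // accumulated certified non-extreme probability
  long double ignored;       // mass skipped under the truncation threshold
  double epsNode;            // per-subtree truncation threshold
  double massTol;            // stop once unresolved mass falls below this
  long long nodes, budget;
  bool overflow, done;
};

static void dfs(FisherCtx &ctx, int j, int s, double logAcc) {
  if (ctx.overflow || ctx.done) return;
  if (++ctx.nodes > ctx.budget) { ctx.overflow = true; return; }
  if (ctx.massTol > 0.0 && (ctx.nodes & 1023) == 0 &&
      (double)((long double)1.0 - ctx.excluded - ctx.acc) <= ctx.massTol) {
    ctx.done = true;           // unresolved mass already below tolerance
    return;
  }
  if (j == ctx.k) {             // s == 0 guaranteed by feasibility bounds
    if (logAcc <= ctx.thresh)
      ctx.acc += std::exp((long double)(logAcc - ctx.logDenom));
    else
      ctx.excluded += std::exp((long double)(logAcc - ctx.logDenom));
    return;
  }
  double mx = ctx.maxS[j][s], mn = ctx.minS[j][s];
  if (mx == NEG_INF) return;    // infeasible
  double lchSuf = lchoose_(ctx.sufTot[j], s);
  double mass = std::exp(logAcc + lchSuf - ctx.logDenom);
  if (logAcc + mx <= ctx.thresh) {
    // every completion is extreme: total mass = C(sufTot[j], s)
    ctx.acc += (long double)mass;
    return;
  }
  if (logAcc + mn > ctx.thresh) {        // no completion is extreme
    ctx.excluded += (long double)mass;
    return;
  }
  if (mass <= ctx.epsNode) {
    // certified truncation: the subtree's entire mass is tallied as
    // unresolved error instead of being enumerated
    ctx.ignored += (long double)mass;
    return;
  }
  int lo = std::max(0, s - (j + 1 < ctx.k ? ctx.sufTot[j + 1] : 0));
  int hi = std::min(ctx.tot[j], s);
  // visit children mode-first (proportional allocation, then outward):
  // the high-mass subtrees get certified first, so the partial-search
  // bounds tighten as fast as possible under a node budget
  int a0 = (int)std::lround((double)s * ctx.tot[j] / ctx.sufTot[j]);
  if (a0 < lo) a0 = lo;
  if (a0 > hi) a0 = hi;
  dfs(ctx, j + 1, s - a0, logAcc + lchoose_(ctx.tot[j], a0));
  for (int d = 1; a0 - d >= lo || a0 + d <= hi; ++d) {
    if (a0 + d <= hi)
      dfs(ctx, j + 1, s - (a0 + d), logAcc + lchoose_(ctx.tot[j], a0 + d));
    if (a0 - d >= lo)
      dfs(ctx, j + 1, s - (a0 - d), logAcc + lchoose_(ctx.tot[j], a0 - d));
    if (ctx.overflow) return;
  }
}

// [[Rcpp::export(name = ".fisher2xk_exact_cpp")]]
List fisher2xk_exact_cpp(IntegerVector alt, IntegerVector tot,
                         double relTol = 1e-7, double nodeBudget = 5e7,
                         double massTol = 0.0) {
  int k = tot.size();
  if (alt.size() != k) stop("alt and tot must have equal length");
  FisherCtx ctx;
  ctx.k = k;
  // visit columns in descending total order: larger columns first give
  // tighter bounds and stronger pruning (the p-value is invariant to
  // column permutation)
  std::vector<int> ord(k);
  for (int i = 0; i < k; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return tot[a] > tot[b]; });
  ctx.tot.resize(k);
  std::vector<int> altS(k);
  for (int i = 0; i < k; ++i) {
    ctx.tot[i] = tot[ord[i]];
    altS[i] = alt[ord[i]];
  }
  ctx.A = 0;
  int N = 0;
  double logPobs = 0.0;
  for (int i = 0; i < k; ++i) {
    if (ctx.tot[i] <= 0) stop("zero-total columns must be dropped before testing");
    if (altS[i] < 0 || altS[i] > ctx.tot[i]) stop("invalid cell counts");
    ctx.A += altS[i];
    N += ctx.tot[i];
    logPobs += lchoose_(ctx.tot[i], altS[i]);
  }
  if (ctx.A == 0 || ctx.A == N || k == 1)
    return List::create(_["p"] = 1.0, _["nodes"] = 0.0, _["ok"] = true,
                        _["lb"] = 1.0, _["ub"] = 1.0);
  ctx.logDenom = lchoose_(N, ctx.A);
  logPobs -= ctx.logDenom;
  ctx.thresh = logPobs + ctx.logDenom + std::log1p(relTol);

  ctx.sufTot.assign(k + 1, 0);
  for (int j = k - 1; j >= 0; --j) ctx.sufTot[j] = ctx.sufTot[j + 1] + ctx.tot[j];

  // DP over suffix columns: extreme values of the log-binomial sum for
  // distributing s alt alleles over columns j..k-1
  ctx.maxS.assign(k + 1, std::vector<double>(ctx.A + 1, NEG_INF));
  ctx.minS.assign(k + 1, std::vector<double>(ctx.A + 1,
                  std::numeric_limits<double>::infinity()));
  ctx.maxS[k][0] = 0.0;
  ctx.minS[k][0] = 0.0;
  for (int j = k - 1; j >= 0; --j) {
    int smax = std::min(ctx.A, ctx.sufTot[j]);
    for (int s = 0; s <= smax; ++s) {
      int lo = std::max(0, s - ctx.sufTot[j + 1]);
      int hi = std::min(ctx.tot[j], s);
      double mx = NEG_INF, mn = std::numeric_limits<double>::infinity();
      for (int a = lo; a <= hi; ++a) {
        if (ctx.maxS[j + 1][s - a] == NEG_INF) continue;
        double lc = lchoose_(ctx.tot[j], a);
        double vmx = lc + ctx.maxS[j + 1][s - a];
        double vmn = lc + ctx.minS[j + 1][s - a];
        if (vmx > mx) mx = vmx;
        if (vmn < mn) mn = vmn;
      }
      ctx.maxS[j][s] = mx;
      ctx.minS[j][s] = (mx == NEG_INF)
        ? std::numeric_limits<double>::infinity() : mn;
    }
  }

  ctx.acc = 0.0;
  ctx.excluded = 0.0;
  ctx.ignored = 0.0;
  ctx.epsNode = (massTol > 0.0) ? massTol / nodeBudget : 0.0;
  ctx.massTol = massTol;
  ctx.nodes = 0;
  ctx.budget = (long long)nodeBudget;
  ctx.overflow = false;
  ctx.done = false;
  dfs(ctx, 0, ctx.A, 0.0);
  double lb = (double)ctx.acc;
  double ub = 1.0 - (double)ctx.excluded;
  if (lb > 1.0) lb = 1.0;
  if (ub > 1.0) ub = 1.0;
  if (ub < lb) ub = lb;          // guard against rounding
  if (ctx.overflow)
    // certified bounds from the partial search: extreme mass found so far
    // and one minus the certified non-extreme mass
    return List::create(_["p"] = NA_REAL, _["nodes"] = (double)ctx.nodes,
                        _["ok"] = false, _["lb"] = lb, _["ub"] = ub,
                        _["ignored"] = (double)ctx.ignored);
  return List::create(_["p"] = lb, _["nodes"] = (double)ctx.nodes,
                      _["ok"] = true, _["lb"] = lb, _["ub"] = ub,
                      _["ignored"] = (double)ctx.ignored);
}
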