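// Evolutionary search over interval rules. The single-rule GA used by the
// iterative rule learner lives here; all randomness comes from R's RNG so a
// set.seed() on the R side makes every run reproducible.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct IntervalRule {
  std::vector<int> g;      // 0-based column indices
  std::vector<double> lo;
  std::vector<double> hi;
  int cls;                 // 1-based class code
};

// uniform integer in [0, n)
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

static void eval_rule(const IntervalRule &r, const NumericMatrix &X,
                      const IntegerVector &y, double cb, double w,
                      double lambda, double &fit, double &cov, double &acc) {
  const int n = X.nrow();
  int matched = 0, correct = 0;
  const size_t np = r.g.size();
  for (int i = 0; i < n; ++i) {
    bool m = true;
    for (size_t j = 0; j < np; ++j) {
      const double v = X(i, r.g[j]);
      if (v < r.lo[j] || v > r.hi[j]) { m = false; break; }
    }
    if (m) {
      ++matched;
      if (y[i] == r.cls) ++correct;
    }
  }
  cov = n > 0 ? (double)matched / n : 0.0;
  acc = matched > 0 ? (double)correct / matched : 0.0;
  const double ct = cov < cb ? cov / cb : 1.0 + w * (cov - cb);
  fit = acc * ct - lambda * (double)np;
}

static bool has_gene(const IntervalRule &r, int g) {
  return std::find(r.g.begin(), r.g.end(), g) != r.g.end();
}

// interval centred on a sample value, width = frac of the observed range
static void add_seed_predicate(IntervalRule &r, int g, double centre,
                               double rmin, double rmax, double frac) {
  double range = rmax - rmin;
  if (range <= 0) range = 1.0;
  r.g.push_back(g);
  r.lo.push_back(centre - 0.5 * frac * range);
  r.hi.push_back(centre + 0.5 * frac * range);
}

static IntervalRule seed_rule(const NumericMatrix &X, const IntegerVector &y,
                              const NumericVector &cmin, const NumericVector &cmax,
                              int max_init, double init_frac) {
  IntervalRule r;
  const int n = X.nrow(), p = X.ncol();
  const int e = runif_int(n);
  r.cls = y[e];
  int k = 1 + runif_int(std::min(max_init, p));
  // sample k distinct genes
  std::vector<int> pool(p);
  for (int j = 0; j < p; ++j) pool[j] = j;
  for (int j = 0; j < k; ++j) {
    const int pick = j + runif_int(p - j);
    std::swap(pool[j], pool[pick]);
    add_seed_predicate(r, pool[j], X(e, pool[j]), cmin[pool[j]], cmax[pool[j]],
                       init_frac);
  }
  return r;
}

static void mutate_rule(IntervalRule &r, const NumericMatrix &X,
                        const IntegerVector &y, const NumericVector &cmin,
                        const NumericVector &cmax, double p_generalize,
                        double init_frac, int max_preds) {
  const int n = X.nrow(), p = X.ncol();
  const size_t np = r.g.size();
  // perturb one bound of one predicate
  if (np > 0) {
    const int j = runif_int((int)np);
    const double step = 0.1 * (cmax[r.g[j]] - cmin[r.g[j]]);
    if (unif_rand() < 0.5) r.lo[j] += norm_rand() * step;
    else                   r.hi[j] += norm_rand() * step;
    if (r.lo[j] > r.hi[j]) std::swap(r.lo[j], r.hi[j]);
  }
  if (unif_rand() < p_generalize) {
    // generalize: drop a predicate or widen a bound to the observed extreme
    if (np == 0) return;
    const int j = runif_int((int)np);
    if (unif_rand() < 0.5) {
      r.g.erase(r.g.begin() + j);
      r.lo.erase(r.lo.begin() + j);
      r.hi.erase(r.hi.begin() + j);
    } else if (unif_rand() < 0.5) {
      r.lo[j] = cmin[r.g[j]];
    } else {
      r.hi[j] = cmax[r.g[j]];
    }
  } else {
    // specialize: add a predicate on an unused gene, or narrow a bound
    bool can_add = (int)np < max_preds && (int)np < p;
    if (can_add && (np == 0 || unif_rand() < 0.5)) {
      int g = runif_int(p);
      for (int tries = 0; tries < 10 && has_gene(r, g); ++tries) g = runif_int(p);
      if (!has_gene(r, g)) {
        // centre on a matched example when one exists, else a random one
        int e = -1;
        for (int i = 0; i < n; ++i) {
          bool m = true;
          for (size_t jj = 0; jj < r.g.size(); ++jj) {
            const double v = X(i, r.g[jj]);
            if (v < r.lo[jj] || v > r.hi[jj]) { m = false; break; }
          }
          if (m && (e < 0 || unif_rand() < 0.25)) e = i;
        }
        if (e < 0) e = runif_int(n);
        add_seed_predicate(r, g, X(e, g), cmin[g], cmax[g], init_frac);
      }
    } else if (np > 0) {
      const int j = runif_int((int)np);
      const double mid = 0.5 * (r.lo[j] + r.hi[j]);
      if (unif_rand() < 0.5) r.lo[j] = 0.5 * (r.lo[j] + mid);
      else                   r.hi[j] = 0.5 * (r.hi[j] + mid);
    }
  }
}

static IntervalRule crossover_rules(const IntervalRule &a, const IntervalRule &b,
                                    int max_preds) {
  // one-point crossover on the two predicate collections
  IntervalRule child;
  child.cls = a.cls;
  const int na = (int)a.g.size(), nb = (int)b.g.size();
  const int i = runif_int(na + 1);
  const int j = runif_int(nb + 1);
  for (int k = 0; k < i; ++k) {
    child.g.push_back(a.g[k]); child.lo.push_back(a.lo[k]); child.hi.push_back(a.hi[k]);
  }
  for (int k = j; k < nb; ++k) {
    if ((int)child.g.size() >= max_preds) break;
    if (!has_gene(child, b.g[k])) {
      child.g.push_back(b.g[k]); child.lo.push_back(b.lo[k]); child.hi.push_back(b.hi[k]);
    }
  }
  return child;
}

// [[Rcpp::export(name = ".evolve_rule_cpp")]]
List evolve_rule_cpp(NumericMatrix X, IntegerVector y, List params) {
  const int pop_size    = as<int>(params["population_size"]);
  const int generations = as<int>(params["ga_generations"]);
  const int tourn       = as<int>(params["tournament_size"]);
  const double cx_prob  = as<double>(params["crossover_prob"]);
  const double mut_prob = as<double>(params["mutation_prob"]);
  const double p_gen    = as<double>(params["p_generalize"]);
  const double cb       = as<double>(params["coverage_breakpoint"]);
  const double w        = as<double>(params["coverage_slope_after"]);
  const double lambda   = as<double>(params["complexity_weight"]);
  const double initfrac = as<double>(params["init_fraction"]);
  const int max_init    = as<int>(params["max_init_predicates"]);
  const int max_preds   = as<int>(params["max_predicates"]);

  const int p = X.ncol();
  NumericVector cmin(p), cmax(p);
  for (int j = 0; j < p; ++j) {
    double lo = X(0, j), hi = X(0, j);
    for (int i = 1; i < X.nrow(); ++i) {
      if (X(i, j) < lo) lo = X(i, j);
      if (X(i, j) > hi) hi = X(i, j);
    }
    cmin[j] = lo; cmax[j] = hi;
  }

  std::vector<IntervalRule> pop(pop_size);
  std::vector<double> fit(pop_size), cov(pop_size), acc(pop_size);
  for (int i = 0; i < pop_size; ++i) {
    pop[i] = seed_rule(X, y, cmin, cmax, max_init, initfrac);
    eval_rule(pop[i], X, y, cb, w, lambda, fit[i], cov[i], acc[i]);
  }

  IntervalRule best = pop[0];
  double best_fit = fit[0], best_cov = cov[0], best_acc = acc[0];
  for (int i = 1; i < pop_size; ++i)
    if (fit[i] > best_fit) {
      best = pop[i]; best_fit = fit[i]; best_cov = cov[i]; best_acc = acc[i];
    }

  std::vector<IntervalRule> next(pop_size);
  for (int gen = 0; gen < generations; ++gen) {
    next[0] = best;  // elitism of one
    for (int i = 1; i < pop_size; ++i) {
      // tournament selection
      int pa = runif_int(pop_size);
      for (int t = 1; t < tourn; ++t) {
        const int c = runif_int(pop_size);
        if (fit[c] > fit[pa]) pa = c;
      }
      IntervalRule child;
      if (unif_rand() < cx_prob) {
        int pb = runif_int(pop_size);
        for (int t = 1; t < tourn; ++t) {
          const int c = runif_int(pop_size);
          if (fit[c] > fit[pb]) pb = c;
        }
        child = crossover_rules(pop[pa], pop[pb], max_preds);
      } else {
        child = pop[pa];
      }
      if (unif_rand() < mut_prob)
        mutate_rule(child, X, y, cmin, cmax, p_gen, initfrac, max_preds);
      next[i] = child;
    }
    std::swap(pop, next);
    for (int i = 0; i < pop_size; ++i) {
      eval_rule(pop[i], X, y, cb, w, lambda, fit[i], cov[i], acc[i]);
      if (fit[i] > best_fit) {
        best = pop[i]; best_fit = fit[i]; best_cov = cov[i]; best_acc = acc[i];
      }
    }
  }

  return List::create(
      _["gidx"] = IntegerVector(best.g.begin(), best.g.end()),
      _["lo"] = NumericVector(best.lo.begin(), best.lo.end()),
      _["hi"] = NumericVector(best.hi.begin(), best.hi.end()),
      _["cls"] = best.cls, _["fitness"] = best_fit, _["coverage"] = best_cov,
      _["accuracy"] = best_acc);
}

// matched rows of a single rule (1-based gene indices)
// [[Rcpp::export(name = ".rule_match_cpp")]]
LogicalVector rule_match_cpp(NumericMatrix X, IntegerVector gidx,
                             NumericVector lo, NumericVector hi) {
  const int n = X.nrow(), np = gidx.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool m = true;
    for (int j = 0; j < np; ++j) {
      const double v = X(i, gidx[j] - 1);
      if (v < lo[j] || v > hi[j]) { m = false; break; }
    }
    out[i] = m;
  }
  return out;
}

// first-match decision-list prediction; gidx 1-based; returns class codes
// [[Rcpp::export(name = ".predict_dl_cpp")]]
IntegerVector predict_dl_cpp(NumericMatrix X, List rule_gidx, List rule_lo,
                             List rule_hi, IntegerVector rule_cls,
                             int default_cls) {
  const int n = X.nrow(), nr = rule_gidx.size();
  IntegerVector out(n);
  std::vector<std::vector<int> > G(nr);
  std::vector<std::vector<double> > L(nr), H(nr);
  for (int r = 0; r < nr; ++r) {
    G[r] = as<std::vector<int> >(rule_gidx[r]);
    L[r] = as<std::vector<double> >(rule_lo[r]);
    H[r] = as<std::vector<double> >(rule_hi[r]);
  }
  for (int i = 0; i < n; ++i) {
    int cls = default_cls;
    for (int r = 0; r < nr; ++r) {
      bool m = true;
      for (size_t j = 0; j < G[r].size(); ++j) {
        const double v = X(i, G[r][j] - 1);
        if (v < L[r][j] || v > H[r][j]) { m = false; break; }
      }
      if (m) { cls = rule_cls[r]; break; }
    }
    out[i] = cls;
  }
  return out;
}
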