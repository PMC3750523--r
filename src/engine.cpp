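// Event-driven exact SSA with delayed product release (direct method +
// time-ordered waitlist). Rates: mass-action constants, INSTANT (fired as a
// deterministic fixpoint after every state change), promoter-repression
// (k / (1 + P/K)), or an arbitrary R function of the state. All randomness
// goes through R's RNG so set.seed() gives bit-identical trajectories.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Wait {
  double t;
  int spec;
  int count;
};
struct WaitCmp {
  bool operator()(const Wait& a, const Wait& b) const { return a.t > b.t; }
};

struct Entry {
  int s;  // species index
  int v;  // stoichiometric count
};

typedef std::vector<Entry> Sparse;

Sparse sparsify(const IntegerMatrix& m, int j) {
  Sparse out;
  for (int s = 0; s < m.nrow(); ++s)
    if (m(s, j) > 0) out.push_back(Entry{s, m(s, j)});
  return out;
}

double draw_delay_c(int fam, double p1, double p2) {
  switch (fam) {
    case 1:
      return p1;
    case 2:
      return R::rgamma(p1, p2);
    case 3: {
      double x = R::rnorm(p1, p2);
      int tries = 0;
      while (x < 0.0 && ++tries < 1000000) x = R::rnorm(p1, p2);
      return x < 0.0 ? 0.0 : x;
    }
    default:
      return 0.0;
  }
}

}  // namespace

// [[Rcpp::export]]
List sim_engine(IntegerMatrix reactants, IntegerMatrix products,
                IntegerMatrix prop_stoich, IntegerMatrix delayed,
                IntegerVector rate_type, NumericVector rate_const,
                NumericVector rep_K, IntegerVector rep_spec, List rate_funs,
                IntegerVector delay_family, NumericVector delay_p1,
                NumericVector delay_p2, LogicalVector delay_shared,
                IntegerVector instant_order, CharacterVector rxn_names,
                CharacterVector species, IntegerVector init, double t_end,
                double dt, bool record_events, double step_limit) {
  const int nspec = species.size();
  const int nrxn = rate_type.size();
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<Sparse> reac(nrxn), imm(nrxn), del(nrxn), prop(nrxn);
  std::vector<int> noninstant;
  for (int j = 0; j < nrxn; ++j) {
    reac[j] = sparsify(reactants, j);
    del[j] = sparsify(delayed, j);
    prop[j] = sparsify(prop_stoich, j);
    // immediate products = products - delayed
    for (int s = 0; s < nspec; ++s) {
      int v = products(s, j) - delayed(s, j);
      if (v > 0) imm[j].push_back(Entry{s, v});
      if (v < 0) stop("delayed product stoichiometry exceeds products");
    }
    if (rate_type[j] != 1) noninstant.push_back(j);
  }

  std::vector<long long> x(init.begin(), init.end());
  std::vector<double> firings(nrxn, 0.0);
  std::priority_queue<Wait, std::vector<Wait>, WaitCmp> waitlist;
  double clock = 0.0;
  std::vector<double> ev_t;
  std::vector<int> ev_r;

  RNGScope scope;

  // propensity of a non-instant reaction
  auto propensity = [&](int j) -> double {
    double a;
    switch (rate_type[j]) {
      case 0: {  // mass action: k * prod_s C(x_s, nu_s)
        a = rate_const[j];
        for (size_t e = 0; e < prop[j].size(); ++e) {
          long long xs = x[prop[j][e].s];
          int v = prop[j][e].v;
          if (xs < v) return 0.0;
          for (int i = 0; i < v; ++i) a *= double(xs - i) / double(i + 1);
        }
        break;
      }
      case 2:  // repression: kmax / (1 + P / K)
        a = rate_const[j] / (1.0 + double(x[rep_spec[j]]) / rep_K[j]);
        break;
      case 3: {  // user R function of the state
        IntegerVector st(nspec);
        for (int s = 0; s < nspec; ++s) st[s] = (int)x[s];
        st.names() = species;
        Function f = rate_funs[j];
        a = as<double>(f(st));
        break;
      }
      default:
        a = 0.0;
    }
    if (!std::isfinite(a) || a < 0.0)
      stop("non-finite or negative propensity in reaction '%s'",
           as<std::string>(rxn_names[j]).c_str());
    return a;
  };

  auto applicable = [&](int j) -> bool {
    for (size_t e = 0; e < reac[j].size(); ++e)
      if (x[reac[j][e].s] < reac[j][e].v) return false;
    return true;
  };

  auto fire = [&](int j) {
    for (size_t e = 0; e < reac[j].size(); ++e) {
      if (x[reac[j][e].s] < reac[j][e].v)
        stop("reaction '%s' would drive species '%s' negative",
             as<std::string>(rxn_names[j]).c_str(),
             as<std::string>(species[reac[j][e].s]).c_str());
      x[reac[j][e].s] -= reac[j][e].v;
    }
    for (size_t e = 0; e < imm[j].size(); ++e) x[imm[j][e].s] += imm[j][e].v;
    if (!del[j].empty()) {
      if (delay_shared[j]) {
        double tau = draw_delay_c(delay_family[j], delay_p1[j], delay_p2[j]);
        for (size_t e = 0; e < del[j].size(); ++e)
          waitlist.push(Wait{clock + tau, del[j][e].s, del[j][e].v});
      } else {
        for (size_t e = 0; e < del[j].size(); ++e)
          for (int m = 0; m < del[j][e].v; ++m) {
            double tau =
                draw_delay_c(delay_family[j], delay_p1[j], delay_p2[j]);
            waitlist.push(Wait{clock + tau, del[j][e].s, 1});
          }
      }
    }
    firings[j] += 1.0;
    if (record_events) {
      ev_t.push_back(clock);
      ev_r.push_back(j + 1);
    }
  };

  // deterministic fixpoint over INSTANT reactions in the given priority order
  auto resolve_instants = [&]() {
    if (instant_order.size() == 0) return;
    long guard = 0;
    bool again = true;
    while (again) {
      again = false;
      for (int k = 0; k < instant_order.size(); ++k) {
        int j = instant_order[k];
        if (applicable(j)) {
          fire(j);
          if (++guard > 50000000L)
            stop("instant reaction cascade did not terminate (cycle?)");
          again = true;
          break;  // restart scan so higher-priority reactions fire first
        }
      }
    }
  };

  const int nsamp = (int)std::floor(t_end / dt + 1e-9) + 1;
  IntegerMatrix out(nsamp, nspec);
  int samp = 0;
  auto record_through = [&](double t_ev) {
    while (samp < nsamp && (double)samp * dt <= t_ev + 1e-12) {
      for (int s = 0; s < nspec; ++s) out(samp, s) = (int)x[s];
      ++samp;
    }
  };

  resolve_instants();

  std::vector<double> a(nrxn, 0.0);
  double steps = 0.0;
  for (;;) {
    double A = 0.0;
    for (size_t k = 0; k < noninstant.size(); ++k) {
      int j = noninstant[k];
      a[j] = propensity(j);
      A += a[j];
    }
    double t_rxn = (A > 0.0) ? clock + R::exp_rand() / A : INF;
    double t_wait = waitlist.empty() ? INF : waitlist.top().t;
    double t_ev = std::min(t_rxn, t_wait);

    record_through(std::min(t_ev, INF));
    if (t_ev > t_end || !std::isfinite(t_ev)) break;

    if (t_wait <= t_rxn) {
      Wait w = waitlist.top();
      waitlist.pop();
      clock = w.t;
      x[w.spec] += w.count;
    } else {
      clock = t_rxn;
      double u = R::unif_rand() * A;
      double cum = 0.0;
      int j = -1;
      for (size_t k = 0; k < noninstant.size(); ++k) {
        cum += a[noninstant[k]];
        if (u <= cum) {
          j = noninstant[k];
          break;
        }
      }
      if (j < 0) {  // numerical edge: pick last with positive propensity
        for (int k = (int)noninstant.size() - 1; k >= 0; --k)
          if (a[noninstant[k]] > 0.0) {
            j = noninstant[k];
            break;
          }
        if (j < 0) stop("internal error: no reaction selectable");
      }
      fire(j);
    }
    resolve_instants();
    if (++steps > step_limit)
      stop("step limit (%g events) exceeded before t_end", step_limit);
  }

  IntegerVector pending(nspec);
  while (!waitlist.empty()) {
    pending[waitlist.top().spec] += waitlist.top().count;
    waitlist.pop();
  }

  List res = List::create(
      _["counts"] = out, _["firings"] = NumericVector(wrap(firings)),
      _["pending"] = pending, _["n_events"] = steps);
  if (record_events) {
    res["event_times"] = NumericVector(wrap(ev_t));
    res["event_reaction"] = IntegerVector(wrap(ev_r));
  }
  return res;
}
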