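#include <Rcpp.h>
using namespace Rcpp;

// strategy codes: 1 coop-all, 2 coop-green, 3 coop-blue, 4 defect-all
// label codes: 0 blue, 1 green
static inline int act(int s, int lab) {
  switch (s) {
  case 1: return 1;
  case 2: return lab == 1;
  case 3: return lab == 0;
  default: return 0;
  }
}

static inline double payoff_one(int i, const int* ptr, const int* idx,
                                const int* lab, const int* strat, double b) {
  double p = 0.0;
  for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
    int j = idx[e];
    p += b * act(strat[j], lab[i]) - act(strat[i], lab[j]);
  }
  return p;
}

// [[Rcpp::export]]
NumericVector payoffs_cpp(IntegerVector ptr, IntegerVector idx,
                          IntegerVector labels, IntegerVector strategies,
                          double b) {
  int n = labels.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = payoff_one(i, ptr.begin(), idx.begin(), labels.begin(),
                        strategies.begin(), b);
  }
  return out;
}

// number of realized directed donations S_i(lambda_j) over all directed edges
// [[Rcpp::export]]
double donations_cpp(IntegerVector ptr, IntegerVector idx,
                     IntegerVector labels, IntegerVector strategies) {
  int n = labels.size();
  double d = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
      d += act(strategies[i], labels[idx[e]]);
    }
  }
  return d;
}

// Asynchronous event loop. Per event the RNG is consumed in fixed order:
// (1) focal agent uniform over `active`, (2) mutation coin, (3) either the
// uniform strategy draw (mutation) or the fitness-proportional neighbour
// draw (imitation). Selection weights are exp(w * (p - pmax)) accumulated in
// long double to mirror R's sum()/cumsum(), keeping the R and C++ paths
// bit-identical under equal seeds. w = Inf selects uniformly among
// co-maximal neighbours.
// [[Rcpp::export]]
List run_events_cpp(IntegerVector ptr, IntegerVector idx,
                    IntegerVector labels, IntegerVector strategies,
                    IntegerVector active, double b, double w, double mu,
                    double n_events, NumericVector sample_at) {
  const int* P = ptr.begin();
  const int* X = idx.begin();
  const int* L = labels.begin();
  IntegerVector strat = clone(strategies);
  int* S = strat.begin();
  const int n_act = active.size();
  const int n = labels.size();
  const double n_edges = (double)ptr[n];
  const bool winf = !R_finite(w) && w > 0;
  const long long total = (long long)n_events;
  const int n_samp = sample_at.size();

  NumericVector samp_t(n_samp), samp_pay(n_samp);
  IntegerMatrix samp_counts(n_samp, 4);
  int next_samp = 0;

  std::vector<double> pbuf(64);
  std::vector<long double> wbuf(64);

  RNGScope scope;
  for (long long t = 1; t <= total; ++t) {
    double u1 = unif_rand();
    int fi = (int)(u1 * n_act);
    if (fi >= n_act) fi = n_act - 1;
    int f = active[fi];
    double u2 = unif_rand();
    if (u2 < mu) {
      double u3 = unif_rand();
      int s = 1 + (int)(u3 * 4.0);
      if (s > 4) s = 4;
      S[f] = s;
    } else {
      int d = P[f + 1] - P[f];
      if (d == 0)
        stop("agent %d has no neighbours; imitation undefined", f + 1);
      if ((int)pbuf.size() < d) { pbuf.resize(d); wbuf.resize(d); }
      double pmax = R_NegInf;
      for (int e = 0; e < d; ++e) {
        double p = payoff_one(X[P[f] + e], P, X, L, S, b);
        pbuf[e] = p;
        if (p > pmax) pmax = p;
      }
      long double tot = 0.0L;
      for (int e = 0; e < d; ++e) {
        long double wt = winf ? (long double)(pbuf[e] == pmax)
                              : (long double)std::exp(w * (pbuf[e] - pmax));
        wbuf[e] = wt;
        tot += wt;
      }
      double u3 = unif_rand();
      long double target = (long double)u3 * tot;
      long double cum = 0.0L;
      int pick = d - 1;
      for (int e = 0; e < d; ++e) {
        cum += wbuf[e];
        if (cum >= target) { pick = e; break; }
      }
      S[f] = S[X[P[f] + pick]];
    }
    if (next_samp < n_samp && (double)t >= sample_at[next_samp]) {
      while (next_samp < n_samp && (double)t >= sample_at[next_samp]) {
        samp_t[next_samp] = (double)t;
        double don = 0.0;
        int c1 = 0, c2 = 0, c3 = 0, c4 = 0;
        for (int i = 0; i < n; ++i) {
          for (int e = P[i]; e < P[i + 1]; ++e)
            don += act(S[i], L[X[e]]);
          switch (S[i]) {
          case 1: ++c1; break;
          case 2: ++c2; break;
          case 3: ++c3; break;
          default: ++c4;
          }
        }
        samp_pay[next_samp] = n_edges > 0 ? don / n_edges : NA_REAL;
        samp_counts(next_samp, 0) = c1;
        samp_counts(next_samp, 1) = c2;
        samp_counts(next_samp, 2) = c3;
        samp_counts(next_samp, 3) = c4;
        ++next_samp;
      }
    }
  }
  return List::create(_["strategies"] = strat,
                      _["sample_t"] = samp_t,
                      _["sample_payoff_norm"] = samp_pay,
                      _["sample_counts"] = samp_counts);
}
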