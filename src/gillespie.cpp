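// Event-based (Gillespie) evolution of one sequence along one branch.
//
// Sequence encoding: 1..K = alphabet states, 0 = gap. Site rates travel with
// the sequence; gap positions carry rate 0. Uses R's RNG (unif_rand etc.) so
// results are reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// inverse-CDF draw from a cumulative table (support 1..n)
inline int draw_from_cdf(const NumericVector &cdf) {
  double u = unif_rand();
  int lo = 0, hi = cdf.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (u <= cdf[mid]) hi = mid; else lo = mid + 1;
  }
  return lo + 1;
}

struct RateSampler {
  int mode;           // 1 categorical, 2 continuous Gamma
  double p_inv, alpha, scale;
  NumericVector cat_cdf, cat_rates;
  double draw() const {
    if (p_inv > 0 && unif_rand() < p_inv) return 0.0;
    if (mode == 2) return R::rgamma(alpha, 1.0 / alpha) * scale;
    return cat_rates[draw_from_cdf(cat_cdf) - 1];
  }
};

} // namespace

// [[Rcpp::export]]
List gillespie_branch_cpp(IntegerVector code0, NumericVector rates0,
                          double t, NumericMatrix Q, NumericVector pi,
                          double r_ins, double r_del, double u_del,
                          NumericVector ins_cdf, NumericVector del_cdf,
                          int rate_mode, double p_inv, double alpha,
                          double rate_scale, NumericVector cat_cdf,
                          NumericVector cat_rates, bool do_subst) {
  const int K = Q.nrow();
  const int n0 = code0.size();
  std::vector<int> y(code0.begin(), code0.end());
  std::vector<double> r(rates0.begin(), rates0.end());
  std::vector<double> w(n0); // per-site substitution weight -q_xx * r
  RateSampler rs{rate_mode, p_inv, alpha, rate_scale, cat_cdf, cat_rates};

  long L = 0;
  double S = 0.0;
  for (int i = 0; i < n0; ++i) {
    if (y[i] > 0) {
      ++L;
      w[i] = do_subst ? -Q(y[i] - 1, y[i] - 1) * r[i] : 0.0;
      S += w[i];
    } else {
      w[i] = 0.0;
    }
  }

  std::vector<int> ev_pos, ev_len;
  long n_sub = 0, n_ins = 0, n_del = 0, n_events = 0;
  double trem = t;
  NumericVector pi_cdf(K);
  {
    double c = 0;
    for (int k = 0; k < K; ++k) { c += pi[k]; pi_cdf[k] = c; }
    pi_cdf[K - 1] = 1.0;
  }

  while (trem > 0) {
    if (L == 0) break; // all-gap sequence: branch ends here
    if (!do_subst) S = 0.0;
    double I = r_ins > 0 ? r_ins * (L + 1) : 0.0;
    double D = r_del > 0 ? r_del * (L - 1 + u_del) : 0.0;
    double M = S + I + D;
    if (M <= 0) break;
    double wt = exp_rand() / M; // waiting time, mean 1/M
    if (wt > trem) break;
    trem -= wt;
    double u = unif_rand() * M;

    if (u < S) {
      // ---- substitution ----
      double target = unif_rand() * S;
      double acc = 0.0;
      size_t i = 0, last = 0;
      bool found = false;
      for (; i < y.size(); ++i) {
        if (w[i] > 0) {
          last = i;
          acc += w[i];
          if (acc >= target) { found = true; break; }
        }
      }
      if (!found) i = last; // float drift guard
      int x = y[i];
      double qx = -Q(x - 1, x - 1);
      double t2 = unif_rand() * qx, acc2 = 0.0;
      int z = x;
      for (int c = 1; c <= K; ++c) {
        if (c == x) continue;
        acc2 += Q(x - 1, c - 1);
        z = c;
        if (acc2 >= t2) break;
      }
      S += (Q(x - 1, x - 1) - Q(z - 1, z - 1)) * r[i];
      y[i] = z;
      w[i] = -Q(z - 1, z - 1) * r[i];
      ++n_sub;
    } else if (u < S + I) {
      // ---- insertion ----
      long slot = (long)(unif_rand() * (L + 1)) + 1;
      if (slot > L + 1) slot = L + 1;
      int j = draw_from_cdf(ins_cdf);
      // column index: new block goes immediately before the slot-th non-gap
      // residue; slot L+1 appends at the very end of the row
      size_t pos = y.size();
      if (slot <= L) {
        long seen = 0;
        for (size_t q = 0; q < y.size(); ++q) {
          if (y[q] > 0 && ++seen == slot) { pos = q; break; }
        }
      }
      std::vector<int> z(j);
      std::vector<double> s(j), wnew(j);
      for (int q = 0; q < j; ++q) z[q] = draw_from_cdf(pi_cdf);
      for (int q = 0; q < j; ++q) {
        s[q] = rs.draw();
        wnew[q] = do_subst ? -Q(z[q] - 1, z[q] - 1) * s[q] : 0.0;
        S += wnew[q];
      }
      y.insert(y.begin() + pos, z.begin(), z.end());
      r.insert(r.begin() + pos, s.begin(), s.end());
      w.insert(w.begin() + pos, wnew.begin(), wnew.end());
      ev_pos.push_back((int)pos + 1); // 1-based column of the new block
      ev_len.push_back(j);
      L += j;
      ++n_ins;
    } else {
      // ---- deletion ----
      int j = draw_from_cdf(del_cdf);
      long start = (long)(unif_rand() * L) + 1;
      if (start > L) start = L;
      long seen = 0;
      int removed = 0;
      for (size_t q = 0; q < y.size() && removed < j; ++q) {
        if (y[q] > 0) {
          ++seen;
          if (seen >= start) {
            S -= w[q];
            y[q] = 0;
            r[q] = 0.0;
            w[q] = 0.0;
            ++removed; // truncates silently at the sequence end
          }
        }
      }
      L -= removed;
      ++n_del;
    }
    if (++n_events % 1000000 == 0 && do_subst) {
      // cap drift of the incremental S updates
      S = 0.0;
      for (size_t q = 0; q < y.size(); ++q) S += w[q];
    }
  }

  IntegerMatrix events(ev_pos.size(), 2);
  for (size_t e = 0; e < ev_pos.size(); ++e) {
    events(e, 0) = ev_pos[e];
    events(e, 1) = ev_len[e];
  }
  colnames(events) = CharacterVector::create("pos", "len");
  return List::create(
    _["code"] = IntegerVector(y.begin(), y.end()),
    _["rates"] = NumericVector(r.begin(), r.end()),
    _["events"] = events,
    _["counts"] = IntegerVector::create(_["n_sub"] = (int)n_sub,
                                        _["n_ins"] = (int)n_ins,
                                        _["n_del"] = (int)n_del));
}
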