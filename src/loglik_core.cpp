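// Numerical core of the island-wide likelihood: propagates the vector of
// consistency probabilities Q[n, e] between observed events, where n is the
// number of hidden island species (alive now, leaving no sampled extant
// descendant) and e the number of observed endemic singleton lineages that
// have not yet acquired their endemizing event. The generator is a Metzler
// matrix; the action of its exponential is computed by uniformization
// (a positive Taylor series, no cancellation), with the accumulated log
// normalizer returned separately so that event multiplications by small
// rates cannot underflow.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double rate_dd(double r0, double N, double K) {
  if (!R_finite(K)) return r0;
  double v = r0 * (1.0 - N / K);
  return v > 0.0 ? v : 0.0;
}

// Extinction probability within time t of a single birth-death lineage at
// birth rate lambda (an upper bound on the diversity-dependent rate) and
// death rate mu. Used only to weight the adaptive truncation criterion.
static double p_extinct(double lambda, double mu, double t) {
  if (mu <= 0.0 || t <= 0.0) return 0.0;
  double r = lambda - mu;
  double p;
  if (std::fabs(r) * t < 1e-8) {
    p = mu * t / (1.0 + mu * t);
  } else if (r * t > 700.0) {
    p = mu / lambda;
  } else {
    double e = std::exp(r * t);
    p = mu * (e - 1.0) / (lambda * e - mu);
  }
  if (p < 0.0) p = 0.0;
  if (p >= 1.0) p = 1.0 - 1e-12;
  return p;
}

struct Gen {
  int nmax, n_hi, eact, k, kne, stride;
  double lambda0, mu, K, gamma0, la;
  double Mfound, Mreset;
  // per-interval precomputed coefficient arrays, indexed by hidden count n
  std::vector<double> lamN, gamN, lamNm1, diag0, birth0, death;

  // Fill coefficient arrays for the current (k, kne, multiplicities); the
  // state range is restricted to n <= n_hi (n + k can never exceed the
  // diversity cap, because the birth rates vanish there).
  void prepare() {
    int nn = n_hi + 1;
    lamN.assign(nn, 0.0); gamN.assign(nn, 0.0); lamNm1.assign(nn, 0.0);
    diag0.assign(nn, 0.0); birth0.assign(nn, 0.0); death.assign(nn, 0.0);
    for (int n = 0; n < nn; ++n) {
      double N = n + k;
      lamN[n] = rate_dd(lambda0, N, K);
      gamN[n] = rate_dd(gamma0, N, K);
      lamNm1[n] = (n > 0) ? lamN[n - 1] : rate_dd(lambda0, k - 1.0, K);
      diag0[n] = (Mfound + Mreset) * gamN[n] + (lamN[n] + mu) * N;
      if (n > 0) birth0[n] = Mfound * gamN[n - 1] + lamN[n - 1] * (n - 1);
      death[n] = mu * (n + 1);
    }
  }

  // y = A x, restricted to n <= hi (the support of x plus one state)
  void apply(const std::vector<double>& x, std::vector<double>& y,
             int hi) const {
    for (int e = 0; e <= eact; ++e) {
      int g = k - kne - e;
      if (g < 0) g = 0;
      double two_g = 2.0 * g;
      double la_e = la * (e + kne);
      const double* xe = x.data() + (size_t)e * stride;
      const double* xe1 = (e < eact) ? xe + stride : nullptr;
      double* ye = y.data() + (size_t)e * stride;
      for (int n = 0; n <= hi; ++n) {
        double acc = -(diag0[n] + la_e) * xe[n];
        if (n > 0) {
          // an observed lineage's split leaves either daughter as the
          // continuing observed lineage: each grower counts twice
          acc += (birth0[n] + lamNm1[n] * two_g) * xe[n - 1];
          if (xe1) acc += lamNm1[n] * 2.0 * (e + 1) * xe1[n - 1];
        }
        if (xe1) acc += la * (e + 1) * xe1[n];
        if (n < n_hi) acc += death[n] * xe[n + 1];
        ye[n] = acc;
      }
    }
  }

  // topmost state with mass, across pending columns (support is exact:
  // unreachable entries are kept at hard zero)
  int support(const std::vector<double>& x) const {
    int live = 0;
    for (int e = 0; e <= eact; ++e) {
      const double* xe = x.data() + (size_t)e * stride;
      for (int n = n_hi; n > live; --n) {
        if (xe[n] != 0.0) { if (n > live) live = n; break; }
      }
    }
    return live;
  }

  double max_diag() const {
    double cmax = 0.0;
    for (int n = 0; n <= n_hi; ++n)
      if (diag0[n] > cmax) cmax = diag0[n];
    return cmax + la * (eact + kne);
  }
};

// exp(A*dt) applied to q by uniformization; q is renormalized to max 1 and
// the log factor accumulated in logscale. Returns false if the vector
// vanishes (data impossible).
static bool propagate_unif(const Gen& gen, std::vector<double>& q,
                           double& logscale, double dt, double tol) {
  if (dt <= 0.0) return true;
  double cmax = gen.max_diag();
  // the grower inflow (2g) exceeds the outflow by up to lambda0 * k, so the
  // series hump can sit beyond cmax * h; widen the term target accordingly
  double cnorm = cmax + gen.lambda0 * gen.k;
  if (cnorm * dt < 1e-300) return true; // generator is (numerically) zero
  size_t len = q.size();
  int nsub = (int)std::ceil(cnorm * dt / 30000.0);
  if (nsub < 1) nsub = 1;
  double h = dt / nsub;
  std::vector<double> v(len), w(len), s(len);
  int live = gen.support(q);
  for (int sub = 0; sub < nsub; ++sub) {
    double target = cnorm * h;
    s = q;
    v = q;
    double local_log = 0.0;
    int maxit = (int)(target + 12.0 * std::sqrt(target + 1.0) + 50.0);
    for (int j = 1; j <= maxit; ++j) {
      // the generator couples nearest hidden counts only, so the support
      // grows by at most one state per series term
      int hi = live + 1 < gen.n_hi ? live + 1 : gen.n_hi;
      gen.apply(v, w, hi);
      live = hi;
      double f = h / j;
      double sv = 0.0, ss = 0.0;
      for (int e = 0; e <= gen.eact; ++e) {
        size_t off = (size_t)e * gen.stride;
        for (int n = 0; n <= hi; ++n) {
          size_t i = off + n;
          double nv = f * (w[i] + cmax * v[i]);
          v[i] = nv;
          s[i] += nv;
          sv += std::fabs(nv);
          ss += s[i];
        }
      }
      if (ss > 1e280) {
        for (size_t i = 0; i < len; ++i) { s[i] *= 1e-280; v[i] *= 1e-280; }
        local_log += std::log(1e280);
      }
      if (j >= target && sv <= tol * (ss > 0 ? ss : 1.0)) break;
    }
    logscale += local_log - cmax * h;
    double m = 0.0;
    for (size_t i = 0; i < len; ++i) if (s[i] > m) m = s[i];
    if (!(m > 0.0) || !R_finite(m)) return false;
    for (size_t i = 0; i < len; ++i) q[i] = s[i] / m;
    logscale += std::log(m);
  }
  return true;
}

// [[Rcpp::export]]
List propagate_interval_cpp(NumericVector q, double logscale, int nmax, int eact,
                            int k, int kne, double dt, double lambda0, double mu,
                            double K, double gamma0, double la, double Mfound,
                            double Mreset, double tol) {
  Gen gen;
  gen.nmax = nmax; gen.n_hi = nmax; gen.stride = nmax + 1;
  gen.eact = eact; gen.k = k; gen.kne = kne;
  gen.lambda0 = lambda0; gen.mu = mu; gen.K = K; gen.gamma0 = gamma0;
  gen.la = la; gen.Mfound = Mfound; gen.Mreset = Mreset;
  gen.prepare();
  std::vector<double> qq(q.begin(), q.end());
  bool ok = propagate_unif(gen, qq, logscale, dt, tol);
  return List::create(_["q"] = NumericVector(qq.begin(), qq.end()),
                      _["log_scale"] = logscale, _["ok"] = ok);
}

// Full-timeline likelihood driver. Events are ordered by decreasing age.
// ev_type: 0 colonization, 1 branching. ev_status (colonizations only):
// 0 endemic-clade root, 1 non-endemic singleton, 2 endemic singleton
// (pending endemization). ev_mult: event rate multiplicity (1 for
// colonizations; for branchings the number of observed lineages of the
// branching clade just before the event). reset_r: per-interval reset-loss
// multiplicity (0 under the default pooled convention).
// [[Rcpp::export]]
List loglik_core_cpp(double island_age, double M, double lambda0, double mu,
                     double K, double gamma0, double la, NumericVector ev_age,
                     IntegerVector ev_type, IntegerVector ev_status,
                     NumericVector ev_mult, NumericVector reset_r, double tol,
                     double tail_tol, bool weighted_tail, int nmax0,
                     int nmax_limit) {
  int nev = ev_age.size();
  bool finiteK = R_finite(K) != 0;
  double cap = finiteK ? std::ceil(K) : R_PosInf;
  int ecap = 0;
  for (int i = 0; i < nev; ++i) if (ev_type[i] == 0 && ev_status[i] == 2) ++ecap;

  int hard_max = nmax_limit;
  if (finiteK && cap < hard_max) hard_max = (int)cap;
  int nmax = nmax0 < hard_max ? nmax0 : hard_max;
  if (nmax < 2) nmax = 2;

  int stride = nmax + 1;
  std::vector<double> q((size_t)stride * (ecap + 1), 0.0);
  q[0] = 1.0;
  double logscale = 0.0;
  int k = 0, kne = 0, eact = 0;
  double age = island_age;
  int final_nmax = nmax;

  Gen gen;
  gen.lambda0 = lambda0; gen.mu = mu; gen.K = K; gen.gamma0 = gamma0; gen.la = la;

  for (int i = 0; i <= nev; ++i) {
    double to_age = (i < nev) ? ev_age[i] : 0.0;
    double dt = age - to_age;
    double rr = reset_r[i];
    // with a finite cap the hidden count can never exceed cap - k
    int n_cap = finiteK ? (int)cap - k : nmax;
    if (n_cap < 0) n_cap = 0;
    for (;;) {
      gen.nmax = nmax; gen.stride = stride;
      gen.n_hi = n_cap < nmax ? n_cap : nmax;
      gen.eact = eact; gen.k = k; gen.kne = kne;
      gen.Mfound = M - rr; gen.Mreset = rr;
      gen.prepare();
      std::vector<double> qsnap = q;
      double lssnap = logscale;
      bool ok = propagate_unif(gen, q, logscale, dt, tol);
      if (!ok)
        return List::create(_["loglik"] = R_NegInf, _["nmax"] = nmax,
                            _["log_scale"] = logscale);
      // adaptive truncation: grow only while the working range is limited
      // by nmax itself, not by the diversity cap
      bool can_grow = gen.n_hi < n_cap && nmax < hard_max;
      bool grow = false;
      if (can_grow && dt > 0.0) {
        double w = weighted_tail ? p_extinct(lambda0, mu, to_age) : 1.0;
        double tot = 0.0, top = 0.0;
        for (int e = 0; e <= eact; ++e) {
          double wn = 1.0;
          for (int n = 0; n <= gen.n_hi; ++n) {
            double val = q[(size_t)e * stride + n] * wn;
            tot += val;
            if (n == gen.n_hi) top += val;
            wn *= w;
            if (wn < 1e-320) wn = 0.0;
          }
        }
        grow = top > tail_tol * tot;
      }
      if (!grow) break;
      int newmax = nmax + nmax / 2 + 10;
      if (newmax > hard_max) newmax = hard_max;
      int newstride = newmax + 1;
      std::vector<double> q2((size_t)newstride * (ecap + 1), 0.0);
      for (int e = 0; e <= ecap; ++e)
        for (int n = 0; n <= nmax; ++n)
          q2[(size_t)e * newstride + n] = qsnap[(size_t)e * stride + n];
      q = q2;
      nmax = newmax;
      stride = newstride;
      logscale = lssnap;
      if (nmax > final_nmax) final_nmax = nmax;
    }
    age = to_age;
    if (i == nev) break;

    // event operator
    double mult = ev_mult[i];
    int n_hi = gen.n_hi;
    if (ev_type[i] == 0) { // colonization
      for (int e = 0; e <= eact; ++e)
        for (int n = 0; n <= n_hi; ++n)
          q[(size_t)e * stride + n] *= rate_dd(gamma0, n + k, K) * mult;
      if (ev_status[i] == 2) { // new pending endemic singleton: shift e up
        for (int e = eact; e >= 0; --e)
          for (int n = 0; n <= n_hi; ++n)
            q[(size_t)(e + 1) * stride + n] = q[(size_t)e * stride + n];
        for (int n = 0; n <= n_hi; ++n) q[n] = 0.0;
        ++eact;
      } else if (ev_status[i] == 1) {
        ++kne;
      }
      ++k;
    } else { // branching
      for (int e = 0; e <= eact; ++e)
        for (int n = 0; n <= n_hi; ++n)
          q[(size_t)e * stride + n] *= rate_dd(lambda0, n + k, K) * mult;
      ++k;
    }
    // entries beyond the new cap range are unreachable; clear them so the
    // restricted loops of later intervals stay consistent
    if (finiteK) {
      int new_cap = (int)cap - k;
      if (new_cap < 0) new_cap = 0;
      for (int e = 0; e <= eact; ++e)
        for (int n = new_cap + 1; n <= nmax; ++n)
          q[(size_t)e * stride + n] = 0.0;
    }
    double m = 0.0;
    for (size_t idx = 0; idx < q.size(); ++idx) if (q[idx] > m) m = q[idx];
    if (!(m > 0.0) || !R_finite(m))
      return List::create(_["loglik"] = R_NegInf, _["nmax"] = nmax,
                          _["log_scale"] = logscale);
    for (size_t idx = 0; idx < q.size(); ++idx) q[idx] /= m;
    logscale += std::log(m);
  }

  double q00 = q[0];
  double ll = (q00 > 0.0) ? std::log(q00) + logscale : R_NegInf;
  return List::create(_["loglik"] = ll, _["nmax"] = final_nmax,
                      _["log_scale"] = logscale);
}
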