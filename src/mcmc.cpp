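// Metropolis-within-Gibbs engine for abundance-mediated interaction models.
//
// Latent abundances N are updated by exact categorical draws from their full
// conditional on 0..Nmax (Poisson state term x binomial Royle-Nichols
// observation terms x downstream state/detection terms in which N enters a
// linear predictor). Latent occupancy states z use their closed-form
// Bernoulli conditional. Coefficients use per-parameter random-walk
// Metropolis with Robbins-Monro scale adaptation during burn-in only.
//
// All randomness comes from R's RNG, so runs are reproducible from set.seed.
// Observation counts are fixed over the run, so each site's histogram of
// counts over occasions is precomputed once and observation likelihoods
// reduce to small table contractions.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PFLOOR = 1e-12;
static const double ETA_CAP = 35.0;

static inline double clampProb(double p) {
  if (p < PFLOOR) return PFLOOR;
  if (p > 1.0 - PFLOOR) return 1.0 - PFLOOR;
  return p;
}
static inline double capEta(double x) {
  if (x > ETA_CAP) return ETA_CAP;
  if (x < -ETA_CAP) return -ETA_CAP;
  return x;
}
// log(1 + exp(x)), stable
static inline double log1pexp_f(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline double invlogit(double x) {
  return 1.0 / (1.0 + std::exp(-capEta(x)));
}

struct Edge {
  int src;      // species index of the source
  int g0;       // theta index of gamma0
  int g1;       // theta index of gamma1, or -1
  bool hasMod;
  NumericVector mod;  // modifier covariate (length I) when hasMod
};

struct Sp {
  int stateVar;        // 0 = abundance, 1 = occupancy
  IntegerMatrix y;     // I x J, NA_INTEGER = masked/missing
  int K;
  NumericMatrix Xs, Xd;
  IntegerVector is_, id_;    // theta indices of state / detection betas
  std::vector<Edge> se, de;  // incoming state / detection edges
  std::vector<int> cntY;     // I x (K+1): per-site counts of each y value
  std::vector<int> nUnmask;  // unmasked occasions per site
  std::vector<bool> anyDet;  // any detection per site
  std::vector<double> lch;   // lchoose(K, y), y = 0..K

  // sufficient-statistic fast paths for the coefficient sweep (valid when
  // the submodel is intercept-only with at most one unmodified incoming
  // edge; latent states are fixed while coefficients are updated)
  bool fsConst, fsOcc, fdA, fdO;
  double sumN, sumLgt, detA, detB;
  std::vector<double> hNY;       // (Nmax+1) x (K+1) joint N-count histogram
  std::vector<double> hc0, hc1;  // source-state histograms by z = 0 / 1
};

// one downstream dependency of a source species: all edges from that source
// into (target t, submodel sub)
struct Down {
  int t;
  int sub;  // 0 = state, 1 = detection
  std::vector<int> eidx;  // indices into t's se or de
};

// per-site evaluation of a downstream dependency: the target's linear
// predictor is base + slope * f(candidate)
struct DownPrep {
  int t, sub, stateVar, lat;
  double base, slope;
};

class Engine {
public:
  int I, J, S, P, Nmax;
  bool occMed;
  std::vector<Sp> sp;
  std::vector<std::vector<Down> > down;  // per source species
  std::vector<double> th, priorMean, priorSd;
  std::vector<double> lgt;  // lgamma(n + 1), n = 0..Nmax
  IntegerMatrix latent;  // I x S; N for abundance species, z for occupancy
  std::vector<int> parSp, parSub;  // block membership of each parameter
  int truncWarn;
  bool monitorTrunc;  // truncation is only monitored after burn-in

  Engine(List eng) : truncWarn(0), monitorTrunc(false) {
    I = as<int>(eng["I"]);
    J = as<int>(eng["J"]);
    Nmax = as<int>(eng["Nmax"]);
    occMed = as<bool>(eng["occmed"]);
    List spl = eng["species"];
    S = spl.size();
    NumericVector t0 = eng["theta0"];
    P = t0.size();
    th.assign(t0.begin(), t0.end());
    NumericVector pm = eng["prior_mean"], ps = eng["prior_sd"];
    priorMean.assign(pm.begin(), pm.end());
    priorSd.assign(ps.begin(), ps.end());
    IntegerVector psp = eng["par_sp"], psub = eng["par_sub"];
    parSp.assign(psp.begin(), psp.end());
    parSub.assign(psub.begin(), psub.end());
    latent = clone(as<IntegerMatrix>(eng["init_latent"]));

    lgt.resize(Nmax + 1);
    for (int n = 0; n <= Nmax; ++n) lgt[n] = R::lgammafn(n + 1.0);

    for (int s = 0; s < S; ++s) {
      List e = spl[s];
      Sp x;
      x.stateVar = as<int>(e["state_var"]);
      x.y = as<IntegerMatrix>(e["y"]);
      x.K = as<int>(e["K"]);
      x.Xs = as<NumericMatrix>(e["Xs"]);
      x.Xd = as<NumericMatrix>(e["Xd"]);
      x.is_ = as<IntegerVector>(e["is"]);
      x.id_ = as<IntegerVector>(e["id"]);
      x.se = parseEdges(e["se"]);
      x.de = parseEdges(e["de"]);
      x.cntY.assign(I * (x.K + 1), 0);
      x.nUnmask.assign(I, 0);
      x.anyDet.assign(I, false);
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j) {
          int y = x.y(i, j);
          if (y == NA_INTEGER) continue;
          ++x.cntY[i * (x.K + 1) + y];
          ++x.nUnmask[i];
          if (y > 0) x.anyDet[i] = true;
        }
      x.lch.resize(x.K + 1);
      for (int y = 0; y <= x.K; ++y) x.lch[y] = R::lchoose(x.K, y);
      x.fsConst = (x.stateVar == 0) && x.Xs.ncol() == 1 && x.se.empty();
      x.fsOcc = (x.stateVar == 1) && x.Xs.ncol() == 1 &&
        x.se.size() == 1 && !x.se[0].hasMod;
      x.fdA = (x.stateVar == 0) && x.Xd.ncol() == 1 && x.de.empty();
      x.fdO = (x.stateVar == 1) && x.Xd.ncol() == 1 && x.de.empty();
      sp.push_back(x);
    }
    // downstream map
    down.assign(S, std::vector<Down>());
    for (int t = 0; t < S; ++t) {
      for (int sub = 0; sub < 2; ++sub) {
        std::vector<Edge>& es = (sub == 0) ? sp[t].se : sp[t].de;
        for (int s = 0; s < S; ++s) {
          std::vector<int> idx;
          for (size_t k = 0; k < es.size(); ++k)
            if (es[k].src == s) idx.push_back((int)k);
          if (!idx.empty()) {
            Down d; d.t = t; d.sub = sub; d.eidx = idx;
            down[s].push_back(d);
          }
        }
      }
    }
  }

  std::vector<Edge> parseEdges(List el) {
    std::vector<Edge> out;
    for (int k = 0; k < el.size(); ++k) {
      List e = el[k];
      Edge ed;
      ed.src = as<int>(e["src"]);
      ed.g0 = as<int>(e["g0"]);
      ed.g1 = as<int>(e["g1"]);
      ed.hasMod = (ed.g1 >= 0);
      if (ed.hasMod) ed.mod = as<NumericVector>(e["mod"]);
      out.push_back(ed);
    }
    return out;
  }

  inline double fOf(double n) const {
    return occMed ? (n > 0 ? 1.0 : 0.0) : n;
  }
  inline double srcVal(int i, int s) const { return fOf(latent(i, s)); }

  double edgeContrib(const Edge& e, int i, double f) const {
    double c = th[e.g0] * f;
    if (e.hasMod) c += th[e.g1] * f * e.mod[i];
    return c;
  }

  double etaX(int s, int i, int sub) const {
    const Sp& x = sp[s];
    const NumericMatrix& X = (sub == 0) ? x.Xs : x.Xd;
    const IntegerVector& ip = (sub == 0) ? x.is_ : x.id_;
    const std::vector<Edge>& es = (sub == 0) ? x.se : x.de;
    double eta = 0.0;
    for (int c = 0; c < X.ncol(); ++c) eta += X(i, c) * th[ip[c]];
    for (size_t k = 0; k < es.size(); ++k)
      eta += edgeContrib(es[k], i, srcVal(i, es[k].src));
    return eta;
  }

  // observation log-likelihood of species s at site i given latent value v
  // and detection linear predictor etaD
  double obsLL(int s, int i, int v, double etaD) const {
    const Sp& x = sp[s];
    const int* cnt = &x.cntY[i * (x.K + 1)];
    if (v == 0) return x.anyDet[i] ? R_NegInf : 0.0;
    double ll = 0.0;
    if (x.stateVar == 0) {
      double r = clampProb(invlogit(etaD));
      double p = clampProb(1.0 - std::pow(1.0 - r, (double)v));
      double lp = std::log(p), lq = std::log1p(-p);
      for (int y = 0; y <= x.K; ++y)
        if (cnt[y]) ll += cnt[y] * (x.lch[y] + y * lp + (x.K - y) * lq);
    } else {
      double p = clampProb(invlogit(etaD));
      double lp = std::log(p), lq = std::log1p(-p);
      for (int y = 0; y <= x.K; ++y)
        if (cnt[y]) ll += cnt[y] * (y > 0 ? lp : lq);
    }
    return ll;
  }

  // state log-density of species t at site i given its state eta
  double stateLL(int t, int i, double eta) const {
    if (sp[t].stateVar == 0) {
      int n = latent(i, t);
      double ce = capEta(eta);
      return n * ce - std::exp(ce) - lgt[n];
    }
    int z = latent(i, t);
    return z * eta - log1pexp_f(eta);
  }

  // prepare the downstream dependencies of source s at site i
  void downPrep(int s, int i, std::vector<DownPrep>& prep) const {
    prep.resize(down[s].size());
    double fcur = srcVal(i, s);
    for (size_t k = 0; k < down[s].size(); ++k) {
      const Down& d = down[s][k];
      const std::vector<Edge>& es = (d.sub == 0) ? sp[d.t].se : sp[d.t].de;
      DownPrep& pr = prep[k];
      pr.t = d.t; pr.sub = d.sub;
      pr.stateVar = sp[d.t].stateVar;
      pr.lat = latent(i, d.t);
      double slope = 0.0;
      for (size_t q = 0; q < d.eidx.size(); ++q) {
        const Edge& e = es[d.eidx[q]];
        slope += th[e.g0] + (e.hasMod ? th[e.g1] * e.mod[i] : 0.0);
      }
      pr.slope = slope;
      pr.base = etaX(d.t, i, d.sub) - slope * fcur;
    }
  }

  // downstream log-likelihood contribution at site i when the source takes
  // transformed value f
  double downTerm(const std::vector<DownPrep>& prep, int i, double f) const {
    double ll = 0.0;
    for (size_t k = 0; k < prep.size(); ++k) {
      const DownPrep& pr = prep[k];
      double eta = pr.base + pr.slope * f;
      if (pr.sub == 0) {
        if (pr.stateVar == 0) {
          double ce = capEta(eta);
          ll += pr.lat * ce - std::exp(ce);  // lgamma term constant in f
        } else {
          ll += pr.lat * eta - log1pexp_f(eta);
        }
      } else {
        ll += obsLL(pr.t, i, pr.lat, eta);
      }
    }
    return ll;
  }

  // exact categorical Gibbs update of latent N for abundance species s
  void updateAbundance(int s) {
    const Sp& x = sp[s];
    const int K1 = x.K + 1;
    bool fastDet = (x.Xd.ncol() == 1) && x.de.empty();
    // tab[y + K1 * n]: binomial log-pmf at each (count, abundance) pair;
    // valid whenever detection probability is constant across sites
    std::vector<double> tab;
    if (fastDet) {
      double r = clampProb(invlogit(th[x.id_[0]]));
      tab.assign(K1 * (Nmax + 1), 0.0);
      for (int n = 1; n <= Nmax; ++n) {
        double p = clampProb(1.0 - std::pow(1.0 - r, (double)n));
        double lp = std::log(p), lq = std::log1p(-p);
        for (int y = 0; y <= x.K; ++y)
          tab[y + K1 * n] = x.lch[y] + y * lp + (x.K - y) * lq;
      }
    }
    std::vector<double> logw(Nmax + 1), w(Nmax + 1);
    std::vector<DownPrep> prep;
    std::vector<double> dEta, dExp, dQ;
    bool hasDown = !down[s].empty();
    for (int i = 0; i < I; ++i) {
      double llam = capEta(etaX(s, i, 0));  // log lambda
      double d0 = 0.0, d1 = 0.0;
      bool twoLevel = false, affine = false;
      if (hasDown) {
        downPrep(s, i, prep);
        if (occMed) {
          // the indicator takes two values: precompute both contributions
          twoLevel = true;
          d0 = downTerm(prep, i, 0.0);
          d1 = downTerm(prep, i, 1.0);
        } else {
          // state-submodel targets are affine in N: exp(eta_n) follows a
          // multiplicative recurrence, avoiding per-candidate exp calls
          affine = true;
          for (size_t k = 0; k < prep.size(); ++k)
            if (prep[k].sub != 0) affine = false;
          if (affine) {
            dEta.resize(prep.size()); dExp.resize(prep.size());
            dQ.resize(prep.size());
            for (size_t k = 0; k < prep.size(); ++k) {
              // uncapped: dExp is only consumed while |dEta| <= 35, where
              // the plain exponential cannot over/underflow
              dEta[k] = prep[k].base;
              dExp[k] = std::exp(prep[k].base);
              dQ[k] = std::exp(prep[k].slope);
            }
          }
        }
      }
      double etaD = fastDet ? 0.0 : etaX(s, i, 1);
      const int* cnt = &x.cntY[i * K1];
      int n0 = x.anyDet[i] ? 1 : 0;  // structural zero below n0
      for (int n = n0; n <= Nmax; ++n) {
        double lw = n * llam - lgt[n];
        if (n > 0) {
          if (fastDet) {
            const double* tn = &tab[K1 * n];
            for (int y = 0; y <= x.K; ++y)
              if (cnt[y]) lw += cnt[y] * tn[y];
          } else {
            lw += obsLL(s, i, n, etaD);
          }
        }
        if (hasDown) {
          if (twoLevel) {
            lw += (n > 0) ? d1 : d0;
          } else if (affine) {
            if (n > n0)
              for (size_t k = 0; k < prep.size(); ++k) {
                dEta[k] += prep[k].slope;
                dExp[k] *= dQ[k];
              }
            else if (n0 > 0)  // catch up to n = n0
              for (size_t k = 0; k < prep.size(); ++k) {
                dEta[k] += n0 * prep[k].slope;
                dExp[k] = std::exp(dEta[k]);
              }
            for (size_t k = 0; k < prep.size(); ++k) {
              const DownPrep& pr = prep[k];
              double etak = dEta[k];
              if (pr.stateVar == 0) {
                double ce = capEta(etak);
                lw += pr.lat * ce -
                  (etak == ce ? dExp[k] : std::exp(ce));
              } else {
                double lp = (etak > 35.0) ? etak
                  : (etak < -35.0 ? std::exp(etak) : std::log1p(dExp[k]));
                lw += pr.lat * etak - lp;
              }
            }
          } else {
            lw += downTerm(prep, i, fOf(n));
          }
        }
        logw[n] = lw;
      }
      double m = R_NegInf;
      for (int n = n0; n <= Nmax; ++n) if (logw[n] > m) m = logw[n];
      if (!R_FINITE(m))
        stop("sampler error: latent abundance conditional has no support mass at site %d (species %d)",
             i + 1, s + 1);
      double tot = 0.0;
      for (int n = n0; n <= Nmax; ++n) {
        double d = logw[n] - m;
        w[n] = (d < -45.0) ? 0.0 : std::exp(d);  // below double resolution
        tot += w[n];
      }
      if (monitorTrunc && w[Nmax] / tot > 1e-6) ++truncWarn;
      double u = unif_rand() * tot, acc = 0.0;
      int pick = Nmax;
      for (int n = n0; n <= Nmax; ++n) {
        acc += w[n];
        if (u <= acc) { pick = n; break; }
      }
      latent(i, s) = pick;
    }
  }

  // closed-form Bernoulli Gibbs update of latent z for occupancy species s
  void updateOccupancy(int s) {
    const Sp& x = sp[s];
    std::vector<DownPrep> prep;
    bool hasDown = !down[s].empty();
    for (int i = 0; i < I; ++i) {
      if (x.anyDet[i]) { latent(i, s) = 1; continue; }
      double psi = clampProb(invlogit(etaX(s, i, 0)));
      double p = clampProb(invlogit(etaX(s, i, 1)));
      double lw1 = std::log(psi) + x.nUnmask[i] * std::log1p(-p);
      double lw0 = std::log1p(-psi);
      if (hasDown) {
        downPrep(s, i, prep);
        lw1 += downTerm(prep, i, fOf(1));
        lw0 += downTerm(prep, i, fOf(0));
      }
      double pz1 = 1.0 / (1.0 + std::exp(lw0 - lw1));
      latent(i, s) = (unif_rand() < pz1) ? 1 : 0;
    }
  }

  // recompute the latent-state sufficient statistics used by the
  // coefficient sweep (latent states do not move during that sweep)
  void refreshStats() {
    for (int t = 0; t < S; ++t) {
      Sp& x = sp[t];
      if (x.fsConst) {
        x.sumN = 0.0; x.sumLgt = 0.0;
        for (int i = 0; i < I; ++i) {
          int n = latent(i, t);
          x.sumN += n; x.sumLgt += lgt[n];
        }
      }
      if (x.fsOcc) {
        x.hc0.assign(Nmax + 1, 0.0);
        x.hc1.assign(Nmax + 1, 0.0);
        int src = x.se[0].src;
        for (int i = 0; i < I; ++i) {
          int v = latent(i, src);
          if (latent(i, t)) ++x.hc1[v]; else ++x.hc0[v];
        }
      }
      if (x.fdA) {
        x.hNY.assign((Nmax + 1) * (x.K + 1), 0.0);
        for (int i = 0; i < I; ++i) {
          int n = latent(i, t);
          const int* cnt = &x.cntY[i * (x.K + 1)];
          for (int y = 0; y <= x.K; ++y)
            x.hNY[y + (x.K + 1) * n] += cnt[y];
        }
      }
      if (x.fdO) {
        x.detA = 0.0; x.detB = 0.0;
        for (int i = 0; i < I; ++i) {
          if (!latent(i, t)) continue;
          const int* cnt = &x.cntY[i * (x.K + 1)];
          x.detB += cnt[0];
          for (int y = 1; y <= x.K; ++y) x.detA += cnt[y];
        }
      }
    }
  }

  // full log-likelihood of one (species, submodel) block
  double blockLL(int t, int sub) {
    const Sp& x = sp[t];
    double ll = 0.0;
    if (sub == 0) {
      if (x.fsConst) {
        double ce = capEta(th[x.is_[0]]);
        return ce * x.sumN - I * std::exp(ce) - x.sumLgt;
      }
      if (x.fsOcc) {
        double b0 = th[x.is_[0]], g = th[x.se[0].g0];
        for (int v = 0; v <= Nmax; ++v) {
          double c0 = x.hc0[v], c1 = x.hc1[v];
          if (c0 == 0.0 && c1 == 0.0) continue;
          double eta = b0 + g * fOf(v);
          ll += c1 * eta - (c0 + c1) * log1pexp_f(eta);
        }
        return ll;
      }
      for (int i = 0; i < I; ++i) ll += stateLL(t, i, etaX(t, i, 0));
    } else {
      if (x.fdA) {
        double r = clampProb(invlogit(th[x.id_[0]]));
        double l1mr = std::log1p(-r);
        for (int n = 1; n <= Nmax; ++n) {
          const double* h = &x.hNY[(x.K + 1) * n];
          bool any = false;
          for (int y = 0; y <= x.K; ++y) if (h[y] != 0.0) { any = true; break; }
          if (!any) continue;
          double p = clampProb(1.0 - std::exp(n * l1mr));
          double lp = std::log(p), lq = std::log1p(-p);
          for (int y = 0; y <= x.K; ++y)
            if (h[y] != 0.0) ll += h[y] * (x.lch[y] + y * lp + (x.K - y) * lq);
        }
        return ll;
      }
      if (x.fdO) {
        double p = clampProb(invlogit(th[x.id_[0]]));
        return x.detA * std::log(p) + x.detB * std::log1p(-p);
      }
      for (int i = 0; i < I; ++i)
        ll += obsLL(t, i, latent(i, t), etaX(t, i, 1));
    }
    return ll;
  }

  double logPrior(int p) const {
    double z = (th[p] - priorMean[p]) / priorSd[p];
    return -0.5 * z * z;
  }
};

// [[Rcpp::export(name = ".runChainCpp")]]
List runChainCpp(List eng, int n_iter, int burn_in, int thin,
                 int adapt_interval, double target_accept,
                 double init_scale, bool fix_coef, bool save_latent) {
  Engine E(eng);
  const int P = E.P;

  std::vector<double> lscale(P, std::log(init_scale));
  std::vector<int> accBatch(P, 0);
  std::vector<long> accTotal(P, 0);
  int batch = 0, postIter = 0;

  int nKeep = (n_iter - burn_in) / thin;
  NumericMatrix out(nKeep > 0 ? nKeep : 0, P);
  IntegerMatrix latOut(save_latent && nKeep > 0 ? nKeep : 0,
                       save_latent ? E.I * E.S : 0);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    E.monitorTrunc = (it > burn_in);
    // latent sweep in topological (stored) species order
    for (int s = 0; s < E.S; ++s) {
      if (E.sp[s].stateVar == 0) E.updateAbundance(s);
      else E.updateOccupancy(s);
    }
    // coefficient sweep, blockwise
    if (!fix_coef) {
      E.refreshStats();
      int curT = -1, curSub = -1;
      double curLL = 0.0;
      for (int p = 0; p < P; ++p) {
        int t = E.parSp[p], sub = E.parSub[p];
        if (t != curT || sub != curSub) {
          curT = t; curSub = sub;
          curLL = E.blockLL(t, sub);
        }
        double old = E.th[p];
        double oldPrior = E.logPrior(p);
        E.th[p] = old + std::exp(lscale[p]) * norm_rand();
        double newLL = E.blockLL(t, sub);
        double lacc = (newLL - curLL) + (E.logPrior(p) - oldPrior);
        if (R_FINITE(lacc) && std::log(unif_rand()) < lacc) {
          curLL = newLL;
          ++accBatch[p];
          ++accTotal[p];
        } else {
          E.th[p] = old;
        }
      }
      // Robbins-Monro adaptation during burn-in only
      if (it <= burn_in && it % adapt_interval == 0) {
        ++batch;
        for (int p = 0; p < P; ++p) {
          double rate = (double)accBatch[p] / adapt_interval;
          lscale[p] += (rate - target_accept) / std::sqrt((double)batch);
          if (lscale[p] < -8.0) lscale[p] = -8.0;
          if (lscale[p] > 3.0) lscale[p] = 3.0;
          accBatch[p] = 0;
        }
      }
    }
    if (it > burn_in) {
      ++postIter;
      if (postIter % thin == 0 && kept < nKeep) {
        for (int p = 0; p < P; ++p) out(kept, p) = E.th[p];
        if (save_latent)
          for (int s = 0; s < E.S; ++s)
            for (int i = 0; i < E.I; ++i)
              latOut(kept, i + E.I * s) = E.latent(i, s);
        ++kept;
      }
    }
  }

  NumericVector accRate(P);
  for (int p = 0; p < P; ++p)
    accRate[p] = fix_coef ? NA_REAL : (double)accTotal[p] / n_iter;
  NumericVector scales(P);
  for (int p = 0; p < P; ++p) scales[p] = std::exp(lscale[p]);

  return List::create(
    _["draws"] = out,
    _["latent"] = save_latent ? (RObject)latOut : (RObject)R_NilValue,
    _["final_latent"] = E.latent,
    _["accept_rate"] = accRate,
    _["proposal_scales"] = scales,
    _["trunc_warn"] = E.truncWarn);
}
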