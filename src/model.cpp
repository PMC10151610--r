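// Core of the latent-property reactivity model: noisy-OR likelihood over
// ordered property-index assignments of every modelled sub-combination,
// optional emission map onto multi-bit outcomes, Bernoulli observation
// noise, Beta priors in the unconstrained logit parameterization, and
// analytic gradients for Hamiltonian Monte Carlo.
//
// Parameter layout (constrained scale, matching R's param_meta()):
//   M  (entities x K, column-major)
//   R_k unique multiset entries, arities ascending, multiset-lex order
//   E  (modes x B, column-major), modes ordered by arity then multiset-lex

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PFLOOR = 1e-9;
static const double UCAP = 1.0 - 1e-12;

struct ArityInfo {
  const int* tuples;   // n_t x k, column-major, 0-based property indices
  const int* t2m;      // tuple -> multiset index (0-based), length n_t
  int n_t, k, toff, moff, nm;
  bool present = false;
};

struct ModelStr {
  int K, B, n_ent, n_param, n_modes;
  double eps_fp, eps_fn;
  ArityInfo ar[5];                       // indexed by arity 2..4
  std::vector<std::vector<int>> cbits;   // compound -> entity indices
  List obs;                              // per-obs: units, subs, y
};

static ModelStr parse_structure(List str) {
  ModelStr m;
  m.K = as<int>(str["K"]);
  m.B = as<int>(str["B"]);
  m.n_ent = as<int>(str["n_ent"]);
  m.n_param = as<int>(str["n_param"]);
  m.n_modes = as<int>(str["n_modes"]);
  m.eps_fp = as<double>(str["eps_fp"]);
  m.eps_fn = as<double>(str["eps_fn"]);
  List ainfo = str["arities"];
  for (int i = 0; i < ainfo.size(); ++i) {
    List ai = ainfo[i];
    int k = as<int>(ai["k"]);
    ArityInfo& A = m.ar[k];
    IntegerMatrix tp = ai["tuples"];
    IntegerVector t2m = ai["t2m"];
    A.tuples = INTEGER(tp);
    A.t2m = INTEGER(t2m);
    A.n_t = tp.nrow();
    A.k = k;
    A.toff = as<int>(ai["toff"]);
    A.moff = as<int>(ai["moff"]);
    A.nm = as<int>(ai["nm"]);
    A.present = true;
  }
  List cb = str["compound_bits"];
  m.cbits.resize(cb.size());
  for (int i = 0; i < cb.size(); ++i) {
    IntegerVector v = cb[i];
    m.cbits[i] = std::vector<int>(v.begin(), v.end());
  }
  m.obs = str["obs"];
  return m;
}

// Per-observation forward pass (+ optional gradient accumulation scaled by
// wmult). p: constrained parameters. gp: gradient wrt p. Fills pbits with
// the per-bit outcome probabilities (clamped). Returns the observation's
// Bernoulli log-likelihood; when ll_only is true the y-dependent part still
// runs but gradient code is skipped.
static double obs_forward(const ModelStr& m, const double* p, List ob,
                          bool do_grad, double wmult, double* gp,
                          std::vector<double>& pbits) {
  IntegerVector units = ob["units"];
  List subs = ob["subs"];
  IntegerVector y = ob["y"];
  const int K = m.K, B = m.B;
  const int nu = units.size(), ns = subs.size();
  const double cn = 1.0 - m.eps_fp - m.eps_fn;

  // membership rows per unit (noisy-OR over the compound's basis entities)
  std::vector<std::vector<double>> rows(nu, std::vector<double>(K));
  for (int j = 0; j < nu; ++j) {
    const std::vector<int>& ents = m.cbits[units[j]];
    for (int I = 0; I < K; ++I) {
      if (ents.size() == 1) {
        rows[j][I] = p[I * m.n_ent + ents[0]];
      } else {
        double lq = 0.0;
        for (size_t e = 0; e < ents.size(); ++e)
          lq += std::log1p(-std::min(p[I * m.n_ent + ents[e]], UCAP));
        rows[j][I] = -std::expm1(lq);
      }
    }
  }

  // pass A: per-subset per-multiset log(1 - u) sums
  std::vector<std::vector<double>> W(ns);
  std::vector<int> sub_arity(ns);
  double logS_total = 0.0; // binary path accumulator
  for (int s = 0; s < ns; ++s) {
    IntegerVector sub = subs[s];
    const int k = sub.size();
    const ArityInfo& A = m.ar[k];
    sub_arity[s] = k;
    W[s].assign(A.nm, 0.0);
    const double* mv[4];
    for (int j = 0; j < k; ++j) mv[j] = rows[sub[j]].data();
    for (int t = 0; t < A.n_t; ++t) {
      double prodm = 1.0;
      for (int j = 0; j < k; ++j) prodm *= mv[j][A.tuples[j * A.n_t + t]];
      double u = prodm * p[A.toff + A.t2m[t]];
      if (u > UCAP) u = UCAP;
      W[s][A.t2m[t]] += std::log1p(-u);
    }
    for (int mo = 0; mo < A.nm; ++mo) logS_total += W[s][mo];
  }

  // forward outcome probabilities + log-likelihood
  double ll = 0.0;
  std::vector<double> dldW; // per (s, mode) flattened, for gradient
  std::vector<double> gE;   // handled inline below
  pbits.assign(B, 0.0);
  std::vector<double> dll_dp(B, 0.0);

  if (B == 1) {
    double sig = -std::expm1(logS_total);
    double pb = m.eps_fp + cn * sig;
    double pc = std::min(std::max(pb, PFLOOR), 1.0 - PFLOOR);
    pbits[0] = pc;
    ll = (y[0] == 1) ? std::log(pc) : std::log1p(-pc);
    if (do_grad && pb > PFLOOR && pb < 1.0 - PFLOOR) {
      dll_dp[0] = (y[0] == 1) ? 1.0 / pc : -1.0 / (1.0 - pc);
    }
  } else {
    // A_b = sum over causes log(1 - C * E[., b])
    std::vector<double> Aacc(B, 0.0);
    for (int s = 0; s < ns; ++s) {
      const ArityInfo& A = m.ar[sub_arity[s]];
      for (int mo = 0; mo < A.nm; ++mo) {
        double C = -std::expm1(W[s][mo]);
        int gm = A.moff + mo;
        for (int b = 0; b < B; ++b) {
          double ce = std::min(C * p[m.n_param - m.n_modes * B + b * m.n_modes + gm], UCAP);
          Aacc[b] += std::log1p(-ce);
        }
      }
    }
    for (int b = 0; b < B; ++b) {
      double sig = -std::expm1(Aacc[b]);
      double pb = m.eps_fp + cn * sig;
      double pc = std::min(std::max(pb, PFLOOR), 1.0 - PFLOOR);
      pbits[b] = pc;
      ll += (y[b] == 1) ? std::log(pc) : std::log1p(-pc);
      if (do_grad && pb > PFLOOR && pb < 1.0 - PFLOOR) {
        dll_dp[b] = (y[b] == 1) ? 1.0 / pc : -1.0 / (1.0 - pc);
      }
    }
    if (do_grad) {
      // dll/dA_b then per-cause dll/dC and emission gradient
      std::vector<double> dldA(B);
      for (int b = 0; b < B; ++b) dldA[b] = dll_dp[b] * cn * (-std::exp(Aacc[b]));
      dldW.resize(0);
      int Eoff = m.n_param - m.n_modes * B;
      for (int s = 0; s < ns; ++s) {
        const ArityInfo& A = m.ar[sub_arity[s]];
        for (int mo = 0; mo < A.nm; ++mo) {
          double C = -std::expm1(W[s][mo]);
          int gm = A.moff + mo;
          double dldC = 0.0;
          for (int b = 0; b < B; ++b) {
            double E = p[Eoff + b * m.n_modes + gm];
            double denom = std::max(1.0 - C * E, 1e-12);
            dldC += dldA[b] * (-E / denom);
            gp[Eoff + b * m.n_modes + gm] += wmult * dldA[b] * (-C / denom);
          }
          // dC/dW = -exp(W) = C - 1
          dldW.push_back(dldC * (C - 1.0));
        }
      }
    }
  }

  if (!do_grad) return ll;

  // pass B: per-tuple gradients into R entries and membership rows
  std::vector<std::vector<double>> grow(nu, std::vector<double>(K, 0.0));
  double dldW_bin = 0.0;
  if (B == 1) {
    dldW_bin = dll_dp[0] * cn * (-std::exp(logS_total));
  }
  int widx = 0;
  for (int s = 0; s < ns; ++s) {
    IntegerVector sub = subs[s];
    const int k = sub.size();
    const ArityInfo& A = m.ar[k];
    const double* mv[4];
    for (int j = 0; j < k; ++j) mv[j] = rows[sub[j]].data();
    for (int t = 0; t < A.n_t; ++t) {
      int mo = A.t2m[t];
      double dW = (B == 1) ? dldW_bin : dldW[widx + mo];
      if (dW == 0.0) continue;
      double m0[4];
      double prodm = 1.0;
      for (int j = 0; j < k; ++j) {
        m0[j] = mv[j][A.tuples[j * A.n_t + t]];
        prodm *= m0[j];
      }
      double Rv = p[A.toff + mo];
      double u = prodm * Rv;
      if (u > UCAP) continue; // clamped: zero local gradient
      double dldu = dW * (-1.0 / (1.0 - u));
      gp[A.toff + mo] += wmult * dldu * prodm;
      for (int j = 0; j < k; ++j) {
        double excl = Rv;
        for (int l = 0; l < k; ++l) if (l != j) excl *= m0[l];
        grow[sub[j]][A.tuples[j * A.n_t + t]] += dldu * excl;
      }
    }
    widx += A.nm;
  }
  // backprop rows -> entity memberships
  for (int j = 0; j < nu; ++j) {
    const std::vector<int>& ents = m.cbits[units[j]];
    for (int I = 0; I < K; ++I) {
      double g = grow[j][I];
      if (g == 0.0) continue;
      if (ents.size() == 1) {
        gp[I * m.n_ent + ents[0]] += wmult * g;
      } else {
        double q = 1.0 - rows[j][I]; // = prod(1 - M[e,I])
        for (size_t e = 0; e < ents.size(); ++e) {
          double denom = std::max(1.0 - p[I * m.n_ent + ents[e]], 1e-12);
          gp[I * m.n_ent + ents[e]] += wmult * g * q / denom;
        }
      }
    }
  }
  return ll;
}

static inline double sigmoid(double x) {
  return x >= 0 ? 1.0 / (1.0 + std::exp(-x)) : std::exp(x) / (1.0 + std::exp(x));
}
static inline double log_sigmoid(double x) {
  return x >= 0 ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
}

// Log-posterior (up to a constant) and gradient in the unconstrained logit
// parameterization; the Beta prior density and the logit Jacobian combine
// to a*log(sigma(x)) + b*log(sigma(-x)).
// [[Rcpp::export]]
List cpp_lp_grad(NumericVector x, List str, NumericVector a, NumericVector b,
                 bool want_grad = true) {
  ModelStr m = parse_structure(str);
  int n = x.size();
  std::vector<double> p(n);
  double lp = 0.0;
  for (int i = 0; i < n; ++i) {
    p[i] = sigmoid(x[i]);
    lp += a[i] * log_sigmoid(x[i]) + b[i] * log_sigmoid(-x[i]);
  }
  std::vector<double> gp(want_grad ? n : 0, 0.0);
  std::vector<double> pbits;
  for (int o = 0; o < m.obs.size(); ++o) {
    lp += obs_forward(m, p.data(), m.obs[o], want_grad, 1.0,
                      want_grad ? gp.data() : nullptr, pbits);
  }
  if (!want_grad) return List::create(_["lp"] = lp);
  NumericVector gx(n);
  for (int i = 0; i < n; ++i) {
    gx[i] = a[i] - (a[i] + b[i]) * p[i] + gp[i] * p[i] * (1.0 - p[i]);
  }
  return List::create(_["lp"] = lp, _["grad"] = gx);
}

// Per-draw, per-observation log-likelihood (constrained-scale draws).
// [[Rcpp::export]]
NumericMatrix cpp_obs_loglik(NumericMatrix P, List str) {
  ModelStr m = parse_structure(str);
  int nd = P.nrow(), no = m.obs.size();
  NumericMatrix out(nd, no);
  std::vector<double> p(P.ncol()), pbits;
  for (int d = 0; d < nd; ++d) {
    for (int i = 0; i < P.ncol(); ++i) p[i] = P(d, i);
    for (int o = 0; o < no; ++o) {
      out(d, o) = obs_forward(m, p.data(), m.obs[o], false, 1.0, nullptr,
                              pbits);
    }
  }
  return out;
}

// Per-draw, per-observation, per-bit outcome probabilities;
// returns an array with dim (n_draws, n_obs, B).
// [[Rcpp::export]]
NumericVector cpp_predict_bits(NumericMatrix P, List str) {
  ModelStr m = parse_structure(str);
  int nd = P.nrow(), no = m.obs.size(), B = m.B;
  NumericVector out(nd * no * B);
  std::vector<double> p(P.ncol()), pbits;
  for (int d = 0; d < nd; ++d) {
    for (int i = 0; i < P.ncol(); ++i) p[i] = P(d, i);
    for (int o = 0; o < no; ++o) {
      obs_forward(m, p.data(), m.obs[o], false, 1.0, nullptr, pbits);
      for (int b = 0; b < B; ++b) out[d + nd * (o + no * b)] = pbits[b];
    }
  }
  out.attr("dim") = IntegerVector::create(nd, no, B);
  return out;
}

// Mixture posterior of two rival theories sharing an observation log:
// per-observation likelihood w * L_a + (1 - w) * L_b, with w ~ Beta(wa, wb)
// and each theory's latents sampled jointly.
// x = [x_a, x_b, logit(w)].
// [[Rcpp::export]]
List cpp_mix_lp_grad(NumericVector x, List strA, NumericVector aA,
                     NumericVector bA, List strB, NumericVector aB,
                     NumericVector bB, double wa, double wb) {
  ModelStr A = parse_structure(strA);
  ModelStr Bm = parse_structure(strB);
  int nA = aA.size(), nB = aB.size();
  int n = nA + nB + 1;
  if (x.size() != n) stop("mixture parameter length mismatch");
  std::vector<double> pA(nA), pB(nB);
  double lp = 0.0;
  for (int i = 0; i < nA; ++i) {
    pA[i] = sigmoid(x[i]);
    lp += aA[i] * log_sigmoid(x[i]) + bA[i] * log_sigmoid(-x[i]);
  }
  for (int i = 0; i < nB; ++i) {
    pB[i] = sigmoid(x[nA + i]);
    lp += aB[i] * log_sigmoid(x[nA + i]) + bB[i] * log_sigmoid(-x[nA + i]);
  }
  double xw = x[n - 1];
  double w = sigmoid(xw);
  lp += wa * log_sigmoid(xw) + wb * log_sigmoid(-xw);

  int no = A.obs.size();
  if ((int)Bm.obs.size() != no) stop("theories disagree on log length");
  std::vector<double> gA(nA, 0.0), gB(nB, 0.0), pbits;
  double gw_acc = 0.0;
  double lw = log_sigmoid(xw), l1w = log_sigmoid(-xw);
  for (int o = 0; o < no; ++o) {
    double lla = obs_forward(A, pA.data(), A.obs[o], false, 1.0, nullptr, pbits);
    double llb = obs_forward(Bm, pB.data(), Bm.obs[o], false, 1.0, nullptr, pbits);
    double ta = lw + lla, tb = l1w + llb;
    double mx = std::max(ta, tb);
    double mixll = mx + std::log(std::exp(ta - mx) + std::exp(tb - mx));
    lp += mixll;
    double fA = std::exp(ta - mixll), fB = std::exp(tb - mixll);
    obs_forward(A, pA.data(), A.obs[o], true, fA, gA.data(), pbits);
    obs_forward(Bm, pB.data(), Bm.obs[o], true, fB, gB.data(), pbits);
    gw_acc += fA * (1.0 - w) - fB * w;
  }
  NumericVector gx(n);
  for (int i = 0; i < nA; ++i)
    gx[i] = aA[i] - (aA[i] + bA[i]) * pA[i] + gA[i] * pA[i] * (1.0 - pA[i]);
  for (int i = 0; i < nB; ++i)
    gx[nA + i] = aB[i] - (aB[i] + bB[i]) * pB[i] + gB[i] * pB[i] * (1.0 - pB[i]);
  gx[n - 1] = wa - (wa + wb) * w + gw_acc;
  return List::create(_["lp"] = lp, _["grad"] = gx);
}
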