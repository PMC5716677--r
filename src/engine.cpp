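// Compiled trial engine: integrates one forward (and optionally one target)
// phase of the multi-compartment spiking network with forward Euler at dt,
// updating each layer bottom-to-top (dendrites -> soma -> spikes) and
// accumulating post-settle time averages of voltages, rates and filtered
// spike trains. All randomness comes from R's RNG stream (R::unif_rand),
// one uniform per unit per step, input layer first, then hidden layers
// bottom-to-top, then the output layer, so that runs are reproducible under
// set.seed() and bit-comparable with the pure-R reference simulator.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec sigv(const arma::vec& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// [[Rcpp::export(name = ".trial_engine")]]
List trial_engine(List W, List b, List Y,
                  const arma::vec& input_rates,
                  int target,              // 0-based output unit; -1 = no teaching
                  int steps_forward, int steps_target, int settle,
                  List par) {
  const int L = Y.size();
  const double gl = as<double>(par["g_l"]);
  const double gb = as<double>(par["g_b"]);
  const double ga = as<double>(par["g_a"]);
  const double gd = as<double>(par["g_d"]);
  const double cm = as<double>(par["c_m"]);
  const double vr = as<double>(par["v_r"]);
  const double phimax = as<double>(par["phi_max"]);
  const double dt = as<double>(par["dt"]);
  const double tau_l = as<double>(par["tau_l"]);
  const double tau_s = as<double>(par["tau_s"]);
  const double ee = as<double>(par["e_e"]);
  const double ei = as<double>(par["e_i"]);
  const bool teach_literal = as<bool>(par["teach_literal"]);
  const bool apical_rates = as<bool>(par["apical_rates"]);

  const double tau = cm / gl;
  const double dl = std::exp(-dt / tau_l), ds = std::exp(-dt / tau_s);
  const double knorm = tau_l - tau_s;
  const double teach_scale = teach_literal ? 1.0 : 1.0 / gl;

  const int l = input_rates.n_elem;
  std::vector<arma::mat> Wm(L + 1), Ym(L);
  std::vector<arma::vec> bv(L + 1);
  for (int k = 0; k <= L; ++k) {
    Wm[k] = as<arma::mat>(W[k]);
    bv[k] = as<arma::vec>(b[k]);
  }
  for (int k = 0; k < L; ++k) Ym[k] = as<arma::mat>(Y[k]);
  std::vector<int> m(L);
  for (int k = 0; k < L; ++k) m[k] = Wm[k].n_rows;
  const int n = Wm[L].n_rows;

  // network state, persists across the two phases of a trial
  arma::vec inL(l, arma::fill::zeros), inS(l, arma::fill::zeros),
      s_in(l, arma::fill::zeros);
  std::vector<arma::vec> hV(L), hL(L), hS(L), s_h(L);
  for (int k = 0; k < L; ++k) {
    hV[k].zeros(m[k]); hL[k].zeros(m[k]); hS[k].zeros(m[k]); s_h[k].zeros(m[k]);
  }
  arma::vec oV(n, arma::fill::zeros), oSL(n, arma::fill::zeros),
      oSS(n, arma::fill::zeros), s_o(n, arma::fill::zeros),
      phi_o(n, arma::fill::zeros);

  auto run_phase = [&](int nsteps, bool teaching) -> List {
    std::vector<arma::vec> sumVh(L), sumPh(L), sumSh(L), sumVa(L);
    std::vector<arma::mat> vaHist(L);
    for (int k = 0; k < L; ++k) {
      sumVh[k].zeros(m[k]); sumPh[k].zeros(m[k]);
      sumSh[k].zeros(m[k]); sumVa[k].zeros(m[k]);
      vaHist[k].zeros(nsteps, m[k]);
    }
    arma::vec sumVo(n, arma::fill::zeros), sumPo(n, arma::fill::zeros),
        sumSo(n, arma::fill::zeros), sumSin(l, arma::fill::zeros);
    int navg = 0;

    for (int t = 0; t < nsteps; ++t) {
      // input layer: Poisson spikes, then filtered traces
      for (int j = 0; j < l; ++j) {
        const double u = R::unif_rand();
        const double sp = (u < input_rates[j] * dt) ? 1.0 : 0.0;
        inL[j] = inL[j] * dl + sp;
        inS[j] = inS[j] * ds + sp;
      }
      s_in = (inL - inS) / knorm;

      // feedback seen by apical compartments this step: output state from
      // the previous step (layers are updated bottom-to-top)
      const arma::vec fb = apical_rates ? phi_o : s_o;

      for (int k = 0; k < L; ++k) {
        const arma::vec& pre = (k == 0) ? s_in : s_h[k - 1];
        const arma::vec vb = Wm[k] * pre + bv[k];
        const arma::vec va = Ym[k] * fb;
        hV[k] += (dt / tau) * ((vr - hV[k]) + (gb / gl) * (vb - hV[k]) +
                               (ga / gl) * (va - hV[k]));
        const arma::vec phi = phimax * sigv(hV[k]);
        for (int i = 0; i < m[k]; ++i) {
          const double u = R::unif_rand();
          const double sp = (u < phi[i] * dt) ? 1.0 : 0.0;
          hL[k][i] = hL[k][i] * dl + sp;
          hS[k][i] = hS[k][i] * ds + sp;
        }
        s_h[k] = (hL[k] - hS[k]) / knorm;
        vaHist[k].row(t) = va.t();
        if (t >= settle) {
          sumVh[k] += hV[k]; sumPh[k] += phi;
          sumSh[k] += s_h[k]; sumVa[k] += va;
        }
      }

      // output layer
      const arma::vec& preo = (L == 0) ? s_in : s_h[L - 1];
      const arma::vec vbo = Wm[L] * preo + bv[L];
      arma::vec I(n, arma::fill::zeros);
      if (teaching && target >= 0) {
        for (int i = 0; i < n; ++i) {
          const double gE = (i == target) ? 1.0 : 0.0;
          const double gI = 1.0 - gE;
          I[i] = teach_scale * (gE * (ee - oV[i]) + gI * (ei - oV[i]));
        }
      }
      oV += (dt / tau) * ((vr - oV) + (gd / gl) * (vbo - oV) + I);
      phi_o = phimax * sigv(oV);
      for (int i = 0; i < n; ++i) {
        const double u = R::unif_rand();
        const double sp = (u < phi_o[i] * dt) ? 1.0 : 0.0;
        oSL[i] = oSL[i] * dl + sp;
        oSS[i] = oSS[i] * ds + sp;
      }
      s_o = (oSL - oSS) / knorm;
      if (t >= settle) {
        sumVo += oV; sumPo += phi_o; sumSo += s_o; sumSin += s_in;
        ++navg;
      }
    }

    const double cnt = (navg > 0) ? static_cast<double>(navg) : 1.0;
    List Vs(L + 1), Ps(L + 1), Ss(L + 2), Va(L), Hs(L);
    Ss[0] = sumSin / cnt;
    for (int k = 0; k < L; ++k) {
      Vs[k] = sumVh[k] / cnt;
      Ps[k] = sumPh[k] / cnt;
      Ss[k + 1] = sumSh[k] / cnt;
      Va[k] = sumVa[k] / cnt;
      Hs[k] = vaHist[k];
    }
    Vs[L] = sumVo / cnt;
    Ps[L] = sumPo / cnt;
    Ss[L + 1] = sumSo / cnt;
    return List::create(_["v"] = Vs, _["phi"] = Ps, _["s"] = Ss,
                        _["va"] = Va, _["va_hist"] = Hs,
                        _["steps"] = nsteps, _["averaged_steps"] = navg);
  };

  List fwd = run_phase(steps_forward, false);
  List out = List::create(_["forward"] = fwd, _["target"] = R_NilValue);
  if (steps_target > 0) out["target"] = run_phase(steps_target, true);
  return out;
}
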