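#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Deterministic, platform-independent RNG: splitmix64 + Box-Muller.
// std::normal_distribution is implementation-defined, so normals are
// generated by hand to keep identical seeds bit-identical everywhere.
namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1): top 53 bits, offset to exclude 0
  double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct Gauss {
  SplitMix64 rng;
  bool has_spare;
  double spare;
  explicit Gauss(uint64_t seed) : rng(seed), has_spare(false), spare(0.0) {}
  double next() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = rng.runif(), u2 = rng.runif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

inline double sigm(double v, double qmax, double theta, double sp) {
  return qmax / (1.0 + std::exp(-(v - theta) / sp));
}

} // namespace

// Isolated second-order dendritic filter driven by a given input series,
// integrated with the same Heun stepping as the full model; used to verify
// DC gain and impulse-response timing of the dendritic operator.
// [[Rcpp::export(name = ".ct_dendritic_filter")]]
NumericVector ct_dendritic_filter(NumericVector drive, double alpha,
                                  double beta, double dt) {
  const int n = drive.size();
  NumericVector out(n);
  double V = 0.0, dV = 0.0;
  const double ab = alpha * beta, apb = alpha + beta;
  for (int i = 0; i < n; ++i) {
    double P = drive[i];
    double k1V = dV, k1d = ab * (P - V) - apb * dV;
    double Vp = V + dt * k1V, dVp = dV + dt * k1d;
    double P2 = (i + 1 < n) ? drive[i + 1] : P;
    double k2V = dVp, k2d = ab * (P2 - Vp) - apb * dVp;
    V += 0.5 * dt * (k1V + k2V);
    dV += 0.5 * dt * (k1d + k2d);
    out[i] = V;
  }
  return out;
}

// Integrate the delay-coupled corticothalamic network with a stochastic
// Heun scheme. State per region: (V_a, dV_a) for a in {e,i,r,s} plus the
// axonal field (phi_e, dphi_e); 10 doubles per region.
//
// init: n x 5 matrix of initial values (V_e, V_i, V_r, V_s, phi_e);
//       derivatives start at 0 and delay buffers are filled with the
//       initial phi_e and Q_s values.
// sE, sI: per-region multiplicative scales on (nu_ee, nu_ie) and
//       (nu_ei, nu_ii); gc_scale multiplies the long-range gain.
// Returns list(series = kept x n matrix of block-averaged phi_e, fs,
// diverged, div_step, div_region).
// [[Rcpp::export(name = ".ct_integrate")]]
List ct_integrate(NumericMatrix W, NumericMatrix init,
                  List par, NumericVector sE, NumericVector sI,
                  double gc_scale, double master_seed) {
  const int n = W.nrow();

  const double qmax  = as<double>(par["Q_max"]);
  const double theta = as<double>(par["theta"]);
  const double sp    = as<double>(par["sigma_prime"]);
  const double alpha = as<double>(par["alpha_d"]);
  const double beta  = as<double>(par["beta_d"]);
  const double gam   = as<double>(par["gamma_e"]);
  const double t0    = as<double>(par["t0"]);
  const double nmean = as<double>(par["noise_mean"]);
  const double nstd  = as<double>(par["noise_std"]);
  const double dt    = as<double>(par["dt"]);
  const double duration  = as<double>(par["duration"]);
  const double transient = as<double>(par["transient"]);
  const double gc    = as<double>(par["global_coupling"]) * gc_scale;
  const double inter_delay = as<double>(par["inter_delay"]);
  const int decim = as<int>(par["decim"]);

  const double nu_ee = as<double>(par["nu_ee"]);
  const double nu_ei = as<double>(par["nu_ei"]);
  const double nu_es = as<double>(par["nu_es"]);
  const double nu_ie = as<double>(par["nu_ie"]);
  const double nu_ii = as<double>(par["nu_ii"]);
  const double nu_is = as<double>(par["nu_is"]);
  const double nu_re = as<double>(par["nu_re"]);
  const double nu_rs = as<double>(par["nu_rs"]);
  const double nu_se = as<double>(par["nu_se"]);
  const double nu_sr = as<double>(par["nu_sr"]);
  const double nu_sn = as<double>(par["nu_sn"]);

  const double ab = alpha * beta, apb = alpha + beta;
  const double g2 = gam * gam, tg = 2.0 * gam;
  const double noise_amp = nstd / std::sqrt(dt);

  const long n_steps = (long)std::llround(duration / dt);
  const long t_skip  = (long)std::llround(transient / dt);
  const int D  = (int)std::llround(0.5 * t0 / dt);       // loop half-delay
  const int Dn = (int)std::llround(inter_delay / dt);    // inter-regional
  const int buflen = std::max(std::max(D, Dn), 1) + 2;

  const long n_keep_steps = n_steps - t_skip;
  const long kept = n_keep_steps / decim;

  // state arrays
  std::vector<double> Ve(n), dVe(n), Vi(n), dVi(n), Vr(n), dVr(n),
      Vs(n), dVs(n), Fe(n), dFe(n);
  std::vector<double> hist_fe((size_t)buflen * n), hist_qs((size_t)buflen * n);

  for (int j = 0; j < n; ++j) {
    Ve[j] = init(j, 0); Vi[j] = init(j, 1); Vr[j] = init(j, 2);
    Vs[j] = init(j, 3); Fe[j] = init(j, 4);
    dVe[j] = dVi[j] = dVr[j] = dVs[j] = dFe[j] = 0.0;
    double qs0 = sigm(Vs[j], qmax, theta, sp);
    for (int b = 0; b < buflen; ++b) {
      hist_fe[(size_t)b * n + j] = Fe[j];
      hist_qs[(size_t)b * n + j] = qs0;
    }
  }

  // per-region noise streams derived from the master seed
  std::vector<Gauss> noise;
  noise.reserve(n);
  {
    uint64_t base = (uint64_t)std::llround(master_seed);
    for (int j = 0; j < n; ++j)
      noise.emplace_back(base * 0x9e3779b97f4a7c15ULL + 0x517cc1b727220a95ULL * (uint64_t)(j + 1));
  }

  // effective couplings per region
  std::vector<double> cee(n), cie(n), cei(n), cii(n);
  for (int j = 0; j < n; ++j) {
    cee[j] = nu_ee * sE[j]; cie[j] = nu_ie * sE[j];
    cei[j] = nu_ei * sI[j]; cii[j] = nu_ii * sI[j];
  }

  NumericMatrix series(kept, n);
  std::vector<double> acc(n, 0.0);
  int acc_count = 0;
  long out_row = 0;

  // scratch for the two Heun stages
  std::vector<double> k_ddVe(n), k_ddVi(n), k_ddVr(n), k_ddVs(n), k_ddFe(n);
  std::vector<double> pVe(n), pdVe(n), pVi(n), pdVi(n), pVr(n), pdVr(n),
      pVs(n), pdVs(n), pFe(n), pdFe(n);
  std::vector<double> xi(n), net(n), fe_del(n), qs_del(n), fe_net(n);

  const double guardV = 1.0, guardF = 10.0 * qmax;

  int buf_pos = 0; // slot holding values at current time t
  bool diverged = false;
  long div_step = -1;
  int div_region = -1;

  for (long step = 0; step < n_steps && !diverged; ++step) {
    // delayed values at t - tau (stage 1)
    int idxD  = (buf_pos - D  % buflen + buflen) % buflen;
    int idxDn = (buf_pos - Dn % buflen + buflen) % buflen;
    for (int j = 0; j < n; ++j) {
      fe_del[j] = hist_fe[(size_t)idxD * n + j];
      qs_del[j] = hist_qs[(size_t)idxD * n + j];
      fe_net[j] = (Dn == 0) ? Fe[j] : hist_fe[(size_t)idxDn * n + j];
      xi[j] = noise_amp * noise[j].next();
    }
    if (gc != 0.0) {
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        const double *wrow = &W(0, 0); // column-major: W(j,k) = W[j + k*n]
        for (int k = 0; k < n; ++k) s += wrow[j + (size_t)k * n] * fe_net[k];
        net[j] = gc * s;
      }
    } else {
      std::fill(net.begin(), net.end(), 0.0);
    }

    // stage 1 derivatives
    for (int j = 0; j < n; ++j) {
      double Qe = sigm(Ve[j], qmax, theta, sp);
      double Qi = sigm(Vi[j], qmax, theta, sp);
      double Qr = sigm(Vr[j], qmax, theta, sp);
      double Qs = sigm(Vs[j], qmax, theta, sp);
      double Pe = cee[j] * Fe[j] + cei[j] * Qi + nu_es * qs_del[j] + net[j];
      double Pi = cie[j] * Fe[j] + cii[j] * Qi + nu_is * qs_del[j];
      double Pr = nu_re * fe_del[j] + nu_rs * Qs;
      double Ps = nu_se * fe_del[j] + nu_sr * Qr + nu_sn * (nmean + xi[j]);
      k_ddVe[j] = ab * (Pe - Ve[j]) - apb * dVe[j];
      k_ddVi[j] = ab * (Pi - Vi[j]) - apb * dVi[j];
      k_ddVr[j] = ab * (Pr - Vr[j]) - apb * dVr[j];
      k_ddVs[j] = ab * (Ps - Vs[j]) - apb * dVs[j];
      k_ddFe[j] = g2 * (Qe - Fe[j]) - tg * dFe[j];
      // Euler predictor
      pVe[j] = Ve[j] + dt * dVe[j]; pdVe[j] = dVe[j] + dt * k_ddVe[j];
      pVi[j] = Vi[j] + dt * dVi[j]; pdVi[j] = dVi[j] + dt * k_ddVi[j];
      pVr[j] = Vr[j] + dt * dVr[j]; pdVr[j] = dVr[j] + dt * k_ddVr[j];
      pVs[j] = Vs[j] + dt * dVs[j]; pdVs[j] = dVs[j] + dt * k_ddVs[j];
      pFe[j] = Fe[j] + dt * dFe[j]; pdFe[j] = dFe[j] + dt * k_ddFe[j];
    }

    // delayed values at t + dt - tau (stage 2): one slot forward
    int idxD2  = (buf_pos + 1 - D  % buflen + buflen) % buflen;
    int idxDn2 = (buf_pos + 1 - Dn % buflen + buflen) % buflen;
    for (int j = 0; j < n; ++j) {
      fe_del[j] = (D  == 0) ? pFe[j] : hist_fe[(size_t)idxD2 * n + j];
      qs_del[j] = (D  == 0) ? sigm(pVs[j], qmax, theta, sp)
                            : hist_qs[(size_t)idxD2 * n + j];
      fe_net[j] = (Dn == 0) ? pFe[j] : hist_fe[(size_t)idxDn2 * n + j];
    }
    if (gc != 0.0) {
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        const double *wrow = &W(0, 0);
        for (int k = 0; k < n; ++k) s += wrow[j + (size_t)k * n] * fe_net[k];
        net[j] = gc * s;
      }
    }

    // stage 2 + Heun average (same noise draw as stage 1)
    for (int j = 0; j < n; ++j) {
      double Qe = sigm(pVe[j], qmax, theta, sp);
      double Qi = sigm(pVi[j], qmax, theta, sp);
      double Qr = sigm(pVr[j], qmax, theta, sp);
      double Qs = sigm(pVs[j], qmax, theta, sp);
      double Pe = cee[j] * pFe[j] + cei[j] * Qi + nu_es * qs_del[j] + net[j];
      double Pi = cie[j] * pFe[j] + cii[j] * Qi + nu_is * qs_del[j];
      double Pr = nu_re * fe_del[j] + nu_rs * Qs;
      double Ps = nu_se * fe_del[j] + nu_sr * Qr + nu_sn * (nmean + xi[j]);
      double ddVe2 = ab * (Pe - pVe[j]) - apb * pdVe[j];
      double ddVi2 = ab * (Pi - pVi[j]) - apb * pdVi[j];
      double ddVr2 = ab * (Pr - pVr[j]) - apb * pdVr[j];
      double ddVs2 = ab * (Ps - pVs[j]) - apb * pdVs[j];
      double ddFe2 = g2 * (Qe - pFe[j]) - tg * pdFe[j];

      Ve[j] += 0.5 * dt * (dVe[j] + pdVe[j]);
      dVe[j] += 0.5 * dt * (k_ddVe[j] + ddVe2);
      Vi[j] += 0.5 * dt * (dVi[j] + pdVi[j]);
      dVi[j] += 0.5 * dt * (k_ddVi[j] + ddVi2);
      Vr[j] += 0.5 * dt * (dVr[j] + pdVr[j]);
      dVr[j] += 0.5 * dt * (k_ddVr[j] + ddVr2);
      Vs[j] += 0.5 * dt * (dVs[j] + pdVs[j]);
      dVs[j] += 0.5 * dt * (k_ddVs[j] + ddVs2);
      Fe[j] += 0.5 * dt * (dFe[j] + pdFe[j]);
      dFe[j] += 0.5 * dt * (k_ddFe[j] + ddFe2);

      if (!(std::fabs(Ve[j]) < guardV) || !(std::fabs(Vi[j]) < guardV) ||
          !(std::fabs(Vr[j]) < guardV) || !(std::fabs(Vs[j]) < guardV) ||
          !(std::fabs(Fe[j]) < guardF) || !std::isfinite(Fe[j])) {
        diverged = true; div_step = step; div_region = j + 1;
      }
    }

    // advance history ring: slot for time t + dt
    buf_pos = (buf_pos + 1) % buflen;
    for (int j = 0; j < n; ++j) {
      hist_fe[(size_t)buf_pos * n + j] = Fe[j];
      hist_qs[(size_t)buf_pos * n + j] = sigm(Vs[j], qmax, theta, sp);
    }

    if (!diverged && step >= t_skip) {
      for (int j = 0; j < n; ++j) acc[j] += Fe[j];
      if (++acc_count == decim) {
        if (out_row < kept) {
          for (int j = 0; j < n; ++j) series(out_row, j) = acc[j] / decim;
          ++out_row;
        }
        std::fill(acc.begin(), acc.end(), 0.0);
        acc_count = 0;
      }
    }
  }

  return List::create(
      _["series"] = series, _["fs"] = 1.0 / (dt * decim),
      _["diverged"] = diverged, _["div_step"] = (double)div_step,
      _["div_region"] = div_region);
}
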