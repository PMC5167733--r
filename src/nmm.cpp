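#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Three-subpopulation evoked-response neural mass network, integrated with
// fixed-step RK4 and interpolated firing-rate history for conduction delays.
//
// Per-node states (8): x1,x4 spiny-stellate PSP and its derivative;
// x2,x5 pyramidal excitatory PSP; x3,x6 pyramidal inhibitory PSP;
// x7,x8 inhibitory-interneuron PSP.  Node output is pyramidal
// depolarization x2 - x3.
//
// Firing rates pass through a centred sigmoid S(v) = 1/(1+exp(-r v)) - 1/2,
// so the zero state is a fixed point and zero input gives zero output.
// Extrinsic forward connections drive the stellate population, backward
// connections drive pyramidal and inhibitory populations, both with a
// common extrinsic delay; intrinsic couplings use the intrinsic delay.
// Delays exceed the integration step, so every delayed evaluation falls
// strictly inside the stored history (quiescent zero before onset) and is
// linearly interpolated; interpolation weights are shared across nodes.

namespace {
inline double sigm(double v, double r) {
  return 1.0 / (1.0 + std::exp(-r * v)) - 0.5;
}
}

// [[Rcpp::export(name = ".nmm_integrate")]]
NumericMatrix nmm_integrate(NumericVector times, double dt,
                            NumericMatrix AF, NumericMatrix AB,
                            NumericVector gamma, NumericVector selfgain,
                            double He, double Hi, double taue, double taui,
                            double slope, double d_ext, double d_int,
                            NumericMatrix Cmat, NumericVector mu,
                            NumericVector sigma, bool return_states) {
  const int n = AF.nrow();
  const int nt = times.size();
  const int ncomp = Cmat.ncol();
  const double t0 = times[0], tend = times[nt - 1];
  const int nsteps = (int)std::ceil((tend - t0) / dt - 1e-9);

  std::vector<double> g1(n), g2(n), g3(n), g4(n);
  for (int i = 0; i < n; ++i) {
    double s = std::exp(selfgain[i]);
    g1[i] = gamma[0] * s;
    g2[i] = gamma[1] * s;
    g3[i] = gamma[2] * s;
    g4[i] = gamma[3] * s;
  }

  // sparse extrinsic edge lists
  std::vector<int> fi, fj, bi, bj;
  std::vector<double> fw, bw;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (AF(i, j) != 0.0) { fi.push_back(i); fj.push_back(j); fw.push_back(AF(i, j)); }
      if (AB(i, j) != 0.0) { bi.push_back(i); bj.push_back(j); bw.push_back(AB(i, j)); }
    }

  const double ke = He / taue, ki = Hi / taui;
  const double ae = 2.0 / taue, be = 1.0 / (taue * taue);
  const double ai = 2.0 / taui, bi2 = 1.0 / (taui * taui);

  // thalamic drive precomputed at half-step resolution (RK4 stage times)
  const int nhalf = 2 * nsteps + 1;
  std::vector<double> U((size_t)nhalf * n, 0.0);
  for (int h = 0; h < nhalf; ++h) {
    double t = t0 + 0.5 * dt * h;
    for (int c = 0; c < ncomp; ++c) {
      double z = (t - mu[c]) / sigma[c];
      double ev = std::exp(-0.5 * z * z);
      for (int i = 0; i < n; ++i) U[(size_t)h * n + i] += Cmat(i, c) * ev;
    }
  }

  const int ns = 8 * n;
  std::vector<double> x(ns, 0.0), k1(ns), k2(ns), k3(ns), k4(ns), xs(ns);

  // firing-rate history at internal grid points, row-major [step][node]
  std::vector<double> Sp((size_t)(nsteps + 1) * n, 0.0),
      S1((size_t)(nsteps + 1) * n, 0.0), S7((size_t)(nsteps + 1) * n, 0.0);
  int filled = 0;

  std::vector<double> vout((size_t)(nsteps + 1) * n);
  std::vector<double> sall;
  if (return_states) sall.resize((size_t)(nsteps + 1) * ns);

  // delayed interpolation: base row + weight, shared across nodes/rates
  struct Lag { int k; double w; bool on; };
  auto lag_at = [&](double t) -> Lag {
    double u = (t - t0) / dt;
    if (u <= 0.0 || filled == 0) return {0, 0.0, false};
    int k = (int)u;
    if (k >= filled - 1) k = filled - 2;
    if (k < 0) return {0, 0.0, false};
    return {k, u - k, true};
  };
  auto look = [&](const std::vector<double>& buf, const Lag& L, int node) {
    if (!L.on) return 0.0;
    return (1.0 - L.w) * buf[(size_t)L.k * n + node] +
           L.w * buf[(size_t)(L.k + 1) * n + node];
  };

  std::vector<double> spd(n), s1d(n), s7d(n), fwd(n), bwd(n);

  auto deriv = [&](double t, int uh, const std::vector<double>& y,
                   std::vector<double>& dy) {
    Lag Li = lag_at(t - d_int), Le = lag_at(t - d_ext);
    for (int i = 0; i < n; ++i) {
      spd[i] = look(Sp, Li, i);
      s1d[i] = look(S1, Li, i);
      s7d[i] = look(S7, Li, i);
      fwd[i] = 0.0;
      bwd[i] = 0.0;
    }
    for (size_t e = 0; e < fi.size(); ++e)
      fwd[fi[e]] += fw[e] * look(Sp, Le, fj[e]);
    for (size_t e = 0; e < bi.size(); ++e)
      bwd[bi[e]] += bw[e] * look(Sp, Le, bj[e]);
    const double* u = &U[(size_t)uh * n];
    for (int i = 0; i < n; ++i) {
      const double* yi = &y[8 * i];
      double* di = &dy[8 * i];
      di[0] = yi[3];
      di[3] = ke * (g1[i] * spd[i] + fwd[i] + u[i]) - ae * yi[3] - be * yi[0];
      di[1] = yi[4];
      di[4] = ke * (g2[i] * s1d[i] + bwd[i]) - ae * yi[4] - be * yi[1];
      di[2] = yi[5];
      di[5] = ki * g4[i] * s7d[i] - ai * yi[5] - bi2 * yi[2];
      di[6] = yi[7];
      di[7] = ke * (g3[i] * spd[i] + bwd[i]) - ae * yi[7] - be * yi[6];
    }
  };

  auto record = [&](int step) {
    for (int i = 0; i < n; ++i) {
      double vp = x[8 * i + 1] - x[8 * i + 2];
      Sp[(size_t)step * n + i] = sigm(vp, slope);
      S1[(size_t)step * n + i] = sigm(x[8 * i + 0], slope);
      S7[(size_t)step * n + i] = sigm(x[8 * i + 6], slope);
      vout[(size_t)step * n + i] = vp;
    }
    filled = step + 1;
    if (return_states)
      for (int s = 0; s < ns; ++s) sall[(size_t)step * ns + s] = x[s];
  };

  record(0);
  for (int step = 0; step < nsteps; ++step) {
    double t = t0 + step * dt;
    deriv(t, 2 * step, x, k1);
    for (int s = 0; s < ns; ++s) xs[s] = x[s] + 0.5 * dt * k1[s];
    deriv(t + 0.5 * dt, 2 * step + 1, xs, k2);
    for (int s = 0; s < ns; ++s) xs[s] = x[s] + 0.5 * dt * k2[s];
    deriv(t + 0.5 * dt, 2 * step + 1, xs, k3);
    for (int s = 0; s < ns; ++s) xs[s] = x[s] + dt * k3[s];
    deriv(t + dt, 2 * step + 2, xs, k4);
    for (int s = 0; s < ns; ++s)
      x[s] += dt / 6.0 * (k1[s] + 2.0 * k2[s] + 2.0 * k3[s] + k4[s]);
    record(step + 1);
    if (!std::isfinite(x[1]) || !std::isfinite(x[2])) {
      stop("divergent integration (non-finite state) at t = %f; "
           "check synaptic gains, coupling strengths and input amplitudes",
           t + dt);
    }
  }

  const int outrows = return_states ? ns : n;
  NumericMatrix out(outrows, nt);
  for (int k = 0; k < nt; ++k) {
    double uu = (times[k] - t0) / dt;
    int j = (int)uu;
    if (j >= nsteps) j = nsteps - 1;
    if (j < 0) j = 0;
    double w = uu - j;
    if (return_states) {
      for (int s = 0; s < ns; ++s)
        out(s, k) = (1.0 - w) * sall[(size_t)j * ns + s] +
                    w * sall[(size_t)(j + 1) * ns + s];
    } else {
      for (int i = 0; i < n; ++i)
        out(i, k) = (1.0 - w) * vout[(size_t)j * n + i] +
                    w * vout[(size_t)(j + 1) * n + i];
    }
  }
  return out;
}
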