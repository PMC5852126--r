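// Fixed-step Euler / Euler-Maruyama core for the 4-variable interneuron
// model with I_h. Kept in C++ because the reference integration step is
// 0.001 ms while protocols span tens to hundreds of simulated seconds.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double C, gNa, ENa, gK, EK, gL, EL, gh, Eh, phi, Iapp;
};

inline Pars unpack(const NumericVector& p) {
  Pars q;
  q.C = p["C"];   q.gNa = p["gNa"]; q.ENa = p["ENa"];
  q.gK = p["gK"]; q.EK = p["EK"];   q.gL = p["gL"];
  q.EL = p["EL"]; q.gh = p["gh"];   q.Eh = p["Eh"];
  q.phi = p["phi"]; q.Iapp = p["Iapp"];
  return q;
}

// y/(1 - exp(-y)) with its removable singularity at y = 0 filled in.
inline double sratio(double y) {
  if (std::fabs(y) < 1e-7) return 1.0 + 0.5 * y + y * y / 12.0;
  return y / (-std::expm1(-y));
}

// Deterministic stimulus value at time t (ms).
// kind: 0 constant, 1 square pulse, 2 ramp, 3 zap chirp, 4 sine.
inline double stim_at(double t, int kind, const double* sp) {
  switch (kind) {
  case 0: return sp[0];
  case 1: // amplitude, onset, duration; half-open window
    return (t >= sp[1] && t < sp[1] + sp[2]) ? sp[0] : 0.0;
  case 2: // rate (uA/cm2 per ms), onset
    return (t >= sp[1]) ? sp[0] * (t - sp[1]) : 0.0;
  case 3: { // Istim, fmin (Hz), fmax (Hz), T (s); literal sin(2*pi*f(t)*t)
    double ts = t / 1000.0;
    if (ts < 0.0 || ts > sp[3]) return 0.0;
    double f = sp[1] + (sp[2] - sp[1]) * ts / sp[3];
    return sp[0] * std::sin(2.0 * M_PI * f * ts);
  }
  case 4: // amplitude, f1 (Hz), onset (ms)
    return (t >= sp[2])
      ? sp[0] * std::sin(2.0 * M_PI * sp[1] * (t - sp[2]) / 1000.0)
      : 0.0;
  }
  return 0.0;
}

struct Deriv { double dV, dh, dn, dH; };

inline Deriv rhs(const Pars& q, double V, double h, double n, double H,
                 double Iext) {
  double am = sratio(0.1 * (V + 35.0));
  double bm = 4.0 * std::exp(-(V + 60.0) / 18.0);
  double minf = am / (am + bm);
  double ah = 0.07 * std::exp(-(V + 58.0) / 20.0);
  double bh = 1.0 / (std::exp(-0.1 * (V + 28.0)) + 1.0);
  double an = 0.1 * sratio(0.1 * (V + 34.0));
  double bn = 0.125 * std::exp(-(V + 44.0) / 80.0);
  double Hinf = 1.0 / (1.0 + std::exp((V + 80.0) / 10.0));
  double w = (V + 70.0) / 20.0;
  double tauH = 200.0 / (std::exp(w) + std::exp(-w)) + 5.0;

  double m3 = minf * minf * minf;
  double INa = q.gNa * m3 * h * (V - q.ENa);
  double IK = q.gK * n * n * n * n * (V - q.EK);
  double Ih = q.gh * H * (V - q.Eh);
  double IL = q.gL * (V - q.EL);

  Deriv d;
  d.dV = (-INa - IK - Ih - IL + q.Iapp + Iext) / q.C;
  d.dh = q.phi * (ah * (1.0 - h) - bh * h);
  d.dn = q.phi * (an * (1.0 - n) - bn * n);
  d.dH = (Hinf - H) / tauH;
  return d;
}

inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

} // namespace

//' @keywords internal
// [[Rcpp::export(name = ".cpp_integrate")]]
List cpp_integrate(NumericVector par, int stim_kind, NumericVector stim_par,
                   NumericVector x0, double t_end, double dt, double D,
                   int thin) {
  Pars q = unpack(par);
  const double* sp = stim_par.begin();
  double V = x0[0], h = x0[1], n = x0[2], H = x0[3];
  long nstep = (long)std::floor(t_end / dt + 0.5);
  long nrec = nstep / thin + 1;
  NumericVector Tt(nrec), Vv(nrec), Hh(nrec), Nn(nrec), HH(nrec), Ss(nrec);
  double noise_sd = (D > 0.0) ? (D / q.C) * std::sqrt(dt) : 0.0;
  long k = 0;
  for (long i = 0; i <= nstep; ++i) {
    double t = i * dt;
    double Iext = stim_at(t, stim_kind, sp);
    if (i % thin == 0) {
      Tt[k] = t; Vv[k] = V; Hh[k] = h; Nn[k] = n; HH[k] = H; Ss[k] = Iext;
      ++k;
    }
    if (i == nstep) break;
    Deriv d = rhs(q, V, h, n, H, Iext);
    V += dt * d.dV;
    if (noise_sd > 0.0) V += noise_sd * norm_rand();
    h = clip01(h + dt * d.dh);
    n = clip01(n + dt * d.dn);
    H = clip01(H + dt * d.dH);
    if (!std::isfinite(V) || std::fabs(V) > 500.0)
      stop("integration blew up at step %ld (t = %g ms)", i + 1,
           (i + 1) * dt);
  }
  return List::create(_["t"] = Tt, _["V"] = Vv, _["h"] = Hh, _["n"] = Nn,
                      _["H"] = HH, _["stim"] = Ss);
}

//' @keywords internal
// [[Rcpp::export(name = ".cpp_spike_run")]]
List cpp_spike_run(NumericVector par, int stim_kind, NumericVector stim_par,
                   NumericVector x0, double t_end, double dt, double D,
                   double threshold, double refractory, double t_discard,
                   int max_spikes) {
  Pars q = unpack(par);
  const double* sp = stim_par.begin();
  double V = x0[0], h = x0[1], n = x0[2], H = x0[3];
  long nstep = (long)std::floor(t_end / dt + 0.5);
  double noise_sd = (D > 0.0) ? (D / q.C) * std::sqrt(dt) : 0.0;
  std::vector<double> spikes;
  double last_spike = -1e300;
  double Vprev = V;
  double t_final = 0.0;
  for (long i = 0; i < nstep; ++i) {
    double t = i * dt;
    double Iext = stim_at(t, stim_kind, sp);
    Deriv d = rhs(q, V, h, n, H, Iext);
    Vprev = V;
    V += dt * d.dV;
    if (noise_sd > 0.0) V += noise_sd * norm_rand();
    h = clip01(h + dt * d.dh);
    n = clip01(n + dt * d.dn);
    H = clip01(H + dt * d.dH);
    if (!std::isfinite(V) || std::fabs(V) > 500.0)
      stop("integration blew up at step %ld (t = %g ms)", i + 1,
           (i + 1) * dt);
    double tnew = t + dt;
    if (Vprev < threshold && V >= threshold) {
      double tc = t + dt * (threshold - Vprev) / (V - Vprev);
      if (tc >= t_discard && tc - last_spike >= refractory) {
        spikes.push_back(tc);
        last_spike = tc;
        if (max_spikes > 0 && (int)spikes.size() >= max_spikes) {
          t_final = tnew;
          break;
        }
      } else if (tc - last_spike >= refractory) {
        last_spike = tc; // refractory bookkeeping also before discard
      }
    }
    t_final = tnew;
  }
  return List::create(
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["state"] = NumericVector::create(_["V"] = V, _["h"] = h, _["n"] = n,
                                       _["H"] = H),
    _["t_final"] = t_final);
}
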