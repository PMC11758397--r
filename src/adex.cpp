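#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step Euler-Maruyama integration of the adaptive exponential
// integrate-and-fire (AdEx) membrane equation with an Ornstein-Uhlenbeck
// noise current. Units: mV, pA, nS, pF, ms. The exponential spike drive
// is capped so the upstroke completes in a few samples without overflow;
// a sample reaching v_peak is recorded as a spike, drawn at v_peak, and
// followed by reset to v_r with the adaptation increment b.
//
// [[Rcpp::export]]
List adex_integrate_cpp(NumericVector current_pa, double dt,
                        double C, double gL, double EL, double VT,
                        double DeltaT, double a, double b, double tauw,
                        double Vr, double Vpeak,
                        double noise_sigma, double noise_tau,
                        double V0, double w0) {
  const int n = current_pa.size();
  NumericVector V(n);
  std::vector<int> spikes;
  double v = V0, w = w0, eta = 0.0;
  const double edt = (noise_tau > 0) ? std::exp(-dt / noise_tau) : 0.0;
  const double sde = (noise_tau > 0) ? std::sqrt(1.0 - edt * edt) : 1.0;
  const double exp_cap = 10.0;  // cap on (V - VT)/DeltaT inside exp()
  bool refractory_reset = false;

  for (int k = 0; k < n; ++k) {
    if (refractory_reset) {
      v = Vr;
      w += b;
      refractory_reset = false;
    }
    double ex = (v - VT) / DeltaT;
    if (ex > exp_cap) ex = exp_cap;
    double I_noise = 0.0;
    if (noise_sigma > 0) {
      eta = eta * edt + noise_sigma * sde * R::rnorm(0.0, 1.0);
      I_noise = eta;
    }
    double dv = (-gL * (v - EL) + gL * DeltaT * std::exp(ex) - w +
                 current_pa[k] + I_noise) / C * dt;
    double dw = (a * (v - EL) - w) / tauw * dt;
    v += dv;
    w += dw;
    if (v >= Vpeak) {
      v = Vpeak;
      spikes.push_back(k + 1);  // 1-based sample index of the peak
      refractory_reset = true;
    }
    if (v < -200.0 || !R_finite(v)) {
      stop("AdEx trajectory diverged (|V| > 200 mV); check parameters");
    }
    V[k] = v;
  }
  return List::create(_["voltage_mv"] = V,
                      _["spike_idx"] = wrap(spikes));
}
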