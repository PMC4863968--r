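#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of the two-channel
// contact process:
//   O -> P at total rate alpha * (n_I / N) * n_O
//   P -> O at total rate beta  * (n_O / N) * n_P
// The per-capita hazards are normalized by N so the large-N limit recovers
// the mean-field ODE with the same alpha, beta. Inflexible agents never
// change state; every event moves one agent between P and O, so
// n_I + n_P + n_O is conserved. Uses R's RNG: runs are reproducible under
// set.seed().
// [[Rcpp::export]]
List gillespie_run_cpp(int n_I, int n_P, int n_O,
                       double alpha, double beta, double t_max) {
  const double N = static_cast<double>(n_I) + n_P + n_O;
  std::vector<double> ts;
  std::vector<int> Ps, Os;
  double t = 0.0;
  ts.push_back(t); Ps.push_back(n_P); Os.push_back(n_O);
  bool absorbed = false;

  while (true) {
    const double a1 = alpha * (n_I / N) * n_O;  // O -> P
    const double a2 = beta * (n_O / N) * n_P;   // P -> O
    const double a0 = a1 + a2;
    if (a0 <= 0.0) { absorbed = true; break; }  // no enabled channel
    const double dt = R::exp_rand() / a0;
    if (t + dt > t_max) break;
    t += dt;
    if (R::unif_rand() * a0 < a1) { --n_O; ++n_P; } else { --n_P; ++n_O; }
    ts.push_back(t); Ps.push_back(n_P); Os.push_back(n_O);
  }

  return List::create(_["t"] = ts, _["n_P"] = Ps, _["n_O"] = Os,
                      _["absorbed"] = absorbed);
}
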