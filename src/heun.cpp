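#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Drift of the noisy Kuramoto system: f_i = omega_i + K * sum_{j ~ i} sin(theta_j - theta_i).
// Edge list is 0-based; each undirected edge appears once and contributes
// antisymmetrically to both endpoints.  The pairwise sine is expanded as
// sin(a - b) = sin(a) cos(b) - cos(a) sin(b) over per-node sin/cos tables so
// the trigonometric work scales with the node count, not the edge count.
static inline void kuramoto_drift_edges(const double* theta,
                                        const double* omega,
                                        const int* ei, const int* ej,
                                        int n_edges, int n, double K,
                                        double* sn, double* cs, double* f) {
  for (int i = 0; i < n; ++i) {
    sn[i] = std::sin(theta[i]);
    cs[i] = std::cos(theta[i]);
    f[i] = 0.0;
  }
  for (int e = 0; e < n_edges; ++e) {
    const int a = ei[e], b = ej[e];
    const double s = sn[b] * cs[a] - cs[b] * sn[a];
    f[a] += s;
    f[b] -= s;
  }
  for (int i = 0; i < n; ++i) f[i] = omega[i] + K * f[i];
}

//' @title Stochastic Heun integration of the noisy Kuramoto model (internal)
//' @description Advances theta' = omega + K * sum_j A_ij sin(theta_j - theta_i) + xi
//'   with additive Gaussian white noise of intensity D by the improved Euler
//'   (Heun) predictor-corrector.  The same Gaussian increment, of standard
//'   deviation sqrt(2 D dt), is used in the predictor and the corrector so the
//'   scheme reduces to deterministic Heun at D = 0.  Uses R's RNG stream so
//'   trajectories are reproducible under set.seed().
//' @return matrix of unwrapped phases, one row per retained sample (columns = nodes)
//' @keywords internal
// [[Rcpp::export(name = ".heun_kuramoto")]]
NumericMatrix heun_kuramoto(IntegerVector edge_i, IntegerVector edge_j,
                            int n, NumericVector theta0, NumericVector omega,
                            double K, double D, double dt,
                            int n_transient_steps, int n_measure_steps,
                            int stride) {
  const int n_edges = edge_i.size();
  if (edge_j.size() != n_edges) stop("edge index vectors differ in length");
  if (theta0.size() != n || omega.size() != n)
    stop("theta0/omega length must equal the node count");
  if (dt <= 0) stop("dt must be positive");
  if (stride < 1) stop("stride must be >= 1");

  const int n_samples = n_measure_steps / stride;
  NumericMatrix out(n_samples, n);

  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> pred(n), f0(n), f1(n), eta(n), sn(n), cs(n);
  const double sigma = std::sqrt(2.0 * D * dt);
  const int total_steps = n_transient_steps + n_measure_steps;

  // The drift is invariant under per-node shifts by 2*pi, so the dynamic
  // state is kept wrapped in [-pi, pi] (keeping sin/cos on their fast paths
  // for arbitrarily long runs) while per-node winding offsets accumulate the
  // unwrapped trajectory for the output.
  std::vector<double> winding(n, 0.0);
  const double two_pi = 2.0 * M_PI;

  RNGScope scope;
  int sample = 0;
  for (int step = 1; step <= total_steps; ++step) {
    if (sigma > 0.0) {
      for (int i = 0; i < n; ++i) eta[i] = sigma * norm_rand();
    } else {
      for (int i = 0; i < n; ++i) eta[i] = 0.0;
    }
    kuramoto_drift_edges(theta.data(), omega.begin(), edge_i.begin(),
                         edge_j.begin(), n_edges, n, K, sn.data(),
                         cs.data(), f0.data());
    for (int i = 0; i < n; ++i) pred[i] = theta[i] + dt * f0[i] + eta[i];
    kuramoto_drift_edges(pred.data(), omega.begin(), edge_i.begin(),
                         edge_j.begin(), n_edges, n, K, sn.data(),
                         cs.data(), f1.data());
    const double hdt = 0.5 * dt;
    for (int i = 0; i < n; ++i) {
      theta[i] += hdt * (f0[i] + f1[i]) + eta[i];
      if (theta[i] > M_PI) {
        theta[i] -= two_pi;
        winding[i] += two_pi;
      } else if (theta[i] < -M_PI) {
        theta[i] += two_pi;
        winding[i] -= two_pi;
      }
    }

    if (step > n_transient_steps) {
      const int m_step = step - n_transient_steps;
      if (m_step % stride == 0 && sample < n_samples) {
        for (int i = 0; i < n; ++i) {
          if (!std::isfinite(theta[i]))
            stop("non-finite phase at t = %f, node %d: integration diverged",
                 step * dt, i + 1);
          out(sample, i) = theta[i] + winding[i];
        }
        ++sample;
      }
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
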