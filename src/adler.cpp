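#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the stochastic Adler equation for the
// phase difference Delta (in beats):
//   dDelta = (delta_nu - 2*pi*eps*sin(2*pi*Delta)) dt + sqrt(2*Teff*dt) dW
// Uses R's RNG so results are reproducible via set.seed() on the R side.
// Returns the series thinned by `thin` (first element is Delta at t = 0).
// [[Rcpp::export]]
NumericVector adler_em_cpp(double delta0, double delta_nu, double eps,
                           double teff, double dt, int nsteps, int thin) {
    const double twopi = 2.0 * M_PI;
    const double drift_eps = twopi * eps;
    const double noise_amp = std::sqrt(2.0 * teff * dt);
    int nout = nsteps / thin + 1;
    NumericVector out(nout);
    double delta = delta0;
    out[0] = delta;
    int k = 1;
    if (teff > 0.0) {
        for (int i = 1; i <= nsteps; ++i) {
            delta += (delta_nu - drift_eps * std::sin(twopi * delta)) * dt
                   + noise_amp * R::norm_rand();
            if (i % thin == 0 && k < nout) out[k++] = delta;
        }
    } else {
        for (int i = 1; i <= nsteps; ++i) {
            delta += (delta_nu - drift_eps * std::sin(twopi * delta)) * dt;
            if (i % thin == 0 && k < nout) out[k++] = delta;
        }
    }
    return out;
}

// Single noisy phase oscillator theta (in beats): dtheta = f dt + sqrt(2 D dt) dW.
// Returns the successive beat periods (first-passage times across integer
// phase levels), used to validate the period-distribution noise estimator.
// [[Rcpp::export]]
NumericVector noisy_oscillator_periods_cpp(double freq, double diff,
                                           double dt, int nbeats) {
    NumericVector periods(nbeats);
    const double amp = std::sqrt(2.0 * diff * dt);
    double theta = 0.0, t = 0.0, tlast = 0.0;
    int level = 1, guard = 0;
    const int max_iter = 2000000000;
    for (int b = 0; b < nbeats; ++b) {
        while (theta < level) {
            theta += freq * dt + amp * R::norm_rand();
            t += dt;
            if (++guard > max_iter) stop("oscillator failed to advance");
        }
        periods[b] = t - tlast;
        tlast = t;
        ++level;
    }
    return periods;
}
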