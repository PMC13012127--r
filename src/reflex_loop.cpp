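#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step integration of the closed-loop segmental reflex.  Kept in C++
// because gain fitting and sensitivity sweeps re-run it thousands of times.
// State: e (EMG, first order on the motoneuron drive), (f, fd) force
// (critically damped second order on e scaled by the force-length factor),
// (x, xd) plant displacement against a damped elastic load.
// [[Rcpp::export(name = ".reflex_loop")]]
List reflex_loop(int n, double dt, int d_ib, int d_ia, int n_pulse,
                 double sp, double g_ib, double g_ia, double tau,
                 double omega, double fl_coef, double inertia,
                 double damping, double stiffness, double sat,
                 double ia_sign) {
  NumericVector e(n), f(n), x(n), a(n), m(n);
  std::vector<double> fd(n, 0.0), xd(n, 0.0);
  for (int i = 0; i < n - 1; ++i) {
    double f_del = (i >= d_ib) ? f[i - d_ib] : 0.0;
    double x_del = (i >= d_ia) ? x[i - d_ia] : 0.0;
    double drive = ((i < n_pulse) ? sp : 0.0) + g_ib * f_del;
    a[i] = drive > 0.0 ? drive : 0.0;
    double u = a[i] + ia_sign * g_ia * x_del;
    m[i] = u > 0.0 ? sat * std::tanh(u / sat) : 0.0;
    e[i + 1] = e[i] + dt * (m[i] - e[i]) / tau;
    double fl = 1.0 - fl_coef * x[i];
    if (fl < 0.0) fl = 0.0;
    double fdd = omega * omega * (e[i] * fl - f[i]) - 2.0 * omega * fd[i];
    fd[i + 1] = fd[i] + dt * fdd;
    f[i + 1] = f[i] + dt * fd[i];
    double xdd = (f[i] - damping * xd[i] - stiffness * x[i]) / inertia;
    xd[i + 1] = xd[i] + dt * xdd;
    x[i + 1] = x[i] + dt * xd[i];
    if (!std::isfinite(e[i + 1]) || !std::isfinite(f[i + 1]) ||
        !std::isfinite(x[i + 1]))
      stop("non-finite state at t = %f s", (i + 1) * dt);
  }
  if (n > 1) { a[n - 1] = a[n - 2]; m[n - 1] = m[n - 2]; }
  return List::create(_["emg"] = e, _["force"] = f, _["displacement"] = x,
                      _["activation"] = a, _["motoneuron"] = m);
}
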