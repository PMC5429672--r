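#include <Rcpp.h>
using namespace Rcpp;

// Explicit finite-volume update of 1-D diffusion across the gel, with a
// Robin (membrane-flux) condition at either end: J = Pd * (C_lumen(t) - C_end).
// A negative Pd marks a zero-flux wall (single-monolayer device / symmetry).
// The lumen ramps linearly from 0 to cLumen over fillTime (time counted from
// injection); the caller guarantees dt satisfies the stability bound.
// Returns the advanced field plus the cumulative influx (um * conc units)
// through both membranes, for mass-balance checks.
// [[Rcpp::export(name = ".diffusionAdvance")]]
List diffusionAdvance(NumericVector C0, double D, double dx, double dt,
                      int nsteps, double tStart, double leftPd, double rightPd,
                      double cLumen, double fillTime, double influx0) {
  int n = C0.size();
  NumericVector C = clone(C0);
  std::vector<double> Cn(n);
  const double r = D * dt / (dx * dx);
  double t = tStart;
  double influx = influx0;
  for (int s = 0; s < nsteps; ++s) {
    double tm = t + 0.5 * dt;  // midpoint lumen value for the ramp
    double clum;
    if (tm <= 0.0) clum = 0.0;
    else if (fillTime <= 0.0 || tm >= fillTime) clum = cLumen;
    else clum = cLumen * tm / fillTime;
    double Jl = (leftPd >= 0.0) ? leftPd * (clum - C[0]) : 0.0;
    double Jr = (rightPd >= 0.0) ? rightPd * (clum - C[n - 1]) : 0.0;
    Cn[0] = C[0] + dt * (Jl / dx - D * (C[0] - C[1]) / (dx * dx));
    for (int i = 1; i < n - 1; ++i)
      Cn[i] = C[i] + r * (C[i - 1] - 2.0 * C[i] + C[i + 1]);
    Cn[n - 1] = C[n - 1] +
      dt * (Jr / dx - D * (C[n - 1] - C[n - 2]) / (dx * dx));
    for (int i = 0; i < n; ++i) C[i] = (Cn[i] < 0.0) ? 0.0 : Cn[i];
    influx += (Jl + Jr) * dt;
    t += dt;
  }
  return List::create(_["C"] = C, _["influx"] = influx, _["t"] = t);
}
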