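#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of the linear two-region two-state system:
// x[n+1] = (I + dt*A) x[n] + dt * B u[n], with u driving the excitatory
// states (columns 1 and 3). Returns the full state trajectory.
// [[Rcpp::export(name = ".euler_integrate")]]
NumericMatrix euler_integrate(NumericMatrix Ad, NumericMatrix u, double dt) {
  const int n = u.nrow();
  NumericMatrix x(n, 4);
  double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double n0 = Ad(0,0)*s0 + Ad(0,1)*s1 + Ad(0,2)*s2 + Ad(0,3)*s3 + dt*u(i,0);
    double n1 = Ad(1,0)*s0 + Ad(1,1)*s1 + Ad(1,2)*s2 + Ad(1,3)*s3;
    double n2 = Ad(2,0)*s0 + Ad(2,1)*s1 + Ad(2,2)*s2 + Ad(2,3)*s3 + dt*u(i,1);
    double n3 = Ad(3,0)*s0 + Ad(3,1)*s1 + Ad(3,2)*s2 + Ad(3,3)*s3;
    s0 = n0; s1 = n1; s2 = n2; s3 = n3;
    x(i+1,0) = s0; x(i+1,1) = s1; x(i+1,2) = s2; x(i+1,3) = s3;
  }
  return x;
}
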