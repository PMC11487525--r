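// Fixed-step RK4 integrators for the leaky tanh reservoir ODE.
//
// Open loop:   dr/dt = gamma * ( -r + tanh(M r + sigma * Win * u(t)) )
// Closed loop: dr/dt = gamma * ( -r + tanh(M r + sigma * Win * Wout q(r)) )
// with q(r) = [r; r^2] (quadratic feature map) or q(r) = r (linear).
//
// M is sparse (connection probability ~0.04); it is passed as a dgCMatrix
// and multiplied through its raw CSC arrays. The feedback term is
// evaluated as Win * (Wout * q(r)), never as a precomputed dense N x 2N
// product, so one derivative evaluation costs O(nnz(M) + N*D) flops with
// no heap allocation inside the step loop.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

struct CscMat {
  const int* i;
  const int* p;
  const double* x;
  int n;  // square: n x n
  explicit CscMat(const Rcpp::S4& m)
      : i(INTEGER(m.slot("i"))), p(INTEGER(m.slot("p"))),
        x(REAL(m.slot("x"))), n(INTEGER(m.slot("Dim"))[1]) {}
};

static inline void sp_mv(const CscMat& M, const double* v, double* out) {
  std::fill(out, out + M.n, 0.0);
  for (int c = 0; c < M.n; ++c) {
    const double vc = v[c];
    if (vc == 0.0) continue;
    for (int k = M.p[c]; k < M.p[c + 1]; ++k) out[M.i[k]] += M.x[k] * vc;
  }
}

// deriv <- gamma * (-r + tanh(M r + sigma * Win * u)), work: length N
static inline void open_deriv(const CscMat& M, const double* Win, int N,
                              int D, double gamma, double sigma,
                              const double* r, const double* u,
                              double* work, double* deriv) {
  sp_mv(M, r, work);
  for (int d = 0; d < D; ++d) {
    const double su = sigma * u[d];
    if (su == 0.0) continue;
    const double* wcol = Win + (size_t)d * N;
    for (int n = 0; n < N; ++n) work[n] += wcol[n] * su;
  }
  for (int n = 0; n < N; ++n) deriv[n] = gamma * (-r[n] + std::tanh(work[n]));
}

// u_half: D x (2*n_steps + 1), input sampled on the half-step grid
// t0, t0 + tau/2, t0 + tau, ... so every RK4 stage sees an exact value.
// [[Rcpp::export]]
NumericMatrix rk4_open_cpp(const Rcpp::S4& M_csc, const NumericMatrix& Win,
                           double gamma, double sigma, double tau,
                           const NumericVector& r0,
                           const NumericMatrix& u_half, int n_steps) {
  const CscMat M(M_csc);
  const int N = r0.size();
  const int D = Win.ncol();
  if (u_half.ncol() < 2 * n_steps + 1)
    Rcpp::stop("input series too short: need %d half-step samples, got %d",
               2 * n_steps + 1, u_half.ncol());
  if (u_half.nrow() != D) Rcpp::stop("input dimension mismatch");
  NumericMatrix out(n_steps + 1, N);
  std::vector<double> r(r0.begin(), r0.end()), rt(N), work(N),
      k1(N), k2(N), k3(N), k4(N);
  const double* win = &Win(0, 0);
  const double* uh = &u_half(0, 0);
  for (int n = 0; n < N; ++n) out(0, n) = r[n];
  for (int s = 0; s < n_steps; ++s) {
    const double* u0 = uh + (size_t)D * (2 * s);
    const double* um = uh + (size_t)D * (2 * s + 1);
    const double* u1 = uh + (size_t)D * (2 * s + 2);
    open_deriv(M, win, N, D, gamma, sigma, r.data(), u0, work.data(), k1.data());
    for (int n = 0; n < N; ++n) rt[n] = r[n] + 0.5 * tau * k1[n];
    open_deriv(M, win, N, D, gamma, sigma, rt.data(), um, work.data(), k2.data());
    for (int n = 0; n < N; ++n) rt[n] = r[n] + 0.5 * tau * k2[n];
    open_deriv(M, win, N, D, gamma, sigma, rt.data(), um, work.data(), k3.data());
    for (int n = 0; n < N; ++n) rt[n] = r[n] + tau * k3[n];
    open_deriv(M, win, N, D, gamma, sigma, rt.data(), u1, work.data(), k4.data());
    for (int n = 0; n < N; ++n) {
      r[n] += (tau / 6.0) * (k1[n] + 2.0 * k2[n] + 2.0 * k3[n] + k4[n]);
      out(s + 1, n) = r[n];
    }
  }
  return out;
}

// w <- Wout q(r); W1, W2 are D x N blocks (column-major)
static inline void readout_eval(const double* W1, const double* W2,
                                bool quadratic, int N, int D,
                                const double* r, double* w) {
  std::fill(w, w + D, 0.0);
  for (int n = 0; n < N; ++n) {
    const double rn = r[n];
    const double* c1 = W1 + (size_t)D * n;
    for (int d = 0; d < D; ++d) w[d] += c1[d] * rn;
  }
  if (quadratic) {
    for (int n = 0; n < N; ++n) {
      const double rn2 = r[n] * r[n];
      const double* c2 = W2 + (size_t)D * n;
      for (int d = 0; d < D; ++d) w[d] += c2[d] * rn2;
    }
  }
}

static inline void closed_deriv(const CscMat& M, const double* Win,
                                const double* W1, const double* W2,
                                bool quadratic, int N, int D, double gamma,
                                double sigma, const double* r, double* w,
                                double* work, double* deriv) {
  readout_eval(W1, W2, quadratic, N, D, r, w);
  open_deriv(M, Win, N, D, gamma, sigma, r, w, work, deriv);
}

// Wout: D x 2N (quadratic) or D x N (linear). Records the projected
// output at every step; full states only when record_states is true.
// [[Rcpp::export]]
Rcpp::List rk4_closed_cpp(const Rcpp::S4& M_csc, const NumericMatrix& Win,
                          const NumericMatrix& Wout, double gamma,
                          double sigma, double tau, const NumericVector& r0,
                          int n_steps, bool quadratic, bool record_states,
                          double diverge_guard) {
  const CscMat M(M_csc);
  const int N = r0.size();
  const int D = Wout.nrow();
  if (Wout.ncol() != (quadratic ? 2 * N : N))
    Rcpp::stop("readout shape inconsistent with feature map");
  // split Wout into the linear and quadratic blocks, both D x N
  std::vector<double> W1(&Wout(0, 0), &Wout(0, 0) + (size_t)D * N);
  std::vector<double> W2;
  if (quadratic)
    W2.assign(&Wout(0, 0) + (size_t)D * N, &Wout(0, 0) + (size_t)2 * D * N);
  else
    W2.assign((size_t)D * N, 0.0);
  NumericMatrix proj(n_steps + 1, D);
  NumericMatrix states;
  if (record_states) states = NumericMatrix(n_steps + 1, N);
  std::vector<double> r(r0.begin(), r0.end()), rt(N), work(N), w(D),
      k1(N), k2(N), k3(N), k4(N);
  const double* win = &Win(0, 0);
  readout_eval(W1.data(), W2.data(), quadratic, N, D, r.data(), w.data());
  for (int d = 0; d < D; ++d) proj(0, d) = w[d];
  if (record_states)
    for (int n = 0; n < N; ++n) states(0, n) = r[n];
  for (int s = 0; s < n_steps; ++s) {
    closed_deriv(M, win, W1.data(), W2.data(), quadratic, N, D, gamma, sigma,
                 r.data(), w.data(), work.data(), k1.data());
    for (int n = 0; n < N; ++n) rt[n] = r[n] + 0.5 * tau * k1[n];
    closed_deriv(M, win, W1.data(), W2.data(), quadratic, N, D, gamma, sigma,
                 rt.data(), w.data(), work.data(), k2.data());
    for (int n = 0; n < N; ++n) rt[n] = r[n] + 0.5 * tau * k2[n];
    closed_deriv(M, win, W1.data(), W2.data(), quadratic, N, D, gamma, sigma,
                 rt.data(), w.data(), work.data(), k3.data());
    for (int n = 0; n < N; ++n) rt[n] = r[n] + tau * k3[n];
    closed_deriv(M, win, W1.data(), W2.data(), quadratic, N, D, gamma, sigma,
                 rt.data(), w.data(), work.data(), k4.data());
    bool bad = false;
    double amax = 0.0;
    for (int n = 0; n < N; ++n) {
      r[n] += (tau / 6.0) * (k1[n] + 2.0 * k2[n] + 2.0 * k3[n] + k4[n]);
      if (!std::isfinite(r[n])) bad = true;
      const double a = std::fabs(r[n]);
      if (a > amax) amax = a;
    }
    if (bad) Rcpp::stop("non-finite closed-loop state at step %d", s + 1);
    if (amax > diverge_guard)
      Rcpp::stop("closed-loop state exceeded divergence guard %g at step %d",
                 diverge_guard, s + 1);
    readout_eval(W1.data(), W2.data(), quadratic, N, D, r.data(), w.data());
    for (int d = 0; d < D; ++d) proj(s + 1, d) = w[d];
    if (record_states)
      for (int n = 0; n < N; ++n) states(s + 1, n) = r[n];
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("projected") = proj,
      Rcpp::Named("final_state") = NumericVector(r.begin(), r.end()));
  if (record_states) out["states"] = states;
  return out;
}
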