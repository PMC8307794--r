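// Quasi-Newton (BFGS) trainer for a small fully connected network with tanh
// hidden layers and a linear output layer.  The loss is the mean squared
// error averaged over samples and output positions.  The scalar step along
// each search direction is chosen by Brent's derivative-free minimizer on
// [0, 10]; the inverse-Hessian approximation is reset to the identity
// whenever the curvature condition fails.  Everything is deterministic.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
#if defined(__SSE2__) || defined(__x86_64__)
#define GLUCOPRED_HAVE_SSE 1
#include <xmmintrin.h>
#endif

using arma::mat;
using arma::vec;
using arma::rowvec;

namespace {

struct Net {
  std::vector<mat> W;
  std::vector<vec> b;
  int n_layers;  // number of weight layers
};

Net unpack(const vec &w, const std::vector<int> &sizes) {
  Net net;
  net.n_layers = static_cast<int>(sizes.size()) - 1;
  arma::uword pos = 0;
  for (int l = 0; l < net.n_layers; ++l) {
    int nin = sizes[l], nout = sizes[l + 1];
    mat Wl(nin, nout);
    std::copy(w.memptr() + pos, w.memptr() + pos + nin * nout, Wl.memptr());
    pos += nin * nout;
    vec bl(nout);
    std::copy(w.memptr() + pos, w.memptr() + pos + nout, bl.memptr());
    pos += nout;
    net.W.push_back(std::move(Wl));
    net.b.push_back(std::move(bl));
  }
  return net;
}

void pack_grad(const std::vector<mat> &gW, const std::vector<vec> &gb,
               vec &g) {
  arma::uword pos = 0;
  for (size_t l = 0; l < gW.size(); ++l) {
    std::copy(gW[l].memptr(), gW[l].memptr() + gW[l].n_elem,
              g.memptr() + pos);
    pos += gW[l].n_elem;
    std::copy(gb[l].memptr(), gb[l].memptr() + gb[l].n_elem,
              g.memptr() + pos);
    pos += gb[l].n_elem;
  }
}

// forward pass; returns loss, optionally fills activations
double loss_only(const vec &w, const std::vector<int> &sizes,
                 const mat &X, const mat &Y) {
  Net net = unpack(w, sizes);
  mat A = X;
  for (int l = 0; l < net.n_layers; ++l) {
    A = A * net.W[l];
    A.each_row() += net.b[l].t();
    if (l < net.n_layers - 1) A = arma::tanh(A);
  }
  const mat E = A - Y;
  return arma::accu(E % E) / static_cast<double>(Y.n_elem);
}

double loss_grad(const vec &w, const std::vector<int> &sizes,
                 const mat &X, const mat &Y, vec &g) {
  Net net = unpack(w, sizes);
  const int L = net.n_layers;
  std::vector<mat> acts(L + 1);
  acts[0] = X;
  for (int l = 0; l < L; ++l) {
    mat Z = acts[l] * net.W[l];
    Z.each_row() += net.b[l].t();
    acts[l + 1] = (l < L - 1) ? mat(arma::tanh(Z)) : Z;
  }
  const mat E = acts[L] - Y;
  const double f = arma::accu(E % E) / static_cast<double>(Y.n_elem);

  std::vector<mat> gW(L);
  std::vector<vec> gb(L);
  mat D = (2.0 / static_cast<double>(Y.n_elem)) * E;
  for (int l = L - 1; l >= 0; --l) {
    gW[l] = acts[l].t() * D;
    gb[l] = arma::sum(D, 0).t();
    if (l > 0) {
      D = (D * net.W[l].t()) % (1.0 - acts[l] % acts[l]);
    }
  }
  pack_grad(gW, gb, g);
  return f;
}

// Brent's local minimizer on [a, b] (derivative-free, parabolic
// interpolation with golden-section fallback).
template <class F>
double brent_min(F phi, double a, double b, double tol, double &fmin) {
  const double golden = 0.5 * (3.0 - std::sqrt(5.0));
  const double eps = std::sqrt(std::numeric_limits<double>::epsilon());
  double x = a + golden * (b - a);
  double wp = x, v = x;
  double fx = phi(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    const double xm = 0.5 * (a + b);
    const double tol1 = eps * std::fabs(x) + tol / 3.0;
    const double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool use_golden = true;
    if (std::fabs(e) > tol1) {
      const double r = (x - wp) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - wp) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      const double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) &&
          p > q * (a - x) && p < q * (b - x)) {
        d = p / q;
        const double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        use_golden = false;
      }
    }
    if (use_golden) {
      e = (x >= xm) ? a - x : b - x;
      d = golden * e;
    }
    const double u =
        (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    const double fu = phi(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = wp; fv = fw; wp = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || wp == x) {
        v = wp; fv = fw; wp = u; fw = fu;
      } else if (fu <= fv || v == x || v == wp) {
        v = u; fv = fu;
      }
    }
  }
  fmin = fx;
  return x;
}

// Saturated tanh units shed gradients in the denormal range, and the dense
// rank-2 BFGS update then crawls through denormal arithmetic.  Treating
// those magnitudes (< 1e-308) as zero changes nothing the optimization can
// resolve and keeps the update running at full speed.
struct ScopedFlushDenormals {
#ifdef GLUCOPRED_HAVE_SSE
  unsigned int saved;
  ScopedFlushDenormals() : saved(_mm_getcsr()) {
    _mm_setcsr(saved | 0x8040);  // FTZ | DAZ
  }
  ~ScopedFlushDenormals() { _mm_setcsr(saved); }
#endif
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List fnn_train_bfgs(const arma::vec &w0,
                          const Rcpp::IntegerVector &layer_sizes,
                          const arma::mat &X, const arma::mat &Y,
                          int max_iter, double ls_tol, double error_goal,
                          double ls_upper = 10.0) {
  std::vector<int> sizes(layer_sizes.begin(), layer_sizes.end());
  const arma::uword p = w0.n_elem;
  ScopedFlushDenormals ftz;

  vec w = w0, g(p), g_new(p);
  double f = loss_grad(w, sizes, X, Y, g);
  if (!std::isfinite(f))
    Rcpp::stop("non-finite training loss at iteration 0");
  const double f0 = f;

  mat H(p, p, arma::fill::eye);
  std::vector<double> history;
  history.reserve(max_iter);

  for (int it = 1; it <= max_iter; ++it) {
    if (f < error_goal) break;
    vec d = -(H * g);
    if (arma::dot(g, d) >= 0.0) {  // not a descent direction: reset
      H.eye();
      d = -g;
    }
    auto phi = [&](double a) { return loss_only(w + a * d, sizes, X, Y); };
    double f_ls;
    double alpha = brent_min(phi, 0.0, ls_upper, ls_tol, f_ls);
    if (f_ls > f) {  // Brent found nothing better: backtrack
      alpha = 1.0;
      double fa = phi(alpha);
      while (fa > f && alpha > 1e-14) {
        alpha *= 0.5;
        fa = phi(alpha);
      }
      if (fa > f) alpha = 0.0;
    }
    const vec s = alpha * d;
    const vec w_new = w + s;
    const double f_new = loss_grad(w_new, sizes, X, Y, g_new);
    if (!std::isfinite(f_new))
      Rcpp::stop("non-finite training loss at iteration %d", it);
    const vec y = g_new - g;
    const double sy = arma::dot(s, y);
    if (sy > 1e-12) {
      const vec Hy = H * y;
      const double yHy = arma::dot(y, Hy);
      const double c1 = (sy + yHy) / (sy * sy);
      // column-wise rank-2 update, no p*p temporaries
      for (arma::uword j = 0; j < p; ++j) {
        const double sj = s(j), hyj = Hy(j);
        H.col(j) += (c1 * sj) * s - (sj / sy) * Hy - (hyj / sy) * s;
      }
    } else {
      H.eye();  // curvature condition failed
    }
    w = w_new;
    f = f_new;
    g = g_new;
    history.push_back(f);
    Rcpp::checkUserInterrupt();
  }

  if (history.empty()) history.push_back(f);
  return Rcpp::List::create(Rcpp::Named("weights") = w,
                            Rcpp::Named("history") = history,
                            Rcpp::Named("initial_mse") = f0,
                            Rcpp::Named("final_mse") = f);
}

// [[Rcpp::export]]
double fnn_mse_cpp(const arma::vec &w, const Rcpp::IntegerVector &layer_sizes,
                   const arma::mat &X, const arma::mat &Y) {
  std::vector<int> sizes(layer_sizes.begin(), layer_sizes.end());
  return loss_only(w, sizes, X, Y);
}
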