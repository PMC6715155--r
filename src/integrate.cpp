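// Core integrator for the multiplex bioenergetic model.
//
// The right-hand side is evaluated on a flattened, link-list representation
// of the model (built in R by build_sim_model()), and the system is advanced
// with an embedded Runge-Kutta-Fehlberg 4(5) pair with standard PI-free step
// control.  Species whose biomass falls below the extinction threshold at an
// accepted step are clamped to zero and frozen for the rest of the run.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Model {
  int S;
  bool clamp_g;
  std::vector<int> is_plant;
  std::vector<double> m, r, K, x, d, w;
  double q, i0_intra;
  // trophic links (consumer -> resource)
  std::vector<int> cons, res;
  std::vector<double> a_base, h, eps;
  // NTI link lists, [source -> target]
  std::vector<int> ref_src, ref_tgt;          // refuge: sessile -> prey
  std::vector<int> n_src, n_tgt, p_src, p_tgt; // mortality +/-
  std::vector<int> eta_src, eta_tgt;          // recruitment -> plant
  std::vector<int> comp_src, comp_tgt;        // competition l -> i
  std::vector<double> comp_w;                  // gamma0 * m_l^(2/3)
  double c0, i0, n0, p0, r0_refuge, e0;
  // interference partners of each consumer: (s, delta_si)
  std::vector<std::vector<std::pair<int, double> > > ipart;
  // adjacency lookup for "s preys on j"
  std::vector<char> adj;  // S*S, row-major [consumer*S + resource]

  bool eats(int s, int j) const { return adj[(size_t)s * S + j] != 0; }
};

Model build_model(const List& ml) {
  Model M;
  M.S = as<int>(ml["S"]);
  M.clamp_g = ml.containsElementNamed("clamp_g") && as<bool>(ml["clamp_g"]);
  M.is_plant = as<std::vector<int> >(ml["is_plant"]);
  M.m = as<std::vector<double> >(ml["m"]);
  M.r = as<std::vector<double> >(ml["r"]);
  M.K = as<std::vector<double> >(ml["K"]);
  M.x = as<std::vector<double> >(ml["x"]);
  M.d = as<std::vector<double> >(ml["d"]);
  M.w = as<std::vector<double> >(ml["w"]);
  M.q = as<double>(ml["q"]);
  M.i0_intra = as<double>(ml["i0_intra"]);
  M.cons = as<std::vector<int> >(ml["cons"]);
  M.res = as<std::vector<int> >(ml["res"]);
  M.a_base = as<std::vector<double> >(ml["a_base"]);
  M.h = as<std::vector<double> >(ml["h"]);
  M.eps = as<std::vector<double> >(ml["eps"]);
  M.ref_src = as<std::vector<int> >(ml["ref_src"]);
  M.ref_tgt = as<std::vector<int> >(ml["ref_tgt"]);
  M.n_src = as<std::vector<int> >(ml["n_src"]);
  M.n_tgt = as<std::vector<int> >(ml["n_tgt"]);
  M.p_src = as<std::vector<int> >(ml["p_src"]);
  M.p_tgt = as<std::vector<int> >(ml["p_tgt"]);
  M.eta_src = as<std::vector<int> >(ml["eta_src"]);
  M.eta_tgt = as<std::vector<int> >(ml["eta_tgt"]);
  M.comp_src = as<std::vector<int> >(ml["comp_src"]);
  M.comp_tgt = as<std::vector<int> >(ml["comp_tgt"]);
  M.comp_w = as<std::vector<double> >(ml["comp_w"]);
  M.c0 = as<double>(ml["c0"]);
  M.i0 = as<double>(ml["i0"]);
  M.n0 = as<double>(ml["n0"]);
  M.p0 = as<double>(ml["p0"]);
  M.r0_refuge = as<double>(ml["r0_refuge"]);
  M.e0 = as<double>(ml["e0"]);

  M.adj.assign((size_t)M.S * M.S, 0);
  for (size_t l = 0; l < M.cons.size(); ++l)
    M.adj[(size_t)M.cons[l] * M.S + M.res[l]] = 1;

  M.ipart.assign(M.S, std::vector<std::pair<int, double> >());
  std::vector<int> d_src = as<std::vector<int> >(ml["delta_src"]);
  std::vector<int> d_tgt = as<std::vector<int> >(ml["delta_tgt"]);
  std::vector<double> d_w = as<std::vector<double> >(ml["delta_w"]);
  for (size_t l = 0; l < d_src.size(); ++l)
    M.ipart[d_tgt[l]].push_back(std::make_pair(d_src[l], d_w[l]));
  return M;
}

inline double hill_pow(double b, double q) {
  if (b <= 0.0) return 0.0;
  if (q == 0.5) return b * std::sqrt(b);
  return std::pow(b, 1.0 + q);
}

// dB/dt; extinct species (mask) are frozen at zero derivative
void eval_rhs(const Model& M, const std::vector<char>& extinct,
              const std::vector<double>& B, std::vector<double>& dB,
              std::vector<double>& scratch) {
  const int S = M.S;
  const size_t L = M.cons.size();
  // scratch layout: refsum | Bq | handling | gains | predloss (5*S)
  double* refsum = &scratch[0];
  double* Bq = refsum + S;
  double* handling = Bq + S;
  double* gains = handling + S;
  double* predloss = gains + S;
  for (int i = 0; i < S; ++i) {
    refsum[i] = 0.0;
    Bq[i] = extinct[i] ? 0.0 : hill_pow(B[i], M.q);
    handling[i] = gains[i] = predloss[i] = 0.0;
  }
  for (size_t l = 0; l < M.ref_src.size(); ++l) {
    int s = M.ref_src[l];
    if (!extinct[s] && B[s] > 0) refsum[M.ref_tgt[l]] += B[s];
  }
  // effective capture coefficients and handling sums
  std::vector<double> anew(L);
  for (size_t l = 0; l < L; ++l) {
    anew[l] = M.a_base[l] / (1.0 + M.r0_refuge * refsum[M.res[l]]);
    handling[M.cons[l]] += M.w[M.cons[l]] * anew[l] * M.h[l] * Bq[M.res[l]];
  }
  for (size_t l = 0; l < L; ++l) {
    const int i = M.cons[l], j = M.res[l];
    if (extinct[i] || Bq[j] <= 0.0) continue;
    double interf = 0.0;
    if (M.i0 > 0.0) {
      const std::vector<std::pair<int, double> >& part = M.ipart[i];
      for (size_t u = 0; u < part.size(); ++u) {
        const int s = part[u].first;
        if (!extinct[s] && B[s] > 0 && M.eats(s, j))
          interf += part[u].second * B[s];
      }
      interf *= M.i0;
    }
    const double Bi = B[i] > 0 ? B[i] : 0.0;
    const double denom = 1.0 + M.i0_intra * Bi + interf + handling[i];
    const double F = M.w[i] * anew[l] * Bq[j] / (M.m[i] * denom);
    gains[i] += M.eps[l] * F;
    predloss[j] += Bi * F;
  }
  // mortality and recruitment modifiers, competition sums
  std::vector<double> mort_up(S, 0.0), mort_down(S, 0.0), rec(S, 0.0),
      comp(S, 0.0);
  for (size_t l = 0; l < M.n_src.size(); ++l) {
    int s = M.n_src[l];
    if (!extinct[s] && B[s] > 0) mort_up[M.n_tgt[l]] += B[s];
  }
  for (size_t l = 0; l < M.p_src.size(); ++l) {
    int s = M.p_src[l];
    if (!extinct[s] && B[s] > 0) mort_down[M.p_tgt[l]] += B[s];
  }
  for (size_t l = 0; l < M.eta_src.size(); ++l) {
    int s = M.eta_src[l];
    if (!extinct[s] && B[s] > 0) rec[M.eta_tgt[l]] += B[s];
  }
  for (size_t l = 0; l < M.comp_src.size(); ++l) {
    int s = M.comp_src[l];
    if (!extinct[s] && B[s] > 0) comp[M.comp_tgt[l]] += M.comp_w[l] * B[s];
  }
  for (int i = 0; i < S; ++i) {
    if (extinct[i] || B[i] <= 0.0) { dB[i] = 0.0; continue; }
    const double rnew = M.r[i] * (1.0 + M.e0 * rec[i]);
    const double G = 1.0 - B[i] / M.K[i];
    const double net = rnew * G + gains[i] - M.x[i];
    double g = 1.0;
    if (M.c0 > 0.0 && net > 0.0) {
      g = 1.0 - M.c0 * comp[i];
      if (M.clamp_g && g < 0.0) g = 0.0;
    }
    const double dnew =
        M.d[i] * (1.0 + M.n0 * mort_up[i]) / (1.0 + M.p0 * mort_down[i]);
    dB[i] = g * net * B[i] - predloss[i] - dnew * B[i];
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(rng = false)]]
NumericVector rhs_compiled(List model, NumericVector B) {
  Model M = build_model(model);
  std::vector<char> extinct(M.S, 0);
  std::vector<double> y(B.begin(), B.end()), dy(M.S), scratch(5 * M.S);
  for (int i = 0; i < M.S; ++i) if (y[i] <= 0.0) extinct[i] = 1;
  eval_rhs(M, extinct, y, dy, scratch);
  return wrap(dy);
}

//' @noRd
// [[Rcpp::export(rng = false)]]
List integrate_rkf45(List model, NumericVector B0, double t_max,
                     double threshold, double rtol, double atol,
                     NumericVector sample_times, double h_init,
                     double h_min, double max_steps) {
  Model M = build_model(model);
  const int S = M.S;
  if ((int)B0.size() != S) stop("B0 length does not match model size");

  // Fehlberg 4(5) tableau
  const double a21 = 1.0 / 4.0;
  const double a31 = 3.0 / 32.0, a32 = 9.0 / 32.0;
  const double a41 = 1932.0 / 2197.0, a42 = -7200.0 / 2197.0,
               a43 = 7296.0 / 2197.0;
  const double a51 = 439.0 / 216.0, a52 = -8.0, a53 = 3680.0 / 513.0,
               a54 = -845.0 / 4104.0;
  const double a61 = -8.0 / 27.0, a62 = 2.0, a63 = -3544.0 / 2565.0,
               a64 = 1859.0 / 4104.0, a65 = -11.0 / 40.0;
  const double b51 = 16.0 / 135.0, b53 = 6656.0 / 12825.0,
               b54 = 28561.0 / 56430.0, b55 = -9.0 / 50.0, b56 = 2.0 / 55.0;
  const double b41 = 25.0 / 216.0, b43 = 1408.0 / 2565.0,
               b44 = 2197.0 / 4104.0, b45 = -1.0 / 5.0;

  std::vector<double> y(B0.begin(), B0.end());
  std::vector<char> extinct(S, 0);
  std::vector<double> ext_time(S, NA_REAL);
  for (int i = 0; i < S; ++i) {
    if (!(y[i] == y[i]))
      stop("non-finite initial biomass for species %d", i + 1);
    if (y[i] < threshold) { y[i] = 0.0; extinct[i] = 1; ext_time[i] = 0.0; }
  }

  std::vector<double> k1(S), k2(S), k3(S), k4(S), k5(S), k6(S),
      ytmp(S), y4(S), y5(S), scratch(5 * S);
  const int n_out = sample_times.size();
  NumericMatrix traj(n_out > 0 ? n_out : 0, n_out > 0 ? S : 0);
  int out_idx = 0;

  double t = 0.0, h = h_init;
  double steps = 0.0, rejected = 0.0;

  while (t < t_max) {
    if (steps >= max_steps)
      stop("integrator exceeded %.0f steps at t = %g", max_steps, t);
    double t_stop = t_max;
    if (out_idx < n_out && sample_times[out_idx] < t_stop)
      t_stop = sample_times[out_idx];
    if (t_stop <= t) t_stop = t_max;   // sample time already passed
    if (h > t_stop - t) h = t_stop - t;
    if (h < h_min) h = h_min;

    eval_rhs(M, extinct, y, k1, scratch);
    for (int i = 0; i < S; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    eval_rhs(M, extinct, ytmp, k2, scratch);
    for (int i = 0; i < S; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    eval_rhs(M, extinct, ytmp, k3, scratch);
    for (int i = 0; i < S; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    eval_rhs(M, extinct, ytmp, k4, scratch);
    for (int i = 0; i < S; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    eval_rhs(M, extinct, ytmp, k5, scratch);
    for (int i = 0; i < S; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    eval_rhs(M, extinct, ytmp, k6, scratch);

    double errnorm = 0.0;
    for (int i = 0; i < S; ++i) {
      y5[i] = y[i] + h * (b51 * k1[i] + b53 * k3[i] + b54 * k4[i] +
                          b55 * k5[i] + b56 * k6[i]);
      y4[i] = y[i] + h * (b41 * k1[i] + b43 * k3[i] + b44 * k4[i] +
                          b45 * k5[i]);
      const double sc =
          atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      const double e = std::fabs(y5[i] - y4[i]) / sc;
      if (e > errnorm) errnorm = e;
      if (!(y5[i] == y5[i]))
        stop("non-finite state during integration at t = %g", t);
    }

    steps += 1.0;
    const bool forced_min = (h <= h_min * (1.0 + 1e-12));
    if (errnorm <= 1.0 || forced_min) {
      t += h;
      for (int i = 0; i < S; ++i) {
        y[i] = y5[i];
        if (!extinct[i] && y[i] < threshold) {
          y[i] = 0.0;
          extinct[i] = 1;
          ext_time[i] = t;
        }
      }
      while (out_idx < n_out && t >= sample_times[out_idx] - 1e-12) {
        for (int i = 0; i < S; ++i) traj(out_idx, i) = y[i];
        ++out_idx;
      }
    } else {
      rejected += 1.0;
    }
    double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < h_min) {
      if (forced_min && errnorm > 1.0)
        stop("step size underflow at t = %g (error %g at minimal step)", t,
             errnorm);
      h = h_min;
    }
  }

  LogicalVector alive(S);
  for (int i = 0; i < S; ++i) alive[i] = !extinct[i];
  List out = List::create(
      _["B_final"] = wrap(y), _["alive"] = alive,
      _["extinction_times"] = wrap(ext_time), _["t_end"] = t,
      _["n_accepted"] = steps - rejected, _["n_rejected"] = rejected);
  if (n_out > 0) out["trajectory"] = traj;
  return out;
}
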