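#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Compiled reaction-network model.
//
// The model is a list of fluxes; each flux is
//   value = rate * prod(Hill gates) * prod(linear factors)
// and enters the derivative of each state it consumes (-1) or produces (+1).
// Species indices may point past the state vector into "derived" species,
// conserved remainders of the form max(total - sum(members), 0).
struct CompiledModel {
  int n_state;
  int n_derived;
  std::vector<double> der_total;
  std::vector<std::vector<int> > der_members; // 0-based state indices
  std::vector<double> f_rate;
  // gates (flattened)
  std::vector<int> g_flux, g_species, g_type; // type 0 = activation, 1 = repression
  std::vector<double> g_half, g_n;
  // linear factors
  std::vector<int> l_flux, l_species;
  // stoichiometry
  std::vector<int> s_flux, s_species;
  std::vector<double> s_coef;
};

static CompiledModel parseModel(const List& cm) {
  CompiledModel m;
  m.n_state = as<int>(cm["n_state"]);
  NumericVector dt = cm["der_total"];
  List dm = cm["der_members"];
  m.n_derived = dt.size();
  for (int i = 0; i < m.n_derived; ++i) {
    m.der_total.push_back(dt[i]);
    IntegerVector mem = dm[i];
    std::vector<int> v;
    for (int j = 0; j < mem.size(); ++j) v.push_back(mem[j] - 1);
    m.der_members.push_back(v);
  }
  NumericVector fr = cm["f_rate"];
  m.f_rate.assign(fr.begin(), fr.end());
  IntegerVector gf = cm["g_flux"], gs = cm["g_species"], gt = cm["g_type"];
  NumericVector gh = cm["g_half"], gn = cm["g_n"];
  for (int i = 0; i < gf.size(); ++i) {
    m.g_flux.push_back(gf[i] - 1);
    m.g_species.push_back(gs[i] - 1);
    m.g_type.push_back(gt[i]);
    m.g_half.push_back(gh[i]);
    m.g_n.push_back(gn[i]);
  }
  IntegerVector lf = cm["l_flux"], ls = cm["l_species"];
  for (int i = 0; i < lf.size(); ++i) {
    m.l_flux.push_back(lf[i] - 1);
    m.l_species.push_back(ls[i] - 1);
  }
  IntegerVector sf = cm["s_flux"], ss = cm["s_species"];
  NumericVector sc = cm["s_coef"];
  for (int i = 0; i < sf.size(); ++i) {
    m.s_flux.push_back(sf[i] - 1);
    m.s_species.push_back(ss[i] - 1);
    m.s_coef.push_back(sc[i]);
  }
  return m;
}

static inline double hillA(double x, double a, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n), an = std::pow(a, n);
  return xn / (an + xn);
}

static inline double hillR(double x, double r, double n) {
  double rn = std::pow(r, n);
  if (x <= 0.0) return 1.0;
  return rn / (rn + std::pow(x, n));
}

// Derivative for the compiled model; `ext` is scratch of length
// n_state + n_derived holding state values then derived values.
static void modelRhs(const CompiledModel& m, const double* y, double* dy,
                     std::vector<double>& ext, std::vector<double>& fval) {
  const int ns = m.n_state;
  for (int i = 0; i < ns; ++i) ext[i] = y[i];
  for (int d = 0; d < m.n_derived; ++d) {
    double v = m.der_total[d];
    const std::vector<int>& mem = m.der_members[d];
    for (size_t j = 0; j < mem.size(); ++j) v -= y[mem[j]];
    ext[ns + d] = (v > 0.0) ? v : 0.0;
  }
  const int nf = (int)m.f_rate.size();
  for (int f = 0; f < nf; ++f) fval[f] = m.f_rate[f];
  for (size_t g = 0; g < m.g_flux.size(); ++g) {
    double x = ext[m.g_species[g]];
    fval[m.g_flux[g]] *= (m.g_type[g] == 0)
      ? hillA(x, m.g_half[g], m.g_n[g])
      : hillR(x, m.g_half[g], m.g_n[g]);
  }
  for (size_t l = 0; l < m.l_flux.size(); ++l)
    fval[m.l_flux[l]] *= ext[m.l_species[l]];
  for (int i = 0; i < ns; ++i) dy[i] = 0.0;
  for (size_t s = 0; s < m.s_flux.size(); ++s)
    dy[m.s_species[s]] += m.s_coef[s] * fval[m.s_flux[s]];
}

// [[Rcpp::export]]
NumericVector rhs_eval_cpp(List cm, NumericVector y) {
  CompiledModel m = parseModel(cm);
  if (y.size() != m.n_state) stop("state vector has wrong length");
  std::vector<double> ext(m.n_state + m.n_derived), fval(m.f_rate.size());
  NumericVector dy(m.n_state);
  modelRhs(m, REAL(y), REAL(dy), ext, fval);
  return dy;
}

// ---------------------------------------------------------------------------
// Adaptive second-order Runge-Kutta (explicit midpoint) with step-doubling
// error estimation: one full step is compared against two half steps and the
// step is halved while any component's discrepancy exceeds
// relerr * |y_i| + abserr. After two consecutive acceptances the step is
// doubled, up to h_max.

template <class RHS>
static List rk2Drive(RHS rhs, int n, NumericVector y0, double t0, double t_end,
                     double relerr, double abserr, double h0, double h_min,
                     double h_max, int max_steps) {
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), ymid(n), ybig(n), yhalf(n), ysmall(n);
  std::vector<double> times;
  std::vector<double> states; // row-major: step x species
  double t = t0, h = h0;
  if (h > h_max) h = h_max;
  long accepted = 0, rejected = 0;
  times.push_back(t);
  for (int i = 0; i < n; ++i) states.push_back(y[i]);

  // one explicit-midpoint step from `from` into `to`
  const double inf = R_PosInf;
  int streak = 0;
  long iter = 0;
  while (t < t_end) {
    if (++iter > max_steps)
      stop("step limit exceeded (%ld steps) at t = %g", (long)max_steps, t);
    double hstep = h;
    if (t + hstep > t_end) hstep = t_end - t;

    // full step
    rhs(t, y.data(), k1.data());
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(k1[i]))
        stop("non-finite derivative in component %d at t = %g", i + 1, t);
      ymid[i] = y[i] + 0.5 * hstep * k1[i];
    }
    rhs(t + 0.5 * hstep, ymid.data(), k2.data());
    for (int i = 0; i < n; ++i) ybig[i] = y[i] + hstep * k2[i];

    // two half steps
    double hh = 0.5 * hstep;
    for (int i = 0; i < n; ++i) ymid[i] = y[i] + 0.5 * hh * k1[i];
    rhs(t + 0.5 * hh, ymid.data(), k2.data());
    for (int i = 0; i < n; ++i) yhalf[i] = y[i] + hh * k2[i];
    rhs(t + hh, yhalf.data(), k1.data());
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(k1[i]))
        stop("non-finite derivative in component %d at t = %g", i + 1, t + hh);
      ymid[i] = yhalf[i] + 0.5 * hh * k1[i];
    }
    rhs(t + 1.5 * hh, ymid.data(), k2.data());
    for (int i = 0; i < n; ++i) ysmall[i] = yhalf[i] + hh * k2[i];

    double worst = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(ysmall[i])) { worst = inf; break; }
      double err = std::fabs(ysmall[i] - ybig[i]);
      double tol = relerr * std::fabs(ysmall[i]) + abserr;
      double ratio = (tol > 0.0) ? err / tol : inf;
      if (ratio > worst) worst = ratio;
    }

    if (worst <= 1.0) {
      t += hstep;
      y = ysmall;
      ++accepted;
      times.push_back(t);
      for (int i = 0; i < n; ++i) states.push_back(y[i]);
      if (++streak >= 2) {
        h = std::min(2.0 * h, h_max);
        streak = 0;
      }
    } else {
      ++rejected;
      streak = 0;
      h = 0.5 * hstep;
      if (h < h_min)
        stop("step size underflow (h = %g < h_min) at t = %g: system too stiff "
             "for the requested tolerances", h, t);
    }
  }

  int nt = (int)times.size();
  NumericMatrix S(nt, n);
  for (int r = 0; r < nt; ++r)
    for (int c = 0; c < n; ++c) S(r, c) = states[(size_t)r * n + c];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = S,
                      _["accepted"] = (double)accepted,
                      _["rejected"] = (double)rejected);
}

struct ModelFunctor {
  const CompiledModel* m;
  std::vector<double>* ext;
  std::vector<double>* fval;
  void operator()(double, const double* y, double* dy) const {
    modelRhs(*m, y, dy, *ext, *fval);
  }
};

// [[Rcpp::export]]
List integrate_model_cpp(List cm, NumericVector y0, double t0, double t_end,
                         double relerr, double abserr, double h0, double h_min,
                         double h_max, double max_steps) {
  CompiledModel m = parseModel(cm);
  if (y0.size() != m.n_state) stop("initial state has wrong length");
  std::vector<double> ext(m.n_state + m.n_derived), fval(m.f_rate.size());
  ModelFunctor f; f.m = &m; f.ext = &ext; f.fval = &fval;
  return rk2Drive(f, m.n_state, y0, t0, t_end, relerr, abserr, h0, h_min,
                  h_max, (int)max_steps);
}

struct CallbackFunctor {
  Function* fn;
  int n;
  void operator()(double t, const double* y, double* dy) const {
    NumericVector yy(n);
    for (int i = 0; i < n; ++i) yy[i] = y[i];
    NumericVector out = (*fn)(t, yy);
    if (out.size() != n) stop("rhs returned wrong length");
    for (int i = 0; i < n; ++i) dy[i] = out[i];
  }
};

// [[Rcpp::export]]
List integrate_fun_cpp(Function f, NumericVector y0, double t0, double t_end,
                       double relerr, double abserr, double h0, double h_min,
                       double h_max, double max_steps) {
  int n = y0.size();
  CallbackFunctor cb; cb.fn = &f; cb.n = n;
  return rk2Drive(cb, n, y0, t0, t_end, relerr, abserr, h0, h_min, h_max,
                  (int)max_steps);
}
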