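// Hybrid stochastic-deterministic single-cell engine.
//
// The continuous partition (reaction-term table compiled to flat arrays) is
// advanced with fixed-step RK4; the stochastic partition (gene allele
// switching, DSB appearance/repair, TNF receptor turnover) fires as discrete
// events sampled with the direct Gillespie method.  Propensities are frozen
// over each deterministic step window; an event is applied at its sampled
// sub-step time, with the ODE state integrated piecewise up to it.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

enum FType { F_ONE = 0, F_LIN = 1, F_MM = 2, F_INH = 3, F_HILL = 4,
             F_GENE = 5, F_DSB = 6, F_DSBMM = 7, F_RECEPT = 8 };

struct Model {
  int n_det;
  int n_terms;
  std::vector<double> rate;
  std::vector<int> src, dst;           // -1 = none
  std::vector<int> ftype, fref;        // 3 * n_terms, column-major per term
  std::vector<double> fK, fn;
  int n_genes;
  std::vector<double> g_q0, g_deact;
  int n_regs;
  std::vector<int> r_gene, r_species, r_inh_species;
  std::vector<double> r_weight, r_inh_K;
  double dsb_k_per_gy, dsb_background, dsb_vmax, dsb_km;
  int rec_total;
  double rec_k_act, rec_k_deact;
};

static Model unpack(const List& cm) {
  Model m;
  m.n_det = as<int>(cm["n_det"]);
  NumericVector rate = cm["t_rate"];
  IntegerVector src = cm["t_src"], dst = cm["t_dst"];
  IntegerVector ftype = cm["t_ftype"], fref = cm["t_fref"];
  NumericVector fK = cm["t_fK"], fn = cm["t_fn"];
  m.n_terms = rate.size();
  m.rate.assign(rate.begin(), rate.end());
  m.src.assign(src.begin(), src.end());
  m.dst.assign(dst.begin(), dst.end());
  m.ftype.assign(ftype.begin(), ftype.end());
  m.fref.assign(fref.begin(), fref.end());
  m.fK.assign(fK.begin(), fK.end());
  m.fn.assign(fn.begin(), fn.end());
  NumericVector q0 = cm["g_q0"], gd = cm["g_deact"];
  m.n_genes = q0.size();
  m.g_q0.assign(q0.begin(), q0.end());
  m.g_deact.assign(gd.begin(), gd.end());
  IntegerVector rg = cm["r_gene"], rs = cm["r_species"],
    ri = cm["r_inh_species"];
  NumericVector rw = cm["r_weight"], rk = cm["r_inh_K"];
  m.n_regs = rg.size();
  m.r_gene.assign(rg.begin(), rg.end());
  m.r_species.assign(rs.begin(), rs.end());
  m.r_inh_species.assign(ri.begin(), ri.end());
  m.r_weight.assign(rw.begin(), rw.end());
  m.r_inh_K.assign(rk.begin(), rk.end());
  m.dsb_k_per_gy = as<double>(cm["dsb_k_per_gy"]);
  m.dsb_background = as<double>(cm["dsb_background"]);
  m.dsb_vmax = as<double>(cm["dsb_vmax"]);
  m.dsb_km = as<double>(cm["dsb_km"]);
  m.rec_total = as<int>(cm["rec_total"]);
  m.rec_k_act = as<double>(cm["rec_k_act"]);
  m.rec_k_deact = as<double>(cm["rec_k_deact"]);
  return m;
}

static inline double eval_factor(const Model& m, int k, const double* y,
                                 const double* g, double dsb, double rec) {
  switch (m.ftype[k]) {
  case F_ONE: return 1.0;
  case F_LIN: return y[m.fref[k]];
  case F_MM: { double x = y[m.fref[k]]; return x / (m.fK[k] + x); }
  case F_INH: { double x = y[m.fref[k]]; return m.fK[k] / (m.fK[k] + x); }
  case F_HILL: { double x = y[m.fref[k]];
    double xn = std::pow(x, m.fn[k]), Kn = std::pow(m.fK[k], m.fn[k]);
    return xn / (Kn + xn); }
  case F_GENE: return g[m.fref[k]];
  case F_DSB: return dsb;
  case F_DSBMM: return dsb / (m.fK[k] + dsb);
  case F_RECEPT: return rec;
  }
  return 1.0;
}

// dy/dt for the continuous partition at frozen discrete state
static void deriv(const Model& m, const double* y, const double* g,
                  double dsb, double rec, double* dy) {
  for (int i = 0; i < m.n_det; ++i) dy[i] = 0.0;
  for (int t = 0; t < m.n_terms; ++t) {
    double v = m.rate[t];
    int base = 3 * t;
    for (int k = base; k < base + 3; ++k) {
      if (m.ftype[k] == F_ONE) continue;
      v *= eval_factor(m, k, y, g, dsb, rec);
    }
    if (m.src[t] >= 0) dy[m.src[t]] -= v;
    if (m.dst[t] >= 0) dy[m.dst[t]] += v;
  }
}

// one RK4 step of size h (discrete state frozen)
static void rk4_step(const Model& m, double* y, const double* g, double dsb,
                     double rec, double h, std::vector<double>& k1,
                     std::vector<double>& k2, std::vector<double>& k3,
                     std::vector<double>& k4, std::vector<double>& tmp) {
  int n = m.n_det;
  deriv(m, y, g, dsb, rec, k1.data());
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  deriv(m, tmp.data(), g, dsb, rec, k2.data());
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  deriv(m, tmp.data(), g, dsb, rec, k3.data());
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + h * k3[i];
  deriv(m, tmp.data(), g, dsb, rec, k4.data());
  for (int i = 0; i < n; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// propensities: per gene [act, deact] then dsb ind, dsb rep, rec act, rec
// deact.  Gene activation: (q0 + sum w * level * [inhK/(inhK+inh)]) *
// inactive alleles; deactivation: d * active alleles.
static void propensities(const Model& m, const double* y, const int* gi,
                         double dsb, int rec, double dose_rate, double tnf,
                         std::vector<double>& a) {
  for (int g = 0; g < m.n_genes; ++g) {
    double act = m.g_q0[g];
    for (int r = 0; r < m.n_regs; ++r) {
      if (m.r_gene[r] != g) continue;
      double c = m.r_weight[r] * y[m.r_species[r]];
      if (m.r_inh_species[r] >= 0)
        c *= m.r_inh_K[r] / (m.r_inh_K[r] + y[m.r_inh_species[r]]);
      act += c;
    }
    a[2 * g] = act * (2 - gi[g]);
    a[2 * g + 1] = m.g_deact[g] * gi[g];
  }
  int off = 2 * m.n_genes;
  a[off] = m.dsb_k_per_gy * dose_rate + m.dsb_background;
  a[off + 1] = dsb > 0 ? m.dsb_vmax * dsb / (m.dsb_km + dsb) : 0.0;
  a[off + 2] = m.rec_k_act * tnf * (m.rec_total - rec);
  a[off + 3] = m.rec_k_deact * rec;
}

// [[Rcpp::export]]
List simulate_cell_cpp(List cm, NumericVector y0, IntegerVector genes0,
                       int dsb0, int rec0, List protocol, List cfg) {
  Model m = unpack(cm);
  double ir_start = as<double>(protocol["ir_start"]);
  double ir_stop = as<double>(protocol["ir_stop"]);
  double ir_rate = as<double>(protocol["ir_rate_gy_s"]);
  double tnf_start = as<double>(protocol["tnf_start"]);
  double tnf_stop = as<double>(protocol["tnf_stop"]);
  double tnf_level = as<double>(protocol["tnf_level"]);
  double dt = as<double>(cfg["dt"]);
  double save_every = as<double>(cfg["save_every"]);
  double t_start = as<double>(cfg["t_start"]);
  double t_end = as<double>(cfg["t_end"]);
  bool clip_neg = as<bool>(cfg["clip_negative"]);
  bool stochastic = as<bool>(cfg["stochastic"]);

  int n = m.n_det;
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<int> gi(genes0.begin(), genes0.end());
  std::vector<double> gd(m.n_genes);
  for (int g = 0; g < m.n_genes; ++g) gd[g] = gi[g];
  double dsb = dsb0;
  int rec = rec0;

  long n_steps = (long) std::llround((t_end - t_start) / dt);
  int stride = std::max(1, (int) std::llround(save_every / dt));
  long n_save = n_steps / stride + 1;
  NumericMatrix Y(n_save, n);
  IntegerMatrix G(n_save, m.n_genes);
  NumericVector times(n_save), dsb_out(n_save);
  IntegerVector rec_out(n_save);
  long clip_count = 0;

  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  int n_chan = 2 * m.n_genes + 4;
  std::vector<double> a(n_chan);

  long isave = 0;
  auto save = [&](double t) {
    times[isave] = t;
    for (int i = 0; i < n; ++i) Y(isave, i) = y[i];
    for (int g = 0; g < m.n_genes; ++g) G(isave, g) = gi[g];
    dsb_out[isave] = dsb;
    rec_out[isave] = rec;
    ++isave;
  };
  save(t_start);

  for (long s = 0; s < n_steps; ++s) {
    double t = t_start + s * dt;
    double dose_rate = (t >= ir_start && t < ir_stop) ? ir_rate : 0.0;
    double tnf = (t >= tnf_start && t < tnf_stop) ? tnf_level : 0.0;

    if (stochastic) {
      double s_in = 0.0;  // elapsed inside the window
      propensities(m, y.data(), gi.data(), dsb, rec, dose_rate, tnf, a);
      for (;;) {
        double atot = 0.0;
        for (int c = 0; c < n_chan; ++c) atot += a[c];
        if (atot <= 0.0) break;
        double tau = -std::log(unif_rand()) / atot;
        if (s_in + tau > dt) break;
        // integrate up to the event, then apply it
        if (tau > 0)
          rk4_step(m, y.data(), gd.data(), dsb, rec, tau, k1, k2, k3, k4,
                   tmp);
        s_in += tau;
        double u = unif_rand() * atot, acc = 0.0;
        int chan = n_chan - 1;
        for (int c = 0; c < n_chan; ++c) {
          acc += a[c];
          if (u <= acc) { chan = c; break; }
        }
        if (chan < 2 * m.n_genes) {
          int g = chan / 2;
          if (chan % 2 == 0) { if (gi[g] < 2) ++gi[g]; }
          else { if (gi[g] > 0) --gi[g]; }
          gd[g] = gi[g];
        } else {
          int c = chan - 2 * m.n_genes;
          if (c == 0) dsb += 1.0;
          else if (c == 1) { if (dsb > 0) dsb -= 1.0; }
          else if (c == 2) { if (rec < m.rec_total) ++rec; }
          else { if (rec > 0) --rec; }
        }
        propensities(m, y.data(), gi.data(), dsb, rec, dose_rate, tnf, a);
      }
      if (dt - s_in > 0)
        rk4_step(m, y.data(), gd.data(), dsb, rec, dt - s_in, k1, k2, k3,
                 k4, tmp);
    } else {
      rk4_step(m, y.data(), gd.data(), dsb, rec, dt, k1, k2, k3, k4, tmp);
    }

    if (clip_neg) {
      for (int i = 0; i < n; ++i)
        if (y[i] < 0) { y[i] = 0.0; ++clip_count; }
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(y[i]))
        stop("non-finite level for species index %d at t = %.1f s", i + 1,
             t + dt);
    }
    if ((s + 1) % stride == 0) save(t + dt);
  }

  IntegerVector gfinal(gi.begin(), gi.end());
  return List::create(_["times"] = times, _["Y"] = Y, _["G"] = G,
                      _["dsb"] = dsb_out, _["receptors"] = rec_out,
                      _["genes_final"] = gfinal,
                      _["clip_count"] = (double) clip_count);
}

// Mean-field relaxation used to locate the deterministic resting point:
// gene allele states and the DSB count are treated as continuous variables
// (dg/dt = a(y) * (2 - g) - d * g; dDSB/dt = induction - repair).
// [[Rcpp::export]]
List relax_meanfield_cpp(List cm, NumericVector y0, NumericVector genes0,
                         double dsb0, double rec_frac, double dose_rate,
                         double tnf, double dt, double t_total,
                         bool freeze_genes = false) {
  Model m = unpack(cm);
  int n = m.n_det;
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> gd(genes0.begin(), genes0.end());
  double dsb = dsb0;
  double rec = rec_frac * m.rec_total;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  long n_steps = (long) std::llround(t_total / dt);
  for (long s = 0; s < n_steps; ++s) {
    rk4_step(m, y.data(), gd.data(), dsb, rec, dt, k1, k2, k3, k4, tmp);
    for (int i = 0; i < n; ++i) if (y[i] < 0) y[i] = 0.0;
    if (!freeze_genes) {
      for (int g = 0; g < m.n_genes; ++g) {
        double act = m.g_q0[g];
        for (int r = 0; r < m.n_regs; ++r) {
          if (m.r_gene[r] != g) continue;
          double c = m.r_weight[r] * y[m.r_species[r]];
          if (m.r_inh_species[r] >= 0)
            c *= m.r_inh_K[r] / (m.r_inh_K[r] + y[m.r_inh_species[r]]);
          act += c;
        }
        gd[g] += dt * (act * (2.0 - gd[g]) - m.g_deact[g] * gd[g]);
        if (gd[g] < 0) gd[g] = 0;
        if (gd[g] > 2) gd[g] = 2;
      }
    }
    double ind = m.dsb_k_per_gy * dose_rate + m.dsb_background;
    double rep = dsb > 0 ? m.dsb_vmax * dsb / (m.dsb_km + dsb) : 0.0;
    dsb += dt * (ind - rep);
    if (dsb < 0) dsb = 0;
    double ra = m.rec_k_act * tnf * (m.rec_total - rec);
    double rd = m.rec_k_deact * rec;
    rec += dt * (ra - rd);
    if (rec < 0) rec = 0;
  }
  return List::create(_["y"] = NumericVector(y.begin(), y.end()),
                      _["genes"] = NumericVector(gd.begin(), gd.end()),
                      _["dsb"] = dsb, _["receptors"] = rec);
}

// [[Rcpp::export]]
NumericVector rhs_cpp(List cm, NumericVector y, NumericVector genes,
                      double dsb, double rec) {
  Model m = unpack(cm);
  NumericVector dy(m.n_det);
  deriv(m, REAL(y), REAL(genes), dsb, rec, REAL(dy));
  return dy;
}
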