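// Daily-stepped single-site remodeling engine.
//
// Mirrors the pure-R reference loop in R/engine.R operation for operation
// (same update order, same formulas); the R path is the readable
// specification, this one makes multi-decade runs cheap enough to sit
// inside a calibration loop.  Layer ash fractions are carried as decay
// factors exp(-age/tau) updated multiplicatively, so the per-day cost is a
// single pass over the layer stack with no transcendental calls.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sv_eval(const NumericVector& coef, double p) {
  double out = 0.0;
  for (int k = coef.size() - 1; k >= 0; --k) out = (out + coef[k]) * p;
  return out > 0.0 ? out : 0.0;
}

static inline double fbb_eval(double x, double kap, double w, double v,
                              double lo, double hi) {
  double y;
  if (x <= -(w + v)) y = lo;
  else if (x < -w)   y = lo + (1.0 - lo) * (x + w + v) / v;
  else if (x <= w)   y = 1.0;
  else if (x < w + v) y = 1.0 + (hi - 1.0) * (x - w) / v;
  else y = hi;
  return kap * y;
}

// [[Rcpp::export(name = ".sim_site_cpp")]]
List sim_site_cpp(List par, NumericVector th0, NumericVector age0,
                  NumericVector sigma, NumericVector cycles,
                  double zeta_ref0, double n_bmu_eq,
                  NumericVector kfbio, NumericVector kfbb,
                  NumericVector loadf) {
  const int ndays = kfbio.size();
  const int T_R = as<int>(par["T_R"]);
  const int T_I = as<int>(par["T_I"]);
  const int T_F = as<int>(par["T_F"]);
  const double a_bmu = par["a_bmu"], v_bmu = par["v_bmu"], f_bio = par["f_bio"];
  const double fbb_lo = par["f_bb_min"], fbb_hi = par["f_bb_max"];
  const double w = par["w"], v = par["v"], m = par["m"], phi = par["phi"];
  const double alpha0 = par["alpha_0"], alpha_max = par["alpha_max"];
  const double tau = par["tau_sec"];
  const double lifo = par["lifo_fraction"];
  const double coalesce = par["coalesce_days"];
  const double rho_m = par["rho_m"], rho_o = par["rho_o"], v_o = par["v_o"];
  const NumericVector sv_coef = par["sv_coef"];
  const int ncase = sigma.size();
  const double dt = 1.0;
  const double day_decay = std::exp(-1.0 / tau);
  const double amp = alpha_max - alpha0;

  // layer stack, youngest first
  std::vector<double> th(th0.begin(), th0.end());
  std::vector<double> age(age0.begin(), age0.end());
  std::vector<double> dec(th.size());
  for (size_t i = 0; i < th.size(); ++i) dec[i] = std::exp(-age[i] / tau);

  // history ring, oldest first; incremental window sums
  const int W = T_R + T_I + T_F;
  std::vector<double> hN(W, n_bmu_eq), hF(W, 1.0);
  int head = 0;  // index of oldest entry
  double sum_r = n_bmu_eq * T_R;
  double sum_f = n_bmu_eq * T_F;

  double zref = zeta_ref0;

  NumericMatrix out(ndays, 9);
  colnames(out) = CharacterVector::create("v_b", "alpha_mean", "v_m_mean",
    "bmd", "zeta", "zeta_ref", "f_or", "v_f_dot", "v_r_dot");

  for (int d = 0; d < ndays; ++d) {
    // (1) composition summary
    double vb = 0.0, asum = 0.0, vmsum = 0.0;
    for (size_t i = 0; i < th.size(); ++i) {
      double al = alpha_max - amp * dec[i];
      vb += th[i];
      asum += th[i] * al;
      vmsum += th[i] * rho_o * v_o * al / (rho_m * (1.0 - al));
    }
    double abar = vb > 0.0 ? asum / vb : 0.0;
    double vmbar = vb > 0.0 ? vmsum / vb : 0.0;

    // (2) stiffness
    double E = 84370.0 * std::pow(vb, 2.58) * std::pow(abar, 2.74);

    // (3) daily stimulus
    double zeta = 0.0;
    if (E > 0.0) {
      double acc = 0.0;
      for (int c = 0; c < ncase; ++c) {
        double eps = sigma[c] * loadf[d] / E;
        acc += cycles[c] * std::pow(eps, m);
      }
      zeta = std::pow(acc, 1.0 / m);
    }
    double x = zeta - zref;

    // (4)-(6) focal balance, activation, origination
    double fbb = fbb_eval(x, kfbb[d], w, v, fbb_lo, fbb_hi);
    double f_or = f_bio * kfbio[d] * zref / (zeta + zref);
    double Ndot = f_or * sv_eval(sv_coef, 1.0 - vb);

    // (7) windowed rates from history
    double vf = a_bmu * v_bmu / T_F * sum_f;
    double vr = a_bmu * v_bmu / T_R * sum_r;

    out(d, 0) = vb; out(d, 1) = abar; out(d, 2) = vmbar;
    out(d, 3) = rho_m * vmbar * vb;
    out(d, 4) = zeta; out(d, 5) = zref; out(d, 6) = f_or;
    out(d, 7) = vf; out(d, 8) = vr;

    // (8) turnover: mixed resorption, then aging, then deposit
    double resorb = vr * dt;
    if (resorb > vb) resorb = vb;  // degenerate tissue guard
    if (resorb > 0.0 && vb > 0.0) {
      double mix = (1.0 - lifo) * resorb;
      if (mix > 0.0) {
        double s = 1.0 - mix / vb;
        for (size_t i = 0; i < th.size(); ++i) th[i] *= s;
      }
      double rem = lifo * resorb;
      while (rem > 0.0 && !th.empty()) {
        if (th.front() > rem) { th.front() -= rem; rem = 0.0; }
        else {
          rem -= th.front();
          th.erase(th.begin());
          age.erase(age.begin());
          dec.erase(dec.begin());
        }
      }
    }
    for (size_t i = 0; i < th.size(); ++i) { age[i] += dt; dec[i] *= day_decay; }
    double form = vf * dt;
    if (form > 0.0) {
      if (!th.empty() && age.front() < coalesce) {
        double wsum = th.front() + form;
        double anew = (age.front() * th.front()) / wsum;  // deposit age 0
        age.front() = anew;
        dec.front() = std::exp(-anew / tau);
        th.front() = wsum;
      } else {
        th.insert(th.begin(), form);
        age.insert(age.begin(), 0.0);
        dec.insert(dec.begin(), 1.0);
      }
    }

    // (9) accommodation
    zref = zref + phi * (zeta - zref) * dt;

    // (10) push history, update window sums
    // oldest leaves the formation window tail; the entry aging past
    // T_R leaves the resorption window; the entry aging past T_R + T_I
    // enters the formation window.
    int idx_out_f = head;                         // age W -> leaves formation
    int idx_in_f = (head + T_F) % W;              // age T_R+T_I -> enters formation
    int idx_out_r = (head + W - T_R) % W;         // age T_R -> leaves resorption
    sum_f += hN[idx_in_f] * hF[idx_in_f] - hN[idx_out_f] * hF[idx_out_f];
    sum_r += Ndot - hN[idx_out_r];
    hN[head] = Ndot;
    hF[head] = fbb;
    head = (head + 1) % W;
  }

  return List::create(_["series"] = out,
                      _["thickness"] = NumericVector(th.begin(), th.end()),
                      _["age"] = NumericVector(age.begin(), age.end()),
                      _["zeta_ref"] = zref);
}
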