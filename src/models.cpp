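#include <Rcpp.h>
using namespace Rcpp;

// Model ids: 1 conventional, 2 interactive, 3 Michaelis-Menten, 4 reverse MM.
//
// State layouts (all masses mg C g^-1 soil; 'l' = isotope-labelled, 'n' = not):
//   conventional (10): lN lL lR nN nL nR | co2 new_l new_n old_l old_n
//   interactive   (8): lN lO nN nO       | co2 new_l new_n old_l old_n
//   mm / rmm     (12): lN lO lB nN nO nB | co2 ... (last 4, as above, plus
//                      positions 6..9 are the ledger -> total length 10)
// The cumulative-CO2 ledger is always the last 4 entries, partitioned by
// source pool (new substrate vs old SOC) and isotope label.

static inline int n_state(int model) {
  switch (model) {
    case 1: return 10;
    case 2: return 8;
    default: return 10; // mm / rmm: 6 pools + 4 ledger
  }
}

static inline int n_pools(int model) {
  switch (model) {
    case 1: return 6;
    case 2: return 4;
    default: return 6;
  }
}

// piecewise-linear input rate I(t); empty schedule means no input
static inline double input_rate(double t, const NumericVector& ft,
                                const NumericVector& fr) {
  const int m = ft.size();
  if (m == 0) return 0.0;
  if (t <= ft[0]) return fr[0];
  if (t >= ft[m - 1]) return fr[m - 1];
  int lo = 0, hi = m - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (ft[mid] <= t) lo = mid; else hi = mid;
  }
  double w = (t - ft[lo]) / (ft[hi] - ft[lo]);
  return fr[lo] + w * (fr[hi] - fr[lo]);
}

static void deriv(int model, const double* p, const double* y, double t,
                  double I_l, double I_n, double* dy) {
  if (model == 1) {
    // p: K_N K_L K_R a_LN a_RN a_LR a_RL
    const double KN = p[0], KL = p[1], KR = p[2];
    const double aLN = p[3], aRN = p[4], aLR = p[5], aRL = p[6];
    const double lN = y[0], lL = y[1], lR = y[2];
    const double nN = y[3], nL = y[4], nR = y[5];
    dy[0] = I_l - KN * lN;
    dy[1] = KN * lN * aLN + KR * lR * aLR - KL * lL;
    dy[2] = KN * lN * aRN + KL * lL * aRL - KR * lR;
    dy[3] = I_n - KN * nN;
    dy[4] = KN * nN * aLN + KR * nR * aLR - KL * nL;
    dy[5] = KN * nN * aRN + KL * nL * aRL - KR * nR;
    const double respN = 1.0 - aLN - aRN;
    dy[6] = KN * lN * respN;
    dy[7] = KN * nN * respN;
    dy[8] = KL * lL * (1.0 - aRL) + KR * lR * (1.0 - aLR);
    dy[9] = KL * nL * (1.0 - aRL) + KR * nR * (1.0 - aLR);
  } else if (model == 2) {
    // p: K_N K_O r K_p pw
    const double KN = p[0], KO = p[1], r = p[2], Kp = p[3], pw = p[4];
    const double lN = y[0], lO = y[1], nN = y[2], nO = y[3];
    const double N = lN + nN;
    const double prime = (N > 0.0 && Kp > 0.0) ? Kp * std::pow(N, pw) : 0.0;
    const double ktot = KO + prime;
    dy[0] = I_l - KN * lN;
    dy[1] = KN * lN * r - ktot * lO;
    dy[2] = I_n - KN * nN;
    dy[3] = KN * nN * r - ktot * nO;
    dy[4] = KN * lN * (1.0 - r);
    dy[5] = KN * nN * (1.0 - r);
    dy[6] = ktot * lO;
    dy[7] = ktot * nO;
  } else if (model == 3) {
    // p: V_N V_O K_N K_O mu_B eps
    const double VN = p[0], VO = p[1], KN = p[2], KO = p[3];
    const double muB = p[4], eps = p[5];
    const double lN = y[0], lO = y[1], lB = y[2];
    const double nN = y[3], nO = y[4], nB = y[5];
    const double N = lN + nN, O = lO + nO, B = lB + nB;
    const double upN_l = B * VN * lN / (N + KN);
    const double upN_n = B * VN * nN / (N + KN);
    const double upO_l = B * VO * lO / (O + KO);
    const double upO_n = B * VO * nO / (O + KO);
    dy[0] = I_l - upN_l;
    dy[1] = muB * lB - upO_l;
    dy[2] = -muB * lB + eps * (upN_l + upO_l);
    dy[3] = I_n - upN_n;
    dy[4] = muB * nB - upO_n;
    dy[5] = -muB * nB + eps * (upN_n + upO_n);
    dy[6] = (1.0 - eps) * upN_l;
    dy[7] = (1.0 - eps) * upN_n;
    dy[8] = (1.0 - eps) * upO_l;
    dy[9] = (1.0 - eps) * upO_n;
  } else {
    // p: mu_N mu_O mu_B K_B eps
    const double muN = p[0], muO = p[1], muB = p[2], KB = p[3], eps = p[4];
    const double lN = y[0], lO = y[1], lB = y[2];
    const double nN = y[3], nO = y[4], nB = y[5];
    const double B = lB + nB;
    const double f = B / (B + KB);
    const double upN_l = muN * lN * f, upN_n = muN * nN * f;
    const double upO_l = muO * lO * f, upO_n = muO * nO * f;
    dy[0] = I_l - upN_l;
    dy[1] = muB * lB - upO_l;
    dy[2] = -muB * lB + eps * (upN_l + upO_l);
    dy[3] = I_n - upN_n;
    dy[4] = muB * nB - upO_n;
    dy[5] = -muB * nB + eps * (upN_n + upO_n);
    dy[6] = (1.0 - eps) * upN_l;
    dy[7] = (1.0 - eps) * upN_n;
    dy[8] = (1.0 - eps) * upO_l;
    dy[9] = (1.0 - eps) * upO_n;
  }
}

struct Stepper {
  int model;
  const double* p;
  NumericVector ft, fr;
  bool labeled_input;
  int ny;
  double k1[10], k2[10], k3[10], k4[10], tmp[10];

  void rk4(double* y, double t, double h) {
    double I0 = input_rate(t, ft, fr);
    double Ih = input_rate(t + 0.5 * h, ft, fr);
    double I1 = input_rate(t + h, ft, fr);
    double Il0 = labeled_input ? I0 : 0.0, In0 = labeled_input ? 0.0 : I0;
    double Ilh = labeled_input ? Ih : 0.0, Inh = labeled_input ? 0.0 : Ih;
    double Il1 = labeled_input ? I1 : 0.0, In1 = labeled_input ? 0.0 : I1;
    deriv(model, p, y, t, Il0, In0, k1);
    for (int i = 0; i < ny; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
    deriv(model, p, tmp, t + 0.5 * h, Ilh, Inh, k2);
    for (int i = 0; i < ny; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
    deriv(model, p, tmp, t + 0.5 * h, Ilh, Inh, k3);
    for (int i = 0; i < ny; ++i) tmp[i] = y[i] + h * k3[i];
    deriv(model, p, tmp, t + h, Il1, In1, k4);
    for (int i = 0; i < ny; ++i)
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }
};

static inline bool bad_state(const double* y, int ny) {
  for (int i = 0; i < ny; ++i) {
    if (!std::isfinite(y[i])) return true;
    if (y[i] < -1e-6) return true;
  }
  return false;
}

// Integrate from t=0 to max(times), fixed-step RK4 (dt), linear interpolation
// onto the requested output times. Impulse additions (to the new pool, labelled
// or not) are applied when the integration clock reaches their time.
// [[Rcpp::export]]
List simulate_cpp(int model, NumericVector params, NumericVector y0,
                  NumericVector times, double dt,
                  NumericVector ftimes, NumericVector frates,
                  bool labeled_input,
                  NumericVector imp_times, NumericVector imp_amounts,
                  LogicalVector imp_labeled) {
  const int ny = n_state(model);
  if (y0.size() != ny) stop("state length %d does not match model", y0.size());
  const int nt = times.size();
  NumericMatrix out(nt, ny);
  double y[10], yprev[10];
  for (int i = 0; i < ny; ++i) y[i] = y0[i];

  Stepper st;
  st.model = model; st.p = REAL(params); st.ft = ftimes; st.fr = frates;
  st.labeled_input = labeled_input; st.ny = ny;

  int next_imp = 0;
  const int nimp = imp_times.size();
  auto apply_impulses = [&](double t) {
    while (next_imp < nimp && imp_times[next_imp] <= t + 1e-9) {
      int idx = imp_labeled[next_imp] ? 0 : (model == 2 ? 2 : 3);
      y[idx] += imp_amounts[next_imp];
      ++next_imp;
    }
  };

  double t = 0.0;
  apply_impulses(0.0);
  double tmax = times[nt - 1];
  int iout = 0;
  bool ok = true;
  // emit any outputs at (or numerically at) t = 0
  while (iout < nt && times[iout] <= 1e-12) {
    for (int i = 0; i < ny; ++i) out(iout, i) = y[i];
    ++iout;
  }
  while (t < tmax - 1e-12 && ok) {
    double h = std::min(dt, tmax - t);
    for (int i = 0; i < ny; ++i) yprev[i] = y[i];
    st.rk4(y, t, h);
    double tnew = t + h;
    if (bad_state(y, ny)) { ok = false; break; }
    while (iout < nt && times[iout] <= tnew + 1e-9) {
      double w = (times[iout] - t) / h;
      if (w < 0.0) w = 0.0;
      if (w > 1.0) w = 1.0;
      for (int i = 0; i < ny; ++i)
        out(iout, i) = yprev[i] + w * (y[i] - yprev[i]);
      ++iout;
    }
    t = tnew;
    apply_impulses(t);
  }
  return List::create(_["state"] = out, _["ok"] = ok);
}

// Fused study log-likelihood: simulate the control and treatment arms and sum
// -(Z - X)^2 / (2 sigma^2) over the three cumulative-CO2 series.
// series code: 0 = old-C CO2 control, 1 = old-C CO2 treatment,
//              2 = new-C CO2 treatment.
// "old-C CO2" is the unlabelled cumulative CO2 (new_n + old_n ledger entries),
// "new-C CO2" the labelled one (new_l + old_l); native SOC is unlabelled and
// the added substrate labelled, so label totals are the observed quantities.
// [[Rcpp::export]]
double study_loglik_cpp(int model,
                        NumericVector params_ctrl, NumericVector y0_ctrl,
                        NumericVector params_trt, NumericVector y0_trt,
                        NumericVector obs_time, NumericVector obs_z,
                        NumericVector obs_sd, IntegerVector obs_series,
                        double dt) {
  const int ny = n_state(model);
  const int co2 = n_pools(model); // ledger offset
  const int nobs = obs_time.size();
  // unique sorted times
  std::vector<double> ut(obs_time.begin(), obs_time.end());
  std::sort(ut.begin(), ut.end());
  ut.erase(std::unique(ut.begin(), ut.end()), ut.end());
  NumericVector tt(ut.begin(), ut.end());
  NumericVector none(0);
  LogicalVector noneL(0);
  List sc = simulate_cpp(model, params_ctrl, y0_ctrl, tt, dt,
                         none, none, false, none, none, noneL);
  if (!as<bool>(sc["ok"])) return R_NegInf;
  List stt = simulate_cpp(model, params_trt, y0_trt, tt, dt,
                          none, none, false, none, none, noneL);
  if (!as<bool>(stt["ok"])) return R_NegInf;
  NumericMatrix yc = sc["state"], yt = stt["state"];

  double ll = 0.0;
  for (int k = 0; k < nobs; ++k) {
    // index of obs time in ut
    int j = std::lower_bound(ut.begin(), ut.end(), obs_time[k]) - ut.begin();
    double x;
    if (obs_series[k] == 0)      x = yc(j, co2 + 1) + yc(j, co2 + 3);
    else if (obs_series[k] == 1) x = yt(j, co2 + 1) + yt(j, co2 + 3);
    else                         x = yt(j, co2 + 0) + yt(j, co2 + 2);
    double e = (obs_z[k] - x) / obs_sd[k];
    ll -= 0.5 * e * e;
  }
  return ll;
}
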