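#include <Rcpp.h>
using namespace Rcpp;

// Two-state chain over pair separations: state 0 = free, 1 = dimer.
// Transition matrix T = [[1-p_on, p_on], [p_off, 1-p_off]].
// g-step power in closed form: T^g = Pi + lambda^g (I - Pi), where Pi has
// rows equal to the stationary distribution and lambda = 1 - p_on - p_off.
static inline void trans_power(double p_on, double p_off, int g, double T[2][2]) {
  double s = p_on + p_off;
  if (s <= 0.0) { // frozen chain
    T[0][0] = 1.0; T[0][1] = 0.0; T[1][0] = 0.0; T[1][1] = 1.0;
    return;
  }
  double pi_free = p_off / s, pi_dim = p_on / s;
  double lg = std::pow(1.0 - s, g);
  T[0][0] = pi_free + lg * (1.0 - pi_free);
  T[0][1] = pi_dim  - lg * pi_dim;
  T[1][0] = pi_free - lg * pi_free;
  T[1][1] = pi_dim  + lg * (1.0 - pi_dim);
}

static inline double emit_free(double s, double s_max) {
  return (s > 0.0 && s <= s_max) ? 2.0 * s / (s_max * s_max) : 0.0;
}

static inline double emit_dimer(double s, double sigma_d) {
  if (s <= 0.0) return 0.0;
  double z = s / sigma_d;
  return (z / sigma_d) * std::exp(-0.5 * z * z);
}

// Scaled forward log-likelihood of one separation series. gap[t] is the
// frame distance to the previous observation (gap[0] ignored); missing
// frames contribute a transition-matrix power and no emission.
// [[Rcpp::export]]
double hmm_forward_cpp(NumericVector s, IntegerVector gap,
                       double p_on, double p_off,
                       double sigma_d, double s_max, double pi_dimer) {
  int n = s.size();
  if (n == 0) stop("empty series");
  double a0 = (1.0 - pi_dimer) * emit_free(s[0], s_max);
  double a1 = pi_dimer * emit_dimer(s[0], sigma_d);
  double c = a0 + a1;
  if (c <= 0.0) return R_NegInf;
  double ll = std::log(c);
  a0 /= c; a1 /= c;
  double T[2][2];
  for (int t = 1; t < n; ++t) {
    trans_power(p_on, p_off, gap[t], T);
    double b0 = (a0 * T[0][0] + a1 * T[1][0]) * emit_free(s[t], s_max);
    double b1 = (a0 * T[0][1] + a1 * T[1][1]) * emit_dimer(s[t], sigma_d);
    c = b0 + b1;
    if (c <= 0.0) return R_NegInf;
    ll += std::log(c);
    a0 = b0 / c; a1 = b1 / c;
  }
  return ll;
}

// Summed forward log-likelihood over concatenated series.
// start: 0-based offsets, len: series lengths.
// [[Rcpp::export]]
double hmm_forward_batch_cpp(NumericVector s, IntegerVector gap,
                             IntegerVector start, IntegerVector len,
                             double p_on, double p_off,
                             double sigma_d, double s_max, double pi_dimer) {
  double total = 0.0;
  for (int k = 0; k < start.size(); ++k) {
    NumericVector ss(s.begin() + start[k], s.begin() + start[k] + len[k]);
    IntegerVector gg(gap.begin() + start[k], gap.begin() + start[k] + len[k]);
    double ll = hmm_forward_cpp(ss, gg, p_on, p_off, sigma_d, s_max, pi_dimer);
    if (!R_FINITE(ll)) return R_NegInf;
    total += ll;
  }
  return total;
}

// Viterbi path of one series; returns 1 = free, 2 = dimer per observation.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector s, IntegerVector gap,
                              double p_on, double p_off,
                              double sigma_d, double s_max, double pi_dimer) {
  int n = s.size();
  if (n == 0) stop("empty series");
  std::vector<double> d0(n), d1(n);
  std::vector<int> b0(n), b1(n);
  d0[0] = std::log(1.0 - pi_dimer) + std::log(emit_free(s[0], s_max));
  d1[0] = std::log(pi_dimer) + std::log(emit_dimer(s[0], sigma_d));
  double T[2][2];
  for (int t = 1; t < n; ++t) {
    trans_power(p_on, p_off, gap[t], T);
    double lt00 = std::log(T[0][0]), lt01 = std::log(T[0][1]);
    double lt10 = std::log(T[1][0]), lt11 = std::log(T[1][1]);
    double f_from0 = d0[t - 1] + lt00, f_from1 = d1[t - 1] + lt10;
    if (f_from0 >= f_from1) { d0[t] = f_from0; b0[t] = 0; }
    else { d0[t] = f_from1; b0[t] = 1; }
    d0[t] += std::log(emit_free(s[t], s_max));
    double g_from0 = d0[t - 1] + lt01, g_from1 = d1[t - 1] + lt11;
    if (g_from0 >= g_from1) { d1[t] = g_from0; b1[t] = 0; }
    else { d1[t] = g_from1; b1[t] = 1; }
    d1[t] += std::log(emit_dimer(s[t], sigma_d));
  }
  IntegerVector path(n);
  int cur = (d1[n - 1] > d0[n - 1]) ? 1 : 0;
  path[n - 1] = cur + 1;
  for (int t = n - 1; t > 0; --t) {
    cur = (cur == 0) ? b0[t] : b1[t];
    path[t - 1] = cur + 1;
  }
  return path;
}
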