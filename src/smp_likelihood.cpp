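// Fast evaluation of the joint (report, RT) likelihood of the semi-Markov
// association-sampling process. The absorption transform of each variant is
// inverted with the fixed-Talbot contour; the rejection-free case has a
// closed-form Gamma density and skips the inversion.
//
// On the fixed-Talbot contour s_k = (2M/5t) theta_k (cot theta_k + i),
// s_k * t does not depend on t, so the contour points (scaled by 1/t), the
// exponential factors exp(s_k t) and the trapezoidal weights are
// precomputed once per node count and shared by every trial.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cd;

static const double MU_MIN = 1e-4;
static const int MAX_REP = 8;   // repeated set size bound (design: <= 4)

// (1 + theta*s)^(-k) via polar decomposition
static inline cd glt(const cd& s, double theta, double k) {
  double a = 1.0 + theta * s.real();
  double b = theta * s.imag();
  double mag = std::exp(-0.5 * k * std::log(a * a + b * b));
  double ang = -k * std::atan2(b, a);
  return cd(mag * std::cos(ang), mag * std::sin(ang));
}

static inline double gamma_pdf(double t, double k, double theta) {
  if (t <= 0.0) return 0.0;
  return std::exp((k - 1.0) * std::log(t) - t / theta -
                  k * std::log(theta) - R::lgammafn(k));
}

static inline double mean_time(double p, double s_mu, double e_mu) {
  if (p >= 1.0) return MU_MIN;
  double mu = std::exp(s_mu) * std::pow(-std::log(p), e_mu);
  return (mu < MU_MIN) ? MU_MIN : mu;
}

// Precomputed Talbot contour for a given node count M:
//   st[k]   = s_k * t   (t-invariant)
//   coef[k] = exp(s_k t) * (1 + i sigma_k)  [k = 0 carries the half weight]
struct TalbotGrid {
  int M;
  std::vector<cd> st, coef;
  explicit TalbotGrid(int M_) : M(M_), st(M_), coef(M_) {
    double rt = 2.0 * M / 5.0;  // r * t
    st[0] = cd(rt, 0.0);
    coef[0] = cd(0.5 * std::exp(rt), 0.0);
    for (int k = 1; k < M; ++k) {
      double th = k * M_PI / M;
      double cot = std::cos(th) / std::sin(th);
      st[k] = cd(rt * th * cot, rt * th);
      double sigma = th + (th * cot - 1.0) * cot;
      cd e = std::exp(st[k]);
      coef[k] = e * cd(1.0, sigma);
    }
  }
};

static const TalbotGrid& talbot_grid(int M) {
  static std::vector<TalbotGrid*> cache;
  for (size_t i = 0; i < cache.size(); ++i)
    if (cache[i]->M == M) return *cache[i];
  cache.push_back(new TalbotGrid(M));
  return *cache.back();
}

// solve A x = b in place, complex m x m with partial pivoting (m <= MAX_REP)
static inline void solve_small(cd A[MAX_REP][MAX_REP], cd b[MAX_REP], int m) {
  for (int c = 0; c < m; ++c) {
    int piv = c;
    double best = std::norm(A[c][c]);
    for (int r = c + 1; r < m; ++r) {
      double v = std::norm(A[r][c]);
      if (v > best) { best = v; piv = r; }
    }
    if (piv != c) {
      for (int cc = 0; cc < m; ++cc) std::swap(A[piv][cc], A[c][cc]);
      std::swap(b[piv], b[c]);
    }
    cd d = A[c][c];
    for (int r = c + 1; r < m; ++r) {
      cd f = A[r][c] / d;
      for (int cc = c; cc < m; ++cc) A[r][cc] -= f * A[c][cc];
      b[r] -= f * b[c];
    }
  }
  for (int c = m - 1; c >= 0; --c) {
    cd acc = b[c];
    for (int cc = c + 1; cc < m; ++cc) acc -= A[c][cc] * b[cc];
    b[c] = acc / A[c][c];
  }
}

struct ModelPar {
  double rho, rho_w, alpha, s_mu, e_mu, lam, tau;
};

// variant codes: 0 no_reject, 1 reject, 2 reject_rhow, 3 reject_noresample
// One trial: strengths AS[0..n), repeated indices R (0-based, size m),
// reported j (0-based), decision time t = rt - tau.
static double trial_density_core(const double* AS, int n,
                                 const int* R, int m,
                                 int j, double t, int variant,
                                 const ModelPar& mp, int M,
                                 std::vector<double>& work) {
  if (t <= 0.0) return 0.0;
  double k = 1.0 / (mp.lam * mp.lam), lam2 = mp.lam * mp.lam;
  double erho = std::exp(mp.rho);

  if (work.size() < (size_t)(2 * n)) work.resize(2 * n);
  double* p1 = work.data();

  double tot = 0.0;
  for (int i = 0; i < n; ++i) { p1[i] = AS[i]; tot += AS[i]; }
  for (int a = 0; a < m; ++a) {
    p1[R[a]] = AS[R[a]] * erho;
    tot += (erho - 1.0) * AS[R[a]];
  }
  if (!(tot > 0.0) || !std::isfinite(tot)) return 0.0;
  double inv_tot = 1.0 / tot;

  bool j_rep = false;
  for (int a = 0; a < m; ++a) if (R[a] == j) { j_rep = true; break; }
  double qj = j_rep ? (1.0 - mp.alpha) : 1.0;
  if (qj <= 0.0) return 0.0;

  double p1j = p1[j] * inv_tot;
  double th1j = mean_time(p1j, mp.s_mu, mp.e_mu) * lam2;

  // no rejections possible: closed-form Gamma density
  if (variant == 0 || m == 0 || mp.alpha <= 0.0)
    return p1j * qj * gamma_pdf(t, k, th1j);

  double p1R[MAX_REP], th1R[MAX_REP];
  for (int a = 0; a < m; ++a) {
    p1R[a] = p1[R[a]] * inv_tot;
    th1R[a] = mean_time(p1R[a], mp.s_mu, mp.e_mu) * lam2;
  }

  // phase-2 quantities for reject_rhow
  double p2j = 0, th2j = 0, p2R[MAX_REP], th2R[MAX_REP];
  if (variant == 2) {
    double erw = std::exp(mp.rho_w);
    double tot2 = 0.0;
    for (int i = 0; i < n; ++i) tot2 += AS[i];
    double srep = 0.0;
    for (int a = 0; a < m; ++a) srep += AS[R[a]];
    tot2 += (erw - 1.0) * srep;
    double inv2 = 1.0 / tot2;
    p2j = (j_rep ? AS[j] * erw : AS[j]) * inv2;
    th2j = mean_time(p2j, mp.s_mu, mp.e_mu) * lam2;
    for (int a = 0; a < m; ++a) {
      p2R[a] = AS[R[a]] * erw * inv2;
      th2R[a] = mean_time(p2R[a], mp.s_mu, mp.e_mu) * lam2;
    }
  }

  // exclusion-renormalized quantities for reject_noresample:
  // from state "just rejected R[a]": peR[a][b] is the prob of drawing R[b],
  // pej[a] the prob of drawing j; the* are the matching Gamma scales.
  double peR[MAX_REP][MAX_REP], theR[MAX_REP][MAX_REP];
  double pej[MAX_REP], thej[MAX_REP];
  if (variant == 3) {
    for (int a = 0; a < m; ++a) {
      double denom = 1.0 - p1R[a];
      if (denom <= 1e-12) denom = 1e-12;
      double inv_d = 1.0 / denom;
      for (int b = 0; b < m; ++b) {
        if (b == a) { peR[a][b] = 0.0; theR[a][b] = 0.0; continue; }
        double p = p1R[b] * inv_d;
        if (p > 1.0) p = 1.0;
        peR[a][b] = p;
        theR[a][b] = mean_time(p, mp.s_mu, mp.e_mu) * lam2;
      }
      if (j_rep && R[a] == j) { pej[a] = 0.0; thej[a] = 0.0; }
      else {
        double p = p1j * inv_d;
        if (p > 1.0) p = 1.0;
        pej[a] = p;
        thej[a] = mean_time(p, mp.s_mu, mp.e_mu) * lam2;
      }
    }
  }

  const TalbotGrid& grid = talbot_grid(M);
  double inv_t = 1.0 / t;
  double sum = 0.0;
  cd A[MAX_REP][MAX_REP], rhs[MAX_REP];
  for (int node = 0; node < M; ++node) {
    cd s = grid.st[node] * inv_t;
    cd F;
    if (variant == 1) {
      cd rej(0.0, 0.0);
      for (int a = 0; a < m; ++a)
        rej += p1R[a] * glt(s, th1R[a], k);
      F = p1j * qj * glt(s, th1j, k) / (cd(1.0, 0.0) - mp.alpha * rej);
    } else if (variant == 2) {
      cd r1(0.0, 0.0), r2(0.0, 0.0);
      for (int a = 0; a < m; ++a) {
        r1 += p1R[a] * glt(s, th1R[a], k);
        r2 += p2R[a] * glt(s, th2R[a], k);
      }
      F = p1j * qj * glt(s, th1j, k) +
          (mp.alpha * r1) * (p2j * qj * glt(s, th2j, k)) /
            (cd(1.0, 0.0) - mp.alpha * r2);
    } else { // variant == 3
      for (int a = 0; a < m; ++a) {
        for (int b = 0; b < m; ++b) {
          if (b == a || peR[a][b] <= 0.0) {
            A[a][b] = (a == b) ? cd(1.0, 0.0) : cd(0.0, 0.0);
          } else {
            A[a][b] = -mp.alpha * peR[a][b] * glt(s, theR[a][b], k);
          }
        }
        rhs[a] = (pej[a] > 0.0) ? pej[a] * qj * glt(s, thej[a], k)
                                : cd(0.0, 0.0);
      }
      solve_small(A, rhs, m);
      F = p1j * qj * glt(s, th1j, k);
      for (int a = 0; a < m; ++a)
        F += mp.alpha * p1R[a] * glt(s, th1R[a], k) * rhs[a];
    }
    cd val = grid.coef[node] * F;
    sum += val.real();
  }
  return (2.0 / (5.0 * t)) * sum;
}

// ---- session container ----------------------------------------------------

struct SessionData {
  std::vector<double> strengths;       // concatenated spaces
  std::vector<int> offset, nsize;      // per trial
  std::vector<int> rep_flat, rep_off, rep_n;
  std::vector<int> reported;           // 0-based
  std::vector<double> rt;
  int n_trials;
};

static ModelPar read_par(const List& par) {
  ModelPar mp;
  mp.rho = as<double>(par["rho"]);
  mp.alpha = as<double>(par["alpha"]);
  mp.rho_w = 0.0;
  if (par.containsElementNamed("rho_w")) {
    SEXP rw = par["rho_w"];
    if (!Rf_isNull(rw)) mp.rho_w = as<double>(rw);
  }
  mp.s_mu = as<double>(par["s_mu"]);
  mp.e_mu = as<double>(par["e_mu"]);
  mp.lam = as<double>(par["lam"]);
  mp.tau = as<double>(par["tau"]);
  return mp;
}

static int variant_code_cpp(const std::string& v) {
  if (v == "no_reject") return 0;
  if (v == "reject") return 1;
  if (v == "reject_rhow") return 2;
  if (v == "reject_noresample") return 3;
  stop("unknown variant '%s'", v.c_str());
  return -1;
}

// trials: list of lists with elements strengths (numeric), repeated
// (logical), reported (int, 1-based) and rt (seconds). Censored/missing
// trials must be removed by the caller.
// [[Rcpp::export]]
SEXP smp_make_session_cpp(List trials) {
  SessionData* sd = new SessionData();
  int nt = trials.size();
  sd->n_trials = nt;
  for (int t = 0; t < nt; ++t) {
    List tr = trials[t];
    NumericVector strengths = tr["strengths"];
    LogicalVector repeated = tr["repeated"];
    int reported = as<int>(tr["reported"]);
    double rt = as<double>(tr["rt"]);
    int n = strengths.size();
    sd->offset.push_back((int)sd->strengths.size());
    sd->nsize.push_back(n);
    sd->strengths.insert(sd->strengths.end(), strengths.begin(),
                         strengths.end());
    sd->rep_off.push_back((int)sd->rep_flat.size());
    int nr = 0;
    for (int i = 0; i < n; ++i)
      if (repeated[i]) { sd->rep_flat.push_back(i); ++nr; }
    if (nr > MAX_REP) { delete sd; stop("repeated set larger than supported"); }
    sd->rep_n.push_back(nr);
    sd->reported.push_back(reported - 1);
    sd->rt.push_back(rt);
  }
  XPtr<SessionData> ptr(sd, true);
  return ptr;
}

static double session_loglik_impl(SessionData* sd, const ModelPar& mp,
                                  int vc, int n_nodes) {
  if (!std::isfinite(mp.rho) || !std::isfinite(mp.s_mu) ||
      !std::isfinite(mp.e_mu) || !std::isfinite(mp.lam) ||
      !std::isfinite(mp.tau) || mp.lam <= 0.0 || mp.e_mu <= 0.0)
    return -1e10;
  std::vector<double> work;
  double ll = 0.0;
  for (int t = 0; t < sd->n_trials; ++t) {
    double f = trial_density_core(sd->strengths.data() + sd->offset[t],
                                  sd->nsize[t],
                                  sd->rep_flat.data() + sd->rep_off[t],
                                  sd->rep_n[t],
                                  sd->reported[t], sd->rt[t] - mp.tau,
                                  vc, mp, n_nodes, work);
    if (!(f > 1e-300) || !std::isfinite(f)) f = 1e-300;
    ll += std::log(f);
  }
  return ll;
}

// [[Rcpp::export]]
double smp_session_loglik_ptr_cpp(SEXP session, List par,
                                  std::string variant, int n_nodes = 24) {
  XPtr<SessionData> sd(session);
  return session_loglik_impl(sd.get(), read_par(par),
                             variant_code_cpp(variant), n_nodes);
}

// [[Rcpp::export]]
double smp_session_loglik_cpp(List trials, List par, std::string variant,
                              int n_nodes = 48) {
  SEXP p = smp_make_session_cpp(trials);
  XPtr<SessionData> sd(p);
  return session_loglik_impl(sd.get(), read_par(par),
                             variant_code_cpp(variant), n_nodes);
}

// [[Rcpp::export]]
double smp_trial_density_cpp(NumericVector strengths, LogicalVector repeated,
                             int reported, double rt, List par,
                             std::string variant, int n_nodes = 48) {
  int n = strengths.size();
  std::vector<int> R;
  for (int i = 0; i < n; ++i) if (repeated[i]) R.push_back(i);
  if ((int)R.size() > MAX_REP) stop("repeated set larger than supported");
  ModelPar mp = read_par(par);
  std::vector<double> work;
  double f = trial_density_core(strengths.begin(), n,
                                R.data(), (int)R.size(), reported - 1,
                                rt - mp.tau, variant_code_cpp(variant), mp,
                                n_nodes, work);
  return f < 0.0 ? 0.0 : f;
}
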