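#include <Rcpp.h>
using namespace Rcpp;

// Jukes-Cantor transition probabilities are parameterised here by
// q = exp(-4 d / 3), with q = 0 encoding an infinite branch exactly:
//   P(same end states)           s = (1 + 3 q) / 4
//   P(a specific different pair) t = (1 - q) / 4
//
// Three-taxon class probabilities are multilinear in the (s_i, t_i) pairs,
// so each class is stored as a sum of terms; a term is a coefficient (the
// class multiplicity folded in) and a 3-bit code saying which of s/t enters
// for branches A, B, C (bit set => s).

struct Term {
  double coef;
  int code;
};

// classes in fixed order: xxx, xxy, xyx, yxx, xyz
static const Term TERMS3[5][4] = {
  { {1.0, 7}, {3.0, 0}, {0.0, 0}, {0.0, 0} },                 // xxx
  { {3.0, 3}, {3.0, 4}, {6.0, 0}, {0.0, 0} },                 // xxy (A=B)
  { {3.0, 5}, {3.0, 2}, {6.0, 0}, {0.0, 0} },                 // xyx (A=C)
  { {3.0, 6}, {3.0, 1}, {6.0, 0}, {0.0, 0} },                 // yxx (B=C)
  { {6.0, 1}, {6.0, 2}, {6.0, 4}, {6.0, 0} }                  // xyz
};
static const int NT3[5] = {2, 3, 3, 3, 4};

static inline void probs3_impl(const double *q, double *p) {
  double s[3], t[3];
  for (int k = 0; k < 3; ++k) {
    s[k] = (1.0 + 3.0 * q[k]) / 4.0;
    t[k] = (1.0 - q[k]) / 4.0;
  }
  for (int r = 0; r < 5; ++r) {
    double acc = 0.0;
    for (int j = 0; j < NT3[r]; ++j) {
      const Term &tm = TERMS3[r][j];
      double prod = tm.coef;
      for (int k = 0; k < 3; ++k)
        prod *= (tm.code >> k & 1) ? s[k] : t[k];
      acc += prod;
    }
    p[r] = acc;
  }
}

// derivative of class probabilities with respect to q[k]
static inline void dprobs3_impl(const double *q, int k, double *dp) {
  double s[3], t[3];
  for (int j = 0; j < 3; ++j) {
    s[j] = (1.0 + 3.0 * q[j]) / 4.0;
    t[j] = (1.0 - q[j]) / 4.0;
  }
  for (int r = 0; r < 5; ++r) {
    double acc = 0.0;
    for (int j = 0; j < NT3[r]; ++j) {
      const Term &tm = TERMS3[r][j];
      double prod = tm.coef;
      for (int m = 0; m < 3; ++m) {
        if (m == k)
          prod *= (tm.code >> m & 1) ? 0.75 : -0.25;
        else
          prod *= (tm.code >> m & 1) ? s[m] : t[m];
      }
      acc += prod;
    }
    dp[r] = acc;
  }
}

// [[Rcpp::export]]
NumericVector cpp_probs3(NumericVector q) {
  NumericVector out(5);
  probs3_impl(q.begin(), out.begin());
  return out;
}

// the data likelihood is that of the observed site patterns themselves, so
// each class contributes its class probability divided by the class
// multiplicity; this makes the closed forms -n log 4 / -n log 16 /
// -n log 64 exact rather than shifted by a constant
static const double LOGMULT3[5] = {
  1.3862943611198906, 2.4849066497880004, 2.4849066497880004,
  2.4849066497880004, 3.1780538303479458
};

// [[Rcpp::export]]
double cpp_loglik3(NumericVector counts, NumericVector q, bool floor_probs = false) {
  double p[5];
  probs3_impl(q.begin(), p);
  double ll = 0.0;
  for (int r = 0; r < 5; ++r) {
    if (counts[r] > 0) {
      if (p[r] <= 0.0 && !floor_probs) return R_NegInf;
      double pr = p[r] > 1e-300 ? p[r] : 1e-300;
      ll += counts[r] * (std::log(pr) - LOGMULT3[r]);
    }
  }
  return ll;
}

// gradient of the log-likelihood with respect to q (chain rule to branch
// lengths is done on the R side); probabilities are floored to keep the
// quasi-Newton search finite near impossible boundaries
// [[Rcpp::export]]
NumericVector cpp_grad3_q(NumericVector counts, NumericVector q) {
  double p[5], dp[5];
  probs3_impl(q.begin(), p);
  NumericVector g(3);
  for (int k = 0; k < 3; ++k) {
    dprobs3_impl(q.begin(), k, dp);
    double acc = 0.0;
    for (int r = 0; r < 5; ++r) {
      if (counts[r] > 0) {
        double pr = p[r] > 1e-300 ? p[r] : 1e-300;
        acc += counts[r] * dp[r] / pr;
      }
    }
    g[k] = acc;
  }
  return g;
}

// ---------------------------------------------------------------------------
// Four-taxon trees.
//
// reps: 15 x 4 integer matrix of representative site patterns (bases 0..3),
// tipnode: length-4 0/1 vector assigning each tip to internal node u (0) or
// v (1); q has 5 entries, tips 1..4 then the internal branch. The class
// probability is mult[r] times the probability of the representative.

static inline double ftrans(int a, int b, double q) {
  return (a == b) ? (1.0 + 3.0 * q) / 4.0 : (1.0 - q) / 4.0;
}
static inline double dftrans(int a, int b) {
  return (a == b) ? 0.75 : -0.25;
}

// [[Rcpp::export]]
NumericVector cpp_probs4(NumericVector q, IntegerMatrix reps,
                         NumericVector mult, IntegerVector tipnode) {
  int nc = reps.nrow();
  NumericVector out(nc);
  for (int r = 0; r < nc; ++r) {
    double acc = 0.0;
    for (int u = 0; u < 4; ++u) {
      for (int v = 0; v < 4; ++v) {
        double prod = 0.25 * ftrans(u, v, q[4]);
        for (int i = 0; i < 4; ++i) {
          int node = tipnode[i] == 0 ? u : v;
          prod *= ftrans(node, reps(r, i), q[i]);
        }
        acc += prod;
      }
    }
    out[r] = mult[r] * acc;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_loglik4(NumericVector counts, NumericVector q, IntegerMatrix reps,
                   NumericVector mult, IntegerVector tipnode,
                   bool floor_probs = false) {
  NumericVector p = cpp_probs4(q, reps, mult, tipnode);
  double ll = 0.0;
  for (int r = 0; r < p.size(); ++r) {
    if (counts[r] > 0) {
      if (p[r] <= 0.0 && !floor_probs) return R_NegInf;
      double pr = p[r] > 1e-300 ? p[r] : 1e-300;
      ll += counts[r] * (std::log(pr) - std::log(mult[r]));
    }
  }
  return ll;
}

// gradient with respect to the five q values, via leave-one-out products so
// zero factors (t = 0 at d = 0) stay exact
// [[Rcpp::export]]
NumericVector cpp_grad4_q(NumericVector counts, NumericVector q,
                          IntegerMatrix reps, NumericVector mult,
                          IntegerVector tipnode) {
  int nc = reps.nrow();
  NumericVector g(5);
  std::vector<double> p(nc, 0.0);
  std::vector<double> dp(5 * nc, 0.0);
  double f[5], df[5], pre[6], suf[6];
  for (int r = 0; r < nc; ++r) {
    for (int u = 0; u < 4; ++u) {
      for (int v = 0; v < 4; ++v) {
        for (int i = 0; i < 4; ++i) {
          int node = tipnode[i] == 0 ? u : v;
          f[i] = ftrans(node, reps(r, i), q[i]);
          df[i] = dftrans(node, reps(r, i));
        }
        f[4] = ftrans(u, v, q[4]);
        df[4] = dftrans(u, v);
        pre[0] = 1.0;
        for (int k = 0; k < 5; ++k) pre[k + 1] = pre[k] * f[k];
        suf[5] = 1.0;
        for (int k = 4; k >= 0; --k) suf[k] = suf[k + 1] * f[k];
        p[r] += 0.25 * pre[5];
        for (int k = 0; k < 5; ++k)
          dp[k * nc + r] += 0.25 * pre[k] * df[k] * suf[k + 1];
      }
    }
    p[r] *= mult[r];
    for (int k = 0; k < 5; ++k) dp[k * nc + r] *= mult[r];
  }
  for (int k = 0; k < 5; ++k) {
    double acc = 0.0;
    for (int r = 0; r < nc; ++r) {
      if (counts[r] > 0) {
        double pr = p[r] > 1e-300 ? p[r] : 1e-300;
        acc += counts[r] * dp[k * nc + r] / pr;
      }
    }
    g[k] = acc;
  }
  return g;
}
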