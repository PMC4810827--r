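#include <Rcpp.h>
using namespace Rcpp;

// Graph state for O(n) arc toggles: adjacency X plus maintained products
//   P(i,j)   = #two-paths i->k->j            (X %*% X)
//   Sout(i,j)= #shared predators of i and j  (X %*% t(X))
//   Sin(i,j) = #shared prey of i and j       (t(X) %*% X)
// and in/out degree vectors. Arc i->j: prey i eaten by predator j.
struct GraphState {
  int n;
  std::vector<int> X, P, Sout, Sin, din, dout;

  explicit GraphState(const IntegerMatrix &adj) {
    n = adj.nrow();
    X.assign(n * n, 0);
    P.assign(n * n, 0);
    Sout.assign(n * n, 0);
    Sin.assign(n * n, 0);
    din.assign(n, 0);
    dout.assign(n, 0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (adj(i, j) == 1 && i != j) X[i * n + j] = 1;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        if (x(i, j)) { dout[i]++; din[j]++; }
      }
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        int p = 0, so = 0, si = 0;
        for (int k = 0; k < n; ++k) {
          p += x(i, k) * x(k, j);
          so += x(i, k) * x(j, k);
          si += x(k, i) * x(k, j);
        }
        P[i * n + j] = p;
        Sout[i * n + j] = so;
        Sin[i * n + j] = si;
      }
  }

  inline int x(int i, int j) const { return X[i * n + j]; }
  inline int p(int i, int j) const { return P[i * n + j]; }
  inline int sout(int i, int j) const { return Sout[i * n + j]; }
  inline int sin_(int i, int j) const { return Sin[i * n + j]; }

  // add arc a->b (must be absent); products updated before X is set so that
  // only other entries feed the increments
  void add_arc(int a, int b) {
    for (int j = 0; j < n; ++j) {
      P[a * n + j] += X[b * n + j];     // a->b->j
      P[j * n + b] += X[j * n + a];     // j->a->b
      Sout[a * n + j] += X[j * n + b];  // both a,j -> b
      Sout[j * n + a] += X[j * n + b];
      Sin[b * n + j] += X[a * n + j];   // a -> both b,j
      Sin[j * n + b] += X[a * n + j];
    }
    X[a * n + b] = 1;
    dout[a]++; din[b]++;
  }

  // remove arc a->b (must be present)
  void remove_arc(int a, int b) {
    X[a * n + b] = 0;
    dout[a]--; din[b]--;
    for (int j = 0; j < n; ++j) {
      P[a * n + j] -= X[b * n + j];
      P[j * n + b] -= X[j * n + a];
      Sout[a * n + j] -= X[j * n + b];
      Sout[j * n + a] -= X[j * n + b];
      Sin[b * n + j] -= X[a * n + j];
      Sin[j * n + b] -= X[a * n + j];
    }
  }

  IntegerMatrix adjacency() const {
    IntegerMatrix out(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) out(i, j) = X[i * n + j];
    return out;
  }
};

// geometrically weighted partner/star kernels
static inline double g_lam(int d, double lambda) {
  return lambda * (1.0 - std::pow(1.0 - 1.0 / lambda, (double)d));
}
static inline double h_star(int d, double lambda) {
  return lambda * lambda *
         (std::pow(1.0 - 1.0 / lambda, (double)d) + d / lambda - 1.0);
}

// statistic codes (kept in sync with the R-side catalogue):
//  1 arc              2 reciprocity       3 generalist (alt in-star)
//  4 highly_predated  5 keystone          6 tri_trophic (alt two-path)
//  7 apparent_competition (common sink)   8 exploitative_competition (source)
//  9 omnivory (alt transitive triangle)  10 cyclic_triangle (alt cyclic)
// 11 in_2_star  12 in_3_star  13 out_2_star  14 out_3_star
// 15 two_path   16 transitive_triangle    17 cyclic_triangle_raw

// per-statistic lookup tables: rt[d] = (1 - 1/lambda)^d and
// gt[d] = g_lambda(d) for all attainable counts d (bounded by n(n-2)+1)
struct StatDef {
  int code;
  double lambda;
  std::vector<double> rt, gt;
};

static std::vector<StatDef> make_defs(const IntegerVector &codes,
                                      const NumericVector &lambdas, int n) {
  int maxd = n * n + 1;
  std::vector<StatDef> defs(codes.size());
  for (int s = 0; s < codes.size(); ++s) {
    defs[s].code = codes[s];
    defs[s].lambda = lambdas[s];
    double r = 1.0 - 1.0 / lambdas[s];
    defs[s].rt.resize(maxd + 1);
    defs[s].gt.resize(maxd + 1);
    double pw = 1.0;
    for (int d = 0; d <= maxd; ++d) {
      defs[s].rt[d] = pw;
      defs[s].gt[d] = lambdas[s] * (1.0 - pw);
      pw *= r;
    }
  }
  return defs;
}

// change statistic for ADDING absent arc a->b: z(G + ab) - z(G)
static double change_stat(const GraphState &G, const StatDef &S, int a, int b) {
  const std::vector<double> &rt = S.rt;
  const std::vector<double> &gt = S.gt;
  double d = 0.0;
  switch (S.code) {
  case 1: return 1.0;
  case 2: return (double)G.x(b, a);
  case 3: return gt[G.din[b]];
  case 4: return gt[G.dout[a]];
  case 5:
    return gt[G.din[a]] * rt[G.dout[a]] + gt[G.dout[b]] * rt[G.din[b]];
  case 6:
    for (int m = 0; m < G.n; ++m) {
      if (m != a && G.x(b, m)) d += rt[G.p(a, m)];
      if (m != b && G.x(m, a)) d += rt[G.p(m, b)];
    }
    return d;
  case 7:
    for (int j = 0; j < G.n; ++j)
      if (j != a && G.x(j, b)) d += rt[G.sout(a, j)];
    return d;
  case 8:
    for (int j = 0; j < G.n; ++j)
      if (j != b && G.x(a, j)) d += rt[G.sin_(b, j)];
    return d;
  case 9:
    d = gt[G.p(a, b)];
    for (int m = 0; m < G.n; ++m) {
      if (G.x(a, m) && G.x(b, m)) d += rt[G.p(a, m)];
      if (G.x(m, a) && G.x(m, b)) d += rt[G.p(m, b)];
    }
    return d;
  case 10:
    d = gt[G.p(b, a)];
    for (int m = 0; m < G.n; ++m) {
      if (G.x(m, a) && G.x(b, m)) d += rt[G.p(a, m)];
      if (G.x(b, m) && G.x(m, a)) d += rt[G.p(m, b)];
    }
    return d;
  case 11: return (double)G.din[b];
  case 12: return (double)(G.din[b] * (G.din[b] - 1)) / 2.0;
  case 13: return (double)G.dout[a];
  case 14: return (double)(G.dout[a] * (G.dout[a] - 1)) / 2.0;
  case 15: return (double)(G.din[a] + G.dout[b] - 2 * G.x(b, a));
  case 16: {
    int t = G.p(a, b);
    for (int m = 0; m < G.n; ++m) {
      if (G.x(a, m) && G.x(b, m)) t++;
      if (G.x(m, a) && G.x(m, b)) t++;
    }
    return (double)t;
  }
  case 17: return (double)G.p(b, a);
  default: stop("unknown statistic code %d", S.code);
  }
  return 0.0;
}

static NumericVector full_stats(const GraphState &G, const IntegerVector &codes,
                                const NumericVector &lambdas) {
  int n = G.n, p = codes.size();
  NumericVector z(p);
  for (int s = 0; s < p; ++s) {
    double lambda = lambdas[s], v = 0.0;
    switch (codes[s]) {
    case 1:
      for (int i = 0; i < n * n; ++i) v += G.X[i];
      break;
    case 2:
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) v += G.x(i, j) * G.x(j, i);
      break;
    case 3:
      for (int j = 0; j < n; ++j) v += h_star(G.din[j], lambda);
      break;
    case 4:
      for (int i = 0; i < n; ++i) v += h_star(G.dout[i], lambda);
      break;
    case 5:
      for (int i = 0; i < n; ++i)
        v += g_lam(G.din[i], lambda) * g_lam(G.dout[i], lambda);
      break;
    case 6:
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          if (i != j) v += g_lam(G.p(i, j), lambda);
      break;
    case 7:
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) v += g_lam(G.sout(i, j), lambda);
      break;
    case 8:
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) v += g_lam(G.sin_(i, j), lambda);
      break;
    case 9:
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          if (G.x(i, j)) v += g_lam(G.p(i, j), lambda);
      break;
    case 10:
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          if (G.x(i, j)) v += g_lam(G.p(j, i), lambda);
      break;
    case 11:
      for (int i = 0; i < n; ++i) v += G.din[i] * (G.din[i] - 1) / 2.0;
      break;
    case 12:
      for (int i = 0; i < n; ++i)
        v += G.din[i] * (G.din[i] - 1.0) * (G.din[i] - 2.0) / 6.0;
      break;
    case 13:
      for (int i = 0; i < n; ++i) v += G.dout[i] * (G.dout[i] - 1) / 2.0;
      break;
    case 14:
      for (int i = 0; i < n; ++i)
        v += G.dout[i] * (G.dout[i] - 1.0) * (G.dout[i] - 2.0) / 6.0;
      break;
    case 15:
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          if (i != j) v += G.p(i, j);
      break;
    case 16:
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          if (G.x(i, j)) v += G.p(i, j);
      break;
    case 17:
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          if (G.x(i, j)) v += G.p(j, i);
      v /= 3.0;
      break;
    default: stop("unknown statistic code %d", codes[s]);
    }
    z[s] = v;
  }
  return z;
}

// [[Rcpp::export]]
NumericVector cpp_compute_stats(IntegerMatrix adj, IntegerVector codes,
                                NumericVector lambdas) {
  GraphState G(adj);
  return full_stats(G, codes, lambdas);
}

// [[Rcpp::export]]
NumericVector cpp_change_stats(IntegerMatrix adj, IntegerVector codes,
                               NumericVector lambdas, int a, int b) {
  if (a == b) stop("self-loop dyad");
  GraphState G(adj);
  bool present = G.x(a - 1, b - 1) == 1;
  if (present) G.remove_arc(a - 1, b - 1);
  std::vector<StatDef> defs = make_defs(codes, lambdas, G.n);
  int p = codes.size();
  NumericVector d(p);
  for (int s = 0; s < p; ++s)
    d[s] = change_stat(G, defs[s], a - 1, b - 1);
  return d;
}

// Metropolis-Hastings single-arc-toggle sampler. Uses R's RNG so set.seed()
// on the R side gives a deterministic trace.
// [[Rcpp::export]]
List cpp_ergm_sample(IntegerMatrix adj, IntegerVector codes,
                     NumericVector lambdas, NumericVector theta,
                     double burn_in, double thinning, int sample_size,
                     bool keep_networks) {
  GraphState G(adj);
  const int n = G.n, p = codes.size();
  std::vector<StatDef> defs = make_defs(codes, lambdas, n);
  NumericVector z = full_stats(G, codes, lambdas);
  NumericMatrix stats(sample_size, p);
  List nets(keep_networks ? sample_size : 0);
  double accepted = 0.0, total = 0.0;
  std::vector<double> delta(p);

  long bsteps = (long)burn_in, tsteps = (long)thinning;
  for (int rep = -1; rep < sample_size; ++rep) {
    long steps = (rep < 0) ? bsteps : tsteps;
    for (long it = 0; it < steps; ++it) {
      int a = (int)(unif_rand() * n);
      int b = (int)(unif_rand() * (n - 1));
      if (b >= a) b++;
      bool present = G.x(a, b) == 1;
      if (present) G.remove_arc(a, b);
      double lr = 0.0;
      for (int s = 0; s < p; ++s) {
        delta[s] = change_stat(G, defs[s], a, b);
        lr += theta[s] * delta[s];
      }
      total += 1.0;
      if (!present) {
        // propose adding
        if (lr >= 0.0 || unif_rand() < std::exp(lr)) {
          G.add_arc(a, b);
          for (int s = 0; s < p; ++s) z[s] += delta[s];
          accepted += 1.0;
        }
      } else {
        // propose deletion: log-ratio is -lr
        if (-lr >= 0.0 || unif_rand() < std::exp(-lr)) {
          for (int s = 0; s < p; ++s) z[s] -= delta[s];
          accepted += 1.0;  // stays removed
        } else {
          G.add_arc(a, b);  // rejected: restore
        }
      }
    }
    if (rep >= 0) {
      for (int s = 0; s < p; ++s) stats(rep, s) = z[s];
      if (keep_networks) nets[rep] = G.adjacency();
    }
  }
  return List::create(_["statistics"] = stats,
                      _["networks"] = nets,
                      _["acceptance_rate"] = total > 0 ? accepted / total : 0.0,
                      _["final_adjacency"] = G.adjacency());
}

// directed triad census, standard 16 MAN classes
// 003 012 102 021D 021U 021C 111D 111U 030T 030C 201 120D 120U 120C 210 300
static int classify_triad(int xij, int xji, int xik, int xki, int xjk, int xkj) {
  int dy[3][2] = {{xij, xji}, {xik, xki}, {xjk, xkj}};
  int M = 0, A = 0;
  for (int d = 0; d < 3; ++d) {
    int s = dy[d][0] + dy[d][1];
    if (s == 2) M++;
    else if (s == 1) A++;
  }
  int N = 3 - M - A;
  // within-triple degrees over asymmetric arcs only
  int out[3] = {0, 0, 0}, in[3] = {0, 0, 0};
  int pairs[3][2] = {{0, 1}, {0, 2}, {1, 2}};
  for (int d = 0; d < 3; ++d) {
    int u = pairs[d][0], v = pairs[d][1];
    if (dy[d][0] + dy[d][1] == 1) {
      if (dy[d][0]) { out[u]++; in[v]++; }
      else { out[v]++; in[u]++; }
    }
  }
  if (M == 0 && A == 0) return 0;                       // 003
  if (M == 0 && A == 1) return 1;                       // 012
  if (M == 1 && N == 2) return 2;                       // 102
  if (M == 0 && A == 2) {
    for (int v = 0; v < 3; ++v) {
      if (out[v] == 2) return 3;                        // 021D
      if (in[v] == 2) return 4;                         // 021U
    }
    return 5;                                           // 021C
  }
  if (M == 1 && A == 1) {
    // third node w is the one not in the mutual dyad
    int w = -1;
    for (int d = 0; d < 3; ++d)
      if (dy[d][0] && dy[d][1]) w = 3 - pairs[d][0] - pairs[d][1];
    return (out[w] == 1) ? 6 : 7;                       // w sends: 111D, receives: 111U
  }
  if (M == 0 && A == 3) {
    for (int v = 0; v < 3; ++v)
      if (out[v] == 2) return 8;                        // 030T
    return 9;                                           // 030C
  }
  if (M == 2 && A == 0) return 10;                      // 201
  if (M == 1 && A == 2) {
    int w = -1;
    for (int d = 0; d < 3; ++d)
      if (dy[d][0] && dy[d][1]) w = 3 - pairs[d][0] - pairs[d][1];
    if (out[w] == 2) return 11;                         // 120D
    if (in[w] == 2) return 12;                          // 120U
    return 13;                                          // 120C
  }
  if (M == 2 && A == 1) return 14;                      // 210
  return 15;                                            // 300
}

// [[Rcpp::export]]
NumericVector cpp_triad_census(IntegerMatrix adj) {
  int n = adj.nrow();
  NumericVector counts(16);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      for (int k = j + 1; k < n; ++k)
        counts[classify_triad(adj(i, j), adj(j, i), adj(i, k), adj(k, i),
                              adj(j, k), adj(k, j))] += 1.0;
  return counts;
}
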