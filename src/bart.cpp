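// Sum-of-trees machinery: regularized tree prior, BIRTH/DEATH
// Metropolis-Hastings with acceptance-ratio accounting (for the MI
// importance score), conjugate leaf updates, and split-probability
// support for the sparse Dirichlet variant.
//
// All randomness goes through R's RNG so that set.seed() in R makes
// every chain reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct Node {
  int var;     // split covariate (0-based); -1 leaf; -2 dead slot
  double cut;  // rule: x <= cut goes left
  int left, right, parent;
  int depth;
  double mu;   // leaf value (only meaningful at leaves)
  double birth_alpha;  // MH acceptance probability of the BIRTH that
                       // created this split (internal nodes only)
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> assign;  // leaf index per training row

  explicit Tree(int n) {
    nodes.push_back({-1, 0.0, -1, -1, -1, 0, 0.0, 0.0});
    assign.assign(n, 0);
  }
  bool is_leaf(int i) const { return nodes[i].var == -1; }
  bool is_live(int i) const { return nodes[i].var != -2; }

  std::vector<int> leaves() const {
    std::vector<int> out;
    for (int i = 0; i < (int)nodes.size(); ++i)
      if (is_live(i) && is_leaf(i)) out.push_back(i);
    return out;
  }
  // internal nodes whose both children are leaves ("not-on-grandparent")
  std::vector<int> nogs() const {
    std::vector<int> out;
    for (int i = 0; i < (int)nodes.size(); ++i)
      if (is_live(i) && !is_leaf(i) &&
          is_leaf(nodes[i].left) && is_leaf(nodes[i].right))
        out.push_back(i);
    return out;
  }
  int n_internal() const {
    int c = 0;
    for (int i = 0; i < (int)nodes.size(); ++i)
      if (is_live(i) && !is_leaf(i)) ++c;
    return c;
  }
};

class Forest {
public:
  int n, P, H;
  NumericMatrix X;
  IntegerVector xtype;  // 0 continuous, 1 binary/dummy (informational)
  double a, b, sigma_mu;
  NumericVector s;      // splitting probabilities over covariates
  std::vector<Tree> trees;
  std::vector<double> fit;      // sum over trees of leaf values, per row

  Forest(NumericMatrix X_, IntegerVector xtype_, int H_, double a_,
         double b_, double sigma_mu_, NumericVector s_)
      : n(X_.nrow()), P(X_.ncol()), H(H_), X(X_), xtype(xtype_),
        a(a_), b(b_), sigma_mu(sigma_mu_), s(clone(s_)) {
    for (int h = 0; h < H; ++h) trees.emplace_back(n);
    fit.assign(n, 0.0);
  }

  // marginal-likelihood kernel for a leaf with r-sum S over m rows,
  // leaf value integrated out (terms constant across the move cancel)
  double ll_kernel(int m, double S, double sigma2) const {
    double smu2 = sigma_mu * sigma_mu;
    double denom = sigma2 + m * smu2;
    return 0.5 * std::log(sigma2 / denom) +
           smu2 * S * S / (2.0 * sigma2 * denom);
  }

  double log_struct_ratio_birth(int depth) const {
    // node at `depth` becomes internal with two depth+1 leaves
    double pg  = a * std::pow(1.0 + depth, -b);
    double pg2 = a * std::pow(2.0 + depth, -b);
    return std::log(pg) + 2.0 * std::log(1.0 - pg2) - std::log(1.0 - pg);
  }

  void rows_in_leaf(const Tree& tr, int leaf, std::vector<int>& rows) const {
    rows.clear();
    for (int i = 0; i < n; ++i)
      if (tr.assign[i] == leaf) rows.push_back(i);
  }

  // one MH structural move (BIRTH/DEATH) + leaf redraw for tree h
  void update_tree(int h, const std::vector<double>& resid, double sigma2) {
    Tree& tr = trees[h];
    std::vector<int> lv = tr.leaves();
    std::vector<int> ng = tr.nogs();
    bool stump = tr.n_internal() == 0;
    double p_birth = stump ? 1.0 : 0.5;
    bool do_birth = (unif_rand() < p_birth);

    if (do_birth) {
      int leaf = lv[(int)std::floor(unif_rand() * lv.size())];
      // covariate drawn from s
      double u = unif_rand(), acc = 0.0;
      int j = P - 1;
      for (int jj = 0; jj < P; ++jj) {
        acc += s[jj];
        if (u <= acc) { j = jj; break; }
      }
      std::vector<int> rows;
      rows_in_leaf(tr, leaf, rows);
      // distinct values of X[rows, j]
      std::vector<double> vals;
      vals.reserve(rows.size());
      for (int r : rows) vals.push_back(X(r, j));
      std::sort(vals.begin(), vals.end());
      vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
      if (vals.size() < 2) return;  // no legal cut: rejected, no MI record
      // cut uniform over distinct values strictly below the max
      int ncut = (int)vals.size() - 1;
      double cut = vals[(int)std::floor(unif_rand() * ncut)];

      double Sl = 0, Sr = 0;
      int nl = 0, nr = 0;
      for (int r : rows) {
        if (X(r, j) <= cut) { Sl += resid[r]; ++nl; }
        else                { Sr += resid[r]; ++nr; }
      }
      double Sp = Sl + Sr;
      int np = nl + nr;
      // after birth the tree surely has a nog and is not a stump
      int nnog_star = (int)ng.size();
      // leaf's parent was a nog iff its sibling is a leaf; splitting the
      // leaf removes that nog and adds one
      int par = tr.nodes[leaf].parent;
      bool parent_was_nog = false;
      if (par >= 0) {
        int sib = (tr.nodes[par].left == leaf) ? tr.nodes[par].right
                                               : tr.nodes[par].left;
        parent_was_nog = tr.is_leaf(sib);
      }
      nnog_star += parent_was_nog ? 0 : 1;
      double p_death_star = 0.5;
      double logr =
          std::log(p_death_star) - std::log(p_birth) +
          std::log((double)lv.size()) - std::log((double)nnog_star) +
          log_struct_ratio_birth(tr.nodes[leaf].depth) +
          ll_kernel(nl, Sl, sigma2) + ll_kernel(nr, Sr, sigma2) -
          ll_kernel(np, Sp, sigma2);
      double alpha = std::min(1.0, std::exp(logr));
      if (unif_rand() < alpha) {
        int li = (int)tr.nodes.size(), ri = li + 1;
        int d = tr.nodes[leaf].depth;
        tr.nodes.push_back({-1, 0.0, -1, -1, leaf, d + 1, 0.0, 0.0});
        tr.nodes.push_back({-1, 0.0, -1, -1, leaf, d + 1, 0.0, 0.0});
        tr.nodes[leaf].var = j;
        tr.nodes[leaf].cut = cut;
        tr.nodes[leaf].left = li;
        tr.nodes[leaf].right = ri;
        tr.nodes[leaf].birth_alpha = alpha;
        for (int r : rows) tr.assign[r] = (X(r, j) <= cut) ? li : ri;
      }
    } else {
      if (ng.empty()) return;  // no legal DEATH: rejected, no MI record
      int node = ng[(int)std::floor(unif_rand() * ng.size())];
      int li = tr.nodes[node].left, ri = tr.nodes[node].right;
      double Sl = 0, Sr = 0;
      int nl = 0, nr = 0;
      for (int i = 0; i < n; ++i) {
        if (tr.assign[i] == li) { Sl += resid[i]; ++nl; }
        else if (tr.assign[i] == ri) { Sr += resid[i]; ++nr; }
      }
      // state after death
      int internal_star = tr.n_internal() - 1;
      double p_birth_star = (internal_star == 0) ? 1.0 : 0.5;
      int nleaves = 0;
      for (int i = 0; i < (int)tr.nodes.size(); ++i)
        if (tr.is_live(i) && tr.is_leaf(i)) ++nleaves;
      int nleaves_star = nleaves - 1;
      double logr =
          std::log(p_birth_star) - std::log(0.5) +
          std::log((double)ng.size()) - std::log((double)nleaves_star) -
          log_struct_ratio_birth(tr.nodes[node].depth) +
          ll_kernel(nl + nr, Sl + Sr, sigma2) -
          ll_kernel(nl, Sl, sigma2) - ll_kernel(nr, Sr, sigma2);
      double alpha = std::min(1.0, std::exp(logr));
      if (unif_rand() < alpha) {
        tr.nodes[li].var = -2;
        tr.nodes[ri].var = -2;
        tr.nodes[node].var = -1;
        tr.nodes[node].left = tr.nodes[node].right = -1;
        for (int i = 0; i < n; ++i)
          if (tr.assign[i] == li || tr.assign[i] == ri) tr.assign[i] = node;
      }
    }
  }

  void draw_leaves(int h, const std::vector<double>& resid, double sigma2) {
    Tree& tr = trees[h];
    std::vector<int> lv = tr.leaves();
    std::vector<double> S(tr.nodes.size(), 0.0);
    std::vector<int> m(tr.nodes.size(), 0);
    for (int i = 0; i < n; ++i) {
      S[tr.assign[i]] += resid[i];
      m[tr.assign[i]] += 1;
    }
    double smu2 = sigma_mu * sigma_mu;
    for (int l : lv) {
      if (m[l] == 0) stop("empty leaf encountered (structural bug)");
      double post_var = sigma2 * smu2 / (sigma2 + m[l] * smu2);
      double post_mean = smu2 * S[l] / (sigma2 + m[l] * smu2);
      tr.nodes[l].mu = post_mean + std::sqrt(post_var) * norm_rand();
    }
  }

  void sweep(const NumericVector& partial, double sigma2) {
    std::vector<double> resid(n);
    for (int h = 0; h < H; ++h) {
      Tree& tr = trees[h];
      for (int i = 0; i < n; ++i) {
        if (!R_finite(partial[i])) stop("non-finite partial response");
        resid[i] = partial[i] - fit[i] + tr.nodes[tr.assign[i]].mu;
      }
      // remove tree h's contribution from fit, update, add back
      for (int i = 0; i < n; ++i) fit[i] -= tr.nodes[tr.assign[i]].mu;
      update_tree(h, resid, sigma2);
      draw_leaves(h, resid, sigma2);
      for (int i = 0; i < n; ++i) fit[i] += tr.nodes[tr.assign[i]].mu;
    }
  }

  IntegerVector split_counts() const {
    IntegerVector out(P);
    for (int h = 0; h < H; ++h)
      for (const Node& nd : trees[h].nodes)
        if (nd.var >= 0) out[nd.var] += 1;
    return out;
  }

  NumericVector fit_recompute() const {
    NumericVector out(n);
    for (int h = 0; h < H; ++h)
      for (int i = 0; i < n; ++i)
        out[i] += trees[h].nodes[trees[h].assign[i]].mu;
    return out;
  }

  NumericVector predict(const NumericMatrix& Xn) const {
    int m = Xn.nrow();
    NumericVector out(m);
    for (int h = 0; h < H; ++h) {
      const Tree& tr = trees[h];
      for (int i = 0; i < m; ++i) {
        int node = 0;
        while (!tr.is_leaf(node))
          node = (Xn(i, tr.nodes[node].var) <= tr.nodes[node].cut)
                     ? tr.nodes[node].left
                     : tr.nodes[node].right;
        out[i] += tr.nodes[node].mu;
      }
    }
    return out;
  }
};

// [[Rcpp::export(name = ".forest_create")]]
SEXP forest_create(NumericMatrix X, IntegerVector xtype, int H, double a,
                   double b, double sigma_mu, NumericVector s) {
  XPtr<Forest> p(new Forest(X, xtype, H, a, b, sigma_mu, s), true);
  return p;
}

// [[Rcpp::export(name = ".forest_sweep")]]
void forest_sweep(SEXP ptr, NumericVector partial, double sigma2) {
  XPtr<Forest> p(ptr);
  p->sweep(partial, sigma2);
}

// [[Rcpp::export(name = ".forest_fit")]]
NumericVector forest_fit(SEXP ptr) {
  XPtr<Forest> p(ptr);
  return wrap(p->fit);
}

// [[Rcpp::export(name = ".forest_fit_recompute")]]
NumericVector forest_fit_recompute(SEXP ptr) {
  XPtr<Forest> p(ptr);
  return p->fit_recompute();
}

// [[Rcpp::export(name = ".forest_counts")]]
IntegerVector forest_counts(SEXP ptr) {
  XPtr<Forest> p(ptr);
  return p->split_counts();
}

// [[Rcpp::export(name = ".forest_mi")]]
List forest_mi(SEXP ptr) {
  // per-covariate sum and count of stored BIRTH acceptance
  // probabilities over the split nodes of the current forest state
  XPtr<Forest> p(ptr);
  NumericVector s(p->P);
  IntegerVector c(p->P);
  for (int h = 0; h < p->H; ++h)
    for (const Node& nd : p->trees[h].nodes)
      if (nd.var >= 0) {
        s[nd.var] += nd.birth_alpha;
        c[nd.var] += 1;
      }
  return List::create(_["sum"] = s, _["cnt"] = c);
}

// [[Rcpp::export(name = ".forest_set_s")]]
void forest_set_s(SEXP ptr, NumericVector s) {
  XPtr<Forest> p(ptr);
  if (s.size() != p->P) stop("length(s) must equal the covariate count");
  p->s = clone(s);
}

// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(SEXP ptr, NumericMatrix Xnew) {
  XPtr<Forest> p(ptr);
  if (Xnew.ncol() != p->P) stop("Xnew has the wrong number of columns");
  return p->predict(Xnew);
}

// [[Rcpp::export(name = ".forest_sizes")]]
IntegerVector forest_sizes(SEXP ptr) {
  XPtr<Forest> p(ptr);
  IntegerVector out(p->H);
  for (int h = 0; h < p->H; ++h) {
    int c = 0;
    for (const Node& nd : p->trees[h].nodes)
      if (nd.var != -2) ++c;
    out[h] = c;
  }
  return out;
}

// conjugate MVN draw of the latent cluster effects b_k:
// precision A_k = (LG' Szz_k LG)/sigma2 + I, mean A_k^{-1} LG' Zr_k / sigma2.
// Szz is Q*Q x K (column k = vec of Z_k'Z_k), Zr is K x Q, LG = Lambda Gamma.
// [[Rcpp::export(name = ".sample_b")]]
NumericMatrix sample_b(NumericMatrix Szz, NumericMatrix Zr,
                       NumericMatrix LG, double sigma2) {
  int K = Zr.nrow(), Q = Zr.ncol();
  NumericMatrix out(K, Q);
  std::vector<double> A(Q * Q), S(Q * Q), tmp(Q * Q), rhs(Q), z(Q);
  for (int k = 0; k < K; ++k) {
    // S = Szz_k ; tmp = S * LG ; A = LG' * tmp / sigma2 + I
    for (int i = 0; i < Q * Q; ++i) S[i] = Szz(i, k);
    for (int i = 0; i < Q; ++i)
      for (int j = 0; j < Q; ++j) {
        double acc = 0;
        for (int l = 0; l < Q; ++l) acc += S[i + l * Q] * LG(l, j);
        tmp[i + j * Q] = acc;
      }
    for (int i = 0; i < Q; ++i)
      for (int j = 0; j < Q; ++j) {
        double acc = 0;
        for (int l = 0; l < Q; ++l) acc += LG(l, i) * tmp[l + j * Q];
        A[i + j * Q] = acc / sigma2 + (i == j ? 1.0 : 0.0);
      }
    // rhs = LG' Zr_k / sigma2
    for (int i = 0; i < Q; ++i) {
      double acc = 0;
      for (int l = 0; l < Q; ++l) acc += LG(l, i) * Zr(k, l);
      rhs[i] = acc / sigma2;
    }
    // lower Cholesky of A (in place, column-major lower)
    for (int j = 0; j < Q; ++j) {
      double d = A[j + j * Q];
      for (int l = 0; l < j; ++l) d -= A[j + l * Q] * A[j + l * Q];
      if (d <= 0) stop("cluster-effect posterior precision not PD");
      double lj = std::sqrt(d);
      A[j + j * Q] = lj;
      for (int i = j + 1; i < Q; ++i) {
        double acc = A[i + j * Q];
        for (int l = 0; l < j; ++l) acc -= A[i + l * Q] * A[j + l * Q];
        A[i + j * Q] = acc / lj;
      }
    }
    // solve L w = rhs (forward), then L' m = w (backward)
    for (int i = 0; i < Q; ++i) {
      double acc = rhs[i];
      for (int l = 0; l < i; ++l) acc -= A[i + l * Q] * rhs[l];
      rhs[i] = acc / A[i + i * Q];
    }
    for (int i = Q - 1; i >= 0; --i) {
      double acc = rhs[i];
      for (int l = i + 1; l < Q; ++l) acc -= A[l + i * Q] * rhs[l];
      rhs[i] = acc / A[i + i * Q];
    }
    // draw: m + L'^{-1} z
    for (int i = 0; i < Q; ++i) z[i] = norm_rand();
    for (int i = Q - 1; i >= 0; --i) {
      double acc = z[i];
      for (int l = i + 1; l < Q; ++l) acc -= A[l + i * Q] * z[l];
      z[i] = acc / A[i + i * Q];
    }
    for (int i = 0; i < Q; ++i) out(k, i) = rhs[i] + z[i];
  }
  return out;
}
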