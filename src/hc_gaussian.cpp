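// Greedy hill-climbing structure search maximising the Gaussian BIC
// network score, operating on the MLE covariance matrix. Mirrors the pure-R
// reference implementation (R/bn-consensus.R) move for move: same score,
// same ridge stabilisation, same lexicographic tie-breaks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::uvec to_uvec(const std::vector<unsigned int>& v) {
  arma::uvec out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i];
  return out;
}

static double node_score_c(const arma::mat& S, double n, unsigned int v,
                           const std::vector<unsigned int>& par) {
  double s2;
  if (par.empty()) {
    s2 = S(v, v);
  } else {
    arma::uvec p = to_uvec(par);
    arma::mat Spp = S.submat(p, p);
    Spp.diag() += 1e-8 * arma::mean(Spp.diag());
    arma::vec svp = S.submat(p, arma::uvec{v});
    arma::vec b = arma::solve(Spp, svp, arma::solve_opts::fast);
    s2 = S(v, v) - arma::dot(svp, b);
  }
  if (s2 < 1e-12) s2 = 1e-12;
  return -n / 2.0 * (std::log(2.0 * M_PI * s2) + 1.0) -
         (par.size() + 2) / 2.0 * std::log(n);
}

static arma::vec add_deltas_c(const arma::mat& S, double n, unsigned int y,
                              const std::vector<unsigned int>& par) {
  unsigned int p = S.n_cols;
  arma::mat Sp;
  if (par.empty()) {
    Sp = S;
  } else {
    arma::uvec pu = to_uvec(par);
    arma::mat Spp = S.submat(pu, pu);
    Spp.diag() += 1e-8 * arma::mean(Spp.diag());
    arma::mat B = arma::solve(Spp, S.rows(pu), arma::solve_opts::fast);
    Sp = S - S.cols(pu) * B;
  }
  arma::vec out(p);
  for (unsigned int x = 0; x < p; ++x) {
    double denom = Sp(y, y) * Sp(x, x);
    double rho2 = denom > 1e-12 ? Sp(x, y) * Sp(x, y) / denom : 0.0;
    if (rho2 > 1.0 - 1e-8) rho2 = 1.0 - 1e-8;
    out[x] = -n / 2.0 * std::log(1.0 - rho2) - 0.5 * std::log(n);
  }
  out[y] = -arma::datum::inf;
  for (unsigned int x : par) out[x] = -arma::datum::inf;
  return out;
}

static bool has_path_c(const std::vector<char>& adj, unsigned int p,
                       unsigned int from, unsigned int to) {
  if (from == to) return true;
  std::vector<char> visited(p, 0);
  std::vector<unsigned int> stack{from};
  while (!stack.empty()) {
    unsigned int v = stack.back();
    stack.pop_back();
    if (visited[v]) continue;
    visited[v] = 1;
    for (unsigned int w = 0; w < p; ++w) {
      if (adj[v * p + w]) {
        if (w == to) return true;
        if (!visited[w]) stack.push_back(w);
      }
    }
  }
  return false;
}

// [[Rcpp::export(name = ".hc_climb_cpp")]]
List hc_climb_cpp(const arma::mat& S, double n, int max_parents,
                  int max_iter, LogicalMatrix adj0) {
  unsigned int p = S.n_cols;
  std::vector<char> adj(p * p, 0);  // adj[x*p + y] = edge x -> y
  for (unsigned int x = 0; x < p; ++x)
    for (unsigned int y = 0; y < p; ++y)
      if (adj0(x, y)) adj[x * p + y] = 1;

  std::vector<std::vector<unsigned int>> parents(p);
  for (unsigned int y = 0; y < p; ++y)
    for (unsigned int x = 0; x < p; ++x)
      if (adj[x * p + y]) parents[y].push_back(x);

  arma::vec sc(p);
  arma::mat Dadd(p, p);
  for (unsigned int y = 0; y < p; ++y) {
    sc[y] = node_score_c(S, n, y, parents[y]);
    Dadd.col(y) = add_deltas_c(S, n, y, parents[y]);
  }

  struct Cand { double delta; unsigned int x, y; };
  int it = 0;
  while (it++ < max_iter) {
    double best_delta = 1e-10;
    int best_op = -1;  // 0 add, 1 delete, 2 reverse
    unsigned int bx = 0, by = 0;

    // additions: sort candidates by (-delta, x, y), take first acyclic
    std::vector<Cand> cands;
    for (unsigned int x = 0; x < p; ++x) {
      for (unsigned int y = 0; y < p; ++y) {
        if (x == y || adj[x * p + y] || adj[y * p + x]) continue;
        double d = Dadd(x, y);
        if (d > best_delta) cands.push_back({d, x, y});
      }
    }
    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      if (a.delta != b.delta) return a.delta > b.delta;
      if (a.x != b.x) return a.x < b.x;
      return a.y < b.y;
    });
    for (const Cand& c : cands) {
      if (c.delta <= best_delta + 1e-9) break;
      if ((int)parents[c.y].size() >= max_parents) continue;
      if (!has_path_c(adj, p, c.y, c.x)) {
        best_delta = c.delta; best_op = 0; bx = c.x; by = c.y;
        break;
      }
    }

    // deletions and reversals, edges in (x, y) lexicographic order
    for (unsigned int x = 0; x < p; ++x) {
      for (unsigned int y = 0; y < p; ++y) {
        if (!adj[x * p + y]) continue;
        std::vector<unsigned int> par_minus;
        for (unsigned int q : parents[y]) if (q != x) par_minus.push_back(q);
        double dd = node_score_c(S, n, y, par_minus) - sc[y];
        if (dd > best_delta + 1e-9) {
          best_delta = dd; best_op = 1; bx = x; by = y;
        }
        double rd = dd + Dadd(y, x);
        if (rd > best_delta + 1e-9 &&
            (int)parents[x].size() < max_parents) {
          adj[x * p + y] = 0;
          bool cyc = has_path_c(adj, p, x, y);
          adj[x * p + y] = 1;
          if (!cyc) {
            best_delta = rd; best_op = 2; bx = x; by = y;
          }
        }
      }
    }

    if (best_op < 0) break;
    std::vector<unsigned int> touched;
    if (best_op == 0) {
      adj[bx * p + by] = 1;
      touched = {by};
    } else if (best_op == 1) {
      adj[bx * p + by] = 0;
      touched = {by};
    } else {
      adj[bx * p + by] = 0;
      adj[by * p + bx] = 1;
      touched = {bx, by};
    }
    for (unsigned int v : touched) {
      parents[v].clear();
      for (unsigned int x = 0; x < p; ++x)
        if (adj[x * p + v]) parents[v].push_back(x);
      sc[v] = node_score_c(S, n, v, parents[v]);
      Dadd.col(v) = add_deltas_c(S, n, v, parents[v]);
    }
  }

  LogicalMatrix out(p, p);
  for (unsigned int x = 0; x < p; ++x)
    for (unsigned int y = 0; y < p; ++y)
      out(x, y) = adj[x * p + y] != 0;
  return List::create(_["adj"] = out, _["score"] = arma::accu(sc));
}
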