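// Felsenstein pruning log-likelihood for a Goldman-Yang style codon model
// with per-branch omega. The 61x61 generator is diagonalized through the
// symmetric similarity transform afforded by time reversibility; the
// (kappa, omega) -> eigensystem map is memoised across calls because
// quasi-Newton optimisation re-evaluates the likelihood at parameter points
// that differ in a single coordinate (branch lengths reuse the same
// eigensystem outright).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>

namespace {

struct Eig {
  arma::vec values;
  arma::mat vectors;
};

// cache key: exact double bit patterns are fine here -- the optimiser
// revisits identical parameter values, not merely close ones.
typedef std::pair<double, double> Key;
static std::map<Key, Eig> g_cache;
// quasi-Newton gradient steps perturb one coordinate at a time, so most
// (kappa, omega, t) triples repeat between evaluations: cache P outright.
struct PKey {
  double kappa, omega, t;
  bool operator<(const PKey& o) const {
    if (kappa != o.kappa) return kappa < o.kappa;
    if (omega != o.omega) return omega < o.omega;
    return t < o.t;
  }
};
static std::map<PKey, arma::mat> g_pcache;
static int g_cache_tag = -1;

void build_eig(double kappa, double omega, const arma::vec& pi,
               const arma::mat& syn_ts, const arma::mat& syn_tv,
               const arma::mat& non_ts, const arma::mat& non_tv, Eig& out) {
  arma::mat M = kappa * (syn_ts + omega * non_ts) + (syn_tv + omega * non_tv);
  arma::mat Q = M;
  Q.each_row() %= pi.t();
  arma::vec rs = arma::sum(Q, 1);
  Q.diag() -= rs;
  double rate = arma::dot(pi, rs);  // = -sum(pi * diag(Q))
  Q /= rate;
  arma::vec sp = arma::sqrt(pi);
  arma::mat S = Q;
  S.each_col() %= sp;
  S.each_row() /= sp.t();
  S = 0.5 * (S + S.t());
  arma::eig_sym(out.values, out.vectors, S);
}

const Eig& cached_eig(double kappa, double omega, const arma::vec& pi,
                      const arma::mat& syn_ts, const arma::mat& syn_tv,
                      const arma::mat& non_ts, const arma::mat& non_tv) {
  Key k(kappa, omega);
  std::map<Key, Eig>::iterator it = g_cache.find(k);
  if (it != g_cache.end()) return it->second;
  if (g_cache.size() > 600) g_cache.clear();
  Eig& e = g_cache[k];
  build_eig(kappa, omega, pi, syn_ts, syn_tv, non_ts, non_tv, e);
  return e;
}

arma::mat pmatrix(const Eig& e, const arma::vec& pi, double t) {
  arma::vec sp = arma::sqrt(pi);
  arma::mat P = e.vectors * arma::diagmat(arma::exp(e.values * t)) *
                e.vectors.t();
  P.each_col() /= sp;
  P.each_row() %= sp.t();
  P.elem(arma::find(P < 0)).zeros();
  return P;
}

}  // namespace

// states: n_tips x n_patterns integer matrix, 1..61, 0 = missing.
// edge: postorder (parent, child) 1-based node ids; tips are 1..n_tips.
// omega, tvec: per-edge, aligned with rows of `edge`.
// cache_tag: bump when pi (i.e. the dataset) changes, to invalidate the
// memoised eigensystems.
// [[Rcpp::export]]
double codon_loglik_cpp(const arma::imat& states,
                        const arma::vec& weights,
                        const arma::imat& edge,
                        int n_tips,
                        const arma::vec& pi,
                        double kappa,
                        const arma::vec& omega,
                        const arma::vec& tvec,
                        const arma::mat& syn_ts,
                        const arma::mat& syn_tv,
                        const arma::mat& non_ts,
                        const arma::mat& non_tv,
                        int cache_tag) {
  const int n_pat = states.n_cols;
  const int n_edge = edge.n_rows;
  const int n_node = n_tips + n_edge + 1 - n_tips;  // upper bound: see below
  const int n_total = n_tips + (n_edge + 1);        // generous node count

  if (cache_tag != g_cache_tag) {
    g_cache.clear();
    g_pcache.clear();
    g_cache_tag = cache_tag;
  }

  std::vector<arma::mat> partial(n_total + 1);
  std::vector<char> has_partial(n_total + 1, 0);
  arma::rowvec logscale(n_pat, arma::fill::zeros);
  (void)n_node;

  for (int e = 0; e < n_edge; ++e) {
    const int parent = edge(e, 0);
    const int child = edge(e, 1);
    PKey pk = {kappa, omega[e], tvec[e]};
    std::map<PKey, arma::mat>::iterator pit = g_pcache.find(pk);
    if (pit == g_pcache.end()) {
      const Eig& eg = cached_eig(kappa, omega[e], pi, syn_ts, syn_tv,
                                 non_ts, non_tv);
      if (g_pcache.size() > 800) g_pcache.clear();
      pit = g_pcache.insert(std::make_pair(pk, pmatrix(eg, pi, tvec[e]))).first;
    }
    const arma::mat& P = pit->second;

    arma::mat X;
    if (child <= n_tips) {
      // P * indicator(child) selects columns of P (or row sums for missing)
      X.set_size(61, n_pat);
      arma::vec ones61(61, arma::fill::ones);
      for (int p = 0; p < n_pat; ++p) {
        int s = states(child - 1, p);
        if (s == 0)
          X.col(p) = P * ones61;  // == 1 vector, but keep generic
        else
          X.col(p) = P.col(s - 1);
      }
    } else {
      X = P * partial[child];
    }
    if (!has_partial[parent]) {
      partial[parent] = X;
      has_partial[parent] = 1;
    } else {
      partial[parent] %= X;
      // rescale to avoid underflow on larger trees
      arma::rowvec m = arma::max(partial[parent], 0);
      for (int p = 0; p < n_pat; ++p) {
        if (m[p] > 0 && m[p] < 1e-200) {
          partial[parent].col(p) /= m[p];
          logscale[p] += std::log(m[p]);
        }
      }
    }
  }

  const int root = edge(n_edge - 1, 0);
  double ll = 0.0;
  for (int p = 0; p < n_pat; ++p) {
    double site = arma::dot(pi, partial[root].col(p));
    if (site <= 0) return -1e300;
    ll += weights[p] * (std::log(site) + logscale[p]);
  }
  return ll;
}

// Transition matrix exposed for the simulator / diagnostics (no caching).
// [[Rcpp::export]]
arma::mat codon_pmatrix_cpp(const arma::vec& pi, double kappa, double omega,
                            double t, const arma::mat& syn_ts,
                            const arma::mat& syn_tv, const arma::mat& non_ts,
                            const arma::mat& non_tv) {
  Eig e;
  build_eig(kappa, omega, pi, syn_ts, syn_tv, non_ts, non_tv, e);
  return pmatrix(e, pi, t);
}
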