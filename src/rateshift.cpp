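#include <Rcpp.h>
using namespace Rcpp;

// Log Metropolis-Hastings acceptance ratio for the trans-dimensional
// moves of the rate-shift sampler, exposed so the same arithmetic is
// testable from R. Conventions: k = current number of shifts, m = number
// of eligible nodes, pois_mean = mean of the (truncated) Poisson prior on
// the shift count; given k the prior is uniform over which k nodes carry
// the shifts. Birth proposes the new log-rate from its prior, so the
// rate-prior density cancels against the proposal density; the uniform
// configuration prior's binomial normaliser cancels against the uniform
// node choice, leaving likelihood ratio x pois_mean / (k + 1) for birth
// and the exact reverse, likelihood ratio x k / pois_mean, for death.
// Relocate is symmetric.
// [[Rcpp::export]]
double rj_log_alpha(std::string type, double loglik_ratio, int k, int m,
                    double pois_mean) {
  if (type == "birth") {
    if (k >= m) return R_NegInf;
    return loglik_ratio + std::log(pois_mean / (k + 1.0));
  }
  if (type == "death") {
    if (k <= 0) return R_NegInf;
    return loglik_ratio + std::log(k / pois_mean);
  }
  if (type == "relocate") return loglik_ratio;
  stop("unknown move type");
  return NA_REAL;
}

// REML (contrast) log-likelihood of Brownian motion with per-node rates:
// the variance contributed by the edge above node i is rate[i] * elen[i].
static double bm_reml_loglik(const IntegerVector &po_nodes,
                             const IntegerVector &child_left,
                             const IntegerVector &child_right,
                             const NumericVector &elen,
                             const std::vector<double> &rate,
                             const NumericVector &x, int ntip,
                             std::vector<double> &xval,
                             std::vector<double> &vadj) {
  int n_node = elen.size() - 1; // arrays are 1-based
  for (int i = 1; i <= ntip; ++i) {
    xval[i] = x[i - 1];
    vadj[i] = rate[i] * elen[i];
  }
  double ll = 0.0;
  for (int j = 0; j < po_nodes.size(); ++j) {
    int nd = po_nodes[j];
    int a = child_left[nd], b = child_right[nd];
    double V = vadj[a] + vadj[b];
    if (V <= 0.0) return R_NegInf;
    double d = xval[a] - xval[b];
    ll += -0.5 * (std::log(2.0 * M_PI * V) + d * d / V);
    xval[nd] = (vadj[b] * xval[a] + vadj[a] * xval[b]) / V;
    vadj[nd] = rate[nd] * elen[nd] + vadj[a] * vadj[b] / V;
  }
  (void)n_node;
  return ll;
}

// derive per-node edge rates from the shift configuration (preorder walk)
static void derive_rates(const IntegerVector &pre_nodes,
                         const IntegerVector &parent,
                         const std::vector<int> &is_shift,
                         const std::vector<double> &lr,
                         double lr0, int root,
                         std::vector<double> &rate) {
  rate[root] = std::exp(lr0);
  for (int j = 0; j < pre_nodes.size(); ++j) {
    int nd = pre_nodes[j];
    rate[nd] = is_shift[nd] ? std::exp(lr[nd]) : rate[parent[nd]];
  }
}

// Reversible-jump MCMC over clade-wise Brownian rate shifts.
// Node ids are 1-based ape ids (tips 1..ntip, root ntip+1). Eligible
// shift locations are all non-root nodes; a shift at a node applies its
// rate to the node's own edge and is inherited by all descendant edges
// until overridden by a nested shift.
// [[Rcpp::export]]
List rjmcmc_rates_cpp(IntegerVector po_nodes, IntegerVector child_left,
                      IntegerVector child_right, IntegerVector pre_nodes,
                      IntegerVector parent, NumericVector elen,
                      NumericVector x, int ntip, int generations,
                      int sample_interval, double pois_mean,
                      double rate_meanlog, double rate_sdlog,
                      double step_sd, NumericVector move_weights) {
  int n_node = elen.size() - 1;
  int root = ntip + 1;
  int m = n_node - 1; // eligible nodes: everything but the root
  std::vector<int> is_shift(n_node + 1, 0);
  std::vector<double> lr(n_node + 1, 0.0);
  std::vector<int> shift_nodes;
  double lr0 = rate_meanlog;
  std::vector<double> rate(n_node + 1, 0.0), xval(n_node + 1), vadj(n_node + 1);
  derive_rates(pre_nodes, parent, is_shift, lr, lr0, root, rate);
  double ll = bm_reml_loglik(po_nodes, child_left, child_right, elen, rate,
                             x, ntip, xval, vadj);
  if (!R_FINITE(ll)) stop("initial likelihood is not finite");

  double wsum = move_weights[0] + move_weights[1] + move_weights[2] +
                move_weights[3];
  double w_rate = move_weights[0] / wsum, w_birth = move_weights[1] / wsum,
         w_death = move_weights[2] / wsum;

  int n_samples = generations / sample_interval;
  NumericMatrix rate_samples(n_samples, n_node);
  IntegerMatrix shift_samples(n_samples, n_node);
  IntegerVector k_trace(n_samples);
  NumericVector r0_trace(n_samples), ll_trace(n_samples);
  IntegerVector attempts(4), accepts(4);
  std::vector<double> rate_prop(n_node + 1);
  int s = 0;

  for (int gen = 1; gen <= generations; ++gen) {
    int k = shift_nodes.size();
    double u = R::runif(0.0, 1.0);
    if (u < w_rate) {
      // --- rate update (log-scale random walk on one of the k+1 rates)
      attempts[0]++;
      int j = (int)std::floor(R::runif(0.0, 1.0) * (k + 1));
      if (j > k) j = k;
      double old_lr = (j == 0) ? lr0 : lr[shift_nodes[j - 1]];
      double new_lr = old_lr + R::rnorm(0.0, step_sd);
      if (j == 0) lr0 = new_lr; else lr[shift_nodes[j - 1]] = new_lr;
      derive_rates(pre_nodes, parent, is_shift, lr, lr0, root, rate_prop);
      double ll_new = bm_reml_loglik(po_nodes, child_left, child_right, elen,
                                     rate_prop, x, ntip, xval, vadj);
      double la = (ll_new - ll) +
        R::dnorm(new_lr, rate_meanlog, rate_sdlog, 1) -
        R::dnorm(old_lr, rate_meanlog, rate_sdlog, 1);
      if (std::log(R::runif(0.0, 1.0)) < la) {
        ll = ll_new;
        rate = rate_prop;
        accepts[0]++;
      } else {
        if (j == 0) lr0 = old_lr; else lr[shift_nodes[j - 1]] = old_lr;
      }
    } else if (u < w_rate + w_birth) {
      // --- birth: add a shift at a uniformly chosen non-shift node
      attempts[1]++;
      if (k < m) {
        std::vector<int> avail;
        avail.reserve(m - k);
        for (int nd = 1; nd <= n_node; ++nd)
          if (nd != root && !is_shift[nd]) avail.push_back(nd);
        int nd = avail[(int)std::floor(R::runif(0.0, 1.0) * avail.size())];
        double new_lr = R::rnorm(rate_meanlog, rate_sdlog);
        is_shift[nd] = 1;
        lr[nd] = new_lr;
        derive_rates(pre_nodes, parent, is_shift, lr, lr0, root, rate_prop);
        double ll_new = bm_reml_loglik(po_nodes, child_left, child_right,
                                       elen, rate_prop, x, ntip, xval, vadj);
        double la = rj_log_alpha("birth", ll_new - ll, k, m, pois_mean);
        if (std::log(R::runif(0.0, 1.0)) < la) {
          ll = ll_new;
          rate = rate_prop;
          shift_nodes.push_back(nd);
          accepts[1]++;
        } else {
          is_shift[nd] = 0;
        }
      }
    } else if (u < w_rate + w_birth + w_death) {
      // --- death: remove a uniformly chosen shift
      attempts[2]++;
      if (k > 0) {
        int idx = (int)std::floor(R::runif(0.0, 1.0) * k);
        int nd = shift_nodes[idx];
        is_shift[nd] = 0;
        derive_rates(pre_nodes, parent, is_shift, lr, lr0, root, rate_prop);
        double ll_new = bm_reml_loglik(po_nodes, child_left, child_right,
                                       elen, rate_prop, x, ntip, xval, vadj);
        double la = rj_log_alpha("death", ll_new - ll, k, m, pois_mean);
        if (std::log(R::runif(0.0, 1.0)) < la) {
          ll = ll_new;
          rate = rate_prop;
          shift_nodes.erase(shift_nodes.begin() + idx);
          accepts[2]++;
        } else {
          is_shift[nd] = 1;
        }
      }
    } else {
      // --- relocate: move a shift (keeping its rate) to a free node
      attempts[3]++;
      if (k > 0 && k < m) {
        int idx = (int)std::floor(R::runif(0.0, 1.0) * k);
        int nd_old = shift_nodes[idx];
        std::vector<int> avail;
        avail.reserve(m - k);
        for (int nd = 1; nd <= n_node; ++nd)
          if (nd != root && !is_shift[nd]) avail.push_back(nd);
        int nd_new = avail[(int)std::floor(R::runif(0.0, 1.0) * avail.size())];
        is_shift[nd_old] = 0;
        is_shift[nd_new] = 1;
        lr[nd_new] = lr[nd_old];
        derive_rates(pre_nodes, parent, is_shift, lr, lr0, root, rate_prop);
        double ll_new = bm_reml_loglik(po_nodes, child_left, child_right,
                                       elen, rate_prop, x, ntip, xval, vadj);
        double la = rj_log_alpha("relocate", ll_new - ll, k, m, pois_mean);
        if (std::log(R::runif(0.0, 1.0)) < la) {
          ll = ll_new;
          rate = rate_prop;
          shift_nodes[idx] = nd_new;
          accepts[3]++;
        } else {
          is_shift[nd_old] = 1;
          is_shift[nd_new] = 0;
        }
      }
    }
    if (gen % sample_interval == 0) {
      for (int nd = 1; nd <= n_node; ++nd) {
        rate_samples(s, nd - 1) = rate[nd];
        shift_samples(s, nd - 1) = is_shift[nd];
      }
      k_trace[s] = shift_nodes.size();
      r0_trace[s] = std::exp(lr0);
      ll_trace[s] = ll;
      s++;
    }
  }
  return List::create(_["rates"] = rate_samples,
                      _["shifts"] = shift_samples,
                      _["k"] = k_trace, _["r0"] = r0_trace,
                      _["logL"] = ll_trace,
                      _["attempts"] = attempts, _["accepts"] = accepts);
}
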