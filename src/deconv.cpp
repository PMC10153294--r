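#include <Rcpp.h>
using namespace Rcpp;

// Gaussian log-density with heteroscedastic variance sigma_b^2 + beta1 * g.
static inline double gauss_ll(double a, double g, double sb2, double b1) {
  double v = sb2 + b1 * g;
  return -0.5 * (std::log(2.0 * M_PI * v) + (a - g) * (a - g) / v);
}

//' Causal discrete convolution of a fine-resolution event series with a kernel.
//'
//' G_i = sum_{j=1}^{min(k,i)} I_{i-j+1} kappa_j at full fine resolution.
//' @noRd
// [[Rcpp::export]]
NumericVector conv_events_cpp(NumericVector events, NumericVector kern) {
  int n = events.size(), k = kern.size();
  NumericVector G(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    int jmax = std::min(k, i + 1);
    for (int j = 0; j < jmax; ++j) s += events[i - j] * kern[j];
    G[i] = s;
  }
  return G;
}

// Signal at coarse sample i (1-based) uses fine steps up to f_i = (i-1)*ratio;
// the first coarse sample has no preceding fine steps and G_1 = 0.
// [[Rcpp::export]]
NumericVector conv_downsample_cpp(NumericVector events, NumericVector kern,
                                  int ratio, int n_coarse) {
  int k = kern.size(), nI = events.size();
  NumericVector G(n_coarse);
  for (int i = 0; i < n_coarse; ++i) {
    int f = i * ratio;  // number of fine steps preceding coarse sample i+1
    if (f > nI) f = nI;
    double s = 0.0;
    int jmax = std::min(k, f);
    for (int j = 0; j < jmax; ++j) s += events[f - 1 - j] * kern[j];
    G[i] = s;
  }
  return G;
}

// [[Rcpp::export]]
double trace_loglik_cpp(NumericVector A, NumericVector events, NumericVector kern,
                        int ratio, double sigma_b, double beta1) {
  NumericVector G = conv_downsample_cpp(events, kern, ratio, A.size());
  double sb2 = sigma_b * sigma_b, ll = 0.0;
  for (int i = 0; i < A.size(); ++i) ll += gauss_ll(A[i], G[i], sb2, beta1);
  return ll;
}

// Adaptive block-independence MCMC over binary initiation configurations.
// Supports one or two channels sharing a common fine grid (dual-colour traces).
// All randomness comes from R's RNG so set.seed() in R controls the chain.
// [[Rcpp::export]]
List deconv_mcmc_cpp(List A_list, List kern_list,
                     NumericVector sigma_b, NumericVector beta1,
                     int ratio, NumericVector prior_p, NumericVector q_init,
                     int n_samples, int n_burn, int block_w, int thin,
                     IntegerVector I_init, double iter_offset,
                     bool adapt, bool record) {
  const int nC = A_list.size();
  std::vector<NumericVector> A(nC), kern(nC);
  std::vector<double> sb2(nC);
  for (int c = 0; c < nC; ++c) {
    A[c] = as<NumericVector>(A_list[c]);
    kern[c] = as<NumericVector>(kern_list[c]);
    sb2[c] = sigma_b[c] * sigma_b[c];
  }
  const int Nt = A[0].size();
  const int NI = Nt * ratio - 1;
  if (prior_p.size() != NI || q_init.size() != NI)
    stop("prior/proposal length must equal Nt*ratio - 1");
  int w = std::min(block_w, NI);

  std::vector<int> I(NI, 0);
  if (I_init.size() == NI) for (int j = 0; j < NI; ++j) I[j] = I_init[j];

  // per-channel coarse signal and cached per-point log-likelihood
  std::vector<std::vector<double> > G(nC), llv(nC);
  for (int c = 0; c < nC; ++c) {
    G[c].assign(Nt, 0.0);
    int k = kern[c].size();
    for (int i = 0; i < Nt; ++i) {
      int f = i * ratio; if (f > NI) f = NI;
      double s = 0.0; int jmax = std::min(k, f);
      for (int j = 0; j < jmax; ++j) s += I[f - 1 - j] * kern[c][j];
      G[c][i] = s;
    }
    llv[c].assign(Nt, 0.0);
    for (int i = 0; i < Nt; ++i) llv[c][i] = gauss_ll(A[c][i], G[c][i], sb2[c], beta1[c]);
  }

  std::vector<double> q(NI), logp1(NI), logp0(NI);
  for (int j = 0; j < NI; ++j) {
    q[j] = std::min(std::max(q_init[j], 0.05), 0.999);
    logp1[j] = std::log(prior_p[j]);
    logp0[j] = std::log(1.0 - prior_p[j]);
  }

  const int sweep = (NI + w - 1) / w;  // iterations per recorded sample unit
  const long total_iter = (long)n_samples * sweep;
  const long burn_iter = (long)n_burn * sweep;
  long accepted = 0;

  std::vector<double> marg(NI, 0.0);
  long n_marg = 0;
  int n_store = record ? (n_samples - n_burn + thin - 1) / thin : 0;
  IntegerMatrix configs(n_store > 0 ? n_store : 1, n_store > 0 ? NI : 1);
  int stored = 0, sample_idx = 0;

  std::vector<int> diff_idx; diff_idx.reserve(w);
  std::vector<int> diff_bit; diff_bit.reserve(w);
  std::vector<double> oldG, oldll;

  for (long it = 1; it <= total_iter; ++it) {
    int b = (int)std::floor(unif_rand() * (NI - w + 1));
    if (b > NI - w) b = NI - w;
    diff_idx.clear(); diff_bit.clear();
    double dlogprior = 0.0, dlogq = 0.0;
    for (int j = b; j < b + w; ++j) {
      int bit = (unif_rand() < q[j]) ? 1 : 0;
      if (bit != I[j]) {
        diff_idx.push_back(j); diff_bit.push_back(bit);
        if (bit == 1) {  // 0 -> 1 flip
          dlogprior += logp1[j] - logp0[j];
          dlogq += std::log(1.0 - q[j]) - std::log(q[j]);
        } else {
          dlogprior += logp0[j] - logp1[j];
          dlogq += std::log(q[j]) - std::log(1.0 - q[j]);
        }
      }
    }
    double logalpha = dlogprior + dlogq;
    int nd = diff_idx.size();
    std::vector<std::pair<int,int> > rng_c(nC);  // affected coarse index range
    if (nd > 0) {
      int smin = diff_idx[0] + 1, smax = diff_idx[nd - 1] + 1;  // 1-based fine
      for (int c = 0; c < nC; ++c) {
        int k = kern[c].size();
        int ilo = smin / ratio + ((smin % ratio) ? 1 : 0) + 1;  // ceil(smin/ratio)+1
        int ihi = (smax + k - 1) / ratio + 1;
        if (ilo < 1) ilo = 1;
        if (ihi > Nt) ihi = Nt;
        rng_c[c] = std::make_pair(ilo, ihi);
        if (ilo > ihi) continue;
        // save old slice, apply event deltas, accumulate delta log-lik
        for (int d = 0; d < nd; ++d) {
          int s = diff_idx[d] + 1;
          double delta = diff_bit[d] == 1 ? 1.0 : -1.0;
          int i0 = s / ratio + ((s % ratio) ? 1 : 0) + 1;  // first coarse with f_i >= s
          int i1 = (s + k - 1) / ratio + 1;
          if (i0 < 1) i0 = 1;
          if (i1 > Nt) i1 = Nt;
          for (int i = i0; i <= i1; ++i) {
            int f = (i - 1) * ratio;
            G[c][i - 1] += delta * kern[c][f - s];
          }
        }
        for (int i = rng_c[c].first; i <= rng_c[c].second; ++i) {
          double newll = gauss_ll(A[c][i - 1], G[c][i - 1], sb2[c], beta1[c]);
          logalpha += newll - llv[c][i - 1];
        }
      }
      bool accept = std::log(unif_rand()) < logalpha;
      if (accept) {
        ++accepted;
        for (int d = 0; d < nd; ++d) I[diff_idx[d]] = diff_bit[d];
        for (int c = 0; c < nC; ++c)
          for (int i = rng_c[c].first; i <= rng_c[c].second; ++i)
            llv[c][i - 1] = gauss_ll(A[c][i - 1], G[c][i - 1], sb2[c], beta1[c]);
      } else {  // roll back signal updates
        for (int c = 0; c < nC; ++c) {
          int k = kern[c].size();
          for (int d = 0; d < nd; ++d) {
            int s = diff_idx[d] + 1;
            double delta = diff_bit[d] == 1 ? -1.0 : 1.0;
            int i0 = s / ratio + ((s % ratio) ? 1 : 0) + 1;
            int i1 = (s + k - 1) / ratio + 1;
            if (i0 < 1) i0 = 1;
            if (i1 > Nt) i1 = Nt;
            for (int i = i0; i <= i1; ++i) {
              int f = (i - 1) * ratio;
              G[c][i - 1] += delta * kern[c][f - s];
            }
          }
        }
      }
    } else {
      ++accepted;  // identical proposal: trivially accepted
    }

    if (adapt) {
      double l = 1.0 / (3.0 * (iter_offset + (double)it));
      double om = 1.0 - l;
      for (int j = 0; j < NI; ++j) {
        double v = q[j] * om + l * (double)I[j];
        q[j] = std::min(std::max(v, 0.05), 0.999);
      }
    }

    if (it % sweep == 0) {
      ++sample_idx;
      if (sample_idx > n_burn) {
        ++n_marg;
        for (int j = 0; j < NI; ++j) marg[j] += I[j];
        if (record && ((sample_idx - n_burn - 1) % thin == 0) && stored < n_store) {
          for (int j = 0; j < NI; ++j) configs(stored, j) = I[j];
          ++stored;
        }
      }
    }
  }

  NumericVector marginal(NI), qv(NI);
  for (int j = 0; j < NI; ++j) {
    marginal[j] = n_marg > 0 ? marg[j] / (double)n_marg : NA_REAL;
    qv[j] = q[j];
  }
  IntegerVector Iout(NI);
  for (int j = 0; j < NI; ++j) Iout[j] = I[j];
  double lltot = 0.0;
  for (int c = 0; c < nC; ++c)
    for (int i = 0; i < Nt; ++i) lltot += llv[c][i];

  return List::create(
    _["configs"] = record ? configs : IntegerMatrix(0, 0),
    _["n_stored"] = stored,
    _["marginal"] = marginal,
    _["proposal_probs"] = qv,
    _["acceptance_rate"] = (double)accepted / (double)total_iter,
    _["final_config"] = Iout,
    _["loglik"] = lltot,
    _["n_iter"] = (double)total_iter);
}

// Events per coarse interval (t_{i-1}, t_i] for each stored configuration:
// rows = samples, cols = coarse time points; first coarse point has no
// preceding fine steps, so column 1 is always 0.
// [[Rcpp::export]]
IntegerMatrix window_counts_cpp(IntegerMatrix configs, int ratio, int n_coarse) {
  int S = configs.nrow(), NI = configs.ncol();
  IntegerMatrix out(S, n_coarse);
  for (int s = 0; s < S; ++s) {
    for (int i = 1; i < n_coarse; ++i) {
      int hi = i * ratio;            // fine index f_i (1-based), inclusive
      int lo = hi - ratio + 1;       // fine steps in (t_{i-1}, t_i]
      if (hi > NI) hi = NI;
      int g = 0;
      for (int j = lo; j <= hi; ++j) g += configs(s, j - 1);
      out(s, i) = g;
    }
  }
  return out;
}
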