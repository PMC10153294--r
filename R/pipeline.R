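#' Deconvolve and burst-call a pooled bin of traces
#'
#' Runs the full single-allele pipeline for all traces of one spatiotemporal
#' bin: builds the fine-grid Bernoulli prior from the bin mean activity,
#' samples initiation configurations per allele by adaptive block MCMC,
#' computes instantaneous rates (v = 1), and calls bursts on every posterior
#' sample.
#'
#' @param traces List of `activity_trace` sharing one time base.
#' @param gm Gene model used to build the deconvolution kernel.
#' @param nm Noise model.
#' @param dt_fine_s Fine step (s).
#' @param n_samples,n_burn,thin MCMC sweeps, burn-in, and storage thinning.
#' @param w Burst-calling window (min; default 5 sampling intervals).
#' @param gb Burst threshold in events per window (default 2).
#' @param seed Optional seed covering the whole bin.
#' @return List with `rate_list`, `state_list` (per-allele samples x time
#'   matrices), `times`, `dt`, `acceptance` (per allele), `prior`.
#' @export
analyze_bin <- function(traces, gm, nm, dt_fine_s = 1,
                        n_samples = 3500, n_burn = 500, thin = 10,
                        w = NULL, gb = 2, seed = NULL) {
  stopifnot(length(traces) >= 1)
  if (!is.null(seed)) set.seed(seed)
  times <- traces[[1]]$times
  dt <- traces[[1]]$dt
  if (is.null(w)) w <- 5 * dt
  kern <- build_kernel(gm, dt_fine_s)
  mu <- rowMeans(vapply(traces, function(tr) pmax(tr$values, 0),
                        numeric(length(times))))
  prior <- build_prior(mu, times, gm, dt_fine_s)
  rate_list <- vector("list", length(traces))
  state_list <- vector("list", length(traces))
  acc <- numeric(length(traces))
  for (a in seq_along(traces)) {
    ps <- sample_posterior(traces[[a]], kern, nm, prior,
                           n_samples = n_samples, n_burn = n_burn, thin = thin)
    r <- rate_from_samples(ps, v = 1)
    rate_list[[a]] <- r$r_samples
    state_list[[a]] <- call_bursts(r$r_samples, dt, w = w, gb = gb)
    acc[a] <- ps$acceptance_rate
  }
  list(rate_list = rate_list, state_list = state_list, times = times,
       dt = dt, acceptance = acc, prior = prior)
}

#' Propagator-based predictions of the effective bursting parameters
#'
#' Ground-truth expectations for a pooled bin of two-chromatid alleles with
#' (possibly time-dependent) single-copy telegraph rates, on the actual
#' sampling grid, so that censoring and discreteness biases of the empirical
#' estimators are reproduced: P_ON from the three-state occupancy, T_ON and
#' T_OFF from the first-passage machinery with the estimator's
#' length-reweighting, R = 2 k eta, K = R / P_ON, and T_C, B, F from the
#' usual compositions.
#'
#' @param p Single-copy `two_state_params`.
#' @param times Sampling grid (min).
#' @return Data frame with one column per parameter (`R`, `P_ON`, `K`,
#'   `T_ON`, `T_OFF`, `T_C`, `B`, `F`) and `t_min`.
#' @export
predict_effective_params <- function(p, times) {
  nt <- length(times)
  kon <- rep_len(p$k_on, nt); koff <- rep_len(p$k_off, nt)
  k <- rep_len(p$k, nt)
  eta1 <- kon / (kon + koff)
  ps2 <- build_propagator(p, times, n_copies = 2)
  p1 <- c((1 - eta1[1])^2, 2 * eta1[1] * (1 - eta1[1]), eta1[1]^2)
  occ <- expected_pon(ps2, p1)
  # ON/OFF first-passage with the empirical estimator's weighting
  rd_on <- residence_distributions(ps2, residence = 1:2, absorbing = 0, p1 = p1)
  rd_off <- residence_distributions(ps2, residence = 0, absorbing = 1:2, p1 = p1)
  T_ON <- expected_on_off_times(rd_on)
  T_OFF <- expected_on_off_times(rd_off)
  R <- 2 * k * eta_occ(occ)
  P_ON <- occ$P_ON
  K <- ifelse(P_ON > 0, R / P_ON, NA_real_)
  T_C <- T_ON * T_OFF / (T_ON + T_OFF)
  data.frame(t_min = times, R = R, P_ON = P_ON, K = K,
             T_ON = T_ON, T_OFF = T_OFF, T_C = T_C,
             B = K * T_ON, F = 1 / (T_ON + T_OFF))
}

# mean active-copy fraction from the occupancy matrix (columns n = 0,1,2)
eta_occ <- function(occ) {
  as.numeric(occ$occ %*% c(0, 1, 2)) / 2
}

#' Synthetic validation of the deconvolution + burst-calling pipeline
#'
#' For each combination of single-copy ON-probability and switching
#' correlation time, simulates two-chromatid traces at K(1) = `k1` mRNA/min,
#' runs the deconvolution and burst-calling pipeline, estimates the
#' effective bursting parameters, and compares their time medians with the
#' propagator-based predictions. The full-scale study uses 56 combinations
#' at 200 alleles; the desk-scale default reduces alleles and combinations
#' only (generator parameters are untouched).
#'
#' @param p_on1 Vector of single-copy ON-probabilities.
#' @param t_c1 Vector of single-copy correlation times (min).
#' @param k1 Single-copy initiation rate (default 8 mRNA/min).
#' @param n_alleles Alleles per combination (default 20 at desk scale).
#' @param duration Trace length (min, default 50).
#' @param seed Base seed; each combination derives its own.
#' @param gm Gene model for both simulation and deconvolution kernels
#'   (default synthetic hb at K_elo = 2 kb/min).
#' @param nm Noise model.
#' @param n_samples,n_burn,thin MCMC settings (desk default 1500/300/4,
#'   i.e. 300 stored samples).
#' @param params Parameters entering the error summary.
#' @return List with `table` (per combo x parameter: median estimate,
#'   median prediction, relative error), `median_rel_error` (global median,
#'   fraction), and `per_combo` medians.
#' @export
validation_grid <- function(p_on1, t_c1, k1 = 8, n_alleles = 20,
                            duration = 50, seed = 1,
                            gm = gene_model_hb_synthetic(elongation_rate = 2),
                            nm = noise_model(),
                            n_samples = 1500, n_burn = 300, thin = 4,
                            params = c("R", "P_ON", "K", "T_ON", "T_OFF", "T_C")) {
  combos <- expand.grid(p_on1 = p_on1, t_c1 = t_c1)
  rows <- list()
  for (ci in seq_len(nrow(combos))) {
    eta <- combos$p_on1[ci]; Tc <- combos$t_c1[ci]
    p <- two_state_from_occupancy(k1, eta, Tc)
    spec <- simulation_spec(p, n_alleles = n_alleles, duration = duration,
                            gm = gm, nm = nm,
                            seed = (seed * 1000L + ci) %% .Machine$integer.max)
    sim <- simulate_traces(spec, method = "gillespie")
    bin <- analyze_bin(sim$traces, gm, nm, n_samples = n_samples,
                       n_burn = n_burn, thin = thin)
    bp <- estimate_params(bin$rate_list, bin$state_list, bin$times)
    pred <- predict_effective_params(p, bin$times)
    sel <- -1                      # drop the degenerate first sample point
    for (pa in params) {
      est <- median(bp$estimate[[pa]][sel], na.rm = TRUE)
      prd <- median(pred[[pa]][sel], na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        p_on1 = eta, t_c1 = Tc, param = pa, estimate = est, predicted = prd,
        rel_error = abs(est - prd) / abs(prd))
    }
  }
  tab <- do.call(rbind, rows)
  per_combo <- stats::aggregate(rel_error ~ p_on1 + t_c1, tab, median)
  list(table = tab,
       median_rel_error = median(tab$rel_error, na.rm = TRUE),
       per_combo = per_combo)
}

#' Sensitivity of the rate autocorrelation to kernel misspecification
#'
#' Simulates two-chromatid traces at T_C(1) = `t_c1` for a set of
#' ON-probabilities with the kernel built at the true elongation rate, then
#' deconvolves the same traces with kernels built at alternative elongation
#' rates and compares the fitted autocorrelation amplitude Sigma_AC and
#' correlation time tau_AC against the correct-kernel estimates.
#'
#' @param p_on1 Single-copy ON-probabilities to probe.
#' @param t_c1 Single-copy correlation time (min, default 2).
#' @param k1 Single-copy initiation rate (default 8).
#' @param k_elo_true True (simulation) elongation rate, kb/min (default 2).
#' @param k_elo_alt Alternative deconvolution rates (default 1.5 and 2.5).
#' @param n_alleles Alleles per combination.
#' @param duration Trace length (min).
#' @param seed Base seed.
#' @param nm Noise model.
#' @param n_samples,n_burn,thin MCMC settings.
#' @return Data frame with one row per (p_on1, k_elo): fitted `Sigma_AC`,
#'   `tau_AC`, and their relative deviations from the correct-kernel fit
#'   (`rel_sigma`, `rel_tau`; 0 for the true kernel).
#' @export
ac_misspecification_study <- function(p_on1 = c(0.03, 0.12, 0.23, 0.36,
                                                0.52, 0.78, 0.90),
                                      t_c1 = 2, k1 = 8, k_elo_true = 2,
                                      k_elo_alt = c(1.5, 2.5),
                                      n_alleles = 20, duration = 50, seed = 1,
                                      nm = noise_model(),
                                      n_samples = 1500, n_burn = 300, thin = 4) {
  gm_true <- gene_model_hb_synthetic(elongation_rate = k_elo_true)
  res <- list()
  for (ei in seq_along(p_on1)) {
    eta <- p_on1[ei]
    p <- two_state_from_occupancy(k1, eta, t_c1)
    spec <- simulation_spec(p, n_alleles = n_alleles, duration = duration,
                            gm = gm_true, nm = nm,
                            seed = (seed * 1000L + 600L + ei) %% .Machine$integer.max)
    sim <- simulate_traces(spec, method = "gillespie")
    fits <- list()
    for (ke in c(k_elo_true, k_elo_alt)) {
      gm_dec <- gene_model_hb_synthetic(elongation_rate = ke)
      bin <- analyze_bin(sim$traces, gm_dec, nm, n_samples = n_samples,
                         n_burn = n_burn, thin = thin,
                         seed = (seed * 1000L + 700L + ei) %% .Machine$integer.max)
      ac <- empirical_autocorrelation(bin$rate_list, bin$dt)
      fits[[as.character(ke)]] <- fit_ac(ac, bin$dt)
    }
    ref <- fits[[as.character(k_elo_true)]]
    for (ke in c(k_elo_true, k_elo_alt)) {
      f <- fits[[as.character(ke)]]
      res[[length(res) + 1]] <- data.frame(
        p_on1 = eta, k_elo = ke, Sigma_AC = f$Sigma_AC, tau_AC = f$tau_AC,
        rel_sigma = abs(f$Sigma_AC - ref$Sigma_AC) / ref$Sigma_AC,
        rel_tau = abs(f$tau_AC - ref$tau_AC) / ref$tau_AC)
    }
  }
  do.call(rbind, res)
}
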