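#' Pool conditional rate distributions at a common mean rate
#'
#' The conditional distribution P(r | R0) is reconstructed as a mixture of
#' the per-bin distributions P(r | x, t) over all spatiotemporal bins whose
#' mean rate lies within `eps` of `R0`, weighted by allele counts. A
#' homogeneity fraction records how many member bins stay inside the pooled
#' CDF's 95% envelope, since pooling is only meaningful when members are
#' mutually similar.
#'
#' @param dists List of per-bin distributions, each a data frame with
#'   columns `r` and `p` (probabilities summing to 1 on a shared support).
#' @param R_bins Mean rate of each bin (same length as `dists`).
#' @param n_alleles Allele count of each bin.
#' @param R0 Conditioning rate (mRNA/min).
#' @param eps Half-width of the R window (> 0); with 15 equal bins on
#'   \[0, 16\] mRNA/min, eps = 0.53.
#' @param warn_frac Warn when fewer than this fraction of members lie inside
#'   the pooled envelope (default 0.8).
#' @return Object of class `rate_distribution`: data frame (`r`, `p`) plus
#'   attributes `R0`, `eps`, `members`, `homogeneity`.
#' @export
pool_conditional <- function(dists, R_bins, n_alleles, R0, eps = 0.53,
                             warn_frac = 0.8) {
  stopifnot(eps > 0, length(dists) == length(R_bins),
            length(dists) == length(n_alleles))
  sel <- which(abs(R_bins - R0) <= eps)
  if (length(sel) == 0) stop("no bins within eps of R0")
  support <- dists[[sel[1]]]$r
  wts <- n_alleles[sel] / sum(n_alleles[sel])
  p <- Reduce(`+`, Map(function(d, w) {
    stopifnot(isTRUE(all.equal(d$r, support)))
    w * d$p
  }, dists[sel], wts))
  pooled_cdf <- cumsum(p)
  # pointwise binomial 95% envelope around the pooled CDF
  n_tot <- sum(n_alleles[sel])
  half <- 1.96 * sqrt(pmax(pooled_cdf * (1 - pooled_cdf), 0) / n_tot)
  inside <- vapply(dists[sel], function(d)
    all(abs(cumsum(d$p) - pooled_cdf) <= half + 1e-12), TRUE)
  frac_in <- mean(inside)
  if (frac_in < warn_frac)
    warning(sprintf("only %.0f%% of member bins inside the pooled 95%% envelope",
                    100 * frac_in))
  structure(data.frame(r = support, p = p),
            class = c("rate_distribution", "data.frame"),
            R0 = R0, eps = eps, members = sel, homogeneity = frac_in)
}

#' Constitutive (non-bursting) reference distribution of windowed rates
#'
#' With initiation a memoryless process at rate R but a Pol II footprint
#' forbidding two events within one fine interval dt', the number of events
#' g in a window tau is Binomial(n_t = tau/dt', p = R dt') and the rate is
#' r = g/tau. As dt' -> 0 this recovers the Poisson reference. Closed-form
#' cumulants of r: sigma^2 = n_t p (1-p)/tau^2,
#' kappa3 = n_t p (1-p)(1-2p)/tau^3,
#' kappa4 = n_t p (1-p)(1-6p(1-p))/tau^4.
#'
#' @param R Mean rate (mRNA/min), with R * dt' <= 1.
#' @param tau Window length (min).
#' @param dt_fine Fine interval dt' in minutes (default 1/60, i.e. 1 s).
#' @return List with `dist` (data frame `r`, `p`) and `cumulants`
#'   (mean, sigma2, kappa3, kappa4).
#' @export
constitutive_binomial <- function(R, tau, dt_fine = 1 / 60) {
  nt <- round(tau / dt_fine)
  p <- R * dt_fine
  if (p > 1) stop("R exceeds the maximal physical rate 1/dt'")
  g <- 0:nt
  dist <- data.frame(r = g / tau, p = dbinom(g, nt, p))
  cum <- list(mean = nt * p / tau,
              sigma2 = nt * p * (1 - p) / tau^2,
              kappa3 = nt * p * (1 - p) * (1 - 2 * p) / tau^3,
              kappa4 = nt * p * (1 - p) * (1 - 6 * p * (1 - p)) / tau^4)
  list(dist = dist, cumulants = cum)
}

#' Cumulants of a discrete rate distribution
#'
#' Mean, variance, and third/fourth cumulants from raw moments:
#' kappa3 = ⟨r^3⟩ - 3⟨r^2⟩⟨r⟩ + 2⟨r⟩^3,
#' kappa4 = ⟨r^4⟩ - 4⟨r^3⟩⟨r⟩ - 3⟨r^2⟩^2 + 12⟨r^2⟩⟨r⟩^2 - 6⟨r⟩^4.
#'
#' @param rd Data frame with columns `r`, `p` (probabilities summing to 1).
#' @return List `mean`, `sigma2`, `kappa3`, `kappa4`.
#' @export
rate_cumulants <- function(rd) {
  if (abs(sum(rd$p) - 1) > 1e-8) stop("distribution must be normalized")
  m <- vapply(1:4, function(k) sum(rd$r^k * rd$p), 0)
  list(mean = m[1],
       sigma2 = m[2] - m[1]^2,
       kappa3 = m[3] - 3 * m[2] * m[1] + 2 * m[1]^3,
       kappa4 = m[4] - 4 * m[3] * m[1] - 3 * m[2]^2 + 12 * m[2] * m[1]^2 -
         6 * m[1]^4)
}

#' Empirical ensemble autocorrelation of deconvolved rates
#'
#' For each MCMC sample s, rates are standardized per time point across the
#' alleles of the bin (ensemble mean and SD), lag products are averaged over
#' alleles and time, and the per-sample curves rho_s(tau) are averaged with
#' their SD over samples as the error. Time points with zero ensemble
#' variance are masked.
#'
#' @param rate_list List (one per allele, >= 20 recommended) of rate matrices
#'   (samples x time) from [rate_from_samples()].
#' @param dt Sampling interval (min).
#' @param max_lag_min Largest lag (min, default 10).
#' @return Data frame `tau`, `rho`, `sigma_rho`.
#' @export
empirical_autocorrelation <- function(rate_list, dt, max_lag_min = 10) {
  nal <- length(rate_list)
  if (nal < 2) stop("need at least 2 alleles")
  S <- nrow(rate_list[[1]])
  nt <- ncol(rate_list[[1]])
  nlag <- min(nt - 2, floor(max_lag_min / dt))
  rho_s <- matrix(NA_real_, S, nlag + 1)
  for (s in seq_len(S)) {
    Rm <- vapply(rate_list, function(m) m[s, ], numeric(nt))  # nt x alleles
    mu <- rowMeans(Rm)
    sg <- sqrt(rowMeans((Rm - mu)^2))
    ok <- sg > 0
    Z <- (Rm - mu) / ifelse(ok, sg, NA_real_)
    C <- Z %*% t(Z) / nal                                      # nt x nt
    rho_s[s, ] <- vapply(0:nlag, function(l) {
      d <- C[cbind(seq_len(nt - l), seq_len(nt - l) + l)]
      mean(d, na.rm = TRUE)
    }, 0)
  }
  data.frame(tau = (0:nlag) * dt,
             rho = colMeans(rho_s, na.rm = TRUE),
             sigma_rho = apply(rho_s, 2, sd, na.rm = TRUE))
}

#' Fit the exponential-with-floor model to a rate autocorrelation
#'
#' Sigma_AC is read off as rho(dt); the correlation time tau_AC and noise
#' floor beta come from a weighted least-squares fit of
#' rho(tau) = Sigma_AC ((1 - beta) exp(-(tau - dt)/tau_AC) + beta) over
#' dt <= tau < `max_lag_min`, with weights 1/sigma_rho^2. A non-decaying
#' curve is flagged.
#'
#' @param ac Data frame from [empirical_autocorrelation()] (columns `tau`,
#'   `rho`, optionally `sigma_rho`).
#' @param dt Sampling interval (min).
#' @param max_lag_min Upper end of the fit range (default 10 min).
#' @return List with `Sigma_AC`, `tau_AC`, `beta`, `flagged`.
#' @export
fit_ac <- function(ac, dt, max_lag_min = 10) {
  sel <- ac$tau >= dt - 1e-9 & ac$tau < max_lag_min & is.finite(ac$rho)
  if (sum(sel) < 5) stop("need at least 5 lags in the fit range")
  tau <- ac$tau[sel]; rho <- ac$rho[sel]
  wts <- if (!is.null(ac$sigma_rho) && all(is.finite(ac$sigma_rho[sel])) &&
             all(ac$sigma_rho[sel] > 0)) 1 / ac$sigma_rho[sel]^2 else
           rep(1, sum(sel))
  Sig <- rho[which.min(abs(tau - dt))]
  obj <- function(par) {
    tAC <- exp(par[1]); beta <- 1 / (1 + exp(-par[2]))
    pred <- Sig * ((1 - beta) * exp(-(tau - dt) / tAC) + beta)
    sum(wts * (rho - pred)^2)
  }
  best <- NULL
  for (t0 in c(0.5, 1.5, 4)) {
    o <- optim(c(log(t0), -3), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  flagged <- mean(diff(rho) >= 0) > 0.5 || Sig <= 0
  list(Sigma_AC = Sig, tau_AC = exp(best$par[1]),
       beta = 1 / (1 + exp(-best$par[2])), flagged = flagged)
}

#' Between- and within-group variance decomposition
#'
#' For traces replicated across groups (e.g. embryos), the between-group
#' variance of the group means and the weighted within-group variance, with
#' weights proportional to 1/N_i (N_i = group size), decompose the total
#' variance by the law of total variance. The ratio between/total gauges how
#' exchangeable the groups are before pooling.
#'
#' @param values List of numeric vectors, one per group (>= 2 groups).
#' @return List with `sigma2_between`, `sigma2_within`, `sigma2_total`,
#'   `ratio`.
#' @export
group_variance_decomposition <- function(values) {
  if (length(values) < 2) stop("need at least 2 groups")
  ni <- vapply(values, length, 0L)
  w <- (1 / ni) / sum(1 / ni)
  mui <- vapply(values, mean, 0)
  s2i <- vapply(values, function(v) mean((v - mean(v))^2), 0)
  mu <- sum(w * mui)
  between <- sum(w * (mui - mu)^2)
  within <- sum(w * s2i)
  list(sigma2_between = between, sigma2_within = within,
       sigma2_total = between + within, ratio = between / (between + within))
}
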