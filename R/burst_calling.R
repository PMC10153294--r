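#' Super-Gaussian smoothing kernel for burst calling
#'
#' Centered moving-average weights kappa(t) proportional to
#' exp(-(2 t / w)^4), normalized to sum to 1 on the sampling grid. The
#' quartic exponent makes the window nearly flat over its width w and with
#' sharp shoulders, averaging Poisson initiation fluctuations without
#' spreading bursts much beyond their true extent.
#'
#' @param w Window width in minutes.
#' @param dt Grid spacing in minutes.
#' @return List with `weights` (normalized, symmetric) and `offsets`
#'   (in grid steps).
#' @export
smoothing_kernel <- function(w, dt) {
  stopifnot(w > 0, dt > 0)
  r <- ceiling(1.5 * w / dt) + 1L          # support where weights < 1e-12
  off <- -r:r
  kw <- exp(-(2 * off * dt / w)^4)
  list(weights = kw / sum(kw), offsets = off)
}

# centered moving average with zero padding outside the trace
moving_average <- function(x, weights, offsets) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_along(offsets)) {
    o <- offsets[i]
    src <- seq_len(n) - o
    ok <- src >= 1 & src <= n
    out[ok] <- out[ok] + weights[i] * x[src[ok]]
  }
  out
}

#' Call ON/OFF bursts from single-allele transcription rates
#'
#' The instantaneous rate r(t) (one posterior sample per row) is smoothed
#' with the super-Gaussian moving average of width `w` and thresholded at
#' r_b = g_b / w, the rate corresponding to `g_b` initiation events in one
#' window: n(t) = 1 iff the smoothed rate is >= r_b (ties count as ON).
#' With the defaults (w = 5 dt at dt = 10 s, g_b = 2, so r_b = 2.4 mRNA/min)
#' an isolated impulse of g_b events yields an ON interval of 3 dt = 30 s,
#' the shortest reliably detectable burst.
#'
#' @param r Matrix of rates (samples x time, mRNA/min) or a single vector.
#' @param dt Sampling interval in minutes.
#' @param w Smoothing window in minutes (default 5 dt).
#' @param gb Minimal number of initiation events per burst (default 2).
#' @return Binary matrix (or vector) of ON states, same shape as `r`.
#' @export
call_bursts <- function(r, dt, w = 5 * dt, gb = 2) {
  vec <- is.null(dim(r))
  if (vec) r <- matrix(r, nrow = 1)
  kk <- smoothing_kernel(w, dt)
  rb <- gb / w
  n <- t(apply(r, 1, function(x)
    as.integer(moving_average(x, kk$weights, kk$offsets) >= rb)))
  if (vec) n[1, ] else n
}

# Period-duration bookkeeping for one binary state vector. Boundaries sit at
# the last point of each run, plus forced boundaries at both trace ends; the
# state and rate at t refer to the interval (t - dt, t]. Returns tau (minutes)
# per time point; tau(t1) = 0-length first period is possible.
period_durations <- function(n, dt) {
  nt <- length(n)
  rl <- rle(n)
  ends <- cumsum(rl$lengths)              # run end indices
  bpts <- unique(c(1L, ends, nt))         # boundary indices, t1/tNt forced
  tau <- numeric(nt)
  for (j in seq_len(length(bpts) - 1)) {
    lo <- bpts[j]; hi <- bpts[j + 1]
    tau[(lo + 1):hi] <- (hi - lo) * dt
  }
  tau[1] <- (bpts[2] - bpts[1]) * dt      # first point takes the first period
  tau
}

#' Estimate bursting parameters for a pooled bin of alleles
#'
#' Per MCMC sample and time point: the mean rate R and ON-probability P_ON
#' are across-allele means of r(t) and n(t); the initiation rate K averages
#' r(t) over ON alleles and the leak rate K_L over OFF alleles; the mean ON
#' and OFF durations weight each allele's current period duration tau(t) by
#' the inverse of its length in samples (pi(t) = tau/dt), so that long
#' periods are not over-counted across the time points they span. Parameter
#' point estimates and SDs are the mean and SD over MCMC samples; remaining
#' missing values (e.g. no OFF allele at some t) are interpolated with a
#' 1-min Gaussian kernel over time.
#'
#' @param rate_list List (one per allele) of rate matrices (samples x time,
#'   from [rate_from_samples()] with v = 1).
#' @param state_list List of matching ON-state matrices (from
#'   [call_bursts()]).
#' @param times Coarse sample times in minutes.
#' @param smooth_sd_min SD of the interpolating Gaussian kernel (minutes).
#' @return Object of class `bursting_params`: a list of per-time estimate
#'   and SD matrices plus a tidy `as.data.frame` method. Parameters: R, P_ON,
#'   K, K_L, T_ON, T_OFF, T_C, B, F.
#' @export
estimate_params <- function(rate_list, state_list, times, smooth_sd_min = 1) {
  stopifnot(length(rate_list) == length(state_list), length(rate_list) >= 1)
  nal <- length(rate_list)
  S <- nrow(rate_list[[1]])
  nt <- length(times)
  dt <- diff(times)[1]
  pars <- c("R", "P_ON", "K", "K_L", "T_ON", "T_OFF")
  acc <- lapply(pars, function(p) matrix(NA_real_, S, nt))
  names(acc) <- pars
  # per-allele per-sample period durations
  for (s in seq_len(S)) {
    rmat <- t(vapply(rate_list, function(m) m[s, ], numeric(nt)))   # alleles x t
    nmat <- t(vapply(state_list, function(m) m[s, ], numeric(nt)))
    taumat <- t(apply(nmat, 1, period_durations, dt = dt))
    pimat <- taumat / dt
    invpi <- ifelse(pimat > 0, 1 / pimat, 0)
    acc$R[s, ] <- colMeans(rmat)
    acc$P_ON[s, ] <- colMeans(nmat)
    zk <- colSums(nmat)
    acc$K[s, ] <- ifelse(zk > 0, colSums(rmat * nmat) / zk, NA_real_)
    zl <- colSums(1 - nmat)
    acc$K_L[s, ] <- ifelse(zl > 0, colSums(rmat * (1 - nmat)) / zl, NA_real_)
    won <- nmat * invpi
    zon <- colSums(won)
    acc$T_ON[s, ] <- ifelse(zon > 0, colSums(taumat * won) / zon, NA_real_)
    woff <- (1 - nmat) * invpi
    zoff <- colSums(woff)
    acc$T_OFF[s, ] <- ifelse(zoff > 0, colSums(taumat * woff) / zoff, NA_real_)
  }
  est <- lapply(acc, function(m) colMeans(m, na.rm = TRUE))
  sds <- lapply(acc, function(m) apply(m, 2, sd, na.rm = TRUE))
  est <- lapply(est, gaussian_interp, times = times, sd_min = smooth_sd_min)
  # derived parameters from the interpolated point estimates
  dp <- derived_params(est$K, est$T_ON, est$T_OFF)
  est$T_C <- dp$T_C; est$B <- dp$B; est$F <- dp$F
  structure(list(estimate = est, sd = sds, times = times, n_alleles = nal,
                 n_samples = S),
            class = "bursting_params")
}

# Replace NA/NaN entries by a Gaussian-kernel average of the non-missing
# values over the time axis; non-missing entries are left untouched.
gaussian_interp <- function(x, times, sd_min = 1) {
  bad <- !is.finite(x)
  if (!any(bad) || all(bad)) return(ifelse(is.finite(x), x, NA_real_))
  for (i in which(bad)) {
    wgt <- exp(-0.5 * ((times - times[i]) / sd_min)^2)
    wgt[bad] <- 0
    x[i] <- sum(wgt * ifelse(bad, 0, x)) / sum(wgt)
  }
  x
}

#' @export
as.data.frame.bursting_params <- function(x, ...) {
  do.call(rbind, lapply(names(x$estimate), function(p)
    data.frame(t_min = x$times, param = p, value = x$estimate[[p]],
               sd = if (p %in% names(x$sd)) x$sd[[p]] else NA_real_)))
}

#' @export
print.bursting_params <- function(x, ...) {
  cat(sprintf("<bursting_params> %d alleles, %d MCMC samples, %d time points\n",
              x$n_alleles, x$n_samples, length(x$times)))
  med <- vapply(x$estimate, median, 0, na.rm = TRUE)
  print(round(med, 3))
  invisible(x)
}

#' Derived bursting parameters
#'
#' T_C = T_ON T_OFF / (T_ON + T_OFF) (switching correlation time),
#' B = K T_ON (burst size), F = 1 / (T_ON + T_OFF) (burst frequency).
#'
#' @param K Initiation rate (mRNA/min).
#' @param T_ON,T_OFF Mean ON/OFF durations (min, > 0).
#' @return List with `T_C`, `B`, `F` (vectorized).
#' @export
derived_params <- function(K, T_ON, T_OFF) {
  if (any(stats::na.omit(c(T_ON, T_OFF)) <= 0))
    stop("T_ON and T_OFF must be positive")
  list(T_C = T_ON * T_OFF / (T_ON + T_OFF),
       B = K * T_ON,
       F = 1 / (T_ON + T_OFF))
}

#' Convert effective (two-chromatid) parameters to single-gene-copy values
#'
#' The two unresolved sister chromatids are assumed identical and
#' independent, so the effective ON-probability is
#' P_ON = 1 - (1 - P_ON1)^2. Inverting, and matching mean rates and the
#' stationary residence times of the three-state chain of two copies:
#' P_ON1 = 1 - sqrt(1 - P_ON), K1 = K (1 + sqrt(1 - P_ON)) / 2,
#' T_C1 = 2 T_C / (1 + sqrt(1 - P_ON)). These relations are exact at
#' stationarity and approximate when the switching rates drift slowly.
#'
#' @param P_ON Effective ON-probability in \[0, 1\].
#' @param K Effective initiation rate (mRNA/min).
#' @param T_C Effective switching correlation time (min).
#' @return List with `P_ON1`, `K1`, `T_C1`.
#' @export
to_single_copy <- function(P_ON, K = NULL, T_C = NULL) {
  if (any(P_ON > 1 | P_ON < 0)) stop("P_ON must lie in [0, 1]")
  srt <- sqrt(1 - P_ON)
  out <- list(P_ON1 = 1 - srt)
  if (!is.null(K)) out$K1 <- K * (1 + srt) / 2
  if (!is.null(T_C)) out$T_C1 <- 2 * T_C / (1 + srt)
  out
}
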