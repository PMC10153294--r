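#' Two-state (telegraph) promoter model parameters
#'
#' The promoter toggles between OFF and ON with rates k_on and k_off
#' (1/min) and initiates transcripts at rate k (mRNA/min) while ON. Derived
#' quantities: stationary occupancy eta = k_on/(k_on + k_off) and switching
#' correlation time T = 1/(k_on + k_off). Rates may be tabulated on a time
#' grid for the non-stationary propagator machinery.
#'
#' @param k Initiation rate (mRNA/min), scalar or vector on `times`.
#' @param k_on,k_off Switching rates (1/min), scalars or vectors on `times`.
#' @param times Optional time grid (min) for time-dependent rates.
#' @return Object of class `two_state_params`.
#' @export
two_state_params <- function(k, k_on, k_off, times = NULL) {
  if (any(c(k, k_on, k_off) < 0)) stop("rates must be non-negative")
  n <- max(length(k), length(k_on), length(k_off))
  if (n > 1 && is.null(times)) stop("time-dependent rates need a time grid")
  if (!is.null(times)) {
    k <- rep_len(k, length(times)); k_on <- rep_len(k_on, length(times))
    k_off <- rep_len(k_off, length(times))
  }
  structure(list(k = k, k_on = k_on, k_off = k_off, times = times,
                 eta = k_on / (k_on + k_off), T = 1 / (k_on + k_off)),
            class = "two_state_params")
}

#' Construct telegraph parameters from occupancy and correlation time
#' @param k Initiation rate (mRNA/min).
#' @param eta Stationary ON occupancy (P_ON of one copy).
#' @param T_c Switching correlation time 1/(k_on + k_off), minutes.
#' @param times Optional time grid for time-dependent inputs.
#' @return A `two_state_params` with k_on = eta/T_c, k_off = (1 - eta)/T_c.
#' @export
two_state_from_occupancy <- function(k, eta, T_c, times = NULL) {
  two_state_params(k, eta / T_c, (1 - eta) / T_c, times = times)
}

#' Stationary-start moments of the initiation count
#'
#' Closed forms for the telegraph model started at stationarity: the mean
#' count over \[0, t\] is k eta t; the ON/OFF-conditioned means and the second
#' moment carry the switching memory through exp(-t/T) terms. The variance
#' follows as g2 - mean^2 = k eta t + 2 k^2 eta (1 - eta) (tT - T^2 +
#' T^2 exp(-t/T)) and reduces to the Poisson limit as T -> 0.
#'
#' @param p A stationary `two_state_params`.
#' @param t Elapsed time(s), minutes, >= 0.
#' @return Data frame with `t`, `mean` (⟨g⟩), `mean_on` (⟨g(1,t)⟩),
#'   `mean_off` (⟨g(0,t)⟩), `second` (⟨g^2⟩), `var`.
#' @export
stationary_moments <- function(p, t) {
  stopifnot(inherits(p, "two_state_params"))
  if (any(t < 0)) stop("t must be non-negative")
  k <- p$k[1]; eta <- p$eta[1]; Tc <- p$T[1]
  ex <- exp(-t / Tc)
  m <- k * eta * t
  m1 <- k * eta^2 * t + k * eta * (1 - eta) * Tc * (1 - ex)
  m0 <- k * eta * (1 - eta) * t - k * eta * (1 - eta) * Tc * (1 - ex)
  g2 <- k * eta * t + (k * eta * t)^2 +
    2 * k^2 * eta * (1 - eta) * (Tc^2 * ex + t * Tc - Tc^2)
  data.frame(t = t, mean = m, mean_on = m1, mean_off = m0, second = g2,
             var = g2 - m^2)
}

#' Normalized autocorrelation of windowed initiation counts
#'
#' Autocorrelation of g(t; t - tau_tilde), the number of initiations in a
#' trailing window of length tau_tilde, for the stationary telegraph model.
#' Two regimes: for lags shorter than the window the overlapping counts share
#' trajectory (window-dominated decay); for longer lags the correlation
#' decays purely as exp(-(tau - tau_tilde)/T) through the promoter state.
#' rho(0) = 1 exactly and the two branches are continuous at tau =
#' tau_tilde. Identical for any number of independent gene copies.
#'
#' @param p A stationary `two_state_params`.
#' @param tau_tilde Integration window (min): the sampling interval for rate
#'   autocorrelations, the elongation time for activity autocorrelations.
#' @param tau Lag(s), minutes, >= 0.
#' @return Numeric vector rho(tau).
#' @export
model_autocorrelation <- function(p, tau_tilde, tau) {
  stopifnot(inherits(p, "two_state_params"), tau_tilde > 0)
  if (any(tau < 0)) stop("lags must be non-negative")
  k <- p$k[1]; eta <- p$eta[1]; Tc <- p$T[1]
  s2 <- k * eta * tau_tilde +
    2 * k^2 * eta * (1 - eta) * (tau_tilde * Tc - Tc^2 + Tc^2 * exp(-tau_tilde / Tc))
  vapply(tau, function(tt) {
    if (tt < tau_tilde) {
      num <- k * eta * (tau_tilde - tt) +
        2 * k^2 * eta * (1 - eta) * Tc * (tau_tilde - tt) +
        k^2 * eta * (1 - eta) * Tc^2 *
          (exp(-(tau_tilde + tt) / Tc) + exp(-(tau_tilde - tt) / Tc) -
             2 * exp(-tt / Tc))
    } else {
      num <- k^2 * eta * (1 - eta) * Tc^2 * (1 - exp(-tau_tilde / Tc))^2 *
        exp(-(tt - tau_tilde) / Tc)
    }
    num / s2
  }, 0)
}

phi1 <- function(x) ifelse(x < 1e-5, 1 - x / 3 + x^2 / 12,
                           2 * (exp(-x) + x - 1) / x^2)
phi2 <- function(x) ifelse(x < 1e-5, 1 - x + 7 * x^2 / 12,
                           (1 - exp(-x))^2 / x^2)

#' Amplitude of time-correlated rate fluctuations
#'
#' Sigma_AC, the rate autocorrelation at one sampling lag, in closed form:
#' Sigma_AC = k dt (1 - eta) phi2(dt/T) / (1 + k dt (1 - eta) phi1(dt/T))
#' with filter functions phi1(x) = 2(exp(-x) + x - 1)/x^2 and
#' phi2(x) = (1 - exp(-x))^2/x^2. Vanishes as dt -> 0; grows with k at fixed
#' eta and falls with eta at fixed mean rate.
#'
#' @param p A stationary `two_state_params`.
#' @param dt Sampling interval (min).
#' @return Sigma_AC in \[0, 1\].
#' @export
sigma_ac <- function(p, dt) {
  stopifnot(inherits(p, "two_state_params"), dt > 0)
  k <- p$k[1]; eta <- p$eta[1]; Tc <- p$T[1]
  x <- dt / Tc
  k * dt * (1 - eta) * phi2(x) / (1 + k * dt * (1 - eta) * phi1(x))
}

# generator of the promoter-state chain; states n = 0..n_copies
state_generator <- function(k_on, k_off, n_copies) {
  if (n_copies == 1) {
    matrix(c(-k_on, k_on, k_off, -k_off), 2, 2)
  } else {
    matrix(c(-2 * k_on, 2 * k_on, 0,
             k_off, -(k_off + k_on), k_on,
             0, 2 * k_off, -2 * k_off), 3, 3)
  }
}

#' Time-ordered propagators of the promoter-state chain
#'
#' Per-step transition matrices U(t_\{j+1\}, t_j) =
#' expm((M(t_\{j+1\}) + M(t_j)) dt / 2) for one gene copy (2 states) or two
#' independent identical copies (3 states, n = number of active copies);
#' their ordered product approximates the time-ordered exponential of the
#' master equation. Columns sum to 1 by construction.
#'
#' @param p A `two_state_params` (tabulated on `times` if time-dependent).
#' @param times Time grid (min, uniform or not).
#' @param n_copies 1 or 2.
#' @return Object of class `propagator_set`: list with `U` (array
#'   n_state x n_state x (length(times) - 1)), `times`, `n_copies`.
#' @export
build_propagator <- function(p, times, n_copies = 2) {
  stopifnot(inherits(p, "two_state_params"), n_copies %in% c(1, 2))
  nt <- length(times)
  kon <- rep_len(p$k_on, nt); koff <- rep_len(p$k_off, nt)
  if (any(kon < 0) || any(koff < 0)) stop("negative rates")
  ns <- n_copies + 1
  U <- array(0, c(ns, ns, nt - 1))
  const <- length(unique(kon)) == 1 && length(unique(koff)) == 1 &&
    length(unique(round(diff(times), 12))) == 1
  if (const) {
    M <- state_generator(kon[1], koff[1], n_copies)
    U1 <- as.matrix(Matrix::expm(M * diff(times)[1]))
    for (j in seq_len(nt - 1)) U[, , j] <- U1
  } else {
    for (j in seq_len(nt - 1)) {
      M <- (state_generator(kon[j + 1], koff[j + 1], n_copies) +
              state_generator(kon[j], koff[j], n_copies)) / 2
      U[, , j] <- as.matrix(Matrix::expm(M * (times[j + 1] - times[j])))
    }
  }
  structure(list(U = U, times = times, n_copies = n_copies), class = "propagator_set")
}

#' ON-probability predicted by the propagator
#'
#' Propagates an initial state distribution and sums the occupancy of the
#' active states (n > 0) at each grid point.
#'
#' @param ps A `propagator_set`.
#' @param p1 Initial distribution over states at the first grid point
#'   (must sum to 1).
#' @return Data frame with `t`, `P_ON`, and the state occupancies.
#' @export
expected_pon <- function(ps, p1) {
  ns <- dim(ps$U)[1]
  stopifnot(length(p1) == ns)
  if (abs(sum(p1) - 1) > 1e-8) stop("initial distribution must sum to 1")
  nt <- length(ps$times)
  occ <- matrix(0, nt, ns)
  occ[1, ] <- p1
  for (j in seq_len(nt - 1)) occ[j + 1, ] <- ps$U[, , j] %*% occ[j, ]
  data.frame(t = ps$times, P_ON = rowSums(occ[, -1, drop = FALSE]),
             occ = I(occ))
}

#' First-passage (residence-time) distributions on a finite grid
#'
#' For disjoint residence and absorbing state sets, W\[j, i\] is the
#' probability that a system which just settled in the residence set at grid
#' point i first reaches the absorbing set after duration t_j - t_i.
#' Computed by propagating, with the absorbing boundary, the settling
#' distribution (probability flux from absorbing into residence states,
#' occupancy-proportional at the first grid point); the truncated mass is
#' assigned to j = N_t so each column is a normalized distribution.
#' W\[i, i\] = 0 by construction.
#'
#' @param ps A `propagator_set`.
#' @param residence,absorbing Integer state labels (counts of active copies,
#'   e.g. `0` and `1:2`); together they must cover all states.
#' @param p1 Initial state distribution at the first grid point.
#' @return List with `W` (N_t x N_t, columns sum to 1), `Z` (settling
#'   weights), `times`.
#' @export
residence_distributions <- function(ps, residence, absorbing, p1) {
  ns <- dim(ps$U)[1]
  states <- 0:(ns - 1)
  if (length(intersect(residence, absorbing)) > 0 ||
      !setequal(union(residence, absorbing), states))
    stop("residence and absorbing sets must partition the state space")
  ir <- residence + 1; ia <- absorbing + 1
  nt <- length(ps$times)
  occ <- expected_pon(ps, p1)$occ
  W <- matrix(0, nt, nt)
  Z <- numeric(nt)
  # settling distributions as columns of Q (states x settling time i)
  Q <- matrix(0, ns, nt)
  Z[1] <- sum(p1[ir])
  if (Z[1] > 0) Q[ir, 1] <- p1[ir] / Z[1]
  for (i in 2:nt) {
    # flux from absorbing into residence states over (t_{i-1}, t_i]
    f <- (ps$U[, , i - 1])[ir, ia, drop = FALSE] %*% occ[i - 1, ia]
    Z[i] <- sum(f)
    if (Z[i] > 0) Q[ir, i] <- f / Z[i]
  }
  # propagate all settling columns forward with absorbing boundary
  active <- Q
  for (j in 2:nt) {
    idx <- seq_len(j - 1)                      # columns that settled before t_j
    prop <- ps$U[, , j - 1] %*% active[, idx, drop = FALSE]
    W[j, idx] <- colSums(prop[ia, , drop = FALSE])
    prop[ia, ] <- 0
    active[, idx] <- prop
  }
  # truncation mass to the last row so columns are normalized
  W[nt, ] <- W[nt, ] + pmax(1 - colSums(W), 0)
  list(W = W, Z = Z, times = ps$times)
}

#' Expected ON/OFF durations under the empirical estimator's weighting
#'
#' Converts first-passage distributions into the censoring-aware expected
#' period duration at each time point, mirroring the empirical T_ON/T_OFF
#' estimator: a period that settled at t_i and first leaves at t_j covers
#' the j - i time points in between, so at observation time t_m every
#' straddling period (i < m <= j) enters with its settling weight Z_i, its
#' first-passage probability W\[j, i\], and the multiplicity correction
#' 1/(j - i) that cancels the coverage bias of long periods. At
#' stationarity, interior values converge to the plain mean residence times
#' (the two-copy closed forms); near the grid ends truncation bends the
#' expectation downward exactly as censoring biases the empirical
#' estimator.
#'
#' @param rd Result of [residence_distributions()].
#' @return Numeric vector T(t_m) (NA where no period can straddle).
#' @export
expected_on_off_times <- function(rd) {
  W <- rd$W; Z <- rd$Z; times <- rd$times
  nt <- length(times)
  ji <- outer(seq_len(nt), seq_len(nt), `-`)        # j - i
  dur <- outer(times, times, `-`)                   # t_j - t_i
  A1 <- ifelse(ji > 0, W / ifelse(ji > 0, ji, 1), 0)
  A1 <- sweep(A1, 2, Z, `*`)                        # Z_i W[j,i] / (j-i)
  A2 <- A1 * dur
  # suffix sums over j >= m, per settling column i
  S1 <- apply(A1[nt:1, , drop = FALSE], 2, cumsum)[nt:1, , drop = FALSE]
  S2 <- apply(A2[nt:1, , drop = FALSE], 2, cumsum)[nt:1, , drop = FALSE]
  out <- rep(NA_real_, nt)
  for (m in 2:nt) {
    i <- seq_len(m - 1)
    den <- sum(S1[m, i])
    if (den > 0) out[m] <- sum(S2[m, i]) / den
  }
  out
}

#' Stationary mean ON/OFF residence times for two independent copies
#'
#' Phase-type means of the three-state chain of two identical independent
#' copies: T_OFF = 1/(2 k_on) and T_ON = (k_on + 2 k_off)/(2 k_off^2),
#' where ON means at least one copy active.
#'
#' @param k_on,k_off Single-copy switching rates (1/min, > 0).
#' @return List with `T_OFF`, `T_ON`.
#' @export
two_copy_stationary_times <- function(k_on, k_off) {
  if (any(k_on <= 0) || any(k_off <= 0)) stop("rates must be positive")
  list(T_OFF = 1 / (2 * k_on),
       T_ON = (k_on + 2 * k_off) / (2 * k_off^2))
}
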