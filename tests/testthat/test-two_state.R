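test_that("stationary moments: limits and Gillespie agreement", {
  p <- two_state_from_occupancy(8, 0.5, 1)
  m0 <- stationary_moments(p, 0)
  expect_equal(unlist(m0[c("mean", "mean_on", "mean_off", "second", "var")]),
               c(mean = 0, mean_on = 0, mean_off = 0, second = 0, var = 0))
  # fast-switching limit is Poisson: var -> mean
  pfast <- two_state_from_occupancy(8, 0.5, 1e-5)
  mf <- stationary_moments(pfast, 2)
  expect_equal(mf$var, mf$mean, tolerance = 1e-3)
  expect_error(stationary_moments(p, -1), "non-negative")
  # Gillespie oracle at (k = 8, eta = 0.5, T = 1), t = 2 min
  set.seed(71)
  nrep <- 4000
  ev <- simulate_gillespie(p, 2, n_copies = 1, n_alleles = nrep)
  cnt <- vapply(ev, function(a) length(a[[1]]), 0L)
  m <- stationary_moments(p, 2)
  se_mean <- sd(cnt) / sqrt(nrep)
  expect_lt(abs(mean(cnt) - m$mean), 3 * se_mean)
  se_var <- var(cnt) * sqrt(2 / (nrep - 1))        # approx SE of variance
  expect_lt(abs(var(cnt) - m$var), 3 * se_var)
})

test_that("model autocorrelation: exact endpoints and Gillespie agreement", {
  p <- two_state_from_occupancy(8, 0.3, 2)
  tt <- 1 / 6
  expect_equal(model_autocorrelation(p, tt, 0), 1)
  # beyond the window the decay is exactly exp(-(tau - tau_tilde)/T)
  taus <- c(0.5, 1, 2, 4)
  rho <- model_autocorrelation(p, tt, taus)
  expect_equal(rho / rho[1], exp(-(taus - taus[1]) / 2), tolerance = 1e-12)
  # continuity at tau = tau_tilde
  expect_equal(model_autocorrelation(p, tt, tt - 1e-10),
               model_autocorrelation(p, tt, tt), tolerance = 1e-6)
  # empirical autocorrelation of Gillespie-simulated windowed counts
  set.seed(72)
  nal <- 1500; dur <- 12; dtp <- 1 / 60
  nf <- round(dur / dtp)
  ev <- simulate_gillespie(p, dur, n_copies = 1, n_alleles = nal)
  counts <- t(vapply(ev, function(a)
    events_to_fine(a[[1]], nf, dtp), integer(nf)))
  # aggregate to 10-s windows
  agg <- t(apply(counts, 1, function(x) colSums(matrix(x, nrow = 10))))
  nc <- ncol(agg)
  for (lag in c(1, 3, 6)) {
    x <- as.numeric(agg[, 1:(nc - lag)]); y <- as.numeric(agg[, (1 + lag):nc])
    emp <- cor(x, y)
    se <- 1 / sqrt(length(x) / 2)       # conservative MC SE for a correlation
    expect_lt(abs(emp - model_autocorrelation(p, tt, lag * tt)), 3 * se)
  }
})

test_that("Sigma_AC closed form and its filter functions", {
  p <- two_state_from_occupancy(8, 0.3, 2)
  expect_equal(bursttrace:::phi2(1), (1 - exp(-1))^2, tolerance = 1e-12)
  expect_equal(bursttrace:::phi1(1e-9), 1, tolerance = 1e-6)
  expect_equal(bursttrace:::phi2(1e-9), 1, tolerance = 1e-6)
  # vanishes as dt -> 0
  expect_lt(sigma_ac(p, 1e-6), 1e-4)
  # matches the rate-autocorrelation at one sampling lag
  dt <- 1 / 6
  expect_equal(sigma_ac(p, dt), model_autocorrelation(p, dt, dt),
               tolerance = 1e-12)
  # scaling: Sigma_AC grows with k at fixed eta, falls with eta at fixed R
  s_k <- vapply(c(4, 8, 16), function(k)
    sigma_ac(two_state_from_occupancy(k, 0.3, 2), dt), 0)
  expect_true(all(diff(s_k) > 0))
  R0 <- 4
  s_eta <- vapply(c(0.2, 0.4, 0.8), function(eta)
    sigma_ac(two_state_from_occupancy(R0 / eta, eta, 2), dt), 0)
  expect_true(all(diff(s_eta) < 0))
})

test_that("propagators are column-stochastic and match the telegraph closed form", {
  p <- two_state_params(8, 0.4, 0.6)
  times <- seq(0, 10, by = 1 / 6)
  ps1 <- build_propagator(p, times, n_copies = 1)
  eta <- p$eta; Tc <- p$T
  # closed form: P(n | n'; t) = (n eta + (1-n)(1-eta))(1 - e^{-t/T}) +
  # delta_{nn'} e^{-t/T}, checked on single and composed steps
  for (nstep in c(1, 7, 30)) {
    U <- diag(2)
    for (j in seq_len(nstep)) U <- ps1$U[, , j] %*% U
    t <- nstep / 6
    ex <- exp(-t / Tc)
    Uex <- matrix(c((1 - eta) * (1 - ex) + ex, eta * (1 - ex),
                    (1 - eta) * (1 - ex), eta * (1 - ex) + ex), 2, 2)
    expect_lt(max(abs(U - Uex)), 1e-8)
    expect_lt(max(abs(colSums(U) - 1)), 1e-10)
  }
  # two copies: stationary distribution is Binomial(2, eta)
  ps2 <- build_propagator(p, seq(0, 200, by = 1), n_copies = 2)
  U <- diag(3)
  for (j in 1:200) U <- ps2$U[, , j] %*% U
  statd <- U %*% c(1, 0, 0)
  expect_equal(as.numeric(statd), dbinom(0:2, 2, eta), tolerance = 1e-10)
  expect_error(build_propagator(two_state_params(8, 0.4, 0.6),
                                times, n_copies = 3))
})

test_that("occupancy propagation reproduces relaxation closed forms", {
  p <- two_state_params(8, 0.4, 0.6)
  times <- seq(0, 8, by = 1 / 6)
  ps1 <- build_propagator(p, times, n_copies = 1)
  # stationary start stays flat at eta
  po <- expected_pon(ps1, c(1 - p$eta, p$eta))
  expect_equal(po$P_ON, rep(p$eta, length(times)), tolerance = 1e-12)
  # all-OFF start relaxes as eta (1 - exp(-t/T))
  po0 <- expected_pon(ps1, c(1, 0))
  expect_equal(po0$P_ON, p$eta * (1 - exp(-times / p$T)), tolerance = 1e-8)
  # two copies from all-OFF: 1 - (1 - P_ON1(t))^2 by independence
  ps2 <- build_propagator(p, times, n_copies = 2)
  po2 <- expected_pon(ps2, c(1, 0, 0))
  expect_equal(po2$P_ON, 1 - (1 - po0$P_ON)^2, tolerance = 1e-8)
  expect_error(expected_pon(ps1, c(0.7, 0.7)), "sum to 1")
})

test_that("residence distributions are proper first-passage laws", {
  p <- two_state_params(8, 0.5, 0.5)
  times <- seq(0, 60, by = 1 / 6)
  ps1 <- build_propagator(p, times, n_copies = 1)
  rd <- residence_distributions(ps1, residence = 1, absorbing = 0,
                                p1 = c(1 - p$eta, p$eta))
  expect_true(all(abs(diag(rd$W)[-length(times)]) == 0))   # W_ii = 0
  expect_equal(colSums(rd$W), rep(1, length(times)), tolerance = 1e-10)
  # ON residence of one copy is exponential with mean 1/k_off; on a fine
  # grid the discretely-sampled mean approaches it
  fine <- seq(0, 120, by = 1 / 60)
  psf <- build_propagator(p, fine, n_copies = 1)
  rdf <- residence_distributions(psf, residence = 1, absorbing = 0,
                                 p1 = c(1 - p$eta, p$eta))
  # plain first-passage mean from a mid-grid settling column
  i0 <- 3000
  m <- sum((fine[i0:length(fine)] - fine[i0]) * rdf$W[i0:length(fine), i0])
  expect_lt(abs(m - 1 / p$k_off[1]) / (1 / p$k_off[1]), 0.02)
  expect_error(residence_distributions(ps1, residence = 0:1, absorbing = 1,
                                       p1 = c(0.5, 0.5)), "partition")
})

test_that("expected ON/OFF durations converge to the two-copy closed forms", {
  kon <- 0.18; koff <- 0.32
  p <- two_state_params(8, kon, koff)
  eta <- p$eta
  p1 <- dbinom(0:2, 2, eta)
  cl <- two_copy_stationary_times(kon, koff)
  # fine grid: discretization bias vanishes, interior matches Eq closed forms
  fine <- seq(0, 200, by = 1 / 30)
  psf <- build_propagator(p, fine, n_copies = 2)
  T_ON <- expected_on_off_times(
    residence_distributions(psf, residence = 1:2, absorbing = 0, p1 = p1))
  T_OFF <- expected_on_off_times(
    residence_distributions(psf, residence = 0, absorbing = 1:2, p1 = p1))
  mid <- seq(round(length(fine) * 0.4), round(length(fine) * 0.6))
  expect_lt(abs(mean(T_ON[mid]) - cl$T_ON) / cl$T_ON, 0.02)
  expect_lt(abs(mean(T_OFF[mid]) - cl$T_OFF) / cl$T_OFF, 0.02)
  # censoring bends the expectation downward near both grid ends
  expect_lt(T_ON[20], mean(T_ON[mid]))
  expect_lt(T_ON[length(fine) - 5], mean(T_ON[mid]))
})

test_that("two-copy stationary times: closed form vs phase-type solve", {
  tt <- two_copy_stationary_times(1, 1)
  expect_equal(tt$T_OFF, 0.5)
  expect_equal(tt$T_ON, 1.5)
  for (kon in c(0.2, 1, 3)) for (koff in c(0.4, 1.3)) {
    tt <- two_copy_stationary_times(kon, koff)
    expect_equal(tt$T_ON, phase_type_on_time(kon, koff), tolerance = 1e-9)
    expect_equal(tt$T_OFF, 1 / (2 * kon), tolerance = 1e-12)
    # consistency with the effective/single-copy correlation-time algebra
    eta <- kon / (kon + koff); tc1 <- 1 / (kon + koff)
    eff_tc <- tt$T_ON * tt$T_OFF / (tt$T_ON + tt$T_OFF)
    expect_equal(eff_tc, 0.5 * tc1 * (2 - eta), tolerance = 1e-12)
  }
  # k_off -> infinity: vanishing ON periods
  expect_lt(two_copy_stationary_times(1, 1e6)$T_ON, 1e-5)
  expect_error(two_copy_stationary_times(0, 1), "positive")
})
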