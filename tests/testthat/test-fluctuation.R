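test_that("conditional pooling mixes member bins by allele count", {
  supp <- data.frame(r = 0:10)
  d1 <- data.frame(r = 0:10, p = dbinom(0:10, 10, 0.3))
  d2 <- data.frame(r = 0:10, p = dbinom(0:10, 10, 0.32))
  # single qualifying bin: returned unchanged
  out <- pool_conditional(list(d1, d2), R_bins = c(3, 10), n_alleles = c(50, 50),
                          R0 = 3, eps = 0.53)
  expect_equal(out$p, d1$p)
  # two identical bins with different counts: mixture equals either
  out2 <- pool_conditional(list(d1, d1), c(3, 3.2), c(30, 200), R0 = 3)
  expect_equal(out2$p, d1$p, tolerance = 1e-12)
  expect_equal(sum(out2$p), 1, tolerance = 1e-12)
  # allele-count weighting
  out3 <- pool_conditional(list(d1, d2), c(3, 3.2), c(100, 300), R0 = 3)
  expect_equal(out3$p, 0.25 * d1$p + 0.75 * d2$p, tolerance = 1e-12)
  expect_error(pool_conditional(list(d1), 12, 10, R0 = 3), "no bins")
  # the default binning arithmetic: 15 equal bins on [0, 16] -> eps = 0.53
  expect_equal(16 / 15 / 2, 0.533, tolerance = 1e-2)
})

test_that("constitutive binomial reference and its closed-form cumulants", {
  # R = 0: point mass at zero with vanishing cumulants
  cb0 <- constitutive_binomial(0, 1)
  expect_equal(cb0$dist$p[1], 1)
  expect_equal(unlist(cb0$cumulants), c(mean = 0, sigma2 = 0, kappa3 = 0,
                                        kappa4 = 0))
  # saturation p = 1: deterministic initiation, zero variance
  cbs <- constitutive_binomial(60, 1, dt_fine = 1 / 60)
  expect_equal(cbs$cumulants$sigma2, 0)
  expect_error(constitutive_binomial(120, 1, dt_fine = 1 / 60), "maximal")
  # dt' -> 0 recovers Poisson
  cbp <- constitutive_binomial(6, 1, dt_fine = 1 / 6000)
  pois <- dpois(round(cbp$dist$r * 1), 6)
  expect_lt(max(abs(cumsum(cbp$dist$p) - cumsum(pois / sum(pois)))), 1e-3)
  # closed-form cumulants match brute force from the pmf
  cb <- constitutive_binomial(8, 1, dt_fine = 1 / 60)
  bf <- rate_cumulants(cb$dist)
  expect_equal(cb$cumulants$sigma2, bf$sigma2, tolerance = 1e-10)
  expect_equal(cb$cumulants$kappa3, bf$kappa3, tolerance = 1e-10)
  expect_equal(cb$cumulants$kappa4, bf$kappa4, tolerance = 1e-10)
})

test_that("rate cumulants from raw moments", {
  pt <- data.frame(r = 4, p = 1)
  cc <- rate_cumulants(pt)
  expect_equal(unlist(cc), c(mean = 4, sigma2 = 0, kappa3 = 0, kappa4 = 0))
  # Poisson counts scaled by 1/tau: kappa_k = lambda / tau^k
  lam <- 5; tau <- 2
  g <- 0:60
  d <- data.frame(r = g / tau, p = dpois(g, lam))
  d$p <- d$p / sum(d$p)
  cp <- rate_cumulants(d)
  expect_equal(cp$sigma2, lam / tau^2, tolerance = 1e-6)
  expect_equal(cp$kappa3, lam / tau^3, tolerance = 1e-6)
  expect_equal(cp$kappa4, lam / tau^4, tolerance = 1e-5)
  expect_error(rate_cumulants(data.frame(r = 0:1, p = c(0.5, 0.4))),
               "normalized")
})

test_that("pooled two-state rates deviate from the constitutive reference", {
  # windowed (1-min) rates from bursty initiation are over-dispersed
  # relative to the footprint-corrected binomial at the same mean
  set.seed(88)
  p <- two_state_from_occupancy(8, 0.4, 2)
  dtp <- 1 / 60; nf <- 60 * 30
  ev <- simulate_gillespie(p, 30, n_copies = 1, n_alleles = 300)
  counts <- t(vapply(ev, function(a) events_to_fine(a[[1]], nf, dtp),
                     integer(nf)))
  g1 <- t(apply(counts, 1, function(x) colSums(matrix(x, nrow = 60))))
  R <- mean(g1)
  cb <- constitutive_binomial(R, 1)
  expect_gt(var(as.numeric(g1)), 3 * cb$cumulants$sigma2)
})

test_that("empirical autocorrelation of white noise is flat at zero", {
  set.seed(99)
  rl <- lapply(1:25, function(a) matrix(rpois(40 * 120, 3), nrow = 40))
  ac <- empirical_autocorrelation(rl, dt = 1 / 6, max_lag_min = 5)
  expect_equal(ac$rho[1], 1, tolerance = 1e-12)
  expect_lt(max(abs(ac$rho[-1])), 0.05)
  expect_error(empirical_autocorrelation(rl[1], 1 / 6), "2 alleles")
})

test_that("autocorrelation fit recovers exact synthetic parameters", {
  dt <- 1 / 6
  tau <- seq(0, 10 - dt, by = dt)
  Sig <- 0.4; tAC <- 1.5; beta <- 0.04
  rho <- c(1, Sig * ((1 - beta) * exp(-(tau[-1] - dt) / tAC) + beta))
  f <- fit_ac(data.frame(tau = tau, rho = rho), dt)
  expect_equal(f$Sigma_AC, 0.4)
  expect_equal(f$tau_AC, 1.5, tolerance = 1e-3)
  expect_equal(f$beta, 0.04, tolerance = 1e-2)
  expect_false(f$flagged)
  # non-decaying input is flagged
  f2 <- fit_ac(data.frame(tau = tau, rho = c(1, rep(0.5, length(tau) - 1)) +
                            c(0, seq(0, 0.3, length.out = length(tau) - 1))),
               dt)
  expect_true(f2$flagged)
})

test_that("fitted tau_AC tracks the input switching time on simulated data", {
  # deconvolution-free check: windowed Gillespie rates, eta x T grid corners
  set.seed(100)
  dt <- 1 / 6
  for (pars in list(c(0.12, 1), c(0.52, 3))) {
    p <- two_state_from_occupancy(8, pars[1], pars[2])
    nf <- 60 * 40
    ev <- simulate_gillespie(p, 40, n_copies = 2, n_alleles = 60)
    rl <- lapply(ev, function(a) {
      cnt <- Reduce(`+`, lapply(a, events_to_fine, n_fine = nf,
                                dt_fine_min = 1 / 60))
      matrix(colSums(matrix(cnt, nrow = 10)) / dt, nrow = 1)
    })
    ac <- empirical_autocorrelation(rl, dt)
    f <- fit_ac(ac, dt)
    expect_lt(abs(f$tau_AC - pars[2]) / pars[2], 0.45)
    # amplitude agrees with the analytic Sigma_AC
    expect_lt(abs(f$Sigma_AC - sigma_ac(p, dt)) / sigma_ac(p, dt), 0.35)
  }
})

test_that("group variance decomposition obeys the law of total variance", {
  set.seed(111)
  g1 <- rnorm(40, 5); g2 <- rnorm(60, 5); g3 <- rnorm(55, 5)
  gv <- group_variance_decomposition(list(g1, g2, g3))
  # identity: weighted between + weighted within = decomposition total
  expect_equal(gv$sigma2_between + gv$sigma2_within, gv$sigma2_total)
  expect_lte(gv$ratio, 1)
  # identical groups: zero between-group variance
  gv0 <- group_variance_decomposition(list(g1, g1, g1))
  expect_equal(gv0$sigma2_between, 0, tolerance = 1e-12)
  expect_error(group_variance_decomposition(list(g1)), "2 groups")
  # shifting replicate means by delta grows sigma2_between as delta^2
  deltas <- c(0.5, 1, 2, 4)
  b <- vapply(deltas, function(d)
    group_variance_decomposition(list(g1, g2 + d))$sigma2_between, 0)
  fitq <- stats::lm(b ~ I(deltas^2))
  expect_gt(summary(fitq)$r.squared, 0.99)
})
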