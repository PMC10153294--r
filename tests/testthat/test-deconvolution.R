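test_that("event convolution is causal, linear, and downsampled by superposition", {
  gm <- toy_gene()
  kern <- build_kernel(gm, 10)
  nI <- 39
  expect_equal(convolve_events(rep(0, nI), kern), rep(0, nI))
  # single event: the kernel shifted to the event position
  I1 <- rep(0, nI); I1[5] <- 1
  G1 <- convolve_events(I1, kern)
  expect_equal(G1[5:(4 + kern$n_steps)], kern$weights)
  expect_true(all(G1[1:4] == 0))
  expect_true(all(G1[(5 + kern$n_steps):nI] == 0))
  # two events superpose
  I2 <- rep(0, nI); I2[12] <- 1
  expect_equal(convolve_events(I1 + I2, kern),
               G1 + convolve_events(I2, kern))
  # downsampling takes the value at the coarse points; first point empty
  G <- convolve_events(I1 + I2, kern, ratio = 4, n_coarse = 10)
  full <- convolve_events(I1 + I2, kern)
  expect_equal(G[1], 0)
  expect_equal(G[2:10], full[(1:9) * 4])
})

test_that("trace log-likelihood matches the Gaussian form exactly", {
  gm <- toy_gene()
  kern <- build_kernel(gm, 10)
  nm <- noise_model(1.1, 0)
  nt <- 12
  tr <- activity_trace(seq(0, by = 1 / 6, length.out = nt), rep(0, nt))
  ll <- trace_loglik(tr, rep(0, nt * 1 - 1), kern, nm, dt_fine = 10)
  expect_equal(ll, nt * dnorm(0, 0, 1.1, log = TRUE))
  # a spurious event strictly lowers the likelihood of a noiseless trace
  I_sp <- rep(0, nt - 1); I_sp[4] <- 1
  expect_lt(trace_loglik(tr, I_sp, kern, nm, dt_fine = 10), ll)
})

test_that("prior construction follows the mean-activity rate approximation", {
  gm <- toy_gene()                       # tau_elo = 1500/1800 min
  tau <- elongation_time(gm)
  times <- seq(0, by = 1 / 6, length.out = 30)
  # constant mean activity mu = tau_elo * R0 gives p_i = R0 dt'
  R0 <- 6                                 # mRNA/min
  p <- build_prior(rep(tau * R0, 30), times, gm, dt_fine = 1)
  expect_equal(unique(round(p, 12)), R0 / 60)
  # p = 0.5 corresponds to R_max/2 = 30/min at dt' = 1 s
  p2 <- build_prior(rep(tau * 30, 30), times, gm, dt_fine = 1)
  expect_equal(unique(round(p2, 12)), 0.5)
  # empty bin floors at the clip value
  p0 <- build_prior(rep(0, 30), times, gm, dt_fine = 1)
  expect_equal(unique(p0), 1e-4)
})

test_that("MCMC posterior matches exhaustive enumeration on a short trace", {
  set.seed(42)
  gm <- gene_model(900, c(300, 600), 1.8)
  kern <- build_kernel(gm, 10)
  nm <- noise_model(0.5, 0)
  nt <- 10; ratio <- 1                    # 9 fine steps, 512 configurations
  true_I <- c(0, 1, 0, 0, 1, 0, 0, 0, 1)
  G <- convolve_events(true_I, kern, ratio = ratio, n_coarse = nt)
  A <- G + rnorm(nt, 0, 0.3)
  prior <- rep(0.3, nt * ratio - 1)
  ex <- exact_posterior(A, kern, nm, prior, ratio)
  expect_equal(sum(ex$weights), 1)
  # the enumerated MAP is the likelihood-and-prior argmax by construction;
  # the posterior marginals from MCMC agree within Monte-Carlo error
  tr <- activity_trace(seq(0, by = 1 / 6, length.out = nt), A)
  ps <- sample_posterior(tr, kern, nm, prior, n_samples = 10000,
                         n_burn = 1000, thin = 5, seed = 7)
  expect_lt(max(abs(ex$marginal - ps$marginal)), 0.05)
  # frozen-adaptation chain converges to the same distribution: the stored
  # configurations' empirical frequencies match the analytic posterior
  key_ex <- apply(ex$configs, 1, paste, collapse = "")
  key_mc <- apply(ps$configs, 1, paste, collapse = "")
  freq <- table(factor(key_mc, levels = key_ex)) / length(key_mc)
  tv <- 0.5 * sum(abs(as.numeric(freq) - ex$weights))
  expect_lt(tv, 0.12)                     # TV on 512 states, 1800 samples
})

test_that("deconvolution recovers sparse events and reports mid-band acceptance", {
  set.seed(5)
  gm <- gene_model_hb_synthetic(2)
  kern <- build_kernel(gm, 1)
  nm_lo <- noise_model(0.1, 0.005)        # low noise: events identifiable
  nt <- 60; ratio <- 10; nI <- nt * ratio - 1
  I <- rep(0, nI)
  I[c(80, 250, 412)] <- 1
  G <- convolve_events(I, kern, ratio = ratio, n_coarse = nt)
  tr <- activity_trace(seq(0, by = 1 / 6, length.out = nt), G)
  ps <- sample_posterior(tr, kern, nm_lo, prior = 0.005,
                         n_samples = 1500, n_burn = 300, seed = 2)
  # high marginal mass near true events, low elsewhere; a few fine steps of
  # slack, since neighbouring steps shift the downsampled signal by at most
  # one or two loop increments (well below the noise floor)
  near <- unlist(lapply(c(80, 250, 412), function(j) j + (-4:4)))
  expect_gt(min(vapply(c(80, 250, 412), function(j)
    sum(ps$marginal[j + (-4:4)]), 0)), 0.9)
  expect_lt(max(ps$marginal[setdiff(seq_len(nI), near)]), 0.15)
  expect_gt(ps$acceptance_rate, 0.10)
  expect_lt(ps$acceptance_rate, 0.70)
})

test_that("posterior predictive reproduces the observed trace within the noise envelope", {
  bin <- small_sim_bin(eta = 0.5, t_c = 2, n_alleles = 1, duration = 20,
                       seed = 31)
  tr <- bin$sim$traces[[1]]
  gm <- bin$spec$gm; nm <- bin$spec$nm
  kern <- build_kernel(gm, 1)
  mu <- pmax(tr$values, 0)
  prior <- build_prior(mu, tr$times, gm, 1)
  ps <- sample_posterior(tr, kern, nm, prior, n_samples = 1200, n_burn = 300,
                         thin = 5, seed = 3)
  # mean reconstructed signal vs observation, standardized by sigma(G)
  Gbar <- colMeans(t(apply(ps$configs, 1, function(I)
    convolve_events(I, kern, ratio = ps$ratio, n_coarse = length(tr$values)))))
  z <- (tr$values - Gbar) / noise_sd(pmax(Gbar, 0), nm)
  expect_gt(mean(abs(z) < 2), 0.95 - 0.03)
  expect_lt(abs(mean(z)), 0.2)
  expect_lt(abs(sd(z) - 1), 0.3)
})

test_that("windowed rates count events in (t - v dt, t]", {
  gm <- gene_model_hb_synthetic(2)
  kern <- build_kernel(gm, 1)
  nt <- 12; ratio <- 10; nI <- nt * ratio - 1
  ps <- structure(list(configs = matrix(0L, 2, nI), ratio = ratio,
                       times = seq(0, by = 1 / 6, length.out = nt)),
                  class = "posterior_samples")
  # empty configuration: zero rate everywhere
  r0 <- rate_from_samples(ps, v = 1)
  expect_true(all(r0$r_samples == 0))
  # 3 events inside one 10-s interval: r = 18 mRNA/min at that point
  ps$configs[1, 32:34] <- 1L              # fine steps 32..34 lie in (t4, t5]
  r1 <- rate_from_samples(ps, v = 1)
  expect_equal(r1$r_samples[1, 5], 18)
  expect_equal(sum(r1$r_samples[1, ]), 18)
  # v = 6: granularity becomes 1 mRNA/min
  r6 <- rate_from_samples(ps, v = 6)
  vals <- unique(as.numeric(r6$r_samples))
  expect_true(all(abs(vals - round(vals)) < 1e-12))
  expect_equal(max(r6$r_samples), 3)
})

test_that("joint dual-colour sampling infers the elongation rate", {
  set.seed(11)
  gm_g <- gene_model(4500, 600 + 54 * (1:24), 1.8, name = "5p")
  gm_r <- gene_model(4500, 2900 + 54 * (1:24), 1.8, name = "3p")
  nm <- noise_model()
  p <- two_state_from_occupancy(8, 0.4, 2)
  nt <- 180; ratio <- 10; nI <- nt * ratio - 1; dtp <- 1 / 60
  est <- numeric(5)
  for (i in 1:5) {
    ev <- simulate_gillespie(p, nI * dtp, n_copies = 2, n_alleles = 1)[[1]]
    I <- Reduce(`+`, lapply(ev, events_to_fine, n_fine = nI, dt_fine_min = dtp))
    Gg <- convolve_events(I, build_kernel(gm_g, 1), ratio = ratio, n_coarse = nt)
    Gr <- convolve_events(I, build_kernel(gm_r, 1), ratio = ratio, n_coarse = nt)
    tg <- activity_trace(seq(0, by = 1 / 6, length.out = nt),
                         Gg + rnorm(nt, 0, noise_sd(Gg, nm)))
    tr <- activity_trace(seq(0, by = 1 / 6, length.out = nt),
                         Gr + rnorm(nt, 0, noise_sd(Gr, nm)))
    est[i] <- infer_elongation_joint(tg, tr, gm_g, gm_r, nm, nm,
                                     n_outer = 300, n_burn = 100)$k_elo_mean
  }
  expect_lt(abs(mean(est) - 1.8) / 1.8, 0.15)
  # identical cassettes carry no delay information: flagged unidentifiable
  tg2 <- activity_trace(seq(0, by = 1 / 6, length.out = nt), rnorm(nt))
  fit0 <- infer_elongation_joint(tg2, tg2, gm_g, gm_g, nm, nm, n_outer = 10,
                                 n_burn = 2)
  expect_false(fit0$identifiable)
  # the noiseless-limit delay between channels equals the cassette
  # separation over K_elo: signal onsets of a single event differ by
  # (l_r - l_g)/K_elo since the cassettes share the same internal layout
  I1 <- rep(0, nI); I1[100] <- 1
  on_g <- which(convolve_events(I1, build_kernel(gm_g, 1)) > 0)[1]
  on_r <- which(convolve_events(I1, build_kernel(gm_r, 1)) > 0)[1]
  delay_pred_s <- (mean(gm_r$loop_ends_bp) - mean(gm_g$loop_ends_bp)) / 30
  expect_lt(abs((on_r - on_g) - delay_pred_s), 1.5)
})
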