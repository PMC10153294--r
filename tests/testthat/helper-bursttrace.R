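# Shared fixtures, all built in code.

toy_gene <- function() gene_model(3000, c(1000, 2000), 1.8, name = "toy")

# exact posterior by exhaustive enumeration over all binary configurations
# of a short trace (ratio * Nt - 1 fine steps)
exact_posterior <- function(A, kern, nm, prior, ratio) {
  nI <- length(A) * ratio - 1
  configs <- as.matrix(expand.grid(rep(list(0:1), nI)))
  ll <- apply(configs, 1, function(I)
    bursttrace:::trace_loglik_cpp(A, as.numeric(I), kern$weights,
                                  as.integer(ratio), nm$sigma_b, nm$beta1))
  lp <- as.numeric(configs %*% log(prior) + (1 - configs) %*% log(1 - prior))
  w <- exp(ll + lp - max(ll + lp))
  w <- w / sum(w)
  list(configs = configs, weights = w, marginal = colSums(configs * w),
       map = configs[which.max(ll + lp), ])
}

# numeric phase-type mean absorption times for the two-copy chain:
# mean time to reach the absorbing set from the entry state, solved linearly
phase_type_on_time <- function(k_on, k_off) {
  # ON set {1, 2}, entry always at state 1 (from 0); generator restricted
  # tau = solve(-Q_rr) %*% 1 with Q_rr over states (1, 2)
  Qrr <- matrix(c(-(k_off + k_on), k_on, 2 * k_off, -2 * k_off), 2, 2)
  tau <- solve(-t(Qrr), c(1, 1))
  tau[1]
}

# small stationary two-chromatid synthetic bin used by several tests
small_sim_bin <- function(eta = 0.36, t_c = 2, n_alleles = 6, duration = 20,
                          seed = 99) {
  p <- two_state_from_occupancy(8, eta, t_c)
  spec <- simulation_spec(p, n_alleles = n_alleles, duration = duration,
                          seed = seed)
  list(sim = simulate_traces(spec), p = p, spec = spec)
}

make_profiles <- function(nu_true = 0.25, noise = 0, seed = 1, ngene = 3) {
  set.seed(seed)
  x <- seq(0.2, 0.8, by = 0.025)
  live <- list(); reference <- list(); meta <- list()
  for (g in seq_len(ngene)) {
    A <- 15 * exp(-((x - 0.3 - 0.1 * g) / 0.12)^2) + 0.5
    meta[[g]] <- list(n_live = 1, n_fixed = 2,
                      leff_live = 3000 + 200 * g, leff_fixed = 2500)
    sc <- (meta[[g]]$n_live * meta[[g]]$leff_live) /
      (meta[[g]]$n_fixed * meta[[g]]$leff_fixed)
    reference[[g]] <- data.frame(x = x, A = A / sc, se = pmax(0.05 * A / sc, 0.02))
    S <- A / nu_true * (1 + rnorm(length(x), 0, noise))
    live[[g]] <- data.frame(x = x, S = S, se = pmax(0.05 * S, 0.02))
  }
  list(live = live, reference = reference, meta = meta)
}


# CTMC birth-death + telegraph simulation to steady state: the independent
# oracle for the Beta-Poisson pmf
simulate_bd_cells <- function(n_cells, K, P_ON, T_C, T_M, horizon = 12) {
  kon <- P_ON / T_C; koff <- (1 - P_ON) / T_C; del <- 1 / T_M
  vapply(seq_len(n_cells), function(i) {
    t <- 0; n <- rbinom(1, 1, P_ON); m <- 0
    Tend <- horizon * T_M
    repeat {
      rates <- c(if (n == 0) kon else koff, if (n == 1) K else 0, m * del)
      t <- t + rexp(1, sum(rates))
      if (t >= Tend) break
      w <- sample.int(3, 1, prob = rates)
      if (w == 1) n <- 1 - n else if (w == 2) m <- m + 1 else m <- m - 1
    }
    as.integer(m)
  }, 0L)
}

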