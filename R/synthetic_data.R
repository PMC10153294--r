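#' Specification of a synthetic bursting-trace data set
#'
#' The stated world of the synthetic study: two-state initiation at
#' single-copy rate k on two identical, independent sister chromatids,
#' convolved with the gene's elongation kernel (built at K_elo = 2 kb/min by
#' default, as in the validation study) and corrupted by the calibrated
#' heteroscedastic imaging noise. Defaults mirror the full-scale validation:
#' 200 alleles, 50-min traces at 10-s sampling, 1-s fine grid.
#'
#' @param params A `two_state_params` (single-copy rates; possibly
#'   time-dependent, tabulated on the fine grid for the propagator sampler).
#' @param n_alleles Number of alleles (default 200).
#' @param duration Trace duration in minutes (default 50).
#' @param dt_s Sampling interval in seconds (default 10).
#' @param dt_fine_s Fine grid interval in seconds (default 1).
#' @param n_copies Gene copies per allele (default 2).
#' @param gm Gene model for the simulation kernel (default synthetic hb at
#'   2 kb/min).
#' @param nm Noise model (default sigma_b = 1.22, beta1 = 0.16).
#' @param seed Integer seed (recorded; all randomness flows from it).
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(params, n_alleles = 200, duration = 50,
                            dt_s = 10, dt_fine_s = 1, n_copies = 2,
                            gm = gene_model_hb_synthetic(elongation_rate = 2),
                            nm = noise_model(), seed = 1L) {
  stopifnot(inherits(params, "two_state_params"),
            duration * 60 %% dt_s == 0, dt_s %% dt_fine_s == 0)
  structure(list(params = params, n_alleles = n_alleles, duration = duration,
                 dt_s = dt_s, dt_fine_s = dt_fine_s, n_copies = n_copies,
                 gm = gm, nm = nm, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Exact stochastic simulation of the telegraph model
#'
#' Gillespie simulation of promoter switching and initiation for stationary
#' rates: the promoter starts from its stationary occupancy and, while ON,
#' initiates at rate k in competition with switching OFF.
#'
#' @param p Stationary `two_state_params`.
#' @param duration Simulated time (min).
#' @param n_copies Independent copies per allele.
#' @param n_alleles Number of alleles.
#' @return List (one per allele) of lists (one per copy) of initiation event
#'   times in (0, duration\].
#' @export
simulate_gillespie <- function(p, duration, n_copies = 2, n_alleles = 1) {
  stopifnot(inherits(p, "two_state_params"))
  k <- p$k[1]; kon <- p$k_on[1]; koff <- p$k_off[1]
  eta <- if (kon + koff > 0) kon / (kon + koff) else 0
  one_copy <- function() {
    state <- rbinom(1, 1, eta)
    t <- 0
    ev <- numeric(0)
    while (t < duration) {
      if (state == 0) {
        if (kon == 0) break
        t <- t + rexp(1, kon)
        state <- 1
      } else {
        tot <- koff + k
        if (tot == 0) break
        t <- t + rexp(1, tot)
        if (t >= duration) break
        if (runif(1) < k / tot) ev <- c(ev, t) else state <- 0
      }
    }
    ev[ev <= duration]
  }
  lapply(seq_len(n_alleles), function(a)
    lapply(seq_len(n_copies), function(cc) one_copy()))
}

#' Bin event times onto the fine grid
#' @param ev Event times in minutes.
#' @param n_fine Number of fine steps.
#' @param dt_fine_min Fine step in minutes.
#' @return Integer counts per fine step (step j covers ((j-1)dt', j dt'\]).
#' @export
events_to_fine <- function(ev, n_fine, dt_fine_min) {
  idx <- ceiling(ev / dt_fine_min)
  idx[idx < 1] <- 1
  tabulate(idx[idx <= n_fine], nbins = n_fine)
}

#' Expanded state-and-count propagator for exact fine-grid sampling
#'
#' Joint per-step propagator over (promoter state of two copies, number of
#' initiation events in the step): the generator is
#' M' = M2 (x) I + R2 (x) K_g, where M2 is the three-state two-copy switching
#' generator, K_g shifts the event count up at rate k, and R2 = diag(0, 1, 2)
#' scales initiation by the number of active copies. The event count is
#' truncated at N_g - 1 (initiation halts there, keeping the matrix
#' stochastic); N_g = 6 is safe for k <= 8/min at a 1-s step.
#'
#' @param p A `two_state_params`; time-dependent rates must be tabulated on
#'   `times`.
#' @param dt_fine_min Fine step (min).
#' @param n_g Event-count cutoff N_g (>= 3).
#' @param times Fine time grid (min); NULL for stationary rates (a single
#'   matrix is returned).
#' @return A 3 N_g square stochastic matrix (stationary) or an array with one
#'   slice per step.
#' @export
build_expanded_propagator <- function(p, dt_fine_min, n_g = 6, times = NULL) {
  stopifnot(inherits(p, "two_state_params"), n_g >= 3)
  kmax <- max(p$k)
  if (stats::ppois(n_g - 2, 2 * kmax * dt_fine_min, lower.tail = FALSE) > 1e-4)
    warning("n_g may be too small for k * dt_fine; event counts will saturate")
  mk <- function(k, kon, koff) {
    Kg <- diag(-k, n_g)
    Kg[n_g, n_g] <- 0
    Kg[cbind(2:n_g, 1:(n_g - 1))] <- k
    M2 <- state_generator(kon, koff, 2)
    kronecker(M2, diag(n_g)) + kronecker(diag(c(0, 1, 2)), Kg)
  }
  if (is.null(times)) {
    as.matrix(Matrix::expm(mk(p$k[1], p$k_on[1], p$k_off[1]) * dt_fine_min))
  } else {
    nt <- length(times)
    k <- rep_len(p$k, nt); kon <- rep_len(p$k_on, nt); koff <- rep_len(p$k_off, nt)
    U <- array(0, c(3 * n_g, 3 * n_g, nt - 1))
    for (j in seq_len(nt - 1)) {
      M <- (mk(k[j + 1], kon[j + 1], koff[j + 1]) + mk(k[j], kon[j], koff[j])) / 2
      U[, , j] <- as.matrix(Matrix::expm(M * (times[j + 1] - times[j])))
    }
    U
  }
}

#' Sample fine-grid initiation series through the expanded propagator
#'
#' Iterates the joint (state, event-count) propagator: at each fine step the
#' allele state n and the number of initiation events g are drawn from the
#' propagator column of the current state (event count reset to 0 at each
#' step). Works for time-dependent switching rates, where Gillespie sampling
#' would need time-rescaling. Output is the combined initiation series of
#' both sister chromatids.
#'
#' @param spec A `simulation_spec` (n_copies must be 2).
#' @param n_g Event-count cutoff.
#' @return List with `events` (matrix alleles x fine steps, counts) and
#'   `states` (matrix alleles x (fine steps + 1), active-copy counts).
#' @export
sample_time_dependent <- function(spec, n_g = 6) {
  stopifnot(inherits(spec, "simulation_spec"), spec$n_copies == 2)
  set.seed(spec$seed)
  nt <- spec$duration * 60 / spec$dt_s
  ratio <- spec$dt_s / spec$dt_fine_s
  nI <- nt * ratio - 1
  dtp <- spec$dt_fine_s / 60
  p <- spec$params
  stationary <- length(unique(p$k_on)) == 1 && length(unique(p$k_off)) == 1 &&
    length(unique(p$k)) == 1
  t_fine <- seq_len(nI + 1) * dtp - dtp
  if (stationary) {
    U1 <- build_expanded_propagator(p, dtp, n_g)
    Ucols <- lapply(0:2, function(n) cumsum(U1[, n * n_g + 1]))
  } else {
    pf <- two_state_params(approx(p$times, p$k, t_fine, rule = 2)$y,
                           approx(p$times, p$k_on, t_fine, rule = 2)$y,
                           approx(p$times, p$k_off, t_fine, rule = 2)$y,
                           times = t_fine)
    Uarr <- build_expanded_propagator(pf, dtp, n_g, times = t_fine)
  }
  eta1 <- p$eta[1]
  nst <- rbinom(spec$n_alleles, 2, eta1)        # stationary two-copy start
  events <- matrix(0L, spec$n_alleles, nI)
  states <- matrix(0L, spec$n_alleles, nI + 1)
  states[, 1] <- nst
  for (j in seq_len(nI)) {
    u <- runif(spec$n_alleles)
    if (!stationary) Ucols <- lapply(0:2, function(n) cumsum(Uarr[, n * n_g + 1, j]))
    lam <- integer(spec$n_alleles)
    for (n in 0:2) {
      idx <- which(nst == n)
      if (length(idx)) lam[idx] <- findInterval(u[idx], Ucols[[n + 1]]) + 1L
    }
    g <- (lam - 1L) %% n_g
    nst <- (lam - 1L) %/% n_g
    events[, j] <- g
    states[, j + 1] <- nst
  }
  list(events = events, states = states)
}

#' Convolve fine initiation events into a noisy activity trace
#'
#' Sums the per-copy event series, convolves with the elongation kernel,
#' samples at the coarse grid (the first coarse point carries no preceding
#' fine steps), and adds Gaussian noise with SD sigma(G).
#'
#' @param events Combined fine-step initiation counts (length Nt*ratio - 1),
#'   or a list of per-copy series to be summed.
#' @param gm Gene model (simulation kernel).
#' @param nm Noise model; `NULL` for a noiseless trace.
#' @param dt_s,dt_fine_s Coarse and fine intervals (seconds).
#' @param allele_id,bin_label Identifiers.
#' @return An `activity_trace`.
#' @export
synthesize_activity <- function(events, gm, nm, dt_s = 10, dt_fine_s = 1,
                                allele_id = "sim", bin_label = "sim") {
  if (is.list(events)) events <- Reduce(`+`, events)
  ratio <- round(dt_s / dt_fine_s)
  nt <- (length(events) + 1) / ratio
  if (nt != round(nt)) stop("events length must be Nt*ratio - 1")
  kern <- build_kernel(gm, dt_fine_s)
  G <- conv_downsample_cpp(as.numeric(events), kern$weights, as.integer(ratio),
                           as.integer(nt))
  A <- if (is.null(nm)) G else G + rnorm(nt, 0, noise_sd(G, nm))
  activity_trace(times = (seq_len(nt) - 1) * dt_s / 60, values = A,
                 allele_id = allele_id, bin_label = bin_label)
}

#' Generate a full synthetic data set with ground truth
#'
#' Runs the generator of a `simulation_spec` end to end: initiation events
#' by Gillespie (stationary rates) or the expanded propagator, kernel
#' convolution, and measurement noise.
#'
#' @param spec A `simulation_spec`.
#' @param method "gillespie" (stationary only) or "propagator".
#' @return List with `traces` (list of `activity_trace`), `events` (matrix
#'   alleles x fine steps, combined copies), and `spec`.
#' @export
simulate_traces <- function(spec, method = c("gillespie", "propagator")) {
  method <- match.arg(method)
  nt <- spec$duration * 60 / spec$dt_s
  ratio <- spec$dt_s / spec$dt_fine_s
  nI <- nt * ratio - 1
  dtp <- spec$dt_fine_s / 60
  if (method == "gillespie") {
    set.seed(spec$seed)
    ev <- simulate_gillespie(spec$params, duration = nI * dtp,
                             n_copies = spec$n_copies,
                             n_alleles = spec$n_alleles)
    events <- t(vapply(ev, function(a)
      Reduce(`+`, lapply(a, events_to_fine, n_fine = nI, dt_fine_min = dtp)),
      integer(nI)))
  } else {
    events <- sample_time_dependent(spec)$events   # seeds internally
  }
  traces <- lapply(seq_len(spec$n_alleles), function(a)
    synthesize_activity(events[a, ], spec$gm, spec$nm, spec$dt_s,
                        spec$dt_fine_s, allele_id = sprintf("sim_%03d", a)))
  list(traces = traces, events = events, spec = spec)
}
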