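#' Fit a global conversion factor by profile matching
#'
#' Live mean-activity profiles S(x) in arbitrary units are matched to
#' calibrated reference profiles (e.g. smFISH) to estimate a single
#' conversion factor nu shared by all genes, with a small per-gene
#' registration shift Delta_x. The expected live activity is the reference
#' scaled by copy number and effective length,
#' A_L = (n_L L_tilde_L) / (n_F L_tilde_F) * A_F, and the pseudo-likelihood
#' at each position is Gaussian with variance sigma_A^2 + nu^2 sigma_S^2.
#'
#' @param live List (one per gene) of data frames with columns `x`
#'   (position, fraction egg length), `S` (mean activity, a.u.), `se`
#'   (standard error).
#' @param reference List (one per gene) of data frames with columns `x`,
#'   `A` (calibrated mean activity, C.U.), `se`.
#' @param meta List (one per gene) with `n_live`, `n_fixed` (copy numbers)
#'   and `leff_live`, `leff_fixed` (effective lengths, bp).
#' @param dx_max Registration-shift bound (fraction egg length, default
#'   0.02).
#' @return List with `nu`, `delta_x` (per gene), `loglik`.
#' @export
fit_conversion_factor <- function(live, reference, meta, dx_max = 0.02) {
  stopifnot(length(live) == length(reference), length(live) == length(meta))
  ngene <- length(live)
  expected <- lapply(seq_len(ngene), function(g) {
    sc <- (meta[[g]]$n_live * meta[[g]]$leff_live) /
      (meta[[g]]$n_fixed * meta[[g]]$leff_fixed)
    data.frame(x = reference[[g]]$x, A = sc * reference[[g]]$A,
               se = sc * reference[[g]]$se)
  })
  gene_ll <- function(g, nu, dx) {
    lv <- live[[g]]; rf <- expected[[g]]
    xs <- lv$x - dx
    ok <- xs >= min(rf$x) & xs <= max(rf$x)
    if (sum(ok) < 3) return(-Inf)
    mu <- approx(rf$x, rf$A, xout = xs[ok])$y
    sA <- approx(rf$x, rf$se, xout = xs[ok])$y
    s2 <- sA^2 + nu^2 * lv$se[ok]^2
    sum(dnorm(nu * lv$S[ok], mu, sqrt(s2), log = TRUE))
  }
  total_ll <- function(nu, dxs) {
    if (nu <= 0) return(-Inf)
    sum(vapply(seq_len(ngene), function(g) gene_ll(g, nu, dxs[g]), 0))
  }
  # coarse-grid restarts over Delta_x, then joint refinement
  nu0 <- stats::median(unlist(lapply(seq_len(ngene), function(g) {
    mu <- approx(expected[[g]]$x, expected[[g]]$A, xout = live[[g]]$x,
                 rule = 2)$y
    hi <- live[[g]]$S > stats::quantile(live[[g]]$S, 0.5)
    mu[hi] / live[[g]]$S[hi]
  })), na.rm = TRUE)
  dx_grid <- seq(-dx_max, dx_max, length.out = 9)
  dxs <- vapply(seq_len(ngene), function(g) {
    dx_grid[which.max(vapply(dx_grid, function(d) gene_ll(g, nu0, d), 0))]
  }, 0)
  opt <- optim(c(log(nu0), dxs), function(par) {
    dxv <- pmin(pmax(par[-1], -dx_max), dx_max)
    -total_ll(exp(par[1]), dxv)
  }, method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-12))
  nu <- exp(opt$par[1])
  list(nu = nu, delta_x = pmin(pmax(opt$par[-1], -dx_max), dx_max),
       loglik = -opt$value)
}

#' Length- and copy-number-normalized activity cumulants
#'
#' kappa_k' = kappa_k / (n_g C_k) * (L' / L_g)^k rescales measured activity
#' cumulants to a single gene copy of normalized length L', using the
#' k-th order loop-position coefficients C_k, so that cumulant-mean
#' relationships can be compared across constructs and assays.
#'
#' @param kappa Vector of cumulants (orders `k_order`).
#' @param k_order Cumulant orders matching `kappa`.
#' @param n_g Number of contributing gene copies.
#' @param gm Gene model providing C_k and L_g.
#' @param L_prime Normalized gene length in bp (default 3300, the average
#'   gap-gene length without stem-loops).
#' @return Normalized cumulants kappa_k'.
#' @export
normalized_cumulants <- function(kappa, k_order, n_g, gm, L_prime = 3300) {
  stopifnot(length(kappa) == length(k_order))
  Ck <- cumulant_coefficients(gm, k_order)
  kappa / (n_g * Ck) * (L_prime / gm$gene_length_bp)^k_order
}

#' Calibrate live intensities against a reference count distribution
#'
#' Fits the histogram of background-subtracted spot intensities with a
#' mixture of a zero-centred background Gaussian (weight rho, the fraction
#' of time no nascent mRNA is present) and Gaussians at alpha * g for g >= 1
#' weighted by a reference nascent-count distribution P(g):
#' P(s) = rho N(s | 0, sigma_b) + (1 - rho) sum_g N(s | alpha g, sigma_b)
#' P(g). The fitted alpha is the intensity of a single nascent mRNA.
#'
#' @param s Intensities (background subtracted).
#' @param pg Data frame with columns `g` (counts >= 1) and `p`
#'   (probabilities; renormalized over g >= 1).
#' @param sigma_b Background SD (same units as `s`).
#' @return List with `rho`, `alpha`, `loglik`.
#' @export
mixture_calibrate <- function(s, pg, sigma_b) {
  s <- s[is.finite(s)]
  if (length(s) < 50 || sd(s) == 0) stop("degenerate intensity histogram")
  stopifnot(all(pg$g >= 1))
  p <- pg$p / sum(pg$p)
  keep <- cumsum(p) <= 1 - 1e-6
  keep[which.max(!keep)] <- TRUE              # keep first beyond threshold
  g <- pg$g[keep]; p <- p[keep] / sum(p[keep])
  negll <- function(par) {
    rho <- 1 / (1 + exp(-par[1])); alpha <- exp(par[2])
    dens <- rho * dnorm(s, 0, sigma_b)
    for (i in seq_along(g))
      dens <- dens + (1 - rho) * p[i] * dnorm(s, alpha * g[i], sigma_b)
    -sum(log(pmax(dens, 1e-300)))
  }
  a0 <- max(stats::quantile(s, 0.9) / max(sum(g * p), 1), sigma_b)
  opt <- optim(c(0, log(a0)), negll, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-12))
  list(rho = 1 / (1 + exp(-opt$par[1])), alpha = exp(opt$par[2]),
       loglik = -opt$value)
}
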