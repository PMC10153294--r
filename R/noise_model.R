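#' Heteroscedastic measurement-noise model
#'
#' Measured activity A around a true signal G (both in cytoplasmic units,
#' C.U.) is Gaussian with variance sigma_b^2 + beta1 * G: a constant imaging
#' background plus a Poisson-like shot-noise term proportional to the signal,
#' as expected for laser-scanning microscopy.
#'
#' @param sigma_b Background SD in C.U. (default 1.22, the interlaced
#'   dual-colour control fit).
#' @param beta1 Shot-noise slope in C.U. (default 0.16).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_b = 1.22, beta1 = 0.16) {
  stopifnot(sigma_b >= 0, beta1 >= 0)
  structure(list(sigma_b = sigma_b, beta1 = beta1), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> sigma(G) = sqrt(%.4g^2 + %.4g G) C.U.\n",
              x$sigma_b, x$beta1))
  invisible(x)
}

#' Measurement noise SD at a given true signal
#'
#' @param G True signal in C.U. (vectorized, non-negative).
#' @param nm A `noise_model`.
#' @return SD(s) in C.U., monotone non-decreasing in G.
#' @export
noise_sd <- function(G, nm) {
  stopifnot(inherits(nm, "noise_model"))
  if (any(G < 0)) stop("true signal G must be non-negative")
  sqrt(nm$sigma_b^2 + nm$beta1 * G)
}

#' Serialize / read a noise model as JSON
#' @param nm A `noise_model`.
#' @param path File path.
#' @export
write_noise_model <- function(nm, path) {
  jsonlite::write_json(list(sigma_b = nm$sigma_b, beta1 = nm$beta1), path,
                       auto_unbox = TRUE, digits = NA)
}

#' @rdname write_noise_model
#' @export
read_noise_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  noise_model(j$sigma_b, j$beta1)
}

# Pseudo-likelihood of dual-colour pairs for a line y = alpha x + gamma with
# equal per-channel noise expanded along the projection v on the line:
# sigma^2(v) = sigma_b^2 + b1 v + b2 v^2.
dual_color_negll <- function(par, x, y, fix) {
  alpha <- if (is.na(fix["alpha"])) par[["alpha"]] else fix[["alpha"]]
  gamma <- if (is.na(fix["gamma"])) par[["gamma"]] else fix[["gamma"]]
  sb <- exp(par[["log_sb"]])
  b1 <- exp(par[["log_b1"]])
  b2 <- if (is.na(fix["beta2"])) exp(par[["log_b2"]]) else fix[["beta2"]]
  v <- (x + alpha * (y - gamma)) / sqrt(1 + alpha^2)
  s2 <- sb^2 + b1 * v + b2 * v^2
  if (any(s2 <= 0)) return(1e12)
  res2 <- (y - alpha * x - gamma)^2 / (1 + alpha^2)
  0.5 * sum(log(2 * pi * s2) + res2 / s2)
}

#' Fit the measurement-noise law from dual-colour trace pairs
#'
#' Two simultaneous recordings of the same transcription site (e.g. interlaced
#' MS2/PP7 loops read in two colours) should agree up to measurement noise.
#' A straight line y = alpha x + gamma is fitted with error on both axes,
#' with the variance expanded along the line projection v as
#' sigma^2(v) = sigma_b^2 + beta1 v + beta2 v^2. Nested models (alpha fixed
#' to 1, gamma to 0, beta2 to 0, in all combinations) are compared by AIC,
#' ties broken toward the smaller model.
#'
#' The per-channel noise law follows by evaluating sigma^2(v) at the
#' projection of a point with both channels at signal G, i.e.
#' v = sqrt(1 + alpha^2) G on the calibrated diagonal, giving the shot-noise
#' slope beta1_tilde = sqrt(1 + alpha^2) * beta1 (= sqrt(2) beta1 at
#' alpha = 1).
#'
#' @param x,y Paired activities in C.U. (same length, >= 50 pairs).
#' @return List with the selected line parameters (`alpha`, `gamma`,
#'   `beta1_line`, `beta2`), the per-channel `noise` (`noise_model`), the
#'   AIC table, and the selected model label.
#' @export
fit_dual_color <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 50) stop("need at least 50 dual-colour pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate pairs: zero variance")

  specs <- expand.grid(alpha_free = c(FALSE, TRUE), gamma_free = c(FALSE, TRUE),
                       beta2_free = c(FALSE, TRUE))
  s0 <- sd(y - x)
  fits <- lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    fix <- c(alpha = if (sp$alpha_free) NA_real_ else 1,
             gamma = if (sp$gamma_free) NA_real_ else 0,
             beta2 = if (sp$beta2_free) NA_real_ else 0)
    par <- c(log_sb = log(max(s0 / sqrt(2), 1e-3)), log_b1 = log(0.1))
    if (sp$alpha_free) par <- c(par, alpha = 1)
    if (sp$gamma_free) par <- c(par, gamma = 0)
    if (sp$beta2_free) par <- c(par, log_b2 = log(1e-3))
    opt <- optim(par, dual_color_negll, x = x, y = y, fix = fix,
                 method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-10))
    list(spec = sp, fix = fix, par = opt$par, negll = opt$value,
         k = length(par), aic = 2 * length(par) + 2 * opt$value)
  })
  aics <- vapply(fits, `[[`, 0, "aic")
  ks <- vapply(fits, `[[`, 0, "k")
  # AIC selection; ties (within 1e-6) toward the smaller model
  best <- order(round(aics, 6), ks)[1]
  f <- fits[[best]]
  alpha <- if (is.na(f$fix["alpha"])) f$par[["alpha"]] else f$fix[["alpha"]]
  gamma <- if (is.na(f$fix["gamma"])) f$par[["gamma"]] else f$fix[["gamma"]]
  b1 <- exp(f$par[["log_b1"]])
  b2 <- if (is.na(f$fix["beta2"])) exp(f$par[["log_b2"]]) else f$fix[["beta2"]]
  sb <- exp(f$par[["log_sb"]])
  beta1_tilde <- sqrt(1 + alpha^2) * b1
  list(alpha = alpha, gamma = gamma, sigma_b = sb,
       beta1_line = b1, beta2 = b2, beta1_tilde = beta1_tilde,
       noise = noise_model(sigma_b = sb, beta1 = beta1_tilde),
       aic = data.frame(alpha_free = specs$alpha_free,
                        gamma_free = specs$gamma_free,
                        beta2_free = specs$beta2_free, aic = aics),
       model = unlist(f$spec))
}

#' Uncorrelated variability of pooled activity traces
#'
#' The elongation process makes the biological signal strongly correlated
#' between consecutive samples, while imaging noise is not. The variance
#' minus the ensemble lag-1 autocovariance across alleles,
#' sigma_u^2(t) = sigma^2(t) - Cov(t, t + dt), therefore estimates the
#' measurement-noise variance as a function of time; regressed against the
#' mean activity it recovers the noise law without a dual-colour control.
#'
#' @param traces Numeric matrix, alleles x time points (>= 20 alleles,
#'   >= 2 time points), activities in C.U.
#' @param times Optional time stamps (minutes) for the columns.
#' @return Data frame with columns `t`, `mu`, `sigma2`, `sigma_u2` (one row
#'   per time point except the last).
#' @export
uncorrelated_variability <- function(traces, times = NULL) {
  traces <- as.matrix(traces)
  if (nrow(traces) < 2) stop("need at least 2 alleles")
  if (ncol(traces) < 2) stop("need at least 2 time points")
  nt <- ncol(traces)
  mu <- colMeans(traces)
  s2 <- apply(traces, 2, var)
  cv <- vapply(seq_len(nt - 1), function(i) cov(traces[, i], traces[, i + 1]), 0)
  if (is.null(times)) times <- seq_len(nt)
  data.frame(t = times[seq_len(nt - 1)], mu = mu[seq_len(nt - 1)],
             sigma2 = s2[seq_len(nt - 1)],
             sigma_u2 = s2[seq_len(nt - 1)] - cv)
}
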