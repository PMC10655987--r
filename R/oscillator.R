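# ---- precision oscillator and variant schedules ----------------------------

.variants <- c("stationary", "identity", "timing", "full_antiphase",
               "full_samephase")

#' Configure a model variant's precision schedules
#'
#' Returns the stationary log-precisions of the hidden states and the affine
#' log-precision schedules (intercept, slope in the oscillator coordinate
#' `p2`) of the syllable and gamma causal states for each model variant:
#'
#' * `stationary`: both schedules flat (`2.5`, `1.5`); no oscillator states.
#' * `identity`: syllable precision oscillates (`2.5 + 2 p2`), gamma flat.
#' * `timing`: gamma precision oscillates (`1.5 + 4 p2`), syllable flat
#'   (at `5`).
#' * `full_antiphase`: both oscillate in opposite phase
#'   (`2.5 + 2 p2`, `1.5 - 4 p2`).
#' * `full_samephase`: both oscillate in phase (`2.5 + 2 p2`, `1.5 + 4 p2`).
#'
#' Hidden-state log-precisions are `W_omega = 3`, `W_gamma = 5`, `W_p = 5`
#' in every variant. The oscillating variants carry 19 state variables, the
#' stationary baseline 17 (no oscillator pair).
#'
#' @param variant one of `"stationary"`, `"identity"`, `"timing"`,
#'   `"full_antiphase"`, `"full_samephase"`
#' @param psi modulation frequency of the precision oscillator in Hz
#' @return an object of class `variant_config`
#' @export
#' @examples
#' cfg <- variant_config("full_antiphase", psi = 20)
#' precision_schedule(cfg, p2 = 0)
variant_config <- function(variant = "stationary", psi = 20) {
  variant <- match.arg(variant, .variants)
  if (psi <= 0 || psi >= 500) stop("psi must be in (0, 500) Hz")
  sched <- switch(variant,
    stationary     = list(omega = c(2.5, 0), gamma = c(1.5, 0)),
    identity       = list(omega = c(2.5, 2), gamma = c(1.5, 0)),
    timing         = list(omega = c(5.0, 0), gamma = c(1.5, 4)),
    full_antiphase = list(omega = c(2.5, 2), gamma = c(1.5, -4)),
    full_samephase = list(omega = c(2.5, 2), gamma = c(1.5, 4))
  )
  structure(
    list(
      variant = variant,
      psi = psi,
      W = c(omega = 3, gamma = 5, p = 5),
      logV_omega = c(intercept = sched$omega[1], slope = sched$omega[2]),
      logV_gamma = c(intercept = sched$gamma[1], slope = sched$gamma[2]),
      n_state_variables = if (variant == "stationary") 17L else 19L
    ),
    class = "variant_config"
  )
}

#' @export
print.variant_config <- function(x, ...) {
  cat(sprintf(
    "variant_config '%s' (psi = %g Hz, %d state variables)\n  logV_omega = %g %+g * p2\n  logV_gamma = %g %+g * p2\n",
    x$variant, x$psi, x$n_state_variables,
    x$logV_omega[1], x$logV_omega[2], x$logV_gamma[1], x$logV_gamma[2]))
  invisible(x)
}

#' Evaluate the causal-state precisions at an oscillator coordinate
#'
#' @param config a [variant_config()]
#' @param p2 oscillator coordinate (scalar or vector)
#' @return list with `V_omega` and `V_gamma`, strictly positive
#' @export
precision_schedule <- function(config, p2) {
  stopifnot(inherits(config, "variant_config"))
  list(
    V_omega = exp(config$logV_omega[["intercept"]] +
                    config$logV_omega[["slope"]] * p2),
    V_gamma = exp(config$logV_gamma[["intercept"]] +
                    config$logV_gamma[["slope"]] * p2)
  )
}

#' Simulate the precision oscillator
#'
#' The oscillator pair `(p1, p2)` rotates at the modulation frequency `psi`:
#' `dp1/dt = k1 p2`, `dp2/dt = -k1 p1` with angular increment
#' `k1 = 2 * pi * psi / 1000` per sample at the 1000 Hz model rate. The
#' noise-free system is integrated exactly (per-sample rotation by `k1`),
#' which conserves the amplitude `p1^2 + p2^2` to machine precision;
#' optional Gaussian state noise is added after each rotation. Initial
#' condition is `(p1, p2) = (0, 1)`, giving `p2` unit amplitude so the
#' schedule slopes of [variant_config()] span their intended log-precision
#' ranges.
#'
#' @param psi modulation frequency in Hz (> 0)
#' @param n_samples number of 1 ms samples (>= 1)
#' @param noise_sd standard deviation of per-step state noise (default 0)
#' @param seed seed for the noise
#' @return list with `p1`, `p2` (length `n_samples`) and `k1`
#' @export
precision_oscillator <- function(psi, n_samples, noise_sd = 0, seed = 1) {
  if (psi <= 0) stop("psi must be positive")
  if (n_samples < 1) stop("n_samples must be >= 1")
  k1 <- 2 * pi * psi / 1000
  n <- as.integer(n_samples)
  if (noise_sd == 0) {
    # closed form of the rotation
    ang <- k1 * seq_len(n)
    return(list(p1 = sin(ang), p2 = cos(ang), k1 = k1))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p1 <- numeric(n); p2 <- numeric(n)
  c1 <- cos(k1); s1 <- sin(k1)
  a <- 0; b <- 1
  e1 <- stats::rnorm(n, 0, noise_sd)
  e2 <- stats::rnorm(n, 0, noise_sd)
  for (t in seq_len(n)) {
    an <- a * c1 + b * s1
    b <- -a * s1 + b * c1
    a <- an
    a <- a + e1[t]; b <- b + e2[t]
    p1[t] <- a; p2[t] <- b
  }
  list(p1 = p1, p2 = p2, k1 = k1)
}

#' Dominant frequency of a trace by discrete Fourier transform
#'
#' @param x numeric trace sampled at `sample_rate` Hz
#' @param sample_rate samples per second (default 1000)
#' @return frequency in Hz of the largest non-DC spectral peak
#' @export
dominant_frequency <- function(x, sample_rate = 1000) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1) * sample_rate / n
  freqs[which.max(spec)]
}
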