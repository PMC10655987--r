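# ---- model inversion: precision-weighted prediction-error descent ----------

#' Options controlling the inversion dynamics
#'
#' Learning rates were calibrated once on noiseless single-syllable stimuli
#' under the stationary baseline (smallest rates giving fully reliable
#' recognition) and are frozen; see the methods vignette.
#'
#' @param eta_omega learning rate of the syllable accumulators (per unit
#'   precision per ms)
#' @param eta_gamma learning rate of the gamma timing correction
#' @param lambda spectral relaxation rate per ms (see [hopfield_step()])
#' @param theta_gain envelope-to-drive gain of the theta module
#' @param reset_rate relaxation rate of the gamma-triggered evidence reset
#' @param reset_threshold dominance threshold of the last gamma unit that
#'   triggers the reset (shared with the segmentation marker threshold)
#' @param state_noise sd of per-ms Gaussian state noise on the syllable
#'   accumulators during evidence accumulation (suspended during resets)
#' @param onset_gain coupling of the theta onset pulse into the first gamma
#'   unit, in units of the gamma activation floor
#' @param p_noise_sd state noise of the precision oscillator (default 0)
#' @param seed seed for all inference noise
#' @return an object of class `inference_options`
#' @export
inference_options <- function(eta_omega = 0.016, eta_gamma = 0.002,
                              lambda = 0.2, theta_gain = 0.25,
                              reset_rate = 0.03, reset_threshold = 0.6,
                              state_noise = 0.005, onset_gain = 1,
                              p_noise_sd = 0, seed = 1) {
  stopifnot(eta_omega > 0, eta_gamma >= 0, lambda > 0, reset_rate > 0)
  structure(
    list(eta_omega = eta_omega, eta_gamma = eta_gamma, lambda = lambda,
         theta_gain = theta_gain, reset_rate = reset_rate,
         reset_threshold = reset_threshold, state_noise = state_noise,
         onset_gain = onset_gain, p_noise_sd = p_noise_sd, seed = seed),
    class = "inference_options"
  )
}

#' Candidate templates for a sentence (one unit per syllable token)
#'
#' The recognizer's softmax ranges over one evidence accumulator per
#' syllable token in the sentence, each tied to the stored template of that
#' token's syllable.
#'
#' @param inventory a `syllable_inventory`
#' @param sentence a `sentence_stimulus`
#' @return list of 6 x 8 template matrices, one per token
#' @export
sentence_candidates <- function(inventory, sentence) {
  inventory$templates[sentence$syllable_ids]
}

#' Error-driven update of the syllable accumulators
#'
#' The per-ms change of accumulated evidence attributable to the bottom-up
#' syllable prediction error, scaled by the (possibly oscillating) causal
#' precision: `d_omega = eta * V_omega * z_pe`. Raising `V_omega` with all
#' else fixed strictly increases the update magnitude - the gating
#' mechanism by which oscillating precisions modulate bottom-up influence.
#'
#' @param z_pe length-N signed bottom-up syllable prediction error
#' @param V_omega syllable causal precision (scalar)
#' @param eta_omega learning rate
#' @return length-N update vector
#' @export
omega_error_update <- function(z_pe, V_omega, eta_omega = 0.016) {
  eta_omega * V_omega * z_pe
}

#' Invert the generative model on a stimulus
#'
#' Runs the hierarchical dynamics forward while descending precision-weighted
#' squared prediction errors at 1 ms steps: the precision oscillator sets the
#' causal precisions `V_omega(t)`, `V_gamma(t)` through the variant's
#' schedules; the theta neuron tracks the envelope and modulates the gamma
#' sequence's speed; the gamma outputs index template columns; syllable
#' accumulators integrate precision-weighted bottom-up errors (plus small
#' Gaussian state noise) and are reset toward uniform whenever the last
#' gamma unit dominates; the spectral state relaxes toward the compositional
#' prediction, and its mismatch with the input spectrogram is the bottom-up
#' error driving everything above.
#'
#' @param stimulus a `stimulus_arrays` object
#' @param candidates list of 6 x 8 candidate templates (e.g.
#'   [sentence_candidates()]), or a `syllable_inventory`
#' @param config a [variant_config()]; the stationary variant freezes the
#'   oscillator at `p2 = 0`
#' @param opts an [inference_options()]
#' @return an object of class `recognition_trace` with per-sample series
#'   `omega`, `softmax_omega` (N x T), `y` (8 x T), `z` (6 x T), `z_pe`
#'   (N x T), `gamma_pe` (8 x T), `input_pe` (7 x T: 6 spectral channels +
#'   envelope), `logV_omega`, `logV_gamma`, `p1`, `p2`, `h` (0 during active
#'   resetting), segmentation markers `G` (samples, starting at 0 and ending
#'   at T), `status` (`"ok"` or `"singular"`), `failed_at`, `variant`,
#'   `psi`, `n_state_variables`
#' @export
invert <- function(stimulus, candidates, config, opts = inference_options()) {
  stopifnot(inherits(stimulus, "stimulus_arrays"),
            inherits(config, "variant_config"),
            inherits(opts, "inference_options"))
  if (inherits(candidates, "syllable_inventory")) {
    candidates <- candidates$templates
  }
  sg <- stimulus$spectrogram
  env <- stimulus$envelope
  N <- length(candidates)
  Tt <- ncol(sg)
  stopifnot(N >= 1, Tt >= 1, length(env) == Tt)

  # stacked template tensors for fast per-sample contraction
  M3 <- array(unlist(candidates), c(6, 8, N))
  W48 <- matrix(M3, 48, N)                       # vec(T_k) in columns
  M2 <- matrix(aperm(M3, c(1, 3, 2)), 6 * N, 8)  # (channel, unit) x bin

  stationary <- config$variant == "stationary"
  k1 <- 2 * pi * config$psi / 1000
  c1 <- cos(k1); s1 <- sin(k1)
  iw <- config$logV_omega[["intercept"]]; sw <- config$logV_omega[["slope"]]
  ig <- config$logV_gamma[["intercept"]]; sg_ <- config$logV_gamma[["slope"]]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(opts$seed)
  nz <- matrix(stats::rnorm(N * Tt, 0, opts$state_noise), N, Tt)
  pnz <- if (opts$p_noise_sd > 0) {
    matrix(stats::rnorm(2 * Tt, 0, opts$p_noise_sd), 2, Tt)
  } else NULL

  # states
  p1 <- 0; p2 <- if (stationary) 0 else 1
  th <- theta_state()
  I_ref <- th$intrinsic_rate * (1 + opts$theta_gain * mean(env))
  gs <- gamma_state()
  omega <- rep(0, N)
  z <- sg[, 1]

  # traces
  tr <- list(
    omega = matrix(NA_real_, N, Tt), softmax_omega = matrix(NA_real_, N, Tt),
    y = matrix(NA_real_, 8, Tt), z = matrix(NA_real_, 6, Tt),
    z_pe = matrix(NA_real_, N, Tt), gamma_pe = matrix(NA_real_, 8, Tt),
    input_pe = matrix(NA_real_, 7, Tt),
    logV_omega = rep(NA_real_, Tt), logV_gamma = rep(NA_real_, Tt),
    p1 = rep(NA_real_, Tt), p2 = rep(NA_real_, Tt),
    h = rep(NA_integer_, Tt)
  )
  status <- "ok"; failed_at <- NA_integer_

  for (t in seq_len(Tt)) {
    if (!stationary) {
      p1n <- p1 * c1 + p2 * s1
      p2 <- -p1 * s1 + p2 * c1
      p1 <- p1n
      if (!is.null(pnz)) { p1 <- p1 + pnz[1, t]; p2 <- p2 + pnz[2, t] }
    }
    lVo <- iw + sw * p2
    lVg <- ig + sg_ * p2
    Vo <- exp(lVo); Vg <- exp(lVg)

    y <- gs$y
    e <- exp(omega - max(omega)); ps <- e / sum(e)

    st <- theta_step(th, env[t], gain = opts$theta_gain, rate_ref = I_ref)
    th <- st$state

    Ty <- matrix(M2 %*% y, 6, N)
    shat <- as.vector(Ty %*% ps)
    z <- hopfield_step(z, shat, opts$lambda)
    eps <- sg[, t] - z
    env_pe <- env[t] - sum(z)

    z_pe <- as.numeric(crossprod(Ty - shat, eps)) * ps
    gate <- y[8] > opts$reset_threshold
    if (gate) {
      omega <- syllable_reset(omega, 1, opts$reset_rate)
    } else {
      omega <- omega + omega_error_update(z_pe, Vo, opts$eta_omega) + nz[, t]
    }

    Mbar <- matrix(W48 %*% ps, 6, 8)
    g <- as.numeric(crossprod(Mbar, eps))
    g <- g - sum(y * g)
    drive <- opts$eta_gamma * Vg * gs$x * g
    drive[1] <- drive[1] + opts$onset_gain * st$onset_pulse * .gamma_delta
    gs <- gamma_step(gs, st$rate_signal, drive)

    tr$omega[, t] <- omega; tr$softmax_omega[, t] <- ps
    tr$y[, t] <- y; tr$z[, t] <- z
    tr$z_pe[, t] <- z_pe; tr$gamma_pe[, t] <- g
    tr$input_pe[, t] <- c(eps, env_pe)
    tr$logV_omega[t] <- lVo; tr$logV_gamma[t] <- lVg
    tr$p1[t] <- p1; tr$p2[t] <- p2
    tr$h[t] <- if (gate) 0L else 1L

    if (!all(is.finite(omega)) || !all(is.finite(gs$x)) ||
        !all(is.finite(z))) {
      status <- "singular"; failed_at <- t
      break
    }
  }

  y8 <- tr$y[8, ]
  G <- if (status == "ok") {
    segmentation_markers(y8, Tt, threshold = opts$reset_threshold)
  } else c(0L, Tt)
  structure(
    c(tr, list(G = G, status = status, failed_at = failed_at,
               variant = config$variant, psi = config$psi,
               n_state_variables = config$n_state_variables,
               n_units = N, n_samples = Tt)),
    class = "recognition_trace"
  )
}

#' @export
print.recognition_trace <- function(x, ...) {
  cat(sprintf(
    "recognition_trace: %d units x %d ms, variant '%s' (psi %g Hz), status %s\n  %d segmentation windows\n",
    x$n_units, x$n_samples, x$variant, x$psi, x$status, length(x$G) - 1))
  invisible(x)
}

#' Run the stationary-precision baseline
#'
#' Identical to [invert()] with the 17-variable stationary configuration
#' (flat precision schedules, no oscillator states).
#'
#' @inheritParams invert
#' @export
run_baseline <- function(stimulus, candidates, opts = inference_options()) {
  invert(stimulus, candidates, variant_config("stationary", 20), opts)
}

#' Gamma-based segmentation markers
#'
#' Internal syllable-boundary markers: the sample indices where the last
#' gamma unit's output is a strict local maximum with amplitude at least
#' `threshold`, bracketed by 0 and the trace end. Plateaus of a local
#' maximum are tie-broken to their first sample. Consecutive duplicates are
#' removed; a trace with no qualifying peak yields a single window
#' `[0, n_samples]`.
#'
#' @param y8_trace numeric trace of the marker gamma unit (by the main
#'   convention, unit 8; pass `trace$y[1, ]` to use the first unit instead)
#' @param n_samples trace length (defaults to `length(y8_trace)`)
#' @param threshold minimum peak amplitude (default 0.6)
#' @return integer vector of sample markers starting at 0, strictly
#'   increasing, ending at `n_samples`
#' @export
segmentation_markers <- function(y8_trace, n_samples = length(y8_trace),
                                 threshold = 0.6) {
  stopifnot(all(is.finite(y8_trace)))
  r <- rle(y8_trace)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  peaks <- integer(0)
  if (k >= 3) {
    for (i in 2:(k - 1)) {
      if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1] &&
          r$values[i] >= threshold) {
        peaks <- c(peaks, starts[i])
      }
    }
  }
  unique(c(0L, as.integer(peaks), as.integer(n_samples)))
}
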