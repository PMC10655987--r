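# ---- generative dynamics: theta neuron, gamma sequence, syllable and
# ---- spectral levels -------------------------------------------------------

# Calibration constants, fixed once:
# * theta baseline drive (pi/200)^2 gives a free-running cycle of ~199 ms
#   (~5 Hz) under 1 ms Euler steps (canonical theta neuron period pi/sqrt(I)).
# * gamma Lotka-Volterra gain 0.74 with activation floor 1e-4 gives a
#   dominance dwell of ~24.75 ms per unit: 40 transitions/s and 5 complete
#   8-unit cycles/s at rest.
.theta_baseline <- (pi / 200)^2
.theta_gain <- 0.25
.gamma_kappa <- 0.74
.gamma_delta <- 1e-4

#' Initial state of the theta module
#'
#' A canonical theta neuron whose drive is the stimulus amplitude envelope.
#' Its phase emits a Gaussian pulse at a predefined onset phase and its
#' implied instantaneous frequency serves as the speech-rate signal sent to
#' the gamma sequence.
#'
#' @param phase initial phase in radians
#' @param intrinsic_rate baseline drive; the default gives a ~200 ms
#'   free-running cycle (~5 Hz)
#' @param onset_phase phase at which the onset pulse is maximal
#' @param pulse_width pulse width in radians
#' @return an object of class `theta_state`
#' @export
theta_state <- function(phase = 0, intrinsic_rate = .theta_baseline,
                        onset_phase = pi, pulse_width = 0.3) {
  structure(list(phase = phase %% (2 * pi), intrinsic_rate = intrinsic_rate,
                 onset_phase = onset_phase, pulse_width = pulse_width),
            class = "theta_state")
}

#' Advance the theta neuron by one sample
#'
#' Phase update `dphi/dt = (1 - cos phi) + I (1 + cos phi)` with drive
#' `I = intrinsic_rate * (1 + gain * envelope_sample)`. The onset pulse is a
#' Gaussian of the wrapped phase distance to `onset_phase` (value 1 exactly
#' at the onset phase). The rate signal is the oscillator's instantaneous
#' cycle frequency implied by the current drive (period `pi / sqrt(I)`),
#' normalized by `rate_ref` so it equals 1 at the reference drive.
#'
#' @param state a [theta_state()]
#' @param envelope_sample current envelope value (nonnegative)
#' @param gain envelope-to-drive gain (relative to the intrinsic rate)
#' @param rate_ref reference drive for rate normalization; defaults to the
#'   intrinsic rate so a silent input gives rate 1
#' @param dt step in ms (fixed at 1)
#' @return list with `state`, `onset_pulse` in `[0, 1]`, `rate_signal`
#' @export
theta_step <- function(state, envelope_sample, gain = .theta_gain,
                       rate_ref = NULL, dt = 1) {
  stopifnot(inherits(state, "theta_state"), dt == 1)
  I0 <- state$intrinsic_rate
  I <- I0 * (1 + gain * envelope_sample)
  if (is.null(rate_ref)) rate_ref <- I0
  phi <- state$phase
  phi <- (phi + (1 - cos(phi)) + I * (1 + cos(phi))) %% (2 * pi)
  d <- ((phi - state$onset_phase) %% (2 * pi))
  d <- ifelse(d > pi, d - 2 * pi, d)
  pulse <- exp(-d^2 / (2 * state$pulse_width^2))
  state$phase <- phi
  list(state = state, onset_pulse = pulse,
       rate_signal = sqrt(I / rate_ref))
}

#' Simulate the theta neuron over an envelope
#'
#' @inheritParams theta_step
#' @param envelope numeric vector of envelope samples (use zeros for a
#'   free-running simulation)
#' @return list with `phase`, `onset_pulse`, `rate_signal` traces and
#'   `cycle_period_ms`, the mean period between phase wraps
#' @export
theta_simulate <- function(envelope, state = theta_state(),
                           gain = .theta_gain, rate_ref = NULL) {
  n <- length(envelope)
  phase <- numeric(n); pulse <- numeric(n); rate <- numeric(n)
  wraps <- integer(0)
  prev <- state$phase
  for (t in seq_len(n)) {
    st <- theta_step(state, envelope[t], gain, rate_ref)
    state <- st$state
    phase[t] <- state$phase; pulse[t] <- st$onset_pulse
    rate[t] <- st$rate_signal
    if (state$phase < prev) wraps <- c(wraps, t)
    prev <- state$phase
  }
  period <- if (length(wraps) >= 2) mean(diff(wraps)) else NA_real_
  list(phase = phase, onset_pulse = pulse, rate_signal = rate,
       cycle_period_ms = period)
}

# asymmetric inhibition matrix enforcing the cyclic order 1 -> 2 -> ... -> 8
# -> 1: each unit inhibits all others strongly (1.5) except its successor
# (0.5), making the successor's direction the single unstable one at each
# saddle
.gamma_rho <- local({
  rho <- matrix(1.5, 8, 8)
  diag(rho) <- 1
  for (i in 1:8) rho[if (i < 8) i + 1 else 1, i] <- 0.5
  rho
})

#' Initial state of the gamma sequence
#'
#' Eight units in a winnerless-competition (stable heteroclinic channel)
#' arrangement, visited in fixed cyclic order. At rest a new unit becomes
#' dominant every ~25 ms (40 Hz unit rate; 5 Hz full-sequence rate).
#'
#' @param x optional initial activations (default: unit 1 dominant)
#' @return an object of class `gamma_state` with fields `x` (activations)
#'   and `y` (normalized outputs summing to 1)
#' @export
gamma_state <- function(x = NULL) {
  if (is.null(x)) x <- c(1, rep(.gamma_delta, 7))
  structure(list(x = x, y = x / sum(x)), class = "gamma_state")
}

#' Advance the gamma sequence by one sample
#'
#' Lotka-Volterra update
#' `dx_i = kappa * rate * x_i * (1 - sum_j rho_ij x_j) + delta + drive_i`,
#' clipped at zero, with the asymmetric inhibition matrix enforcing cyclic
#' order. `rate` multiplies the intrinsic speed (1 = rest, 40 Hz unit rate).
#' `drive` is an optional additive input (e.g. precision-weighted timing
#' prediction error, or the theta onset pulse on unit 1).
#'
#' @param state a [gamma_state()]
#' @param rate_signal multiplicative speed factor from the theta module
#' @param drive optional length-8 additive drive
#' @param dt step in ms (fixed at 1)
#' @return updated `gamma_state`
#' @export
gamma_step <- function(state, rate_signal = 1, drive = 0, dt = 1) {
  stopifnot(inherits(state, "gamma_state"), dt == 1)
  x <- state$x
  dx <- .gamma_kappa * rate_signal * x *
    (1 - as.vector(.gamma_rho %*% x)) + .gamma_delta + drive
  x <- pmax(x + dx, 0)
  state$x <- x
  state$y <- x / sum(x)
  state
}

#' Simulate the gamma sequence at a fixed rate
#'
#' @param n_ms simulation length in ms
#' @param rate_signal constant speed factor (1 = rest)
#' @return list with `y` (8 x n_ms outputs), `dominant` (argmax trace),
#'   `transition_rate` (dominance changes per second) and `cycle_rate`
#'   (complete 8 -> 1 wraps per second)
#' @export
gamma_simulate <- function(n_ms, rate_signal = 1) {
  state <- gamma_state()
  y <- matrix(0, 8, n_ms)
  dom <- integer(n_ms)
  for (t in seq_len(n_ms)) {
    state <- gamma_step(state, rate_signal)
    y[, t] <- state$y
    dom[t] <- which.max(state$y)
  }
  ch <- diff(dom) != 0
  wraps <- ch & dom[-1] == 1L & dom[-n_ms] == 8L
  list(y = y, dominant = dom,
       transition_rate = sum(ch) / (n_ms / 1000),
       cycle_rate = sum(wraps) / (n_ms / 1000))
}

#' Relax syllable evidence toward uniform (gamma-triggered reset)
#'
#' The last gamma unit's dominance signals the end of a syllable and clears
#' the accumulated evidence so the next segment starts afresh. Relaxation
#' toward the mean preserves the ranking of the accumulators at every
#' intermediate point; a sustained full reset drives the softmax to uniform.
#'
#' @param omega numeric vector of accumulated log-evidence
#' @param reset_gate gate in `[0, 1]` (0 leaves `omega` unchanged)
#' @param rate relaxation rate per ms at gate 1
#' @return updated `omega`
#' @export
syllable_reset <- function(omega, reset_gate, rate = 0.03) {
  omega + rate * reset_gate * (mean(omega) - omega)
}

#' Compositional spectral prediction
#'
#' The predicted spectral column is the syllable-probability-weighted,
#' gamma-weighted blend of the stored template columns:
#' `target = sum_k softmax_omega_k * (T_k %*% y)`. It always lies in the
#' convex hull of the stored columns.
#'
#' @param softmax_omega length-N probability vector over syllable units
#' @param y length-8 gamma output vector (nonnegative, sums to 1)
#' @param templates list of N 6 x 8 template matrices
#' @return length-6 predicted spectral vector
#' @export
predict_spectral_target <- function(softmax_omega, y, templates) {
  N <- length(templates)
  if (length(softmax_omega) != N) {
    stop("softmax_omega length must match the number of templates")
  }
  if (length(y) != 8) stop("y must have length 8")
  out <- numeric(6)
  for (k in seq_len(N)) {
    out <- out + softmax_omega[k] * as.vector(templates[[k]] %*% y)
  }
  out
}

#' Spectral-level relaxation step
#'
#' First-order linear relaxation of the spectral state toward the current
#' compositional target: `dz/dt = -lambda (z - target)`, fixed point
#' `z = target`, time constant `1/lambda` ms.
#'
#' @param z length-6 spectral state
#' @param target length-6 target from [predict_spectral_target()]
#' @param lambda relaxation rate per ms
#' @param dt step in ms (fixed at 1)
#' @return updated `z`
#' @export
hopfield_step <- function(z, target, lambda = 0.2, dt = 1) {
  stopifnot(dt == 1)
  z + lambda * (target - z)
}
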