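# Independent oracles and fixture builders shared across test files.

# Exhaustive LCS oracle: enumerate every subsequence of `a` (bitmask) and
# keep the longest that is also a subsequence of `b`. Independent of the
# dynamic-programming implementation under test.
brute_lcs <- function(a, b) {
  n <- length(a)
  if (n == 0 || length(b) == 0) return(0L)
  is_subseq <- function(s, v) {
    if (length(s) == 0) return(TRUE)
    j <- 1L
    for (x in v) {
      if (x == s[j]) {
        j <- j + 1L
        if (j > length(s)) return(TRUE)
      }
    }
    FALSE
  }
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) <= best) next
    if (is_subseq(a[sel], b)) best <- length(sel)
  }
  best
}

# A recognition trace whose softmax equals the input indicator exactly
# (the perfect-recognition fixed point), with boundary-aligned markers.
perfect_trace <- function(sentence) {
  Tt <- sentence$total_duration_ms
  N <- length(sentence$syllable_ids)
  s <- input_indicator(sentence, Tt)
  structure(list(
    omega = s * 10, softmax_omega = s * 1.0,
    y = matrix(1 / 8, 8, Tt), z = matrix(0, 6, Tt),
    z_pe = matrix(0, N, Tt), gamma_pe = matrix(0, 8, Tt),
    input_pe = matrix(0, 7, Tt),
    logV_omega = rep(2.5, Tt), logV_gamma = rep(1.5, Tt),
    p1 = rep(0, Tt), p2 = rep(0, Tt), h = rep(1L, Tt),
    G = c(0L, sentence$offsets_ms), status = "ok", failed_at = NA_integer_,
    variant = "stationary", psi = 20, n_state_variables = 17L,
    n_units = N, n_samples = Tt
  ), class = "recognition_trace")
}

# Small shared fixtures
tiny_inventory <- function(n = 6, seed = 42) make_inventory(n, seed)

tiny_stimulus <- function(inv, ids = c(2, 4), durs = c(200, 200),
                          noise_sd = 0, seed = 7) {
  sent <- sample_sentence(inv, length(ids), 200, 0, seed = seed)
  sent$syllable_ids <- as.integer(ids)
  sent$durations_ms <- as.integer(durs)
  sent$offsets_ms <- cumsum(sent$durations_ms)
  sent$onsets_ms <- c(0L, sent$offsets_ms[-length(ids)])
  sent$total_duration_ms <- sum(durs)
  list(sentence = sent, arrays = render_stimulus(sent, inv, noise_sd, seed))
}
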