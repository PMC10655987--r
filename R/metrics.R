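# ---- evaluation metrics ----------------------------------------------------

#' Input indicator matrix of a sentence
#'
#' Row `j` is 1 on the half-open sample window `[onset_j, offset_j)` of
#' syllable token `j` and 0 elsewhere; exactly one row is active at every
#' sample (boundary samples belong to the following syllable).
#'
#' @param sentence a `sentence_stimulus`
#' @param n_samples total samples (defaults to the sentence duration)
#' @return N_syl x n_samples binary matrix
#' @export
input_indicator <- function(sentence, n_samples = sentence$total_duration_ms) {
  on <- sentence$onsets_ms; off <- sentence$offsets_ms
  if (any(off[-length(off)] > on[-1])) stop("overlapping syllables")
  if (any(off > n_samples)) stop("boundaries outside [0, n_samples]")
  N <- length(on)
  s <- matrix(0L, N, n_samples)
  for (j in seq_len(N)) s[j, (on[j] + 1):off[j]] <- 1L
  s
}

#' Recognized syllable sequence from softmax trace and window markers
#'
#' For each window `[G_k, G_k+1)` the per-unit mean softmax `M` is computed;
#' the argmax unit (ties to the lowest index) is the window winner and its
#' indicator row is set over the whole window.
#'
#' @param softmax_trace N x T matrix of per-sample syllable probabilities
#' @param G segmentation markers from [segmentation_markers()]
#' @return list with `winners` (per-window unit indices), `M` (N x K window
#'   means), `r` (N x T binary recognized indicator)
#' @export
recognized_sequence <- function(softmax_trace, G) {
  N <- nrow(softmax_trace); Tt <- ncol(softmax_trace)
  stopifnot(G[1] == 0, G[length(G)] <= Tt, !is.unsorted(G, strictly = TRUE))
  K <- length(G) - 1
  r <- matrix(0L, N, Tt)
  winners <- integer(0); Mlist <- list()
  for (k in seq_len(K)) {
    a <- G[k] + 1; b <- G[k + 1]
    if (b < a) {
      warning("empty window skipped")
      next
    }
    M <- rowMeans(softmax_trace[, a:b, drop = FALSE])
    w <- which.max(M)  # which.max ties to lowest index
    r[w, a:b] <- 1L
    winners <- c(winners, w)
    Mlist[[length(Mlist) + 1]] <- M
  }
  list(winners = winners, M = do.call(cbind, Mlist), r = r)
}

#' Overlap between recognized and input syllable sequences
#'
#' The fraction of sentence duration on which the per-window winning unit
#' matches the true syllable token: the mean over samples of the dot
#' product of the two indicator matrices.
#'
#' @param s input indicator from [input_indicator()]
#' @param r recognized indicator from [recognized_sequence()]
#' @return fraction in `[0, 1]`
#' @export
overlap_metric <- function(s, r) {
  stopifnot(all(dim(s) == dim(r)))
  sum(s * r) / ncol(s)
}

#' Normalized entropy of a syllable probability vector
#'
#' `E = -(1 / log N) * sum_j psi_j log psi_j`, with `0 log 0 := 0`; 1 for a
#' uniform vector, 0 for a one-hot vector, independent of the logarithm
#' base. Accepts a matrix (columns = time samples) and returns one value
#' per column.
#'
#' @param psi_t probability vector (or N x T matrix of them)
#' @param N number of syllable units (defaults to `length`/`nrow`)
#' @return normalized entropy in `[0, 1]`
#' @export
normalized_entropy <- function(psi_t, N = NULL) {
  if (is.matrix(psi_t)) {
    if (is.null(N)) N <- nrow(psi_t)
    if (N < 2) stop("N must be >= 2")
    plogp <- psi_t * log(psi_t)
    plogp[psi_t == 0] <- 0
    return(-colSums(plogp) / log(N))
  }
  if (is.null(N)) N <- length(psi_t)
  if (N < 2) stop("N must be >= 2")
  plogp <- psi_t * log(psi_t)
  plogp[psi_t == 0] <- 0
  -sum(plogp) / log(N)
}

#' Entropy-weighted overlap
#'
#' Overlap with each sample discounted by the recognizer's uncertainty:
#' sample `t` contributes `(1 - E(t))` times the indicator dot product.
#' Always less than or equal to the plain overlap.
#'
#' @inheritParams overlap_metric
#' @param E_trace length-T normalized entropy trace in `[0, 1]`
#' @return fraction in `[0, 1]`
#' @export
entropy_weighted_overlap <- function(s, r, E_trace) {
  stopifnot(all(dim(s) == dim(r)), length(E_trace) == ncol(s))
  if (any(!is.finite(E_trace))) {
    stop("non-finite entropy trace: sentence must be flagged and excluded")
  }
  sum((1 - E_trace) * colSums(s * r)) / ncol(s)
}

#' Longest-common-subsequence length
#'
#' Standard dynamic-programming LCS: the length of the longest sequence
#' obtainable from both inputs by deletions only, preserving order.
#'
#' @param a,b integer vectors
#' @return integer length (0 for empty input)
#' @export
#' @examples
#' lcs_length(c(8, 1, 3, 2, 4, 5, 5, 7), 1:8)  # 5
lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L
                    else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

#' LCS-based recognition metric
#'
#' Length of the longest common subsequence between the input token sequence
#' and the per-window winner sequence, divided by the number of input
#' syllables. Sensitive to order only, not to inferred durations.
#'
#' @param input_seq input syllable token indices (`1:N_syl`)
#' @param recog_seq per-window winner indices (length may differ)
#' @param n_syl number of input syllables (defaults to
#'   `length(input_seq)`)
#' @return fraction in `[0, 1]`
#' @export
lcs_metric <- function(input_seq, recog_seq, n_syl = length(input_seq)) {
  if (n_syl < 1) stop("n_syl must be >= 1")
  lcs_length(input_seq, recog_seq) / n_syl
}

#' Sensory-information integration efficacy
#'
#' Per syllable unit `i`, the time-average (excluding active resetting,
#' `h(t) = 0`) of `z_i+ (domega_i/dt)+ + z_i- (domega_i/dt)-`: the product
#' of the positive (negative) part of the bottom-up syllable prediction
#' error with the positive (negative) part of the accumulator derivative.
#' Positive contributions mean the accumulated evidence moved in the
#' direction the bottom-up error indicated. The sentence value is the mean
#' over its syllable units (or the root-sum-square with `rms = TRUE`).
#'
#' @param trace a `recognition_trace`
#' @param rms use root-sum-square aggregation across units instead of the
#'   mean
#' @return sentence-level efficacy (scalar)
#' @export
integration_efficacy <- function(trace, rms = FALSE) {
  stopifnot(inherits(trace, "recognition_trace"))
  Tt <- trace$n_samples
  z <- trace$z_pe
  dom <- cbind(trace$omega[, 1, drop = FALSE] * 0,
               trace$omega[, -1, drop = FALSE] -
                 trace$omega[, -Tt, drop = FALSE])
  h <- trace$h
  zp <- pmax(z, 0); zn <- pmin(z, 0)
  dp <- pmax(dom, 0); dn <- pmin(dom, 0)
  contrib <- sweep(zp * dp + zn * dn, 2, h, `*`)
  r_i <- rowSums(contrib) / Tt
  if (rms) sqrt(sum(r_i^2)) else mean(r_i)
}

#' Per-sentence categorical log-likelihood
#'
#' For each syllable token `j`, the sum over its active samples of the log
#' probability the recognizer assigned to it, divided by the token's
#' duration; the sentence value is the sum over tokens. Probabilities are
#' floored at machine epsilon (a floor application flags the sentence via
#' the `floored` attribute).
#'
#' @param trace a `recognition_trace`
#' @param sentence the matching `sentence_stimulus`
#' @return scalar log-likelihood (<= 0), with attribute `floored`
#' @export
sentence_loglik <- function(trace, sentence) {
  stopifnot(inherits(trace, "recognition_trace"))
  s <- input_indicator(sentence, trace$n_samples)
  psi <- trace$softmax_omega
  floored <- any(psi[s == 1L] < .Machine$double.eps)
  psi <- pmax(psi, .Machine$double.eps)
  ll <- 0
  for (j in seq_len(nrow(s))) {
    act <- s[j, ] == 1L
    ll <- ll + sum(log(psi[j, act])) / sentence$durations_ms[j]
  }
  structure(ll, floored = floored)
}

#' Bayesian information criterion across sentences
#'
#' `BIC = sum_i loglik_i - 0.5 * N_sent * log(N_p)` with natural logarithm;
#' higher is better. `N_p` is the variant's state-variable count (19 for
#' the oscillating variants, 17 for the stationary baseline).
#'
#' @param logliks per-sentence log-likelihoods
#' @param n_params number of model state variables (>= 1)
#' @param n_sentences number of sentences (defaults to `length(logliks)`)
#' @return scalar BIC
#' @export
bic_score <- function(logliks, n_params, n_sentences = length(logliks)) {
  if (n_params < 1) stop("n_params must be >= 1")
  sum(logliks) - 0.5 * n_sentences * log(n_params)
}

#' Evaluate one recognition trace against its sentence
#'
#' Computes all per-sentence metrics in one pass: overlap, entropy-weighted
#' overlap, LCS ratio, integration efficacy, and log-likelihood.
#'
#' @param trace a `recognition_trace`
#' @param sentence the matching `sentence_stimulus`
#' @return one-row data frame: `overlap`, `ent_overlap`, `lcs_ratio`,
#'   `integration`, `loglik`, `n_windows`, `status`
#' @export
evaluate_trace <- function(trace, sentence) {
  if (trace$status != "ok") {
    return(data.frame(overlap = NA_real_, ent_overlap = NA_real_,
                      lcs_ratio = NA_real_, integration = NA_real_,
                      loglik = NA_real_, n_windows = NA_integer_,
                      status = trace$status))
  }
  s <- input_indicator(sentence, trace$n_samples)
  rec <- recognized_sequence(trace$softmax_omega, trace$G)
  E <- normalized_entropy(trace$softmax_omega)
  data.frame(
    overlap = overlap_metric(s, rec$r),
    ent_overlap = entropy_weighted_overlap(s, rec$r, E),
    lcs_ratio = lcs_metric(seq_along(sentence$syllable_ids), rec$winners),
    integration = integration_efficacy(trace),
    loglik = as.numeric(sentence_loglik(trace, sentence)),
    n_windows = length(trace$G) - 1L,
    status = "ok"
  )
}
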