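test_that("input indicator tiles samples with the half-open convention", {
  inv <- tiny_inventory()
  fx <- tiny_stimulus(inv, ids = c(1, 2), durs = c(100, 100))
  s <- input_indicator(fx$sentence, 200)
  expect_equal(colSums(s), rep(1, 200))               # exactly one active row
  expect_equal(rowSums(s), fx$sentence$durations_ms)  # row sums = durations
  # the boundary sample belongs to the following syllable
  expect_equal(s[, 101], c(0, 1))
  expect_equal(s[, 100], c(1, 0))

  bad <- fx$sentence
  bad$onsets_ms <- c(0L, 90L)
  expect_error(input_indicator(bad, 200), "overlap")
})

test_that("window winners and ties follow the mean-softmax argmax rule", {
  psi <- matrix(c(0.7, 0.3), 2, 100)
  rec <- recognized_sequence(psi, c(0L, 100L))
  expect_equal(rec$winners, 1L)
  expect_equal(rec$r[1, ], rep(1L, 100))

  # means tie at 0.5 -> lowest index wins
  psi2 <- cbind(c(0.9, 0.1), c(0.1, 0.9))
  rec2 <- recognized_sequence(psi2, c(0L, 2L))
  expect_equal(rec2$winners, 1L)

  G <- c(0L, 40L, 70L, 100L)
  expect_equal(length(recognized_sequence(psi, G)$winners), length(G) - 1)
})

test_that("overlap matches hand-counted fractions and fixed points", {
  inv <- tiny_inventory()
  fx <- tiny_stimulus(inv, ids = c(1, 2), durs = c(100, 100))
  s <- input_indicator(fx$sentence, 200)
  expect_equal(overlap_metric(s, s), 1)

  # recognized as syllable 1 throughout -> half right
  r1 <- matrix(0L, 2, 200); r1[1, ] <- 1L
  expect_equal(overlap_metric(s, r1), 0.5)

  r_wrong <- s[2:1, ]
  expect_equal(overlap_metric(s, r_wrong), 0)
})

test_that("normalized entropy hits its closed-form anchors", {
  expect_equal(normalized_entropy(rep(0.25, 4)), 1)
  expect_equal(normalized_entropy(c(1, 0, 0)), 0)
  # binary entropy of (0.75, 0.25) over log 2
  h <- -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(2)
  expect_equal(normalized_entropy(c(0.75, 0.25)), h)
  expect_equal(normalized_entropy(c(0.75, 0.25)), 0.811278, tolerance = 1e-6)
  expect_error(normalized_entropy(1, N = 1), "N")

  m <- cbind(rep(0.25, 4), c(1, 0, 0, 0))
  expect_equal(normalized_entropy(m), c(1, 0))
})

test_that("entropy weighting discounts uncertain samples", {
  inv <- tiny_inventory()
  fx <- tiny_stimulus(inv, ids = c(1, 2), durs = c(100, 100))
  s <- input_indicator(fx$sentence, 200)
  expect_equal(entropy_weighted_overlap(s, s, rep(0, 200)),
               overlap_metric(s, s))
  expect_equal(entropy_weighted_overlap(s, s, rep(1, 200)), 0)

  set.seed(3)
  E <- stats::runif(200)
  expect_lte(entropy_weighted_overlap(s, s, E), overlap_metric(s, s))
  expect_error(entropy_weighted_overlap(s, s, c(rep(0, 199), NaN)),
               "flagged")
})

test_that("LCS length equals exhaustive enumeration and the worked example", {
  expect_equal(lcs_length(c(8, 1, 3, 2, 4, 5, 5, 7), 1:8), 5L)
  expect_equal(lcs_length(1:7, 1:7), 7L)
  expect_equal(lcs_length(integer(0), 1:3), 0L)
  expect_equal(lcs_length(1:3, integer(0)), 0L)

  set.seed(99)
  for (i in 1:500) {
    na <- sample(0:10, 1); nb <- sample(0:10, 1)
    a <- sample.int(6, na, replace = TRUE)
    b <- sample.int(6, nb, replace = TRUE)
    expect_identical(lcs_length(a, b), as.integer(brute_lcs(a, b)))
  }
})

test_that("LCS metric normalizes by the input length", {
  expect_equal(lcs_metric(1:4, 1:4), 1)
  expect_equal(lcs_metric(c(1, 2, 3), c(4, 5)), 0)
  expect_equal(lcs_metric(c(1, 2, 3), c(1, 3)), 2 / 3)
  expect_error(lcs_metric(integer(0), 1:2), "n_syl")
})

test_that("integration efficacy combines signed parts under the reset mask", {
  inv <- tiny_inventory()
  sent <- sample_sentence(inv, 1, 200, 0, seed = 1)
  base <- perfect_trace(sent)
  # toy with error trace (+1, -1, +2) and evidence derivative
  # (+0.5, -0.5, -1): contributions are (+)*(+) = 0.5, (-)*(-) = 0.5, and 0
  # for the sign-mismatched sample. Derivatives come from finite
  # differences, so the first sample carries no contribution.
  base$n_samples <- 4L
  base$z_pe <- matrix(c(0, 1, -1, 2), 1, 4)
  base$omega <- matrix(cumsum(c(0, 0.5, -0.5, -1)), 1, 4)
  base$h <- rep(1L, 4)
  expect_equal(integration_efficacy(base), (0.5 + 0.5 + 0) / 4)

  base$h <- rep(0L, 4)
  expect_equal(integration_efficacy(base), 0)

  # same-signed error and drift at every retained sample -> positive
  base$h <- rep(1L, 4)
  base$z_pe <- matrix(1, 1, 4)
  base$omega <- matrix(c(0.5, 1, 1.5, 2), 1, 4)
  expect_gt(integration_efficacy(base), 0)
})

test_that("sentence log-likelihood is duration-normalized and nonpositive", {
  inv <- tiny_inventory()
  fx <- tiny_stimulus(inv, ids = c(1, 2), durs = c(100, 100))
  tr <- perfect_trace(fx$sentence)
  expect_equal(as.numeric(sentence_loglik(tr, fx$sentence)), 0)

  # psi_true = 0.5 everywhere -> N_syl * log 0.5
  tr$softmax_omega <- matrix(0.5, 2, 200)
  expect_equal(as.numeric(sentence_loglik(tr, fx$sentence)), 2 * log(0.5))

  # zero probability on a true sample is floored and flagged
  tr$softmax_omega[1, 5] <- 0
  ll <- sentence_loglik(tr, fx$sentence)
  expect_true(attr(ll, "floored"))
  expect_true(is.finite(ll))
  expect_lte(as.numeric(ll), 0)
})

test_that("BIC penalizes state count with the natural logarithm", {
  expect_equal(bic_score(rep(0, 220), 19), -0.5 * 220 * log(19))
  expect_equal(bic_score(rep(0, 220), 19), -323.888, tolerance = 1e-3)
  expect_equal(bic_score(c(-1, -2), 1), -3)  # N_p = 1 -> no penalty
  ll <- stats::rnorm(10)
  expect_gt(bic_score(ll, 17), bic_score(ll, 19))
  expect_error(bic_score(0, 0), "n_params")
})

test_that("a perfect trace maximizes every metric", {
  inv <- tiny_inventory()
  fx <- tiny_stimulus(inv, ids = c(1, 2, 3), durs = c(100, 150, 100))
  m <- evaluate_trace(perfect_trace(fx$sentence), fx$sentence)
  expect_equal(m$overlap, 1)
  expect_equal(m$ent_overlap, 1)
  expect_equal(m$lcs_ratio, 1)
  expect_equal(m$loglik, 0)
  expect_equal(m$status, "ok")
})

test_that("metric bounds hold on real recognition traces", {
  inv <- tiny_inventory()
  fx <- tiny_stimulus(inv, ids = c(2, 4, 1), durs = c(200, 184, 216),
                      noise_sd = 0.1)
  tr <- invert(fx$arrays, sentence_candidates(inv, fx$sentence),
               variant_config("full_antiphase", 20),
               inference_options(seed = 21))
  m <- evaluate_trace(tr, fx$sentence)
  expect_true(m$overlap >= 0 && m$overlap <= 1)
  expect_true(m$ent_overlap >= 0 && m$ent_overlap <= 1)
  expect_lte(m$ent_overlap, m$overlap)
  expect_true(m$lcs_ratio >= 0 && m$lcs_ratio <= 1)
  expect_lte(m$loglik, 0)
})
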