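test_that("inversion is deterministic and records consistent traces", {
  inv <- tiny_inventory()
  fx <- tiny_stimulus(inv, ids = c(2, 4), durs = c(200, 200), noise_sd = 0.1)
  opts <- inference_options(seed = 11)
  cfg <- variant_config("full_antiphase", 20)
  tr1 <- invert(fx$arrays, sentence_candidates(inv, fx$sentence), cfg, opts)
  tr2 <- invert(fx$arrays, sentence_candidates(inv, fx$sentence), cfg, opts)
  expect_identical(tr1, tr2)

  expect_equal(tr1$status, "ok")
  expect_equal(colSums(tr1$softmax_omega), rep(1, 400), tolerance = 1e-9)
  expect_equal(tr1$n_state_variables, 19L)
  # h is 0 exactly where the reset gate (y8 dominance) is on
  expect_identical(tr1$h == 0L, tr1$y[8, ] > opts$reset_threshold)
  # markers bracket the trace and increase strictly
  expect_equal(tr1$G[1], 0L)
  expect_equal(tr1$G[length(tr1$G)], 400L)
  expect_false(is.unsorted(tr1$G, strictly = TRUE))
})

test_that("stationary baseline has flat precision traces and 17 variables", {
  inv <- tiny_inventory()
  fx <- tiny_stimulus(inv, ids = c(1, 3), durs = c(200, 200))
  tr <- run_baseline(fx$arrays, sentence_candidates(inv, fx$sentence),
                     inference_options(seed = 2))
  expect_equal(tr$n_state_variables, 17L)
  expect_equal(unique(tr$logV_omega), 2.5)
  expect_equal(unique(tr$logV_gamma), 1.5)
  expect_true(all(tr$p2 == 0))
})

test_that("zeroed-slope oscillating variant reproduces the baseline bit-for-bit", {
  inv <- tiny_inventory()
  fx <- tiny_stimulus(inv, ids = c(2, 5), durs = c(200, 200), noise_sd = 0.1)
  cand <- sentence_candidates(inv, fx$sentence)
  opts <- inference_options(seed = 5)

  flat <- variant_config("full_antiphase", 20)
  flat$logV_omega[["slope"]] <- 0
  flat$logV_gamma[["slope"]] <- 0
  tr_flat <- invert(fx$arrays, cand, flat, opts)
  tr_base <- run_baseline(fx$arrays, cand, opts)
  for (field in c("omega", "softmax_omega", "y", "z", "z_pe", "h", "G",
                  "logV_omega", "logV_gamma")) {
    expect_identical(tr_flat[[field]], tr_base[[field]], label = field)
  }
})

test_that("oscillating precisions follow the configured schedule in time", {
  inv <- tiny_inventory()
  fx <- tiny_stimulus(inv, ids = c(1, 2), durs = c(400, 400), noise_sd = 0.05)
  tr <- invert(fx$arrays, sentence_candidates(inv, fx$sentence),
               variant_config("full_antiphase", 20),
               inference_options(seed = 3))
  expect_equal(dominant_frequency(tr$logV_omega, 1000), 20, tolerance = 0.3)
  expect_lt(stats::cor(tr$logV_omega, tr$logV_gamma), -0.99)
  # schedules evaluated on the recorded oscillator coordinate
  expect_equal(tr$logV_omega, 2.5 + 2 * tr$p2)
  expect_equal(tr$logV_gamma, 1.5 - 4 * tr$p2)
})

test_that("numerical singularities are flagged, not dropped", {
  inv <- tiny_inventory()
  fx <- tiny_stimulus(inv, ids = c(1, 2), durs = c(200, 200))
  tr <- invert(fx$arrays, sentence_candidates(inv, fx$sentence),
               variant_config("stationary", 20),
               inference_options(eta_omega = 1e308, seed = 1))
  expect_equal(tr$status, "singular")
  expect_true(is.finite(tr$failed_at) && tr$failed_at >= 1)
  m <- evaluate_trace(tr, fx$sentence)
  expect_equal(m$status, "singular")
  expect_true(is.na(m$overlap))
})

test_that("segmentation markers pick thresholded strict local maxima", {
  y8 <- rep(0, 300)
  y8[80:120] <- dnorm(80:120, 100, 8) / dnorm(100, 100, 8) * 0.9
  y8[180:220] <- dnorm(180:220, 200, 8) / dnorm(200, 200, 8) * 0.5
  expect_equal(segmentation_markers(y8, 300), c(0L, 100L, 300L))

  # monotone trace: no interior markers
  expect_equal(segmentation_markers(seq(0, 1, length.out = 50), 50),
               c(0L, 50L))

  # plateau tie-broken to its first sample
  yp <- c(rep(0.1, 49), rep(0.8, 6), rep(0.1, 45))
  expect_equal(segmentation_markers(yp, 100), c(0L, 50L, 100L))

  # empty marker set yields a single window
  expect_equal(segmentation_markers(rep(0.2, 40), 40), c(0L, 40L))
})

test_that("raising the syllable precision increases the error-driven update", {
  z_pe <- c(0.3, -0.2, 0.05)
  lo <- omega_error_update(z_pe, V_omega = exp(1.5))
  hi <- omega_error_update(z_pe, V_omega = exp(3.5))
  expect_true(all(abs(hi) > abs(lo)))
  expect_equal(hi / lo, rep(exp(2), 3))
})

test_that("noiseless single syllables are recognized across seeded inventories", {
  hits <- 0
  for (seed in 1:20) {
    inv <- make_inventory(10, seed)
    true_id <- (seed %% 10) + 1
    sent <- sample_sentence(inv, 1, 200, 0, seed = seed)
    sent$syllable_ids <- true_id
    arr <- render_stimulus(sent, inv, noise_sd = 0)
    tr <- run_baseline(arr, inv, inference_options(seed = seed + 400))
    hits <- hits + (which.max(tr$omega[, tr$n_samples]) == true_id)
  }
  expect_gte(hits / 20, 0.95)
})
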