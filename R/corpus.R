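# ---- synthetic syllable corpus ---------------------------------------------

# Deterministic onset-loaded energy arc shared by all templates: the summed
# channel energy of every syllable decays from its onset, so the rendered
# envelope rises at each syllable boundary. Values are exp(-0.215 * (0:7)).
.onset_arc <- exp(-0.215 * (0:7))

# 3-tap moving average along both axes, edges truncated
.smooth3 <- function(m) {
  pad <- function(v) (c(v[1], v[-length(v)]) + v + c(v[-1], v[length(v)])) / 3
  m <- t(apply(m, 1, pad))
  apply(m, 2, pad)
}

#' Generate a seeded inventory of syllable templates
#'
#' Each syllable is a 6 x 8 spectrotemporal pattern: 6 frequency channels by
#' 8 temporal bins (one bin per gamma unit). Patterns are smoothed uniform
#' random fields, min-max scaled, and column-normalized to a fixed decaying
#' energy arc so that syllable energy peaks at onset.
#'
#' @param n_syllables number of templates (ids `1:n_syllables`)
#' @param seed integer seed; regeneration with the same seed is bit-for-bit
#'   reproducible
#' @return an object of class `syllable_inventory`: list with `templates`
#'   (list of 6 x 8 matrices with entries in `[0, 1]`), `n_syllables`, `seed`
#' @export
#' @examples
#' inv <- make_inventory(10, seed = 1)
#' dim(inv$templates[[1]])
make_inventory <- function(n_syllables, seed) {
  if (!is.numeric(n_syllables) || n_syllables < 1) {
    stop("n_syllables must be >= 1")
  }
  n_syllables <- as.integer(n_syllables)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  templates <- lapply(seq_len(n_syllables), function(i) {
    p <- .smooth3(matrix(stats::runif(48), 6, 8))
    p <- (p - min(p)) / (max(p) - min(p))
    p <- sweep(p, 2, 3 * .onset_arc / colSums(p), `*`)
    p / max(p)
  })
  structure(
    list(templates = templates, n_syllables = n_syllables, seed = seed),
    class = "syllable_inventory"
  )
}

#' @export
print.syllable_inventory <- function(x, ...) {
  cat(sprintf("syllable_inventory: %d templates (6 x 8), seed %d\n",
              x$n_syllables, x$seed))
  invisible(x)
}

#' Sample a synthetic sentence: syllable sequence plus boundaries
#'
#' Syllable ids are drawn uniformly with replacement from the inventory;
#' durations come from a Gamma distribution with the requested mean and
#' coefficient of variation, rounded to integer milliseconds and floored at
#' 8 ms (one sample per temporal bin). Syllables tile the sentence without
#' gaps or overlaps.
#'
#' @param inventory a `syllable_inventory`
#' @param n_syl number of syllable tokens
#' @param mean_dur_ms mean syllable duration in ms (default 200, the typical
#'   syllable duration of conversational speech)
#' @param cv coefficient of variation of durations in `[0, 1)`; 0 gives every
#'   syllable exactly `mean_dur_ms`
#' @param seed integer seed
#' @return an object of class `sentence_stimulus` with fields `syllable_ids`,
#'   `onsets_ms`, `offsets_ms`, `durations_ms`, `total_duration_ms`, `seed`
#' @export
sample_sentence <- function(inventory, n_syl, mean_dur_ms = 200, cv = 0.3,
                            seed = 1) {
  stopifnot(inherits(inventory, "syllable_inventory"))
  if (inventory$n_syllables < 1) stop("empty inventory")
  if (n_syl < 1) stop("n_syl must be >= 1")
  if (mean_dur_ms <= 0) stop("mean_dur_ms must be positive")
  if (cv < 0 || cv >= 1) stop("cv must be in [0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- sample.int(inventory$n_syllables, n_syl, replace = TRUE)
  if (cv == 0) {
    durs <- rep(round(mean_dur_ms), n_syl)
  } else {
    shape <- 1 / cv^2
    durs <- round(stats::rgamma(n_syl, shape = shape,
                                scale = mean_dur_ms * cv^2))
  }
  durs <- pmax(durs, 8L)
  offs <- cumsum(durs)
  structure(
    list(
      syllable_ids = ids,
      onsets_ms = c(0L, offs[-n_syl]),
      offsets_ms = offs,
      durations_ms = as.integer(durs),
      total_duration_ms = offs[n_syl],
      seed = seed
    ),
    class = "sentence_stimulus"
  )
}

#' @export
print.sentence_stimulus <- function(x, ...) {
  cat(sprintf("sentence_stimulus: %d syllables, %d ms total\n  ids: %s\n",
              length(x$syllable_ids), x$total_duration_ms,
              paste(x$syllable_ids, collapse = " ")))
  invisible(x)
}

#' Render a sentence to spectrogram and envelope arrays at 1000 Hz
#'
#' Each syllable's 8 template columns are expanded piecewise-constant over 8
#' sub-windows of its duration (the inverse of the 8-bin temporal averaging
#' that defines templates), optionally perturbed by rectified Gaussian noise.
#' The envelope is the per-sample spectrogram column sum filtered with a
#' causal 50 ms boxcar (silence assumed before stimulus onset), so it rises
#' at each syllable onset.
#'
#' @param sentence a `sentence_stimulus`
#' @param inventory the `syllable_inventory` it references
#' @param noise_sd standard deviation of additive Gaussian noise, truncated
#'   at zero so channel energies stay nonnegative
#' @param seed integer seed for the noise
#' @return an object of class `stimulus_arrays`: `spectrogram` (6 x T),
#'   `envelope` (length T), `sample_rate` (1000)
#' @export
render_stimulus <- function(sentence, inventory, noise_sd = 0, seed = 1) {
  stopifnot(inherits(sentence, "sentence_stimulus"),
            inherits(inventory, "syllable_inventory"))
  if (any(sentence$syllable_ids < 1 |
          sentence$syllable_ids > inventory$n_syllables)) {
    stop("sentence references syllable ids not present in the inventory")
  }
  durs <- sentence$durations_ms
  total <- sum(durs)
  sg <- matrix(0, 6, total)
  pos <- 0L
  for (k in seq_along(sentence$syllable_ids)) {
    d <- durs[k]
    tpl <- inventory$templates[[sentence$syllable_ids[k]]]
    # sample t (0-based) in syllable belongs to bin b iff
    # floor((b-1)d/8) <= t < floor(bd/8); expand accordingly
    widths <- diff(floor((0:8) * d / 8))
    sg[, pos + seq_len(d)] <- tpl[, rep(1:8, times = widths)]
    pos <- pos + d
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sg <- pmax(sg + matrix(stats::rnorm(length(sg), 0, noise_sd), 6), 0)
  }
  cs <- colSums(sg)
  env <- as.numeric(stats::filter(cs, rep(1 / 50, 50), sides = 1))
  head_n <- min(49L, total)
  env[seq_len(head_n)] <- cumsum(cs[seq_len(head_n)]) / 50
  structure(
    list(spectrogram = sg, envelope = env, sample_rate = 1000),
    class = "stimulus_arrays"
  )
}

#' Average a spectrogram segment into temporal bins
#'
#' Column `b` of the result is the mean of segment columns in the half-open
#' sample window `[floor((b-1) L / n_bins), floor(b L / n_bins))` (0-based).
#' This is the binning that reduces a rendered syllable back to its stored
#' 6 x 8 template.
#'
#' @param segment a numeric matrix with `L >= n_bins` columns
#' @param n_bins number of temporal bins (default 8)
#' @return a matrix with `nrow(segment)` rows and `n_bins` columns
#' @export
binned_average <- function(segment, n_bins = 8) {
  segment <- as.matrix(segment)
  L <- ncol(segment)
  if (L < n_bins) stop("segment must have at least n_bins columns")
  bounds <- floor((0:n_bins) * L / n_bins)
  out <- matrix(0, nrow(segment), n_bins)
  for (b in seq_len(n_bins)) {
    cols <- (bounds[b] + 1):bounds[b + 1]
    out[, b] <- rowMeans(segment[, cols, drop = FALSE])
  }
  out
}

#' Generate a full synthetic corpus
#'
#' Convenience wrapper producing `n_sentences` sentences (with rendered
#' arrays) from one inventory. Per-sentence seeds are derived from `seed` so
#' the whole corpus is a pure function of its arguments.
#'
#' @inheritParams sample_sentence
#' @param n_sentences number of sentences
#' @param noise_sd stimulus noise passed to [render_stimulus()]
#' @param seed master seed
#' @return list with `inventory` and `sentences` (each element: `sentence`,
#'   `arrays`)
#' @export
make_corpus <- function(n_sentences, inventory, n_syl = 5, mean_dur_ms = 200,
                        cv = 0.3, noise_sd = 0.1, seed = 1) {
  sentences <- lapply(seq_len(n_sentences), function(i) {
    s <- sample_sentence(inventory, n_syl, mean_dur_ms, cv,
                         seed = seed * 1000L + i)
    a <- render_stimulus(s, inventory, noise_sd, seed = seed * 1000L + i)
    list(sentence = s, arrays = a)
  })
  list(inventory = inventory, sentences = sentences)
}

#' Write a corpus to a directory of delimited text files
#'
#' One `labels.tsv` table (sentence_id, position, syllable_id, onset_ms,
#' offset_ms) plus per-sentence `sentence_<i>_spectrogram.tsv` and
#' `sentence_<i>_envelope.tsv`, and the inventory as `inventory.tsv`
#' (id, row, values).
#'
#' @param corpus result of [make_corpus()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- do.call(rbind, lapply(seq_along(corpus$sentences), function(i) {
    s <- corpus$sentences[[i]]$sentence
    data.frame(sentence_id = i, position = seq_along(s$syllable_ids),
               syllable_id = s$syllable_ids, onset_ms = s$onsets_ms,
               offset_ms = s$offsets_ms)
  }))
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  inv <- do.call(rbind, lapply(seq_len(corpus$inventory$n_syllables),
    function(k) cbind(id = k, row = 1:6, corpus$inventory$templates[[k]])))
  utils::write.table(inv, file.path(dir, "inventory.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (i in seq_along(corpus$sentences)) {
    a <- corpus$sentences[[i]]$arrays
    utils::write.table(a$spectrogram,
                       file.path(dir, sprintf("sentence_%d_spectrogram.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(envelope = a$envelope),
                       file.path(dir, sprintf("sentence_%d_envelope.tsv", i)),
                       sep = "\t", row.names = FALSE)
  }
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir directory containing `labels.tsv` and per-sentence arrays
#' @return list with `labels` (data frame), `inventory_patterns` (list of
#'   6-row matrices) and `sentences` (list of `spectrogram`/`envelope`)
#' @export
read_corpus <- function(dir) {
  lab <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE,
                           sep = "\t")
  invt <- utils::read.table(file.path(dir, "inventory.tsv"), header = TRUE,
                            sep = "\t")
  ids <- unique(invt$id)
  patterns <- lapply(ids, function(k)
    as.matrix(invt[invt$id == k, -(1:2), drop = FALSE]))
  names(patterns) <- ids
  n_sent <- max(lab$sentence_id)
  sentences <- lapply(seq_len(n_sent), function(i) {
    sg <- as.matrix(utils::read.table(
      file.path(dir, sprintf("sentence_%d_spectrogram.tsv", i)), sep = "\t"))
    env <- utils::read.table(
      file.path(dir, sprintf("sentence_%d_envelope.tsv", i)), header = TRUE,
      sep = "\t")$envelope
    list(spectrogram = unname(sg), envelope = env)
  })
  list(labels = lab, inventory_patterns = patterns, sentences = sentences)
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
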