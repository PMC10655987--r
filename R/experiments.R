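# ---- experiment orchestration: sweeps, bootstrap, paired tests -------------

.default_psis <- c(2, 5, 10, 20, 30, 40, 50, 60)

#' Variant-by-frequency recognition sweep
#'
#' Runs [invert()] for every sentence x variant x modulation frequency and
#' collects all per-sentence metrics in a long-format table. The stationary
#' baseline is computed once per sentence and broadcast across the requested
#' frequencies. Per-sentence inference seeds are derived from `seed`, and
#' are identical across conditions so all comparisons are paired. Sentences
#' that hit a numerical singularity are carried with `status = "singular"`
#' and `NA` metrics.
#'
#' @param corpus result of [make_corpus()]
#' @param variants subset of `"stationary"`, `"identity"`, `"timing"`,
#'   `"full_antiphase"`, `"full_samephase"`
#' @param psis modulation frequencies in Hz (default
#'   `c(2, 5, 10, 20, 30, 40, 50, 60)`)
#' @param seed master seed for inference noise
#' @param opts base [inference_options()]; its seed field is overridden
#'   per sentence
#' @return long data frame: `sentence_id`, `variant`, `psi`, `metric`,
#'   `value`, `status`
#' @export
frequency_sweep <- function(corpus, variants = c("stationary",
                                                 "full_antiphase"),
                            psis = .default_psis, seed = 1,
                            opts = inference_options()) {
  stopifnot(length(corpus$sentences) >= 1, length(variants) >= 1,
            length(psis) >= 1)
  variants <- match.arg(variants, .variants, several.ok = TRUE)
  rows <- list()
  add <- function(i, variant, psi, m) {
    long <- data.frame(
      sentence_id = i, variant = variant, psi = psi,
      metric = c("overlap", "ent_overlap", "lcs_ratio", "integration",
                 "loglik"),
      value = as.numeric(m[1, c("overlap", "ent_overlap", "lcs_ratio",
                                "integration", "loglik")]),
      status = m$status
    )
    rows[[length(rows) + 1L]] <<- long
  }
  for (i in seq_along(corpus$sentences)) {
    sent <- corpus$sentences[[i]]$sentence
    arr <- corpus$sentences[[i]]$arrays
    cand <- sentence_candidates(corpus$inventory, sent)
    o <- opts
    o$seed <- seed * 10000L + i
    for (v in variants) {
      if (v == "stationary") {
        trace <- invert(arr, cand, variant_config("stationary", psis[1]), o)
        m <- evaluate_trace(trace, sent)
        for (psi in psis) add(i, v, psi, m)
      } else {
        for (psi in psis) {
          trace <- invert(arr, cand, variant_config(v, psi), o)
          add(i, v, psi, evaluate_trace(trace, sent))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentile bootstrap of a mean
#'
#' @param values numeric vector (length >= 2; `NA` dropped)
#' @param reps bootstrap replicates (default 10000)
#' @param seed seed
#' @param conf confidence level (default 0.95)
#' @return named vector `mean`, `ci_low`, `ci_high`
#' @export
bootstrap_summary <- function(values, reps = 10000, seed = 1, conf = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(values)
  means <- vapply(seq_len(reps),
                  function(i) mean(values[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  a <- (1 - conf) / 2
  ci <- stats::quantile(means, c(a, 1 - a), names = FALSE)
  c(mean = mean(values), ci_low = ci[1], ci_high = ci[2])
}

# Wilcoxon signed-rank statistic with normal approximation (tie and zero
# corrected), reporting the z statistic alongside the p value
.signed_rank_z <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(c(statistic = NA_real_, z = 0, p = 1, n = 0))
  }
  rk <- rank(abs(d))
  Wp <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (Wp - mu) / sqrt(sig2)
  p <- 2 * stats::pnorm(-abs(z))
  c(statistic = Wp, z = z, p = p, n = n)
}

#' Paired tests of recognition performance across conditions
#'
#' For one metric, compares each contrast condition against a baseline
#' condition with a Wilcoxon signed-rank test (normal approximation with
#' tie correction, as the z statistic is the quantity of interest), applying
#' a Bonferroni threshold `alpha / m`. Sentences missing (excluded) in
#' either member of a pair are dropped from both. Additionally runs a
#' Friedman test across frequencies within each non-stationary variant
#' (with Bonferroni-corrected post-hoc pairwise signed-rank tests) and a
#' two-way analysis of variance with variant as a discrete factor and
#' frequency as a continuous predictor.
#'
#' @param table long results table from [frequency_sweep()]
#' @param metric metric name (default `"overlap"`)
#' @param baseline list with `variant` (and optionally `psi`) defining the
#'   baseline condition; default the stationary variant
#' @param alpha familywise significance level (default 0.05)
#' @param m number of comparisons for the Bonferroni correction (defaults
#'   to the number of contrasts)
#' @return list with `contrasts` (data frame: variant, psi, statistic, z,
#'   p, significant), `threshold`, `friedman` (per-variant chi-squared, df,
#'   p, and post-hoc table), `anova` (data frame)
#' @export
paired_tests <- function(table, metric = "overlap",
                         baseline = list(variant = "stationary"),
                         alpha = 0.05, m = NULL) {
  tb <- table[table$metric == metric, ]
  if (nrow(tb) == 0) stop("metric not present in table")
  base <- tb[tb$variant == baseline$variant, ]
  if (!is.null(baseline$psi)) base <- base[base$psi == baseline$psi, ]
  if (nrow(base) == 0) stop("baseline condition not present")
  base <- base[!duplicated(base$sentence_id), ]

  conds <- unique(tb[tb$variant != baseline$variant, c("variant", "psi")])
  if (is.null(m)) m <- max(1L, nrow(conds))
  thr <- alpha / m
  res <- lapply(seq_len(nrow(conds)), function(k) {
    cc <- tb[tb$variant == conds$variant[k] & tb$psi == conds$psi[k], ]
    merged <- merge(base[, c("sentence_id", "value", "status")],
                    cc[, c("sentence_id", "value", "status")],
                    by = "sentence_id", suffixes = c("_base", "_cond"))
    keep <- merged$status_base == "ok" & merged$status_cond == "ok" &
      !is.na(merged$value_base) & !is.na(merged$value_cond)
    merged <- merged[keep, ]
    if (nrow(merged) < 2) stop("unpaired or insufficient data for contrast")
    st <- .signed_rank_z(merged$value_cond, merged$value_base)
    data.frame(variant = conds$variant[k], psi = conds$psi[k],
               statistic = st[["statistic"]], z = st[["z"]], p = st[["p"]],
               n = st[["n"]], significant = st[["p"]] < thr)
  })
  contrasts <- do.call(rbind, res)

  friedman <- list()
  for (v in setdiff(unique(tb$variant), "stationary")) {
    sub <- tb[tb$variant == v & tb$status == "ok", ]
    wide <- stats::reshape(sub[, c("sentence_id", "psi", "value")],
                           idvar = "sentence_id", timevar = "psi",
                           direction = "wide")
    wide <- wide[stats::complete.cases(wide), -1, drop = FALSE]
    if (nrow(wide) < 2 || ncol(wide) < 2) next
    fr <- stats::friedman.test(as.matrix(wide))
    psis_v <- sort(unique(sub$psi))
    ph <- list()
    np <- length(psis_v) * (length(psis_v) - 1) / 2
    for (a_i in seq_along(psis_v)) {
      for (b_i in seq_len(a_i - 1L)) {
        ci <- match(paste0("value.", psis_v[a_i]), colnames(wide))
        cj <- match(paste0("value.", psis_v[b_i]), colnames(wide))
        st <- .signed_rank_z(wide[[ci]], wide[[cj]])
        ph[[length(ph) + 1]] <- data.frame(
          psi_a = psis_v[a_i], psi_b = psis_v[b_i], z = st[["z"]],
          p_bonferroni = min(1, st[["p"]] * np))
      }
    }
    friedman[[v]] <- list(chisq = unname(fr$statistic),
                          df = unname(fr$parameter),
                          p = fr$p.value,
                          posthoc = do.call(rbind, ph))
  }

  sub <- tb[tb$status == "ok" & !is.na(tb$value), ]
  sub$variant <- factor(sub$variant)
  aovtab <- if (length(levels(sub$variant)) >= 2) {
    fit <- stats::lm(value ~ variant + psi, data = sub)
    as.data.frame(stats::anova(fit))
  } else NULL

  list(contrasts = contrasts, threshold = thr, friedman = friedman,
       anova = aovtab)
}

#' Summarize a sweep by condition
#'
#' Mean and bootstrap confidence interval of one metric per variant x
#' frequency condition.
#'
#' @inheritParams paired_tests
#' @param reps bootstrap replicates
#' @param seed seed
#' @return data frame: `variant`, `psi`, `n`, `mean`, `ci_low`, `ci_high`
#' @export
sweep_summary <- function(table, metric = "overlap", reps = 2000, seed = 1) {
  tb <- table[table$metric == metric & table$status == "ok" &
                !is.na(table$value), ]
  conds <- unique(tb[, c("variant", "psi")])
  out <- lapply(seq_len(nrow(conds)), function(k) {
    v <- tb$value[tb$variant == conds$variant[k] & tb$psi == conds$psi[k]]
    b <- bootstrap_summary(v, reps = reps, seed = seed + k)
    data.frame(variant = conds$variant[k], psi = conds$psi[k],
               n = length(v), mean = b[["mean"]], ci_low = b[["ci_low"]],
               ci_high = b[["ci_high"]])
  })
  out <- do.call(rbind, out)
  out[order(out$variant, out$psi), ]
}
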