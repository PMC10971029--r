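#' Welch two-sample t statistic
#'
#' Unpooled-variance t with Welch-Satterthwaite degrees of freedom. Two
#' identical constant series give t = 0 by convention; zero combined
#' variance with unequal means leaves t undefined and is an error.
#'
#' @param a,b numeric series, each of length >= 2.
#' @return list with `t` and `df`.
#' @export
welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each series needs at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = na + nb - 2))
    stop("zero variance with unequal means: t statistic undefined")
  }
  sa <- va / na; sb <- vb / nb
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  list(t = t, df = df)
}

#' Down-sampled resampling t-test between two frame series
#'
#' Dense trajectory frames are strongly autocorrelated, so a t-test on all
#' frames overstates significance. This procedure draws `m_per_draw`
#' frames from each series (without replacement by default), computes a
#' Welch t per draw, and repeats; the median t over the repetitions is the
#' test statistic. The two-sided p-value evaluates that median t against
#' the t distribution at the median Welch df across repetitions (the raw
#' median t is always reported alongside, since the conversion of a median
#' statistic to a p-value is a convention). Significance uses the
#' conservative default threshold p < 1e-6. Replicates should be pooled
#' into each series before calling.
#'
#' @param variant,wt numeric per-frame series (e.g. energies or PC scores),
#'   each of length >= `m_per_draw`.
#' @param m_per_draw frames per draw (default 100).
#' @param repetitions number of draws (default 1000).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param alpha significance threshold on the p-value (default 1e-6).
#' @param replace draw with replacement instead (default FALSE: each draw
#'   is a subset).
#' @param stride optional frame thinning applied to both series before
#'   drawing (keep every `stride`-th frame), a crude autocorrelation knob.
#' @return object of class `resampling_test`: `median_t`, `median_df`,
#'   `p_value`, `significant`, `direction` (sign of variant-minus-wt pooled
#'   median: -1, 0, +1), `t_values`, and the provenance fields
#'   `m_per_draw`, `repetitions`, `seed`, `alpha`, `replace`, `stride`.
#' @export
downsample_test <- function(variant, wt, m_per_draw = 100L, repetitions = 1000L,
                            seed = 1L, alpha = 1e-6, replace = FALSE,
                            stride = 1L) {
  variant <- as.numeric(variant); wt <- as.numeric(wt)
  if (stride > 1L) {
    variant <- variant[seq(1L, length(variant), by = stride)]
    wt <- wt[seq(1L, length(wt), by = stride)]
  }
  nv <- length(variant); nw <- length(wt)
  m <- as.integer(m_per_draw)
  if (!replace && (nv < m || nw < m))
    stop(sprintf("series lengths (%d, %d) are below m_per_draw = %d; reduce m_per_draw",
                 nv, nw, m))
  if (m < 2L) stop("m_per_draw must be >= 2")
  reps <- as.integer(repetitions)
  ts <- numeric(reps); dfs <- numeric(reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      sv <- variant[sample.int(nv, m, replace = replace)]
      sw <- wt[sample.int(nw, m, replace = replace)]
      wt_r <- welch_t(sv, sw)
      ts[r] <- wt_r$t; dfs[r] <- wt_r$df
    }
  })
  median_t <- stats::median(ts)
  median_df <- stats::median(dfs)
  p <- 2 * stats::pt(-abs(median_t), df = median_df)
  p <- max(p, .Machine$double.xmin)  # keep in (0, 1]
  dmed <- stats::median(variant) - stats::median(wt)
  structure(list(median_t = median_t, median_df = median_df, p_value = p,
                 significant = p < alpha,
                 direction = sign(dmed),
                 t_values = ts,
                 m_per_draw = m, repetitions = reps, seed = as.integer(seed),
                 alpha = alpha, replace = replace, stride = as.integer(stride)),
            class = "resampling_test")
}

#' @export
print.resampling_test <- function(x, ...) {
  cat(sprintf(
    "resampling_test: median t = %.3f (df %.1f), p = %.3g (%ssignificant at %g)\n",
    x$median_t, x$median_df, x$p_value, if (x$significant) "" else "not ",
    x$alpha))
  cat(sprintf("  %d repetitions of %d frames each (seed %d, %s replacement)\n",
              x$repetitions, x$m_per_draw, x$seed,
              if (x$replace) "with" else "without"))
  invisible(x)
}

#' Serialise a resampling test result to JSON (with full provenance)
#' @param test a `resampling_test`.
#' @param path optional file; if `NULL`, the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
test_to_json <- function(test, path = NULL) {
  obj <- test[c("median_t", "median_df", "p_value", "significant", "direction",
                "m_per_draw", "repetitions", "seed", "alpha", "replace", "stride")]
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
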