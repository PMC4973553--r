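## Screen statistics: mutational frequency and clonogenic efficiency of the
## thioguanine assay, the exact Poisson rate-ratio test (conditional
## binomial with Clopper-Pearson interval), the exact two-sided binomial
## test, and 40-bp windowed variant profiles with region comparisons.

#' Mutational frequency of the forward screen
#'
#' `-ln(X_S / N_S) / -ln(X_0 / N_0)` where `N` is the number of cells
#' seeded and `X` the number of colonies formed with (S) and without (0)
#' selection. Equals 1 when the two colony fractions are equal.
#'
#' @param x_s,n_s colonies and cells seeded with selection
#' @param x_0,n_0 colonies and cells seeded without selection
#' @return the mutational frequency (positive number)
#' @export
mutational_frequency <- function(x_s, n_s, x_0, n_0) {
  counts <- c(x_s, n_s, x_0, n_0)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("all counts must be positive (a zero colony count leaves the frequency undefined)")
  if (x_s > n_s || x_0 > n_0) stop("colonies cannot exceed cells seeded")
  log(x_s / n_s) / log(x_0 / n_0)
}

#' Fractional clonogenic efficiency
#'
#' @param colonies colonies formed
#' @param seeded cells seeded (> 0)
#' @return `colonies / seeded`
#' @export
clonogenic_efficiency <- function(colonies, seeded) {
  if (seeded <= 0) stop("seeded must be positive")
  if (colonies < 0 || colonies > seeded)
    stop("need 0 <= colonies <= seeded")
  colonies / seeded
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile form: lower bound `qbeta(a/2, x, n - x + 1)` (0 when
#' `x = 0`), upper bound `qbeta(1 - a/2, x + 1, n - x)` (1 when `x = n`).
#' Coverage is at least `conf_level` by construction.
#'
#' @param x successes, `0 <= x <= n`
#' @param n trials, `n >= 1`
#' @param conf_level confidence level (default 0.95)
#' @return numeric `c(low, high)`
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  if (n < 1L || x < 0L || x > n) stop("need 0 <= x <= n, n >= 1")
  if (conf_level <= 0 || conf_level >= 1) stop("conf_level must lie in (0,1)")
  a <- 1 - conf_level
  low <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(low, high)
}

## two-sided exact binomial p by the minlike convention: the sum of all
## point probabilities not exceeding the observed one (with the customary
## (1 + 1e-7) relative tie tolerance)
minlike_p <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  dobs <- d[k + 1L]
  min(1, sum(d[d <= dobs * (1 + 1e-7)]))
}

central_p <- function(k, n, p0) {
  min(1, 2 * min(pbinom(k, n, p0), 1 - pbinom(k - 1L, n, p0)))
}

#' Exact Poisson rate-ratio test
#'
#' Compares two event counts with exposures by conditioning on the total:
#' given `n = c1 + c2`, `c1` is binomial with success probability
#' `t1 / (t1 + t2)` under the null of equal rates. The two-sided p-value
#' sums binomial point probabilities no larger than the observed one
#' (`"minlike"`, the exact-reference-distribution convention; `"central"`
#' doubles the smaller tail). The confidence interval is the
#' Clopper-Pearson interval for the conditional proportion, transformed to
#' the rate-ratio scale by `(pi / (1 - pi)) * (t2 / t1)`; at `c1 = 0` it is
#' `[0, U]`, at `c2 = 0` it is `[L, Inf)` with an infinite estimate.
#'
#' @param c1,c2 event counts (non-negative, `c1 + c2 >= 1`)
#' @param t1,t2 exposures (positive)
#' @param conf_level confidence level (default 0.95)
#' @param alternative p-value convention, `"minlike"` or `"central"`
#' @return a `RateRatioResult` list: `rate_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `conf_level`
#' @export
exact_poisson_rate_ratio_test <- function(c1, t1, c2, t2, conf_level = 0.95,
                                          alternative = c("minlike", "central")) {
  alternative <- match.arg(alternative)
  if (c1 < 0 || c2 < 0) stop("counts must be non-negative")
  if (t1 <= 0 || t2 <= 0) stop("exposures must be positive")
  if (c1 + c2 < 1) stop("at least one event is required")
  n <- c1 + c2
  pi0 <- t1 / (t1 + t2)
  p <- if (alternative == "minlike") minlike_p(c1, n, pi0) else central_p(c1, n, pi0)
  ci_pi <- clopper_pearson(c1, n, conf_level)
  to_ratio <- function(q) if (q >= 1) Inf else (q / (1 - q)) * (t2 / t1)
  est <- if (c2 == 0) Inf else (c1 / t1) / (c2 / t2)
  structure(
    list(rate_ratio = est, ci_low = to_ratio(ci_pi[1L]),
         ci_high = to_ratio(ci_pi[2L]), p_value = p, conf_level = conf_level),
    class = "RateRatioResult"
  )
}

#' @export
print.RateRatioResult <- function(x, ...) {
  cat(sprintf("Exact Poisson rate ratio: %.4g (%g%% CI %.4g-%.4g), p = %.4g\n",
              x$rate_ratio, 100 * x$conf_level, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Exact two-sided binomial enrichment test
#'
#' Minlike convention: p is the sum of binomial point probabilities not
#' exceeding the observed one under `p0`.
#'
#' @param k observed successes
#' @param n_trials trials
#' @param p0 null success probability, strictly inside (0,1)
#' @param alternative `"minlike"` (default) or `"central"`
#' @return the p-value
#' @export
binomial_enrichment_test <- function(k, n_trials, p0,
                                     alternative = c("minlike", "central")) {
  alternative <- match.arg(alternative)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly inside (0,1)")
  if (k < 0 || k > n_trials) stop("need 0 <= k <= n_trials")
  if (alternative == "minlike") minlike_p(k, n_trials, p0) else central_p(k, n_trials, p0)
}

#' Windowed variant profile
#'
#' Tiles `[0, locus length)` in non-overlapping 40-bp windows (the last
#' window may be short), assigns each variant's supporting reads to the
#' window containing its start position, and labels a window exonic iff it
#' overlaps at least one exon base.
#'
#' @param variants small-variant `data.frame`
#' @param locus a [locus_reference()]
#' @param window_len window length (default 40)
#' @param depth total reads per window; defaults to the maximum
#'   `total_reads` seen among the variants (uniform-coverage assumption)
#' @return `data.frame` with `window_start`, `window_len`, `event_reads`,
#'   `total_reads`, `frequency`, `region`
#' @export
window_profile <- function(variants, locus, window_len = 40L, depth = NULL) {
  L <- nchar(locus$sequence)
  if (nrow(variants) && (any(variants$pos < 0L) || any(variants$pos >= L)))
    stop("variant position outside the locus")
  if (is.null(depth)) {
    if (nrow(variants) == 0L)
      stop("depth must be given when there are no variants")
    depth <- max(variants$total_reads)
  }
  starts <- seq.int(0L, L - 1L, by = window_len)
  ends <- pmin(starts + window_len, L)
  ev <- integer(length(starts))
  if (nrow(variants)) {
    w <- variants$pos %/% window_len + 1L
    agg <- tapply(variants$supporting_reads, w, sum)
    ev[as.integer(names(agg))] <- as.integer(agg)
  }
  exonic <- vapply(seq_along(starts), function(i)
    any(locus$exons$start < ends[i] & locus$exons$end > starts[i]), logical(1L))
  data.frame(
    window_start = starts, window_len = ends - starts,
    event_reads = ev, total_reads = as.integer(depth),
    frequency = ev / depth,
    region = ifelse(exonic, "exonic", "intronic"),
    stringsAsFactors = FALSE
  )
}

#' Compare windowed profiles by region
#'
#' Aggregates event and total reads within each region class (exonic,
#' intronic) and applies the exact Poisson rate-ratio test with exposures
#' equal to the total reads. The reported rate ratio is the rate in
#' `profile_b` relative to `profile_a` (so with `a` = unselected and
#' `b` = selected, an exonic excess under selection gives a ratio > 1).
#'
#' @param profile_a,profile_b [window_profile()] results over the same
#'   windows
#' @param conf_level confidence level (default 0.95)
#' @return named list (`exonic`, `intronic`) of `RateRatioResult`s, each
#'   with the aggregated counts attached
#' @export
compare_region_frequencies <- function(profile_a, profile_b, conf_level = 0.95) {
  if (!identical(profile_a$window_start, profile_b$window_start))
    stop("profiles must cover the same windows")
  out <- list()
  for (region in c("exonic", "intronic")) {
    ia <- profile_a$region == region
    ea <- sum(profile_a$event_reads[ia]); ta <- sum(as.numeric(profile_a$total_reads[ia]))
    eb <- sum(profile_b$event_reads[ia]); tb <- sum(as.numeric(profile_b$total_reads[ia]))
    if (ta == 0 || tb == 0) stop("zero total reads in region ", region)
    res <- exact_poisson_rate_ratio_test(eb, tb, ea, ta, conf_level)
    res$events_a <- ea; res$events_b <- eb
    res$total_a <- ta; res$total_b <- tb
    out[[region]] <- res
  }
  out
}
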