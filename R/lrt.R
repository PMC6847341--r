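# Log-likelihood-ratio tests on estimated mutation frequencies. Replicates
# within a condition are pooled (concatenated) for the condition-level
# estimate: that is the maximum-likelihood fit under the shared-frequency
# hypothesis, and replicate heterogeneity is tested separately by
# lrt_within().

P_FLOOR <- 1e-320      # printable floor; avoids -log10 of an underflow
NEG10LOG10_CAP <- 3200

as_group <- function(x) {
  if (inherits(x, "m7g_obs")) list(x)
  else if (is.list(x)) x
  else stop("expected an observation set or a list of observation sets")
}

test_result <- function(statistic, df, log_p, extra = list()) {
  p <- max(exp(log_p), P_FLOOR)
  neg10 <- min(-10 * log_p / log(10), NEG10LOG10_CAP)
  structure(c(list(statistic = statistic, df = df, p_value = p,
                   neg10log10_p = max(neg10, 0)), extra),
            class = "m7g_test")
}

untestable_result <- function(extra = list()) {
  structure(c(list(statistic = NA_real_, df = NA_integer_,
                   p_value = NA_real_, neg10log10_p = NA_real_,
                   untestable = TRUE), extra),
            class = "m7g_test")
}

#' @export
print.m7g_test <- function(x, ...) {
  if (isTRUE(x$untestable)) cat("<m7g_test> untestable (insufficient data)\n")
  else cat(sprintf("<m7g_test> LRT = %.4g on %d df, p = %.4g\n",
                   x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Between-condition likelihood-ratio test
#'
#' Tests whether the treated and control mutation frequencies differ at one
#' position. Null: a single frequency for the pooled treated+control
#' observations. Alternative: one frequency per condition, each fitted on
#' its pooled replicates. The statistic `2 * (l1 - l0)` (clamped at 0) is
#' referred to chi-square with 1 degree of freedom; when the null estimate
#' sits at the boundary `f = 0` the plain chi-square reference is kept,
#' which is conservative. The test is two-sided: a negative rate difference
#' can be as significant as a positive one.
#'
#' @param treated,control an `m7g_obs` observation set or a list of them
#'   (replicates; pooled by concatenation).
#' @param tol,max_iter passed to [estimate_rate_em()].
#' @return an `m7g_test`: `statistic`, `df`, `p_value` (floored at
#'   `1e-320`), `neg10log10_p` (capped at 3200), plus the fitted
#'   `f_treated`, `f_control`, `f_pooled` and the group sizes. If either
#'   condition has zero observations the result is marked `untestable`.
#' @examples
#' tr <- obs_set(n_match = 80, n_sub = 20)
#' ct <- obs_set(n_match = 100)
#' lrt_between(tr, ct)
#' @export
lrt_between <- function(treated, control, tol = 1e-8, max_iter = 200L) {
  tr <- pool_obs(as_group(treated))
  ct <- pool_obs(as_group(control))
  if (n_obs(tr) == 0 || n_obs(ct) == 0)
    return(untestable_result(list(
      f_treated = if (n_obs(tr) > 0) estimate_rate_em(tr)$f_hat else NA_real_,
      f_control = if (n_obs(ct) > 0) estimate_rate_em(ct)$f_hat else NA_real_,
      n_treated = n_obs(tr), n_control = n_obs(ct))))
  fit_t <- estimate_rate_em(tr, tol, max_iter)
  fit_c <- estimate_rate_em(ct, tol, max_iter)
  pooled <- pool_obs(tr, ct)
  fit_0 <- estimate_rate_em(pooled, tol, max_iter)
  stat <- max(0, 2 * (fit_t$log_likelihood + fit_c$log_likelihood -
                        fit_0$log_likelihood))
  log_p <- pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  test_result(stat, 1L, log_p,
              list(f_treated = fit_t$f_hat, f_control = fit_c$f_hat,
                   f_pooled = fit_0$f_hat,
                   n_treated = n_obs(tr), n_control = n_obs(ct),
                   untestable = FALSE))
}

#' Within-group replicate-heterogeneity likelihood-ratio test
#'
#' Tests whether replicates of one condition share a common mutation
#' frequency. Null: one shared frequency fitted on the pooled replicates.
#' Alternative: one frequency per replicate. The statistic is referred to
#' chi-square with `k - 1` degrees of freedom for `k` contributing
#' replicates; replicates with zero observations are dropped first, and
#' with fewer than two contributing replicates the test is skipped
#' (untestable marker).
#'
#' @param group list of `m7g_obs` observation sets, one per replicate.
#' @param tol,max_iter passed to [estimate_rate_em()].
#' @return an `m7g_test` with `f_replicates` (per-replicate estimates,
#'   including `NA` for empty replicates) and `f_pooled`.
#' @examples
#' reps <- list(obs_set(n_match = 90, n_sub = 10),
#'              obs_set(n_match = 88, n_sub = 12))
#' lrt_within(reps)
#' @export
lrt_within <- function(group, tol = 1e-8, max_iter = 200L) {
  group <- as_group(group)
  f_all <- vapply(group, function(g)
    if (n_obs(g) > 0) estimate_rate_em(g, tol, max_iter)$f_hat else NA_real_, 0)
  use <- vapply(group, function(g) n_obs(g) > 0, TRUE)
  k <- sum(use)
  if (k < 2L)
    return(untestable_result(list(f_replicates = f_all)))
  fits <- lapply(group[use], estimate_rate_em, tol = tol, max_iter = max_iter)
  ll1 <- sum(vapply(fits, `[[`, 0, "log_likelihood"))
  pooled <- pool_obs(group[use])
  fit_0 <- estimate_rate_em(pooled, tol, max_iter)
  stat <- max(0, 2 * (ll1 - fit_0$log_likelihood))
  df <- k - 1L
  log_p <- pchisq(stat, df = df, lower.tail = FALSE, log.p = TRUE)
  test_result(stat, df, log_p,
              list(f_replicates = f_all, f_pooled = fit_0$f_hat,
                   untestable = FALSE))
}

#' Mutation rate difference
#'
#' The method's primary effect size: the estimated control mutation
#' frequency subtracted from the estimated treated frequency. May be
#' negative.
#'
#' @param f_treated,f_control frequencies in `[0, 1]`.
#' @return `f_treated - f_control`.
#' @examples
#' mutation_rate_difference(0.10, 0.00)
#' @export
mutation_rate_difference <- function(f_treated, f_control) {
  for (x in c(f_treated, f_control))
    if (!is.na(x) && (x < 0 || x > 1)) stop("frequencies must lie in [0, 1]")
  f_treated - f_control
}
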