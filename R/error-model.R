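# Two-class per-read emission model. Each aligned observation comes either
# from a reference template or from a mutated (abasic-site-derived)
# template; f is the fraction of mutated templates at the site. With
# per-read error probability e:
#
#   observation      P(o | reference)   P(o | mutated)
#   match            1 - e              e / 3
#   substitution     e                  1 - e/3
#   indel            e                  1 - e
#
# The e/3 factor is the uniform-miscall convention on the 4-letter channel
# (a miscalled mutated base reverts to the reference a third of the time);
# the indel/substitution partition is not a 4-letter channel, so indel-kind
# observations use e without the /3. Any non-reference identity is pooled
# into one "mutated" class, matching how abasic read-through produces all
# mutation types.

#' Convert Phred+33 quality characters to error probabilities
#'
#' Returns `10^(-Q/10)` with `Q = code - 33`, capped at 0.75 to keep the
#' two-class likelihood identifiable (an error probability above 3/4 would
#' make a miscall more likely than a correct call under either class).
#'
#' @param quality_char character vector of single Phred+33 characters (for
#'   example `"I"` is Q40).
#' @return numeric vector of error probabilities in `[0, 0.75]`.
#' @examples
#' phred_to_error(c("!", "+", "I"))  # 0.75 (capped), 0.1, 1e-4
#' @export
phred_to_error <- function(quality_char) {
  code <- utf8ToInt(paste(quality_char, collapse = ""))
  if (any(code < 33L | code > 126L))
    stop("quality character code outside [33, 126]")
  phred_to_error_q(code - 33L)
}

# numeric-Q path used internally (Q = code - 33, already offset)
phred_to_error_q <- function(q) pmin(10^(-q / 10), 0.75)

# ---- observation sets -----------------------------------------------------
# An observation set is the per-sample input to the estimator: observations
# aggregated by (model class, error probability) with counts, since the
# likelihood depends on nothing else. Class is one of "match", "sub",
# "indel".

obs_set_new <- function(class, error_prob, n) {
  structure(
    data.frame(class = class, error_prob = error_prob, n = as.numeric(n),
               stringsAsFactors = FALSE),
    class = c("m7g_obs", "data.frame"))
}

empty_obs_set <- function() obs_set_new(character(), numeric(), numeric())

#' Build an observation set from counts
#'
#' Convenience constructor for the estimator input: `n_match` reference
#' matches, `n_sub` substitutions and `n_indel` indel observations, all
#' with the same error probability.
#'
#' @param n_match,n_sub,n_indel non-negative counts.
#' @param error_prob shared per-read error probability (capped at 0.75).
#' @return an `m7g_obs` observation set.
#' @examples
#' obs_set(n_match = 90, n_sub = 10, error_prob = 1e-3)
#' @export
obs_set <- function(n_match = 0, n_sub = 0, n_indel = 0, error_prob = 0) {
  stop_if_not_scalar_prob(error_prob, "error_prob")
  e <- min(error_prob, 0.75)
  cls <- c("match", "sub", "indel")
  n <- c(n_match, n_sub, n_indel)
  keep <- n > 0
  obs_set_new(cls[keep], rep(e, sum(keep)), n[keep])
}

#' Build an observation set from tokenized observations
#'
#' Collapses the output of [tokenize_bases()] into the aggregated form used
#' by the estimator. `N` calls are discarded (uninformative under the
#' two-class model); insertion and deletion kinds are pooled into one
#' `indel` class.
#'
#' @param obs data frame from [tokenize_bases()].
#' @return an `m7g_obs` observation set.
#' @export
as_obs_set <- function(obs) {
  if (nrow(obs) == 0L) return(empty_obs_set())
  keep <- obs$observed_base != "N"
  obs <- obs[keep, , drop = FALSE]
  if (nrow(obs) == 0L) return(empty_obs_set())
  cls <- c(reference_match = "match", substitution = "sub",
           insertion = "indel", deletion = "indel")[as.character(obs$kind)]
  e <- pmin(obs$error_prob, 0.75)
  key <- paste(cls, format(e, digits = 15), sep = "\r")
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  obs_set_new(cls[first], e[first],
              as.vector(tapply(rep(1, length(idx)), idx, sum)))
}

#' Pool observation sets
#'
#' Concatenates replicate observation sets (the maximum-likelihood pooled
#' data under a shared-frequency hypothesis) and re-aggregates.
#'
#' @param ... `m7g_obs` objects or lists of them.
#' @return an `m7g_obs` observation set.
#' @export
pool_obs <- function(...) {
  parts <- list(...)
  flat <- list()
  for (p in parts) {
    if (inherits(p, "m7g_obs")) flat[[length(flat) + 1L]] <- p
    else flat <- c(flat, p)
  }
  if (length(flat) == 0L) return(empty_obs_set())
  df <- do.call(rbind, lapply(flat, as.data.frame))
  if (nrow(df) == 0L) return(empty_obs_set())
  key <- paste(df$class, format(df$error_prob, digits = 15), sep = "\r")
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  obs_set_new(df$class[first], df$error_prob[first],
              as.vector(tapply(df$n, idx, sum)))
}

n_obs <- function(obs) sum(obs$n)
n_mutated <- function(obs) sum(obs$n[obs$class != "match"])

# per-class emission probabilities
emission_probs <- function(obs) {
  e <- obs$error_prob
  p_ref <- ifelse(obs$class == "match", 1 - e, e)
  p_mut <- ifelse(obs$class == "match", e / 3,
                  ifelse(obs$class == "sub", 1 - e / 3, 1 - e))
  list(p_ref = p_ref, p_mut = p_mut)
}

#' Site log-likelihood of a mutation frequency
#'
#' Log-likelihood of mutated-template fraction `f` for an observation set
#' under the two-class per-read mixture:
#' `sum_i n_i * log(f * P(o_i | mutated) + (1 - f) * P(o_i | reference))`.
#' An empty set has log-likelihood 0; an impossible datum (for example a
#' mismatch with error probability 0 at `f = 0`) yields `-Inf`.
#'
#' @param f mutation frequency in `[0, 1]` (may be a vector).
#' @param obs an `m7g_obs` observation set.
#' @return numeric log-likelihood, one value per element of `f`.
#' @examples
#' site_log_likelihood(0.1, obs_set(n_match = 90, n_sub = 10, error_prob = 0.001))
#' @export
site_log_likelihood <- function(f, obs) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("'f' must lie in [0, 1]")
  if (nrow(obs) == 0L) return(rep(0, length(f)))
  p <- emission_probs(obs)
  vapply(f, function(fi)
    sum(obs$n * log(fi * p$p_mut + (1 - fi) * p$p_ref)), 0)
}

#' Maximum-likelihood mutation frequency by EM
#'
#' Estimates the mutated-template fraction at one site by
#' expectation-maximization: the E-step computes the posterior probability
#' that each read came from a mutated template,
#' `w_i = f p_mut_i / (f p_mut_i + (1 - f) p_ref_i)`, and the M-step sets
#' `f` to the (count-weighted) mean of the `w_i`. The log-likelihood is
#' non-decreasing across iterations. With all error probabilities 0 the
#' estimate equals the raw mutated fraction `k/n` exactly; mismatch-free
#' (or mismatch-only) data sit at the boundary optimum 0 (or 1).
#'
#' @param obs an `m7g_obs` observation set.
#' @param tol convergence tolerance on `|delta f|` (default `1e-8`).
#' @param max_iter maximum EM iterations (default 200).
#' @param trace if `TRUE`, attach the per-iteration log-likelihood trace as
#'   attribute `"ll_trace"`.
#' @return an object of class `m7g_rate`: list with `f_hat`,
#'   `log_likelihood`, `n_obs`, `iterations`, `converged`. An empty set
#'   returns `f_hat = NA` with `n_obs = 0` (undefined estimate, not an
#'   error).
#' @examples
#' estimate_rate_em(obs_set(n_match = 180, n_sub = 20, error_prob = 0.01))
#' @export
estimate_rate_em <- function(obs, tol = 1e-8, max_iter = 200L, trace = FALSE) {
  N <- n_obs(obs)
  if (N == 0)
    return(structure(list(f_hat = NA_real_, log_likelihood = NA_real_,
                          n_obs = 0L, iterations = 0L, converged = NA),
                     class = "m7g_rate"))
  k <- n_mutated(obs)
  f <- k / N
  # boundary optima: mismatch-free data maximize at f = 0, mismatch-only at
  # f = 1 (emission probabilities are ordered for e < 0.75)
  if (f == 0 || f == 1) {
    ll <- site_log_likelihood(f, obs)
    out <- structure(list(f_hat = f, log_likelihood = ll,
                          n_obs = as.integer(N), iterations = 0L,
                          converged = TRUE), class = "m7g_rate")
    if (trace) attr(out, "ll_trace") <- ll
    return(out)
  }
  p <- emission_probs(obs)
  lls <- if (trace) numeric(max_iter) else NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    num <- f * p$p_mut
    w <- num / (num + (1 - f) * p$p_ref)
    f_new <- sum(obs$n * w) / N
    if (trace) lls[it] <- site_log_likelihood(f_new, obs)
    if (abs(f_new - f) < tol) { f <- f_new; converged <- TRUE; break }
    f <- f_new
  }
  out <- structure(list(f_hat = f, log_likelihood = site_log_likelihood(f, obs),
                        n_obs = as.integer(N), iterations = it,
                        converged = converged), class = "m7g_rate")
  if (trace) attr(out, "ll_trace") <- lls[seq_len(it)]
  out
}

#' @export
print.m7g_rate <- function(x, ...) {
  cat(sprintf("<m7g_rate> f_hat = %s (n = %d, %d EM iteration(s), %s)\n",
              format(x$f_hat, digits = 6), x$n_obs, x$iterations,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}
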