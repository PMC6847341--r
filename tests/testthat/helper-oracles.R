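# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: the likelihood is evaluated read by
# read from its definition, binomial LRTs are written in closed form, and
# the power oracle inverts the exact test by brute force.

# naive per-read evaluation of the two-class mixture log-likelihood on an
# expanded observation list (data frame with columns mutated, indel, err)
naive_loglik <- function(f, reads) {
  ll <- 0
  for (i in seq_len(nrow(reads))) {
    e <- reads$err[i]
    if (reads$indel[i]) {
      p_ref <- e; p_mut <- 1 - e
    } else if (reads$mutated[i]) {
      p_ref <- e; p_mut <- 1 - e / 3
    } else {
      p_ref <- 1 - e; p_mut <- e / 3
    }
    ll <- ll + log(f * p_mut + (1 - f) * p_ref)
  }
  ll
}

# expand an aggregated observation set into per-read rows
expand_obs <- function(obs) {
  idx <- rep(seq_len(nrow(obs)), obs$n)
  data.frame(mutated = obs$class[idx] != "match",
             indel = obs$class[idx] == "indel",
             err = obs$error_prob[idx])
}

# random observation set with mixed qualities
random_obs <- function(n_max = 50L) {
  n <- sample(1:n_max, 1L)
  q <- sample(c(10L, 20L, 30L, 40L), n, replace = TRUE)
  cls <- sample(c("match", "sub", "indel"), n, replace = TRUE,
                prob = c(0.8, 0.15, 0.05))
  pool_obs(lapply(seq_len(n), function(i)
    obs_set(n_match = (cls[i] == "match") * 1L,
            n_sub = (cls[i] == "sub") * 1L,
            n_indel = (cls[i] == "indel") * 1L,
            error_prob = 10^(-q[i] / 10))))
}

# 1-D grid-search maximizer of the site log-likelihood
grid_argmax <- function(obs, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  ll <- site_log_likelihood(grid, obs)
  grid[which.max(ll)]
}

# closed-form binomial log-likelihood (0*log(0) = 0 convention)
binom_ll <- function(k, n, p) {
  t1 <- if (k == 0) 0 else k * log(p)
  t2 <- if (k == n) 0 else (n - k) * log(1 - p)
  t1 + t2
}

# closed-form two-sample binomial LRT statistic
binom_lrt2 <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2; p0 <- (k1 + k2) / (n1 + n2)
  2 * (binom_ll(k1, n1, p1) + binom_ll(k2, n2, p2) -
         binom_ll(k1, n1, p0) - binom_ll(k2, n2, p0))
}

# closed-form k-sample binomial heterogeneity LRT statistic
binom_lrtk <- function(k, n) {
  p0 <- sum(k) / sum(n)
  2 * sum(mapply(function(ki, ni)
    binom_ll(ki, ni, ki / ni) - binom_ll(ki, ni, p0), k, n))
}

# exact power oracle at error 0, control rate 0: brute-force inversion of
# the test (smallest treated count whose p-value beats alpha when the
# control count is 0), then the binomial tail at that cut
power_oracle <- function(depth_t, depth_c, rate, alpha) {
  k_star <- NA_integer_
  for (k in 0:depth_t) {
    stat <- binom_lrt2(k, depth_t, 0, depth_c)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    if (p < alpha) { k_star <- k; break }
  }
  if (is.na(k_star)) return(0)
  pbinom(k_star - 1L, depth_t, rate, lower.tail = FALSE)
}

# exact null rejection probabilities (no Monte-Carlo error): the p-value
# depends only on the count tuple, whose distribution is binomial, so the
# rejection probability is an enumerable sum (tail mass beyond k_max is
# negligible at the depths used)
exact_type1_between <- function(depth, bg, alpha = 0.05, k_max = 15L) {
  ks <- 0:k_max
  wk <- dbinom(ks, depth, bg)
  pmat <- outer(ks, ks, Vectorize(function(a, b)
    lrt_between(obs_set(depth - a, a), obs_set(depth - b, b))$p_value))
  sum(outer(wk, wk) * (pmat < alpha))
}

exact_type1_within3 <- function(depth, bg, alpha = 0.05, k_max = 15L) {
  ks <- 0:k_max
  wk <- dbinom(ks, depth, bg)
  g <- expand.grid(a = ks, b = ks, c = ks)
  pv <- mapply(function(a, b, c)
    lrt_within(list(obs_set(depth - a, a), obs_set(depth - b, b),
                    obs_set(depth - c, c)))$p_value, g$a, g$b, g$c)
  sum(wk[g$a + 1L] * wk[g$b + 1L] * wk[g$c + 1L] * (pv < alpha))
}

# independent pileup-column builder for parser tests
pileup_line <- function(ref = "ref", pos = 1L, base = "G", ...) {
  cols <- list(...)
  paste(ref, pos, base, paste(unlist(cols), collapse = "\t"), sep = "\t")
}
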