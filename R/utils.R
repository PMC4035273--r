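# Internal numerical helpers shared across modules.

# NA-aware per-row group means/variances computed with matrix sums; Y is a
# peaks x samples matrix, idx a logical or integer column selector.
row_group_stats <- function(Y, idx) {
  X <- Y[, idx, drop = FALSE]
  obs <- !is.na(X)
  X0 <- X
  X0[!obs] <- 0
  n <- rowSums(obs)
  s <- rowSums(X0)
  m <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums(X0^2)
  v <- ifelse(n > 1, (ss - n * m^2) / (n - 1), NA_real_)
  v[v < 0] <- 0 # guard against tiny negative round-off
  list(mean = m, var = v, n = n)
}

# Vectorized two-sample t test over rows. Welch by default; the pooled
# variance form is available for sensitivity analyses.
row_t_test <- function(Y, idx1, idx2, var_equal = FALSE) {
  g1 <- row_group_stats(Y, idx1)
  g2 <- row_group_stats(Y, idx2)
  d <- g1$mean - g2$mean
  ok <- g1$n >= 2 & g2$n >= 2
  if (var_equal) {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$var + (g2$n - 1) * g2$var) / df
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    a <- g1$var / g1$n
    b <- g2$var / g2$n
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (g1$n - 1) + b^2 / (g2$n - 1))
  }
  t <- d / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  t[!ok] <- NA_real_
  p[!ok] <- NA_real_
  tibble(
    statistic = t, df = df, p_value = p, estimate = d,
    n1 = g1$n, n2 = g2$n
  )
}

# Add-one Monte-Carlo p value: exceed counts among n_perm null draws.
add_one_p <- function(n_exceed, n_perm) (1 + n_exceed) / (n_perm + 1)

# Permutation q values: the FDR estimated at every observed p level as
# (mean permuted discovery count at that level) / (observed discovery
# count at that level), clipped to [0, 1] and made monotone non-decreasing
# in p. `null_counts[i]` is the total count, over all permutations, of
# permuted p values at or below p_obs[i].
perm_q_values <- function(p_obs, null_counts, n_perm) {
  q <- rep(NA_real_, length(p_obs))
  ok <- which(!is.na(p_obs))
  if (length(ok) == 0 || n_perm == 0) return(q)
  p <- p_obs[ok]
  r <- findInterval(p, sort(p)) # observed discoveries at each level
  raw <- pmin(1, (null_counts[ok] / n_perm) / r)
  o <- order(p, decreasing = TRUE)
  raw[o] <- cummin(raw[o])
  q[ok] <- raw
  q
}

# Stage seeds derived from one user seed by a fixed counter scheme, kept
# below 2^31 so they remain valid R integers.
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 1009 + stage * 9973) %% 2147483647L)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive number"))
  }
  invisible(x)
}
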