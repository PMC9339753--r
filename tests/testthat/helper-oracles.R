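# Independent oracles used across the suite. Each is deliberately coded
# by a different route than the package's implementation.

# Simple OLS via the normal equations solved with matrix algebra.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r2 = 1 - ss_res / ss_tot,
       residuals = as.numeric(y - yhat))
}

# Exact 1-D k-means by dynamic programming over sorted values: the
# optimal k-partition of sorted data is contiguous, so minimise total
# within-segment SS over all contiguous splits.
kmeans_dp_ss <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg_ss <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  for (j in 1:n) dp[1, j] <- seg_ss(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf
        for (i in m:j) {
          cand <- dp[m - 1, i - 1] + seg_ss(i, j)
          if (cand < best) best <- cand
        }
        dp[m, j] <- best
      }
    }
  }
  dp[k, n]
}

# Exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1)
# assignments of the pooled values to the first sample.
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Small, fast simulated study shared by several tests.
small_study <- function(seed = 42, n_lit = 3, n_pel = 3, n_loops = 25) {
  cfg <- sim_config(n_littoral = n_lit, n_pelagic = n_pel,
                    n_loops = n_loops)
  simulate_study(cfg, seed = seed)
}

# Build a synthetic measurement-phase slope table directly.
fake_slopes <- function(mo2, r2 = 1, t_mid = seq_along(mo2) * 420) {
  data.frame(loop_index = seq_along(mo2) - 1L, t_mid = t_mid,
             slope = -mo2, intercept = 9, r2 = r2,
             n_points = 210L, mo2_raw = mo2, mo2_corrected = mo2)
}
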