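# Independent oracles, deliberately written from first principles so they
# share no code with the implementation they check.

# hypergeometric upper tail P(X >= k) by direct enumeration with choose()
hyper_tail_oracle <- function(n, a, b, k) {
  j <- seq(max(k, a + b - n), min(a, b))
  if (length(j) == 0 || k > min(a, b)) return(if (k <= max(0, a + b - n)) 1 else 0)
  sum(choose(a, j) * choose(n - a, b - j)) / choose(n, b)
}

# k-group log-rank chi-square from the textbook O-E / V formula
logrank_oracle <- function(time, event, group) {
  groups <- sort(unique(group))
  k <- length(groups)
  ev_times <- sort(unique(time[event == 1]))
  O <- numeric(k - 1); E <- numeric(k - 1)
  V <- matrix(0, k - 1, k - 1)
  for (t in ev_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    n_g <- vapply(groups, function(g) sum(at_risk & group == g), numeric(1))
    d_g <- vapply(groups, function(g) sum(event == 1 & time == t & group == g),
                  numeric(1))
    O <- O + d_g[-k]
    E <- E + d_t * n_g[-k] / n_t
    if (n_t > 1) {
      frac <- d_t * (n_t - d_t) / (n_t^2 * (n_t - 1))
      for (i in seq_len(k - 1)) {
        for (j in seq_len(k - 1)) {
          V[i, j] <- V[i, j] + frac *
            (if (i == j) n_g[i] * (n_t - n_g[i]) else -n_g[i] * n_g[j])
        }
      }
    }
  }
  drop(t(O - E) %*% solve(V) %*% (O - E))
}

# 1-D penalized logistic: brute-force grid over the weight, profiling the
# intercept with optimize() at each grid point
lasso_1d_oracle <- function(x, y, lambda) {
  obj <- function(b, w) {
    eta <- b + x * w
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + lambda * abs(w)
  }
  prof <- function(w) optimize(function(b) obj(b, w), c(-20, 20))$objective
  grid <- seq(-5, 5, by = 1e-3)
  w0 <- grid[which.min(vapply(grid, prof, numeric(1)))]
  fine <- seq(w0 - 2e-3, w0 + 2e-3, by = 1e-5)
  fine[which.min(vapply(fine, prof, numeric(1)))]
}
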