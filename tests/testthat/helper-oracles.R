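# Independent oracles used by several test files.

# Brute-force SPoC oracle on 2 channels: maximize |cov(w' C_e w, z)| over a
# dense grid of filter angles, normalizing w to unit C-norm.
brute_force_spoc_2ch <- function(per_epoch, C, z) {
  zs <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  best <- list(val = -Inf, w = NULL)
  for (theta in seq(0, 179.5, by = 0.5)) {
    w <- c(cos(theta * pi / 180), sin(theta * pi / 180))
    w <- w / sqrt(drop(t(w) %*% C %*% w))
    p <- vapply(per_epoch, function(Ce) drop(t(w) %*% Ce %*% w), 0)
    v <- abs(mean(p * zs) - mean(p) * mean(zs))
    if (v > best$val) best <- list(val = v, w = w)
  }
  best
}

# Epochs with the comodulation planted on channel 1 only.
sim_epochs_2ch <- function(E = 120, Tn = 200, seed = 1, gain = 0.5) {
  set.seed(seed)
  z <- rnorm(E)
  arr <- array(0, c(E, 2, Tn))
  for (e in seq_len(E)) {
    arr[e, 1, ] <- rnorm(Tn, sd = sqrt(exp(gain * z[e])))
    arr[e, 2, ] <- rnorm(Tn)
  }
  list(arr = arr, z = z)
}

# Exhaustive Shapley oracle for an additive value function over feature
# subsets: v(S) = sum_{b in S} beta_b (x_b - mu_b). Enumerates all 2^p
# coalitions with the classic permutation weights.
exhaustive_shapley <- function(beta, x, mu) {
  p <- length(beta)
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  v <- function(S) sum(beta[S] * (x[S] - mu[S]))
  for (b in seq_len(p)) {
    for (r in seq_len(nrow(subsets))) {
      S <- unlist(subsets[r, ])
      if (S[b]) next
      s <- sum(S)
      wgt <- factorial(s) * factorial(p - s - 1) / factorial(p)
      Sb <- S
      Sb[b] <- TRUE
      phi[b] <- phi[b] + wgt * (v(Sb) - v(S))
    }
  }
  phi
}
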