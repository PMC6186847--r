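# Independent full-matrix oracles used to cross-check the scalar-simplified
# implementation. Deliberately textbook-style 2x2 linear algebra with no
# scalar shortcuts.

rotation_matrix <- function(omega0) {
  matrix(c(cos(omega0), sin(omega0), -sin(omega0), cos(omega0)), 2, 2)
}

# full-matrix Kalman filter + RTS smoother for
#   s_{t+1} = B s_t + N(0, sigma I),  y_t = s_t + N(0, alpha I)
# initialised like the package: prior mean = first observation, variance p1 I,
# then the prior is updated with the first observation.
matrix_kalman <- function(obs, omega0, sigma, alpha, p1 = 10 * (alpha + sigma)) {
  Y <- rbind(Re(obs), Im(obs))
  n <- ncol(Y)
  B <- rotation_matrix(omega0)
  Q <- diag(sigma, 2)
  R <- diag(alpha, 2)
  I2 <- diag(2)
  m <- matrix(0, 2, n)
  P <- array(0, c(2, 2, n))
  mp <- matrix(0, 2, n) # predicted means (for RTS)
  Pp <- array(0, c(2, 2, n)) # predicted covariances

  P0 <- diag(p1, 2)
  K <- P0 %*% solve(P0 + R)
  m[, 1] <- Y[, 1] + K %*% (Y[, 1] - Y[, 1])
  P[, , 1] <- (I2 - K) %*% P0
  for (t in seq_len(n - 1)) {
    mp[, t + 1] <- B %*% m[, t]
    Pp[, , t + 1] <- B %*% P[, , t] %*% t(B) + Q
    K <- Pp[, , t + 1] %*% solve(Pp[, , t + 1] + R)
    m[, t + 1] <- mp[, t + 1] + K %*% (Y[, t + 1] - mp[, t + 1])
    P[, , t + 1] <- (I2 - K) %*% Pp[, , t + 1]
  }
  ms <- matrix(0, 2, n)
  Ps <- array(0, c(2, 2, n))
  ms[, n] <- m[, n]
  Ps[, , n] <- P[, , n]
  if (n >= 2) {
    for (t in seq.int(n - 1, 1)) {
      C <- P[, , t] %*% t(B) %*% solve(Pp[, , t + 1])
      ms[, t] <- m[, t] + C %*% (ms[, t + 1] - mp[, t + 1])
      Ps[, , t] <- P[, , t] + C %*% (Ps[, , t + 1] - Pp[, , t + 1]) %*% t(C)
    }
  }
  list(filtered_means = m, filtered_covs = P,
       smoothed_means = ms, smoothed_covs = Ps)
}

# exhaustive least-squares segmentation cost for fixed split positions
segmentation_cost <- function(x, splits) {
  bounds <- c(1, sort(splits), length(x) + 1)
  total <- 0
  for (k in seq_len(length(bounds) - 1)) {
    seg <- x[bounds[k]:(bounds[k + 1] - 1)]
    total <- total + sum((seg - mean(seg))^2)
  }
  total
}

# brute-force best k-split segmentation (k in 0..2), min segment length m.
# splits are first-sample-of-right-segment indices, matching the detector.
brute_force_splits <- function(x, k, m) {
  n <- length(x)
  if (k == 0) return(integer(0))
  S <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x^2))
  cost <- function(i, j) {
    len <- j - i + 1
    (S2[j + 1] - S2[i]) - (S[j + 1] - S[i])^2 / len
  }
  if (k == 1) {
    ss <- seq.int(m, n - m) # split after ss
    tot <- cost(1, ss) + cost(ss + 1, n)
    return(ss[which.min(tot)] + 1L)
  }
  best <- Inf
  best_s <- NULL
  for (s1 in seq.int(m, n - 2 * m)) {
    s2 <- seq.int(s1 + m, n - m)
    tot <- cost(1, s1) + cost(s1 + 1, s2) + cost(s2 + 1, n)
    j <- which.min(tot)
    if (tot[j] < best) {
      best <- tot[j]
      best_s <- c(s1 + 1L, s2[j] + 1L)
    }
  }
  best_s
}

# simulate the exact rotating state-space model
simulate_state_model <- function(n, omega0, sigma, alpha, seed) {
  set.seed(seed)
  rot <- complex(argument = omega0)
  eta <- complex(real = rnorm(n, 0, sqrt(sigma)),
                 imaginary = rnorm(n, 0, sqrt(sigma)))
  W <- complex(real = rnorm(n, 0, sqrt(alpha)),
               imaginary = rnorm(n, 0, sqrt(alpha)))
  s <- complex(n)
  s[1] <- complex(real = 1, imaginary = 0)
  for (t in seq_len(n - 1)) s[t + 1] <- rot * s[t] + eta[t]
  list(states = s, obs = s + W)
}
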