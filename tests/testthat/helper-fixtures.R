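# shared fixtures and independent oracles for the test suite

# partition from a bare label vector, nodes named n1..nN
part <- function(labels, ...) {
  names(labels) <- paste0("n", seq_along(labels))
  partition(labels, ...)
}

random_partition <- function(n, kmax = 4) {
  part(sample.int(sample(2:kmax, 1), n, replace = TRUE))
}

# random symmetric weighted network with uniform edge weights
random_network <- function(n) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  w[ut] <- runif(sum(ut))
  weighted_network(w + t(w))
}

# ARI by brute-force enumeration of all node pairs' co-membership decisions:
# count agreements/disagreements, Rand index, then the expected-index
# correction. Independent of the contingency-table route.
ari_pair_oracle <- function(p1, p2) {
  a1 <- p1$membership
  a2 <- p2$membership[names(a1)]
  n <- length(a1)
  a <- b <- c <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s1 <- a1[i] == a1[j]
      s2 <- a2[i] == a2[j]
      if (s1 && s2) a <- a + 1
      else if (!s1 && !s2) b <- b + 1
      else if (s1 && !s2) c <- c + 1
      else d <- d + 1
    }
  }
  npairs <- a + b + c + d
  same1 <- a + c  # co-membership pairs in p1
  same2 <- a + d  # co-membership pairs in p2
  expected <- same1 * same2 / npairs
  denom <- (same1 + same2) / 2 - expected
  if (denom == 0) return(1)
  (a - expected) / denom
}

# exhaustive Potts ground state for <= 8 nodes
brute_ground_state <- function(W, q, gamma = 1) {
  n <- nrow(W)
  k <- rowSums(W)
  two_m <- sum(W)
  J <- W - gamma * outer(k, k) / two_m
  ut <- upper.tri(J)
  best <- Inf
  cfg <- rep(1L, n)
  repeat {
    same <- outer(cfg, cfg, "==")
    H <- -sum((J * same)[ut])
    if (H < best) best <- H
    i <- 1
    while (i <= n && cfg[i] == q) {
      cfg[i] <- 1L
      i <- i + 1
    }
    if (i > n) break
    cfg[i] <- cfg[i] + 1L
  }
  best
}

# literal from-scratch transcription of the score statistic: kernel, P0,
# traces, all built with naive dense algebra, no reuse of package internals
score_oracle <- function(D, y, X, family, rho) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  K <- exp(-unclass(D)^2 / rho)
  if (family == "binomial") {
    fit <- suppressWarnings(glm(y ~ X - 1, family = binomial(),
                                control = list(epsilon = 1e-14, maxit = 200)))
    mu0 <- fitted(fit)
    D0 <- diag(mu0 * (1 - mu0))
    r <- y - mu0
  } else {
    fit <- lm(y ~ X - 1)
    sigma2 <- sum(resid(fit)^2) / (n - ncol(X))
    D0 <- diag(n)
    r <- resid(fit) / sqrt(sigma2)
  }
  P0 <- D0 - D0 %*% X %*% solve(t(X) %*% D0 %*% X) %*% t(X) %*% D0
  Q <- drop(t(r) %*% K %*% r)
  mu_Q <- sum(diag(P0 %*% K))
  sigma_Q <- sqrt(2 * sum(diag(P0 %*% K %*% P0 %*% K)))
  list(Q = Q, mu_Q = mu_Q, sigma_Q = sigma_Q, S = (Q - mu_Q) / sigma_Q)
}
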