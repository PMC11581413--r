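toy_dist <- function(n, seed = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(2 * n), n)
  subject_dist(as.matrix(dist(pts)) / max(dist(pts)), metric = "nmi")
}

test_that("the Gaussian kernel behaves at its boundaries", {
  D <- subject_dist(matrix(c(0, 1, 1, 0), 2), metric = "nmi")
  expect_equal(gaussian_kernel(D, 1)[1, 2], exp(-1))
  expect_equal(diag(gaussian_kernel(D, 0.3)), c(1, 1), ignore_attr = TRUE)
  expect_equal(gaussian_kernel(D, 1e12)[1, 2], 1, tolerance = 1e-10)
  expect_error(gaussian_kernel(D, 0), "bandwidth")
  expect_error(gaussian_kernel(D, -1), "bandwidth")
})

test_that("bandwidth bounds follow the 0.1 min / 100 max squared-distance rule", {
  Dc <- subject_dist(matrix(0.3, 3, 3) - diag(0.3, 3), metric = "nmi")
  expect_equal(rho_bounds(Dc), c(L = 0.1 * 0.09, U = 100 * 0.09))

  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.2
  d[1, 3] <- d[3, 1] <- 0.5
  d[2, 3] <- d[3, 2] <- 0.5
  expect_equal(rho_bounds(subject_dist(d, metric = "nmi")),
               c(L = 0.004, U = 25))

  # zero minimum falls back to the smallest positive distance
  d[1, 2] <- d[2, 1] <- 0
  expect_equal(rho_bounds(subject_dist(d, metric = "nmi")),
               c(L = 0.1 * 0.25, U = 25))

  expect_error(rho_bounds(subject_dist(matrix(0, 3, 3), metric = "nmi")),
               "degenerate")
})

test_that("rho grids are ordered and span the bounds", {
  g <- rho_grid(0.01, 10, m = 25)
  expect_length(g, 25)
  expect_equal(as.numeric(range(g)), c(0.01, 10))
  expect_true(all(diff(g) > 0))
  expect_error(rho_grid(0, 1), "0 < L")
  expect_error(rho_grid(1, 2, m = 1), "two points")
})

test_that("null fits reproduce closed forms", {
  set.seed(1)
  y <- rnorm(20, 3, 2)
  nf <- fit_null(y, family = "gaussian")
  expect_equal(unname(nf$beta0), mean(y))
  expect_equal(nf$sigma2, var(y))  # RSS/(n-1) for intercept-only

  yb <- rbinom(30, 1, 0.4)
  nfb <- fit_null(yb, family = "binomial")
  expect_equal(unname(nfb$mu0), rep(mean(yb), 30))

  expect_error(fit_null(c(0, 1, 2), family = "binomial"), "0/1")
  expect_error(fit_null(y, X = cbind(1, 1:20, 2 * (1:20))), "full column rank")
})

test_that("logistic null fit maximizes the likelihood (direct search oracle)", {
  set.seed(2)
  x <- rbinom(40, 1, 0.5)
  y <- rbinom(40, 1, plogis(-0.3 + 0.8 * x))
  X <- cbind(1, x)
  nf <- fit_null(y, X, "binomial")
  negll <- function(b) -sum(y * (X %*% b) - log(1 + exp(X %*% b)))
  oracle <- optim(c(0, 0), negll, method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 5000))$par
  expect_equal(unname(nf$beta0), oracle, tolerance = 1e-4)
})

test_that("score statistic with identity kernel reduces to the residual sum", {
  set.seed(3)
  n <- 25
  y <- rbinom(n, 1, 0.5)
  # an identity kernel arises from equal off-diagonal distances and rho -> 0;
  # evaluate the pieces directly against the explicit P0
  D <- subject_dist(matrix(1, n, n) - diag(n), metric = "nmi")
  nf <- fit_null(y, family = "binomial")
  st <- score_statistic(D, nf, rho = 1e-4)  # K ~ I to double precision
  expect_equal(st$Q, sum((y - mean(y))^2), tolerance = 1e-8)
  v <- nf$v; X <- matrix(1, n, 1)
  P0 <- diag(v) - (v %*% t(v)) / sum(v)
  expect_equal(st$mu_Q, sum(diag(P0)), tolerance = 1e-8)
  expect_equal(st$sigma_Q, sqrt(2 * sum(P0 * t(P0))), tolerance = 1e-8)
})

test_that("a constant kernel is annihilated by the intercept projection", {
  set.seed(4)
  n <- 12
  y <- rnorm(n)
  D <- toy_dist(n)
  nf <- fit_null(y, family = "gaussian")
  st <- score_statistic(D, nf, rho = 1e16)  # K -> all-ones
  expect_true(st$degenerate)
  expect_true(is.na(st$S))
  expect_equal(st$mu_Q, 0, tolerance = 1e-6)
})

test_that("score pieces match a from-scratch transcription", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    D <- toy_dist(n, seed = i)
    X <- cbind(1, rnorm(n))
    fam <- if (i %% 2) "binomial" else "gaussian"
    y <- if (fam == "binomial") rbinom(n, 1, 0.5) else rnorm(n)
    rho <- runif(1, 0.1, 2)
    nf <- fit_null(y, X, fam)
    got <- score_statistic(D, nf, rho)
    want <- score_oracle(D, y, X, fam, rho)
    expect_equal(got$Q, want$Q, tolerance = 1e-10)
    expect_equal(got$mu_Q, want$mu_Q, tolerance = 1e-10)
    expect_equal(got$sigma_Q, want$sigma_Q, tolerance = 1e-10)
  }
})

test_that("davies_test reports a coherent trace and bound", {
  set.seed(6)
  n <- 30
  D <- toy_dist(n)
  y <- rbinom(n, 1, 0.5)
  res <- davies_test(D, y, family = "binomial", grid_points = 20)
  expect_s3_class(res, "km_score_test")
  expect_length(res$S_trace, 20)
  expect_equal(res$M, max(res$S_trace, na.rm = TRUE))
  expect_equal(res$W, sum(abs(diff(res$S_trace[!is.na(res$S_trace)]))))
  expect_equal(res$p_value,
               min(1, pnorm(-res$M) + res$W * exp(-res$M^2 / 2) / sqrt(8 * pi)))
  expect_lte(res$p_value, 1)
})

test_that("subject alignment is by id, not row order", {
  set.seed(7)
  n <- 20
  D <- toy_dist(n)
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  y <- rbinom(n, 1, 0.5)
  names(y) <- paste0("s", 1:n)
  p1 <- davies_test(D, y, family = "binomial")$p_value
  p2 <- davies_test(D, y[sample(n)], family = "binomial")$p_value
  expect_equal(p1, p2)
})

test_that("an indefinite kernel triggers a warning but still tests", {
  # triangle-violating distances (possible for the intrinsic metric) are not
  # Euclidean-embeddable, so the Gaussian kernel can lose positive
  # definiteness at moderate bandwidths
  d <- matrix(c(0, 1.9, 0.7,
                1.9, 0, 0.7,
                0.7, 0.7, 0), 3)
  D <- subject_dist(d, metric = "objective")
  y <- c(0, 1, 1)
  expect_warning(res <- davies_test(D, y, family = "binomial",
                                    grid = rho_grid(2.5, 4, 5)),
                 "indefinite")
  expect_true(is.finite(res$p_value))
})

test_that("estimate_h shrinks to the parametric fit as lambda grows", {
  set.seed(8)
  n <- 30
  D <- toy_dist(n)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n, X %*% c(1, 0.5))
  fit <- estimate_h(D, y, X, "gaussian", lambda = 1e8, rho = 1)
  expect_equal(max(abs(fit$h)), 0, tolerance = 1e-5)
  expect_equal(fit$beta, unname(coef(lm(y ~ X - 1))), tolerance = 1e-6,
               ignore_attr = TRUE)

  yb <- rbinom(n, 1, plogis(X %*% c(-0.2, 0.7)))
  fitb <- estimate_h(D, yb, X, "binomial", lambda = 1e8, rho = 1)
  glmfit <- glm(yb ~ X - 1, family = binomial())
  expect_equal(fitb$beta, unname(coef(glmfit)), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(max(abs(fitb$h)), 0, tolerance = 1e-4)
})

test_that("gaussian estimate_h satisfies its defining linear system", {
  set.seed(9)
  n <- 8
  D <- toy_dist(n)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  lambda <- 2; rho <- 0.7
  fit <- estimate_h(D, y, X, "gaussian", lambda = lambda, rho = rho)
  K <- gaussian_kernel(D, rho)
  M <- diag(n) + K / lambda
  # alpha = (1/lambda) M^-1 (y - X beta)
  expect_lt(max(abs(M %*% (lambda * fit$alpha) - (y - X %*% fit$beta))), 1e-10)
  # beta solves X' M^-1 (y - X beta) ... = 0
  expect_lt(max(abs(crossprod(X, solve(M, y - X %*% fit$beta)))), 1e-10)
})

test_that("binomial estimate_h reaches a stationary point", {
  set.seed(10)
  n <- 25
  D <- toy_dist(n)
  X <- matrix(1, n, 1)
  y <- rbinom(n, 1, 0.5)
  lambda <- 5; rho <- 0.5
  fit <- estimate_h(D, y, X, "binomial", lambda = lambda, rho = rho)
  K <- gaussian_kernel(D, rho)
  mu <- fit$fitted
  # gradients of the penalized log likelihood
  expect_lt(max(abs(crossprod(X, y - mu))), 1e-6)
  expect_lt(max(abs(K %*% ((y - mu) - lambda * fit$alpha))), 1e-6)
})
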