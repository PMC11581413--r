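#' Estimate covariate effects and the network effect at fixed tuning values
#'
#' Fits the semiparametric model \eqn{G(E(y)) = X\beta + h(z)} at a fixed
#' regularization \eqn{\lambda} and bandwidth \eqn{\rho}, with the
#' representer form \eqn{h(z_i) = \sum_j \alpha_j K(z_i, z_j)}. For the
#' gaussian family the ridge-type closed forms are used:
#' \deqn{\hat\beta = [X^T(I + K/\lambda)^{-1}X]^{-1} X^T(I+K/\lambda)^{-1}y,
#'   \quad \hat\alpha = \tfrac{1}{\lambda}(I + K/\lambda)^{-1}(y - X\hat\beta).}
#' For the binomial family the penalized likelihood is maximized by a
#' Newton-Raphson iteration on the blocked working-response system, with
#' weights \eqn{D = \mathrm{diag}[\mu(1-\mu)]}.
#'
#' As \eqn{\lambda \to \infty} the penalty forces \eqn{\hat h \to 0} and
#' \eqn{\hat\beta} approaches the ordinary (generalized) linear model fit.
#' This function is an estimation companion to [davies_test()]; it plays no
#' role in the test itself, where \eqn{\tau = 1/\lambda} is the tested
#' variance component.
#'
#' @param D distance matrix (see [partition_distances()]).
#' @param y outcome vector.
#' @param X design matrix including intercept; `NULL` = intercept only.
#' @param family `"binomial"` or `"gaussian"`.
#' @param lambda regularization parameter, > 0.
#' @param rho kernel bandwidth, > 0.
#' @param tol relative-change convergence tolerance for the Newton
#'   iteration.
#' @param maxit maximum Newton iterations.
#' @return List with `beta`, `alpha`, `h` (= K alpha), `fitted` (on the
#'   response scale), `lambda`, `rho`, and for binomial fits `iterations`.
#' @export
estimate_h <- function(D, y, X = NULL,
                       family = c("binomial", "gaussian"),
                       lambda, rho, tol = 1e-8, maxit = 100) {
  family <- match.arg(family)
  if (lambda <= 0) stop("lambda must be positive")
  d <- unclass(D)
  n <- nrow(d)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  K <- gaussian_kernel(d, rho)

  if (family == "gaussian") {
    Minv <- solve(diag(n) + K / lambda)
    beta <- solve(crossprod(X, Minv %*% X), crossprod(X, Minv %*% y))
    alpha <- Minv %*% (y - X %*% beta) / lambda
    h <- K %*% alpha
    return(list(beta = drop(beta), alpha = drop(alpha), h = drop(h),
                fitted = drop(X %*% beta + h), lambda = lambda, rho = rho))
  }

  # binomial: Newton-Raphson on the blocked penalized-likelihood system
  tau <- 1 / lambda
  q <- ncol(X)
  beta <- fit_null(y, X, "binomial")$beta0
  alpha <- rep(0, n)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta + K %*% alpha)
    mu <- 1 / (1 + exp(-eta))
    v <- pmax(mu * (1 - mu), 1e-10)
    ytilde <- eta + (y - mu) / v
    DX <- X * v
    DK <- K * v  # rows scaled by v: D %*% K
    lhs <- rbind(cbind(crossprod(X, DX), crossprod(X, DK)),
                 cbind(DX, diag(n) / tau + DK))
    rhs <- c(crossprod(X, v * ytilde), v * ytilde)
    new <- tryCatch(solve(lhs, rhs),
                    error = function(e) stop("Newton step failed: ",
                                             conditionMessage(e)))
    beta_new <- new[seq_len(q)]
    alpha_new <- new[-seq_len(q)]
    delta <- max(abs(c(beta_new - beta, alpha_new - alpha))) /
      max(1, max(abs(c(beta_new, alpha_new))))
    beta <- beta_new; alpha <- alpha_new
    if (!all(is.finite(c(beta, alpha))))
      stop("Newton iteration diverged at step ", it)
    if (delta < tol) {
      h <- drop(K %*% alpha)
      return(list(beta = drop(beta), alpha = drop(alpha), h = h,
                  fitted = drop(1 / (1 + exp(-(X %*% beta + h)))),
                  lambda = lambda, rho = rho, iterations = it))
    }
  }
  stop("Newton iteration did not converge in ", maxit, " steps")
}
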