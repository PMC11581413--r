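#' Gaussian distance kernel
#'
#' Converts a subject dissimilarity matrix into a similarity kernel
#' \deqn{K_{ij} = \exp\{-d_{ij}^2 / \rho\},}
#' with bandwidth \eqn{\rho > 0}. The diagonal is exactly 1 and entries lie
#' in (0, 1\]. For extrinsic-metric distances this is a proper positive
#' semi-definite kernel; for the intrinsic objective-value distance positive
#' definiteness is not guaranteed (see [davies_test()], which checks and
#' warns).
#'
#' @param D a [subject_dist()] or plain symmetric distance matrix.
#' @param rho bandwidth, > 0. Large `rho` flattens the kernel toward the
#'   all-ones matrix; small `rho` localizes it toward the identity.
#' @return An n x n symmetric kernel matrix.
#' @export
gaussian_kernel <- function(D, rho) {
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0)
    stop("invalid bandwidth: rho must be a single positive number")
  exp(-(unclass(D)^2) / rho)
}

#' Bandwidth search bounds from the distance matrix
#'
#' The kernel bandwidth is inestimable under the null, so the score test
#' searches a grid of \eqn{\rho} values whose bounds follow the standard
#' squared-distance rule: `L = 0.1 * min` and `U = 100 * max` of the
#' off-diagonal squared distances. When the minimum off-diagonal distance is
#' exactly 0 (identical partitions for some subject pair) the lower bound
#' falls back to the smallest *positive* squared distance.
#'
#' @param D a [subject_dist()] or distance matrix with at least one positive
#'   off-diagonal entry.
#' @return `c(L, U)`.
#' @export
rho_bounds <- function(D) {
  d <- unclass(D)
  off <- d[upper.tri(d)]
  if (all(off == 0))
    stop("degenerate distances: all off-diagonal distances are zero")
  dmin <- min(off)
  if (dmin == 0) dmin <- min(off[off > 0])
  c(L = 0.1 * dmin^2, U = 100 * max(off)^2)
}

#' Bandwidth grid
#'
#' Builds the ordered \eqn{\rho} grid searched by [davies_test()], including
#' both endpoints. Linear spacing is the default: it samples the
#' small-bandwidth end of the range sparsely, which matters for the
#' intrinsic metric whose bounds can span many orders of magnitude and
#' whose score process is erratic at tiny bandwidths (see the vignette);
#' `"log"` spacing is available for scale-uniform exploration.
#'
#' @param L,U positive bounds, `L <= U` (e.g. from [rho_bounds()]).
#' @param m number of grid points (>= 2).
#' @param spacing `"linear"` or `"log"`.
#' @return Object of class `rho_grid`: numeric vector of grid values with
#'   attributes `L`, `U`, `spacing`.
#' @export
rho_grid <- function(L, U, m = 50, spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  if (L <= 0 || U < L) stop("need 0 < L <= U")
  if (m < 2) stop("grid needs at least two points")
  pts <- switch(spacing,
    log = exp(seq(log(L), log(U), length.out = m)),
    linear = seq(L, U, length.out = m))
  structure(pts, L = L, U = U, spacing = spacing, class = "rho_grid")
}

#' Fit the null model (no network effect)
#'
#' Maximum likelihood fit of the outcome on the covariates alone:
#' a logistic GLM for binary outcomes, ordinary least squares for
#' continuous ones. Everything the score test needs under
#' \eqn{H_0: h(\cdot) = 0} is returned.
#'
#' @param y outcome vector (0/1 for `"binomial"`).
#' @param X n x q design matrix including the intercept column; `NULL` for
#'   intercept only.
#' @param family `"binomial"` or `"gaussian"`.
#' @return A list of class `km_null_fit`: `beta0`, fitted means `mu0`,
#'   residuals `resid`, variance weights (`v = mu0(1-mu0)` or `sigma2` with
#'   denominator n - q), `X`, `family`.
#' @export
fit_null <- function(y, X = NULL, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and y dimensions disagree")
  if (qr(X)$rank < ncol(X)) stop("X is not of full column rank")
  if (family == "binomial") {
    if (!all(y %in% c(0, 1))) stop("binomial outcome must be coded 0/1")
    fit <- glm.fit(X, y, family = binomial(),
                   control = list(epsilon = 1e-12, maxit = 100))
    if (!fit$converged)
      stop("null logistic fit did not converge (possible perfect separation)")
    mu0 <- fit$fitted.values
    out <- list(beta0 = fit$coefficients, mu0 = mu0, resid = y - mu0,
                v = mu0 * (1 - mu0), sigma2 = NULL, X = X, family = family)
  } else {
    fit <- lm.fit(X, y)
    r <- fit$residuals
    sigma2 <- sum(r^2) / (n - ncol(X))
    out <- list(beta0 = fit$coefficients, mu0 = fit$fitted.values, resid = r,
                v = NULL, sigma2 = sigma2, X = X, family = family)
  }
  class(out) <- "km_null_fit"
  out
}

# Precompute the projection-type matrix P0 and the (standardized) residual
# used by the score statistic.
#   binomial: P0 = D0 - D0 X (X'D0 X)^-1 X'D0 with D0 = diag(mu0(1-mu0)),
#             r = y - mu0
#   gaussian: residuals standardized by sigma-hat, so D0 = I and
#             P0 = I - X(X'X)^-1 X'
score_precompute <- function(null_fit) {
  X <- null_fit$X
  n <- nrow(X)
  if (null_fit$family == "binomial") {
    v <- null_fit$v
    DX <- X * v
    P0 <- diag(v) - DX %*% solve(crossprod(X, DX), t(DX))
    r <- null_fit$resid
  } else {
    P0 <- diag(n) - X %*% solve(crossprod(X), t(X))
    r <- null_fit$resid / sqrt(null_fit$sigma2)
  }
  list(P0 = P0, r = r)
}

#' Score statistic at one bandwidth
#'
#' The variance-component score statistic for \eqn{H_0: \tau = 0} at a fixed
#' kernel bandwidth:
#' \deqn{Q = r^T K(\rho)\, r, \quad
#'   S(\rho) = \frac{Q - \mu_Q}{\sigma_Q},}
#' with \eqn{r} the null residuals (raw `y - mu0` for the logistic model;
#' standardized by \eqn{\hat\sigma} for the linear one),
#' \eqn{\mu_Q = \mathrm{tr}(P_0 K)} and
#' \eqn{\sigma_Q^2 = 2\,\mathrm{tr}(P_0 K P_0 K)}.
#'
#' @param D distance matrix.
#' @param null_fit a [fit_null()] result.
#' @param rho bandwidth.
#' @param precomp optional cached `score_precompute()` result (internal
#'   reuse across a grid).
#' @return List with `Q`, `mu_Q`, `sigma_Q`, `S`, and `degenerate` flag
#'   (`TRUE` when `sigma_Q` vanishes and `S` is undefined).
#' @export
score_statistic <- function(D, null_fit, rho, precomp = NULL) {
  if (is.null(precomp)) precomp <- score_precompute(null_fit)
  K <- gaussian_kernel(D, rho)
  r <- precomp$r
  Q <- drop(crossprod(r, K %*% r))
  PK <- precomp$P0 %*% K
  mu_Q <- sum(diag(PK))
  s2 <- 2 * sum(PK * t(PK))
  sigma_Q <- sqrt(max(s2, 0))
  degenerate <- sigma_Q < 1e-12 * max(1, abs(mu_Q))
  S <- if (degenerate) NA_real_ else (Q - mu_Q) / sigma_Q
  list(Q = Q, mu_Q = mu_Q, sigma_Q = sigma_Q, S = S, degenerate = degenerate)
}

#' Davies upper bound for the supremum of the score process
#'
#' Upper bound on the p-value of the maximum \eqn{M} of a standardized,
#' nuisance-parameter-indexed Gaussian process with total variation \eqn{W}
#' along the searched range:
#' \deqn{p \le \Phi(-M) + W e^{-M^2/2} / \sqrt{8\pi}.}
#' With a flat trace (`W = 0`) the bound reduces to the one-sided normal
#' tail \eqn{\Phi(-M)}; the bound can exceed 1 for small `M` and large `W`
#' and is therefore clamped at 1.
#'
#' @param M maximum of the standardized score over the searched grid.
#' @param W total variation of the score along the grid,
#'   \eqn{\sum_j |S(\rho_{j+1}) - S(\rho_j)|}.
#' @return The clamped upper bound, in (0, 1\].
#' @export
#' @examples
#' davies_bound(2, 0)   # = pnorm(-2)
#' davies_bound(0, 0)   # = 0.5
davies_bound <- function(M, W) {
  if (W < 0) stop("W must be non-negative")
  min(1, pnorm(-M) + W * exp(-M^2 / 2) / sqrt(8 * pi))
}

#' Kernel machine score test with Davies upper bound
#'
#' Tests whether between-subject variation in network community structure,
#' summarized by the distance matrix `D`, is associated with the outcome
#' after adjusting for covariates. The semiparametric model is
#' \eqn{G(E(y_i)) = x_i^T\beta + h(z_i)} with \eqn{h} in the RKHS of the
#' Gaussian distance kernel; the null \eqn{h(\cdot) = 0} is a
#' variance-component hypothesis whose kernel bandwidth \eqn{\rho}
#' disappears under the null. The standardized score \eqn{S(\rho)} is
#' therefore evaluated over a bandwidth grid and treated as a
#' \eqn{\rho}-indexed Gaussian process, giving the Davies upper bound
#' \deqn{p \le \Phi(-M) + W e^{-M^2/2}/\sqrt{8\pi},}
#' where \eqn{M = \max_\rho S(\rho)} and \eqn{W} is the total variation of
#' \eqn{S} along the grid. The bound is clamped at 1 (it can exceed 1 for
#' small \eqn{M} and large \eqn{W}) and is conservative by construction.
#'
#' @param D a [subject_dist()] (or symmetric distance matrix).
#' @param y outcome vector, aligned with the rows of `D` (by subject id when
#'   both are named).
#' @param X covariate design including intercept; `NULL` = intercept only.
#' @param family `"binomial"` or `"gaussian"`.
#' @param grid a [rho_grid()]; by default 50 points between the
#'   [rho_bounds()] of `D`.
#' @param grid_points grid size when `grid` is `NULL`.
#' @param grid_spacing spacing of the default grid, `"linear"` or `"log"`.
#' @param check_kernel if `TRUE`, eigen-check the kernel at the smallest
#'   bandwidth and warn when it is numerically indefinite (possible for the
#'   intrinsic metric); no repair is attempted since \eqn{\mu_Q, \sigma_Q}
#'   remain computable.
#' @return Object of class `km_score_test`: `p_value`, `M`, `W`, `S_trace`,
#'   `grid`, `Q_at_max`, `mu_Q`, `sigma_Q` (at the maximizing bandwidth),
#'   `null_fit`, `family`, `n`, `warnings`.
#' @export
#' @examples
#' set.seed(7)
#' d <- sim_design(30, 3)
#' coh <- simulate_cohort(10, 10, d)
#' parts <- detect_cohort(coh, "louvain")
#' D <- partition_distances(parts, "nmi")
#' davies_test(D, coh$group, family = "binomial")
davies_test <- function(D, y, X = NULL,
                        family = c("binomial", "gaussian"),
                        grid = NULL, grid_points = 50,
                        grid_spacing = c("linear", "log"),
                        check_kernel = TRUE) {
  family <- match.arg(family)
  d <- unclass(D)
  n <- nrow(d)
  if (length(y) != n) stop("outcome length must match the distance matrix")
  if (!is.null(names(y)) && !is.null(rownames(d))) {
    if (!setequal(names(y), rownames(d)))
      stop("subject ids of y and D disagree")
    y <- y[rownames(d)]
    if (!is.null(X)) X <- as.matrix(X)[rownames(d), , drop = FALSE]
  }
  if (is.null(grid)) {
    b <- rho_bounds(d)
    grid <- rho_grid(b[["L"]], b[["U"]], m = grid_points,
                     spacing = match.arg(grid_spacing))
  }
  warn <- character(0)
  if (check_kernel) {
    ev <- eigen(gaussian_kernel(d, grid[1]), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(ev)) {
      warn <- c(warn, sprintf(
        "kernel is numerically indefinite at rho = %.3g (min eigenvalue %.3g)",
        grid[1], min(ev)))
      warning(warn[length(warn)])
    }
  }
  nf <- fit_null(y, X, family)
  pre <- score_precompute(nf)
  stats <- lapply(as.numeric(grid), function(rho)
    score_statistic(d, nf, rho, precomp = pre))
  S <- vapply(stats, `[[`, numeric(1), "S")
  keep <- !is.na(S)
  if (!any(keep)) stop("degenerate kernel at every grid point")
  if (!all(keep)) {
    warn <- c(warn, sprintf("%d degenerate grid point(s) dropped", sum(!keep)))
    warning(warn[length(warn)])
  }
  Sk <- S[keep]
  M <- max(Sk)
  W <- sum(abs(diff(Sk)))
  p <- davies_bound(M, W)
  imax <- which(keep)[which.max(Sk)]
  structure(list(p_value = p, M = M, W = W,
                 S_trace = S, grid = as.numeric(grid),
                 Q_at_max = stats[[imax]]$Q, mu_Q = stats[[imax]]$mu_Q,
                 sigma_Q = stats[[imax]]$sigma_Q,
                 null_fit = nf, family = family, n = n,
                 metric = attr(D, "metric"), warnings = warn),
            class = "km_score_test")
}

#' @export
print.km_score_test <- function(x, ...) {
  cat("Kernel machine score test (Davies upper bound)\n")
  cat(sprintf("  family: %s   subjects: %d   metric: %s\n",
              x$family, x$n, x$metric %||% "?"))
  cat(sprintf("  rho grid: %d points on [%.3g, %.3g]\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  M = %.4f   W = %.4f   p <= %.4g\n", x$M, x$W, x$p_value))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
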