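#' Sensor-space resolution matrix
#'
#' `A = G W`: maps observed data to fitted data.  `A -> I` as `lambda -> 0`
#' for a full-row-rank gain and `A -> 0` as `lambda -> infinity`.
#'
#' @param G a `gain_matrix` or matrix.
#' @param W an `inverse_operator` or matrix.
#' @return n x n numeric matrix.
#' @export
sensor_resolution <- function(G, W) {
  Gm <- if (inherits(G, "gain_matrix")) G$matrix else as.matrix(G)
  Wm <- if (inherits(W, "inverse_operator")) W$W else as.matrix(W)
  Gm %*% Wm
}

#' Ordinary cross-validation cost
#'
#' The leave-one-sensor-out prediction error in closed form:
#' `sum_i ((v_i - (A v)_i) / (1 - A_ii))^2` with `A` the sensor-space
#' resolution matrix.  The numerator penalizes misfit, the denominator
#' penalizes overfitting (`A = I` is a perfect, useless fit).  For
#' multi-sample data the per-sample costs are summed.
#'
#' @param v sensor vector or sensors x samples matrix.
#' @param G a `gain_matrix` or matrix.
#' @param W an `inverse_operator` or matrix (the unnormalized operator).
#' @return scalar cost.
#' @export
ocv_cost <- function(v, G, W) {
  A <- sensor_resolution(G, W)
  ocv_cost_from_A(as.matrix(v), A)
}

ocv_cost_from_A <- function(v, A) {
  d <- 1 - diag(A)
  if (any(abs(d) <= 1e-12))
    stop("overfit: resolution diagonal reaches 1 (lambda too small)")
  r <- (v - A %*% v) / d
  sum(r^2)
}

#' Select the regularization parameter by OCV
#'
#' Evaluates the OCV cost on a log-spaced grid of `lambda` values and
#' returns the arg-min.  All grid work happens in sensor space (the M-dim
#' source space is never touched), so the scan is cheap.  The default grid
#' spans `[1e-4, 1e2]` times the scale-free reference
#' `trace(G R G') / trace(C_n) / n`.
#'
#' @param v sensor vector or sensors x samples matrix (costs pooled).
#' @param G a `gain_matrix` or matrix (orientation-constrained for basis use).
#' @param C_n a `noise_covariance` or matrix.
#' @param prior a `source_prior` (dipole space, or basis space when `basis`
#'   is given); `NULL` for identity.
#' @param basis optional `basis_set`; the operator is then the basis inverse.
#' @param lambda_grid explicit grid (overrides `n_grid`).
#' @param n_grid grid length (default 25, minimum 5).
#' @return an `ocv_result`: grid, costs, selected lambda, resolution
#'   diagonal at the optimum.
#' @export
select_lambda <- function(v, G, C_n, prior = NULL, basis = NULL,
                          lambda_grid = NULL, n_grid = 25) {
  Gm <- if (inherits(G, "gain_matrix")) G$matrix else as.matrix(G)
  C <- if (inherits(C_n, "noise_covariance")) C_n$matrix else as.matrix(C_n)
  v <- as.matrix(v)
  n <- nrow(Gm)
  Geff <- if (is.null(basis)) Gm else Gm %*% t(basis$T)
  K_s <- Geff %*% prior_times(prior, t(Geff))
  K_s <- (K_s + t(K_s)) / 2
  cost_at <- function(lam) {
    A <- tryCatch(t(sensor_space_solve(K_s, C, lam, K_s)),
                  error = function(e) NULL)
    if (is.null(A)) return(Inf)
    tryCatch(ocv_cost_from_A(v, A), error = function(e) Inf)
  }
  auto <- is.null(lambda_grid)
  if (auto) {
    if (n_grid < 5) stop("grid length must be at least 5")
    ref <- sum(diag(K_s)) / sum(diag(C)) / n
    lambda_grid <- exp(seq(log(1e-4 * ref), log(1e2 * ref), length.out = n_grid))
  }
  if (length(lambda_grid) < 5) stop("grid length must be at least 5")
  costs <- vapply(lambda_grid, cost_at, 0)
  if (all(!is.finite(costs))) stop("OCV selection failed: all costs infinite")
  # with the automatic grid, extend toward a boundary minimum (a precision
  # prior can put the natural scale far from the trace-based reference)
  rounds <- 0
  step <- log(lambda_grid[2] / lambda_grid[1])
  while (auto && rounds < 6 &&
         which.min(costs) %in% c(1L, length(lambda_grid))) {
    at_low <- which.min(costs) == 1L
    ext <- if (at_low) exp(log(lambda_grid[1]) - step * seq(n_grid, 1))
           else exp(log(lambda_grid[length(lambda_grid)]) + step * seq_len(n_grid))
    lambda_grid <- if (at_low) c(ext, lambda_grid) else c(lambda_grid, ext)
    costs <- if (at_low) c(vapply(ext, cost_at, 0), costs)
             else c(costs, vapply(ext, cost_at, 0))
    rounds <- rounds + 1
  }
  k <- which.min(costs)
  if (k == 1L || k == length(lambda_grid))
    warning("OCV minimum at the grid boundary; widen the lambda grid")
  A_opt <- t(sensor_space_solve(K_s, C, lambda_grid[k], K_s))
  structure(list(lambda_grid = lambda_grid, costs = costs,
                 lambda = lambda_grid[k],
                 resolution_diag = diag(A_opt)),
            class = "ocv_result")
}

#' @export
print.ocv_result <- function(x, ...) {
  cat(sprintf("ocv_result: lambda = %.4g (grid of %d, cost %.4g)\n",
              x$lambda, length(x$lambda_grid), min(x$costs)))
  invisible(x)
}
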