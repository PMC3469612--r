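#' Source priors
#'
#' A source covariance prior in the active basis, either as strictly
#' positive diagonal weights (length K) or as a sparse symmetric positive
#' definite precision matrix (the inverse covariance; used for the
#' Laplacian-smoothness prior, which is never densely inverted).  Diagonal
#' weights are normalized to unit mean so the regularization parameter
#' `lambda` keeps a comparable scale across recipes.
#'
#' @param weights positive diagonal weights, or `NULL`.
#' @param precision sparse symmetric precision matrix, or `NULL`.
#' @param label recipe label.
#' @param params list of recipe parameters.
#' @return a `source_prior`.
#' @export
source_prior <- function(weights = NULL, precision = NULL, label = "custom",
                         params = list()) {
  if (is.null(weights) == is.null(precision))
    stop("give exactly one of weights or precision")
  if (!is.null(weights)) {
    if (any(weights <= 0)) stop("diagonal prior weights must be positive")
    weights <- weights / mean(weights)
  }
  structure(list(kind = if (is.null(weights)) "precision" else "diagonal",
                 weights = weights, precision = precision,
                 label = label, params = params),
            class = "source_prior")
}

#' @export
print.source_prior <- function(x, ...) {
  cat(sprintf("source_prior (%s, %s)\n", x$label, x$kind))
  invisible(x)
}

#' Identity (minimum-norm) prior
#'
#' @param K dimension of the active basis.
#' @return a `source_prior` with unit diagonal.
#' @export
identity_prior <- function(K) source_prior(weights = rep(1, K), label = "identity")

#' Spectral smoothness prior for the harmonic basis
#'
#' Down-weights high spatial frequencies: diagonal weight `(1 + l)^(-2 gamma)`
#' for the basis function of degree `l`.  `gamma = 0` is the identity prior;
#' values in 0.5-1 are typical for noisy data.  For spline bases the prior
#' is the identity (smoothness is carried by the kernel scale `h` instead).
#'
#' @param basis a `basis_set`.
#' @param gamma non-negative spectral exponent.
#' @return a `source_prior`.
#' @export
harmony_prior <- function(basis, gamma) {
  if (gamma < 0) stop("gamma must be non-negative")
  if (basis$kind == "harmonics") {
    w <- (1 + basis$row_info$l)^(-2 * gamma)
  } else if (basis$kind %in% c("splines", "ibf")) {
    w <- rep(1, nrow(basis$T))
  } else stop("harmony prior needs a harmonic or spline basis")
  source_prior(weights = w, label = "harmony-spectral",
               params = list(gamma = gamma))
}

#' Depth weights from gain column power
#'
#' Weight `(sum_i g_ij^2)^(-gamma_d)` per dipole, so deeper (weaker) dipoles
#' receive higher prior variance.  Free-orientation gains pool the three
#' component columns of each dipole.
#'
#' @param G a `gain_matrix` or plain matrix.
#' @param gamma_d depth exponent (default 1).
#' @return per-dipole weight vector.
#' @export
depth_weights <- function(G, gamma_d = 1) {
  free <- inherits(G, "gain_matrix") && G$orientation == "free"
  Gm <- if (inherits(G, "gain_matrix")) G$matrix else as.matrix(G)
  p <- colSums(Gm^2)
  if (free) p <- colSums(matrix(p, nrow = 3))
  if (any(p == 0))
    stop("zero gain column for dipole(s) ", paste(which(p == 0), collapse = ", "))
  p^(-gamma_d)
}

#' Depth-weighted (WMNE) prior
#'
#' @param G a `gain_matrix`.
#' @param gamma_d depth exponent (default 1).
#' @return a diagonal `source_prior` in dipole space (weights replicated
#'   three-fold for free orientation).
#' @export
depth_prior <- function(G, gamma_d = 1) {
  w <- depth_weights(G, gamma_d)
  if (inherits(G, "gain_matrix") && G$orientation == "free")
    w <- rep(w, each = 3)
  source_prior(weights = w, label = "depth-weighted",
               params = list(gamma_d = gamma_d))
}

# Area-normalized cotangent Laplacian of a folded mesh: the standard
# surface (2D) discrete Laplace-Beltrami operator.  Row sums are zero; on a
# radius-r icosphere it reproduces -l(l+1)/r^2 eigenfunctions to a fraction
# of a percent in the mean-square sense.
mesh_laplacian <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (corner in 1:3) {
    a <- f[, corner]
    b <- f[, (corner %% 3) + 1]
    cc <- f[, ((corner + 1) %% 3) + 1]
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w2 <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    cosang <- rowSums(u * w2) / sqrt(rowSums(u^2) * rowSums(w2^2))
    cotan <- cosang / sqrt(pmax(1e-300, 1 - cosang^2))
    ii <- c(ii, b, cc); jj <- c(jj, cc, b); ww <- c(ww, cotan / 2, cotan / 2)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fa <- sqrt(rowSums(cr^2)) / 2
  va <- rowsum(c(fa, fa, fa) / 3, c(f[, 1], f[, 2], f[, 3]))[, 1]
  L <- Matrix::Diagonal(n, Matrix::rowSums(A)) - A
  Matrix::Diagonal(n, 1 / va) %*% L
}

#' Surface-Laplacian (LORETA) smoothness prior
#'
#' Precision `D^-1 L' L D^-1` built from the area-normalized cotangent
#' Laplacian `L` of each hemisphere's folded mesh (block-diagonal over
#' hemispheres) and `D = diag(w)^(1/2)` with `w` the depth weights, so the
#' implied covariance `D (L'L)^-1 D` combines smoothness with higher
#' variance for deeper dipoles.  A tiny ridge (1e-8 of the mean diagonal)
#' makes the singular Laplacian normal matrix invertible; the prior is only
#' ever applied through sparse factorization.
#'
#' @param space a `source_space` or single `cortical_surface`.
#' @param depth per-dipole depth weights (default all-ones: pure smoothness).
#' @return a precision-form `source_prior` in dipole space.
#' @export
loreta_prior <- function(space, depth = NULL) {
  surfs <- if (inherits(space, "cortical_surface")) list(space) else space
  Ls <- lapply(surfs, function(s) {
    g <- igraph::graph_from_edgelist(mesh_edges(s$folded), directed = FALSE)
    if (igraph::components(g)$no != 1) stop("mesh is not connected")
    mesh_laplacian(s$folded)
  })
  L <- Matrix::bdiag(Ls)
  M <- nrow(L)
  if (is.null(depth)) depth <- rep(1, M)
  if (length(depth) != M) stop("depth weights must have one entry per dipole")
  Dinv <- Matrix::Diagonal(M, depth^(-1 / 2))
  P <- Dinv %*% Matrix::crossprod(L) %*% Dinv
  P <- Matrix::forceSymmetric(P)
  P <- P + Matrix::Diagonal(M, 1e-8 * mean(Matrix::diag(P)))
  source_prior(precision = P, label = "loreta-laplacian",
               params = list(depth = !all(depth == 1)))
}

#' Informed basis functions from a Gaussian coherence matrix
#'
#' Leading eigenvectors, per hemisphere, of the coherence matrix
#' `exp(-d_ij^2 / (2 sigma^2))` over approximate geodesic (graph shortest
#' path) distances on the folded mesh.
#'
#' @param space a `source_space` or single `cortical_surface`.
#' @param sigma coherence length in mm (default 10).
#' @param K_per_hemi basis functions kept per hemisphere (default 512).
#' @return a `basis_set` of kind `"ibf"` (rows are orthonormal per block).
#' @export
ibf_basis <- function(space, sigma = 10, K_per_hemi = 512) {
  if (sigma <= 0) stop("sigma must be positive")
  surfs <- if (inherits(space, "cortical_surface")) list(space) else space
  per <- lapply(surfs, function(s) {
    M <- nrow(s$folded$vertices)
    if (K_per_hemi > M) stop("K_per_hemi exceeds the hemisphere dipole count")
    e <- mesh_edges(s$folded)
    v <- s$folded$vertices
    len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    d <- igraph::distances(g, weights = len)
    C <- exp(-d^2 / (2 * sigma^2))
    ev <- eigen((C + t(C)) / 2, symmetric = TRUE)
    list(T = t(ev$vectors[, seq_len(K_per_hemi), drop = FALSE]),
         info = data.frame(eigenvalue = ev$values[seq_len(K_per_hemi)]))
  })
  assemble_blocks(space, per, "ibf")
}

# Solve (K_s + lambda C) X = B symmetrically, ridge-loading C if singular.
sensor_space_solve <- function(K_s, C, lambda, B) {
  A <- (K_s + t(K_s)) / 2 + lambda * (C + t(C)) / 2
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    A <- A + diag(1e-10 * sum(diag(A)), nrow(A))
    ch <- tryCatch(chol(A), error = function(e)
      stop("singular sensor-space matrix even after ridge loading"))
  }
  backsolve(ch, forwardsolve(t(ch), B))
}

prior_times <- function(prior, X) {
  # returns R %*% X without forming R densely
  if (is.null(prior)) return(X)
  if (prior$kind == "diagonal") prior$weights * X
  else as.matrix(Matrix::solve(prior$precision, X))
}

#' Bayesian linear inverse operator
#'
#' `W = R G' (G R G' + lambda C_n)^-1` in the dipole basis; `R` is given by
#' a `source_prior` (identity when omitted) and is applied implicitly (a
#' diagonal scales rows; a precision prior is solved sparsely).
#'
#' @param G a `gain_matrix` or plain matrix (sensors x columns).
#' @param C_n a `noise_covariance` or matrix.
#' @param prior a `source_prior` in dipole space, or `NULL` for minimum norm.
#' @param lambda positive regularization parameter.
#' @return an `inverse_operator`.
#' @export
linear_inverse <- function(G, C_n, prior = NULL, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  Gm <- if (inherits(G, "gain_matrix")) G$matrix else as.matrix(G)
  C <- if (inherits(C_n, "noise_covariance")) C_n$matrix else as.matrix(C_n)
  RGt <- prior_times(prior, t(Gm))
  K_s <- Gm %*% RGt
  W <- RGt %*% sensor_space_solve(K_s, C, lambda, diag(nrow(Gm)))
  inverse_operator(W, algorithm = if (is.null(prior)) "mne" else prior$label,
                   lambda = lambda,
                   orientation = if (inherits(G, "gain_matrix")) G$orientation
                                 else "constrained",
                   reference = if (inherits(G, "gain_matrix")) G$reference
                               else "none")
}

#' Basis-transformed inverse operator
#'
#' `W = T' R_b Gt' (Gt R_b Gt' + lambda C_n)^-1` with `Gt = G T'`: the
#' inverse is solved in the K-dimensional global basis and mapped back to
#' dipoles; algebraically identical to [linear_inverse()] with the
#' dipole-space prior `T' R_b T`.
#'
#' @param G a `gain_matrix` or matrix (orientation-constrained).
#' @param basis a `basis_set` (K x M transform).
#' @param prior a `source_prior` in basis space, or `NULL` for identity.
#' @param C_n a `noise_covariance` or matrix.
#' @param lambda positive regularization parameter.
#' @return an `inverse_operator`.
#' @export
basis_inverse <- function(G, basis, prior = NULL, C_n, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  Gm <- if (inherits(G, "gain_matrix")) G$matrix else as.matrix(G)
  if (inherits(G, "gain_matrix") && G$orientation == "free")
    stop("basis inverses are defined for orientation-constrained gains")
  T <- basis$T
  if (ncol(Gm) != ncol(T)) stop("gain columns and basis columns must match")
  C <- if (inherits(C_n, "noise_covariance")) C_n$matrix else as.matrix(C_n)
  Gt <- Gm %*% t(T)
  RGt <- prior_times(prior, t(Gt))
  K_s <- Gt %*% RGt
  Wb <- RGt %*% sensor_space_solve(K_s, C, lambda, diag(nrow(Gm)))
  W <- t(T) %*% Wb
  inverse_operator(W, algorithm = paste0("basis-", basis$kind),
                   lambda = lambda, basis = basis$kind,
                   orientation = "constrained",
                   reference = if (inherits(G, "gain_matrix")) G$reference
                               else "none",
                   basis_operator = Wb)
}

#' Inverse-operator container
#'
#' @param W M (or 3M) x sensors matrix mapping data to source amplitudes.
#' @param algorithm label of the recipe that produced it.
#' @param lambda regularization parameter used.
#' @param basis basis kind, if any.
#' @param orientation `"constrained"` or `"free"`.
#' @param normalization `"none"`, `"dspm"` or `"sloreta"`.
#' @param sigma per-source noise SDs (filled by dSPM normalization).
#' @param reference `"average"` if the operator was built from an
#'   average-referenced gain (incoming data are then re-referenced on
#'   application), `"none"` otherwise.
#' @param basis_operator optional K x sensors operator in basis space.
#' @return an `inverse_operator`.
#' @export
inverse_operator <- function(W, algorithm, lambda, basis = NULL,
                             orientation = "constrained",
                             normalization = "none", sigma = NULL,
                             reference = "none", basis_operator = NULL) {
  structure(list(W = W, algorithm = algorithm, lambda = lambda,
                 basis = basis, orientation = orientation,
                 normalization = normalization, sigma = sigma,
                 reference = reference, basis_operator = basis_operator),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("inverse_operator (%s): %d x %d, lambda %.3g, normalization %s\n",
              x$algorithm, nrow(x$W), ncol(x$W), x$lambda, x$normalization))
  invisible(x)
}

# Dipole count of an operator (rows / 3 in free mode).
op_n_sources <- function(op) {
  if (op$orientation == "free") nrow(op$W) / 3 else nrow(op$W)
}

#' Per-source noise standard deviation
#'
#' Propagates the sensor-noise covariance through the operator:
#' `sigma_j^2 = sum_ab W_ja C_ab W_jb`; free orientation sums the three
#' component variances per dipole.
#'
#' @param op an `inverse_operator` (or plain W matrix).
#' @param C_n a `noise_covariance` or matrix.
#' @param orientation used when `op` is a plain matrix.
#' @return per-dipole noise SD vector.
#' @export
solution_noise_sd <- function(op, C_n, orientation = "constrained") {
  W <- if (inherits(op, "inverse_operator")) op$W else as.matrix(op)
  if (inherits(op, "inverse_operator")) orientation <- op$orientation
  C <- if (inherits(C_n, "noise_covariance")) C_n$matrix else as.matrix(C_n)
  v <- rowSums((W %*% C) * W)
  if (orientation == "free") v <- colSums(matrix(v, nrow = 3))
  sqrt(pmax(v, 0))
}

#' Noise-normalize an inverse operator
#'
#' dSPM divides each operator row by the source's propagated noise SD,
#' turning estimates into Z-scores under the noise model; sLORETA divides by
#' the square root of the corresponding diagonal of the model resolution
#' matrix `W G` (free orientation uses the trace of each 3x3 resolution
#' block).
#'
#' @param op an unnormalized `inverse_operator`.
#' @param method `"dspm"` or `"sloreta"`.
#' @param G the `gain_matrix` (required for sLORETA).
#' @param C_n the `noise_covariance` (required for dSPM).
#' @return a normalized `inverse_operator` with `sigma` filled for dSPM.
#' @export
normalize_operator <- function(op, method = c("dspm", "sloreta"), G = NULL,
                               C_n = NULL) {
  method <- match.arg(method)
  free <- op$orientation == "free"
  if (method == "dspm") {
    if (is.null(C_n)) stop("dSPM needs the noise covariance")
    s <- solution_noise_sd(op, C_n)
    if (any(s <= 0))
      stop("non-positive noise SD for dipole(s) ", paste(which(s <= 0), collapse = ", "))
    denom <- if (free) rep(s, each = 3) else s
    op$W <- op$W / denom
    op$sigma <- s
  } else {
    if (is.null(G)) stop("sLORETA needs the gain matrix")
    Gm <- if (inherits(G, "gain_matrix")) G$matrix else as.matrix(G)
    d <- rowSums(op$W * t(Gm))          # diag(W G)
    if (free) d <- colSums(matrix(d, nrow = 3))
    if (any(d <= 0))
      stop("non-positive resolution diagonal for dipole(s) ",
           paste(which(d <= 0), collapse = ", "))
    denom <- if (free) rep(sqrt(d), each = 3) else sqrt(d)
    op$W <- op$W / denom
  }
  op$normalization <- method
  op
}

#' Signal-to-noise significance mask
#'
#' Per-dipole statistic `q_j = s_j^2 / sigma_j^2` (squared amplitude over
#' propagated noise variance; free orientation uses the squared component
#' norm), compared against the chi-square quantile with 1 (constrained) or 3
#' (free) degrees of freedom at the Bonferroni-corrected level
#' `alpha / n_sensors`.
#'
#' @param estimate a `source_estimate` or per-dipole amplitude vector.
#' @param sigma per-dipole noise SDs.
#' @param alpha family-wise level before correction (default 0.05).
#' @param n_sensors Bonferroni divisor (number of sensors).
#' @param df numerator degrees of freedom; inferred from the estimate's
#'   orientation when it is a `source_estimate`.
#' @return list with `q` (statistic) and `significant` (logical mask).
#' @export
f_threshold <- function(estimate, sigma, alpha = 0.05, n_sensors, df = 1) {
  if (inherits(estimate, "source_estimate")) {
    df <- if (estimate$orientation == "free") 3 else 1
    amp <- estimate$magnitude[, 1]
  } else amp <- abs(as.numeric(estimate))
  if (any(sigma <= 0)) stop("sigma must be positive")
  q <- amp^2 / sigma^2
  thr <- stats::qchisq(1 - alpha / n_sensors, df = df)
  list(q = q, threshold = thr, significant = q > thr)
}

#' Apply an inverse operator to sensor data
#'
#' @param op an `inverse_operator`.
#' @param v sensor vector or sensors x time matrix (V).
#' @return a `source_estimate` with signed `values` (constrained: outward
#'   positive) or stacked 3-vectors, and per-dipole `magnitude`.
#' @export
apply_inverse <- function(op, v) {
  v <- as.matrix(v)
  if (nrow(v) != ncol(op$W))
    stop(sprintf("data has %d sensors; operator expects %d", nrow(v), ncol(op$W)))
  if (identical(op$reference, "average")) v <- apply_average_reference(v)
  vals <- op$W %*% v
  mag <- if (op$orientation == "free") {
    sq <- vals^2
    sqrt(sq[seq(1, nrow(vals), 3), , drop = FALSE] +
         sq[seq(2, nrow(vals), 3), , drop = FALSE] +
         sq[seq(3, nrow(vals), 3), , drop = FALSE])
  } else abs(vals)
  structure(list(values = vals, magnitude = mag,
                 orientation = op$orientation, algorithm = op$algorithm,
                 normalization = op$normalization),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("source_estimate (%s): %d dipoles x %d samples (%s)\n",
              x$algorithm, nrow(x$magnitude), ncol(x$magnitude),
              x$orientation))
  invisible(x)
}
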