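#' Sensor arrays
#'
#' @param labels character vector of unique sensor names.
#' @param positions numeric matrix (sensors x 3, mm).
#' @param reference reference convention of data recorded with this array;
#'   only `"average"` is supported.
#' @return a `sensor_array`.
#' @export
sensor_array <- function(labels, positions, reference = "average") {
  positions <- as.matrix(positions)
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("sensor labels must be unique")
  if (length(labels) < 2) stop("need at least 2 sensors")
  if (nrow(positions) != length(labels) || ncol(positions) != 3)
    stop("positions must be a sensors x 3 matrix")
  structure(list(labels = labels, positions = positions,
                 reference = match.arg(reference, "average")),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d sensors (%s reference)\n",
              length(x$labels), x$reference))
  invisible(x)
}

#' Fibonacci-lattice electrode net
#'
#' Quasi-uniform sensor layout on the upper part of a sphere, emulating the
#' coverage of a high-density EEG net.
#'
#' @param n number of sensors (default 128).
#' @param radius sphere radius in mm (default 92, the default outer shell).
#' @param coverage fraction of the full sphere covered from the vertex down
#'   (default 0.75, leaving the "face/neck" region free).
#' @return a `sensor_array` with labels `E1..En`.
#' @export
fibonacci_sensors <- function(n = 128, radius = 92, coverage = 0.75) {
  k <- seq_len(n)
  z <- 1 - 2 * coverage * (k - 0.5) / n
  phi <- 2 * pi * k * (2 / (1 + sqrt(5)))
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(rho * cos(phi), rho * sin(phi), z)
  sensor_array(paste0("E", k), pos)
}

# Per-degree surface transfer coefficients of the concentric-shell conductor.
# The primary interior potential is normalized to (rho_1 / rho)^(l+1)
# (unit value at the innermost interface, rho = r / r_outer), and each
# layer's radial basis is scaled at its own boundaries so the linear system
# stays well-conditioned at high degree.  Returns the outer-surface
# potential per degree; equal conductivities give (2l+1)/l * rho_1^(l+1).
shell_transfer <- function(radii, conductivities, lmax) {
  nl <- length(radii)
  if (nl != length(conductivities)) stop("radii/conductivities length mismatch")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  rho <- radii / radii[nl]
  S <- numeric(lmax)
  # layer j potential: a_j (rho/rho_j)^l + b_j (rho_{j-1}/rho)^(l+1), b_1 fixed
  for (l in seq_len(lmax)) {
    nun <- 1 + 2 * (nl - 1)
    A <- matrix(0, nun, nun)
    rhs <- numeric(nun)
    idx <- function(j, which) if (j == 1) 1 else 1 + 2 * (j - 2) + which
    row <- 0
    for (j in seq_len(nl - 1)) {
      r <- rho[j]
      ratio_in <- if (j == 1) 1 else (rho[j - 1] / rho[j])^(l + 1)
      ratio_up <- (rho[j] / rho[j + 1])^l
      # potential continuity at rho_j
      row <- row + 1
      A[row, idx(j, 1)] <- 1
      if (j > 1) A[row, idx(j, 2)] <- ratio_in
      A[row, idx(j + 1, 1)] <- -ratio_up
      A[row, idx(j + 1, 2)] <- -1
      if (j == 1) rhs[row] <- -1                       # primary value at rho_1
      # radial current continuity at rho_j (common 1/r factor dropped)
      row <- row + 1
      A[row, idx(j, 1)] <- conductivities[j] * l
      if (j > 1) A[row, idx(j, 2)] <- -conductivities[j] * (l + 1) * ratio_in
      A[row, idx(j + 1, 1)] <- -conductivities[j + 1] * l * ratio_up
      A[row, idx(j + 1, 2)] <- conductivities[j + 1] * (l + 1)
      if (j == 1) rhs[row] <- conductivities[1] * (l + 1)   # primary derivative
    }
    # insulating outer boundary at rho = 1
    row <- row + 1
    A[row, idx(nl, 1)] <- l
    A[row, idx(nl, 2)] <- -(l + 1) * rho[nl - 1]^(l + 1)
    sol <- solve(A, rhs)
    S[l] <- sol[idx(nl, 1)] + sol[idx(nl, 2)] * rho[nl - 1]^(l + 1)
  }
  S
}

#' Analytic layered-sphere EEG gain matrix
#'
#' Potential of each unit cortical dipole at each sensor for a concentric
#' multi-shell (default 3-shell: brain/CSF, skull, scalp) spherical
#' conductor, via the truncated Legendre series solution with per-degree
#' shell transfer coefficients, then average-referenced.  In constrained
#' mode the three Cartesian components are projected onto the outward
#' cortical normals, one column per dipole; in free mode there are three
#' columns (x, y, z moments) per dipole.
#'
#' @param sensors a `sensor_array`; positions are projected radially onto the
#'   outer shell (a warning is given beyond 2% radial mismatch).
#' @param space a `source_space` or single `cortical_surface`; all folded
#'   vertices must lie strictly inside the innermost shell.
#' @param radii shell radii in mm, innermost first (default `c(80, 85, 92)`).
#' @param conductivities relative conductivities per shell
#'   (default `c(1, 1/30, 1)` for brain, skull, scalp).
#' @param truncation number of series terms (default 80, minimum 20).
#' @param orientation `"constrained"` (normal dipoles) or `"free"`.
#' @param sigma_base absolute conductivity of a unit relative shell, S/m
#'   (default 0.33), fixing the gain units to V per A*m.
#' @return a `gain_matrix`.
#' @export
layered_sphere_gain <- function(sensors, space, radii = c(80, 85, 92),
                                conductivities = c(1, 1 / 30, 1),
                                truncation = 80,
                                orientation = c("constrained", "free"),
                                sigma_base = 0.33) {
  orientation <- match.arg(orientation)
  if (truncation < 20) stop("series truncation must be at least 20")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  dip <- space_vertices(space)             # mm
  b <- sqrt(rowSums(dip^2))
  if (any(b >= radii[1])) stop("geometry error: dipole(s) outside the innermost shell")
  pos <- sensors$positions
  rs <- sqrt(rowSums(pos^2))
  if (any(abs(rs / radii[length(radii)] - 1) > 0.02))
    warning("sensor radii deviate more than 2% from the outer shell; projecting radially")
  xhat <- pos / rs                          # unit sensor directions
  ns <- nrow(xhat)
  M <- nrow(dip)
  phat <- dip / pmax(b, .Machine$double.eps)
  t_d <- b / radii[1]                       # dipole radius relative to inner shell
  S <- shell_transfer(radii, conductivities, truncation)
  cosg <- xhat %*% t(phat)                  # ns x M
  cosg <- pmin(1, pmax(-1, cosg))
  # accumulate sum_rad = sum_l S_l l t^(l-1) P_l(x), sum_tan with P_l'(x)
  Pm1 <- matrix(1, ns, M)                   # P_0
  P <- cosg                                 # P_1
  dPm1 <- matrix(0, ns, M)                  # P_0'
  dP <- matrix(1, ns, M)                    # P_1'
  tl <- rep(1, M)                           # t^(l-1) for l = 1
  col_t <- function(mat, v) mat * rep(v, each = ns)
  sum_rad <- col_t(P, S[1] * 1 * tl)
  sum_tan <- col_t(dP, S[1] * tl)
  for (l in 2:truncation) {
    Pn <- ((2 * l - 1) * cosg * P - (l - 1) * Pm1) / l
    dPn <- dPm1 + (2 * l - 1) * P
    Pm1 <- P; P <- Pn
    dPm1 <- dP; dP <- dPn
    tl <- tl * t_d
    sum_rad <- sum_rad + col_t(P, S[l] * l * tl)
    sum_tan <- sum_tan + col_t(dP, S[l] * tl)
  }
  r1_m <- radii[1] / 1000
  kappa <- 1 / (4 * pi * conductivities[1] * sigma_base * r1_m^2)
  G3 <- matrix(0, ns, 3 * M)
  for (comp in 1:3) {
    e_pr <- phat[, comp]                    # e . phat per dipole
    e_xs <- xhat[, comp]                    # e . xhat per sensor
    dot_perp <- outer(e_xs, rep(1, M)) - cosg * rep(e_pr, each = ns)
    G3[, seq(comp, by = 3, length.out = M)] <-
      kappa * (col_t(sum_rad, e_pr) + sum_tan * dot_perp)
  }
  if (orientation == "constrained") {
    nrm <- space_normals(space)
    G <- matrix(0, ns, M)
    for (comp in 1:3)
      G <- G + G3[, seq(comp, by = 3, length.out = M), drop = FALSE] *
        rep(nrm[, comp], each = ns)
  } else {
    G <- G3
  }
  gain_matrix(apply_average_reference(G), orientation = orientation,
              n_sources = M, reference = "average")
}

#' Gain matrix container
#'
#' @param matrix sensors x (M or 3M) numeric matrix, V per A*m.
#' @param orientation `"constrained"` or `"free"`.
#' @param n_sources dipole count M.
#' @param reference `"average"` if the average reference has been applied.
#' @return a `gain_matrix`.
#' @export
gain_matrix <- function(matrix, orientation = c("constrained", "free"),
                        n_sources, reference = c("average", "none")) {
  orientation <- match.arg(orientation)
  reference <- match.arg(reference)
  matrix <- as.matrix(matrix)
  want <- if (orientation == "constrained") n_sources else 3 * n_sources
  if (ncol(matrix) != want)
    stop(sprintf("gain has %d columns; %d expected for %d %s sources",
                 ncol(matrix), want, n_sources, orientation))
  structure(list(matrix = matrix, orientation = orientation,
                 n_sources = n_sources, reference = reference),
            class = "gain_matrix")
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat(sprintf("gain_matrix: %d sensors x %d columns (%d %s sources, %s reference)\n",
              nrow(x$matrix), ncol(x$matrix), x$n_sources, x$orientation,
              x$reference))
  invisible(x)
}

#' Apply the average reference
#'
#' Subtracts the across-sensor mean from every column so each column of the
#' gain (or each sensor vector) sums to zero.
#'
#' @param x numeric matrix (sensors x columns) or vector.
#' @return same shape, average-referenced.
#' @export
apply_average_reference <- function(x) {
  if (is.matrix(x)) sweep(x, 2, colMeans(x)) else x - mean(x)
}

#' Noise covariance estimate from epochs
#'
#' Empirical covariance of noise epochs after subtracting the across-epoch
#' mean, optionally shrunk toward its own diagonal.
#'
#' @param epochs epochs x sensors numeric matrix (V).
#' @param shrinkage weight in `[0, 1]` of the diagonal target (default 0).
#' @return a `noise_covariance`.
#' @export
estimate_noise_covariance <- function(epochs, shrinkage = 0) {
  epochs <- as.matrix(epochs)
  if (nrow(epochs) < 2) stop("need at least 2 epochs to estimate noise covariance")
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  centered <- sweep(epochs, 2, colMeans(epochs))
  C <- crossprod(centered) / (nrow(epochs) - 1)
  C <- (1 - shrinkage) * C + shrinkage * diag(diag(C), ncol(C))
  noise_covariance(C, recipe = sprintf("empirical (%d epochs, shrinkage %.2f)",
                                       nrow(epochs), shrinkage))
}

#' Noise covariance container
#'
#' @param matrix symmetric PSD sensors x sensors matrix (V^2).
#' @param recipe free-text provenance of the estimate.
#' @return a `noise_covariance`.
#' @export
noise_covariance <- function(matrix, recipe = "analytic") {
  matrix <- as.matrix(matrix)
  matrix <- (matrix + t(matrix)) / 2
  ev <- eigen(matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(sum(diag(matrix)), .Machine$double.eps))
    stop("noise covariance is not positive semi-definite")
  structure(list(matrix = matrix, recipe = recipe), class = "noise_covariance")
}

#' Spatially correlated sensor-noise covariance
#'
#' Squared-exponential spatial correlation
#' `sd^2 [(1 - f) exp(-d^2 / (2 l^2)) + f I]` over Euclidean inter-sensor
#' distances, mimicking the smooth residual noise of averaged evoked
#' recordings plus a per-channel white (amplifier) floor of variance
#' fraction `f`.  A purely smooth kernel would be numerically rank-deficient
#' (its spectrum decays below machine precision), which no physical
#' recording exhibits.  The default per-channel SD of 1/3 uV keeps noise
#' amplitudes essentially within 1 uV.
#'
#' @param sensors a `sensor_array`.
#' @param sd per-channel noise SD in volts (default `1e-6 / 3`).
#' @param length_scale correlation length in mm (default 30).
#' @param white_fraction variance fraction of the uncorrelated floor
#'   (default 0.2).
#' @return a `noise_covariance`.
#' @export
sensor_noise_covariance <- function(sensors, sd = 1e-6 / 3, length_scale = 30,
                                    white_fraction = 0.2) {
  if (white_fraction < 0 || white_fraction > 1)
    stop("white_fraction must be in [0, 1]")
  d2 <- as.matrix(dist(sensors$positions))^2
  C <- sd^2 * ((1 - white_fraction) * exp(-d2 / (2 * length_scale^2)) +
               white_fraction * diag(nrow(d2)))
  noise_covariance(C, recipe = sprintf(
    "squared-exponential + white floor (sd %.3g V, l %.3g mm, f %.2f)",
    sd, length_scale, white_fraction))
}

#' Draw zero-mean Gaussian sensor noise
#'
#' @param covariance a `noise_covariance` (or matrix).
#' @param n_samples number of draws.
#' @param seed integer seed; draws are reproducible and do not disturb the
#'   caller's RNG state.
#' @return `n_samples` x sensors matrix.
#' @export
synth_noise <- function(covariance, n_samples, seed = 1) {
  C <- if (inherits(covariance, "noise_covariance")) covariance$matrix else as.matrix(covariance)
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-12 * max(sum(diag(C)), .Machine$double.eps))
    stop("covariance is not positive semi-definite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), ncol(C))
  rng <- local_rng(seed)
  Z <- matrix(rng$norm(n_samples * ncol(C)), n_samples, ncol(C))
  Z %*% t(L)
}
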