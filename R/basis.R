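# Fully normalized associated Legendre functions via the standard stable
# (sectoral-seeded) recurrences; no Condon-Shortley phase.  Returns a list
# indexed by m+1 of matrices (rows l = m..L) evaluated at x = cos(theta).
normalized_legendre <- function(L, x) {
  n <- length(x)
  sx <- sqrt(pmax(0, 1 - x^2))
  out <- vector("list", L + 1)
  Pmm <- rep(sqrt(1 / (4 * pi)), n)
  for (m in 0:L) {
    if (m > 0) Pmm <- sqrt((2 * m + 1) / (2 * m)) * sx * Pmm
    block <- matrix(0, L - m + 1, n)
    block[1, ] <- Pmm
    if (L > m) {
      Plm1 <- Pmm
      Pl <- sqrt(2 * m + 3) * x * Pmm
      block[2, ] <- Pl
      if (L > m + 1) {
        for (l in (m + 2):L) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          Pn <- a * (x * Pl - b * Plm1)
          Plm1 <- Pl; Pl <- Pn
          block[l - m + 1, ] <- Pl
        }
      }
    }
    out[[m + 1]] <- block
  }
  out
}

# Real orthonormal spherical harmonics evaluated at spherical angles.
# Rows enumerate (l, m) with l = 0..L and m = -l..l (sine harmonics for
# m < 0, cosine for m > 0); columns are the evaluation points.
real_spherical_harmonics <- function(L, theta, phi) {
  x <- cos(theta)
  P <- normalized_legendre(L, x)
  K <- (L + 1)^2
  n <- length(theta)
  T <- matrix(0, K, n)
  ldeg <- integer(K); mord <- integer(K)
  row <- 0
  for (l in 0:L) {
    for (m in (-l):l) {
      row <- row + 1
      ldeg[row] <- l; mord[row] <- m
      am <- abs(m)
      p <- P[[am + 1]][l - am + 1, ]
      T[row, ] <- if (m == 0) p
                  else if (m > 0) sqrt(2) * p * cos(m * phi)
                  else sqrt(2) * p * sin(am * phi)
    }
  }
  list(T = T, l = ldeg, m = mord)
}

# Spherical angles (colatitude from +z, azimuth in [0, 2pi)) of the
# unit-sphere vertices of a cortical surface.
sphere_angles <- function(surface) {
  v <- surface$sphere$vertices
  theta <- acos(pmin(1, pmax(-1, v[, 3])))
  phi <- atan2(v[, 2], v[, 1]) %% (2 * pi)
  list(theta = theta, phi = phi)
}

#' Basis-set container
#'
#' A linear transform `T` (basis functions x dipoles) from a small global
#' basis to dipole amplitudes, block-diagonal over hemispheres: rows of one
#' hemisphere have exact zeros on the other hemisphere's dipole columns.
#'
#' @param T K x M numeric matrix.
#' @param kind `"harmonics"`, `"splines"`, `"ibf"` or `"dipole-identity"`.
#' @param row_info data.frame with one row per basis function (hemisphere
#'   plus degree `l`/order `m` labels or center vertices).
#' @param blocks named list of row/column index ranges per hemisphere.
#' @return a `basis_set`.
#' @export
basis_set <- function(T, kind, row_info, blocks) {
  if (nrow(T) > ncol(T)) stop("basis must not exceed the dipole count (K <= M)")
  structure(list(T = T, kind = kind, row_info = row_info, blocks = blocks),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("basis_set (%s): %d functions x %d dipoles\n",
              x$kind, nrow(x$T), ncol(x$T)))
  invisible(x)
}

# Assemble per-hemisphere evaluation blocks into a block-diagonal basis_set.
assemble_blocks <- function(space, per_hemi, kind) {
  if (inherits(space, "cortical_surface")) space <- list(space)
  Ms <- vapply(space, function(s) nrow(s$sphere$vertices), 0L)
  Ks <- vapply(per_hemi, function(b) nrow(b$T), 0L)
  T <- matrix(0, sum(Ks), sum(Ms))
  info <- list(); blocks <- list()
  r0 <- 0L; c0 <- 0L
  for (i in seq_along(space)) {
    T[r0 + seq_len(Ks[i]), c0 + seq_len(Ms[i])] <- per_hemi[[i]]$T
    info[[i]] <- cbind(hemisphere = space[[i]]$hemisphere, per_hemi[[i]]$info)
    blocks[[space[[i]]$hemisphere]] <- list(rows = r0 + seq_len(Ks[i]),
                                            cols = c0 + seq_len(Ms[i]))
    r0 <- r0 + Ks[i]; c0 <- c0 + Ms[i]
  }
  basis_set(T, kind, do.call(rbind, info), blocks)
}

#' Spherical-harmonic source basis
#'
#' Real orthonormal spherical harmonics up to degree `L_max`, evaluated at
#' each dipole's spherical angles on the hemisphere's sphere mapping;
#' `(L_max + 1)^2` functions per hemisphere, assembled block-diagonally.
#'
#' @param space a `source_space` or single `cortical_surface`.
#' @param L_max degree cutoff (default 10, i.e. 121 harmonics per hemisphere).
#' @return a `basis_set` of kind `"harmonics"`.
#' @export
harmonics_basis <- function(space, L_max = 10) {
  if (L_max < 0) stop("L_max must be non-negative")
  surfs <- if (inherits(space, "cortical_surface")) list(space) else space
  per <- lapply(surfs, function(s) {
    if (is.null(s$sphere)) stop("surface has no sphere mapping")
    ang <- sphere_angles(s)
    sh <- real_spherical_harmonics(L_max, ang$theta, ang$phi)
    list(T = sh$T, info = data.frame(l = sh$l, m = sh$m))
  })
  assemble_blocks(space, per, "harmonics")
}

#' Abel-Poisson kernel
#'
#' Closed form `(1/4pi) (1 - h^2) / (1 + h^2 - 2 h cos(gamma))^(3/2)`,
#' equal to the Legendre series `sum_l (2l+1) h^l P_l(cos gamma) / 4pi`.
#'
#' @param cos_gamma cosine of the angle between kernel center and evaluation
#'   point.
#' @param h scale parameter in (0, 1); larger is more concentrated.
#' @return kernel values (strictly positive).
#' @export
abel_poisson_kernel <- function(cos_gamma, h) {
  if (h <= 0 || h >= 1) stop("h must be in (0, 1)")
  (1 - h^2) / (4 * pi * (1 + h^2 - 2 * h * cos_gamma)^1.5)
}

#' Spherical-spline source basis
#'
#' Abel-Poisson spherical splines centered on a quasi-uniform subset of the
#' sphere mapping.  Default centers are the level-2 icosphere nodes snapped
#' to the nearest mesh vertex (162 per hemisphere; exact vertices for meshes
#' generated by [icosphere()] at level 2 or above).
#'
#' @param space a `source_space` or single `cortical_surface`.
#' @param centers optional integer vector of center vertices (applied per
#'   hemisphere).
#' @param h spline scale in (0, 1) (default 0.8).
#' @return a `basis_set` of kind `"splines"`.
#' @export
splines_basis <- function(space, centers = NULL, h = 0.8) {
  if (h <= 0 || h >= 1) stop("h must be in (0, 1)")
  surfs <- if (inherits(space, "cortical_surface")) list(space) else space
  per <- lapply(surfs, function(s) {
    v <- s$sphere$vertices
    ctr <- centers
    if (is.null(ctr)) {
      grid <- icosphere(2)$vertices
      ctr <- apply(grid, 1, function(g) which.max(v %*% g))
      ctr <- unique(ctr)
    }
    cosg <- v[ctr, , drop = FALSE] %*% t(v)
    cosg[cosg > 1] <- 1; cosg[cosg < -1] <- -1
    list(T = abel_poisson_kernel(cosg, h),
         info = data.frame(center_vertex = ctr))
  })
  assemble_blocks(space, per, "splines")
}

#' Identity (single-dipole) basis
#'
#' The trivial basis in which every dipole is its own basis function; the
#' inverse in this basis is the plain minimum-norm family.
#'
#' @param space a `source_space` or single `cortical_surface`.
#' @return a `basis_set` of kind `"dipole-identity"`.
#' @export
dipole_basis <- function(space) {
  surfs <- if (inherits(space, "cortical_surface")) list(space) else space
  per <- lapply(surfs, function(s) {
    M <- nrow(s$sphere$vertices)
    list(T = diag(M), info = data.frame(center_vertex = seq_len(M)))
  })
  assemble_blocks(space, per, "dipole-identity")
}

#' Spatial Nyquist degree cutoff for a sensor array
#'
#' The smallest harmonic degree `L` whose sub-`L` harmonic count `L^2`
#' reaches the number of independent average-referenced signals
#' (`n_sensors - 1`): a 128-channel net gives `L = 12`, i.e. 169 harmonics
#' per surface.
#'
#' @param n_sensors number of sensors (at least 4).
#' @return integer degree cutoff.
#' @export
nyquist_cutoff <- function(n_sensors) {
  if (n_sensors < 1) stop("n_sensors must be positive")
  as.integer(ceiling(sqrt(n_sensors - 1)))
}

#' Encode basis coefficients as a compact stream
#'
#' Serializes a coefficients-by-time matrix (e.g. the 242 harmonic
#' coefficients per sample of a two-hemisphere orientation-constrained
#' solution) as little-endian float32 or scaled int16, with a header
#' carrying the shape, precision and scale.  The basis must be of kind
#' `"harmonics"`; free-orientation input is not supported.
#'
#' @param coefficients K x n_samples numeric matrix (or vector, one sample).
#' @param basis the `basis_set` the coefficients live in.
#' @param precision `"float32"` or `"int16"`.
#' @return a `coefficient_stream`: header list plus raw payload.
#' @export
encode_coefficients <- function(coefficients, basis,
                                precision = c("float32", "int16")) {
  precision <- match.arg(precision)
  if (basis$kind != "harmonics")
    stop("unsupported mode: coefficient streams are defined for the harmonic basis")
  x <- as.matrix(coefficients)
  if (nrow(x) != nrow(basis$T))
    stop("coefficient rows must match the basis size")
  if (precision == "float32") {
    payload <- writeBin(as.numeric(x), raw(), size = 4, endian = "little")
    scale <- 1
    tol <- max(abs(x)) * 2^-23 + 1e-45
  } else {
    scale <- max(abs(x)) / 32767
    if (scale == 0) scale <- 1
    payload <- writeBin(as.integer(round(x / scale)), raw(), size = 2,
                        endian = "little")
    tol <- scale / 2
  }
  structure(list(header = list(K = nrow(x), n_samples = ncol(x),
                               precision = precision, scale = scale,
                               declared_precision = tol),
                 data = payload),
            class = "coefficient_stream")
}

#' Decode a coefficient stream
#'
#' @param stream a `coefficient_stream` from [encode_coefficients()].
#' @return K x n_samples numeric matrix; round-trip error is below the
#'   stream's declared precision.
#' @export
decode_coefficients <- function(stream) {
  h <- stream$header
  n <- h$K * h$n_samples
  x <- if (h$precision == "float32")
    readBin(stream$data, numeric(), n = n, size = 4, endian = "little")
  else
    readBin(stream$data, integer(), n = n, size = 2, endian = "little") * h$scale
  matrix(x, h$K, h$n_samples)
}
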