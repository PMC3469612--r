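# Closed-form surface potential (degrees >= 1) of a current monopole inside
# an insulated homogeneous sphere; summing the Legendre generating-function
# identities gives 2(1/s - 1) + log(2 / (1 - t x + s)).
mono_closed <- function(src, sens, R, sigma) {
  b <- sqrt(sum(src^2)); t <- b / R
  xh <- sens / sqrt(sum(sens^2)); ph <- src / b
  x <- sum(xh * ph)
  s <- sqrt(1 - 2 * t * x + t^2)
  (1 / (4 * pi * sigma * R)) * (2 * (1 / s - 1) + log(2 / (1 - t * x + s)))
}

one_dipole_surface <- function(pos_mm, normal) {
  structure(list(
    hemisphere = "left",
    folded = structure(list(vertices = rbind(pos_mm),
                            faces = matrix(c(1, 1, 1), 1)), class = "tri_mesh"),
    sphere = structure(list(vertices = rbind(c(0, 0, 1)),
                            faces = matrix(c(1, 1, 1), 1)), class = "tri_mesh"),
    normals = rbind(normal)), class = "cortical_surface")
}

test_that("equal-conductivity layered sphere matches the closed-form dipole", {
  R <- 0.092; sigma <- 0.33
  src <- c(0.030, 0.020, 0.045)
  mom <- c(0.2, -0.5, 0.84); mom <- mom / sqrt(sum(mom^2))
  dirs <- rbind(c(0, 0, 1), c(0.6, 0.1, 0.79), c(-0.3, 0.8, 0.5),
                c(0.9, -0.4, 0.1), c(-0.7, -0.6, 0.4))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  eps <- 1e-7
  oracle <- apply(dirs, 1, function(s)
    (mono_closed(src + eps * mom / 2, s * R, R, sigma) -
     mono_closed(src - eps * mom / 2, s * R, R, sigma)) / eps)
  oracle <- oracle - mean(oracle)
  sa <- sensor_array(paste0("E", 1:5), dirs * 92)
  G <- layered_sphere_gain(sa, one_dipole_surface(src * 1000, mom),
                           conductivities = c(1, 1, 1), truncation = 250)
  expect_lt(max(abs(G$matrix[, 1] - oracle)) / max(abs(oracle)), 1e-8)
})

test_that("shell transfer reduces to the homogeneous closed form", {
  S <- harmonyeeg:::shell_transfer(c(80, 85, 92), c(1, 1, 1), 100)
  l <- 1:100
  expect_lt(max(abs(S / ((2 * l + 1) / l * (80 / 92)^(l + 1)) - 1)), 1e-12)
  expect_error(harmonyeeg:::shell_transfer(c(80, 85, 92), c(1, -1, 1), 10),
               "positive")
})

test_that("radial z-axis dipole gives axially symmetric potentials", {
  ph <- seq(0, 2 * pi, length.out = 17)[-17]
  ring <- function(th) 92 * cbind(sin(th) * cos(ph), sin(th) * sin(ph),
                                  rep(cos(th), length(ph)))
  sa <- sensor_array(paste0("R", seq_len(2 * length(ph))),
                     rbind(ring(pi / 3), ring(2 * pi / 3)))
  G <- layered_sphere_gain(sa, one_dipole_surface(c(0, 0, 50), c(0, 0, 1)))
  v <- G$matrix[, 1]
  # equal values within each equal-polar-angle ring, distinct across rings
  expect_lt(diff(range(v[1:16])), 1e-10 * diff(range(v)))
  expect_lt(diff(range(v[17:32])), 1e-10 * diff(range(v)))
})

test_that("potentials decay with angular distance from a superficial radial dipole", {
  th <- seq(0.05, pi - 0.05, length.out = 60)
  arc <- 92 * cbind(sin(th), 0, cos(th))
  sa <- sensor_array(paste0("A", seq_along(th)), arc)
  G <- layered_sphere_gain(sa, one_dipole_surface(c(0, 0, 70), c(0, 0, 1)),
                           truncation = 150)
  expect_true(all(diff(G$matrix[, 1]) < 0))
})

test_that("series truncation has converged by 60 terms for deep-enough sources", {
  surf <- make_pseudo_cortex(2, 0, hemisphere = "left", seed = 1,
                             radius = 0.85 * 80 * 0.8, offset = 0)
  sa <- fx$sensors(64)
  G60 <- layered_sphere_gain(sa, surf, truncation = 60)
  G200 <- layered_sphere_gain(sa, surf, truncation = 200)
  expect_lt(max(abs(G60$matrix - G200$matrix)) / max(abs(G200$matrix)), 1e-6)
})

test_that("gain contracts: average reference, linearity, geometry guards", {
  G <- fx$gain(2)
  expect_lt(max(abs(colSums(G$matrix))), 1e-10 * max(abs(G$matrix)))
  # linearity: doubling the dipole amplitude vector doubles the potentials
  s <- rnorm(G$n_sources)
  expect_equal(G$matrix %*% (2 * s), 2 * (G$matrix %*% s), tolerance = 1e-12)
  big <- make_pseudo_cortex(2, 0, hemisphere = "left", seed = 1, radius = 85,
                            offset = 0)
  expect_error(layered_sphere_gain(fx$sensors(64), big), "innermost shell")
  expect_error(layered_sphere_gain(fx$sensors(64), fx$space(2)$left,
                                   truncation = 10), "at least 20")
})

test_that("noise covariance estimation recovers a known covariance", {
  set.seed(8)
  p <- 12
  A <- matrix(rnorm(p * p), p)
  Sigma <- crossprod(A) / p + diag(p)
  eps <- synth_noise(Sigma, 10000, seed = 2)
  est <- estimate_noise_covariance(eps)
  expect_lt(norm(est$matrix - Sigma, "F") / norm(Sigma, "F"), 0.05)
  # identical epochs have zero covariance after mean subtraction
  same <- matrix(rep(rnorm(p), each = 5), 5, byrow = FALSE)
  expect_equal(max(abs(estimate_noise_covariance(same)$matrix)), 0)
  # full shrinkage leaves only the diagonal
  sh <- estimate_noise_covariance(eps, shrinkage = 1)
  expect_identical(sh$matrix, diag(diag(sh$matrix), p))
  expect_error(estimate_noise_covariance(eps[1, , drop = FALSE]), "2 epochs")
})

test_that("synthetic noise draws are reproducible and match their covariance", {
  expect_equal(max(abs(synth_noise(matrix(0, 4, 4), 10, seed = 1))), 0)
  expect_identical(synth_noise(diag(3), 5, seed = 7),
                   synth_noise(diag(3), 5, seed = 7))
  C <- sensor_noise_covariance(fx$sensors(16))$matrix
  N <- synth_noise(C, 100000, seed = 3)
  S <- crossprod(N) / nrow(N)
  expect_lt(norm(S - C, "F") / norm(C, "F"), 0.03)
  expect_error(synth_noise(matrix(c(1, 2, 2, 1), 2), 5), "positive semi-definite")
})

test_that("synthetic sensor noise stays within the evoked-noise amplitude budget", {
  C <- fx$noise_cov()
  N <- synth_noise(C, 200, seed = 4)
  expect_lt(sqrt(mean(N^2)), 1e-6)          # RMS at most 1 uV
  expect_lt(mean(abs(N) > 1e-6), 0.01)      # amplitudes essentially within 1 uV
})
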