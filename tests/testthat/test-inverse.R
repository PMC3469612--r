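test_that("minimum-norm limit reaches the Moore-Penrose pseudoinverse", {
  set.seed(42)
  G <- matrix(rnorm(16 * 200), 16)
  lam <- 1e-12 * sum(diag(tcrossprod(G))) / 16
  W <- linear_inverse(G, diag(16), NULL, lam)$W
  pinv <- t(G) %*% solve(tcrossprod(G))
  expect_lt(max(abs(W - pinv)), 1e-8)
  # shrinkage: operator norm decreases monotonically in lambda
  nrm <- sapply(10^(0:4), function(l) norm(linear_inverse(G, diag(16), NULL, l)$W, "F"))
  expect_true(all(diff(nrm) < 0))
  # row-space signals are recovered at tiny lambda
  s_row <- t(G) %*% rnorm(16)
  G2 <- matrix(rnorm(10 * 40), 10)
  s2 <- t(G2) %*% rnorm(10)
  W2 <- linear_inverse(G2, diag(10), NULL, 1e-12 * sum(diag(tcrossprod(G2))) / 10)$W
  rec <- W2 %*% (G2 %*% s2)
  expect_lt(max(abs(rec - s2)) / max(abs(s2)), 1e-6)
})

test_that("basis path and explicit dipole-space prior agree (central identity)", {
  set.seed(5)
  for (i in 1:5) {
    ns <- 8; M <- 30; K <- 9
    G <- matrix(rnorm(ns * M), ns)
    T <- matrix(rnorm(K * M), K)
    wts <- runif(K, 0.5, 2)
    C <- crossprod(matrix(rnorm(ns * ns), ns)) + diag(ns)
    lam <- runif(1, 0.1, 2)
    b <- basis_set(T, "harmonics", data.frame(l = rep(1, K), m = seq_len(K)),
                   list())
    W6 <- basis_inverse(G, b, source_prior(weights = wts), C, lam)$W
    Rdip <- t(T) %*% diag(wts / mean(wts)) %*% T
    W7 <- Rdip %*% t(G) %*% solve(G %*% Rdip %*% t(G) + lam * C)
    expect_lt(max(abs(W6 - W7)), 1e-10)
  }
  # identity transform reduces exactly to the plain linear inverse
  ns <- 8; M <- 20
  G <- matrix(rnorm(ns * M), ns)
  bI <- basis_set(diag(M), "dipole-identity",
                  data.frame(center_vertex = 1:M), list())
  expect_lt(max(abs(basis_inverse(G, bI, NULL, diag(ns), 0.5)$W -
                    linear_inverse(G, diag(ns), NULL, 0.5)$W)), 1e-12)
  # any complete orthonormal basis with identity prior is minimum norm
  Tq <- t(qr.Q(qr(matrix(rnorm(M * M), M))))
  bQ <- basis_set(Tq, "harmonics", data.frame(l = rep(1, M), m = 1:M), list())
  expect_lt(max(abs(basis_inverse(G, bQ, NULL, diag(ns), 1e-9)$W -
                    linear_inverse(G, diag(ns), NULL, 1e-9)$W)), 1e-8)
})

test_that("spectral prior weights follow (1+l)^(-2 gamma)", {
  sp <- fx$space(2)
  B <- harmonics_basis(sp, 5)
  expect_equal(harmony_prior(B, 0)$weights, rep(1, nrow(B$T)))
  pr <- harmony_prior(B, 1)
  raw <- (1 + B$row_info$l)^(-2)
  expect_equal(pr$weights, raw / mean(raw), tolerance = 1e-12)
  l3 <- which(B$row_info$l == 3)[1]
  l0 <- which(B$row_info$l == 0)[1]
  expect_equal(pr$weights[l3] / pr$weights[l0], 1 / 16)
  # non-increasing in l for gamma > 0
  expect_true(all(diff(pr$weights[order(B$row_info$l)]) <= 1e-15))
})

test_that("depth weights scale with gain column power and source depth", {
  a <- c(1, 2, 0.5)
  G <- unname(cbind(a, a / 2, a))
  w <- depth_weights(G)
  expect_equal(w[2] / w[1], 4)         # halving a column quadruples its weight
  expect_equal(depth_weights(matrix(1, 4, 3)), rep(1 / 4, 3))
  expect_error(depth_weights(cbind(G, 0)), "zero gain column")
  # on the layered sphere, weights grow with depth; a full-coverage net and
  # free orientation (pooled components) isolate the depth dependence from
  # dipole orientation and sensor-cap geometry
  sp <- fx$space(2)
  Gf <- layered_sphere_gain(fibonacci_sensors(128, coverage = 0.999), sp,
                            orientation = "free")
  depth <- 80 - sqrt(rowSums(space_vertices_test(sp)^2))
  expect_gt(cor(rank(depth), rank(depth_weights(Gf))), 0.9)
})

test_that("cotangent Laplacian annihilates constants and matches sphere eigenfunctions", {
  sp <- fx$space(3)
  L <- harmonyeeg:::mesh_laplacian(sp$left$folded)
  expect_lt(max(abs(L %*% rep(1, nrow(L)))), 1e-10 * max(abs(L)))
  # degree-1 spherical harmonic on a radius-r icosphere: L f ~ (2 / r^2) f
  m <- icosphere(4)
  r <- 52
  Ls <- harmonyeeg:::mesh_laplacian(tri_mesh(m$vertices * r, m$faces))
  f <- m$vertices[, 3]
  Lf <- as.vector(Ls %*% f)
  expect_lt(sqrt(sum((Lf - (2 / r^2) * f)^2) / sum(((2 / r^2) * f)^2)), 0.05)
  # the implied prior penalizes rough fields more than smoothed ones
  pr <- loreta_prior(sp)
  set.seed(2)
  rough <- sample(c(-1, 1), nrow(L), replace = TRUE)
  rough <- c(rough, rep(0, n_sources_test(sp) - length(rough)))
  adj <- igraph::graph_from_edgelist(harmonyeeg:::mesh_edges(sp$left$folded),
                                     directed = FALSE)
  sm <- (rough[seq_len(nrow(L))] +
         sapply(igraph::adjacent_vertices(adj, seq_len(nrow(L))),
                function(nb) mean(rough[as.integer(nb)]))) / 2
  smooth <- c(sm, rep(0, n_sources_test(sp) - length(sm)))
  quad <- function(x) as.numeric(t(x) %*% (pr$precision %*% x))
  expect_gt(quad(rough), quad(smooth))
})

test_that("IBF basis has a PSD spectrum and near-constant leading mode", {
  sp <- fx$sphere_space(2)
  B <- ibf_basis(sp, sigma = 15, K_per_hemi = 40)
  ev <- B$row_info$eigenvalue[B$blocks$left$rows]
  expect_true(all(ev >= -1e-8))
  expect_true(all(diff(ev) <= 1e-10))
  lead <- B$T[B$blocks$left$rows[1], B$blocks$left$cols]
  expect_lt(sd(lead) / abs(mean(lead)), 0.05)
  expect_error(ibf_basis(sp, sigma = 15, K_per_hemi = 10^6), "exceeds")
  # sigma -> 0 degenerates to the identity coherence (coordinate modes)
  B0 <- ibf_basis(sp, sigma = 1e-6, K_per_hemi = 10)
  expect_equal(abs(range(B0$row_info$eigenvalue)), c(1, 1), tolerance = 1e-9)
})

test_that("propagated noise SDs match Monte-Carlo and the closed forms", {
  set.seed(6)
  W <- matrix(rnorm(50 * 12), 50)
  expect_equal(solution_noise_sd(W, diag(12)), sqrt(rowSums(W^2)))
  expect_equal(solution_noise_sd(W, matrix(0, 12, 12)), rep(0, 50))
  C <- crossprod(matrix(rnorm(144), 12)) / 12 + diag(12) * 0.3
  s <- solution_noise_sd(W, C)
  draws <- synth_noise(C, 20000, seed = 11)
  emp <- apply(W %*% t(draws), 1, sd)
  expect_lt(max(abs(emp - s) / s), 0.03)
})

test_that("dSPM normalization yields unit noise SD and is idempotent", {
  G <- fx$gain(2)
  C <- fx$noise_cov()
  op <- linear_inverse(G, C, NULL, 1)
  opd <- normalize_operator(op, "dspm", C_n = C)
  expect_equal(solution_noise_sd(opd, C), rep(1, nrow(opd$W)), tolerance = 1e-10)
  # Z-score property under actual noise draws
  draws <- synth_noise(C, 1000, seed = 13)
  sds <- apply(opd$W %*% t(draws), 1, sd)
  expect_true(all(abs(sds - 1) < 0.15))
  # normalizing an already-normalized operator changes nothing
  opd2 <- normalize_operator(opd, "dspm", C_n = C)
  opd2$normalization <- opd$normalization
  expect_equal(opd2$W, opd$W, tolerance = 1e-12)
})

test_that("sLORETA locates a noiseless point source exactly", {
  sp <- fx$sphere_space(3)
  G <- fx$gain(3, folded = FALSE)
  lam <- 1e-3 * sum(diag(tcrossprod(G$matrix))) / nrow(G$matrix)
  ops <- normalize_operator(linear_inverse(G, diag(nrow(G$matrix)), NULL, lam),
                            "sloreta", G = G)
  for (j in c(11L, 200L, 641L, 700L, 1100L)) {
    est <- apply_inverse(ops, G$matrix[, j])
    expect_identical(which.max(est$magnitude[, 1]), j)
  }
})

test_that("significance thresholding is calibrated", {
  expect_false(f_threshold(0, sigma = 1, n_sensors = 128)$significant)
  thr <- f_threshold(1, sigma = 1, n_sensors = 128, alpha = 0.05)$threshold
  # independent quantile oracle by root finding on the chi-square CDF
  oracle <- uniroot(function(q) pchisq(q, 1) - (1 - 0.05 / 128), c(0.1, 50),
                    tol = 1e-12)$root
  expect_equal(thr, oracle, tolerance = 1e-8)
  # pure noise: flagged dipole fraction stays below alpha; family-wise rate
  # is approximate because dipoles outnumber the sensor-space rank
  G <- fx$gain(2)
  C <- fx$noise_cov()
  op <- linear_inverse(G, C, NULL, 1)
  s <- solution_noise_sd(op, C)
  draws <- synth_noise(C, 1000, seed = 17)
  est <- op$W %*% t(draws)
  flagged <- apply(est, 2, function(x)
    f_threshold(abs(x), s, n_sensors = 128)$significant)
  expect_lt(mean(colMeans(flagged)), 0.05)
  expect_lt(mean(colSums(flagged) > 0), 0.09)
})

test_that("estimates are linear and null on the average-reference direction", {
  G <- fx$gain(2)
  op <- linear_inverse(G, fx$noise_cov(), NULL, 0.5)
  expect_true(all(apply_inverse(op, rep(0, 128))$values == 0))
  v1 <- rnorm(128); v2 <- rnorm(128)
  lhs <- apply_inverse(op, 2 * v1 - 3 * v2)$values
  rhs <- 2 * apply_inverse(op, v1)$values - 3 * apply_inverse(op, v2)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # constant sensor offsets map to (numerically) zero sources
  null <- apply_inverse(op, rep(1, 128))$values
  typical <- max(abs(apply_inverse(op, v1)$values))
  expect_lt(max(abs(null)), 1e-10 * typical)
  expect_error(apply_inverse(op, rep(0, 12)), "sensors")
})

test_that("a smooth in-subspace source is recovered at high SNR", {
  sp <- fx$sphere_space(3)
  G <- fx$gain(3, folded = FALSE)
  # the recoverable subspace must fit inside the sensor rank (127 for 128
  # average-referenced channels): degree 6 gives 2 x 49 = 98 coefficients
  B <- harmonics_basis(sp, 6)
  set.seed(21)
  coef <- rnorm(nrow(B$T)) * (1 + B$row_info$l)^(-1)
  s_true <- as.vector(t(B$T) %*% coef)
  v <- as.vector(G$matrix %*% s_true)
  op <- basis_inverse(G, B, NULL, diag(128),
                      1e-8 * sum(diag(tcrossprod(G$matrix))) / 128)
  est <- apply_inverse(op, v)
  expect_gt(cor(est$values[, 1], s_true), 0.95)
})

test_that("stronger spectral damping strictly removes high-degree content", {
  sp <- fx$space(3)
  G <- fx$gain(3)
  C <- fx$noise_cov()
  B <- harmonics_basis(sp, 10)
  ctr <- 300
  patch <- k_ring_patch(sp$left, ctr, 3)
  sim <- simulate_measurement(G, sp, list(patch))
  v <- sim$v + synth_noise(C, 1, seed = 23)[1, ]
  high_power <- sapply(c(0, 0.5, 1), function(g) {
    op <- basis_inverse(G, B, harmony_prior(B, g), C, 1)
    coef <- op$basis_operator %*% v
    sum(coef[B$row_info$l > 6]^2) / sum(coef^2)
  })
  expect_true(all(diff(high_power) < 0))
})
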