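test_that("localization error matches its transliteration and closed forms", {
  sp <- fx$space(3)
  patch <- k_ring_patch(sp$left, 321, 3)
  # the patch itself reconstructed with its own amplitudes scores zero
  amp <- numeric(n_sources_test(sp))
  amp[patch$vertices] <- patch$amplitudes
  expect_equal(localization_error(amp, patch, sp), 0)
  # point source, mass concentrated on one distant vertex: LE = arc * r_eff
  p1 <- k_ring_patch(sp$left, 100, 0)
  amp1 <- numeric(n_sources_test(sp))
  amp1[500] <- 1
  theta <- great_arc_distance(sp$left, 500, 100)
  expect_equal(localization_error(amp1, p1, sp),
               theta * effective_radius(sp$left), tolerance = 1e-12)
  # transliteration oracle on seeded random sparse estimates
  M_left <- nrow(sp$left$sphere$vertices)
  for (a in seeded_estimates(sp, 25, seed = 101)) {
    expect_equal(localization_error(a, patch, sp),
                 tr_le(a[seq_len(M_left)], sp$left, patch), tolerance = 1e-9)
  }
})

test_that("amplitude ratio reads 2 for a perfect 2:1 pair and is scale-free", {
  sp <- fx$space(3)
  pl <- k_ring_patch(sp$left, 321, 3)
  pr <- k_ring_patch(sp$right, 200, 3)
  pr$amplitudes <- pr$amplitudes / 2
  amp <- numeric(n_sources_test(sp))
  amp[pl$vertices] <- pl$amplitudes
  amp[hemi_offset_test(sp, "right") + pr$vertices] <- pr$amplitudes
  expect_equal(amplitude_ratio(amp, list(pl, pr), sp), 2)
  expect_equal(amplitude_ratio(7 * amp, list(pl, pr), sp), 2)
  pr$amplitudes <- pr$amplitudes * 2
  amp[hemi_offset_test(sp, "right") + pr$vertices] <- pr$amplitudes
  expect_equal(amplitude_ratio(amp, list(pl, pr), sp), 1)
  expect_error(amplitude_ratio(amp, list(pl, pl), sp), "different hemispheres")
})

test_that("surface bias is zero for truth, positive for crown-loaded mass", {
  sp <- fx$space(3)
  ctr <- head_center(fx$sensors())
  pl <- k_ring_patch(sp$left, 321, 3)
  pr <- k_ring_patch(sp$right, 200, 3)
  pr$amplitudes <- pr$amplitudes / 2
  patches <- list(pl, pr)
  amp <- numeric(n_sources_test(sp))
  amp[pl$vertices] <- pl$amplitudes
  amp[hemi_offset_test(sp, "right") + pr$vertices] <- pr$amplitudes
  expect_equal(surface_bias(amp, patches, sp, ctr), 0, tolerance = 1e-12)
  # all mass on the outermost gyral crowns
  pos <- space_vertices_test(sp)
  r <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
  amp_out <- numeric(length(r))
  amp_out[order(r, decreasing = TRUE)[1:74]] <- 1
  expect_gt(surface_bias(amp_out, patches, sp, ctr), 0)
  for (a in seeded_estimates(sp, 25, seed = 103))
    expect_equal(surface_bias(a, patches, sp, ctr),
                 tr_sb(a, sp, patches, ctr), tolerance = 1e-9)
})

test_that("solution widths match the transliteration and degenerate cases", {
  sp <- fx$space(3)
  amp <- numeric(n_sources_test(sp))
  amp[400] <- 2
  w <- solution_widths(amp, sp, "left", 1)
  expect_equal(unname(w), c(0, 0))
  M_left <- nrow(sp$left$sphere$vertices)
  for (a in seeded_estimates(sp, 25, seed = 105)) {
    al <- a[seq_len(M_left)]
    w <- solution_widths(a, sp, "left", 37)
    sel_min <- order(al, decreasing = TRUE)[1:37]
    sel_mid <- which(al > max(al) / 2)
    expect_equal(unname(w["W_min"]), tr_width(al, sp$left, sel_min),
                 tolerance = 1e-9)
    expect_equal(unname(w["W_mid"]), tr_width(al, sp$left, sel_mid),
                 tolerance = 1e-9)
  }
})

test_that("coherence is 1 for truth, capped, undefined for point sources", {
  sp <- fx$space(3)
  patch <- k_ring_patch(sp$left, 321, 3)
  amp <- numeric(n_sources_test(sp))
  amp[patch$vertices] <- patch$amplitudes
  expect_equal(coherence(amp, patch, sp), 1)
  expect_error(coherence(amp, k_ring_patch(sp$left, 321, 0), sp),
               "single-dipole")
  # adding a remote spurious hotspot never increases coherence
  set.seed(77)
  for (i in 1:10) {
    base <- amp
    spur <- base
    far <- sample(which(great_arc_distance(
      sp$left, seq_len(nrow(sp$left$sphere$vertices)),
      rep(321, nrow(sp$left$sphere$vertices))) > 1), 5)
    spur[far] <- max(base) * runif(5, 0.5, 1)
    expect_lte(coherence(spur, patch, sp), coherence(base, patch, sp) + 1e-12)
  }
})

test_that("congruency equals the textbook Pearson coefficient", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(congruency(x, x), 1)
  expect_equal(congruency(x, -x), -1)
  set.seed(9)
  a <- runif(20); b <- runif(20)
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  expect_equal(congruency(a, b), num / den, tolerance = 1e-12)
  expect_error(congruency(rep(1, 5), runif(5)), "zero variance")
  expect_error(congruency(1:2, 1:2), "at least 3")
})

test_that("AUC equals the all-pairs win probability, ties included", {
  sp <- fx$space(3)
  pl <- k_ring_patch(sp$left, 321, 3)
  pr <- k_ring_patch(sp$right, 200, 3)
  patches <- list(pl, pr)
  # perfect separation and total failure
  amp <- numeric(n_sources_test(sp))
  amp[c(pl$vertices, hemi_offset_test(sp, "right") + pr$vertices)] <- 1
  expect_equal(auc_overlap(amp, patches, sp), 1)
  expect_equal(auc_overlap(1 - amp, patches, sp), 0)
  # all-pairs oracle with deliberate ties (quantized magnitudes)
  set.seed(11)
  for (i in 1:20) {
    a <- round(abs(rnorm(n_sources_test(sp))), 1)
    expect_equal(auc_overlap(a, patches, sp), tr_auc(a, sp, patches),
                 tolerance = 1e-12)
  }
})

test_that("most-active non-source policy scores below random selection", {
  sp <- fx$space(3)
  pl <- k_ring_patch(sp$left, 321, 3)
  patches <- list(pl)
  set.seed(13)
  diff_sum <- 0
  for (i in 1:200) {
    a <- abs(rnorm(n_sources_test(sp)))
    a[pl$vertices] <- a[pl$vertices] + 0.5
    restrictive <- auc_overlap(a, patches, sp)
    cand <- setdiff(seq_len(nrow(sp$left$sphere$vertices)), pl$vertices)
    rand_ns <- sample(cand, length(pl$vertices))
    vals <- c(a[pl$vertices], a[rand_ns])
    r <- rank(vals)
    n_s <- length(pl$vertices)
    random_auc <- (sum(r[1:n_s]) - n_s * (n_s + 1) / 2) / n_s^2
    diff_sum <- diff_sum + (random_auc - restrictive)
  }
  expect_gt(diff_sum / 200, 0)
})

test_that("all metrics are invariant to global positive rescaling", {
  sp <- fx$space(3)
  pl <- k_ring_patch(sp$left, 321, 3)
  pr <- k_ring_patch(sp$right, 200, 3)
  pr$amplitudes <- pr$amplitudes / 2
  patches <- list(pl, pr)
  ctr <- head_center(fx$sensors())
  a <- seeded_estimates(sp, 1, seed = 107)[[1]]
  for (c0 in c(0.001, 1, 1000)) {
    expect_equal(localization_error(c0 * a, pl, sp),
                 localization_error(a, pl, sp), tolerance = 1e-10)
    expect_equal(amplitude_ratio(c0 * a, patches, sp),
                 amplitude_ratio(a, patches, sp), tolerance = 1e-10)
    expect_equal(surface_bias(c0 * a, patches, sp, ctr),
                 surface_bias(a, patches, sp, ctr), tolerance = 1e-10)
    expect_equal(coherence(c0 * a, pl, sp), coherence(a, pl, sp),
                 tolerance = 1e-10)
    expect_equal(auc_overlap(c0 * a, patches, sp),
                 auc_overlap(a, patches, sp), tolerance = 1e-12)
  }
})
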