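# --- Independent transliterations of the metric definitions (plain loops,
# --- no shared code with the package implementations).

tr_r_eff <- function(surface) {
  v <- surface$folded$vertices; f <- surface$folded$faces
  A <- 0
  for (r in seq_len(nrow(f))) {
    a <- v[f[r, 2], ] - v[f[r, 1], ]
    b <- v[f[r, 3], ] - v[f[r, 1], ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    A <- A + sqrt(sum(cr^2)) / 2
  }
  sqrt(A / (4 * pi))
}

tr_arc <- function(surface, i, j) {
  if (i == j) return(0)
  acos(min(1, max(-1, sum(surface$sphere$vertices[i, ] *
                          surface$sphere$vertices[j, ]))))
}

tr_true_center <- function(surface, patch) {
  ctr <- colMeans(surface$sphere$vertices[patch$vertices, , drop = FALSE])
  best <- 1; bestdot <- -Inf
  for (i in seq_len(nrow(surface$sphere$vertices))) {
    d <- sum(surface$sphere$vertices[i, ] * ctr)
    if (d > bestdot) { bestdot <- d; best <- i }
  }
  best
}

tr_le <- function(amp_hemi, surface, patch) {
  r_eff <- tr_r_eff(surface)
  c0 <- tr_true_center(surface, patch)
  N <- length(patch$vertices)
  sel <- order(amp_hemi, decreasing = TRUE)[1:N]
  raw <- 0; wsum <- 0
  for (i in sel) {
    raw <- raw + amp_hemi[i] * tr_arc(surface, i, c0) * r_eff
    wsum <- wsum + amp_hemi[i]
  }
  raw <- raw / wsum
  ext <- 0; esum <- 0
  for (k in seq_along(patch$vertices)) {
    ext <- ext + abs(patch$amplitudes[k]) *
      tr_arc(surface, patch$vertices[k], c0) * r_eff
    esum <- esum + abs(patch$amplitudes[k])
  }
  max(0, raw - ext / esum)
}

tr_sb <- function(amp, space, patches, center) {
  pos <- space_vertices_test(space)
  Ntot <- sum(sapply(patches, function(p) length(p$vertices)))
  sel <- order(amp, decreasing = TRUE)[1:Ntot]
  D_sol <- sum(amp[sel] * sqrt(rowSums(sweep(pos[sel, , drop = FALSE], 2,
                                             center)^2))) / sum(amp[sel])
  num <- 0; den <- 0
  for (p in patches) {
    gi <- hemi_offset_test(space, p$hemisphere) + p$vertices
    d <- sqrt(rowSums(sweep(pos[gi, , drop = FALSE], 2, center)^2))
    num <- num + sum(abs(p$amplitudes) * d)
    den <- den + sum(abs(p$amplitudes))
  }
  (D_sol - num / den) / (num / den)
}

tr_width <- function(amp_hemi, surface, sel) {
  r_eff <- tr_r_eff(surface)
  ctr <- rep(0, 3)
  for (i in sel) ctr <- ctr + amp_hemi[i] * surface$sphere$vertices[i, ]
  best <- 1; bestdot <- -Inf
  for (i in seq_len(nrow(surface$sphere$vertices))) {
    d <- sum(surface$sphere$vertices[i, ] * ctr)
    if (d > bestdot) { bestdot <- d; best <- i }
  }
  num <- 0; den <- 0
  for (i in sel) {
    num <- num + amp_hemi[i] * tr_arc(surface, i, best) * r_eff
    den <- den + amp_hemi[i]
  }
  num / den
}

tr_auc <- function(amp, space, patches) {
  src <- c(); nsrc <- c()
  for (p in patches) {
    off <- hemi_offset_test(space, p$hemisphere)
    src <- c(src, off + p$vertices)
    hemi_all <- off + seq_len(nrow(space[[p$hemisphere]]$sphere$vertices))
    excl <- off + unlist(lapply(patches, function(q)
      if (q$hemisphere == p$hemisphere) q$vertices else integer(0)))
    cand <- setdiff(hemi_all, excl)
    nsrc <- c(nsrc, cand[order(amp[cand],
                               decreasing = TRUE)[seq_along(p$vertices)]])
  }
  wins <- 0
  for (i in src) for (j in nsrc)
    wins <- wins + (amp[i] > amp[j]) + 0.5 * (amp[i] == amp[j])
  wins / (length(src) * length(nsrc))
}

seeded_estimates <- function(space, n, seed) {
  M <- n_sources_test(space)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    a <- numeric(M)
    k <- sample(20:60, 1)
    a[sample(M, k)] <- abs(rnorm(k))
    a
  })
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}
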