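# Magnitude vector (one value per dipole) from a source_estimate or plain
# numeric vector; multi-sample estimates use the first column.
estimate_magnitudes <- function(estimate) {
  if (inherits(estimate, "source_estimate")) estimate$magnitude[, 1]
  else abs(as.numeric(estimate))
}

# Indices (global) and magnitudes of one hemisphere's dipoles.
hemi_slice <- function(space, estimate, hemisphere) {
  amp <- estimate_magnitudes(estimate)
  lab <- hemi_labels(space)
  idx <- which(lab == hemisphere)
  list(idx = idx, amp = amp[idx], local = seq_along(idx))
}

# Project a (non-unit) direction onto the nearest sphere-mesh vertex.
nearest_sphere_vertex <- function(surface, direction) {
  which.max(as.vector(surface$sphere$vertices %*% direction))
}

# Amplitude-weighted mean arc distance (mm) of a local vertex set to a
# reference sphere vertex.
weighted_arc_mm <- function(surface, verts, weights, ref_vertex) {
  d <- sphere_to_folded_mm(surface, great_arc_distance(
    surface, verts, rep(ref_vertex, length(verts))))
  sum(weights * d) / sum(weights)
}

#' Localization error of a reconstructed source
#'
#' Distance (mm, along the cortical surface) between a reconstruction and
#' the true patch: the true location is the patch's unweighted vertex
#' centroid snapped to the nearest sphere vertex; the `N` strongest dipoles
#' of the patch's hemisphere (`N` = patch size) contribute their great-arc
#' distances to it, amplitude-weighted; the patch's own extent (the same
#' average computed on the patch with its true amplitudes) is subtracted and
#' the result clamped at zero.
#'
#' @param estimate a `source_estimate` or per-dipole magnitude vector.
#' @param patch the true `source_patch`.
#' @param space the `source_space`.
#' @return localization error in mm.
#' @export
localization_error <- function(estimate, patch, space) {
  surface <- space[[patch$hemisphere]]
  sl <- hemi_slice(space, estimate, patch$hemisphere)
  if (all(sl$amp == 0)) stop("empty estimate")
  ctr_dir <- colMeans(surface$sphere$vertices[patch$vertices, , drop = FALSE])
  c0 <- nearest_sphere_vertex(surface, ctr_dir)
  N <- length(patch$vertices)
  sel <- order(sl$amp, decreasing = TRUE)[seq_len(N)]
  raw <- weighted_arc_mm(surface, sel, sl$amp[sel], c0)
  extent <- weighted_arc_mm(surface, patch$vertices, abs(patch$amplitudes), c0)
  max(raw - extent, 0)
}

#' Amplitude ratio between two reconstructed sources
#'
#' Mean of the `N` largest magnitudes in the hemisphere of the stronger true
#' source over the same in the weaker's hemisphere; defined only for sources
#' in different hemispheres.
#'
#' @param estimate a `source_estimate` or magnitude vector.
#' @param patches list of two `source_patch` objects in different
#'   hemispheres (their `amplitudes` decide which is the stronger truth).
#' @param space the `source_space`.
#' @return the amplitude ratio (1 would be perfect for equal sources; the
#'   benchmark's ground truth is 2).
#' @export
amplitude_ratio <- function(estimate, patches, space) {
  hems <- vapply(patches, function(p) p$hemisphere, "")
  if (length(unique(hems)) != 2)
    stop("amplitude ratio is defined for sources in different hemispheres")
  peak <- vapply(patches, function(p) max(abs(p$amplitudes)), 0)
  strong <- patches[[which.max(peak)]]
  weak <- patches[[which.min(peak)]]
  mean_top <- function(p) {
    sl <- hemi_slice(space, estimate, p$hemisphere)
    N <- length(p$vertices)
    mean(sort(sl$amp, decreasing = TRUE)[seq_len(N)])
  }
  mean_top(strong) / mean_top(weak)
}

#' Surface bias of a reconstruction
#'
#' Relative radial displacement of the solution: the amplitude-weighted mean
#' distance `D` from the head center of the `2N` most active dipoles (both
#' hemispheres pooled) is compared with the same quantity for the true
#' patches; `SB = (D_sol - D_src) / D_src`.  Zero for a perfect
#' reconstruction, positive when mass is pushed toward the surface.
#'
#' @param estimate a `source_estimate` or magnitude vector.
#' @param patches list of true `source_patch` objects.
#' @param space the `source_space`.
#' @param center head center (mm), e.g. from [head_center()].
#' @return surface bias (dimensionless fraction).
#' @export
surface_bias <- function(estimate, patches, space, center) {
  amp <- estimate_magnitudes(estimate)
  pos <- space_vertices(space)
  Ntot <- sum(vapply(patches, function(p) length(p$vertices), 0L))
  sel <- order(amp, decreasing = TRUE)[seq_len(Ntot)]
  dist_c <- function(idx, w) {
    d <- sqrt(rowSums(sweep(pos[idx, , drop = FALSE], 2, center)^2))
    sum(w * d) / sum(w)
  }
  D_sol <- dist_c(sel, amp[sel])
  src_idx <- unlist(lapply(patches, function(p)
    hemi_offset(space, p$hemisphere) + p$vertices))
  src_w <- unlist(lapply(patches, function(p) abs(p$amplitudes)))
  D_src <- dist_c(src_idx, src_w)
  (D_sol - D_src) / D_src
}

# Width of a weighted local vertex set: amplitude-weighted mean arc (mm) to
# the amplitude-weighted spherical center of the set itself.
weighted_width <- function(surface, verts, weights) {
  ctr <- colSums(surface$sphere$vertices[verts, , drop = FALSE] * weights)
  if (sum(ctr^2) == 0) return(0)
  c0 <- nearest_sphere_vertex(surface, ctr)
  weighted_arc_mm(surface, verts, weights, c0)
}

#' Solution widths (hotspot and spread)
#'
#' `W_min`: amplitude-weighted mean distance of the `N` strongest dipoles to
#' their own amplitude-weighted center.  `W_mid`: the same over all dipoles
#' above half the maximum amplitude.  Both in mm, per hemisphere.
#'
#' @param estimate a `source_estimate` or magnitude vector.
#' @param space the `source_space`.
#' @param hemisphere which hemisphere to measure.
#' @param N hotspot size (the true patch size in the benchmark).
#' @return named vector `c(W_min, W_mid)`.
#' @export
solution_widths <- function(estimate, space, hemisphere, N) {
  surface <- space[[hemisphere]]
  sl <- hemi_slice(space, estimate, hemisphere)
  if (all(sl$amp == 0)) stop("empty estimate")
  sel_min <- order(sl$amp, decreasing = TRUE)[seq_len(N)]
  sel_mid <- which(sl$amp > max(sl$amp) / 2)
  c(W_min = weighted_width(surface, sel_min, sl$amp[sel_min]),
    W_mid = weighted_width(surface, sel_mid, sl$amp[sel_mid]))
}

#' Coherence of a reconstruction
#'
#' Ratio of the true patch's hotspot width to the solution's hotspot width
#' (`W_min` of the patch over `W_min` of the solution), capped at 1; 1 means
#' the solution's hotspot has the size of the simulated source, smaller
#' values mean a scattered solution.  Undefined for single-dipole sources.
#'
#' @param estimate a `source_estimate` or magnitude vector.
#' @param patch the true `source_patch` (size > 1).
#' @param space the `source_space`.
#' @return coherence in (0, 1].
#' @export
coherence <- function(estimate, patch, space) {
  if (length(patch$vertices) < 2)
    stop("coherence is not defined for a single-dipole source")
  surface <- space[[patch$hemisphere]]
  w_true <- weighted_width(surface, patch$vertices, abs(patch$amplitudes))
  w_sol <- solution_widths(estimate, space, patch$hemisphere,
                           length(patch$vertices))[["W_min"]]
  min(1, w_true / w_sol)
}

#' Congruency (width-error correlation)
#'
#' Pearson correlation, across source configurations, between the
#' solution's spread (`W_mid`) and its localization error: high values mean
#' the solution's extent honestly signals its uncertainty.
#'
#' @param w_mid per-configuration `W_mid` values.
#' @param le per-configuration localization errors.
#' @return correlation in `[-1, 1]`.
#' @export
congruency <- function(w_mid, le) {
  if (length(w_mid) != length(le) || length(le) < 3)
    stop("congruency needs at least 3 paired configurations")
  if (stats::sd(w_mid) == 0 || stats::sd(le) == 0)
    stop("undefined metric: zero variance in widths or errors")
  stats::cor(w_mid, le)
}

#' Area under the ROC curve of source detection
#'
#' Overlap between reconstruction and truth: source vertices (all patches
#' pooled) are ranked together with an equal number of most-active
#' non-source vertices, each patch drawing its competitors from its own
#' hemisphere.  With ranks ascending in absolute activation and ties shared
#' as average ranks, `AUC = (sum of source ranks - n_s (n_s + 1) / 2) /
#' (n_s n_ns)`: exactly the probability that a random source vertex out-ranks
#' a random selected non-source vertex (ties counting one half).
#'
#' @param estimate a `source_estimate` or magnitude vector.
#' @param patches list of true `source_patch` objects.
#' @param space the `source_space`.
#' @return AUC in `[0, 1]`.
#' @export
auc_overlap <- function(estimate, patches, space) {
  amp <- estimate_magnitudes(estimate)
  src_idx <- integer(0); ns_idx <- integer(0)
  for (p in patches) {
    off <- hemi_offset(space, p$hemisphere)
    gsrc <- off + p$vertices
    src_idx <- c(src_idx, gsrc)
    hemi_all <- off + seq_len(nrow(space[[p$hemisphere]]$sphere$vertices))
    cand <- setdiff(hemi_all, off + unlist(lapply(patches, function(q)
      if (q$hemisphere == p$hemisphere) q$vertices else integer(0))))
    if (length(cand) < length(p$vertices))
      stop("not enough non-source candidate vertices")
    ns_idx <- c(ns_idx, cand[order(amp[cand], decreasing = TRUE)[seq_along(p$vertices)]])
  }
  vals <- c(amp[src_idx], amp[ns_idx])
  r <- rank(vals)                        # average ranks on ties
  n_s <- length(src_idx); n_ns <- length(ns_idx)
  (sum(r[seq_len(n_s)]) - n_s * (n_s + 1) / 2) / (n_s * n_ns)
}
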