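# Shared, lazily built simulation fixtures (cached across test files).
fx <- local({
  cache <- new.env(parent = emptyenv())
  get_or <- function(key, fn) {
    if (!exists(key, envir = cache)) assign(key, fn(), envir = cache)
    get(key, envir = cache)
  }
  list(
    # two-hemisphere pseudo-cortex, default folding
    space = function(level = 3) get_or(paste0("space", level), function()
      source_space(make_pseudo_cortex(level, hemisphere = "left", seed = 1),
                   make_pseudo_cortex(level, hemisphere = "right", seed = 1))),
    # unfolded (exact-sphere) two-hemisphere space
    sphere_space = function(level = 3) get_or(paste0("sph", level), function()
      source_space(make_pseudo_cortex(level, 0, hemisphere = "left", seed = 1),
                   make_pseudo_cortex(level, 0, hemisphere = "right", seed = 1))),
    sensors = function(n = 128) get_or(paste0("sens", n), function()
      fibonacci_sensors(n)),
    gain = function(level = 3, folded = TRUE) {
      key <- paste0("gain", level, folded)
      get_or(key, function()
        layered_sphere_gain(fx$sensors(),
                            if (folded) fx$space(level) else fx$sphere_space(level)))
    },
    noise_cov = function() get_or("ncov", function()
      sensor_noise_covariance(fx$sensors()))
  )
})

# Shorthands for package internals used by oracles.
space_vertices_test <- function(space) harmonyeeg:::space_vertices(space)
n_sources_test <- function(space) harmonyeeg:::n_sources(space)
hemi_offset_test <- function(space, h) harmonyeeg:::hemi_offset(space, h)

# Independent breadth-first search used as the k-ring oracle.
bfs_oracle <- function(mesh, center, k) {
  adj <- lapply(seq_len(nrow(mesh$vertices)), function(i) integer(0))
  f <- mesh$faces
  for (r in seq_len(nrow(f))) {
    tri <- f[r, ]
    for (a in tri) for (b in tri) if (a != b) adj[[a]] <- union(adj[[a]], b)
  }
  seen <- center
  frontier <- center
  for (d in seq_len(k)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, frontier)
  }
  sort(seen)
}
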