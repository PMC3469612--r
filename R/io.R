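#' Mesh file I/O
#'
#' Plain-text OFF and Wavefront OBJ readers/writers (coordinates in mm; OFF
#' faces are 0-based on disk, OBJ 1-based; both are converted to the 1-based
#' in-memory convention).
#'
#' @param path file path.
#' @param mesh a `tri_mesh`.
#' @return `read_off`/`read_obj` return a `tri_mesh`; writers return the
#'   path invisibly.
#' @name mesh-io
NULL

#' @rdname mesh-io
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
  f <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
              nf, 4, byrow = TRUE)
  if (any(f[, 1] != 3)) stop("non-triangular face in ", path)
  tri_mesh(v, f[, 2:4] + 1L)
}

#' @rdname mesh-io
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3, r), collapse = " ")), con)
  invisible(path)
}

#' @rdname mesh-io
#' @export
read_obj <- function(path) {
  lines <- trimws(readLines(path))
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- matrix(scan(text = gsub("^v ", "", vl), quiet = TRUE),
              length(vl), 3, byrow = TRUE)
  fidx <- lapply(strsplit(gsub("^f ", "", fl), "\\s+"), function(p)
    as.integer(sub("/.*", "", p)))
  f <- do.call(rbind, fidx)
  if (ncol(f) != 3) stop("non-triangular face in ", path)
  tri_mesh(v, f)
}

#' @rdname mesh-io
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(c("v", format(r, digits = 17)), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1, function(r)
    paste(c("f", r), collapse = " ")), con)
  invisible(path)
}

#' Sensor file I/O
#'
#' Whitespace- or comma-delimited text, one row per sensor:
#' `label x y z` (mm).
#'
#' @param path file path.
#' @param sensors a `sensor_array`.
#' @return `read_sensors` returns a `sensor_array`.
#' @name sensor-io
NULL

#' @rdname sensor-io
#' @export
read_sensors <- function(path) {
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt))]
  parts <- strsplit(trimws(gsub(",", " ", txt)), "\\s+")
  labels <- vapply(parts, `[[`, "", 1)
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  sensor_array(labels, pos)
}

#' @rdname sensor-io
#' @export
write_sensors <- function(sensors, path) {
  writeLines(sprintf("%s %.10g %.10g %.10g", sensors$labels,
                     sensors$positions[, 1], sensors$positions[, 2],
                     sensors$positions[, 3]), path)
  invisible(path)
}

#' Numeric matrix file I/O
#'
#' Whitespace-delimited plain text, full double precision.
#'
#' @param path file path.
#' @param x numeric matrix.
#' @return `read_matrix_file` returns a numeric matrix.
#' @name matrix-io
NULL

#' @rdname matrix-io
#' @export
read_matrix_file <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname matrix-io
#' @export
write_matrix_file <- function(x, path) {
  utils::write.table(format(as.matrix(x), digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Gain matrix file I/O
#'
#' The matrix itself goes to a delimited text file; orientation mode,
#' reference convention, source count and units go to a JSON sidecar
#' (`<path>.json`).  Loading without a sidecar requires the orientation to
#' be stated and assumes the reference has not been applied yet, in which
#' case the average reference is applied on load.  A constrained request on
#' a three-column-per-source file is refused (the normals are not in the
#' file).
#'
#' @param gain a `gain_matrix`.
#' @param path matrix file path.
#' @param orientation expected orientation when no sidecar is present.
#' @return `load_gain` returns a `gain_matrix`.
#' @name gain-io
NULL

#' @rdname gain-io
#' @export
save_gain <- function(gain, path) {
  write_matrix_file(gain$matrix, path)
  jsonlite::write_json(list(orientation = gain$orientation,
                            n_sources = gain$n_sources,
                            reference = gain$reference,
                            units = "V/(A.m)"),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname gain-io
#' @export
load_gain <- function(path, orientation = NULL) {
  m <- read_matrix_file(path)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(orientation) && orientation != meta$orientation)
      stop(sprintf("format error: file is %s-orientation, %s requested",
                   meta$orientation, orientation))
    g <- gain_matrix(m, meta$orientation, meta$n_sources, meta$reference)
    if (meta$reference != "average")
      g <- gain_matrix(apply_average_reference(m), meta$orientation,
                       meta$n_sources, "average")
    return(g)
  }
  if (is.null(orientation)) stop("no sidecar metadata: orientation must be given")
  if (orientation == "free" && ncol(m) %% 3 != 0)
    stop("format error: free-orientation gain needs 3 columns per source")
  n_src <- if (orientation == "free") ncol(m) / 3 else ncol(m)
  gain_matrix(apply_average_reference(m), orientation, n_src, "average")
}

#' Inverse operator file I/O
#'
#' W goes to a delimited matrix file; the full recipe (algorithm, basis,
#' lambda, normalization, orientation, per-source sigma) goes to the JSON
#' sidecar, so a loaded operator documents its own provenance.
#'
#' @param op an `inverse_operator`.
#' @param path matrix file path.
#' @return `load_inverse_operator` returns an `inverse_operator`.
#' @name operator-io
NULL

#' @rdname operator-io
#' @export
save_inverse_operator <- function(op, path) {
  write_matrix_file(op$W, path)
  jsonlite::write_json(list(algorithm = op$algorithm, lambda = op$lambda,
                            basis = op$basis, orientation = op$orientation,
                            normalization = op$normalization,
                            sigma = op$sigma),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname operator-io
#' @export
load_inverse_operator <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  sigma <- if (length(meta$sigma)) as.numeric(unlist(meta$sigma)) else NULL
  inverse_operator(unname(read_matrix_file(path)), algorithm = meta$algorithm,
                   lambda = meta$lambda, basis = meta$basis,
                   orientation = meta$orientation,
                   normalization = meta$normalization,
                   sigma = sigma)
}

#' Read and validate a run configuration
#'
#' JSON (or YAML, by extension) configuration for [run_inversion()].
#' Validation reports the offending field by name.
#'
#' @param path configuration file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration needs the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("gain", "sensors", "data", "output_dir", "algorithm")
  for (f in required)
    if (is.null(cfg[[f]])) stop("validation error: missing field '", f, "'")
  for (f in c("gain", "sensors", "data", "noise_epochs", "noise_cov",
              "left_folded", "left_sphere", "right_folded", "right_sphere"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("validation error: field '", f, "' points to a missing file: ",
           cfg[[f]])
  cfg$lambda <- cfg$lambda %||% "ocv"
  cfg$orientation <- cfg$orientation %||% "constrained"
  cfg$seed <- cfg$seed %||% 1
  cfg$params <- as.list(cfg$params %||% list())
  cfg
}

#' Run a source inversion from a configuration
#'
#' Loads the gain, sensors, data (rows = sensors, columns = time samples)
#' and noise (epoch matrix or covariance file), optionally the cortical
#' meshes (required by basis algorithms), builds the requested algorithm's
#' inverse operator, applies it, thresholds, and writes the source estimate
#' (`estimate.txt`), magnitudes, significance mask, a provenance record
#' (`provenance.json`), and for harmonic solutions the compact coefficient
#' stream (`coefficients.bin` + header).
#'
#' @param config configuration list from [read_run_config()] (or compatible).
#' @return invisibly, the output directory.
#' @export
run_inversion <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  sensors <- read_sensors(config$sensors)
  G <- load_gain(config$gain, config$orientation)
  v <- read_matrix_file(config$data)
  if (nrow(v) != nrow(G$matrix))
    stop("validation error: field 'data' has ", nrow(v),
         " rows; gain expects ", nrow(G$matrix), " sensors")
  C <- if (!is.null(config$noise_cov)) {
    noise_covariance(read_matrix_file(config$noise_cov), recipe = "file")
  } else if (!is.null(config$noise_epochs)) {
    estimate_noise_covariance(read_matrix_file(config$noise_epochs))
  } else sensor_noise_covariance(sensors)
  space <- NULL
  if (!is.null(config$left_folded)) {
    space <- source_space(
      cortical_surface("left", read_off(config$left_folded),
                       read_off(config$left_sphere)),
      cortical_surface("right", read_off(config$right_folded),
                       read_off(config$right_sphere)))
  }
  needs_space <- config$algorithm %in% c("harmony", "splines", "loreta", "ibf")
  if (needs_space && is.null(space))
    stop("validation error: algorithm '", config$algorithm,
         "' needs the mesh fields (left_folded, left_sphere, ...)")
  lambda <- config$lambda
  if (!identical(lambda, "ocv")) lambda <- as.numeric(lambda)
  op <- algorithm_operator(config$algorithm, G, space, C, lambda = lambda,
                           data = v, params = config$params)
  est <- apply_inverse(op, v)
  sig <- if (op$normalization == "dspm") op$sigma else solution_noise_sd(op, C)
  thr <- f_threshold(est, sig, n_sensors = nrow(G$matrix),
                     df = if (op$orientation == "free") 3 else 1)
  out <- function(f) file.path(config$output_dir, f)
  write_matrix_file(est$values, out("estimate.txt"))
  write_matrix_file(est$magnitude, out("magnitude.txt"))
  writeLines(as.character(as.integer(thr$significant)), out("significant.txt"))
  if (config$algorithm == "harmony" && !is.null(op$basis_operator)) {
    b <- harmonics_basis(space, config$params$L_max %||% 10)
    stream <- encode_coefficients(op$basis_operator %*% v, b)
    writeBin(stream$data, out("coefficients.bin"))
    jsonlite::write_json(stream$header, out("coefficients.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  prov <- list(package = "harmonyeeg",
               version = as.character(utils::packageVersion("harmonyeeg")),
               algorithm = config$algorithm, lambda = op$lambda,
               orientation = op$orientation, params = config$params,
               seed = config$seed, n_sensors = nrow(G$matrix),
               n_sources = G$n_sources,
               inputs = config[intersect(names(config),
                 c("gain", "sensors", "data", "noise_epochs", "noise_cov",
                   "left_folded", "left_sphere", "right_folded",
                   "right_sphere"))])
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$output_dir)
}

#' Write the standing fixture bundle
#'
#' Generates and saves the synthetic test bed: pseudo-cortex meshes (folded
#' and sphere, both hemispheres, OFF), a 128-sensor Fibonacci net on the
#' outer shell, the layered-sphere gain with sidecar, the noise covariance,
#' and a sample two-patch dataset (noiseless and noisy sensor vectors plus
#' the ground truth).
#'
#' @param outdir output directory (created if needed).
#' @param level mesh subdivision level (default 3).
#' @param seed master seed (default 1).
#' @param n_sensors sensor count (default 128).
#' @return invisibly, a named list of the written paths.
#' @export
make_fixture_bundle <- function(outdir, level = 3, seed = 1, n_sensors = 128) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  space <- source_space(make_pseudo_cortex(level, hemisphere = "left", seed = seed),
                        make_pseudo_cortex(level, hemisphere = "right", seed = seed))
  sensors <- fibonacci_sensors(n_sensors)
  G <- layered_sphere_gain(sensors, space)
  C <- sensor_noise_covariance(sensors)
  p <- function(f) file.path(outdir, f)
  write_off(space$left$folded, p("left_folded.off"))
  write_off(space$left$sphere, p("left_sphere.off"))
  write_off(space$right$folded, p("right_folded.off"))
  write_off(space$right$sphere, p("right_sphere.off"))
  write_sensors(sensors, p("sensors.txt"))
  save_gain(G, p("gain.txt"))
  write_matrix_file(C$matrix, p("noise_cov.txt"))
  ctr <- nrow(space$left$sphere$vertices) %/% 2
  patches <- list(k_ring_patch(space$left, ctr, 3),
                  k_ring_patch(space$right, ctr + 7, 3))
  patches[[2]]$amplitudes <- patches[[2]]$amplitudes / 2
  sim <- simulate_measurement(G, space, patches)
  noise <- synth_noise(C, 1, seed = seed + 9)
  write_matrix_file(cbind(sim$v), p("data_clean.txt"))
  write_matrix_file(cbind(sim$v + noise[1, ]), p("data_noisy.txt"))
  jsonlite::write_json(list(seed = seed, level = level,
                            left_center = patches[[1]]$center_vertex,
                            right_center = patches[[2]]$center_vertex,
                            left_vertices = patches[[1]]$vertices,
                            right_vertices = patches[[2]]$vertices,
                            amplitudes_left = patches[[1]]$amplitudes,
                            amplitudes_right = patches[[2]]$amplitudes),
                      p("truth.json"), digits = NA)
  paths <- list(left_folded = p("left_folded.off"),
                left_sphere = p("left_sphere.off"),
                right_folded = p("right_folded.off"),
                right_sphere = p("right_sphere.off"),
                sensors = p("sensors.txt"), gain = p("gain.txt"),
                noise_cov = p("noise_cov.txt"),
                data_clean = p("data_clean.txt"),
                data_noisy = p("data_noisy.txt"), truth = p("truth.json"))
  invisible(paths)
}
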