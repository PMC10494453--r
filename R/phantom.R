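#' Cohort configuration for synthetic aneurysm phantoms
#'
#' The phantom emulates a subtracted CTA volume: a contrast-bright parent
#' vessel (straight tube) carrying a saccular aneurysm modelled as a spherical
#' cap, on a dark background with additive Gaussian noise. The spherical cap is
#' the one sac shape for which all five standard morphometric features (size,
#' height, neck diameter, dome diameter, volume) have closed forms, so every
#' downstream measurement can be checked against analytic truth.
#'
#' Sampling is parameterised by the clinically reported quantities: aneurysm
#' size (uniform on `size_range`, default the 3-10 mm inclusion window) and a
#' cap-fullness ratio q = h / 2R (how much of the sphere sits above the neck
#' plane; q -> 1 is a narrow-necked berry aneurysm). Sphere radius and cap
#' height follow in closed form. Locations are drawn with the frequencies of a
#' typical saccular-aneurysm cohort (Acom/ACA, ICA, MCA, posterior
#' circulation).
#'
#' @param size_range aneurysm size range in mm (uniform).
#' @param cap_fullness_range range for q = h / 2R; values above 0.5 keep the
#'   dome wider than the neck.
#' @param vessel_radius_range parent-vessel radius range in mm.
#' @param location_probs named probabilities for the four location classes.
#' @param contrast_level intensity added inside vessel and aneurysm on the
#'   post-contrast volume (arbitrary units).
#' @param noise_sd additive Gaussian noise sd (same units).
#' @param neck_tilt_max_deg maximum tilt of the neck normal from the z axis.
#' @param fov_mm cubic field of view in mm; phantom geometry is placed within
#'   it (default matches a 64^3 grid at 0.5 mm).
#' @param with_aneurysm if `FALSE`, phantoms are vessel-only (used as
#'   negative cases for detection).
#' @return A list of class `aneu_cohort_config`.
#' @export
phantom_cohort_config <- function(size_range = c(3, 10),
                                  cap_fullness_range = c(0.55, 0.92),
                                  vessel_radius_range = c(1.5, 2.5),
                                  location_probs = c("Acom/ACA" = 0.307,
                                                     "ICA" = 0.477,
                                                     "MCA" = 0.137,
                                                     "PC" = 0.078),
                                  contrast_level = 200,
                                  noise_sd = 10,
                                  neck_tilt_max_deg = 20,
                                  fov_mm = 32,
                                  with_aneurysm = TRUE) {
  ranges <- list(size_range = size_range,
                 cap_fullness_range = cap_fullness_range,
                 vessel_radius_range = vessel_radius_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      stop_aneu(sprintf("invalid range for %s (min > max?)", nm),
                "aneu_config_error")
    }
  }
  if (size_range[1] < 3 || size_range[2] > 10) {
    stop_aneu("size_range must stay within the 3-10 mm inclusion window",
              "aneu_config_error")
  }
  if (cap_fullness_range[1] <= 0.5 || cap_fullness_range[2] >= 1) {
    stop_aneu("cap_fullness_range must lie in (0.5, 1)", "aneu_config_error")
  }
  if (abs(sum(location_probs) - 1) > 0.01 || any(location_probs < 0)) {
    stop_aneu("location_probs must be nonnegative and sum to ~1",
              "aneu_config_error")
  }
  location_probs <- location_probs / sum(location_probs)
  structure(list(size_range = size_range,
                 cap_fullness_range = cap_fullness_range,
                 vessel_radius_range = vessel_radius_range,
                 location_probs = location_probs,
                 contrast_level = contrast_level,
                 noise_sd = noise_sd,
                 neck_tilt_max_deg = neck_tilt_max_deg,
                 fov_mm = fov_mm,
                 with_aneurysm = with_aneurysm),
            class = "aneu_cohort_config")
}

#' Draw phantom specifications
#'
#' Draws `n` phantom specs from the cohort distributions. Identical seeds
#' yield identical specs. Each row fully determines one phantom: spherical-cap
#' geometry (sphere radius, cap height, neck centre and unit normal), parent
#' vessel (radius, unit axis, perpendicular to the neck normal), location
#' class, and rendering parameters.
#'
#' @param n number of specs to draw.
#' @param config an [phantom_cohort_config()].
#' @param seed integer seed; if `NULL`, the current RNG stream is used.
#' @return A tibble with one row per phantom, class `aneu_phantom_spec`.
#' @export
sample_phantom_spec <- function(n = 1, config = phantom_cohort_config(),
                                seed = NULL) {
  stopifnot(inherits(config, "aneu_cohort_config"), n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  size <- stats::runif(n, config$size_range[1], config$size_range[2])
  q <- stats::runif(n, config$cap_fullness_range[1], config$cap_fullness_range[2])
  # q > 0.5 ensures h > R: the apex is the farthest dome point, so size = h.
  h <- size
  R <- h / (2 * q)
  vessel_radius <- stats::runif(n, config$vessel_radius_range[1],
                                config$vessel_radius_range[2])
  location <- sample(names(config$location_probs), n, replace = TRUE,
                     prob = config$location_probs)
  ctr <- config$fov_mm / 2
  neck_center <- cbind(ctr + stats::runif(n, -1, 1),
                       ctr + stats::runif(n, -1, 1),
                       0.40 * config$fov_mm + stats::runif(n, -1, 1))
  tilt <- stats::runif(n, 0, config$neck_tilt_max_deg) * pi / 180
  azim <- stats::runif(n, 0, 2 * pi)
  normal <- cbind(sin(tilt) * cos(azim), sin(tilt) * sin(azim), cos(tilt))
  # vessel axis: unit vector perpendicular to the neck normal, random azimuth
  axis_az <- stats::runif(n, 0, 2 * pi)
  axis <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    u <- pick_orthonormal(normal[i, ])
    axis[i, ] <- cos(axis_az[i]) * u[, 1] + sin(axis_az[i]) * u[, 2]
  }
  case_seed <- sample.int(.Machine$integer.max, n)
  out <- tibble::tibble(
    id = sprintf("case_%04d", seq_len(n)),
    sphere_radius = R, cap_height = h,
    neck_x = neck_center[, 1], neck_y = neck_center[, 2], neck_z = neck_center[, 3],
    normal_x = normal[, 1], normal_y = normal[, 2], normal_z = normal[, 3],
    vessel_radius = vessel_radius,
    axis_x = axis[, 1], axis_y = axis[, 2], axis_z = axis[, 3],
    location = location,
    contrast_level = config$contrast_level,
    noise_sd = config$noise_sd,
    with_aneurysm = config$with_aneurysm,
    seed = case_seed
  )
  class(out) <- c("aneu_phantom_spec", class(out))
  out
}

# two unit vectors orthonormal to v
pick_orthonormal <- function(v) {
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u1 <- ref - sum(ref * v) * v
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(v[2] * u1[3] - v[3] * u1[2],
          v[3] * u1[1] - v[1] * u1[3],
          v[1] * u1[2] - v[2] * u1[1])
  cbind(u1, u2)
}

#' Closed-form morphometry of a spherical-cap aneurysm
#'
#' For a cap of height h cut from a sphere of radius R by the neck plane, with
#' rim (ostium) radius a = sqrt(h (2R - h)):
#' size (neck-centre to farthest dome point) = max(h, a); height = h;
#' neck diameter = 2 a; dome diameter = 2R when h >= R (the equator is the
#' largest section parallel to the neck plane) and 2 a otherwise (the neck
#' plane itself is the largest parallel section); volume = pi h^2 (3R - h) / 3.
#'
#' @param spec an `aneu_phantom_spec` tibble (or any tibble with
#'   `sphere_radius` and `cap_height` columns).
#' @return A tibble: id, location, size_mm, height_mm, neck_mm, dome_mm,
#'   volume_mm3.
#' @export
analytic_morphometry <- function(spec) {
  R <- spec$sphere_radius
  h <- spec$cap_height
  if (any(h <= 0) || any(h > 2 * R)) {
    stop_aneu("cap height must satisfy 0 < h <= 2R", "aneu_geometry_error")
  }
  a <- sqrt(h * (2 * R - h))
  tibble::tibble(
    id = if ("id" %in% names(spec)) spec$id else
      sprintf("case_%04d", seq_along(R)),
    location = if ("location" %in% names(spec)) spec$location else
      NA_character_,
    size_mm = pmax(h, a),
    height_mm = h,
    neck_mm = 2 * a,
    dome_mm = ifelse(h >= R, 2 * R, 2 * a),
    volume_mm3 = pi * h^2 * (3 * R - h) / 3
  )
}

#' First-coil diameter labels for synthetic cases
#'
#' The synthetic ground-truth label follows the framing-coil heuristic that
#' the first coil approximates the dome calibre: the label is the catalog
#' rounding of `0.5 * (dome + size) + e`, `e ~ N(0, 0.25 mm)`, clipped to the
#' 0.5 mm catalog on \[1, 10\] mm. This stated rule is the recoverable signal
#' the coil recommender is expected to learn.
#'
#' @param morph tibble with `size_mm` and `dome_mm` columns.
#' @param seed integer seed for the label noise; `NULL` uses the current
#'   RNG stream.
#' @param noise_sd label noise sd in mm.
#' @return numeric vector of coil diameters (mm) on the catalog grid.
#' @export
assign_first_coil <- function(morph, seed = NULL, noise_sd = 0.25) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  eps <- stats::rnorm(nrow(morph), 0, noise_sd)
  round_to_catalog(0.5 * (morph$dome_mm + morph$size_mm) + eps)
}

#' Render one phantom to pre/post-contrast volumes with ground truth
#'
#' Voxelises the spec on a regular grid: the post-contrast volume adds
#' `contrast_level` inside vessel and aneurysm, both volumes share an offset
#' background, and independent zero-mean Gaussian noise is added to each, so
#' the subtraction (post minus pre) highlights the vasculature. The aneurysm
#' mask is the set of voxel centres inside the spherical cap on the dome side
#' of the neck plane; the vessel mask is the tube minus those voxels. The tube
#' axis is lowered below the neck plane just enough that the tube crests at
#' the ostium, giving the two labels a genuine interface.
#'
#' @param spec a single-row `aneu_phantom_spec`.
#' @param shape integer length-3 grid shape (default 64^3).
#' @param spacing voxel spacing in mm (default 0.5, isotropic).
#' @return list with `pre`, `post` (aneu_volume) and `truth` (list:
#'   `aneurysm_mask`, `vessel_mask`, `morphometry`, `neck_plane`,
#'   `first_coil_mm`).
#' @export
render_phantom <- function(spec, shape = c(64, 64, 64), spacing = 0.5) {
  stopifnot(nrow(spec) == 1)
  spacing <- rep(spacing, length.out = 3)
  R <- spec$sphere_radius; h <- spec$cap_height
  rv <- spec$vessel_radius
  if (max(spacing) > min(rv, R) / 3) {
    stop_aneu("grid too coarse: spacing must be <= min(vessel_radius, R)/3",
              "aneu_resolution_error")
  }
  p0 <- c(spec$neck_x, spec$neck_y, spec$neck_z)
  nrm <- c(spec$normal_x, spec$normal_y, spec$normal_z)
  ax <- c(spec$axis_x, spec$axis_y, spec$axis_z)
  a <- sqrt(h * (2 * R - h))

  P <- voxel_centers(shape, spacing)
  rel <- sweep(P, 2, p0)
  d_plane <- rel %*% nrm                     # signed distance to neck plane
  ctr_sphere <- p0 + (h - R) * nrm
  d2_sphere <- rowSums(sweep(P, 2, ctr_sphere)^2)
  cap <- spec$with_aneurysm & d2_sphere <= R^2 & d_plane >= 0

  # tube axis through q0 = p0 - d_ax * normal, direction ax
  drop_to_plane <- if (rv <= a) rv else sqrt(rv^2 - a^2)
  d_ax <- max(0, drop_to_plane - 0.25)
  q0 <- p0 - d_ax * nrm
  relq <- sweep(P, 2, q0)
  t_ax <- relq %*% ax
  d2_ax <- rowSums(relq^2) - t_ax^2
  tube <- d2_ax <= rv^2
  vessel <- tube & !cap

  dims <- as.integer(shape)
  set.seed(spec$seed %% .Machine$integer.max)
  n_vox <- prod(dims)
  background <- 40
  noise <- function() {
    if (spec$noise_sd > 0) stats::rnorm(n_vox, 0, spec$noise_sd) else 0
  }
  pre <- array(background + noise(), dims)
  post <- array(background + spec$contrast_level * as.numeric(tube | cap) +
                  noise(), dims)
  morph <- if (spec$with_aneurysm) {
    m <- analytic_morphometry(spec)
    m$coil_mm <- assign_first_coil(m, seed = (spec$seed %% 2147483000L) + 1L)
    m
  } else NULL
  list(
    pre = new_volume(pre, spacing),
    post = new_volume(post, spacing),
    truth = list(
      aneurysm_mask = new_volume(array(as.integer(cap), dims), spacing),
      vessel_mask = new_volume(array(as.integer(vessel), dims), spacing),
      morphometry = morph,
      neck_plane = new_neck_plane(p0, nrm),
      first_coil_mm = if (is.null(morph)) NA_real_ else morph$coil_mm
    )
  )
}

#' Simulate a phantom cohort in memory
#'
#' @param n number of phantoms.
#' @param seed master seed (drives spec sampling, rendering noise and labels).
#' @param shape,spacing rendering grid.
#' @param config cohort configuration.
#' @param n_without number of vessel-only (aneurysm-free) phantoms appended
#'   after the `n - n_without` aneurysm-bearing ones.
#' @param keep_raw keep the raw pre/post-contrast volumes on every case;
#'   `FALSE` stores only the subtracted volume and the truth masks, halving
#'   the memory footprint of large cohorts.
#' @return list with `cases` (list of rendered phantoms, each also carrying
#'   `spec` and `subtracted`) and `table` (tibble of analytic morphometry and
#'   coil labels for the aneurysm-bearing cases).
#' @export
simulate_cohort <- function(n, seed = 1, shape = c(64, 64, 64), spacing = 0.5,
                            config = phantom_cohort_config(), n_without = 0,
                            keep_raw = FALSE) {
  stopifnot(n >= 1, n_without >= 0, n_without <= n)
  spec <- sample_phantom_spec(n, config, seed = seed)
  if (n_without > 0) {
    spec$with_aneurysm[seq(n - n_without + 1, n)] <- FALSE
  }
  cases <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- render_phantom(spec[i, ], shape = shape, spacing = spacing)
    ph$spec <- spec[i, ]
    ph$subtracted <- subtract_volumes(ph$post, ph$pre)
    rows[[i]] <- ph$truth$morphometry
    if (!keep_raw) {
      ph$pre <- NULL
      ph$post <- NULL
    }
    cases[[i]] <- ph
  }
  list(cases = cases, table = dplyr::bind_rows(rows), spec = spec)
}

#' Write a phantom cohort to disk
#'
#' Writes, per case, pre- and post-contrast volumes plus aneurysm and vessel
#' masks as NIfTI, one cohort CSV of analytic morphometry and coil labels, and
#' a JSON manifest listing every file. Fully reproducible from `(n, seed)`.
#'
#' @inheritParams simulate_cohort
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly (list with `files` tibble, `csv`, `n`,
#'   `seed`).
#' @export
generate_cohort <- function(n, seed = 1, shape = c(64, 64, 64), spacing = 0.5,
                            out_dir, config = phantom_cohort_config(),
                            n_without = 0) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop_aneu(sprintf("cannot write to out_dir '%s'", out_dir), "aneu_io_error")
  }
  sim <- simulate_cohort(n, seed = seed, shape = shape, spacing = spacing,
                         config = config, n_without = n_without,
                         keep_raw = TRUE)
  files <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- sim$cases[[i]]
    id <- ph$spec$id
    paths <- file.path(out_dir, paste0(id, c("_pre.nii.gz", "_post.nii.gz",
                                             "_aneurysm.nii.gz",
                                             "_vessel.nii.gz")))
    write_volume(ph$pre, paths[1])
    write_volume(ph$post, paths[2])
    write_volume(ph$truth$aneurysm_mask, paths[3], mask = TRUE)
    write_volume(ph$truth$vessel_mask, paths[4], mask = TRUE)
    files[[i]] <- tibble::tibble(id = id,
                                 pre = paths[1], post = paths[2],
                                 aneurysm = paths[3], vessel = paths[4],
                                 with_aneurysm = ph$spec$with_aneurysm)
  }
  csv_path <- file.path(out_dir, "cohort.csv")
  write_cases(sim$table, csv_path)
  manifest <- list(n = n, seed = seed, shape = as.integer(shape),
                   spacing = spacing, csv = csv_path,
                   files = dplyr::bind_rows(files))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  manifest$path <- manifest_path
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
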