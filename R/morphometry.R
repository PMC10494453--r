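#' Neck plane of an aneurysm
#'
#' An oriented plane separating the aneurysm dome from the parent vessel:
#' centroid (the gravity centre of the neck) in world mm, and a unit normal
#' pointing toward the dome.
#'
#' @param centroid numeric length-3, mm.
#' @param normal numeric length-3; normalised internally.
#' @return list of class `aneu_neck_plane`.
#' @export
new_neck_plane <- function(centroid, normal) {
  n <- normal / sqrt(sum(normal^2))
  structure(list(centroid = as.numeric(centroid), normal = as.numeric(n)),
            class = "aneu_neck_plane")
}

#' @export
print.aneu_neck_plane <- function(x, ...) {
  cat(sprintf("<neck plane> centroid (%.2f, %.2f, %.2f) mm, normal (%.3f, %.3f, %.3f)\n",
              x$centroid[1], x$centroid[2], x$centroid[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Subtract pre-contrast from post-contrast volume
#'
#' @param post,pre aligned `aneu_volume`s (same shape and spacing).
#' @return their voxelwise difference as an `aneu_volume`.
#' @export
subtract_volumes <- function(post, pre) {
  if (!identical(dim(post), dim(pre)) ||
      max(abs(voxel_spacing(post) - voxel_spacing(pre))) > 1e-9) {
    stop_aneu("post and pre volumes are not on the same grid",
              "aneu_alignment_error")
  }
  new_volume(array(as.numeric(post) - as.numeric(pre), dim(post)),
             voxel_spacing(post))
}

# midpoints of faces between voxels of mask A and face-adjacent voxels of
# mask B, in world mm
interface_points <- function(A, B, spacing) {
  dims <- dim(A)
  pts <- list()
  k <- 0
  shift_pair <- function(axis, step) {
    # returns linear indices i in A such that neighbour i+step along axis is in B
    idx_a <- which(A == 1L)
    if (length(idx_a) == 0) return(integer(0))
    coord <- arrayInd(idx_a, dims)
    keep <- coord[, axis] + step >= 1 & coord[, axis] + step <= dims[axis]
    coord <- coord[keep, , drop = FALSE]
    ncoord <- coord
    ncoord[, axis] <- ncoord[, axis] + step
    nb <- ncoord[, 1] + (ncoord[, 2] - 1) * dims[1] +
      (ncoord[, 3] - 1) * dims[1] * dims[2]
    coord[B[nb] == 1L, , drop = FALSE]
  }
  for (axis in 1:3) {
    for (step in c(-1L, 1L)) {
      co <- shift_pair(axis, step)
      if (nrow(co) == 0) next
      p <- sweep(co - 0.5, 2, spacing, `*`)
      p[, axis] <- p[, axis] + 0.5 * step * spacing[axis]
      k <- k + 1
      pts[[k]] <- p
    }
  }
  if (k == 0) matrix(numeric(0), 0, 3) else do.call(rbind, pts)
}

#' Estimate the neck plane from aneurysm and vessel masks
#'
#' The paper's measurement definitions presuppose a neck plane but do not say
#' how to construct one; here it is estimated from the label interface: the
#' centroid is the mean of the midpoints of voxel faces shared by the two
#' labels, and the normal is the smallest-variance principal direction of that
#' interface point cloud, oriented toward the aneurysm centroid.
#'
#' @param aneurysm_mask,vessel_mask aligned binary `aneu_volume`s.
#' @param spacing optional spacing override (mm).
#' @return an `aneu_neck_plane`.
#' @export
estimate_neck_plane <- function(aneurysm_mask, vessel_mask, spacing = NULL) {
  spacing <- spacing %||% voxel_spacing(aneurysm_mask)
  A <- aneurysm_mask; B <- vessel_mask
  if (sum(A) == 0 || sum(B) == 0) {
    stop_aneu("isolated mask: both masks must be nonempty", "aneu_isolated_mask")
  }
  pts <- interface_points(A, B, spacing)
  if (nrow(pts) == 0) {
    stop_aneu("isolated mask: labels share no voxel face", "aneu_isolated_mask")
  }
  centroid <- colMeans(pts)
  ctrd <- sweep(pts, 2, centroid)
  normal <- svd(ctrd, nu = 0, nv = 3)$v[, 3]
  # orient toward the aneurysm centroid
  an_idx <- which(A == 1L)
  an_ctr <- colMeans(sweep(arrayInd(an_idx, dim(A)) - 0.5, 2, spacing, `*`))
  if (sum((an_ctr - centroid) * normal) < 0) normal <- -normal
  new_neck_plane(centroid, normal)
}

# average chord length through the centroid of a filled 2D pixel set (pixel
# centres in mm, pitch `pixel`), over n_chords equally spaced directions;
# pixels within half a pitch of the chord line count. The raster comes from
# the 0.5 level of trilinear interpolation, which already lands on the mask
# surface, so no endpoint correction is applied. Returns NaN when no
# direction yields a measurable chord.
chord_average <- function(pts2, n_chords, pixel) {
  ctr <- colMeans(pts2)
  x <- pts2[, 1] - ctr[1]
  y <- pts2[, 2] - ctr[2]
  half_width <- 0.5 * pixel
  theta <- (seq_len(n_chords) - 1) * pi / n_chords
  chords <- vapply(theta, function(th) {
    t <- x * cos(th) + y * sin(th)
    s <- -x * sin(th) + y * cos(th)
    sel <- abs(s) <= half_width
    if (!any(sel)) return(NA_real_)
    diff(range(t[sel]))
  }, numeric(1))
  mean(chords, na.rm = TRUE)
}

# resample a binary mask onto a 2D raster lying in the plane offset by
# `offset` along the normal: returns pixel-centre coordinates (mm, in-plane)
# of the in-mask pixels, or NULL when the section is empty
plane_section <- function(mask, spacing, centroid, normal, U, offset,
                          extent, step) {
  half_n <- ceiling(extent / step)
  n_pix <- 2L * half_n + 1L
  origin <- centroid + offset * normal - half_n * step * (U[, 1] + U[, 2])
  # affine: raster pixel (i, j, 0) -> source voxel coords
  A <- cbind(step * U[, 1] / spacing, step * U[, 2] / spacing, 0,
             origin / spacing - 0.5)
  v <- .warp_resample(as.numeric(mask), as.integer(dim(mask)),
                      c(n_pix, n_pix, 1L), A, matrix(numeric(0), 0, 3),
                      FALSE, 0, FALSE)
  # threshold slightly below half: at the thin rim wedge of a cap the
  # expected occupancy of in-section pixels dips below 0.5 and a strict
  # majority vote erodes the boundary section (checked against digitized
  # balls of known radius)
  inside <- v >= 0.4
  if (!any(inside)) return(NULL)
  ij <- arrayInd(which(inside), c(n_pix, n_pix))
  (ij - 1L - half_n) * step
}

#' Measure the five morphometric features from an aneurysm mask
#'
#' Given a binary aneurysm (dome) mask and an oriented neck plane, computes in
#' physical mm: size (largest distance of a dome voxel centre from the neck
#' centroid), height (largest perpendicular distance of the dome from the
#' plane), neck diameter (average over `n_chords` equally spaced in-plane
#' directions of the chord length through the neck-section centroid), dome
#' diameter (same chord average on the parallel section of maximal
#' cross-sectional area, searched at half-voxel offsets, ties broken toward
#' the neck) and volume (voxel count times voxel volume). Sections are slabs
#' of half-thickness half a voxel around the sectioning plane; a section with
#' fewer than 3 voxels yields `NaN` for its diameter.
#'
#' @param aneurysm_mask binary `aneu_volume`.
#' @param neck_plane an `aneu_neck_plane`.
#' @param spacing optional spacing override (mm).
#' @param n_chords number of chord directions (1 degree resolution default).
#' @param location optional location label carried into the record.
#' @param id optional case id.
#' @return single-row tibble: id, location, size_mm, height_mm, neck_mm,
#'   dome_mm, volume_mm3.
#' @export
measure_morphometry <- function(aneurysm_mask, neck_plane, spacing = NULL,
                                n_chords = 180, location = NA_character_,
                                id = NA_character_) {
  spacing <- spacing %||% voxel_spacing(aneurysm_mask)
  idx <- which(aneurysm_mask == 1L)
  if (length(idx) == 0) {
    stop_aneu("empty aneurysm mask", "aneu_measurement_error")
  }
  P <- sweep(arrayInd(idx, dim(aneurysm_mask)) - 0.5, 2, spacing, `*`)
  ctr <- neck_plane$centroid
  nrm <- neck_plane$normal
  rel <- sweep(P, 2, ctr)
  d_perp <- as.numeric(rel %*% nrm)
  size <- sqrt(max(rowSums(rel^2)))
  height <- max(d_perp)
  sp <- max(spacing)
  half <- 0.5 * sp
  step <- 0.5 * sp
  U <- pick_orthonormal(nrm)
  extent <- sqrt(max(rowSums(rel^2))) + sp

  section_pixels <- function(offset) {
    # degenerate-section rule operates on the voxels in the slab
    if (sum(abs(d_perp - offset) <= half) < 3) return(NULL)
    plane_section(aneurysm_mask, spacing, ctr, nrm, U, offset, extent, step)
  }
  section_diameter <- function(px) {
    if (is.null(px) || nrow(px) < 3) return(NaN)
    chord_average(px, n_chords, step)
  }
  # sections are sampled half a voxel inside the dome: voxels exactly on the
  # plane belong to the neck section, and probing at their dome-side face
  # height avoids the interpolation mixing with sub-plane (vessel) voxels
  # that would otherwise erode the boundary section
  neck_d <- section_diameter(section_pixels(half))

  offsets <- seq(half, max(height, half), by = half)
  sections <- lapply(offsets, section_pixels)
  areas <- vapply(sections, function(px) if (is.null(px)) 0L else nrow(px),
                  integer(1))
  best <- which.max(areas)   # which.max takes the first: tie -> neck
  dome_d <- section_diameter(sections[[best]])

  tibble::tibble(id = id, location = location,
                 size_mm = size, height_mm = height,
                 neck_mm = neck_d, dome_mm = dome_d,
                 volume_mm3 = length(idx) * prod(spacing))
}

#' Keep the largest 26-connected component of a binary mask
#'
#' @param mask binary `aneu_volume` or array.
#' @return mask of the same type with only the largest component retained.
#' @export
largest_component <- function(mask) {
  dims <- dim(mask)
  lab <- .cc_label(as.integer(mask != 0), as.integer(dims))
  if (max(lab) == 0) return(mask)
  keep <- which.max(tabulate(lab))
  out <- array(as.integer(lab == keep), dims)
  if (!is.null(attr(mask, "spacing"))) out <- new_volume(out, voxel_spacing(mask))
  out
}

#' Morphometry from a predicted (possibly noisy) mask
#'
#' Applies a largest-connected-component filter (CNN false-positive specks
#' would otherwise corrupt the farthest-point size), then estimates the neck
#' plane against the vessel mask and measures the five features.
#'
#' @inheritParams estimate_neck_plane
#' @inheritParams measure_morphometry
#' @param predicted_mask binary `aneu_volume` from the segmenter.
#' @return single-row tibble as [measure_morphometry()].
#' @export
measure_from_prediction <- function(predicted_mask, vessel_mask, spacing = NULL,
                                    n_chords = 180, location = NA_character_,
                                    id = NA_character_) {
  if (sum(predicted_mask) == 0) {
    stop_aneu("no aneurysm detected", "aneu_no_aneurysm")
  }
  spacing <- spacing %||% voxel_spacing(predicted_mask)
  m <- largest_component(predicted_mask)
  plane <- estimate_neck_plane(m, vessel_mask, spacing)
  measure_morphometry(m, plane, spacing, n_chords = n_chords,
                      location = location, id = id)
}
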