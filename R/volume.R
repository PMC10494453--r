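#' 3D volume containers
#'
#' A volume is an ordinary 3D numeric array carrying a `spacing` attribute
#' (voxel edge lengths in mm). Voxel centres sit at `(index0 + 0.5) * spacing`
#' in world coordinates, with 0-based indices and the world origin at the
#' volume corner. Masks are the same thing with 0/1 values.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3 (or length-1, recycled) voxel spacing in mm.
#' @return An `aneu_volume`: the array with `spacing` attached.
#' @export
new_volume <- function(data, spacing = 0.5) {
  stopifnot(length(dim(data)) == 3)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be positive and finite", call. = FALSE)
  }
  structure(data, spacing = spacing, class = c("aneu_volume", class(data)))
}

#' @rdname new_volume
#' @param vol an `aneu_volume` (or any array with a `spacing` attribute).
#' @export
voxel_spacing <- function(vol) {
  sp <- attr(vol, "spacing")
  if (is.null(sp)) stop("volume has no spacing attribute", call. = FALSE)
  sp
}

#' @export
print.aneu_volume <- function(x, ...) {
  d <- dim(x)
  sp <- voxel_spacing(x)
  cat(sprintf("<aneu_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

# World coordinates (mm) of every voxel centre, as an n x 3 matrix in array
# order. Used by the renderer and the morphometry code.
voxel_centers <- function(dims, spacing) {
  g <- lapply(1:3, function(k) (seq_len(dims[k]) - 0.5) * spacing[k])
  cbind(
    rep(g[[1]], times = dims[2] * dims[3]),
    rep(rep(g[[2]], each = dims[1]), times = dims[3]),
    rep(g[[3]], each = dims[1] * dims[2])
  )
}

stop_aneu <- function(msg, class) {
  stop(structure(class = c(class, "aneu_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
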