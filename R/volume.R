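#' Isotropic 3-D scalar volume
#'
#' CT-style image container.  World coordinates follow the voxel-centre
#' convention: `world = origin + (index - 1) * spacing` with 1-based array
#' indices, axial slices along the third axis.
#'
#' @param data 3-D numeric array.
#' @param spacing isotropic voxel spacing (mm).
#' @param origin world coordinate of voxel (1, 1, 1) centre (mm).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(spacing) == 1, is.finite(spacing), spacing > 0,
            length(origin) == 3)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %.4g mm, origin (%.2f, %.2f, %.2f) mm\n",
              d[1], d[2], d[3], x$spacing, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

# World coordinates of voxel centres along each axis.
volume_axes <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing)
}
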