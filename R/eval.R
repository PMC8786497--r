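#' World coordinates of a volume's 8 grid corners
#'
#' The corners of the voxel grid's bounding box (indices 0 or `n - 1` per
#' axis) mapped through [world_from_voxel()]. These are the probe points of
#' the registration-error metric: errors at the corners bound the error
#' anywhere inside the volume for a rigid discrepancy.
#'
#' @param v a [volume()].
#' @return `8 x 3` matrix of world coordinates (mm).
#' @export
volume_vertices <- function(v) {
  stopifnot(inherits(v, "volume"))
  corners <- as.matrix(expand.grid(x = c(0, v$dims[1] - 1),
                                   y = c(0, v$dims[2] - 1),
                                   z = c(0, v$dims[3] - 1)))
  world_from_voxel(v, corners)
}

#' Eight-vertex registration error against a gold standard
#'
#' Maps the 8 vertices of the floating image through both the estimated and
#' the gold-standard transform and summarizes the discrepancy: `delta` is
#' the mean Euclidean distance between corresponding vertices and
#' `delta_xyz` the per-axis mean absolute coordinate differences.
#'
#' @param tf_est estimated transform (a [rigid_transform()] or any rigid
#'   map with fields `R`, `t`).
#' @param tf_ref gold-standard transform (same).
#' @param vertices `8 x 3` matrix of world points, typically
#'   [volume_vertices()] of the floating image.
#' @return object of class `vertex_error` with fields `delta` (mm) and
#'   `delta_xyz` (named length-3, mm).
#' @export
vertex_error <- function(tf_est, tf_ref, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != 8L || ncol(vertices) != 3L)
    stop("'vertices' must be an 8 x 3 matrix")
  q_est <- apply_transform(tf_est, vertices)
  q_ref <- apply_transform(tf_ref, vertices)
  d <- q_ref - q_est
  structure(list(delta = mean(sqrt(rowSums(d^2))),
                 delta_xyz = c(x = mean(abs(d[, 1])),
                               y = mean(abs(d[, 2])),
                               z = mean(abs(d[, 3])))),
            class = "vertex_error")
}

#' @export
print.vertex_error <- function(x, ...) {
  cat(sprintf("<vertex_error> delta = %.3f mm (x %.3f, y %.3f, z %.3f)\n",
              x$delta, x$delta_xyz[1], x$delta_xyz[2], x$delta_xyz[3]))
  invisible(x)
}

#' Voxel diagonal distance
#'
#' `sqrt(sx^2 + sy^2 + sz^2)`: the length of one voxel's space diagonal,
#' used as the single-pixel yardstick of the sub-voxel accuracy criterion.
#'
#' @param voxel_size numeric length-3, mm.
#' @return scalar mm.
#' @examples
#' pixel_diagonal(c(1.25, 1.25, 4.0))  # ~4.373 mm
#' @export
pixel_diagonal <- function(voxel_size) {
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size >= 0),
            any(voxel_size > 0))
  sqrt(sum(voxel_size^2))
}

#' Sub-voxel accuracy check and report row
#'
#' A registration is sub-voxel accurate when its mean 8-vertex error is
#' strictly below the voxel diagonal of the given voxel size.
#'
#' @param err a [vertex_error()].
#' @param voxel_size voxel size (mm) defining the yardstick (conventionally
#'   the reference image's).
#' @return list with `subpixel` (logical) and `row`, a one-row data frame
#'   (delta_x, delta_y, delta_z, delta, threshold, subpixel) rounded to
#'   3 decimals in mm.
#' @export
subpixel_check <- function(err, voxel_size) {
  stopifnot(inherits(err, "vertex_error"))
  thr <- pixel_diagonal(voxel_size)
  ok <- err$delta < thr
  list(subpixel = ok,
       row = data.frame(delta_x = round(err$delta_xyz[["x"]], 3),
                        delta_y = round(err$delta_xyz[["y"]], 3),
                        delta_z = round(err$delta_xyz[["z"]], 3),
                        delta = round(err$delta, 3),
                        threshold = round(thr, 3),
                        subpixel = ok))
}
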