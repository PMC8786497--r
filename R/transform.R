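#' Rigid-body transform
#'
#' The 6-parameter search space of the registration: three translations
#' (mm) and three rotation angles (degrees) about the x, y and z axes.
#' The transform maps world points of the floating image (in its
#' centre-of-gravity frame) into the reference image's centre-of-gravity
#' frame as `p -> R %*% p + t` with `R = Rx(phi_x) Ry(phi_y) Rz(phi_z)`
#' (fixed-axes composition, in that order).
#'
#' @param t numeric length-3 translation in mm.
#' @param phi numeric length-3 rotation angles in degrees.
#' @return An object of class `rigid_transform` with fields `t`, `phi` and
#'   the induced rotation matrix `R`.
#' @examples
#' tf <- rigid_transform(t = c(1, 2, 3), phi = c(0, 0, 90))
#' apply_transform(tf, c(1, 0, 0))
#' @export
rigid_transform <- function(t = c(0, 0, 0), phi = c(0, 0, 0)) {
  t <- as.numeric(t); phi <- as.numeric(phi)
  if (length(t) != 3L || length(phi) != 3L ||
      !all(is.finite(c(t, phi))))
    stop("'t' and 'phi' must be finite length-3 vectors")
  structure(list(t = t, phi = phi, R = rotation_matrix(phi)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.4f, %.4f, %.4f) mm, phi = (%.4f, %.4f, %.4f) deg\n",
              x$t[1], x$t[2], x$t[3], x$phi[1], x$phi[2], x$phi[3]))
  invisible(x)
}

#' Rotation matrix from per-axis angles
#'
#' `R = Rx(phi_x) %*% Ry(phi_y) %*% Rz(phi_z)`, right-handed, applied to
#' column points. Angles are degrees.
#'
#' @param phi numeric length-3 angles in degrees.
#' @return orthogonal 3x3 matrix with determinant +1.
#' @export
rotation_matrix <- function(phi) {
  a <- as.numeric(phi) * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0,  0, cx, sx,  0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy,  0, 1, 0,  sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0,  -sz, cz, 0,  0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

#' Apply a rigid map to world points
#'
#' @param tf a [rigid_transform()] or the inverse map from
#'   [invert_transform()] (anything with fields `R` and `t`).
#' @param p numeric length-3 point or `n x 3` matrix of points (mm).
#' @return transformed point(s), same shape as `p`.
#' @export
apply_transform <- function(tf, p) {
  if (is.matrix(p))
    sweep(p %*% t(tf$R), 2, tf$t, `+`)
  else
    drop(tf$R %*% as.numeric(p)) + tf$t
}

#' Invert a rigid map
#'
#' Returns the mapping `p -> R^T (p - t)` so that
#' `apply_transform(tf, apply_transform(invert_transform(tf), p)) == p`.
#' The inverse is returned as a `rigid_map` (rotation matrix + translation)
#' rather than re-extracting Euler angles.
#'
#' @param tf a [rigid_transform()] or `rigid_map`.
#' @return an object of class `rigid_map` with fields `R` and `t`.
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$R)
  structure(list(R = Rt, t = -drop(Rt %*% tf$t)), class = "rigid_map")
}

#' @export
print.rigid_map <- function(x, ...) {
  cat("<rigid_map> t =", format(x$t, digits = 6), "\n")
  invisible(x)
}

#' Read / write a transform file
#'
#' Plain-text format used for gold standards and registration results: six
#' labelled numbers, one per line (`tx_mm`, `ty_mm`, `tz_mm`, `rx_deg`,
#' `ry_deg`, `rz_deg`).
#'
#' @param path file path.
#' @return `read_transform` returns a [rigid_transform()].
#' @export
read_transform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  keys <- vapply(parts, `[[`, "", 1L)
  vals <- as.numeric(vapply(parts, `[[`, "", 2L))
  names(vals) <- keys
  need <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  if (!all(need %in% keys) || any(is.na(vals[need])))
    stop("transform file must contain labelled numbers ",
         paste(need, collapse = ", "))
  rigid_transform(t = unname(vals[need[1:3]]), phi = unname(vals[need[4:6]]))
}

#' @rdname read_transform
#' @param tf a [rigid_transform()].
#' @export
write_transform <- function(tf, path) {
  stopifnot(inherits(tf, "rigid_transform"))
  writeLines(sprintf("%s %.17g",
                     c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg"),
                     c(tf$t, tf$phi)), path)
  invisible(path)
}
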