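#' Specification of a synthetic multimodal phantom pair
#'
#' The phantom is a field of nested ellipsoids sharing one geometry but
#' rendered with two different per-structure contrast maps, emulating the
#' CT-versus-MR situation: the same anatomy, intensity relations that are
#' not affine (labels are permuted between the maps), so correlation-based
#' similarity fails while mutual information does not. The ellipsoids have
#' unequal semi-axes and the innermost one is slightly off-centre, which
#' makes all three rotation angles identifiable within the optimizer's
#' search range. Additive Gaussian noise is drawn independently for the
#' two renderings.
#'
#' @param dims voxel counts per axis (default `c(64, 64, 64)`, each `>= 8`).
#' @param voxel_size mm per voxel (default `c(1, 1, 1)`, typical of
#'   near-isotropic MR).
#' @param n_structures number of nested ellipsoids (default 3).
#' @param contrast_ref,contrast_flt intensity per region for the reference
#'   and floating rendering; length `n_structures + 1` (background first),
#'   distinct within each map. Defaults are a monotone map versus a
#'   permuted one.
#' @param noise_sd additive Gaussian noise standard deviation (default 2,
#'   i.e. a few percent of the structure contrast).
#' @param seed RNG seed for the noise draws.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64L, 64L, 64L), voxel_size = c(1, 1, 1),
                         n_structures = 3L,
                         contrast_ref = NULL, contrast_flt = NULL,
                         noise_sd = 2, seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 8L))
    stop("'dims' must be three integers >= 8")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  n_structures <- as.integer(n_structures)
  if (n_structures < 1L) stop("need at least one structure")
  if (is.null(contrast_ref))
    contrast_ref <- c(10, seq(80, 220, length.out = n_structures))
  if (is.null(contrast_flt)) {
    # non-monotone reassignment: a bright background and structure
    # intensities alternating between the extremes, so the pair correlates
    # weakly while sharing all region boundaries (the multimodal regime)
    levels <- seq(220, 30, length.out = max(n_structures, 2L))
    idx <- integer(n_structures)
    idx[seq(1L, n_structures, 2L)] <- seq_len(ceiling(n_structures / 2))
    if (n_structures > 1L)
      idx[seq(2L, n_structures, 2L)] <-
        seq(n_structures, by = -1L, length.out = floor(n_structures / 2))
    contrast_flt <- c(120, levels[idx])
  }
  if (length(contrast_ref) != n_structures + 1L ||
      length(contrast_flt) != n_structures + 1L)
    stop("contrast maps must have n_structures + 1 values (background first)")
  if (anyDuplicated(contrast_ref) || anyDuplicated(contrast_flt))
    stop("structure intensities must be distinct within each map")
  structure(list(dims = dims, voxel_size = as.numeric(voxel_size),
                 n_structures = n_structures,
                 contrast_ref = as.numeric(contrast_ref),
                 contrast_flt = as.numeric(contrast_flt),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Nested-ellipsoid label field: 0 = background, k = inside the k-th
# ellipsoid (innermost wins). Semi-axes shrink geometrically and are
# deliberately unequal; the innermost centre is offset along +x/+y.
phantom_labels <- function(spec) {
  d <- spec$dims
  centre <- (d - 1) / 2
  # base semi-axes in voxels; clearly distinct per axis so that every
  # rotation leaves a footprint in the overlap (identifiability)
  ax <- outer(c(0.45, 0.30, 0.37), d)
  x <- (seq_len(d[1]) - 1 - centre[1])
  y <- (seq_len(d[2]) - 1 - centre[2])
  z <- (seq_len(d[3]) - 1 - centre[3])
  labels <- array(0L, dim = d)
  for (k in seq_len(spec$n_structures)) {
    shrink <- 0.62^(k - 1)
    off <- if (k == spec$n_structures && spec$n_structures > 1L)
      c(0.08, 0.05, 0.06) * d else c(0, 0, 0)
    q <- outer(outer(((x - off[1]) / (ax[1, 1] * shrink))^2,
                     ((y - off[2]) / (ax[2, 2] * shrink))^2, `+`),
               ((z - off[3]) / (ax[3, 3] * shrink))^2, `+`)
    labels[q <= 1] <- k
  }
  labels
}

#' Generate a multimodal phantom pair
#'
#' Renders the nested-ellipsoid label field with the two contrast maps and
#' adds independent Gaussian noise (clamped at zero so intensities stay
#' non-negative), returning the reference volume and the floating-image
#' template still in perfect alignment with it. Use [displace()] to move
#' the template by a known ground-truth transform.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `ref` and `flt` (both [volume()]s).
#' @export
make_phantom_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- phantom_labels(spec)
  set.seed(spec$seed)
  n <- prod(spec$dims)
  render <- function(contrast) {
    vals <- contrast[labels + 1L]
    if (spec$noise_sd > 0)
      vals <- vals + stats::rnorm(n, sd = spec$noise_sd)
    volume(array(pmax(vals, 0), dim = spec$dims), spec$voxel_size)
  }
  ref <- render(spec$contrast_ref)
  flt <- render(spec$contrast_flt)
  list(ref = ref, flt = flt)
}

#' Displace a floating-image template by a known transform
#'
#' Produces the floating image whose registration against the untouched
#' template recovers `tf_true`: each output voxel takes the template's
#' trilinearly interpolated value at `apply_transform(tf_true, w)`, where
#' `w` is the voxel's world coordinate in the template's centre-of-gravity
#' frame. Voxels pulled from outside the template are set to 0. Trilinear
#' interpolation is used here as an image resampler; it is distinct from
#' the partial-volume rule of the metric, which interpolates histogram
#' weights, never intensities.
#'
#' @param template a [volume()] (the aligned floating rendering).
#' @param tf_true a [rigid_transform()], the ground truth to recover.
#' @return a displaced [volume()] on the same grid.
#' @export
displace <- function(template, tf_true) {
  stopifnot(inherits(template, "volume"))
  d <- template$dims
  cog <- center_of_gravity(template)
  grid <- as.matrix(expand.grid(x = seq_len(d[1]) - 1,
                                y = seq_len(d[2]) - 1,
                                z = seq_len(d[3]) - 1))
  w <- world_from_voxel(template, grid, cog = cog)
  src <- voxel_from_world(template, apply_transform(tf_true, w), cog = cog)
  vals <- trilinear_sample(as.numeric(template$data), as.integer(d), src, 0)
  volume(array(vals, dim = d), template$voxel_size)
}

#' Gold-standard transform in the frames the optimizer actually uses
#'
#' Registration operates in centre-of-gravity frames of the two volumes as
#' they are, but a displaced phantom's centre of gravity moves with its
#' content (and loses a little mass at the borders), so the transform that
#' perfectly aligns the pair in those frames differs from `tf_true` by
#' centre-of-gravity offsets. With `c_ref`, `c_tpl` and `c_flt` the centres
#' of gravity of the reference volume, the aligned floating template and
#' the displaced floating volume (fractional voxels, `s` the voxel size),
#' the rotation is unchanged and
#' `t_gold = t_true - (c_ref - c_tpl) * s - R_true %*% ((c_tpl - c_flt) * s)`.
#' This function computes that effective gold standard for evaluating a
#' recovered transform.
#'
#' @param ref the reference volume of the registration.
#' @param flt the displaced floating volume.
#' @param tf_true the transform passed to [displace()].
#' @param template the aligned floating template that was displaced; when
#'   omitted its centre of gravity is assumed to equal the reference's
#'   (exact for identical renderings, near-exact for a noisy phantom pair).
#' @return a `rigid_map` (fields `R`, `t`) usable with [vertex_error()].
#' @export
gold_transform <- function(ref, flt, tf_true, template = NULL) {
  s <- flt$voxel_size
  c_ref <- center_of_gravity(ref)
  c_tpl <- if (is.null(template)) c_ref else center_of_gravity(template)
  c_flt <- center_of_gravity(flt)
  t_gold <- tf_true$t - (c_ref - c_tpl) * s -
    drop(tf_true$R %*% ((c_tpl - c_flt) * s))
  structure(list(R = tf_true$R, t = t_gold), class = "rigid_map")
}
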