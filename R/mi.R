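#' Intensity bin edges and bin assignment
#'
#' Bin edges span `[min, max]` of the volume's intensities, divided into
#' `bins` equal-width bins; the top edge is inclusive. A constant volume
#' gets a unit-width bin around its value.
#' @noRd
bin_edges <- function(v, bins) {
  rng <- range(v$data)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = bins + 1L)
}

#' @noRd
bin_index0 <- function(x, edges) {
  bins <- length(edges) - 1L
  width <- (edges[bins + 1L] - edges[1L]) / bins
  i <- floor((x - edges[1L]) / width)
  i[i < 0] <- 0
  i[i > bins - 1L] <- bins - 1L
  as.integer(i)
}

#' Foreground sampling mask
#'
#' Logical mask of voxels whose intensity exceeds the given quantile of the
#' volume. Restricting histogram sampling to such a region around the
#' image's centre of gravity reduces the influence of background voxels on
#' the mutual-information estimate.
#'
#' @param v a [volume()].
#' @param quantile intensity quantile in `[0, 1)` (default 0.5).
#' @return logical array with the volume's dims.
#' @export
foreground_mask <- function(v, quantile = 0.5) {
  stopifnot(inherits(v, "volume"), quantile >= 0, quantile < 1)
  thr <- stats::quantile(v$data, quantile, names = FALSE)
  array(v$data > thr, dim = v$dims)
}

#' Partial-volume joint histogram
#'
#' Estimates the joint intensity distribution of a reference and a
#' transformed floating volume. Every sampled reference voxel is mapped
#' through the inverse of `tf` into floating-image world coordinates; the
#' eight floating-grid neighbours of that location receive their trilinear
#' weights as fractional counts in the row of the reference voxel's
#' intensity bin (partial-volume interpolation: weights go into the
#' histogram, intensities are never interpolated, so the MI surface changes
#' smoothly with the transform). Samples falling outside the floating grid
#' contribute nothing and are excluded from `n_samples`; the weights of
#' every counted sample sum to one.
#'
#' @param ref,flt reference and floating [volume()]s.
#' @param tf a [rigid_transform()] mapping floating world to reference world.
#' @param bins number of intensity bins per image (default 64).
#' @param mask optional logical array over the reference grid restricting
#'   which voxels are sampled (see [foreground_mask()]).
#' @param stride integer length-3 sampling stride over the reference grid
#'   (every `k`-th voxel per axis); geometry stays at full resolution.
#' @return An object of class `joint_histogram` with fields `counts`
#'   (`bins x bins` matrix of fractional counts, reference bins in rows),
#'   `bin_edges_ref`, `bin_edges_flt` and `n_samples`.
#' @export
joint_histogram_pv <- function(ref, flt, tf, bins = 64L, mask = NULL,
                               stride = c(1L, 1L, 1L)) {
  pre <- mi_sampling_setup(ref, flt, bins, mask, stride)
  pv_histogram_from_setup(pre, tf)
}

# Precomputation shared across many evaluations of the same image pair:
# sampled reference voxels (world coordinates + intensity bins) and the
# floating volume's per-voxel bin labels.
#' @noRd
mi_sampling_setup <- function(ref, flt, bins = 64L, mask = NULL,
                              stride = c(1L, 1L, 1L)) {
  stopifnot(inherits(ref, "volume"), inherits(flt, "volume"))
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("'bins' must be an integer >= 2")
  stride <- as.integer(stride)
  if (length(stride) != 3L || any(stride < 1L))
    stop("'stride' must be three integers >= 1")
  if (!is.null(mask) && !identical(dim(mask), as.integer(ref$dims)))
    stop("'mask' must match the reference dims")

  edges_ref <- bin_edges(ref, bins)
  edges_flt <- bin_edges(flt, bins)

  ix <- seq(1L, ref$dims[1], by = stride[1])
  iy <- seq(1L, ref$dims[2], by = stride[2])
  iz <- seq(1L, ref$dims[3], by = stride[3])
  grid <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  if (!is.null(mask)) grid <- grid[mask[grid], , drop = FALSE]
  if (nrow(grid) == 0L) stop("empty sampling set (mask removed all voxels)")

  ref_vals <- ref$data[grid]
  ref_world <- world_from_voxel(ref, grid - 1)
  list(
    ref_bin = bin_index0(ref_vals, edges_ref),
    ref_world = ref_world,
    flt_bin = array(bin_index0(flt$data, edges_flt), dim = flt$dims),
    flt_dim = as.integer(flt$dims),
    flt_voxel = flt$voxel_size,
    flt_cog = center_of_gravity(flt),
    bins = bins,
    edges_ref = edges_ref,
    edges_flt = edges_flt
  )
}

#' @noRd
pv_histogram_from_setup <- function(pre, tf) {
  inv <- invert_transform(tf)
  acc <- pv_accumulate(pre$ref_bin, pre$ref_world, pre$flt_bin,
                       pre$flt_dim, pre$flt_voxel, pre$flt_cog,
                       inv$R, inv$t, pre$bins, pre$bins)
  structure(list(counts = acc$counts,
                 bin_edges_ref = pre$edges_ref,
                 bin_edges_flt = pre$edges_flt,
                 n_samples = acc$n_samples),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("<joint_histogram> %d x %d bins, %.0f samples\n",
              nrow(x$counts), ncol(x$counts), x$n_samples))
  invisible(x)
}

#' Export a joint histogram as delimited text
#'
#' @param h a `joint_histogram`.
#' @param path output file (tab-separated counts matrix).
#' @export
write_histogram <- function(h, path) {
  stopifnot(inherits(h, "joint_histogram"))
  utils::write.table(h$counts, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Marginal and joint entropies of a joint histogram
#'
#' Probabilities are the normalized fractional counts; entropies are in
#' nats with the convention `0 * log(0) = 0`. `H_A` is the reference
#' (row) marginal, `H_B` the floating (column) marginal.
#'
#' @param h a `joint_histogram` (or a bare non-negative counts matrix).
#' @return named numeric vector `c(H_A=, H_B=, H_AB=)`.
#' @export
entropies <- function(h) {
  counts <- if (inherits(h, "joint_histogram")) h$counts else as.matrix(h)
  total <- sum(counts)
  if (!is.finite(total) || total <= 0)
    stop("degenerate histogram: empty overlap (no samples)")
  p <- counts / total
  hfun <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  c(H_A = hfun(rowSums(p)), H_B = hfun(colSums(p)), H_AB = hfun(p))
}

#' Mutual information of a joint histogram
#'
#' `I(A, B) = H(A) + H(B) - H(A, B)` in nats; maximal when the two images
#' are correctly aligned, which is what the optimizer exploits.
#'
#' @inheritParams entropies
#' @return non-negative scalar (nats).
#' @export
mutual_information <- function(h) {
  e <- entropies(h)
  unname(e["H_A"] + e["H_B"] - e["H_AB"])
}

#' Build a mutual-information objective for an image pair
#'
#' Precomputes the sampling set once and returns a deterministic function
#' `RigidTransform -> MI (nats)` suitable for the optimizer. A transform
#' with empty overlap evaluates to 0 rather than erroring, so the search
#' can traverse degenerate regions.
#'
#' @inheritParams joint_histogram_pv
#' @return a function of one argument (a [rigid_transform()]).
#' @export
mi_objective <- function(ref, flt, bins = 64L, mask = NULL,
                         stride = c(1L, 1L, 1L)) {
  pre <- mi_sampling_setup(ref, flt, bins, mask, stride)
  function(tf) {
    h <- pv_histogram_from_setup(pre, tf)
    if (h$n_samples <= 0) return(0)
    mutual_information(h)
  }
}
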