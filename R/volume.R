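#' Construct a 3D image volume
#'
#' A `volume` is the unit being registered: a 3D array of scalar intensities
#' together with its (possibly anisotropic) voxel size in millimetres.
#' Orientation information beyond axis order is deliberately not carried;
#' volumes are treated as axis-aligned grids.
#'
#' @param data numeric 3D array of intensities. All values must be finite.
#' @param voxel_size numeric length-3 vector of per-axis voxel sizes in mm,
#'   all strictly positive.
#' @return An object of class `volume` with fields `data`, `dims` and
#'   `voxel_size`.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), c(1, 1, 1))
#' v$dims
#' @export
volume <- function(data, voxel_size) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) < 1L))
    stop("all dimensions must be >= 1")
  if (!all(is.finite(data)))
    stop("all intensities must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || !all(is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive finite values (mm)")
  structure(list(data = data, dims = dim(data), voxel_size = voxel_size),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %d x %d x %d voxels, voxel size %.6g x %.6g x %.6g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.6g, %.6g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Load a 3D volume from disk
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`), Analyze 7.5 (`.hdr`/`.img`) or a raw
#' binary array accompanied by a plain-text sidecar config. Intensities are
#' cast to double and shifted so the minimum is zero when negative values are
#' present (CT Hounsfield offsets), since histogram binning assumes a
#' non-negative range. Voxel sizes always come from the header/sidecar;
#' a missing or non-positive voxel size is an error, never defaulted to 1 mm.
#'
#' The raw format expects a sidecar file at `<path>.cfg` (or passed via
#' `sidecar`) with `key: value` lines for `dims` (three integers),
#' `voxel_size_mm` (three numbers), `dtype` (one of `uint8`, `int16`,
#' `int32`, `float32`, `float64`) and `byte_order` (`little` or `big`).
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"nifti"`, `"analyze"`, `"raw"`. `"auto"`
#'   dispatches on the file extension.
#' @param sidecar optional sidecar path for `format = "raw"`.
#' @return A [volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "analyze", "raw"),
                        sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path) && !file.exists(paste0(path, ".hdr")))
    stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
    else if (grepl("\\.(hdr|img)$", path) || file.exists(paste0(path, ".hdr")))
      "analyze"
    else "raw"
  }
  v <- switch(format,
    nifti = {
      img <- RNifti::readNifti(path)
      vs <- RNifti::pixdim(img)[1:3]
      volume(clamp_nonneg(as.array(img)), check_voxel_size(vs, path))
    },
    analyze = {
      stem <- sub("\\.(hdr|img)$", "", path)
      img <- oro.nifti::readANALYZE(stem)
      arr <- drop(oro.nifti::img_data(img))
      if (length(dim(arr)) != 3L)
        stop("expected a 3D Analyze volume: ", path)
      vs <- img@pixdim[2:4]
      volume(clamp_nonneg(arr), check_voxel_size(vs, path))
    },
    raw = {
      if (is.null(sidecar)) sidecar <- paste0(path, ".cfg")
      if (!file.exists(sidecar))
        stop("raw volume requires a sidecar config: ", sidecar)
      cfg <- read_sidecar(sidecar)
      read_raw_volume(path, cfg)
    })
  v
}

#' Write a volume to disk
#'
#' Writes NIfTI-1 (by extension `.nii`/`.nii.gz`), Analyze 7.5 (`.hdr`) or
#' raw `float64` + sidecar (any other extension).
#'
#' @param v a [volume()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$voxel_size
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.hdr$", path)) {
    stem <- sub("\\.hdr$", "", path)
    img <- oro.nifti::anlz(v$data, datatype = 16)  # float32
    img@pixdim[2:4] <- v$voxel_size
    oro.nifti::writeANALYZE(img, stem, gzipped = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(v$data), con, size = 8, endian = "little")
    writeLines(c(
      sprintf("dims: %d %d %d", v$dims[1], v$dims[2], v$dims[3]),
      sprintf("voxel_size_mm: %.17g %.17g %.17g",
              v$voxel_size[1], v$voxel_size[2], v$voxel_size[3]),
      "dtype: float64",
      "byte_order: little"), paste0(path, ".cfg"))
  }
  invisible(path)
}

clamp_nonneg <- function(arr) {
  arr <- array(as.numeric(arr), dim = dim(arr))
  if (!all(is.finite(arr))) stop("volume contains non-finite intensities")
  mn <- min(arr)
  if (mn < 0) arr <- arr - mn
  arr
}

check_voxel_size <- function(vs, path) {
  vs <- as.numeric(vs)
  if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
    stop("missing or invalid voxel sizes in header of ", path)
  vs
}

read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) < 2L
  if (any(bad)) stop("malformed sidecar line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  cfg <- as.list(vals)
  names(cfg) <- keys
  for (k in c("dims", "voxel_size_mm", "dtype", "byte_order"))
    if (is.null(cfg[[k]])) stop("sidecar is missing key '", k, "'")
  cfg
}

read_raw_volume <- function(path, cfg) {
  dims <- as.integer(strsplit(cfg$dims, "[ ,]+")[[1]])
  vs <- as.numeric(strsplit(cfg$voxel_size_mm, "[ ,]+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("sidecar 'dims' must be three positive integers")
  endian <- switch(cfg$byte_order, little = "little", big = "big",
                   stop("sidecar 'byte_order' must be little or big"))
  n <- prod(dims)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- switch(cfg$dtype,
    uint8   = readBin(con, "integer", n, size = 1, signed = FALSE,
                      endian = endian),
    int16   = readBin(con, "integer", n, size = 2, signed = TRUE,
                      endian = endian),
    int32   = readBin(con, "integer", n, size = 4, endian = endian),
    float32 = readBin(con, "numeric", n, size = 4, endian = endian),
    float64 = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported sidecar dtype: ", cfg$dtype))
  if (length(raw) != n)
    stop("raw file holds ", length(raw), " values, expected ", n)
  volume(clamp_nonneg(array(as.numeric(raw), dim = dims)),
         check_voxel_size(vs, path))
}

#' Intensity-weighted centre of gravity
#'
#' The centre of gravity of a volume in fractional 0-based voxel indices:
#' the intensity-weighted mean index per axis. It serves as the origin of
#' the volume's world frame, which coarsely pre-aligns two volumes before
#' registration. An all-zero volume falls back to the geometric centre
#' `(n - 1) / 2` per axis.
#'
#' @param v a [volume()].
#' @return numeric length-3 vector of fractional voxel indices.
#' @export
center_of_gravity <- function(v) {
  stopifnot(inherits(v, "volume"))
  total <- sum(v$data)
  if (total <= 0) return((v$dims - 1) / 2)
  vapply(1:3, function(a) {
    m <- apply(v$data, a, sum)
    sum((seq_along(m) - 1) * m) / total
  }, numeric(1))
}

#' Map voxel indices to world coordinates
#'
#' World coordinates are millimetres in a frame whose origin is the volume's
#' centre of gravity: `world = (index - cog) * voxel_size` componentwise,
#' with 0-based fractional voxel indices. The map is affine, so indices
#' outside the grid are allowed.
#'
#' @param v a [volume()].
#' @param index numeric length-3 vector or an `n x 3` matrix of fractional
#'   0-based voxel indices.
#' @param cog optional precomputed [center_of_gravity()] (to avoid
#'   recomputation in inner loops).
#' @return world coordinates with the same shape as `index`.
#' @export
world_from_voxel <- function(v, index, cog = center_of_gravity(v)) {
  if (is.matrix(index))
    sweep(sweep(index, 2, cog), 2, v$voxel_size, `*`)
  else
    (as.numeric(index) - cog) * v$voxel_size
}

#' @rdname world_from_voxel
#' @param world world coordinates (mm), vector or `n x 3` matrix.
#' @export
voxel_from_world <- function(v, world, cog = center_of_gravity(v)) {
  if (is.matrix(world))
    sweep(sweep(world, 2, v$voxel_size, `/`), 2, cog, `+`)
  else
    as.numeric(world) / v$voxel_size + cog
}

#' Subsample a volume by integer strides
#'
#' Keeps every `k`-th voxel per axis starting at index 0 and multiplies the
#' voxel sizes by the factors, so world extents are preserved up to the
#' discarded border. Used to speed up histogram sampling on large volumes.
#'
#' @param v a [volume()].
#' @param factors integer length-3 vector of strides, all `>= 1`. A factor
#'   larger than an axis yields a single-slice axis.
#' @return A subsampled [volume()] with dims `ceiling(n / k)`.
#' @export
subsample <- function(v, factors) {
  stopifnot(inherits(v, "volume"))
  factors <- as.integer(factors)
  if (length(factors) != 3L || any(is.na(factors)) || any(factors < 1L))
    stop("'factors' must be three integers >= 1")
  idx <- lapply(1:3, function(a) seq(1L, v$dims[a], by = factors[a]))
  volume(v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
         v$voxel_size * factors)
}
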