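# Core containers: voxel grids with physical spacing. Axis order is fixed
# (z, y, x), 0-based coordinates in reported centroids; voxel centers sit at
# (i - 0.5) * d along each axis.

#' Voxel spacing in micrometres
#'
#' Physical size of one voxel along each axis, in µm. Holotomography vendors
#' store pixel size in mutually incompatible TIFF tag dialects, so spacing is
#' always supplied explicitly (or through the YAML sidecar written by
#' [write_volume()]).
#'
#' @param dz,dy,dx Voxel edge length along z, y, x in µm; strictly positive.
#' @return An object of class `voxel_spacing`.
#' @examples
#' sp <- voxel_spacing(0.5, 0.2, 0.2)
#' voxel_volume(sp) # 0.02 µm^3
#' @export
voxel_spacing <- function(dz, dy, dx) {
  v <- c(dz = as.numeric(dz), dy = as.numeric(dy), dx = as.numeric(dx))
  if (any(!is.finite(v)) || any(v <= 0))
    stop("voxel spacing must be finite and strictly positive", call. = FALSE)
  structure(as.list(v), class = "voxel_spacing")
}

#' Volume of one voxel in cubic micrometres
#' @param spacing A [voxel_spacing()].
#' @return Scalar µm^3.
#' @export
voxel_volume <- function(spacing) {
  stopifnot(inherits(spacing, "voxel_spacing"))
  spacing$dz * spacing$dy * spacing$dx
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("<voxel_spacing> dz=%g dy=%g dx=%g um (voxel %.4g um^3)\n",
              x$dz, x$dy, x$dx, voxel_volume(x)))
  invisible(x)
}

check_grid3d <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array (z, y, x)", call. = FALSE)
  if (!is.numeric(values))
    stop("values must be numeric", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must all be finite", call. = FALSE)
  invisible(values)
}

#' Refractive-index tomogram
#'
#' A 3D grid of dimensionless refractive-index values, one per voxel, with
#' physical voxel spacing. RI values are gated to the physically plausible
#' range \[1.0, 2.0\] (water is 1.333; dense intracellular material stays well
#' below 2).
#'
#' @param values 3D numeric array, dim `(nz, ny, nx)`.
#' @param spacing A [voxel_spacing()].
#' @return An object of class `ri_tomogram`.
#' @export
ri_tomogram <- function(values, spacing) {
  check_grid3d(values)
  stopifnot(inherits(spacing, "voxel_spacing"))
  if (any(values < 1.0) || any(values > 2.0))
    stop("RI values outside plausible range [1, 2]", call. = FALSE)
  structure(list(values = values, spacing = spacing),
            class = c("ri_tomogram", "hq_volume"))
}

#' Co-registered fluorescence volume
#'
#' Intensity grid (arbitrary units, >= 0) on the same voxel grid as its paired
#' RI tomogram. Channels are assumed co-registered as acquired.
#'
#' @param values 3D numeric array of nonnegative intensities.
#' @param spacing A [voxel_spacing()].
#' @return An object of class `fluorescence_volume`.
#' @export
fluorescence_volume <- function(values, spacing) {
  check_grid3d(values)
  stopifnot(inherits(spacing, "voxel_spacing"))
  if (any(values < 0))
    stop("fluorescence intensities must be >= 0", call. = FALSE)
  structure(list(values = values, spacing = spacing),
            class = c("fluorescence_volume", "hq_volume"))
}

#' Instance label volume
#'
#' Integer labels on a voxel grid; 0 is background, instances are 1..K with a
#' contiguous label set.
#'
#' @param labels 3D integer array.
#' @param spacing A [voxel_spacing()], carried for volume conversions.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be nonnegative integers", call. = FALSE)
  k <- max(labels)
  if (k > 0L) {
    present <- sort(unique(labels[labels > 0L]))
    if (!identical(present, seq_len(k)))
      stop("label set must be contiguous 1..K", call. = FALSE)
  }
  structure(list(labels = labels, spacing = spacing),
            class = "label_volume")
}

#' @export
print.ri_tomogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ri_tomogram> %d x %d x %d (z,y,x), RI %.4f..%.4f\n",
              d[1], d[2], d[3], min(x$values), max(x$values)))
  print(x$spacing)
  invisible(x)
}

#' @export
print.fluorescence_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<fluorescence_volume> %d x %d x %d (z,y,x), I %.3g..%.3g\n",
              d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), %d instance(s)\n",
              d[1], d[2], d[3], max(x$labels)))
  invisible(x)
}

#' @export
dim.ri_tomogram <- function(x) dim(x$values)
#' @export
dim.fluorescence_volume <- function(x) dim(x$values)
#' @export
dim.label_volume <- function(x) dim(x$labels)

# internal: checked extraction of a logical mask array matching a volume
as_mask_array <- function(mask, dims = NULL) {
  m <- if (inherits(mask, "label_volume")) mask$labels > 0L else mask
  if (!is.array(m) || length(dim(m)) != 3L)
    stop("mask must be a 3D array or label_volume", call. = FALSE)
  m <- m != 0
  if (!is.null(dims) && !identical(dim(m), as.integer(dims)))
    stop("mask shape does not match volume", call. = FALSE)
  m
}
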