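#' 3D CT-number volume with physical geometry
#'
#' A `volume3d` holds a 3D array of CT numbers (Hounsfield units) together
#' with its voxel spacing and origin. The physical position of voxel
#' `(i, j, k)` (0-based) is `origin + c(i, j, k) * spacing`; axes are ordered
#' (x, y, z) with z the superior/inferior direction.
#'
#' @param values 3D numeric array of CT numbers (HU); must be finite.
#' @param spacing numeric(3), per-axis voxel size in mm; all > 0.
#' @param origin numeric(3), physical coordinate (mm) of the centre of voxel
#'   (0, 0, 0).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (any(dim(values) < 2L))
    stop("each volume dimension must have at least 2 voxels")
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("volume contains non-finite CT numbers")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels @ %s mm, origin (%s) mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              paste(format(x$origin, trim = TRUE), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$values)

#' Test whether two volumes (or masks) share the same sampling grid
#'
#' Grids are compatible iff shapes match and spacings and origins agree
#' within `tol` mm on every axis.
#'
#' @param a,b `volume3d` or `mask3d` objects.
#' @param tol agreement tolerance in mm.
#' @return logical(1).
#' @export
grid_compatible <- function(a, b, tol = 1e-6) {
  ga <- grid_of(a); gb <- grid_of(b)
  identical(ga$dim, gb$dim) &&
    all(abs(ga$spacing - gb$spacing) <= tol) &&
    all(abs(ga$origin - gb$origin) <= tol)
}

grid_of <- function(x) {
  if (inherits(x, "volume3d"))
    list(dim = dim(x$values), spacing = x$spacing, origin = x$origin)
  else if (inherits(x, "mask3d"))
    list(dim = dim(x$values), spacing = x$spacing, origin = x$origin)
  else stop("not a volume3d or mask3d")
}

stop_if_incompatible <- function(a, b, what = "volumes") {
  if (!grid_compatible(a, b))
    stop(sprintf("%s are not grid-compatible (shape/spacing/origin mismatch)",
                 what))
  invisible(TRUE)
}

#' Read a CT-number volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file; voxel spacing and origin are recovered
#' from the stored transform (column norms and translation of the affine).
#' Values must already be in Hounsfield units. DICOM series are not
#' supported; convert to NIfTI upstream.
#'
#' @param path path to a NIfTI file.
#' @return A [volume3d].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume: ", path)
  arr <- array(as.numeric(arr), dim(arr)) # drop RNifti image attributes
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  origin <- aff[1:3, 4]
  volume3d(arr, spacing = spacing, origin = origin)
}

#' Write a CT-number volume to NIfTI
#'
#' Stores values as float64 so that a write/read round trip is bit-exact;
#' spacing and origin are recorded in the qform (code 2).
#'
#' @param vol a [volume3d].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto another volume's grid
#'
#' Trilinear interpolation of `vol` at the voxel centres of the target grid.
#' Target voxels outside the source physical extent are filled with
#' `fill` (default -1000 HU, air). Used to bring an evaluated CBCT onto the
#' reference grid when the two are not already grid-compatible.
#'
#' @param vol source [volume3d].
#' @param target [volume3d] (or `mask3d`) whose grid defines the output.
#' @param fill HU value for out-of-extent voxels.
#' @return A [volume3d] on the target grid.
#' @export
resample_to_grid <- function(vol, target, fill = -1000) {
  stopifnot(inherits(vol, "volume3d"))
  tg <- grid_of(target)
  if (grid_compatible(vol, target)) {
    return(volume3d(vol$values, tg$spacing, tg$origin))
  }
  # require overlap of physical extents
  s_lo <- vol$origin; s_hi <- vol$origin + (dim(vol$values) - 1L) * vol$spacing
  t_lo <- tg$origin;  t_hi <- tg$origin + (tg$dim - 1L) * tg$spacing
  if (any(pmin(s_hi, t_hi) < pmax(s_lo, t_lo)))
    stop("source and target grids have no overlapping physical extent")
  vals <- resample_trilinear_cpp(as.numeric(vol$values), dim(vol$values),
                                 vol$spacing, vol$origin,
                                 as.integer(tg$dim), tg$spacing, tg$origin,
                                 fill)
  volume3d(array(vals, tg$dim), tg$spacing, tg$origin)
}
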