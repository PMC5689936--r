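#' Boolean structure mask on a volume grid
#'
#' @param values 3D logical array.
#' @param spacing numeric(3) voxel size (mm).
#' @param origin numeric(3) position of voxel (0,0,0) centre (mm).
#' @param provenance free-form record of how the mask was built (source
#'   structure, margin, axial limits).
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(values, spacing, origin = c(0, 0, 0), provenance = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask contains NA")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), provenance = provenance),
            class = "mask3d")
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("<mask3d> %s voxels, %d true (%.1f%%)%s\n",
              paste(dim(x$values), collapse = "x"), sum(x$values),
              100 * mean(x$values),
              if (is.null(x$provenance)) "" else paste0(" [", x$provenance, "]")))
  invisible(x)
}

#' @export
dim.mask3d <- function(x) dim(x$values)

#' Read a structure mask from a NIfTI label volume
#'
#' The mask is true exactly where the stored label equals `label`.
#'
#' @param path NIfTI label volume.
#' @param label label value selecting the structure (default 1).
#' @return A [mask3d] on the label volume's grid.
#' @export
read_structure_mask <- function(path, label = 1) {
  vol <- read_volume(path)
  m <- vol$values == label
  if (!any(m))
    stop(sprintf("no voxels carry label %s in %s", format(label), path))
  mask3d(m, vol$spacing, vol$origin,
         provenance = sprintf("label %s from %s", format(label), basename(path)))
}

#' Write a mask as a NIfTI label volume (0/1)
#'
#' @param mask a [mask3d].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask3d"))
  vol <- volume3d(array(as.numeric(mask$values), dim(mask$values)),
                  mask$spacing, mask$origin)
  write_volume(vol, path)
}

# Even-odd (ray crossing) point-in-polygon test for one closed planar
# contour; points on an edge are resolved by the half-open crossing rule.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize planar contours onto a volume grid
#'
#' Each contour is an n x 3 matrix of (x, y, z) vertices (mm) of a closed
#' planar loop; vertices are assigned to the nearest axial slice by z, and
#' each slice is filled with the even-odd rule over all loops on that slice
#' (so holes and multiple islands are supported). No inter-slice
#' interpolation is performed. This is the geometry underlying an RT
#' structure set; the contour points themselves must be extracted upstream.
#'
#' @param contours list of numeric matrices, each n x 3 (x, y, z in mm).
#' @param grid a [volume3d] or [mask3d] providing the target grid.
#' @return A [mask3d].
#' @export
rasterize_contours <- function(contours, grid) {
  g <- grid_of(grid)
  out <- array(FALSE, g$dim)
  zs <- g$origin[3] + (seq_len(g$dim[3]) - 1) * g$spacing[3]
  xc <- g$origin[1] + (seq_len(g$dim[1]) - 1) * g$spacing[1]
  yc <- g$origin[2] + (seq_len(g$dim[2]) - 1) * g$spacing[2]
  pts <- expand.grid(x = xc, y = yc)
  for (cm in contours) {
    cm <- as.matrix(cm)
    if (ncol(cm) != 3L || nrow(cm) < 3L)
      stop("each contour must be an n x 3 matrix with n >= 3")
    zmean <- mean(cm[, 3])
    k <- which.min(abs(zs - zmean))
    if (abs(zs[k] - zmean) > g$spacing[3] / 2 + 1e-9)
      stop(sprintf("contour at z = %.2f mm lies outside the grid", zmean))
    inside <- point_in_polygon(pts$x, pts$y, cm[, 1], cm[, 2])
    out[, , k] <- xor(out[, , k], array(inside, g$dim[1:2]))
  }
  mask3d(out, g$spacing, g$origin, provenance = "rasterized contours")
}

#' Build a named structure's mask from a contour set
#'
#' @param contour_set named list; each element a list of contour matrices as
#'   in [rasterize_contours].
#' @param name structure name to rasterize.
#' @param grid target grid ([volume3d] or [mask3d]).
#' @return A [mask3d].
#' @export
structure_mask_from_contours <- function(contour_set, name, grid) {
  if (!name %in% names(contour_set))
    stop(sprintf("structure '%s' not found; available: %s", name,
                 paste(names(contour_set), collapse = ", ")))
  m <- rasterize_contours(contour_set[[name]], grid)
  m$provenance <- sprintf("structure '%s' (rasterized)", name)
  m
}

#' Dilate a mask by a physical margin
#'
#' Expands the true set by Euclidean distance <= `margin` mm in physical
#' space, aware of anisotropic voxel spacing; expansion is clipped at the
#' array bounds.
#'
#' @param mask a [mask3d].
#' @param margin margin in mm, >= 0.
#' @return A [mask3d].
#' @export
dilate_mask <- function(mask, margin) {
  stopifnot(inherits(mask, "mask3d"))
  if (!is.finite(margin) || margin < 0) stop("'margin' must be >= 0")
  if (margin == 0) return(mask)
  vals <- dilate_mask_cpp(mask$values, dim(mask$values), mask$spacing, margin)
  mask3d(array(vals, dim(mask$values)), mask$spacing, mask$origin,
         provenance = sprintf("%s + %g mm", mask$provenance %||% "mask", margin))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the gamma analysis mask
#'
#' The analysis region is the external (body) contour dilated by `margin`
#' mm, limited in the superior/inferior (z) direction to the inclusive slice
#' range spanned by the high-dose CTV. Restricting to the body plus margin
#' keeps image artifacts outside the patient from contributing failed
#' pixels; the CTV limit confines the comparison to the clinically critical
#' region.
#'
#' @param external body-outline [mask3d].
#' @param ctv high-dose clinical target volume [mask3d]; must be non-empty.
#' @param margin dilation margin in mm (default 10).
#' @return A [mask3d].
#' @export
build_analysis_mask <- function(external, ctv, margin = 10) {
  stop_if_incompatible(external, ctv, "external and CTV masks")
  if (!any(ctv$values)) stop("CTV mask is empty: axial limits undefined")
  dil <- dilate_mask(external, margin)
  kz <- which(apply(ctv$values, 3, any))
  out <- dil$values
  keep <- seq(min(kz), max(kz))
  drop <- setdiff(seq_len(dim(out)[3]), keep)
  if (length(drop)) out[, , drop] <- FALSE
  if (!any(out)) stop("analysis mask is empty")
  mask3d(out, external$spacing, external$origin,
         provenance = sprintf("external + %g mm, z-slices %d..%d (CTV extent)",
                              margin, min(kz), max(kz)))
}
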