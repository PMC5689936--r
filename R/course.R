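#' One plan segment of a treatment course
#'
#' A segment is the stretch of a course treated under one plan: the first
#' CBCT after the plan starts is the segment's reference scan, and a replan
#' starts a new segment (with a fresh reference). `volumes` may hold
#' in-memory [volume3d] objects or NIfTI file paths (loaded lazily).
#'
#' @param segment_id integer segment identifier.
#' @param fractions integer vector of treatment fraction numbers at which a
#'   CBCT was acquired; strictly increasing.
#' @param volumes list of [volume3d] objects or character paths, one per
#'   fraction.
#' @param rect_order_fraction fraction number at which a repeat CT was
#'   actually ordered for this segment, or `NA` if none.
#' @return An object of class `course_segment`.
#' @export
course_segment <- function(segment_id, fractions, volumes,
                           rect_order_fraction = NA) {
  fractions <- as.integer(fractions)
  if (length(fractions) < 1L || any(fractions < 1L))
    stop("'fractions' must be positive integers")
  if (is.unsorted(fractions, strictly = TRUE))
    stop("'fractions' must be strictly increasing")
  if (!is.list(volumes)) volumes <- as.list(volumes)
  if (length(volumes) != length(fractions))
    stop("one volume (or path) per fraction required")
  if (!is.na(rect_order_fraction) && rect_order_fraction < 1)
    stop("'rect_order_fraction' must be a positive fraction number")
  structure(list(segment_id = as.integer(segment_id), fractions = fractions,
                 volumes = volumes,
                 rect_order_fraction = as.integer(rect_order_fraction)),
            class = "course_segment")
}

#' A CBCT treatment course
#'
#' @param patient_id opaque patient identifier.
#' @param segments list of [course_segment]s; segment ids must be
#'   non-decreasing and fraction numbers strictly increasing across the
#'   whole course.
#' @param external body-outline [mask3d] from the planning structure set.
#' @param ctv high-dose CTV [mask3d].
#' @return An object of class `ct_course`.
#' @export
ct_course <- function(patient_id, segments, external = NULL, ctv = NULL) {
  if (!is.list(segments) || !length(segments) ||
      !all(vapply(segments, inherits, TRUE, "course_segment")))
    stop("'segments' must be a non-empty list of course_segment objects")
  ids <- vapply(segments, function(s) s$segment_id, 1L)
  if (is.unsorted(ids)) stop("segment ids must be non-decreasing")
  allfr <- unlist(lapply(segments, function(s) s$fractions))
  if (is.unsorted(allfr, strictly = TRUE))
    stop("fraction numbers must be strictly increasing across the course")
  structure(list(patient_id = as.character(patient_id), segments = segments,
                 external = external, ctv = ctv),
            class = "ct_course")
}

#' @export
print.ct_course <- function(x, ...) {
  cat(sprintf("<ct_course> patient %s: %d segment(s), %d CBCTs\n",
              x$patient_id, length(x$segments),
              sum(vapply(x$segments, function(s) length(s$fractions), 1L))))
  for (s in x$segments)
    cat(sprintf("  segment %d: fractions %s%s\n", s$segment_id,
                paste(s$fractions, collapse = ","),
                if (is.na(s$rect_order_fraction)) ""
                else sprintf(" (re-CT ordered at fraction %d)",
                             s$rect_order_fraction)))
  invisible(x)
}

# Load a segment volume (path or in-memory) and bring it onto the grid of
# `grid_ref` if needed.
segment_volume <- function(seg, i, grid_ref = NULL) {
  v <- seg$volumes[[i]]
  if (is.character(v)) v <- read_volume(v)
  if (!inherits(v, "volume3d")) stop("segment volume is neither a path nor a volume3d")
  if (!is.null(grid_ref) && !grid_compatible(v, grid_ref))
    v <- resample_to_grid(v, grid_ref)
  v
}

#' Write a course manifest (JSON) referencing on-disk volumes and masks
#'
#' All segment volumes must already be file paths (see
#' [generate_course] with `out_dir`, or [write_volume]).
#'
#' @param course a [ct_course] with path-backed volumes.
#' @param path output JSON path.
#' @param external_path,ctv_path paths of the NIfTI mask files.
#' @return `path`, invisibly.
#' @export
write_course_manifest <- function(course, path, external_path, ctv_path) {
  entries <- do.call(rbind, lapply(course$segments, function(s) {
    if (!all(vapply(s$volumes, is.character, TRUE)))
      stop("manifest requires path-backed volumes; write them to disk first")
    data.frame(fraction = s$fractions, path = unlist(s$volumes),
               segment = s$segment_id)
  }))
  orders <- data.frame(
    segment = vapply(course$segments, function(s) s$segment_id, 1L),
    rect_order_fraction = vapply(course$segments,
                                 function(s) s$rect_order_fraction, 1L))
  jsonlite::write_json(
    list(patient_id = course$patient_id, entries = entries,
         rect_orders = orders,
         masks = list(external = external_path, ctv = ctv_path)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a course manifest written by [write_course_manifest]
#'
#' Volume paths stay lazy (loaded when first needed); masks are read
#' immediately. Relative paths are resolved against the manifest directory.
#'
#' @param path manifest JSON path.
#' @return A [ct_course].
#' @export
read_course_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  ent <- m$entries
  orders <- m$rect_orders
  order_of <- function(id) {
    hit <- which(as.integer(orders$segment) == id)
    if (!length(hit)) return(NA_integer_)
    val <- orders$rect_order_fraction[hit[1]]
    if (is.null(val) || is.na(val)) NA_integer_ else as.integer(val)
  }
  segs <- lapply(sort(unique(as.integer(ent$segment))), function(id) {
    e <- ent[ent$segment == id, , drop = FALSE]
    course_segment(id, e$fraction, as.list(resolve(e$path)),
                   rect_order_fraction = order_of(id))
  })
  ext <- if (!is.null(m$masks$external)) read_structure_mask(resolve(m$masks$external))
  ctv <- if (!is.null(m$masks$ctv)) read_structure_mask(resolve(m$masks$ctv))
  ct_course(m$patient_id, segs, external = ext, ctv = ctv)
}
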