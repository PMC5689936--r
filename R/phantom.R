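#' Head-and-neck phantom geometry specification
#'
#' A simplified neck cross-section extruded along z: an elliptical
#' soft-tissue cylinder (the body/external contour) containing a bony spine
#' cylinder with a low-density canal, and an air-filled airway; background
#' is air. A cylindrical CTV spanning a configurable axial slice range
#' stands in for the high-dose target.
#'
#' @param dim grid size in voxels (x, y, z), default 96 x 96 x 48.
#' @param spacing voxel size in mm, default 2 x 2 x 3.
#' @param neck_semi_axes ellipse semi-axes (x, y) of the soft-tissue
#'   outline in mm.
#' @param soft_tissue_hu soft tissue CT number (HU).
#' @param spine_center,spine_radius,bone_hu spine cylinder (mm / mm / HU).
#' @param canal_radius,canal_hu spinal canal within the spine (mm / HU).
#' @param airway_center,airway_radius airway cylinder (mm / mm); air HU.
#' @param ctv_center,ctv_radius CTV cylinder in-plane geometry (mm).
#' @param ctv_slices inclusive 1-based z-slice range of the CTV.
#' @param edge_mm 10--90% width (mm) of the smooth tissue-interface profile,
#'   emulating the finite spatial resolution of CBCT; 0 gives binary edges.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96, 96, 48), spacing = c(2, 2, 3),
                         neck_semi_axes = c(70, 55), soft_tissue_hu = 40,
                         spine_center = c(0, -25), spine_radius = 12,
                         bone_hu = 800, canal_radius = 4, canal_hu = 0,
                         airway_center = c(0, 20), airway_radius = 8,
                         ctv_center = c(15, 0), ctv_radius = 20,
                         ctv_slices = c(13, 36), edge_mm = 3) {
  dim <- as.integer(dim); spacing <- as.numeric(spacing)
  stopifnot(length(dim) == 3, all(dim >= 8), length(spacing) == 3,
            all(spacing > 0))
  half <- (dim[1:2] - 1) / 2 * spacing[1:2]
  if (neck_semi_axes[1] > half[1] || neck_semi_axes[2] > half[2])
    stop("neck ellipse does not fit inside the grid")
  hu <- c(soft_tissue_hu, bone_hu, canal_hu)
  if (any(hu < -1024 | hu > 3071)) stop("HU values must lie in [-1024, 3071]")
  if (ctv_slices[1] < 1 || ctv_slices[2] > dim[3] ||
      ctv_slices[1] > ctv_slices[2])
    stop("'ctv_slices' must be an increasing range within the grid")
  if (edge_mm < 0) stop("'edge_mm' must be >= 0")
  structure(list(dim = dim, spacing = spacing, edge_mm = edge_mm,
                 neck_semi_axes = as.numeric(neck_semi_axes),
                 soft_tissue_hu = soft_tissue_hu,
                 spine_center = as.numeric(spine_center),
                 spine_radius = spine_radius, bone_hu = bone_hu,
                 canal_radius = canal_radius, canal_hu = canal_hu,
                 airway_center = as.numeric(airway_center),
                 airway_radius = airway_radius,
                 ctv_center = as.numeric(ctv_center), ctv_radius = ctv_radius,
                 ctv_slices = as.integer(ctv_slices)),
            class = "phantom_spec")
}

phantom_origin <- function(spec) -(spec$dim - 1) / 2 * spec$spacing

#' Generate the phantom anatomy
#'
#' Builds the noise-free baseline volume and its structure masks at a given
#' lateral erosion depth. Erosion models soft-tissue (weight) loss: the
#' lateral semi-axis of the body ellipse is reduced by `erosion` mm on each
#' side, and voxels no longer inside the body revert to air (-1000 HU).
#' Tissue interfaces follow a logistic profile of the signed distance to
#' each boundary with 10--90% width `spec$edge_mm`, emulating the finite
#' spatial resolution of a reconstructed CBCT (binary steps at the voxel
#' scale would be unrealistically sharp). The structure masks themselves
#' are binary (profile midpoint).
#'
#' @param spec a [phantom_spec].
#' @param erosion lateral erosion depth in mm (>= 0).
#' @return A list with elements `volume` ([volume3d]), `external`
#'   ([mask3d], soft-tissue outline) and `ctv` ([mask3d]).
#' @export
generate_anatomy <- function(spec, erosion = 0) {
  stopifnot(inherits(spec, "phantom_spec"), is.finite(erosion), erosion >= 0)
  a <- spec$neck_semi_axes[1] - erosion
  b <- spec$neck_semi_axes[2]
  # the eroded body must still contain the inner structures with clearance
  inner_x <- max(abs(spec$spine_center[1]) + spec$spine_radius,
                 abs(spec$airway_center[1]) + spec$airway_radius)
  if (a <= inner_x + 2)
    stop(sprintf("erosion depth %g mm reaches the internal structures", erosion))
  org <- phantom_origin(spec)
  xs <- org[1] + (seq_len(spec$dim[1]) - 1) * spec$spacing[1]
  ys <- org[2] + (seq_len(spec$dim[2]) - 1) * spec$spacing[2]
  X <- matrix(xs, spec$dim[1], spec$dim[2])
  Y <- matrix(ys, spec$dim[1], spec$dim[2], byrow = TRUE)
  # logistic edge on the signed distance (mm, positive inside); the 10-90%
  # width of plogis(k d) is (2 log 9)/k
  blend <- function(hu, d, hu_in) {
    if (spec$edge_mm == 0) {
      alpha <- as.numeric(d >= 0)
    } else {
      alpha <- stats::plogis(2 * log(9) * d / spec$edge_mm)
    }
    hu * (1 - alpha) + hu_in * alpha
  }
  f <- sqrt((X / a)^2 + (Y / b)^2)
  gradf <- sqrt((X / a^2)^2 + (Y / b^2)^2) / pmax(f, 1e-9)
  d_ext <- (1 - f) / gradf          # approximate signed distance to ellipse
  rdist <- function(c0) sqrt((X - c0[1])^2 + (Y - c0[2])^2)
  hu2d <- blend(matrix(-1000, spec$dim[1], spec$dim[2]), d_ext,
                spec$soft_tissue_hu)
  hu2d <- blend(hu2d, spec$spine_radius - rdist(spec$spine_center),
                spec$bone_hu)
  hu2d <- blend(hu2d, spec$canal_radius - rdist(spec$spine_center),
                spec$canal_hu)
  hu2d <- blend(hu2d, spec$airway_radius - rdist(spec$airway_center), -1000)
  ext2d <- f <= 1
  disc <- function(c0, r) (X - c0[1])^2 + (Y - c0[2])^2 <= r^2
  vol <- array(hu2d, spec$dim)
  extm <- array(ext2d, spec$dim)
  ctv2d <- disc(spec$ctv_center, spec$ctv_radius)
  ctvm <- array(FALSE, spec$dim)
  ctvm[, , spec$ctv_slices[1]:spec$ctv_slices[2]] <-
    array(ctv2d, c(spec$dim[1:2], diff(spec$ctv_slices) + 1L))
  list(volume = volume3d(vol, spec$spacing, org),
       external = mask3d(extm, spec$spacing, org, provenance = "phantom external"),
       ctv = mask3d(ctvm, spec$spacing, org, provenance = "phantom CTV"))
}

#' Progressive soft-tissue loss at a given fraction
#'
#' Before `onset` the baseline anatomy is returned unchanged; from `onset`
#' on, the lateral surface is eroded inward by
#' `depth = rate * (fraction - onset)` mm (monotone non-decreasing in
#' fraction), with eroded voxels set to -1000 HU.
#'
#' @param spec a [phantom_spec] describing the baseline.
#' @param fraction treatment fraction number (>= 1).
#' @param onset fraction at which change begins (`NA` = stable patient).
#' @param rate erosion rate in mm per fraction (>= 0).
#' @return A [volume3d].
#' @export
apply_weight_loss <- function(spec, fraction, onset = NA, rate = 0) {
  stopifnot(fraction >= 1, rate >= 0)
  d <- erosion_depth(fraction, onset, rate)
  generate_anatomy(spec, erosion = d)$volume
}

erosion_depth <- function(fraction, onset, rate) {
  if (is.na(onset) || rate == 0) return(0)
  max(0, rate * (fraction - onset))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Degrade a volume with CBCT-like acquisition effects
#'
#' Applies, in order: a small random rigid translation (setup jitter,
#' per-axis normal with s.d. `jitter_sigma` mm, trilinear resampling, air
#' fill), a concentric ring pattern in the axial plane, radial streaks, and
#' zero-mean Gaussian HU noise. Ring artifacts are predominantly a
#' fixed-pattern property of the detector, so the ring phase can be pinned
#' per course via `ring_phase` (as [generate_course] does) while the
#' effective amplitude is modulated per scan (drawn in
#' `[0.85, 1] * ring_amplitude`, emulating scatter-dependent contrast).
#' Streak phase is drawn per scan (streaks vary with patient and motion).
#' Output is clamped to [-1024, 3071] and fully reproducible from `seed`.
#' With all effect sizes zero the volume is returned unchanged.
#'
#' @param vol a [volume3d].
#' @param noise_sigma Gaussian noise s.d. (HU, >= 0).
#' @param jitter_sigma setup translation s.d. per axis (mm, >= 0). The
#'   default is 0: course scans are assumed co-registered upstream, as in
#'   the clinical workflow.
#' @param ring_amplitude ring artifact amplitude (HU, 0..100).
#' @param ring_period radial period of the ring pattern (mm).
#' @param ring_phase fixed ring phase in radians, or `NULL` to draw it from
#'   `seed` (decorrelated rings between scans).
#' @param streak_amplitude streak artifact amplitude (HU, >= 0).
#' @param n_streaks number of streak spokes (integer >= 0).
#' @param seed integer RNG seed.
#' @return A [volume3d] on the same grid.
#' @export
degrade <- function(vol, noise_sigma = 20, jitter_sigma = 0,
                    ring_amplitude = 0, ring_period = 30, ring_phase = NULL,
                    streak_amplitude = 0, n_streaks = 0, seed = 1) {
  stopifnot(inherits(vol, "volume3d"), noise_sigma >= 0, jitter_sigma >= 0,
            ring_period > 0, streak_amplitude >= 0)
  if (ring_amplitude < 0 || ring_amplitude > 100)
    stop("'ring_amplitude' must be within [0, 100] HU")
  if (noise_sigma == 0 && jitter_sigma == 0 && ring_amplitude == 0 &&
      (streak_amplitude == 0 || n_streaks == 0))
    return(vol)
  dm <- dim(vol$values)
  with_seed(seed, {
    vals <- vol$values
    if (jitter_sigma > 0) {
      shift <- stats::rnorm(3, 0, jitter_sigma)
      # content moves by +shift: sample the source at x - shift
      vals <- resample_trilinear_cpp(as.numeric(vals), dm, vol$spacing,
                                     vol$origin + shift, dm, vol$spacing,
                                     vol$origin, -1000)
      vals <- array(vals, dm)
    }
    if (ring_amplitude > 0 || (streak_amplitude > 0 && n_streaks > 0)) {
      xs <- vol$origin[1] + (seq_len(dm[1]) - 1) * vol$spacing[1]
      ys <- vol$origin[2] + (seq_len(dm[2]) - 1) * vol$spacing[2]
      X <- matrix(xs, dm[1], dm[2])
      Y <- matrix(ys, dm[1], dm[2], byrow = TRUE)
      art2d <- matrix(0, dm[1], dm[2])
      if (ring_amplitude > 0) {
        phase <- if (is.null(ring_phase)) stats::runif(1, 0, 2 * pi)
                 else ring_phase
        amp <- ring_amplitude * stats::runif(1, 0.85, 1)
        art2d <- art2d +
          amp * sin(2 * pi * sqrt(X^2 + Y^2) / ring_period + phase)
      }
      if (streak_amplitude > 0 && n_streaks > 0) {
        sphase <- stats::runif(1, 0, 2 * pi)
        art2d <- art2d +
          streak_amplitude * cos(n_streaks * atan2(Y, X) + sphase)
      }
      vals <- vals + array(art2d, dm)
    }
    if (noise_sigma > 0)
      vals <- vals + array(stats::rnorm(length(vals), 0, noise_sigma), dm)
    vals[vals < -1024] <- -1024
    vals[vals > 3071] <- 3071
    volume3d(vals, vol$spacing, vol$origin)
  })
}

#' Course simulation specification
#'
#' @param n_fractions total treatment fractions (default 35).
#' @param cbct_fractions fractions at which a CBCT is acquired; default
#'   every other fraction starting at 1.
#' @param onset fraction at which anatomical change begins (`NA` = stable).
#' @param rate erosion rate (mm per fraction, >= 0).
#' @param noise_sigma HU noise s.d. (default 20).
#' @param jitter_sigma setup jitter s.d. (mm, default 0: scans assumed
#'   co-registered upstream).
#' @param ring_amplitude,ring_period,streak_amplitude,n_streaks artifact
#'   settings (see [degrade]); artifacts off by default. The ring phase is
#'   drawn once per course (fixed-pattern artifact).
#' @param order_rule_mm erosion depth (mm) at which the simulated clinic
#'   orders a repeat CT (default 10, the external-contour review trigger).
#' @param seed integer RNG seed for the course.
#' @return An object of class `course_spec`.
#' @export
course_spec <- function(n_fractions = 35,
                        cbct_fractions = seq(1, n_fractions, by = 2),
                        onset = NA, rate = 0, noise_sigma = 20,
                        jitter_sigma = 0, ring_amplitude = 0,
                        ring_period = 30, streak_amplitude = 0,
                        n_streaks = 0, order_rule_mm = 10, seed = 1) {
  cbct_fractions <- as.integer(cbct_fractions)
  stopifnot(n_fractions >= 1, length(cbct_fractions) >= 1,
            !is.unsorted(cbct_fractions, strictly = TRUE),
            all(cbct_fractions >= 1), all(cbct_fractions <= n_fractions),
            rate >= 0, noise_sigma >= 0, jitter_sigma >= 0, order_rule_mm > 0)
  if (!is.na(onset) && (onset < 1 || onset > max(cbct_fractions)))
    stop("'onset' must lie within the CBCT-covered fraction range")
  if (ring_amplitude < 0 || ring_amplitude > 100)
    stop("'ring_amplitude' must be within [0, 100] HU")
  structure(list(n_fractions = as.integer(n_fractions),
                 cbct_fractions = cbct_fractions,
                 onset = if (is.na(onset)) NA_integer_ else as.integer(onset),
                 rate = rate, noise_sigma = noise_sigma,
                 jitter_sigma = jitter_sigma,
                 ring_amplitude = ring_amplitude, ring_period = ring_period,
                 streak_amplitude = streak_amplitude,
                 n_streaks = as.integer(n_streaks),
                 order_rule_mm = order_rule_mm, seed = as.integer(seed)),
            class = "course_spec")
}

#' Simulate a CBCT course with ground truth
#'
#' For every CBCT fraction: the baseline anatomy is eroded per
#' [apply_weight_loss], then degraded with noise/jitter/artifacts (one
#' derived sub-seed per scan). The ground truth records the per-fraction
#' erosion depth and the simulated re-CT order fraction: the first CBCT
#' fraction whose cumulative erosion depth reaches `order_rule_mm`
#' (mirroring the 1 cm external-contour review trigger). With `out_dir`
#' set, volumes and masks are written as NIfTI and a JSON manifest and
#' ground-truth file are written alongside; otherwise volumes stay in
#' memory.
#'
#' @param spec a [phantom_spec].
#' @param course a [course_spec].
#' @param patient_id identifier used in the manifest (default "phantom").
#' @param out_dir optional output directory.
#' @return A [ct_course] (single segment) carrying external/CTV masks, with
#'   attribute `"ground_truth"`: a list with `onset`, `depths`
#'   (data.frame fraction/depth), and `order_fraction` (`NA` if the rule
#'   never fires).
#' @export
generate_course <- function(spec, course, patient_id = "phantom",
                            out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(course, "course_spec"))
  anat <- generate_anatomy(spec)
  fr <- course$cbct_fractions
  draws <- with_seed(course$seed, list(
    sub_seeds = sample.int(.Machine$integer.max - 1L, length(fr)),
    ring_phase = stats::runif(1, 0, 2 * pi)))
  sub_seeds <- draws$sub_seeds
  depths <- vapply(fr, erosion_depth, 0, onset = course$onset,
                   rate = course$rate)
  vols <- vector("list", length(fr))
  for (i in seq_along(fr)) {
    v <- if (depths[i] == 0) anat$volume
         else generate_anatomy(spec, erosion = depths[i])$volume
    vols[[i]] <- degrade(v, noise_sigma = course$noise_sigma,
                         jitter_sigma = course$jitter_sigma,
                         ring_amplitude = course$ring_amplitude,
                         ring_period = course$ring_period,
                         ring_phase = draws$ring_phase,
                         streak_amplitude = course$streak_amplitude,
                         n_streaks = course$n_streaks, seed = sub_seeds[i])
  }
  hit <- which(depths >= course$order_rule_mm)
  order_fraction <- if (length(hit)) fr[hit[1]] else NA_integer_
  gt <- list(onset = course$onset,
             depths = data.frame(fraction = fr, depth = depths),
             order_fraction = order_fraction,
             order_rule_mm = course$order_rule_mm, seed = course$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, sprintf("%s_fx%03d.nii.gz", patient_id, fr))
    for (i in seq_along(fr)) write_volume(vols[[i]], paths[i])
    ext_path <- file.path(out_dir, sprintf("%s_external.nii.gz", patient_id))
    ctv_path <- file.path(out_dir, sprintf("%s_ctv.nii.gz", patient_id))
    write_mask(anat$external, ext_path)
    write_mask(anat$ctv, ctv_path)
    vols <- as.list(paths)
    co <- ct_course(patient_id,
                    list(course_segment(1L, fr, vols, order_fraction)),
                    external = anat$external, ctv = anat$ctv)
    write_course_manifest(co, file.path(out_dir,
                                        sprintf("%s_manifest.json", patient_id)),
                          ext_path, ctv_path)
    jsonlite::write_json(gt,
                         file.path(out_dir, sprintf("%s_truth.json", patient_id)),
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    co <- ct_course(patient_id,
                    list(course_segment(1L, fr, vols, order_fraction)),
                    external = anat$external, ctv = anat$ctv)
  }
  attr(co, "ground_truth") <- gt
  co
}

#' Simulate a cohort of courses for ROC exercises
#'
#' Changers receive an onset drawn uniformly from `onset_range` and erode
#' at `rate` mm/fraction; stable patients never change. Per-patient course
#' seeds are drawn reproducibly from `master_seed`.
#'
#' @param n_changers,n_stable patient counts (>= 0).
#' @param spec a [phantom_spec] shared by the cohort.
#' @param onset_range inclusive integer range of change onsets.
#' @param rate erosion rate (mm/fraction).
#' @param noise_sigma,jitter_sigma degradation settings shared by the
#'   cohort.
#' @param n_fractions,cbct_fractions schedule shared by the cohort.
#' @param master_seed integer seed controlling all draws.
#' @param out_dir optional directory for on-disk courses.
#' @return A list with `courses` (list of [ct_course]) and `labels`
#'   (data.frame: `patient_id`, `changer`, `onset`, `order_fraction`).
#' @export
generate_cohort <- function(n_changers, n_stable, spec = phantom_spec(),
                            onset_range = c(10, 20), rate = 2,
                            noise_sigma = 20, jitter_sigma = 0,
                            n_fractions = 35,
                            cbct_fractions = seq(1, n_fractions, by = 2),
                            master_seed = 1, out_dir = NULL) {
  stopifnot(n_changers >= 0, n_stable >= 0, n_changers + n_stable >= 1)
  n <- n_changers + n_stable
  draws <- with_seed(master_seed, list(
    onsets = sample(seq(onset_range[1], onset_range[2]), max(n_changers, 1),
                    replace = TRUE),
    seeds = sample.int(.Machine$integer.max - 1L, n)))
  courses <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    changer <- i <= n_changers
    pid <- sprintf("%s%02d", if (changer) "changer" else "stable", i)
    cs <- course_spec(n_fractions = n_fractions,
                      cbct_fractions = cbct_fractions,
                      onset = if (changer) draws$onsets[i] else NA,
                      rate = if (changer) rate else 0,
                      noise_sigma = noise_sigma, jitter_sigma = jitter_sigma,
                      seed = draws$seeds[i])
    courses[[i]] <- generate_course(spec, cs, patient_id = pid,
                                    out_dir = out_dir)
    gt <- attr(courses[[i]], "ground_truth")
    labels[[i]] <- data.frame(patient_id = pid, changer = changer,
                              onset = if (changer) draws$onsets[i] else NA_integer_,
                              order_fraction = gt$order_fraction)
  }
  list(courses = courses, labels = do.call(rbind, labels))
}
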