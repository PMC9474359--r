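# Synthetic-anatomy cohort generator. Subjects are landmark sets built around
# a canonical skull template whose mandibular-fossa plane is the z = 0 plane;
# per-ear true ET angle/length are drawn first and the pharyngeal orifice is
# placed so that measurement exactly inverts generation when jitter is zero.

#' Canonical skull template
#'
#' Mean landmark coordinates (mm, LPS) used as the scaffold for synthetic
#' subjects. The template is plausibility-only plumbing, not an anthropometric
#' model: EAC upper margins sit +/-60 mm laterally, the mandibular fossae
#' ~8 mm anterior of the EACs, the infraorbital margins ~55 mm anterior. The
#' mandibular-fossa plane of the template is exactly z = 0.
#'
#' @param mfp_tilt_deg systematic tilt between the mandibular-fossa plane and
#'   Reid's plane, in degrees, expressed as the expected mean difference
#'   between the two measured ET angles under the default forward-medial
#'   azimuth distribution. Positive values make the mandibular-fossa-plane
#'   angle larger on average. Implemented by lowering the infraorbital
#'   margins out of the z = 0 plane; the geometric dihedral applied is
#'   `mfp_tilt_deg * pi / 2`, the reciprocal of the mean azimuth cosine
#'   (2 / pi) for azimuth uniform on a quadrant. Default 0 (all four plane
#'   anchors coplanar).
#' @param coords optional k x 3 matrix overriding the default landmark means
#'   (rownames from [landmark_ids()], excluding the orifices, which are
#'   placed per ear).
#' @return list with `coords` (8 x 3 matrix: IOM, MF, EAC, TO, both sides)
#'   and `mfp_tilt_deg`.
#' @export
skull_template <- function(mfp_tilt_deg = 0, coords = NULL) {
  stopifnot(is.finite(mfp_tilt_deg))
  if (is.null(coords)) {
    dihedral <- mfp_tilt_deg * (pi / 2) * pi / 180
    z_iom <- -55 * tan(dihedral)
    coords <- rbind(
      IOM_R = c(-33, -55, z_iom),
      IOM_L = c( 33, -55, z_iom),
      MF_R  = c(-52,  -8, 0),
      MF_L  = c( 52,  -8, 0),
      EAC_R = c(-60,   0, 0),
      EAC_L = c( 60,   0, 0),
      TO_R  = c(-47,  -2, 1),
      TO_L  = c( 47,  -2, 1))
  }
  colnames(coords) <- c("x", "y", "z")
  # template plane triplets must be non-degenerate
  for (tri in plane_types()) {
    have <- intersect(tri, rownames(coords))
    if (length(have) == 3L) {
      plane_from_points(coords[tri[1], ], coords[tri[2], ], coords[tri[3], ],
                        ids = tri)
    }
  }
  list(coords = coords, mfp_tilt_deg = mfp_tilt_deg)
}

#' Define a cohort preset
#'
#' A preset fixes the generating distributions of one cohort: true ET angle
#' (degrees, relative to the template's mandibular-fossa plane) and length
#' (mm) as truncated normals, isotropic Gaussian landmark jitter (mm,
#' emulating rater placement error), and demographics.
#'
#' @param name preset name.
#' @param angle_mean_deg,angle_sd_deg ET angle distribution, degrees;
#'   mean in (0, 90), sd >= 0.
#' @param length_mean_mm,length_sd_mm ET length distribution, mm; mean > 0.
#' @param landmark_jitter_sd_mm per-coordinate landmark jitter sd, mm
#'   (default 0 = noise-free geometry).
#' @param age_mean_yr,age_sd_yr age distribution, years.
#' @param female_fraction probability a subject is female, in \[0, 1\].
#' @param mfp_tilt_deg template tilt forwarded to [skull_template()].
#' @param provenance free-text note on where the numbers come from.
#' @return object of class `cohort_preset`.
#' @export
cohort_preset <- function(name, angle_mean_deg, angle_sd_deg,
                          length_mean_mm, length_sd_mm,
                          landmark_jitter_sd_mm = 0,
                          age_mean_yr = 50, age_sd_yr = 15,
                          female_fraction = 0.5,
                          mfp_tilt_deg = 0, provenance = "") {
  stopifnot(angle_mean_deg > 0, angle_mean_deg < 90, angle_sd_deg >= 0,
            length_mean_mm > 0, length_sd_mm >= 0,
            landmark_jitter_sd_mm >= 0, age_sd_yr >= 0,
            female_fraction >= 0, female_fraction <= 1)
  structure(list(name = name,
                 angle_mean_deg = angle_mean_deg, angle_sd_deg = angle_sd_deg,
                 length_mean_mm = length_mean_mm, length_sd_mm = length_sd_mm,
                 landmark_jitter_sd_mm = landmark_jitter_sd_mm,
                 age_mean_yr = age_mean_yr, age_sd_yr = age_sd_yr,
                 female_fraction = female_fraction,
                 mfp_tilt_deg = mfp_tilt_deg, provenance = provenance),
            class = "cohort_preset")
}

preset_dir <- function() system.file("extdata", "presets", package = "etmorph")

#' List the shipped cohort presets
#'
#' @return character vector of preset names.
#' @export
list_presets <- function() {
  sort(sub("\\.json$", "", list.files(preset_dir(), pattern = "\\.json$")))
}

#' Load a cohort preset by name or path
#'
#' @param preset a `cohort_preset`, the name of a shipped preset
#'   (see [list_presets()]) or a path to a preset JSON file.
#' @return a `cohort_preset`.
#' @export
load_preset <- function(preset) {
  if (inherits(preset, "cohort_preset")) return(preset)
  stopifnot(is.character(preset), length(preset) == 1L)
  path <- if (file.exists(preset)) preset else
    file.path(preset_dir(), paste0(preset, ".json"))
  if (!file.exists(path)) {
    stop(sprintf("unknown preset '%s'; registered presets: %s",
                 preset, paste(list_presets(), collapse = ", ")), call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cohort_preset, cfg)
}

# truncated-normal draw by rejection (<= max_tries), avoiding point masses
# at the bounds; sd = 0 returns the mean (checked against the bounds)
rtrunc_norm <- function(mean, sd, lower = -Inf, upper = Inf, max_tries = 100L,
                        what = "value") {
  if (sd == 0) {
    if (mean <= lower || mean >= upper) {
      stop(sprintf("degenerate %s %.3f outside (%g, %g)", what, mean, lower, upper),
           call. = FALSE)
    }
    return(mean)
  }
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x > lower && x < upper) return(x)
  }
  stop(sprintf("could not draw %s in (%g, %g) after %d tries (mean %.3f, sd %.3f)",
               what, lower, upper, max_tries, mean, sd), call. = FALSE)
}

#' Generate one synthetic subject
#'
#' For each ear a true angle `theta* ~ N(angle_mean, angle_sd)` truncated to
#' (0, 90) and true length `L* ~ N(length_mean, length_sd)` truncated to
#' > 5 mm are drawn; the tympanic orifice sits at the template position and
#' the pharyngeal orifice is placed at distance `L*` so the segment makes
#' angle `theta*` with the template's mandibular-fossa plane, with in-plane
#' azimuth uniform over the forward-medial quadrant. Landmark jitter
#' (i.i.d. Gaussian per coordinate) is added last, so with zero jitter
#' measurement recovers the truth exactly.
#'
#' Uses the current RNG state; seed control lives in [generate_cohort()].
#'
#' @param preset a `cohort_preset` (or name, see [load_preset()]).
#' @param template a [skull_template()]; defaults to the template implied by
#'   the preset's `mfp_tilt_deg`.
#' @param subject_id identifier for the subject.
#' @return object of class `subject_record`: list with `subject_id`,
#'   `age_yr`, `sex` ("F"/"M"), `landmarks` (a `landmark_set`) and `truth`
#'   (data.frame side/angle_deg/length_mm).
#' @export
generate_subject <- function(preset, template = NULL, subject_id = "subj") {
  preset <- load_preset(preset)
  if (is.null(template)) template <- skull_template(preset$mfp_tilt_deg)
  coords <- template$coords
  truth <- data.frame(side = c("right", "left"),
                      angle_deg = NA_real_, length_mm = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in 1:2) {
    side <- truth$side[i]
    theta <- rtrunc_norm(preset$angle_mean_deg, preset$angle_sd_deg,
                         0, 90, what = "ET angle")
    len <- rtrunc_norm(preset$length_mean_mm, preset$length_sd_mm,
                       5, Inf, what = "ET length")
    phi <- stats::runif(1L, 0, pi / 2)  # 0 = anterior, pi/2 = medial
    s_med <- if (side == "right") 1 else -1  # medial direction in LPS x
    th <- theta * pi / 180
    d <- c(s_med * cos(th) * sin(phi), -cos(th) * cos(phi), -sin(th))
    to <- coords[paste0("TO", if (side == "right") "_R" else "_L"), ]
    po <- to + len * d
    coords <- rbind(coords, matrix(po, 1, 3,
      dimnames = list(paste0("PO", if (side == "right") "_R" else "_L"), NULL)))
    truth$angle_deg[i] <- theta
    truth$length_mm[i] <- len
  }
  if (preset$landmark_jitter_sd_mm > 0) {
    coords <- coords + matrix(stats::rnorm(length(coords), 0,
                                           preset$landmark_jitter_sd_mm),
                              nrow(coords), 3)
  }
  age <- rtrunc_norm(preset$age_mean_yr, preset$age_sd_yr, 0, 120, what = "age")
  sex <- if (stats::runif(1L) < preset$female_fraction) "F" else "M"
  structure(list(subject_id = subject_id, age_yr = age, sex = sex,
                 landmarks = landmark_set(subject_id, coords),
                 truth = truth),
            class = "subject_record")
}

derive_subject_seed <- function(seed, i) {
  # deterministic substream seed per subject index; exact in doubles, < 2^31
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 1299709) %% 2147483647)
}

#' Generate a reproducible synthetic cohort
#'
#' Subject `i` is drawn from a substream seeded deterministically by
#' `(seed, i)`, so cohorts are reproducible and subjects are independent of
#' cohort size and order.
#'
#' @param preset preset object, name or path (see [load_preset()]).
#' @param n_subjects number of subjects (>= 1); each contributes two ears.
#' @param seed integer master seed.
#' @param template optional [skull_template()] override.
#' @return object of class `et_cohort`: list with `preset`, `seed`,
#'   `subjects` (list of `subject_record`).
#' @export
generate_cohort <- function(preset, n_subjects, seed, template = NULL) {
  preset <- load_preset(preset)
  stopifnot(n_subjects >= 1)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(derive_subject_seed(seed, i))
    subjects[[i]] <- generate_subject(
      preset, template, subject_id = sprintf("%s_%03d", preset$name, i))
  }
  structure(list(preset = preset, seed = as.integer(seed), subjects = subjects),
            class = "et_cohort")
}

#' @export
print.et_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ET cohort: preset '%s', %d subjects (%d ears), seed %d\n",
              x$preset$name, length(x$subjects), 2L * length(x$subjects), x$seed))
  invisible(x)
}

#' Extract the landmark sets of a cohort
#'
#' @param cohort an `et_cohort`.
#' @return list of `landmark_set`, in subject order.
#' @export
cohort_landmark_sets <- function(cohort) {
  stopifnot(inherits(cohort, "et_cohort"))
  lapply(cohort$subjects, `[[`, "landmarks")
}

#' Ground-truth table of a cohort
#'
#' @param cohort an `et_cohort`.
#' @return data.frame `subject_id`, `side`, `angle_deg`, `length_mm` of the
#'   generated (pre-jitter) truths, one row per ear.
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "et_cohort"))
  out <- do.call(rbind, lapply(cohort$subjects, function(s) {
    cbind(subject_id = s$subject_id, s$truth)
  }))
  rownames(out) <- NULL
  out
}

#' Demographics table of a cohort
#'
#' @param cohort an `et_cohort`.
#' @return data.frame `subject_id`, `age_yr`, `sex`.
#' @export
cohort_demographics <- function(cohort) {
  stopifnot(inherits(cohort, "et_cohort"))
  data.frame(subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
             age_yr = vapply(cohort$subjects, `[[`, 0, "age_yr"),
             sex = vapply(cohort$subjects, `[[`, "", "sex"),
             stringsAsFactors = FALSE)
}

#' Canonical landmark-to-label map for phantom volumes
#'
#' @return named integer vector mapping each landmark id to its voxel label.
#' @export
landmark_label_map <- function() {
  stats::setNames(seq_along(landmark_ids()), landmark_ids())
}

#' Rasterize a landmark set into a voxel phantom
#'
#' Each landmark becomes a filled ball of a distinct positive integer label
#' (see [landmark_label_map()]) on a zero background, in a volume covering
#' all landmarks plus padding. Voxel-center world coordinates are exact:
#' world = origin + (index - 1) * spacing.
#'
#' @param landmarks a `landmark_set`.
#' @param spacing isotropic voxel size, mm (default 0.3, a typical cone-beam
#'   sinus-protocol slice thickness).
#' @param marker_radius ball radius, mm; must be >= spacing.
#' @param padding extra margin around the landmark bounding box, mm.
#' @return a [voxel_volume()].
#' @export
rasterize_to_volume <- function(landmarks, spacing = 0.3, marker_radius = 1.5,
                                padding = 5) {
  stopifnot(inherits(landmarks, "landmark_set"), spacing > 0)
  if (marker_radius < spacing) {
    stop("marker_radius must be at least one voxel spacing", call. = FALSE)
  }
  pts <- landmarks$coords
  if (nrow(pts) >= 2L) {
    dd <- as.matrix(stats::dist(pts))
    diag(dd) <- Inf
    if (min(dd) <= 2 * marker_radius) {
      bad <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "landmarks %s and %s are %.2f mm apart: balls of radius %.2f mm overlap; use a smaller marker_radius",
        rownames(pts)[bad[1]], rownames(pts)[bad[2]], min(dd), marker_radius),
        call. = FALSE)
    }
  }
  lo <- apply(pts, 2, min) - padding - marker_radius
  hi <- apply(pts, 2, max) + padding + marker_radius
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  arr <- array(0L, dims)
  labels <- landmark_label_map()
  for (id in rownames(pts)) {
    p <- pts[id, ]
    ctr <- (p - lo) / spacing + 1              # continuous index of center
    rng <- lapply(1:3, function(a) {
      max(1L, floor(ctr[a] - marker_radius / spacing)):
        min(dims[a], ceiling(ctr[a] + marker_radius / spacing))
    })
    g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
    w <- sweep(as.matrix(g), 2, ctr) * spacing  # world offsets from center
    inside <- rowSums(w^2) <= marker_radius^2
    arr[as.matrix(g)[inside, , drop = FALSE]] <- labels[[id]]
  }
  voxel_volume(arr, spacing = rep(spacing, 3), origin = lo)
}
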