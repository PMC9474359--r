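# Landmark vocabulary, reference-plane definitions and per-ear ET measurement.

#' The closed set of landmark identifiers
#'
#' Ten named cranial landmarks, each a 3D point in millimetres (LPS):
#' infraorbital margins (`IOM_R`, `IOM_L`), mandibular fossae (`MF_R`,
#' `MF_L`), upper margins of the external auditory canals (`EAC_R`, `EAC_L`),
#' pharyngeal orifices of the Eustachian tube at the torus tubarius (`PO_R`,
#' `PO_L`) and tympanic orifices (`TO_R`, `TO_L`). Unknown names are rejected
#' wherever landmarks are parsed.
#'
#' @return character vector of the ten identifiers, in canonical order.
#' @export
landmark_ids <- function() {
  c("IOM_R", "IOM_L", "MF_R", "MF_L", "EAC_R", "EAC_L",
    "PO_R", "PO_L", "TO_R", "TO_L")
}

#' Reference-plane types and their defining landmarks
#'
#' Each plane is anchored by one right- or left-sided landmark plus the upper
#' margins of both external auditory canals:
#' * `REIDS` — Reid's standard plane: `IOM_R`, `EAC_R`, `EAC_L`.
#' * `FRANKFORT` — Frankfort plane: `IOM_L`, `EAC_R`, `EAC_L`.
#' * `KC_MFP` — mandibular-fossa plane: `MF_R`, `EAC_R`, `EAC_L`. The
#'   mandibular fossa sits close to the middle ear, so this plane can be
#'   built on limited-window cone-beam CT that omits the orbits.
#'
#' @return named list mapping plane type to its landmark triplet (anchor,
#'   `EAC_R`, `EAC_L`).
#' @export
plane_types <- function() {
  list(REIDS     = c("IOM_R", "EAC_R", "EAC_L"),
       FRANKFORT = c("IOM_L", "EAC_R", "EAC_L"),
       KC_MFP    = c("MF_R",  "EAC_R", "EAC_L"))
}

match_plane_type <- function(plane) {
  plane <- toupper(as.character(plane)[1])
  # file/CLI synonyms
  plane <- switch(plane, REIDS = "REIDS", RSP = "REIDS",
                  FRANKFORT = "FRANKFORT",
                  KC_MFP = "KC_MFP", KC = "KC_MFP", MFP = "KC_MFP",
                  stop(sprintf("unknown plane type '%s' (use REIDS, FRANKFORT or KC_MFP)",
                               plane), call. = FALSE))
  plane
}

#' Construct a per-subject landmark set
#'
#' @param subject_id subject identifier (scalar, coerced to character).
#' @param coords named list of points, or a numeric matrix with landmark ids
#'   as rownames and columns x, y, z (mm, LPS).
#' @return object of class `landmark_set`: list with `subject_id` and
#'   `coords`, a k x 3 matrix with landmark-id rownames in canonical order.
#' @details Identifiers outside [landmark_ids()] are rejected. Right-sided
#'   landmarks must lie at smaller x than their left counterparts (the LPS
#'   +x axis points to the patient's left).
#' @export
landmark_set <- function(subject_id, coords) {
  subject_id <- as.character(subject_id)[1]
  if (is.list(coords)) {
    coords <- do.call(rbind, lapply(coords, as_point3))
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || is.null(rownames(coords))) {
    stop("coords must be a k x 3 matrix with landmark-id rownames", call. = FALSE)
  }
  bad <- setdiff(rownames(coords), landmark_ids())
  if (length(bad)) {
    stop(sprintf("unknown landmark id(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(coords))) {
    stop("duplicate landmark ids in coords", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  coords <- coords[intersect(landmark_ids(), rownames(coords)), , drop = FALSE]
  colnames(coords) <- c("x", "y", "z")
  for (stem in c("IOM", "MF", "EAC", "PO", "TO")) {
    r <- paste0(stem, "_R"); l <- paste0(stem, "_L")
    if (all(c(r, l) %in% rownames(coords)) && coords[r, 1] >= coords[l, 1]) {
      stop(sprintf("side check failed: %s has x >= %s (LPS frame: right is smaller x)",
                   r, l), call. = FALSE)
    }
  }
  structure(list(subject_id = subject_id, coords = coords),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set '%s' (%d landmarks, mm LPS)\n",
              x$subject_id, nrow(x$coords)))
  print(round(x$coords, 3))
  invisible(x)
}

get_landmark <- function(lm, id, context = NULL) {
  if (!id %in% rownames(lm$coords)) {
    ctx <- if (is.null(context)) "" else sprintf(" (required for %s)", context)
    stop(sprintf("subject '%s': missing landmark %s%s", lm$subject_id, id, ctx),
         call. = FALSE)
  }
  lm$coords[id, ]
}

#' Build a reference plane from a subject's landmarks
#'
#' @param landmarks a `landmark_set`.
#' @param plane plane type: `"REIDS"`, `"FRANKFORT"` or `"KC_MFP"`
#'   (synonyms `rsp`, `mfp`, `kc` accepted, case-insensitive).
#' @return a [plane_from_points()] `reference_plane` through the plane's
#'   three landmarks, constructed in the fixed order (anchor, EAC_R, EAC_L).
#' @export
build_reference_plane <- function(landmarks, plane) {
  stopifnot(inherits(landmarks, "landmark_set"))
  plane <- match_plane_type(plane)
  ids <- plane_types()[[plane]]
  pts <- lapply(ids, function(id) get_landmark(landmarks, id, paste("plane", plane)))
  pl <- plane_from_points(pts[[1]], pts[[2]], pts[[3]], ids = ids)
  pl$plane_type <- plane
  pl
}

#' Measure one Eustachian tube
#'
#' ET length is the 3D Euclidean distance from the pharyngeal orifice to the
#' tympanic orifice; ET angle is the angle between that segment and the
#' chosen reference plane. The same right-anchored plane is used for both
#' ears.
#'
#' @param landmarks a `landmark_set`.
#' @param side `"right"` or `"left"`.
#' @param plane plane type (see [build_reference_plane()]).
#' @param ref_plane optional pre-built `reference_plane` (saves rebuilding it
#'   when measuring many ears of one subject).
#' @return one-row data.frame: `subject_id`, `side`, `plane`, `angle_deg`
#'   (in \[0, 90\]), `length_mm`.
#' @examples
#' lm <- landmark_set("s1", list(
#'   MF_R = c(-52, -8, 0), EAC_R = c(-60, 0, 0), EAC_L = c(60, 0, 0),
#'   PO_R = c(-20, -20, -10), TO_R = c(-50, -6, 1)))
#' measure_et(lm, "right", "KC_MFP")
#' @export
measure_et <- function(landmarks, side = c("right", "left"), plane = "KC_MFP",
                       ref_plane = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  side <- match.arg(side)
  if (is.null(ref_plane)) ref_plane <- build_reference_plane(landmarks, plane)
  plane <- ref_plane$plane_type %||% match_plane_type(plane)
  sfx <- if (side == "right") "_R" else "_L"
  po <- get_landmark(landmarks, paste0("PO", sfx), paste(side, "ET"))
  to <- get_landmark(landmarks, paste0("TO", sfx), paste(side, "ET"))
  len <- distance_mm(po, to)
  if (len == 0) {
    stop(sprintf("subject '%s', %s ear: pharyngeal and tympanic orifices coincide",
                 landmarks$subject_id, side), call. = FALSE)
  }
  data.frame(subject_id = landmarks$subject_id, side = side, plane = plane,
             angle_deg = line_plane_angle_deg(po, to, ref_plane),
             length_mm = len, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure every ear of a cohort
#'
#' @param landmark_sets list of `landmark_set` objects (one per subject).
#' @param plane plane type shared by all measurements.
#' @return data.frame of measurements, one row per ear, in stable order
#'   (subject order, right ear before left). Subjects missing one ear's
#'   orifice landmarks contribute the available ear only, with a warning;
#'   a missing plane landmark is an error.
#' @export
measure_cohort <- function(landmark_sets, plane = "KC_MFP") {
  if (inherits(landmark_sets, "landmark_set")) landmark_sets <- list(landmark_sets)
  if (!length(landmark_sets)) stop("empty cohort", call. = FALSE)
  plane <- match_plane_type(plane)
  rows <- vector("list", 2L * length(landmark_sets))
  k <- 0L
  for (lm in landmark_sets) {
    stopifnot(inherits(lm, "landmark_set"))
    ref <- build_reference_plane(lm, plane)
    for (side in c("right", "left")) {
      sfx <- if (side == "right") "_R" else "_L"
      have <- all(paste0(c("PO", "TO"), sfx) %in% rownames(lm$coords))
      if (!have) {
        warning(sprintf("subject '%s': %s ear skipped (orifice landmark missing)",
                        lm$subject_id, side), call. = FALSE)
        next
      }
      k <- k + 1L
      rows[[k]] <- measure_et(lm, side, ref_plane = ref)
    }
  }
  if (k == 0L) stop("no measurable ears in cohort", call. = FALSE)
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Round measurements for display
#'
#' Angles and lengths are kept at full precision internally and in files;
#' this helper applies the 1-decimal presentation rounding used in tables.
#'
#' @param measurements data.frame from [measure_cohort()].
#' @return the data.frame with `angle_deg` and `length_mm` rounded to 1 dp.
#' @export
format_measurements <- function(measurements) {
  measurements$angle_deg <- round(measurements$angle_deg, 1)
  measurements$length_mm <- round(measurements$length_mm, 1)
  measurements
}
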