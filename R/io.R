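# File formats: landmark CSV/JSON, measurement TSV, demographics CSV, cohort
# and report JSON. All writes are atomic (temp file + rename) so failed runs
# never leave partial outputs behind. Coordinates are mm, LPS; angles degrees.

write_atomic <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move output into place: ", path)
  invisible(path)
}

#' Read per-subject landmark sets
#'
#' CSV schema: header `subject_id,landmark_id,x_mm,y_mm,z_mm`, one row per
#' landmark. JSON schema: an array of objects
#' `{"subject_id": ..., "landmarks": {"EAC_R": [x, y, z], ...}}`.
#' The format is chosen by file extension.
#'
#' @param path input file (`.csv` or `.json`).
#' @return list of `landmark_set`, in file order.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(lapply(recs, function(r) {
      if (is.null(r$subject_id) || is.null(r$landmarks)) {
        stop("landmark JSON records need 'subject_id' and 'landmarks'", call. = FALSE)
      }
      landmark_set(r$subject_id, lapply(r$landmarks, as.numeric))
    }))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "landmark_id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop(sprintf("landmark CSV must have header columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!df$landmark_id %in% landmark_ids())
  if (length(bad)) {
    stop(sprintf("unknown landmark id '%s' at data row %d of %s",
                 df$landmark_id[bad[1]], bad[1], path), call. = FALSE)
  }
  for (col in c("x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    nf <- which(!is.finite(v))
    if (length(nf)) {
      stop(sprintf("malformed numeric '%s' in column %s at data row %d of %s",
                   df[[col]][nf[1]], col, nf[1], path), call. = FALSE)
    }
    df[[col]] <- v
  }
  dup <- duplicated(df[c("subject_id", "landmark_id")])
  if (any(dup)) {
    stop(sprintf("duplicate (subject, landmark) pair at data row %d of %s",
                 which(dup)[1], path), call. = FALSE)
  }
  lapply(split(df, factor(df$subject_id, levels = unique(df$subject_id))),
         function(s) {
           m <- as.matrix(s[c("x_mm", "y_mm", "z_mm")])
           rownames(m) <- s$landmark_id
           landmark_set(s$subject_id[1], m)
         }) |> unname()
}

#' Write landmark sets
#'
#' @param landmark_sets list of `landmark_set` (or a single one).
#' @param path output file; `.csv` or `.json` chooses the format (see
#'   [read_landmarks()]). Coordinates are written at full precision.
#' @return the path, invisibly.
#' @export
write_landmarks <- function(landmark_sets, path) {
  if (inherits(landmark_sets, "landmark_set")) landmark_sets <- list(landmark_sets)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(landmark_sets, function(lm) {
      list(subject_id = lm$subject_id,
           landmarks = lapply(seq_len(nrow(lm$coords)),
                              function(i) unname(lm$coords[i, ])) |>
             stats::setNames(rownames(lm$coords)))
    })
    return(write_atomic(path, function(tmp) {
      jsonlite::write_json(recs, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }))
  }
  df <- do.call(rbind, lapply(landmark_sets, function(lm) {
    data.frame(subject_id = lm$subject_id, landmark_id = rownames(lm$coords),
               x_mm = lm$coords[, 1], y_mm = lm$coords[, 2], z_mm = lm$coords[, 3],
               stringsAsFactors = FALSE)
  }))
  write_atomic(path, function(tmp) {
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     tmp, row.names = FALSE, quote = FALSE)
  })
}

#' Write a measurement table
#'
#' TSV with columns `subject_id, side, plane, angle_deg, length_mm` at full
#' precision (presentation rounding belongs to [format_measurements()]).
#'
#' @param measurements data.frame from [measure_cohort()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  write_atomic(path, function(tmp) {
    utils::write.table(measurements, tmp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  })
}

#' Read a measurement table written by [write_measurements()]
#' @param path TSV path.
#' @return data.frame of per-ear measurements.
#' @export
read_measurements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "side", "plane", "angle_deg", "length_mm")
  if (!all(need %in% names(df))) {
    stop("measurement TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$plane <- vapply(df$plane, match_plane_type, "")
  df
}

#' Write a demographics table (`subject_id, age_yr, sex`)
#' @param demographics data.frame, e.g. from [cohort_demographics()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_demographics <- function(demographics, path) {
  write_atomic(path, function(tmp) {
    utils::write.csv(demographics, tmp, row.names = FALSE, quote = FALSE)
  })
}

#' Read a demographics table
#' @param path CSV path with columns `subject_id, age_yr, sex`.
#' @return data.frame.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "age_yr", "sex") %in% names(df))) {
    stop("demographics CSV must have columns subject_id, age_yr, sex",
         call. = FALSE)
  }
  df
}

#' Serialize a cohort to JSON
#'
#' Lossless: numbers are written at full precision, and the preset and seed
#' are embedded so the cohort can be regenerated byte-identically from its
#' own provenance.
#'
#' @param cohort an `et_cohort`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_cohort_json <- function(cohort, path) {
  stopifnot(inherits(cohort, "et_cohort"))
  obj <- list(
    preset = unclass(cohort$preset), seed = cohort$seed,
    subjects = lapply(cohort$subjects, function(s) {
      list(subject_id = s$subject_id, age_yr = s$age_yr, sex = s$sex,
           landmarks = lapply(seq_len(nrow(s$landmarks$coords)),
                              function(i) unname(s$landmarks$coords[i, ])) |>
             stats::setNames(rownames(s$landmarks$coords)),
           truth = s$truth)
    }))
  write_atomic(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  })
}

#' Read a cohort serialized by [write_cohort_json()]
#' @param path JSON path.
#' @return an `et_cohort`.
#' @export
read_cohort_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  preset <- do.call(cohort_preset, obj$preset)
  subjects <- lapply(obj$subjects, function(s) {
    truth <- do.call(rbind, lapply(s$truth, as.data.frame))
    structure(list(subject_id = s$subject_id, age_yr = s$age_yr, sex = s$sex,
                   landmarks = landmark_set(s$subject_id,
                                            lapply(s$landmarks, as.numeric)),
                   truth = truth),
              class = "subject_record")
  })
  structure(list(preset = preset, seed = as.integer(obj$seed), subjects = subjects),
            class = "et_cohort")
}

#' Write a comparison report as JSON (plus optional human-readable TSV)
#'
#' @param report a `comparison_report` from [compare_cohorts()].
#' @param path output JSON path.
#' @param tsv_path optional path for a flat TSV rendering of the same report.
#' @return the JSON path, invisibly.
#' @export
write_report <- function(report, path, tsv_path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  strip <- function(x) {
    if (inherits(x, "summary_stats") || inherits(x, "test_result")) return(unclass(x))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  write_atomic(path, function(tmp) {
    jsonlite::write_json(strip(unclass(report)), tmp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, matrix = "rowmajor")
  })
  if (!is.null(tsv_path)) {
    rows <- list()
    for (m in names(report$measures)) {
      sp <- report$measures[[m]]
      rows[[m]] <- data.frame(
        measure = m, n_a = sp$a$n, mean_a = sp$a$mean, sd_a = sp$a$sd,
        n_b = sp$b$n, mean_b = sp$b$mean, sd_b = sp$b$sd,
        p_student = sp$student$p, p_welch = sp$welch$p)
    }
    if (!is.null(report$demographics)) {
      sp <- report$demographics$age_yr
      rows$age <- data.frame(
        measure = "age_yr", n_a = sp$a$n, mean_a = sp$a$mean, sd_a = sp$a$sd,
        n_b = sp$b$n, mean_b = sp$b$mean, sd_b = sp$b$sd,
        p_student = sp$student$p, p_welch = sp$welch$p)
    }
    write_atomic(tsv_path, function(tmp) {
      utils::write.table(do.call(rbind, rows), tmp, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    })
  }
  invisible(path)
}
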