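#' Angular arrival-time profiles
#'
#' An angular profile is the basic unit of Reviscometer-style data: arrival
#' times (in RRT, "Resonance Running Time" units) of an elastic surface wave
#' measured at a set of angles around a fixed skin site. The full measurement
#' protocol records 36 readings at 10 degree increments (0, 10, ..., 350
#' degrees; 360 is identified with 0), repeated three times per subject and
#' configuration.
#'
#' @param angle_deg Numeric vector of measurement angles in degrees, in
#'   `[0, 360)`, strictly increasing, each a multiple of `grid_step`.
#' @param rrt Numeric vector of strictly positive arrival times (RRT units),
#'   one per angle.
#' @param subject_id Optional subject identifier.
#' @param configuration Optional `"natural"` or `"stretched"`.
#' @param repeat_index Optional repeat number (>= 1), or `NA` for an averaged
#'   profile.
#' @param grid_step Angular grid step in degrees (default 10).
#' @param require_full If `TRUE`, insist on the complete 360/`grid_step`
#'   reading protocol.
#'
#' @return A tibble of class `"angular_profile"` with columns `angle_deg` and
#'   `rrt`, carrying `subject_id`, `configuration` and `repeat_index` as
#'   attributes.
#' @export
#' @examples
#' ang <- seq(0, 350, by = 10)
#' p <- angular_profile(ang, ellipse_polar_radius(224.044, 160, 30, ang))
#' langer_direction_raw(p)
angular_profile <- function(angle_deg, rrt, subject_id = NA_character_,
                            configuration = NA_character_,
                            repeat_index = NA_integer_,
                            grid_step = 10, require_full = FALSE) {
  if (length(angle_deg) != length(rrt)) {
    stop("`angle_deg` and `rrt` must have the same length.", call. = FALSE)
  }
  if (length(angle_deg) == 0L) {
    stop("an angular profile must contain at least one reading.", call. = FALSE)
  }
  if (!is.numeric(angle_deg) || !is.numeric(rrt)) {
    stop("`angle_deg` and `rrt` must be numeric.", call. = FALSE)
  }
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0 | angle_deg >= 360)) {
    stop("angles must be finite and in [0, 360).", call. = FALSE)
  }
  if (any(diff(angle_deg) <= 0)) {
    stop("angles must be strictly increasing.", call. = FALSE)
  }
  off_grid <- angle_deg[abs(angle_deg / grid_step -
                              round(angle_deg / grid_step)) > 1e-9]
  if (length(off_grid) > 0) {
    stop("angles not on the ", grid_step, " degree grid: ",
         paste(off_grid, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(round(angle_deg) %% 360)) {
    stop("duplicate angles modulo 360.", call. = FALSE)
  }
  if (any(!is.finite(rrt)) || any(rrt <= 0)) {
    stop("all arrival times must be finite and > 0.", call. = FALSE)
  }
  n_full <- as.integer(round(360 / grid_step))
  if (require_full && length(angle_deg) != n_full) {
    stop("full protocol profile must have exactly ", n_full, " readings, got ",
         length(angle_deg), ".", call. = FALSE)
  }
  out <- tibble::tibble(angle_deg = as.numeric(angle_deg),
                        rrt = as.numeric(rrt))
  attr(out, "subject_id") <- subject_id
  attr(out, "configuration") <- configuration
  attr(out, "repeat_index") <- repeat_index
  attr(out, "grid_step") <- grid_step
  class(out) <- c("angular_profile", class(out))
  out
}

cohort_columns <- c("subject_id", "age_years", "gender", "configuration",
                    "repeat", "angle_deg", "rrt")

parse_numeric_column <- function(x, name) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "")
  if (length(bad) > 0) {
    stop("non-numeric ", name, " at data row ", bad[1], ": '", x[bad[1]], "'",
         call. = FALSE)
  }
  if (anyNA(out)) {
    stop("missing ", name, " at data row ", which(is.na(out))[1], ".",
         call. = FALSE)
  }
  out
}

#' Read a cohort of angular measurements from CSV
#'
#' Reads a long-format CSV with one row per reading and columns
#' `subject_id, age_years, gender, configuration, repeat, angle_deg, rrt`
#' (gender `F`/`M`; configuration `natural`/`stretched`; `repeat` a positive
#' integer or `"avg"` for pre-averaged profiles). Rows may appear in any
#' order; the result is sorted and validated.
#'
#' @param path Path to the CSV file.
#' @param grid_step Angular grid step in degrees (default 10).
#' @param age_range Plausible age range in years; ages outside it are an error.
#' @return A validated tibble with the columns above, one row per reading.
#' @export
read_cohort <- function(path, grid_step = 10, age_range = c(0, 120)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cohort <- tibble::tibble(
    subject_id = raw$subject_id,
    age_years = parse_numeric_column(raw$age_years, "age_years"),
    gender = raw$gender,
    configuration = raw$configuration,
    "repeat" = raw[["repeat"]],
    angle_deg = parse_numeric_column(raw$angle_deg, "angle_deg"),
    rrt = parse_numeric_column(raw$rrt, "rrt")
  )
  validate_cohort(cohort, grid_step = grid_step, age_range = age_range)
}

#' Validate a long-format cohort table
#'
#' @param cohort Tibble with the columns of [read_cohort()].
#' @inheritParams read_cohort
#' @return The cohort, sorted by subject, configuration, repeat and angle.
#' @export
validate_cohort <- function(cohort, grid_step = 10, age_range = c(0, 120)) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cohort) == 0L) {
    return(tibble::as_tibble(cohort[cohort_columns]))
  }
  bad_gender <- setdiff(unique(cohort$gender), c("F", "M"))
  if (length(bad_gender) > 0) {
    stop("gender must be 'F' or 'M'; found: ",
         paste(bad_gender, collapse = ", "), call. = FALSE)
  }
  bad_config <- setdiff(unique(cohort$configuration),
                        c("natural", "stretched"))
  if (length(bad_config) > 0) {
    stop("configuration must be 'natural' or 'stretched'; found: ",
         paste(bad_config, collapse = ", "), call. = FALSE)
  }
  if (any(cohort$age_years < age_range[1] | cohort$age_years > age_range[2])) {
    stop("age_years outside plausible range [", age_range[1], ", ",
         age_range[2], "].", call. = FALSE)
  }
  key <- paste(cohort$subject_id, cohort$configuration, cohort[["repeat"]],
               cohort$angle_deg %% 360)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (subject, configuration, repeat, angle) reading: ", dup,
         call. = FALSE)
  }
  ages <- dplyr::distinct(cohort, .data$subject_id, .data$age_years,
                          .data$gender)
  if (anyDuplicated(ages$subject_id)) {
    stop("inconsistent age/gender within subject ",
         ages$subject_id[duplicated(ages$subject_id)][1], call. = FALSE)
  }
  out <- dplyr::arrange(cohort, .data$subject_id, .data$configuration,
                        .data[["repeat"]], .data$angle_deg)
  # per-profile validation (grid, positivity, monotone angles)
  split_key <- paste(out$subject_id, out$configuration, out[["repeat"]],
                     sep = "\r")
  for (idx in split(seq_len(nrow(out)), split_key)) {
    angular_profile(out$angle_deg[idx], out$rrt[idx], grid_step = grid_step)
  }
  tibble::as_tibble(out[cohort_columns])
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: writes the same long-format schema, so that
#' reading the file back reproduces the validated table.
#'
#' @param cohort A validated cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[cohort_columns], path)
  invisible(path)
}

#' Average repeated profiles
#'
#' The measurement protocol repeats each 36-angle sweep three times; analysis
#' proceeds on the per-angle arithmetic mean. `average_repeats()` accepts
#' either a list of [angular_profile()]s sharing one subject, configuration
#' and angle grid (returning a single averaged profile) or a long-format
#' cohort table (returning a table with one `"avg"` row per subject,
#' configuration and angle).
#'
#' @param x A list of angular profiles, or a cohort tibble.
#' @return An averaged profile, or a cohort tibble with `repeat = "avg"`.
#' @export
average_repeats <- function(x) {
  UseMethod("average_repeats")
}

#' @export
average_repeats.list <- function(x) {
  if (length(x) == 0L) stop("no profiles to average.", call. = FALSE)
  ref <- x[[1]]
  for (p in x[-1]) {
    if (length(p$angle_deg) != length(ref$angle_deg) ||
        any(p$angle_deg != ref$angle_deg)) {
      off <- union(setdiff(p$angle_deg, ref$angle_deg),
                   setdiff(ref$angle_deg, p$angle_deg))
      stop("mismatched angle grids; offending angles: ",
           paste(sort(off), collapse = ", "), call. = FALSE)
    }
  }
  rrt_mat <- vapply(x, function(p) p$rrt, numeric(length(ref$angle_deg)))
  angular_profile(ref$angle_deg, rowMeans(as.matrix(rrt_mat)),
                  subject_id = attr(ref, "subject_id"),
                  configuration = attr(ref, "configuration"),
                  repeat_index = NA_integer_,
                  grid_step = attr(ref, "grid_step") %||% 10)
}

#' @export
average_repeats.data.frame <- function(x) {
  grp <- dplyr::group_by(x, .data$subject_id, .data$age_years, .data$gender,
                         .data$configuration, .data$angle_deg)
  counts <- dplyr::summarise(grp, n_rep = dplyr::n_distinct(.data[["repeat"]]),
                             .groups = "drop")
  if (length(unique(counts$n_rep)) > 1) {
    stop("mismatched angle grids across repeats; offending angles: ",
         paste(sort(unique(counts$angle_deg[counts$n_rep !=
                                              max(counts$n_rep)])),
               collapse = ", "), call. = FALSE)
  }
  out <- dplyr::summarise(grp, rrt = mean(.data$rrt), .groups = "drop")
  out[["repeat"]] <- "avg"
  dplyr::arrange(out[cohort_columns], .data$subject_id, .data$configuration,
                 .data$angle_deg)
}

#' Raw-data Langer-line direction
#'
#' The field protocol identifies the Langer-line (skin tension line)
#' direction directly from the raw sweep as the direction of the shortest
#' arrival time, i.e. of the fastest travelling wave, to the nearest grid
#' step. Directions are axial, so the result is reduced modulo 180 degrees;
#' ties are broken towards the smallest angle.
#'
#' @param profile An [angular_profile()] (or any data frame with `angle_deg`
#'   and `rrt` columns).
#' @return Direction in degrees, in `[0, 180)`.
#' @export
langer_direction_raw <- function(profile) {
  if (is.null(profile[["rrt"]]) || length(profile[["rrt"]]) == 0L) {
    stop("empty profile.", call. = FALSE)
  }
  ang <- profile$angle_deg %% 180
  cand <- ang[profile$rrt == min(profile$rrt)]
  min(cand)
}

#' Extract one profile from a cohort table
#'
#' @param cohort A cohort tibble.
#' @param subject_id,configuration Which profile to extract.
#' @param which_repeat Repeat label (default `"avg"`).
#' @return An [angular_profile()].
#' @export
cohort_profile <- function(cohort, subject_id, configuration,
                           which_repeat = "avg") {
  rows <- cohort[cohort$subject_id == subject_id &
                   cohort$configuration == configuration &
                   cohort[["repeat"]] == which_repeat, ]
  if (nrow(rows) == 0L) {
    stop("no readings for subject ", subject_id, ", configuration ",
         configuration, ", repeat ", which_repeat, ".", call. = FALSE)
  }
  rows <- rows[order(rows$angle_deg), ]
  angular_profile(rows$angle_deg, rows$rrt, subject_id = subject_id,
                  configuration = configuration)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
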