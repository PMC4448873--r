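#' Read and validate a detection stream CSV
#'
#' Schema: `time_s, day, sampling_period, feeder_id, individual_id`
#' (header required, UTF-8). Malformed rows are reported with their line
#' numbers.
#'
#' @param path CSV path.
#' @return Validated tibble sorted by day then time.
#' @export
read_detections <- function(path) {
  cols <- readr::cols(time_s = readr::col_double(),
                      day = readr::col_integer(),
                      sampling_period = readr::col_integer(),
                      feeder_id = readr::col_character(),
                      individual_id = readr::col_character())
  df <- suppressWarnings(readr::read_csv(path, col_types = cols, progress = FALSE))
  check_columns(df, names(cols$cols), "detections")
  report_bad_rows(df, !is.finite(df$time_s), "non-numeric or missing time_s")
  report_bad_rows(df, is.na(df$individual_id) | df$individual_id == "",
                  "missing individual_id")
  dplyr::arrange(df, .data$day, .data$time_s)
}

#' Read and validate a phenotype table CSV
#'
#' Schema: `individual_id, sex, age_class, residency, wing_mm, tarsus_mm`;
#' empty cells mean unknown.
#'
#' @param path CSV path.
#' @return Tibble with columns `individual_id`, `sex`, `age_class`,
#'   `residency`, `wing`, `tarsus` (`NA` = unknown).
#' @export
read_phenotypes <- function(path) {
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    sex = readr::col_character(),
    age_class = readr::col_character(),
    residency = readr::col_character(),
    wing_mm = readr::col_double(),
    tarsus_mm = readr::col_double()), progress = FALSE))
  check_columns(df, c("individual_id", "sex", "age_class", "residency",
                      "wing_mm", "tarsus_mm"), "phenotypes")
  dup <- duplicated(df$individual_id)
  report_bad_rows(df, dup, "duplicate individual_id")
  chk_level <- function(v, levels) is.na(v) | v %in% levels
  report_bad_rows(df, !chk_level(df$sex, c("male", "female", "unknown")),
                  "invalid sex")
  report_bad_rows(df, !chk_level(df$age_class, c("juvenile", "adult")),
                  "invalid age_class")
  report_bad_rows(df, !chk_level(df$residency, c("immigrant", "local")),
                  "invalid residency")
  report_bad_rows(df, !is.na(df$wing_mm) & df$wing_mm <= 0,
                  "non-positive wing_mm")
  report_bad_rows(df, !is.na(df$tarsus_mm) & df$tarsus_mm <= 0,
                  "non-positive tarsus_mm")
  dplyr::rename(df, wing = "wing_mm", tarsus = "tarsus_mm")
}

#' Read a group-membership file pair
#'
#' Long memberships CSV (`group_id, individual_id`) plus metadata CSV
#' (`group_id, feeder_id, sampling_period, day, time_s`).
#'
#' @param memberships_path,meta_path CSV paths.
#' @return A [group_matrix()].
#' @export
read_groups <- function(memberships_path, meta_path) {
  mem <- readr::read_csv(memberships_path, col_types = readr::cols(
    group_id = readr::col_character(),
    individual_id = readr::col_character()), progress = FALSE)
  check_columns(mem, c("group_id", "individual_id"), "memberships")
  meta <- readr::read_csv(meta_path, col_types = readr::cols(
    group_id = readr::col_character(),
    feeder_id = readr::col_character(),
    sampling_period = readr::col_integer(),
    day = readr::col_integer(),
    time_s = readr::col_double()), progress = FALSE)
  check_columns(meta, c("group_id", "feeder_id", "sampling_period",
                        "time_s"), "group metadata")
  report_bad_rows(mem, duplicated(mem), "duplicate membership row")
  group_matrix(mem, meta)
}

#' Write the detection stream / phenotypes / groups to CSV
#'
#' Inverse of the readers; columns in schema order.
#'
#' @param detections,phenotypes Tibbles in package format.
#' @param matrix A [group_matrix()].
#' @param path,memberships_path,meta_path Output paths.
#' @return The input, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_detections <- function(detections, path) {
  readr::write_csv(detections[c("time_s", "day", "sampling_period",
                                "feeder_id", "individual_id")], path)
  invisible(detections)
}

#' @rdname writers
#' @export
write_phenotypes <- function(phenotypes, path) {
  out <- dplyr::rename(phenotypes, wing_mm = "wing", tarsus_mm = "tarsus")
  readr::write_csv(out[c("individual_id", "sex", "age_class", "residency",
                         "wing_mm", "tarsus_mm")], path, na = "")
  invisible(phenotypes)
}

#' @rdname writers
#' @export
write_groups <- function(matrix, memberships_path, meta_path) {
  readr::write_csv(group_memberships(matrix), memberships_path)
  readr::write_csv(matrix$meta[c("group_id", "feeder_id",
                                 "sampling_period", "day", "time_s")],
                   meta_path)
  invisible(matrix)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

## Line numbers reported are 1-based data lines (header = line 1).
report_bad_rows <- function(df, bad, what) {
  if (any(bad, na.rm = TRUE)) {
    lines <- which(bad) + 1L
    stop(sprintf("%s at line(s): %s", what,
                 paste(head(lines, 10), collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Flag individuals observed but absent from the phenotype table
#'
#' Detected-but-untyped individuals (e.g. birds never caught) stay in the
#' network but carry unknown phenotypes and are excluded from
#' assortativity.
#'
#' @param detections Detection tibble.
#' @param phenotypes Phenotype tibble.
#' @return Phenotype tibble extended with unknown rows for orphan ids, with
#'   attribute `n_unknown`.
#' @export
flag_unknown_individuals <- function(detections, phenotypes) {
  orphan <- setdiff(unique(detections$individual_id),
                    phenotypes$individual_id)
  if (length(orphan)) {
    extra <- tibble::tibble(individual_id = orphan, sex = "unknown",
                            age_class = NA_character_,
                            residency = NA_character_,
                            wing = NA_real_, tarsus = NA_real_)
    phenotypes <- dplyr::bind_rows(phenotypes, extra)
  }
  attr(phenotypes, "n_unknown") <- length(orphan)
  phenotypes
}
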