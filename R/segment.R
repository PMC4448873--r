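#' Segment one feeder-day detection stream into gathering events
#'
#' Fits one-dimensional Gaussian mixtures over detection times with the
#' number of components selected by BIC, then hard-assigns each detection to
#' its maximum-responsibility component. Closely spaced visits therefore
#' fall into one inferred gathering without any fixed time window.
#' Components carrying less than `min_component_weight` of the detections
#' are merged into their nearest neighbour (by centre time).
#'
#' @param events Tibble of detections from a single feeder and day: columns
#'   `time_s`, `individual_id` (plus optional `feeder_id`, `day`,
#'   `sampling_period` carried through to the output).
#' @param k_max Maximum number of mixture components tried. Default: one
#'   component per 10 minutes of the day's detection span.
#' @param min_component_weight Minimum fraction of detections a component
#'   must hold to survive as its own gathering.
#' @return A tibble of gatherings: `group_id` (local, `g1`, `g2`, ... in
#'   time order), `centre_time_s`, `spread_s`, `n_detections`, `members`
#'   (list-column of individual ids), plus carried-through identifiers.
#' @export
segment_stream <- function(events, k_max = NULL,
                           min_component_weight = 0) {
  if (nrow(events) == 0) return(empty_gatherings(events))
  stopifnot(all(is.finite(events$time_s)))
  if (length(unique(events$feeder_id)) > 1 ||
      length(unique(events$day)) > 1) {
    stop("segment_stream: events must come from a single feeder and day",
         call. = FALSE)
  }
  t <- events$time_s
  span <- diff(range(t))
  if (is.null(k_max)) k_max <- max(1L, ceiling(span / 600))
  k_max <- min(k_max, length(unique(t)))

  if (span == 0 || k_max == 1L || nrow(events) == 1L) {
    assign <- rep(1L, length(t))
  } else {
    fit <- suppressWarnings(
      Mclust(t, G = seq_len(k_max), modelNames = c("E", "V"),
                     verbose = FALSE)
    )
    if (is.null(fit)) {
      assign <- rep(1L, length(t))
    } else {
      ## Hard assignment by maximum responsibility; ties go to the earlier
      ## (smaller-mean) component.
      z <- fit$z
      mean_order <- order(fit$parameters$mean)
      z <- z[, mean_order, drop = FALSE]
      assign <- max.col(z, ties.method = "first")
    }
  }
  assign <- merge_light_components(t, assign, min_component_weight)
  finalize_gatherings(events, assign)
}

## Relabel components in time order and merge those under the weight floor
## into the nearest surviving neighbour by centre time.
merge_light_components <- function(t, assign, min_weight) {
  repeat {
    centres <- tapply(t, assign, mean)
    ord <- order(centres)
    relabel <- match(assign, as.integer(names(centres))[ord])
    assign <- relabel
    if (min_weight <= 0) return(assign)
    w <- tabulate(assign) / length(assign)
    light <- which(w > 0 & w < min_weight)
    if (!length(light) || length(unique(assign)) == 1L) return(assign)
    centres <- tapply(t, assign, mean)
    k <- light[which.min(w[light])]
    others <- setdiff(seq_along(centres), k)
    target <- others[which.min(abs(centres[others] - centres[k]))]
    assign[assign == k] <- target
  }
}

finalize_gatherings <- function(events, assign) {
  carried <- intersect(c("feeder_id", "day", "sampling_period"),
                       names(events))
  events$`..g` <- assign
  out <- events |>
    dplyr::group_by(.data$`..g`) |>
    dplyr::summarise(
      centre_time_s = mean(.data$time_s),
      spread_s = stats::sd(.data$time_s),
      n_detections = dplyr::n(),
      members = list(sort(unique(.data$individual_id))),
      dplyr::across(dplyr::all_of(carried), dplyr::first),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$centre_time_s)
  out$spread_s[is.na(out$spread_s)] <- 0
  out$group_id <- sprintf("g%d", seq_len(nrow(out)))
  dplyr::select(out, "group_id", dplyr::all_of(carried), "centre_time_s",
                "spread_s", "n_detections", "members")
}

empty_gatherings <- function(events) {
  carried <- intersect(c("feeder_id", "day", "sampling_period"),
                       names(events))
  out <- tibble::tibble(group_id = character(), centre_time_s = numeric(),
                        spread_s = numeric(), n_detections = integer(),
                        members = list())
  for (cc in carried) out[[cc]] <- events[[cc]][0]
  dplyr::select(out, "group_id", dplyr::all_of(carried),
                dplyr::everything())
}

#' Infer gathering events across a whole detection stream
#'
#' Splits the stream by feeder and day, segments each sub-stream with
#' [segment_stream()], and assembles globally unique group ids and the
#' group-by-individual matrix. Antennae at one feeder are pooled: the
#' feeder is the observation unit.
#'
#' @param detections Tibble with columns `time_s`, `day`, `sampling_period`,
#'   `feeder_id`, `individual_id`.
#' @param k_max Passed to [segment_stream()] (default: per-day span / 600 s).
#' @param min_component_weight Passed to [segment_stream()].
#' @return A list: `gatherings` (tibble, one row per inferred group, with
#'   global `group_id` and `time_s` = centre time) and `matrix` (a
#'   [group_matrix()]).
#' @export
infer_groups <- function(detections, k_max = NULL,
                         min_component_weight = 0) {
  req <- c("time_s", "day", "sampling_period", "feeder_id", "individual_id")
  stopifnot(all(req %in% names(detections)))
  parts <- detections |>
    dplyr::group_by(.data$feeder_id, .data$day) |>
    dplyr::group_split()
  gath <- purrr::map(parts, segment_stream, k_max = k_max,
                     min_component_weight = min_component_weight) |>
    dplyr::bind_rows()
  if (nrow(gath)) {
    gath <- dplyr::arrange(gath, .data$sampling_period, .data$feeder_id,
                           .data$day, .data$centre_time_s)
    gath$group_id <- sprintf("G%06d", seq_len(nrow(gath)))
  }
  gath <- dplyr::rename(gath, time_s = "centre_time_s")
  list(gatherings = gath, matrix = build_group_matrix(gath))
}
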