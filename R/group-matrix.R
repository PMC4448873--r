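#' Group-by-individual matrix
#'
#' The pipeline's central object: a binary incidence matrix (groups in rows,
#' individuals in columns) plus per-group metadata (feeder, sampling period,
#' day, centre time). Rows are ordered by (sampling period, feeder, time).
#'
#' @param memberships Long tibble with columns `group_id`, `individual_id`.
#' @param meta Tibble with columns `group_id`, `feeder_id`,
#'   `sampling_period`, `day`, `time_s` (one row per group). `day` and
#'   `time_s` may be omitted when no timing analyses are needed.
#' @return An object of class `group_matrix` with elements `incidence`
#'   (integer matrix with dimnames) and `meta` (tibble aligned to rows).
#' @export
group_matrix <- function(memberships, meta = NULL) {
  stopifnot(all(c("group_id", "individual_id") %in% names(memberships)))
  gids <- unique(memberships$group_id)
  if (is.null(meta)) {
    meta <- tibble::tibble(group_id = gids, feeder_id = NA_character_,
                           sampling_period = NA_integer_, day = NA_integer_,
                           time_s = NA_real_)
  }
  if (anyDuplicated(meta$group_id)) {
    stop("group_matrix: duplicate group ids in metadata", call. = FALSE)
  }
  missing_meta <- setdiff(gids, meta$group_id)
  if (length(missing_meta)) {
    stop("group_matrix: groups without metadata: ",
         paste(head(missing_meta, 5), collapse = ", "), call. = FALSE)
  }
  meta <- meta[meta$group_id %in% gids, , drop = FALSE]
  if (!"day" %in% names(meta)) meta$day <- NA_integer_
  if (!"time_s" %in% names(meta)) meta$time_s <- NA_real_
  ord <- order(meta$sampling_period, meta$feeder_id, meta$day, meta$time_s,
               meta$group_id)
  meta <- meta[ord, , drop = FALSE]
  inds <- sort(unique(memberships$individual_id))
  inc <- matrix(0L, nrow(meta), length(inds),
                dimnames = list(meta$group_id, inds))
  inc[cbind(match(memberships$group_id, meta$group_id),
            match(memberships$individual_id, inds))] <- 1L
  if (any(rowSums(inc) == 0)) {
    stop("group_matrix: empty group (no members)", call. = FALSE)
  }
  structure(list(incidence = inc, meta = tibble::as_tibble(meta)),
            class = "group_matrix")
}

#' @export
print.group_matrix <- function(x, ...) {
  cat(sprintf("<group_matrix> %d groups x %d individuals\n",
              nrow(x$incidence), ncol(x$incidence)))
  sz <- rowSums(x$incidence)
  cat(sprintf("  group size: mean %.2f, max %d; periods: %s\n",
              mean(sz), max(sz),
              paste(range(x$meta$sampling_period), collapse = "-")))
  invisible(x)
}

#' Group sizes of a group-by-individual matrix
#' @param matrix A [group_matrix()].
#' @return Integer vector of row sums, named by group id.
#' @export
group_sizes <- function(matrix) {
  stopifnot(inherits(matrix, "group_matrix"))
  rowSums(matrix$incidence)
}

#' Long-format memberships of a group-by-individual matrix
#' @param matrix A [group_matrix()].
#' @return Tibble `group_id`, `individual_id`, one row per membership.
#' @export
group_memberships <- function(matrix) {
  stopifnot(inherits(matrix, "group_matrix"))
  idx <- which(matrix$incidence == 1L, arr.ind = TRUE)
  tibble::tibble(
    group_id = rownames(matrix$incidence)[idx[, 1]],
    individual_id = colnames(matrix$incidence)[idx[, 2]]
  ) |> dplyr::arrange(.data$group_id, .data$individual_id)
}

#' Build the group-by-individual matrix from gathering events
#'
#' @param gatherings Tibble of gatherings as returned by [infer_groups()] or
#'   the generator truth (`group_id`, `feeder_id`, `sampling_period`, `day`,
#'   `time_s`, and a list-column `members` or paired long memberships).
#' @param memberships Optional long tibble `group_id`, `individual_id`; if
#'   omitted, `gatherings$members` (a list-column of character vectors) is
#'   used.
#' @return A [group_matrix()].
#' @export
build_group_matrix <- function(gatherings, memberships = NULL) {
  if (anyDuplicated(gatherings$group_id)) {
    stop("build_group_matrix: duplicate group ids", call. = FALSE)
  }
  if (is.null(memberships)) {
    stopifnot("members" %in% names(gatherings))
    memberships <- tibble::tibble(
      group_id = rep(gatherings$group_id,
                     lengths(gatherings$members)),
      individual_id = unlist(gatherings$members, use.names = FALSE)
    )
  }
  if (nrow(memberships) == 0) {
    inc <- matrix(0L, 0, 0)
    return(structure(list(incidence = inc,
                          meta = gatherings[0, , drop = FALSE]),
                     class = "group_matrix"))
  }
  meta_cols <- intersect(c("group_id", "feeder_id", "sampling_period",
                           "day", "time_s"), names(gatherings))
  group_matrix(memberships, gatherings[meta_cols])
}
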