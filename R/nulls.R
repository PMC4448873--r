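#' Phenotypic node-label permutation null
#'
#' Shuffles which phenotype row is attached to which individual id (the
#' whole row moves, preserving trait covariance) and recomputes the
#' statistic on the untouched observation structure. This null asks what
#' the statistic looks like when phenotypes are distributed randomly over a
#' fixed social structure.
#'
#' @param matrix A [group_matrix()].
#' @param phenotypes Phenotype tibble.
#' @param statistic_fn Function `(matrix, phenotypes) -> numeric` (scalar or
#'   named/per-bin vector).
#' @param n_iter Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `null_distribution` object; see [null_distribution()].
#' @export
node_permutation_null <- function(matrix, phenotypes, statistic_fn,
                                  n_iter = 1000, seed = 1L) {
  observed <- statistic_fn(matrix, phenotypes)
  set.seed(seed)
  samples <- base::matrix(NA_real_, n_iter, length(observed))
  colnames(samples) <- names(observed)
  id_col <- phenotypes$individual_id
  for (i in seq_len(n_iter)) {
    perm <- phenotypes[sample.int(nrow(phenotypes)), ]
    perm$individual_id <- id_col
    samples[i, ] <- statistic_fn(matrix, perm)
  }
  null_distribution("node_permutation", observed, samples,
                    n_iterations = n_iter, sampling_interval = 1L)
}

#' One spatio-temporally restricted swap
#'
#' Exchanges two individuals between two different groups observed at the
#' same feeder and in the same sampling period. The swapped individuals
#' must each be absent from the other group, so group sizes, each
#' individual's number of memberships, and all group metadata are
#' preserved exactly.
#'
#' @param matrix A [group_matrix()].
#' @param max_attempts Bounded rejection attempts before giving up.
#' @return List: `matrix` (possibly updated), `swapped` (logical).
#' @export
datastream_swap <- function(matrix, max_attempts = 50) {
  st <- swap_strata(matrix)
  res <- swap_once(matrix$incidence, st, max_attempts)
  matrix$incidence <- res$incidence
  list(matrix = matrix, swapped = res$swapped)
}

## Stratum bookkeeping: groups per (feeder, period), with selection
## probability proportional to the number of group pairs in the stratum.
swap_strata <- function(matrix) {
  meta <- matrix$meta
  key <- paste(meta$feeder_id, meta$sampling_period, sep = "\r")
  groups_by_stratum <- split(seq_len(nrow(meta)), key)
  groups_by_stratum <- groups_by_stratum[lengths(groups_by_stratum) >= 2]
  if (!length(groups_by_stratum)) {
    return(list(strata = list(), prob = numeric()))
  }
  npairs <- vapply(groups_by_stratum,
                   function(g) choose(length(g), 2), numeric(1))
  list(strata = groups_by_stratum, prob = npairs / sum(npairs))
}

swap_once <- function(inc, st, max_attempts = 50) {
  if (!length(st$strata)) return(list(incidence = inc, swapped = FALSE))
  for (a in seq_len(max_attempts)) {
    s <- st$strata[[sample.int(length(st$strata), 1, prob = st$prob)]]
    gg <- s[sample.int(length(s), 2)]
    r1 <- inc[gg[1], ]; r2 <- inc[gg[2], ]
    cand_a <- which(r1 == 1L & r2 == 0L)
    cand_b <- which(r2 == 1L & r1 == 0L)
    if (!length(cand_a) || !length(cand_b)) next
    ia <- cand_a[sample.int(length(cand_a), 1)]
    ib <- cand_b[sample.int(length(cand_b), 1)]
    inc[gg[1], ia] <- 0L; inc[gg[1], ib] <- 1L
    inc[gg[2], ib] <- 0L; inc[gg[2], ia] <- 1L
    return(list(incidence = inc, swapped = TRUE))
  }
  list(incidence = inc, swapped = FALSE)
}

#' Data-stream (spatio-temporally restricted) permutation null
#'
#' Runs a cumulative chain of restricted swaps ([datastream_swap()]),
#' recording the statistic every `sample_every` successful swaps. Because
#' each step swaps a single pair, the data stream becomes increasingly
#' random while group sizes, per-individual observation counts, and the
#' time and place of every group stay fixed. The final permuted matrix is
#' returned for statistics too expensive to sample along the chain (e.g.
#' the stability curve).
#'
#' @param matrix A [group_matrix()].
#' @param statistic_fn Function `(matrix, phenotypes) -> numeric`; pass
#'   `phenotypes` via the argument below.
#' @param phenotypes Phenotype tibble forwarded to `statistic_fn`.
#' @param n_iter Total successful swaps (paper-scale default is 1e6; scale
#'   down for interactive use).
#' @param sample_every Record the statistic every this many swaps.
#' @param seed Integer seed.
#' @param burn_in Successful swaps discarded before sampling starts
#'   (default 0: the chain is sampled cumulatively from the first swap).
#' @return A `null_distribution` with the extra elements `final_matrix` and
#'   `n_skipped` (failed swap draws; these do not count as iterations).
#' @export
datastream_permutation_null <- function(matrix, statistic_fn, phenotypes,
                                        n_iter = 10000,
                                        sample_every = 100, seed = 1L,
                                        burn_in = 0) {
  observed <- statistic_fn(matrix, phenotypes)
  set.seed(seed)
  st <- swap_strata(matrix)
  if (!length(st$strata)) {
    stop("datastream_permutation_null: no valid swap exists", call. = FALSE)
  }
  inc <- matrix$incidence
  n_samples <- floor((n_iter - burn_in) / sample_every)
  samples <- base::matrix(NA_real_, n_samples, length(observed))
  colnames(samples) <- names(observed)
  skipped <- 0L
  done <- 0L
  row_i <- 0L
  work <- matrix
  nstrata <- length(st$strata)
  ## swaps are applied in place in this frame: `inc` keeps refcount 1, so
  ## element assignment does not copy the incidence matrix
  while (done < n_iter) {
    s <- st$strata[[sample.int(nstrata, 1, prob = st$prob)]]
    gg <- s[sample.int(length(s), 2)]
    r1 <- inc[gg[1], ]; r2 <- inc[gg[2], ]
    cand_a <- which(r1 == 1L & r2 == 0L)
    cand_b <- which(r2 == 1L & r1 == 0L)
    if (!length(cand_a) || !length(cand_b)) {
      skipped <- skipped + 1L
      if (skipped > 1000L && done == 0L) {
        stop("datastream_permutation_null: no valid swap found",
             call. = FALSE)
      }
      next
    }
    ia <- cand_a[sample.int(length(cand_a), 1)]
    ib <- cand_b[sample.int(length(cand_b), 1)]
    inc[gg[1], ia] <- 0L; inc[gg[1], ib] <- 1L
    inc[gg[2], ib] <- 0L; inc[gg[2], ia] <- 1L
    done <- done + 1L
    if (done > burn_in && (done - burn_in) %% sample_every == 0L &&
        row_i < n_samples) {
      row_i <- row_i + 1L
      work$incidence <- inc
      val <- tryCatch(statistic_fn(work, phenotypes), error = function(e) {
        stop(sprintf("statistic failed at iteration %d: %s", done,
                     conditionMessage(e)), call. = FALSE)
      })
      samples[row_i, ] <- val
    }
  }
  work$incidence <- inc
  out <- null_distribution("datastream_permutation", observed, samples,
                           n_iterations = n_iter,
                           sampling_interval = sample_every)
  out$final_matrix <- work
  out$n_skipped <- skipped
  out
}

#' Null-distribution container
#'
#' @param name Statistic/null name.
#' @param observed Observed statistic (scalar or per-bin vector).
#' @param samples Matrix of permuted statistic values (iterations x bins).
#' @param n_iterations,sampling_interval Chain bookkeeping.
#' @return An object of class `null_distribution` with the central 95%
#'   envelope and full range per bin.
#' @export
null_distribution <- function(name, observed, samples, n_iterations,
                              sampling_interval) {
  ## exact-level central interval: order statistics x_(k), x_(m+1-k) with
  ## k = floor(0.025 (m + 1)), so P(outside) <= 5% under exchangeability
  env_lo <- function(v) {
    v <- sort(v[!is.na(v)])
    v[max(1L, floor(0.025 * (length(v) + 1)))]
  }
  env_hi <- function(v) {
    v <- sort(v[!is.na(v)])
    v[length(v) + 1L - max(1L, floor(0.025 * (length(v) + 1)))]
  }
  lo <- apply(samples, 2, env_lo)
  hi <- apply(samples, 2, env_hi)
  rng <- apply(samples, 2, range, na.rm = TRUE)
  structure(list(
    name = name, observed = observed, samples = samples,
    envelope = tibble::tibble(bin = seq_along(observed),
                              lower = lo, upper = hi,
                              range_lo = rng[1, ], range_hi = rng[2, ]),
    n_iterations = n_iterations, sampling_interval = sampling_interval
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution: %s> %d samples x %d bin(s)\n", x$name,
              nrow(x$samples), ncol(x$samples)))
  print(tibble::tibble(observed = x$observed,
                       lower = x$envelope$lower, upper = x$envelope$upper))
  invisible(x)
}

outside_null <- function(observed, null, criterion) {
  env <- null$envelope
  if (length(observed) != nrow(env)) {
    stop("classify_effect: observed and null bins differ", call. = FALSE)
  }
  if (criterion == "envelope95") {
    any(observed < env$lower | observed > env$upper, na.rm = TRUE)
  } else {
    any(observed < env$range_lo | observed > env$range_hi, na.rm = TRUE)
  }
}

#' Attribute assortment to social or spatial processes
#'
#' Compares the observed statistic against the phenotypic node-label null
#' and the spatio-temporally restricted data-stream null. Differing from
#' both nulls indicates a social effect (phenotype-dependent grouping
#' decisions); differing only from the phenotypic null indicates a spatial
#' effect (phenotypes unevenly distributed in space but grouping random
#' given location); differing from neither indicates no effect. Differing
#' only from the data-stream null has no interpretation under this logic
#' and is flagged ambiguous.
#'
#' @param observed Observed statistic (scalar or per-bin vector).
#' @param node_null,stream_null `null_distribution` objects for the same
#'   statistic.
#' @param criterion `"envelope95"` (central 95% interval; default for
#'   scalars) or `"range"` (outside the entire permuted range; the
#'   convention for multi-bin profiles). By default `"envelope95"` is used
#'   for scalars and `"range"` for vectors.
#' @param trait Optional trait name recorded in the result.
#' @return A tibble of class `effect_classification`: `trait`, `statistic`,
#'   `verdict`, `outside_node_null`, `outside_stream_null`, `criterion`.
#' @export
classify_effect <- function(observed, node_null, stream_null,
                            criterion = NULL, trait = NA_character_) {
  if (is.null(criterion)) {
    criterion <- if (length(observed) > 1) "range" else "envelope95"
  }
  criterion <- match.arg(criterion, c("envelope95", "range"))
  out_node <- outside_null(observed, node_null, criterion)
  out_stream <- outside_null(observed, stream_null, criterion)
  verdict <- if (out_node && out_stream) {
    "social"
  } else if (out_node) {
    "spatial"
  } else if (out_stream) {
    "ambiguous"
  } else {
    "none"
  }
  out <- tibble::tibble(trait = trait, statistic = node_null$name,
                        verdict = verdict,
                        outside_node_null = out_node,
                        outside_stream_null = out_stream,
                        criterion = criterion)
  class(out) <- c("effect_classification", class(out))
  out
}

#' Assortativity statistic factory for permutation nulls
#'
#' Builds a `(matrix, phenotypes) -> r` closure computing the discrete
#' weighted assortativity of the simple-ratio network for one trait, for
#' use with [node_permutation_null()] and
#' [datastream_permutation_null()].
#'
#' @param trait Phenotype column name.
#' @return A statistic function.
#' @export
assortativity_statistic <- function(trait) {
  force(trait)
  ## node permutations leave the matrix untouched, so cache the network
  ## keyed on the incidence matrix
  cache <- new.env(parent = emptyenv())
  function(matrix, phenotypes) {
    if (is.null(cache$inc) || !identical(cache$inc, matrix$incidence)) {
      cache$inc <- matrix$incidence
      cache$net <- build_network(matrix)
    }
    v <- phenotypes[[trait]]
    v[v == "unknown"] <- NA
    lab <- setNames(as.character(v), phenotypes$individual_id)
    as.numeric(assortativity_discrete(cache$net, lab))
  }
}
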