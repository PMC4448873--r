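#' Per-pair lagged stability
#'
#' For two groups that both contain a focal individual, the proportion of
#' non-focal individuals consistent across the pair:
#' `shared / (only_first + only_second + shared)`, where `shared` counts
#' non-focal individuals present in both groups. A value of 0.5 corresponds
#' to two-thirds of a group remaining the same across two evenly sized
#' groups.
#'
#' @param shared_nonfocal Non-focal individuals in both groups.
#' @param only_first Individuals only in the first group.
#' @param only_second Individuals only in the second group.
#' @return Stability in `[0, 1]`; `NA` when both groups hold only the focal
#'   (the pair is excluded from curves).
#' @export
pair_stability <- function(shared_nonfocal, only_first, only_second) {
  stopifnot(shared_nonfocal >= 0, only_first >= 0, only_second >= 0)
  denom <- shared_nonfocal + only_first + only_second
  ifelse(denom > 0, shared_nonfocal / denom, NA_real_)
}

#' Log-spaced lag bins
#'
#' @param min_lag,max_lag Lag range in seconds.
#' @param n_bins Number of bins.
#' @return Numeric vector of bin edges (length `n_bins + 1`).
#' @export
log_lag_bins <- function(min_lag = 60, max_lag = 2 * 86400, n_bins = 12) {
  10^seq(log10(min_lag), log10(max_lag), length.out = n_bins + 1)
}

#' Lagged group-stability curve
#'
#' For every focal individual and every ordered pair of groups containing
#' it, separated by lag tau (difference of absolute group times), computes
#' the per-pair stability and averages within lag bins. Pairs must share at
#' least `min_shared` non-focal members ("at least one common member"
#' beyond the focal, by default) and at least one non-focal individual
#' overall. Group pairs are formed across feeders by default; restrict with
#' `within_feeder`.
#'
#' @param matrix A [group_matrix()] whose metadata carries `day` and
#'   `time_s` (absolute time = `(day - 1) * 86400 + time_s`).
#' @param lag_bins Bin edges in seconds, e.g. [log_lag_bins()].
#' @param min_shared Minimum non-focal shared members for a pair to count.
#' @param within_feeder If `TRUE`, only pairs at the same feeder are used.
#' @param per_focal If `TRUE`, average per focal first, then across focals;
#'   default pools all qualifying (focal, pair) contributions equally.
#' @return A tibble of class `stability_curve`: `lag_lo`, `lag_hi`,
#'   `lag_mid` (geometric midpoint), `s` (mean stability, `NA` for empty
#'   bins), `n_pairs` (contributing focal-pair count).
#' @export
stability_curve <- function(matrix, lag_bins = log_lag_bins(),
                            min_shared = 1, within_feeder = FALSE,
                            per_focal = FALSE) {
  stopifnot(inherits(matrix, "group_matrix"))
  inc <- matrix$incidence
  meta <- matrix$meta
  if (any(is.na(meta$time_s)) || any(is.na(meta$day))) {
    stop("stability_curve: group metadata must carry day and time_s",
         call. = FALSE)
  }
  tt <- (meta$day - 1) * 86400 + meta$time_s
  G <- nrow(inc)
  co <- tcrossprod(inc)          # shared members between groups
  sz <- rowSums(inc)
  pr <- which(upper.tri(co), arr.ind = TRUE)
  ## orient pairs so lag > 0
  flip <- tt[pr[, 1]] > tt[pr[, 2]]
  j <- ifelse(flip, pr[, 2], pr[, 1])
  k <- ifelse(flip, pr[, 1], pr[, 2])
  lag <- tt[k] - tt[j]
  if (within_feeder) {
    keep <- meta$feeder_id[j] == meta$feeder_id[k]
    j <- j[keep]; k <- k[keep]; lag <- lag[keep]
  }
  c_jk <- co[cbind(j, k)]
  ## focal must be shared: pairs with no common member cannot qualify
  keep <- c_jk >= 1 & lag > 0
  j <- j[keep]; k <- k[keep]; lag <- lag[keep]; c_jk <- c_jk[keep]
  shared_nonfocal <- c_jk - 1
  only_j <- sz[j] - c_jk
  only_k <- sz[k] - c_jk
  s <- pair_stability(shared_nonfocal, only_j, only_k)
  qualifies <- !is.na(s) & shared_nonfocal >= min_shared
  ## each of the c_jk shared individuals is a focal with identical s
  weight <- ifelse(qualifies, c_jk, 0)

  bin <- cut(lag, breaks = lag_bins, include.lowest = TRUE, labels = FALSE)
  out <- tibble::tibble(
    lag_lo = lag_bins[-length(lag_bins)],
    lag_hi = lag_bins[-1],
    lag_mid = sqrt(lag_bins[-length(lag_bins)] * lag_bins[-1])
  )
  if (per_focal) {
    ## expand to focal level: every shared individual of a qualifying pair
    idxq <- which(weight > 0 & !is.na(bin))
    if (length(idxq)) {
      foc <- purrr::map(idxq, function(i) {
        which(inc[j[i], ] == 1L & inc[k[i], ] == 1L)
      })
      df <- tibble::tibble(
        focal = unlist(foc),
        bin = rep(bin[idxq], lengths(foc)),
        s = rep(s[idxq], lengths(foc))
      ) |>
        dplyr::group_by(.data$bin, .data$focal) |>
        dplyr::summarise(s = mean(.data$s), n = dplyr::n(),
                         .groups = "drop") |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(s = mean(.data$s), n_pairs = sum(.data$n),
                         .groups = "drop")
      out$s <- df$s[match(seq_len(nrow(out)), df$bin)]
      out$n_pairs <- dplyr::coalesce(
        df$n_pairs[match(seq_len(nrow(out)), df$bin)], 0)
    } else {
      out$s <- NA_real_; out$n_pairs <- 0
    }
  } else {
    ok <- weight > 0 & !is.na(bin)
    num <- tapply(s[ok] * weight[ok], factor(bin[ok], seq_len(nrow(out))),
                  sum)
    den <- tapply(weight[ok], factor(bin[ok], seq_len(nrow(out))), sum)
    out$s <- as.numeric(num / den)
    out$n_pairs <- as.numeric(ifelse(is.na(den), 0, den))
  }
  class(out) <- c("stability_curve", class(out))
  out
}

#' Ratio of observed to permuted stability
#'
#' Observed stability per lag bin divided by the stability of a permuted
#' group matrix (conventionally the final matrix of a long data-stream
#' permutation chain). Ratios above 1 indicate non-random persistence.
#'
#' @param observed,permuted `stability_curve` tibbles on identical bins.
#' @return Tibble with `lag_mid`, `s_observed`, `s_permuted`, `ratio`
#'   (`NA` with a flag where the permuted value is 0 or missing).
#' @export
stability_ratio <- function(observed, permuted) {
  if (nrow(observed) != nrow(permuted) ||
      any(abs(observed$lag_lo - permuted$lag_lo) > 1e-9)) {
    stop("stability_ratio: lag bins differ", call. = FALSE)
  }
  ratio <- ifelse(!is.na(permuted$s) & permuted$s > 0,
                  observed$s / permuted$s, NA_real_)
  tibble::tibble(
    lag_lo = observed$lag_lo, lag_hi = observed$lag_hi,
    lag_mid = observed$lag_mid,
    s_observed = observed$s, s_permuted = permuted$s,
    ratio = ratio,
    undefined = is.na(ratio) & !is.na(observed$s)
  )
}

#' Group-size summaries
#'
#' @param matrix A [group_matrix()].
#' @return Tibble with `mean_size`, `max_size`, and `typical_size` (the
#'   group size experienced by the average individual, `sum(n^2)/sum(n)`).
#' @export
group_size_summaries <- function(matrix) {
  sz <- group_sizes(matrix)
  if (!length(sz)) stop("group_size_summaries: no groups", call. = FALSE)
  tibble::tibble(mean_size = mean(sz), max_size = max(sz),
                 typical_size = sum(sz^2) / sum(sz))
}

#' Bin group sizes into size classes
#'
#' Small sizes stay as singleton classes; sizes of `start_binning_at` and
#' above are merged greedily upward until each class carries at least
#' `min_share` of all group memberships (a group of size n contributes n
#' memberships). The last class absorbs any remainder.
#'
#' @param matrix A [group_matrix()] (or an integer vector of group sizes).
#' @param start_binning_at First size eligible for merging (default 14:
#'   sizes up to 13 stay unbinned).
#' @param min_share Minimum share of total memberships per merged class.
#' @return Tibble of class `size_binning`: `bin`, `size_lo`, `size_hi`,
#'   `n_groups`, `memberships`, `share`.
#' @export
bin_group_sizes <- function(matrix, start_binning_at = 14,
                            min_share = 0.05) {
  sz <- if (inherits(matrix, "group_matrix")) group_sizes(matrix) else matrix
  stopifnot(all(sz >= 1))
  total <- sum(sz)
  tab <- table(sz)
  sizes <- as.integer(names(tab))
  members <- as.integer(tab) * sizes
  bins <- list()
  small <- sizes < start_binning_at
  for (i in which(small)) {
    bins[[length(bins) + 1]] <- c(sizes[i], sizes[i])
  }
  large <- which(!small)
  if (length(large)) {
    lo <- sizes[large[1]]; acc <- 0
    for (i in large) {
      acc <- acc + members[i]
      if (acc / total >= min_share) {
        bins[[length(bins) + 1]] <- c(lo, sizes[i])
        if (i != large[length(large)]) lo <- sizes[large[large > i][1]]
        acc <- 0
      }
    }
    if (acc > 0) {
      ## remainder under threshold: absorb into the previous class
      last <- bins[[length(bins)]]
      if (last[1] >= start_binning_at) {
        bins[[length(bins)]] <- c(last[1], sizes[length(sizes)])
      } else {
        bins[[length(bins) + 1]] <- c(lo, sizes[length(sizes)])
      }
    }
  }
  out <- purrr::map_dfr(seq_along(bins), function(i) {
    b <- bins[[i]]
    in_bin <- sz >= b[1] & sz <= b[2]
    tibble::tibble(bin = i, size_lo = b[1], size_hi = b[2],
                   n_groups = sum(in_bin),
                   memberships = sum(sz[in_bin]))
  })
  out$share <- out$memberships / total
  class(out) <- c("size_binning", class(out))
  out
}

assign_bins <- function(sizes, binning) {
  idx <- rep(NA_integer_, length(sizes))
  for (i in seq_len(nrow(binning))) {
    idx[sizes >= binning$size_lo[i] & sizes <= binning$size_hi[i]] <-
      binning$bin[i]
  }
  idx
}

phenotype_class_vector <- function(phenotypes, trait, focal_level) {
  v <- phenotypes[[trait]]
  if (is.null(v)) stop("unknown trait: ", trait, call. = FALSE)
  known <- !is.na(v) & v != "unknown"
  out <- rep(NA, nrow(phenotypes))
  out[known] <- v[known] == focal_level
  setNames(out, phenotypes$individual_id)
}

#' Per-size-class composition profile for a binary phenotype class
#'
#' For each group, the proportion of its known-phenotype members belonging
#' to the focal class; pooled as the mean per group-size class. Groups with
#' no known-phenotype member contribute nothing.
#'
#' @param matrix A [group_matrix()].
#' @param phenotypes Phenotype tibble (`individual_id` plus the trait
#'   column). Unknown/`NA` phenotypes are excluded.
#' @param binning A [bin_group_sizes()] result.
#' @param trait Column name, e.g. `"sex"`.
#' @param focal_level Level counted in the numerator, e.g. `"male"`.
#' @return Tibble: `bin`, `size_lo`, `size_hi`, `n_groups`,
#'   `mean_proportion`.
#' @export
class_proportion_profile <- function(matrix, phenotypes, binning, trait,
                                     focal_level) {
  inc <- matrix$incidence
  cls <- phenotype_class_vector(phenotypes, trait, focal_level)
  cls <- cls[colnames(inc)]
  known <- !is.na(cls)
  n_known <- inc[, known, drop = FALSE] %*% rep(1, sum(known))
  n_focal <- inc[, known, drop = FALSE] %*% ifelse(cls[known], 1, 0)
  prop <- ifelse(n_known > 0, n_focal / n_known, NA_real_)
  bin <- assign_bins(rowSums(inc), binning)
  tibble::tibble(bin = bin, prop = as.numeric(prop)) |>
    dplyr::filter(!is.na(.data$bin), !is.na(.data$prop)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_groups = dplyr::n(),
                     mean_proportion = mean(.data$prop),
                     .groups = "drop") |>
    dplyr::left_join(binning[c("bin", "size_lo", "size_hi")], by = "bin") |>
    dplyr::select("bin", "size_lo", "size_hi", "n_groups",
                  "mean_proportion")
}

#' Binomial within-group composition probability
#'
#' Probability of observing exactly `k` focal-class members in a group of
#' size `n` when each member is focal-class with probability `p`:
#' `choose(n, k) p^k (1 - p)^(n - k)`. Values near 0.5 indicate
#' disassortment (even mixes); values near 0 indicate strongly assorted
#' (single-class) groups.
#'
#' @param n Group size.
#' @param k Focal-class count in the group.
#' @param p Class probability (share of the focal class among unique
#'   individuals seen in groups of this size).
#' @return The binomial probability.
#' @export
binomial_composition_probability <- function(n, k, p) {
  if (any(k < 0 | k > n)) {
    stop("binomial_composition_probability: need 0 <= k <= n",
         call. = FALSE)
  }
  stopifnot(all(p >= 0 & p <= 1))
  ## direct product form: exact for the small n used per group
  choose(n, k) * p^k * (1 - p)^(n - k)
}

#' Mean binomial composition probability per size class
#'
#' For every group, the binomial probability of its observed focal-class
#' count, with the class probability estimated per group size as the focal
#' share of unique individuals appearing in groups of that size; then the
#' mean per size class. Higher means (closer to 0.5) = more disassorted.
#'
#' @inheritParams class_proportion_profile
#' @return Tibble: `bin`, `size_lo`, `size_hi`, `n_groups`, `mean_binom_p`.
#' @export
composition_binomial_profile <- function(matrix, phenotypes, binning, trait,
                                         focal_level) {
  inc <- matrix$incidence
  cls <- phenotype_class_vector(phenotypes, trait, focal_level)
  cls <- cls[colnames(inc)]
  known <- !is.na(cls)
  inck <- inc[, known, drop = FALSE]
  clsk <- cls[known]
  sizes <- rowSums(inc)
  n_known <- as.numeric(inck %*% rep(1, ncol(inck)))
  k_focal <- as.numeric(inck %*% ifelse(clsk, 1, 0))
  ## p per group size: focal share of unique individuals in that size
  p_by_size <- vapply(sort(unique(sizes)), function(s) {
    present <- colSums(inck[sizes == s, , drop = FALSE]) > 0
    if (!any(present)) return(NA_real_)
    mean(clsk[present])
  }, numeric(1))
  names(p_by_size) <- sort(unique(sizes))
  p <- p_by_size[as.character(sizes)]
  ok <- n_known > 0 & !is.na(p)
  pr <- rep(NA_real_, length(sizes))
  pr[ok] <- binomial_composition_probability(n_known[ok], k_focal[ok],
                                             p[ok])
  bin <- assign_bins(sizes, binning)
  tibble::tibble(bin = bin, pr = pr) |>
    dplyr::filter(!is.na(.data$bin), !is.na(.data$pr)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_groups = dplyr::n(), mean_binom_p = mean(.data$pr),
                     .groups = "drop") |>
    dplyr::left_join(binning[c("bin", "size_lo", "size_hi")], by = "bin") |>
    dplyr::select("bin", "size_lo", "size_hi", "n_groups", "mean_binom_p")
}

#' Pearson (non-excess) kurtosis
#'
#' Population-moment kurtosis `m4 / m2^2`; a normal distribution scores 3,
#' peaked distributions score higher.
#'
#' @param x Numeric vector.
#' @return Kurtosis, or `NA` when the variance is zero.
#' @export
pearson_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m2 <- mean((x - mean(x))^2)
  if (m2 <= .Machine$double.eps) return(NA_real_)
  mean((x - mean(x))^4) / m2^2
}

#' Size-assortment kurtosis per group-size class
#'
#' For each group, the mean trait value of its (optionally class-filtered)
#' members; per size class, the Pearson kurtosis of those group means. High
#' kurtosis = peaked distribution of group means = size-assorted groups.
#'
#' @param matrix A [group_matrix()].
#' @param trait Named numeric vector of per-individual trait values (e.g.
#'   the body-size PC1 from [body_size_pc1()]); names = individual ids.
#' @param binning A [bin_group_sizes()] result.
#' @param min_groups Minimum groups per class to evaluate (default 4).
#' @return Tibble: `bin`, `size_lo`, `size_hi`, `n_groups`, `kurtosis`
#'   (`NA` and flagged when degenerate).
#' @export
kurtosis_assortment <- function(matrix, trait, binning, min_groups = 4) {
  inc <- matrix$incidence
  tr <- trait[colnames(inc)]
  known <- !is.na(tr)
  inck <- inc[, known, drop = FALSE]
  n_known <- as.numeric(inck %*% rep(1, ncol(inck)))
  sum_tr <- as.numeric(inck %*% tr[known])
  gmean <- ifelse(n_known > 0, sum_tr / n_known, NA_real_)
  bin <- assign_bins(rowSums(inc), binning)
  tibble::tibble(bin = bin, gmean = gmean) |>
    dplyr::filter(!is.na(.data$bin), !is.na(.data$gmean)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      kurtosis = if (dplyr::n() >= min_groups) {
        pearson_kurtosis(.data$gmean)
      } else NA_real_,
      .groups = "drop") |>
    dplyr::left_join(binning[c("bin", "size_lo", "size_hi")], by = "bin") |>
    dplyr::mutate(degenerate = is.na(.data$kurtosis)) |>
    dplyr::select("bin", "size_lo", "size_hi", "n_groups", "kurtosis",
                  "degenerate")
}

#' Within-sex body-size principal component
#'
#' Standardizes wing and tarsus within each sex, takes the first principal
#' component of the two standardized measures, orients it so that it
#' correlates positively with wing, and rescales scores to mean 0 and
#' variance 1 within sex. Individuals missing either measure, of unknown
#' sex, or in a sex with fewer than two measured birds get `NA`.
#'
#' @param phenotypes Phenotype tibble with `individual_id`, `sex`, `wing`,
#'   `tarsus`.
#' @return Named numeric vector of standardized PC1 scores.
#' @export
body_size_pc1 <- function(phenotypes) {
  out <- setNames(rep(NA_real_, nrow(phenotypes)),
                  phenotypes$individual_id)
  for (s in c("male", "female")) {
    rows <- which(phenotypes$sex == s & !is.na(phenotypes$wing) &
                    !is.na(phenotypes$tarsus))
    if (length(rows) < 2) next
    m <- scale(cbind(wing = phenotypes$wing[rows],
                     tarsus = phenotypes$tarsus[rows]))
    if (any(!is.finite(m))) next   # zero variance in a measure
    pc <- prcomp(m, center = FALSE, scale. = FALSE)
    score <- pc$x[, 1]
    if (stats::cor(score, m[, "wing"]) < 0) score <- -score
    score <- as.numeric(scale(score))
    out[phenotypes$individual_id[rows]] <- score
  }
  out
}
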