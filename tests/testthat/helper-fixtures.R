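# Shared fixtures and independent oracles used across test files.

# Tiny group matrix from a list of member vectors, with optional metadata.
toy_matrix <- function(groups, feeder = NULL, period = NULL, day = NULL,
                       time = NULL) {
  n <- length(groups)
  ids <- sprintf("g%02d", seq_len(n))
  mem <- tibble::tibble(
    group_id = rep(ids, lengths(groups)),
    individual_id = unlist(groups, use.names = FALSE)
  )
  meta <- tibble::tibble(
    group_id = ids,
    feeder_id = feeder %||% rep("F01", n),
    sampling_period = period %||% rep(1L, n),
    day = day %||% rep(1L, n),
    time_s = time %||% as.numeric(seq_len(n) * 1000)
  )
  group_matrix(mem, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random toy association network with labelled nodes.
random_toy_network <- function(n_nodes = 10, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n_nodes, n_nodes)
  ids <- letters[seq_len(n_nodes)]
  dimnames(w) <- list(ids, ids)
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1)
    }
  }
  structure(w, class = c("association_network", class(w)))
}

# Brute-force discrete assortativity: assemble the mixing matrix edge by
# edge, independent of the package implementation.
brute_assortativity_discrete <- function(w, labels) {
  labels <- labels[rownames(w)]
  keep <- !is.na(labels)
  w <- w[keep, keep, drop = FALSE]
  labels <- factor(labels[keep])
  lv <- levels(labels)
  e <- matrix(0, length(lv), length(lv))
  tw <- 0
  for (i in seq_len(nrow(w) - 1)) {
    for (j in (i + 1):nrow(w)) tw <- tw + w[i, j]
  }
  for (i in seq_len(nrow(w) - 1)) {
    for (j in (i + 1):nrow(w)) {
      if (w[i, j] > 0) {
        ci <- which(lv == labels[i]); cj <- which(lv == labels[j])
        e[ci, cj] <- e[ci, cj] + w[i, j] / (2 * tw)
        e[cj, ci] <- e[cj, ci] + w[i, j] / (2 * tw)
      }
    }
  }
  ab <- sum(rowSums(e) * colSums(e))
  (sum(diag(e)) - ab) / (1 - ab)
}

# Brute-force continuous assortativity: weighted Pearson correlation over
# ordered dyads, computed from first principles.
brute_assortativity_continuous <- function(w, values) {
  values <- values[rownames(w)]
  xi <- c(); xj <- c(); ww <- c()
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) {
      if (i != j && w[i, j] > 0) {
        xi <- c(xi, values[i]); xj <- c(xj, values[j])
        ww <- c(ww, w[i, j])
      }
    }
  }
  mx <- sum(ww * xi) / sum(ww); my <- sum(ww * xj) / sum(ww)
  cov <- sum(ww * (xi - mx) * (xj - my)) / sum(ww)
  vx <- sum(ww * (xi - mx)^2) / sum(ww)
  vy <- sum(ww * (xj - my)^2) / sum(ww)
  cov / sqrt(vx * vy)
}

# Exhaustive stability-curve enumeration: loop over every focal individual
# and every pair of groups containing it; no matrix algebra.
brute_stability_curve <- function(mat, lag_bins, min_shared = 1) {
  inc <- mat$incidence
  tt <- (mat$meta$day - 1) * 86400 + mat$meta$time_s
  nb <- length(lag_bins) - 1
  svals <- vector("list", nb)
  inds <- colnames(inc)
  for (x in inds) {
    gx <- which(inc[, x] == 1L)
    if (length(gx) < 2) next
    for (a in seq_len(length(gx) - 1)) {
      for (b in (a + 1):length(gx)) {
        j <- gx[a]; k <- gx[b]
        if (tt[j] == tt[k]) next
        if (tt[j] > tt[k]) { tmp <- j; j <- k; k <- tmp }
        lag <- tt[k] - tt[j]
        A <- which(inc[j, ] == 1L); B <- which(inc[k, ] == 1L)
        shared_nonfocal <- length(setdiff(intersect(A, B), match(x, inds)))
        only_j <- length(setdiff(A, B)); only_k <- length(setdiff(B, A))
        if (shared_nonfocal < min_shared) next
        denom <- shared_nonfocal + only_j + only_k
        if (denom == 0) next
        bin <- findInterval(lag, lag_bins, rightmost.closed = TRUE)
        if (bin < 1 || bin > nb) next
        svals[[bin]] <- c(svals[[bin]], shared_nonfocal / denom)
      }
    }
  }
  tibble::tibble(
    bin = seq_len(nb),
    s = vapply(svals, function(v) if (length(v)) mean(v) else NA_real_,
               numeric(1)),
    n_pairs = lengths(svals)
  )
}

# Small neutral simulation reused by several files.
small_sim <- function(seed = 1, ...) {
  args <- list(n_individuals = 60, n_feeders = 9, n_periods = 2,
               gatherings_per_feeder_day = 8, home_range_sd = 200,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  simulate_detections(do.call(sim_config, args))
}

truth_matrix <- function(sim) {
  group_matrix(sim$truth$memberships, sim$truth$groups)
}
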