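#' Simple-ratio association index
#'
#' The fraction of sampling events (gathering events, under the gambit of
#' the group) in which a dyad was observed together, out of all events in
#' which at least one of the two was observed: `x / (x + y_a + y_b)`. Scales
#' from 0 (never observed together) to 1 (always observed together).
#'
#' @param x Count of groups containing both individuals.
#' @param y_a Count of groups containing only the first individual.
#' @param y_b Count of groups containing only the second individual.
#' @return The index, in `[0, 1]`. Dyads with all counts zero are undefined
#'   and return 0 with attribute `undefined = TRUE`.
#' @export
simple_ratio_index <- function(x, y_a, y_b) {
  stopifnot(x >= 0, y_a >= 0, y_b >= 0)
  tot <- x + y_a + y_b
  if (tot == 0) {
    return(structure(0, undefined = TRUE))
  }
  x / tot
}

#' Build the weighted association network
#'
#' Computes the simple-ratio index for every dyad from a group-by-individual
#' matrix. The sampling unit is the gathering event: a dyad is "together"
#' in a group containing both, and "apart" in a group containing exactly one
#' of the two.
#'
#' @param matrix A [group_matrix()].
#' @return An object of class `association_network`: a symmetric numeric
#'   matrix of indices with zero diagonal, node ids as dimnames.
#' @export
build_network <- function(matrix) {
  stopifnot(inherits(matrix, "group_matrix"))
  inc <- matrix$incidence
  if (nrow(inc) == 0 || ncol(inc) == 0) {
    stop("build_network: empty group matrix", call. = FALSE)
  }
  together <- crossprod(inc)            # co-occurrence counts
  n_obs <- diag(together)               # per-individual group counts
  either <- outer(n_obs, n_obs, `+`) - together
  w <- ifelse(either > 0, together / either, 0)
  diag(w) <- 0
  structure(w, class = c("association_network", class(w)))
}

#' @export
print.association_network <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<association_network> %d nodes, %d positive edges, density %.3f\n",
              n, sum(x[upper.tri(x)] > 0),
              if (n >= 2) network_density(x) else NA_real_))
  invisible(x)
}

#' Edge list of an association network
#' @param network An `association_network`.
#' @param keep_zero Keep never-co-observed dyads? Default drops them.
#' @return Tibble `from`, `to`, `weight` (undirected, `from < to`).
#' @export
network_edges <- function(network, keep_zero = FALSE) {
  ids <- rownames(network)
  idx <- which(upper.tri(network), arr.ind = TRUE)
  out <- tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]],
                        weight = network[idx])
  if (!keep_zero) out <- dplyr::filter(out, .data$weight > 0)
  out
}

#' Proportion of realized dyadic edges
#'
#' @param network An `association_network`.
#' @return Count of positive edges over `n (n - 1) / 2`.
#' @export
network_density <- function(network) {
  n <- nrow(network)
  if (n < 2) stop("network_density: need at least two nodes", call. = FALSE)
  sum(network[upper.tri(network)] > 0) / (n * (n - 1) / 2)
}

#' Discrete (categorical) weighted assortativity
#'
#' Newman's assortativity coefficient generalised to weighted edges: the
#' mixing matrix `e` holds the fraction of total edge weight connecting each
#' pair of classes (each undirected edge contributing symmetrically), and
#' `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)` where `a`, `b`
#' are the marginals. Nodes with missing labels are excluded from the mixing
#' matrix (they stay in the network; they carry no label information).
#'
#' @param network An `association_network`.
#' @param labels Named character/factor vector of class labels (names =
#'   node ids), or an unnamed vector aligned to the network's nodes. `NA` =
#'   unknown, excluded.
#' @return `r`, with the mixing matrix and marginals attached as attributes
#'   `mixing`, `a`, `b`.
#' @export
assortativity_discrete <- function(network, labels) {
  lab <- align_labels(network, labels)
  keep <- !is.na(lab)
  w <- unclass(network)[keep, keep, drop = FALSE]
  lab <- factor(lab[keep])
  if (sum(w[upper.tri(w)] > 0) < 1) {
    stop("assortativity_discrete: no positive edges among labelled nodes",
         call. = FALSE)
  }
  k <- nlevels(lab)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  tw <- sum(w[idx])
  ci <- as.integer(lab[idx[, 1]]); cj <- as.integer(lab[idx[, 2]])
  ww <- w[idx] / (2 * tw)
  ## each undirected edge contributes half weight to e[ci,cj] and e[cj,ci]
  e <- matrix(0, k, k, dimnames = list(levels(lab), levels(lab)))
  acc <- tapply(c(ww, ww),
                list(factor(c(ci, cj), seq_len(k)),
                     factor(c(cj, ci), seq_len(k))), sum)
  e[] <- ifelse(is.na(acc), 0, acc)
  a <- rowSums(e); b <- colSums(e)
  ab <- sum(a * b)
  if (abs(1 - ab) < .Machine$double.eps^0.5) {
    stop("assortativity_discrete: single class among connected nodes; r undefined",
         call. = FALSE)
  }
  r <- (sum(diag(e)) - ab) / (1 - ab)
  structure(r, mixing = e, a = a, b = b)
}

#' Continuous-trait weighted assortativity
#'
#' Weighted Pearson correlation of trait values at the two ends of every
#' edge, taken over ordered dyads with edge weights as frequencies (the
#' continuous counterpart of the discrete mixing-matrix coefficient).
#'
#' @param network An `association_network`.
#' @param values Named numeric vector of trait values (names = node ids) or
#'   unnamed vector aligned to nodes. `NA` = unknown, excluded.
#' @return `r` in `[-1, 1]`.
#' @export
assortativity_continuous <- function(network, values) {
  x <- align_labels(network, values, numeric_ok = TRUE)
  keep <- !is.na(x)
  w <- unclass(network)[keep, keep, drop = FALSE]
  x <- as.numeric(x[keep])
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) < 1) {
    stop("assortativity_continuous: no positive edges among scored nodes",
         call. = FALSE)
  }
  ## ordered dyads: each undirected edge contributes (i,j) and (j,i)
  wi <- w[idx]
  xi <- c(x[idx[, 1]], x[idx[, 2]])
  xj <- c(x[idx[, 2]], x[idx[, 1]])
  ww <- c(wi, wi)
  m <- sum(ww * xi) / sum(ww)
  v <- sum(ww * (xi - m)^2) / sum(ww)
  if (v <= .Machine$double.eps) {
    stop("assortativity_continuous: zero weighted trait variance; r undefined",
         call. = FALSE)
  }
  cov <- sum(ww * (xi - m) * (xj - m)) / sum(ww)
  cov / v
}

align_labels <- function(network, labels, numeric_ok = FALSE) {
  ids <- rownames(network)
  if (!is.null(names(labels))) {
    out <- labels[ids]
    names(out) <- ids
  } else {
    if (length(labels) != nrow(network)) {
      stop("labels must be named by node id or aligned to the network",
           call. = FALSE)
    }
    out <- setNames(labels, ids)
  }
  out
}

#' Write an association network to GraphML and/or square CSV
#'
#' @param network An `association_network`.
#' @param graphml Optional path for GraphML output (edge attribute `sri`).
#' @param csv Optional path for a square CSV with id header row/column.
#' @return The network, invisibly.
#' @export
write_network <- function(network, graphml = NULL, csv = NULL) {
  if (!is.null(graphml)) {
    g <- igraph::graph_from_adjacency_matrix(unclass(network),
                                             mode = "undirected",
                                             weighted = "sri", diag = FALSE)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(csv)) {
    df <- as.data.frame(unclass(network))
    df <- cbind(id = rownames(network), df)
    readr::write_csv(tibble::as_tibble(df), csv)
  }
  invisible(network)
}
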