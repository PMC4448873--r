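test_that("simple-ratio index matches its definition and bounds", {
  expect_equal(simple_ratio_index(5, 0, 0), 1)   # always together
  expect_equal(simple_ratio_index(0, 5, 5), 0)   # never together
  expect_equal(simple_ratio_index(2, 1, 1), 0.5)
  und <- simple_ratio_index(0, 0, 0)
  expect_equal(as.numeric(und), 0)
  expect_true(attr(und, "undefined"))
  expect_error(simple_ratio_index(-1, 0, 0))
})

test_that("build_network counts co-occurrences correctly", {
  m <- toy_matrix(list(c("a", "b"), c("a", "b"), c("a", "c")))
  net <- build_network(m)
  expect_equal(net["a", "b"], 2 / 3)
  expect_equal(net["a", "c"], 1 / 3)
  expect_equal(net["b", "c"], 0)
  expect_equal(net, t(net), ignore_attr = TRUE)
  expect_equal(unname(diag(net)), rep(0, 3))

  one <- build_network(toy_matrix(list(c("a", "b", "c"))))
  expect_true(all(one[upper.tri(one)] == 1))

  apart <- build_network(toy_matrix(list("a", "b", "a", "b")))
  expect_true(all(apart == 0))
})

test_that("network weights are invariant to group-row shuffling", {
  sim <- small_sim(seed = 40, n_periods = 1)
  m <- truth_matrix(sim)
  net <- build_network(m)
  set.seed(1)
  shuf <- m
  ord <- sample(nrow(m$incidence))
  shuf$incidence <- m$incidence[ord, ]
  shuf$meta <- m$meta[ord, ]
  net2 <- build_network(shuf)
  expect_equal(net2[rownames(net), colnames(net)], unclass(net),
               ignore_attr = TRUE)
})

test_that("discrete assortativity handles perfect assortment and disassortment", {
  ## two same-class cliques, no between-class edges
  m <- toy_matrix(list(c("a", "b", "c"), c("d", "e", "f")))
  net <- build_network(m)
  lab <- setNames(rep(c("x", "y"), each = 3), letters[1:6])
  expect_equal(as.numeric(assortativity_discrete(net, lab)), 1)

  ## complete bipartite male-female network with equal weights
  w <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  w["a", "c"] <- w["a", "d"] <- w["b", "c"] <- w["b", "d"] <- 0.5
  w <- w + t(w)
  net2 <- structure(w, class = c("association_network", class(w)))
  lab2 <- setNames(c("m", "m", "f", "f"), letters[1:4])
  expect_equal(as.numeric(assortativity_discrete(net2, lab2)), -1)
})

test_that("discrete assortativity equals the hand-built mixing matrix", {
  ## a-b (w=1, both class1), b-c (w=1, class1-class2):
  ## e = [[1/2, 1/4], [1/4, 0]], a = (3/4, 1/4)
  ## r = (1/2 - (3/4 * 3/4 + 1/4 * 1/4)) / (1 - (9/16 + 1/16)) = -1/3
  w <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  w["a", "b"] <- w["b", "a"] <- 1
  w["b", "c"] <- w["c", "b"] <- 1
  net <- structure(w, class = c("association_network", class(w)))
  lab <- setNames(c("c1", "c1", "c2"), c("a", "b", "c"))
  r <- assortativity_discrete(net, lab)
  expect_equal(as.numeric(r), -1 / 3)
  e <- attr(r, "mixing")
  expect_equal(sum(e), 1)
  expect_equal(e["c1", "c1"], 0.5)
  expect_equal(e["c1", "c2"], 0.25)

  ## random toy networks against the brute-force oracle
  for (seed in 1:5) {
    net <- random_toy_network(10, 0.5, seed)
    set.seed(seed + 100)
    lab <- setNames(sample(c("u", "v"), 10, replace = TRUE),
                    rownames(net))
    if (length(unique(lab)) < 2) next
    expect_equal(as.numeric(assortativity_discrete(net, lab)),
                 brute_assortativity_discrete(net, lab),
                 tolerance = 1e-12)
  }
})

test_that("discrete assortativity errors on a single class", {
  m <- toy_matrix(list(c("a", "b")))
  net <- build_network(m)
  expect_error(assortativity_discrete(net, setNames(c("x", "x"),
                                                    c("a", "b"))),
               "single class")
})

test_that("unknown labels are excluded from assortativity but stay in the network", {
  m <- toy_matrix(list(c("a", "b"), c("a", "b"), c("b", "c"), c("a", "c"),
                       c("c", "d")))
  net <- build_network(m)
  expect_equal(nrow(net), 4)
  lab_all <- setNames(c("x", "y", "x", "y"), c("a", "b", "c", "d"))
  lab_na <- lab_all; lab_na["d"] <- NA
  r_na <- as.numeric(assortativity_discrete(net, lab_na))
  sub <- unclass(net)[c("a", "b", "c"), c("a", "b", "c")]
  subnet <- structure(sub, class = c("association_network", class(sub)))
  r_sub <- as.numeric(assortativity_discrete(subnet, lab_all[1:3]))
  expect_equal(r_na, r_sub)
})

test_that("continuous assortativity matches the weighted-correlation oracle", {
  ## trait identical at both ends of every edge -> r = 1
  m <- toy_matrix(list(c("a", "b"), c("c", "d"), c("a", "b")))
  net <- build_network(m)
  vals <- setNames(c(1, 1, 5, 5), c("a", "b", "c", "d"))
  expect_equal(assortativity_continuous(net, vals), 1)

  ## single dyad with distinct values -> r = -1
  one <- build_network(toy_matrix(list(c("a", "b"), "a", "b")))
  expect_equal(assortativity_continuous(one, setNames(c(0, 2),
                                                      c("a", "b"))), -1)
  ## zero variance -> error
  expect_error(assortativity_continuous(one, setNames(c(3, 3),
                                                      c("a", "b"))),
               "variance")

  ## random traits on random toy networks
  for (seed in 1:5) {
    net <- random_toy_network(10, 0.6, seed)
    set.seed(seed + 200)
    vals <- setNames(rnorm(10), rownames(net))
    expect_equal(assortativity_continuous(net, vals),
                 brute_assortativity_continuous(net, vals),
                 tolerance = 1e-12)
  }
})

test_that("discrete equals continuous with 0/1 coding on binary traits", {
  for (seed in 1:5) {
    net <- random_toy_network(10, 0.6, seed)
    set.seed(seed + 300)
    lab <- setNames(sample(c("u", "v"), 10, replace = TRUE),
                    rownames(net))
    if (length(unique(lab)) < 2) next
    r_disc <- as.numeric(assortativity_discrete(net, lab))
    r_cont <- assortativity_continuous(net,
                                       setNames(as.numeric(lab == "u"),
                                                names(lab)))
    expect_equal(r_disc, r_cont, tolerance = 1e-10)
  }
})

test_that("assortativity is invariant to node order", {
  net <- random_toy_network(8, 0.6, 7)
  set.seed(7)
  lab <- setNames(sample(c("u", "v"), 8, replace = TRUE), rownames(net))
  vals <- setNames(rnorm(8), rownames(net))
  ord <- sample(8)
  p <- unclass(net)[ord, ord]
  pnet <- structure(p, class = c("association_network", class(p)))
  expect_equal(as.numeric(assortativity_discrete(net, lab)),
               as.numeric(assortativity_discrete(pnet, lab)))
  expect_equal(assortativity_continuous(net, vals),
               assortativity_continuous(pnet, vals))
})

test_that("network density counts positive edges over possible dyads", {
  full <- build_network(toy_matrix(list(c("a", "b", "c"))))
  expect_equal(network_density(full), 1)
  empty <- build_network(toy_matrix(list("a", "b", "a")))
  expect_equal(network_density(empty), 0)
  ## 4 nodes, 3 positive edges -> 0.5
  m <- toy_matrix(list(c("a", "b"), c("a", "c"), c("a", "d")))
  expect_equal(network_density(build_network(m)), 0.5)
  one_node <- matrix(0, 1, 1, dimnames = list("a", "a"))
  expect_error(network_density(one_node), "two nodes")
})

test_that("networks round-trip to GraphML and square CSV", {
  m <- toy_matrix(list(c("a", "b"), c("a", "b"), c("a", "c")))
  net <- build_network(m)
  gml <- tempfile(fileext = ".graphml")
  csv <- tempfile(fileext = ".csv")
  write_network(net, graphml = gml, csv = csv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(igraph::edge_attr(g, "sri")), sort(c(1 / 3, 2 / 3)))
  df <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(df$id, c("a", "b", "c"))
  expect_equal(df$b[1], 2 / 3)
  unlink(c(gml, csv))
})
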