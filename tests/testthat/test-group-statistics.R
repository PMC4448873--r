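test_that("pair stability matches the defining ratio", {
  ## {X,A,B} vs {X,A,C}: 1 shared non-focal, 1 exclusive each side
  expect_equal(pair_stability(1, 1, 1), 1 / 3)
  ## identical membership
  expect_equal(pair_stability(8, 0, 0), 1)
  ## two groups of 13 sharing 9 members incl. the focal
  expect_equal(pair_stability(8, 4, 4), 0.5)
  ## both groups only the focal: excluded
  expect_true(is.na(pair_stability(0, 0, 0)))
  ## bounds and symmetry in the two exclusive counts
  expect_equal(pair_stability(3, 2, 5), pair_stability(3, 5, 2))
  for (v in list(c(0, 3, 2), c(5, 0, 0), c(2, 2, 2))) {
    s <- pair_stability(v[1], v[2], v[3])
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("stability curve equals exhaustive pair enumeration", {
  ## crafted 5-group fixture across two feeders
  m <- toy_matrix(
    list(c("x", "a", "b"), c("x", "a", "c"), c("x", "d", "e"),
         c("a", "b", "c", "x"), c("b", "c")),
    feeder = c("F01", "F01", "F02", "F01", "F02"),
    day = c(1L, 1L, 1L, 2L, 2L),
    time = c(1000, 4000, 9000, 2000, 5000))
  bins <- log_lag_bins(60, 2 * 86400, 8)
  got <- stability_curve(m, bins, min_shared = 1)
  want <- brute_stability_curve(m, bins, min_shared = 1)
  expect_equal(got$s, want$s)
  expect_equal(got$n_pairs, as.numeric(want$n_pairs))

  ## and on a larger random fixture (<= 200 groups)
  sim <- small_sim(seed = 50, n_periods = 1)
  ms <- truth_matrix(sim)
  keep <- seq_len(min(150, nrow(ms$incidence)))
  sub <- ms
  sub$incidence <- ms$incidence[keep, , drop = FALSE]
  sub$meta <- ms$meta[keep, ]
  got2 <- stability_curve(sub, bins, min_shared = 1)
  want2 <- brute_stability_curve(sub, bins, min_shared = 1)
  expect_equal(got2$s, want2$s, tolerance = 1e-12)
  expect_equal(got2$n_pairs, as.numeric(want2$n_pairs))
})

test_that("stability curve extremes behave as expected", {
  ## all groups identical -> 1 in every populated bin
  m <- toy_matrix(list(c("a", "b", "c"), c("a", "b", "c"), c("a", "b", "c")),
                  time = c(1000, 5000, 20000))
  cur <- stability_curve(m, log_lag_bins(60, 86400, 6))
  expect_true(all(cur$s[cur$n_pairs > 0] == 1))

  ## disjoint non-focal membership at all lags -> zeros with min_shared = 0
  m2 <- toy_matrix(list(c("x", "a"), c("x", "b"), c("x", "c")),
                   time = c(1000, 5000, 20000))
  cur2 <- stability_curve(m2, log_lag_bins(60, 86400, 6), min_shared = 0)
  expect_true(all(cur2$s[cur2$n_pairs > 0] == 0))
  ## with the default min_shared = 1 those pairs do not qualify
  cur3 <- stability_curve(m2, log_lag_bins(60, 86400, 6), min_shared = 1)
  expect_true(all(cur3$n_pairs == 0))
})

test_that("stability ratio divides observed by permuted per bin", {
  m <- toy_matrix(list(c("a", "b", "c"), c("a", "b", "c")),
                  time = c(1000, 2000))
  cur <- stability_curve(m, log_lag_bins(60, 86400, 6))
  r_same <- stability_ratio(cur, cur)
  expect_true(all(r_same$ratio[!is.na(r_same$ratio)] == 1))
  half <- cur; half$s <- cur$s / 2
  r_two <- stability_ratio(cur, half)
  expect_true(all(r_two$ratio[!is.na(r_two$ratio)] == 2))
  ## permuted zero -> undefined, flagged
  zero <- cur; zero$s <- ifelse(is.na(cur$s), NA, 0)
  r_zero <- stability_ratio(cur, zero)
  expect_true(all(is.na(r_zero$ratio)))
  expect_true(any(r_zero$undefined))
  ## mismatched bins -> error
  expect_error(stability_ratio(cur, stability_curve(m, log_lag_bins(10, 100, 6))),
               "bins differ")
})

test_that("group size summaries follow their definitions", {
  m <- toy_matrix(list(c("a", "b"), c("a", "b", "c", "d", "e", "f")))
  s <- group_size_summaries(m)
  expect_equal(s$mean_size, 4)
  expect_equal(s$max_size, 6)
  expect_equal(s$typical_size, 5)  # (4 + 36) / 8

  ones <- toy_matrix(list("a", "b", "c"))
  expect_equal(unlist(group_size_summaries(ones)), c(mean_size = 1,
                                                     max_size = 1,
                                                     typical_size = 1))
  eq <- toy_matrix(list(c("a", "b", "c"), c("d", "e", "f"),
                        c("a", "d", "e")))
  se <- group_size_summaries(eq)
  expect_equal(se$mean_size, 3)
  expect_equal(se$typical_size, 3)
})

test_that("typical size is never below mean size", {
  for (seed in 1:10) {
    set.seed(seed)
    sizes <- sample(1:20, 30, replace = TRUE)
    groups <- lapply(seq_along(sizes), function(i) {
      sprintf("i%02d_%d", seq_len(sizes[i]), i)
    })
    s <- group_size_summaries(toy_matrix(groups))
    expect_gte(s$typical_size, s$mean_size - 1e-12)
  }
})

test_that("size binning merges large sizes greedily to the 5% threshold", {
  ## all memberships at sizes <= 13: singleton bins only
  sizes1 <- rep(c(2, 3, 5), times = c(10, 10, 10))
  b1 <- bin_group_sizes(sizes1)
  expect_equal(nrow(b1), 3)
  expect_true(all(b1$size_lo == b1$size_hi))

  ## sizes 14 and 15 each ~3% of memberships: merged into one class [14,15]
  sizes2 <- c(rep(2, 448), rep(14, 2), rep(15, 2))
  shares <- c(sum(sizes2 == 14) * 14, sum(sizes2 == 15) * 15) / sum(sizes2)
  expect_true(all(shares < 0.05) && sum(shares) >= 0.05)
  b2 <- bin_group_sizes(sizes2)
  merged <- b2[b2$size_lo >= 14, ]
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$size_lo, merged$size_hi), c(14, 15))
  expect_gte(merged$share, 0.05)

  ## a single size-20 class holding all memberships
  b3 <- bin_group_sizes(rep(20, 5))
  expect_equal(nrow(b3), 1)
  expect_equal(c(b3$size_lo, b3$size_hi), c(20, 20))
  expect_equal(b3$share, 1)

  ## remainder below threshold is absorbed into the previous class
  sizes4 <- c(rep(2, 1000), rep(14, 20), rep(30, 2))
  b4 <- bin_group_sizes(sizes4)
  last <- b4[nrow(b4), ]
  expect_equal(last$size_hi, 30)
  expect_true(all(b4$share[b4$size_lo >= 14] >= 0.05 |
                    b4$size_lo > 14))

  ## crafted distribution needing two merges
  sizes5 <- c(rep(1, 400), rep(14, 1), rep(15, 1), rep(16, 1), rep(17, 1),
              rep(18, 1))
  b5 <- bin_group_sizes(sizes5)
  big <- b5[b5$size_lo >= 14, ]
  expect_true(all(big$share >= 0.05))
  ## bins cover observed sizes without overlap
  for (s in unique(sizes5)) {
    hits <- sum(s >= b5$size_lo & s <= b5$size_hi)
    expect_equal(hits, 1)
  }
})

test_that("class proportion profiles average within-group proportions per bin", {
  groups <- list(c("m1", "m2"), c("m1", "f1"))
  m <- toy_matrix(groups)
  phen <- tibble::tibble(individual_id = c("m1", "m2", "f1"),
                         sex = c("male", "male", "female"))
  binning <- bin_group_sizes(m)
  prof <- class_proportion_profile(m, phen, binning, "sex", "male")
  expect_equal(prof$mean_proportion, 0.75)  # (1 + 0.5) / 2

  ## all-male population -> proportion 1 in every bin
  m2 <- toy_matrix(list(c("m1", "m2"), c("m1", "m2", "m3")))
  phen2 <- tibble::tibble(individual_id = c("m1", "m2", "m3"),
                          sex = rep("male", 3))
  prof2 <- class_proportion_profile(m2, phen2, bin_group_sizes(m2),
                                    "sex", "male")
  expect_true(all(prof2$mean_proportion == 1))

  ## unknown-sex members are excluded from the denominator
  m3 <- toy_matrix(list(c("m1", "u1")))
  phen3 <- tibble::tibble(individual_id = c("m1", "u1"),
                          sex = c("male", "unknown"))
  prof3 <- class_proportion_profile(m3, phen3, bin_group_sizes(m3),
                                    "sex", "male")
  expect_equal(prof3$mean_proportion, 1)
})

test_that("binomial composition probabilities match closed forms and sum to one", {
  expect_equal(binomial_composition_probability(2, 2, 0.5), 0.25)
  expect_equal(binomial_composition_probability(2, 1, 0.5), 0.5)
  expect_equal(binomial_composition_probability(3, 3, 0.4), 0.064)
  expect_error(binomial_composition_probability(2, 3, 0.5), "k <= n")
  for (n in c(2, 5, 9)) {
    for (p in c(0.2, 0.5, 0.77)) {
      expect_equal(sum(binomial_composition_probability(n, 0:n, p)), 1)
    }
  }
})

test_that("composition binomial profile estimates p from unique individuals", {
  ## groups of size 2: individuals m1, m2, f1 -> p(male) = 2/3
  groups <- list(c("m1", "m2"), c("m1", "f1"))
  m <- toy_matrix(groups)
  phen <- tibble::tibble(individual_id = c("m1", "m2", "f1"),
                         sex = c("male", "male", "female"))
  prof <- composition_binomial_profile(m, phen, bin_group_sizes(m),
                                       "sex", "male")
  p <- 2 / 3
  expected <- mean(c(dbinom(2, 2, p), dbinom(1, 2, p)))
  expect_equal(prof$mean_binom_p, expected)
})

test_that("kurtosis scores behave like Pearson population kurtosis", {
  set.seed(1)
  x <- rnorm(1e5)
  expect_lt(abs(pearson_kurtosis(x) - 3), 0.1)
  ## symmetric two-point mass at +-1 -> kurtosis 1
  expect_equal(pearson_kurtosis(rep(c(-1, 1), 50)), 1)
  ## constant vector -> undefined
  expect_true(is.na(pearson_kurtosis(rep(2, 10))))
})

test_that("kurtosis assortment flags degenerate bins and needs enough groups", {
  groups <- lapply(1:8, function(i) sprintf("i%d_%d", 1:3, i))
  m <- toy_matrix(groups)
  trait <- setNames(rep(1, length(unique(unlist(groups)))),
                    unique(unlist(groups)))
  res <- kurtosis_assortment(m, trait, bin_group_sizes(m))
  expect_true(all(res$degenerate))

  set.seed(2)
  trait2 <- setNames(rnorm(length(trait)), names(trait))
  res2 <- kurtosis_assortment(m, trait2, bin_group_sizes(m))
  expect_false(any(res2$degenerate))
  ## oracle: direct moment computation on the group means
  inc <- m$incidence
  gm <- as.numeric(inc %*% trait2[colnames(inc)] / rowSums(inc))
  expect_equal(res2$kurtosis, pearson_kurtosis(gm))
})

test_that("body-size PC1 is standardized within sex and tracks wing length", {
  set.seed(3)
  pop <- generate_population(sim_config(n_individuals = 400, seed = 3))
  pc1 <- body_size_pc1(pop)
  for (s in c("male", "female")) {
    sc <- pc1[pop$individual_id[pop$sex == s]]
    expect_equal(mean(sc), 0, tolerance = 1e-10)
    expect_equal(sd(sc), 1, tolerance = 1e-10)
    expect_gt(cor(sc, pop$wing[pop$sex == s]), 0.9)
  }

  ## wing == tarsus: PC1 equals the standardized common variable
  phen <- tibble::tibble(individual_id = sprintf("i%d", 1:10),
                         sex = "male", wing = 1:10, tarsus = 1:10)
  pc <- body_size_pc1(phen)
  expect_equal(unname(pc), as.numeric(scale(1:10)), tolerance = 1e-10)

  ## missing measures and tiny sexes get no score
  phen2 <- tibble::tibble(individual_id = c("a", "b", "c"),
                          sex = c("male", "male", "female"),
                          wing = c(75, NA, 70), tarsus = c(20, 21, 19))
  pc2 <- body_size_pc1(phen2)
  expect_true(is.na(pc2["b"]))
  expect_true(is.na(pc2["c"]))  # only one female
  expect_true(is.na(pc2["a"]))  # one male measured: < 2 in sex
})
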