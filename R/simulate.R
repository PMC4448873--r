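#' Simulation configuration for the synthetic detection-stream generator
#'
#' Bundles every tunable of the generator into a validated list. The defaults
#' emulate a winter feeding-station study on a woodland songbird population:
#' a stratified grid of 65 automated feeders logging PIT-tagged birds over 13
#' two-day sampling periods, bursty within-day visitation, and foraging
#' flocks with a mean size of about five birds.
#'
#' @param n_individuals Number of birds in the population.
#' @param sex_ratio Proportion of males.
#' @param juvenile_prop Proportion of juveniles (first-winter birds).
#' @param immigrant_prop Proportion of immigrants (born outside the study
#'   area) as opposed to locally born birds.
#' @param n_feeders Number of feeding stations, laid out on a stratified
#'   grid with 250-unit spacing (see [make_feeder_layout()]).
#' @param n_periods Number of two-day sampling periods.
#' @param gatherings_per_feeder_day Expected number of gathering events
#'   (flock visits) per feeder per day.
#' @param within_burst_sd Standard deviation, in seconds, of detection times
#'   around a gathering's centre time.
#' @param detections_per_member Expected number of antenna reads each member
#'   emits during a gathering (floored at one read).
#' @param home_range_sd Standard deviation, in distance units, of the
#'   Gaussian availability kernel tying individuals to their home-range
#'   centre, and of the jitter of centres around feeders.
#' @param spatial_segregation_strength Displacement, in distance units, of
#'   immigrant home-range centres towards the eastern edge of the grid.
#'   Zero means immigrants and locals are spatially interchangeable.
#' @param social_preference Named numeric vector of multiplicative weights
#'   for the pairwise features `same_sex`, `same_age`, `same_residency`.
#'   Weights below 1 disfavour pairs sharing the feature (e.g.
#'   `same_sex = 0.3` plants a mixed-sex grouping preference); 1 is neutral.
#' @param group_size_asymptote Upper asymptote, in individuals, of the
#'   logistic map from local pool size to expected group size.
#' @param seed Integer seed fixing the whole stream.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1000,
                       sex_ratio = 0.49,
                       juvenile_prop = 0.47,
                       immigrant_prop = 0.35,
                       n_feeders = 65,
                       n_periods = 13,
                       gatherings_per_feeder_day = 40,
                       within_burst_sd = 30,
                       detections_per_member = 10,
                       home_range_sd = 100,
                       spatial_segregation_strength = 0,
                       social_preference = c(same_sex = 1, same_age = 1,
                                             same_residency = 1),
                       group_size_asymptote = 8,
                       seed = 1L) {
  props <- c(sex_ratio = sex_ratio, juvenile_prop = juvenile_prop,
             immigrant_prop = immigrant_prop)
  if (any(!is.finite(props)) || any(props < 0) || any(props > 1)) {
    stop("sim_config: proportions must lie in [0, 1]", call. = FALSE)
  }
  rates <- c(gatherings_per_feeder_day, within_burst_sd,
             detections_per_member, home_range_sd, group_size_asymptote)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("sim_config: rates and scales must be positive", call. = FALSE)
  }
  if (!is.finite(spatial_segregation_strength) ||
      spatial_segregation_strength < 0) {
    stop("sim_config: spatial_segregation_strength must be >= 0",
         call. = FALSE)
  }
  pref <- c(same_sex = 1, same_age = 1, same_residency = 1)
  if (length(social_preference)) {
    bad <- setdiff(names(social_preference), names(pref))
    if (length(bad)) {
      stop("sim_config: unknown social_preference feature(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    pref[names(social_preference)] <- social_preference
  }
  if (any(pref < 0)) stop("sim_config: preference weights must be >= 0",
                          call. = FALSE)
  structure(list(
    n_individuals = as.integer(n_individuals),
    sex_ratio = sex_ratio,
    juvenile_prop = juvenile_prop,
    immigrant_prop = immigrant_prop,
    n_feeders = as.integer(n_feeders),
    n_periods = as.integer(n_periods),
    gatherings_per_feeder_day = gatherings_per_feeder_day,
    within_burst_sd = within_burst_sd,
    detections_per_member = detections_per_member,
    home_range_sd = home_range_sd,
    spatial_segregation_strength = spatial_segregation_strength,
    social_preference = pref,
    group_size_asymptote = group_size_asymptote,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Stratified grid of feeding stations
#'
#' Places `n_feeders` stations on a near-square grid with fixed spacing,
#' mirroring a stratified-grid deployment over a study wood.
#'
#' @param n_feeders Number of stations.
#' @param spacing Distance between neighbouring grid positions.
#' @return A tibble with columns `feeder_id`, `x`, `y`.
#' @export
make_feeder_layout <- function(n_feeders = 65, spacing = 250) {
  if (n_feeders < 1) stop("make_feeder_layout: need at least one feeder",
                          call. = FALSE)
  ncol_grid <- ceiling(sqrt(n_feeders))
  idx <- seq_len(n_feeders) - 1L
  tibble::tibble(
    feeder_id = sprintf("F%02d", seq_len(n_feeders)),
    x = (idx %% ncol_grid) * spacing,
    y = (idx %/% ncol_grid) * spacing
  )
}

# Sex-specific morphometrics (mm). Males are larger in both measures; a
# shared latent size factor induces a positive wing-tarsus correlation.
.morph <- list(
  wing_mu  = c(male = 76.0, female = 72.5),
  wing_sd  = 1.8,
  tarsus_mu = c(male = 20.8, female = 19.9),
  tarsus_sd = 0.45,
  shared_loading = 0.85
)

#' Generate a synthetic phenotype table
#'
#' Draws sex, age class and residency status independently at the configured
#' proportions, and wing and tarsus lengths from sex-specific normals with a
#' shared latent size factor (males larger in both measures).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `individual_id`, `sex`, `age_class`,
#'   `residency`, `wing`, `tarsus`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  if (n == 0) {
    return(tibble::tibble(individual_id = character(), sex = character(),
                          age_class = character(), residency = character(),
                          wing = numeric(), tarsus = numeric()))
  }
  withr_seed(config$seed, "population", {
    sex <- ifelse(runif(n) < config$sex_ratio, "male", "female")
    age <- ifelse(runif(n) < config$juvenile_prop, "juvenile", "adult")
    res <- ifelse(runif(n) < config$immigrant_prop, "immigrant", "local")
    z <- rnorm(n)
    lam <- .morph$shared_loading
    resid_sd <- sqrt(1 - lam^2)
    wing <- .morph$wing_mu[sex] +
      .morph$wing_sd * (lam * z + resid_sd * rnorm(n))
    tarsus <- .morph$tarsus_mu[sex] +
      .morph$tarsus_sd * (lam * z + resid_sd * rnorm(n))
    tibble::tibble(
      individual_id = sprintf("ind%04d", seq_len(n)),
      sex = sex, age_class = age, residency = res,
      wing = unname(wing), tarsus = unname(tarsus)
    )
  })
}

#' Assign home-range centres
#'
#' Each individual is anchored to a uniformly chosen feeder and jittered by
#' an isotropic Gaussian of scale `home_range_sd`. Immigrant centres are
#' additionally displaced along +x (towards the eastern edge of the grid) by
#' `spatial_segregation_strength` distance units, emulating exclusion of
#' immigrants from core areas; at strength 0 immigrant and local centres are
#' drawn from the same distribution.
#'
#' @param population Phenotype tibble from [generate_population()].
#' @param layout Feeder layout tibble from [make_feeder_layout()].
#' @param config A [sim_config()].
#' @return A tibble with columns `individual_id`, `home_x`, `home_y`.
#' @export
assign_home_ranges <- function(population, layout, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(layout) == 0) {
    stop("assign_home_ranges: feeder layout is empty", call. = FALSE)
  }
  n <- nrow(population)
  withr_seed(config$seed, "homeranges", {
    anchor <- sample.int(nrow(layout), n, replace = TRUE)
    hx <- layout$x[anchor] + rnorm(n, 0, config$home_range_sd)
    hy <- layout$y[anchor] + rnorm(n, 0, config$home_range_sd)
    shift <- ifelse(population$residency == "immigrant",
                    config$spatial_segregation_strength, 0)
    tibble::tibble(individual_id = population$individual_id,
                   home_x = hx + shift, home_y = hy)
  })
}

## Zero-truncated negative binomial draw (size = dispersion, mu = mean of
## the untruncated law). Inverse-CDF so a single uniform drives each draw.
rztnbinom <- function(n, mu, size = 4) {
  p0 <- stats::dnbinom(0, size = size, mu = mu)
  u <- runif(n, min = p0, max = 1)
  stats::qnbinom(u, size = size, mu = mu)
}

## Logistic map from local pool size to expected (untruncated) group size.
## Midpoint and scale are tied to the asymptote so small pools give small
## groups and pools >> K saturate at K.
expected_group_size <- function(pool, K) {
  K / (1 + exp(-(pool - K) / (K / 3)))
}

#' Simulate gathering events and the detection stream
#'
#' For every feeder x day, gathering times are drawn uniformly over daylight
#' hours at the configured rate. Members are sampled sequentially from the
#' locally available pool: availability decays as a Gaussian kernel of
#' distance between home-range centre and feeder, and each candidate's
#' weight is multiplied by the product of pairwise social-preference weights
#' with the members already in the group. Each member emits at least one
#' read at times normal around the gathering centre. The returned truth
#' bundle records every planted membership for downstream oracle tests.
#'
#' @param population Phenotype tibble.
#' @param layout Feeder layout tibble.
#' @param home_ranges Tibble from [assign_home_ranges()].
#' @param config A [sim_config()].
#' @return A list with elements `detections` (tibble: `time_s`, `day`,
#'   `sampling_period`, `feeder_id`, `individual_id`, sorted by day then
#'   time), `truth` (list with `memberships` long tibble `group_id`,
#'   `individual_id` and `groups` metadata tibble), and
#'   `planted_effect_labels`.
#' @export
simulate_gatherings <- function(population, layout, home_ranges, config) {
  stopifnot(inherits(config, "sim_config"))
  empty <- list(
    detections = tibble::tibble(time_s = numeric(), day = integer(),
                                sampling_period = integer(),
                                feeder_id = character(),
                                individual_id = character()),
    truth = list(
      memberships = tibble::tibble(group_id = character(),
                                   individual_id = character()),
      groups = tibble::tibble(group_id = character(), feeder_id = character(),
                              sampling_period = integer(), day = integer(),
                              time_s = numeric())
    ),
    planted_effect_labels = planted_labels(config)
  )
  if (nrow(population) == 0) return(empty)

  pref <- config$social_preference
  hr <- home_ranges[match(population$individual_id,
                          home_ranges$individual_id), ]
  sex <- population$sex
  age <- population$age_class
  res <- population$residency
  ids <- population$individual_id
  n_days <- 2L * config$n_periods
  day_start <- 6 * 3600; day_end <- 18 * 3600

  withr_seed(config$seed, "gatherings", {
    det_list <- list(); mem_list <- list(); meta_list <- list()
    gid <- 0L
    for (f in seq_len(nrow(layout))) {
      d2 <- (hr$home_x - layout$x[f])^2 + (hr$home_y - layout$y[f])^2
      avail <- exp(-d2 / (2 * config$home_range_sd^2))
      pool_size <- sum(avail)
      usable <- which(avail > 1e-8)
      if (!length(usable)) next
      for (day in seq_len(n_days)) {
        n_g <- rpois(1, config$gatherings_per_feeder_day)
        if (n_g == 0) next
        times <- sort(runif(n_g, day_start, day_end))
        mu <- expected_group_size(pool_size, config$group_size_asymptote)
        sizes <- pmin(rztnbinom(n_g, mu = max(mu, 0.2)), length(usable))
        for (g in seq_len(n_g)) {
          gid <- gid + 1L
          members <- sample_group_members(usable, avail, sizes[g],
                                          sex, age, res, pref)
          n_reads <- pmax(1L, rpois(length(members),
                                    config$detections_per_member))
          t_reads <- rnorm(sum(n_reads), times[g], config$within_burst_sd)
          id_chr <- sprintf("G%06d", gid)
          det_list[[gid]] <- tibble::tibble(
            time_s = t_reads, day = day,
            sampling_period = (day + 1L) %/% 2L,
            feeder_id = layout$feeder_id[f],
            individual_id = rep(ids[members], times = n_reads)
          )
          mem_list[[gid]] <- tibble::tibble(group_id = id_chr,
                                            individual_id = ids[members])
          meta_list[[gid]] <- tibble::tibble(
            group_id = id_chr, feeder_id = layout$feeder_id[f],
            sampling_period = (day + 1L) %/% 2L, day = day,
            time_s = times[g])
        }
      }
    }
    if (gid == 0L) {
      empty
    } else {
      detections <- dplyr::arrange(dplyr::bind_rows(det_list),
                                   .data$day, .data$time_s)
      list(
        detections = detections,
        truth = list(memberships = dplyr::bind_rows(mem_list),
                     groups = dplyr::bind_rows(meta_list)),
        planted_effect_labels = planted_labels(config)
      )
    }
  })
}

## Sequential weighted sampling of one group's members. The first member is
## drawn by availability alone; each later draw multiplies availability by
## the product of pairwise feature weights against current members.
sample_group_members <- function(usable, avail, size, sex, age, res, pref) {
  size <- min(size, length(usable))
  first <- usable[sample.int(length(usable), 1, prob = avail[usable])]
  members <- first
  neutral <- all(pref == 1)
  while (length(members) < size) {
    cand <- setdiff(usable, members)
    w <- avail[cand]
    if (!neutral) {
      for (m in members) {
        fw <- ifelse(sex[cand] == sex[m], pref[["same_sex"]], 1) *
          ifelse(age[cand] == age[m], pref[["same_age"]], 1) *
          ifelse(res[cand] == res[m], pref[["same_residency"]], 1)
        w <- w * fw
      }
    }
    if (!any(w > 0)) break
    members <- c(members, cand[sample.int(length(cand), 1, prob = w)])
  }
  members
}

planted_labels <- function(config) {
  pref <- config$social_preference
  lab <- c(sex = "none", age_class = "none", residency = "none")
  if (pref[["same_sex"]] != 1) lab["sex"] <- "social"
  if (pref[["same_age"]] != 1) lab["age_class"] <- "social"
  if (pref[["same_residency"]] != 1) lab["residency"] <- "social"
  if (config$spatial_segregation_strength > 0 &&
      lab["residency"] == "none") lab["residency"] <- "spatial"
  lab
}

#' Run the full generator
#'
#' Convenience wrapper: population, layout, home ranges and the gathering
#' stream in one call, all driven by `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `population`, `layout`, `home_ranges`, `detections`,
#'   `truth`, `planted_effect_labels`.
#' @export
simulate_detections <- function(config = sim_config()) {
  population <- generate_population(config)
  layout <- make_feeder_layout(config$n_feeders)
  home_ranges <- assign_home_ranges(population, layout, config)
  sim <- simulate_gatherings(population, layout, home_ranges, config)
  c(list(population = population, layout = layout,
         home_ranges = home_ranges), sim)
}

## Scoped RNG: each generator stage draws from a stream derived from the
## global seed plus a stage tag, so stages are reproducible in isolation.
withr_seed <- function(seed, tag, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, tag))
  force(code)
}

## Deterministic 31-bit sub-seed from (seed, tag).
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435 + h * 97) %% .Machine$integer.max)
}
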