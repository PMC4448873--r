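#' Default pipeline configuration
#'
#' One nested list drives the whole run: simulation (or input paths),
#' inference, statistics, null models and saturation fits. Unknown keys are
#' rejected so a typo cannot silently disable a stage.
#'
#' @param ... Overrides as `stage = list(key = value)`; `seed` and `stages`
#'   may be set at top level.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(...) {
  base <- list(
    seed = 1L,
    stages = c("simulate", "infer", "network", "stats", "nulls",
               "saturation"),
    paths = list(detections = NULL, phenotypes = NULL, out_dir = NULL),
    simulate = list(),              # overrides forwarded to sim_config()
    infer = list(k_max = NULL, min_component_weight = 0),
    stats = list(start_binning_at = 14, min_share = 0.05, min_shared = 1,
                 lag_bins = NULL),
    nulls = list(node_iter = 1000, stream_iter = 10000,
                 sample_every = 100,
                 traits = c("sex", "age_class", "residency")),
    saturation = list(response = "mean")
  )
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) {
    stop("run_config: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      inner_bad <- setdiff(names(over[[nm]]), names(base[[nm]]))
      if (length(inner_bad) && nm != "simulate") {
        stop(sprintf("run_config: unknown key(s) in %s: %s", nm,
                     paste(inner_bad, collapse = ", ")), call. = FALSE)
      }
      base[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base$seed <- as.integer(base$seed)
  structure(base, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [run_config()] structure.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_run_config requires the yaml package", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' simulate (or read inputs) -> infer groups -> association network ->
#' group statistics -> null models and social/spatial attribution ->
#' saturation fits, in dependency order, with a provenance block. The same
#' config and seed always produce the same report.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage logging.
#' @return A list of class `run_report`; see Details for sections.
#' @details Sections (present when the owning stage is enabled):
#' `population`, `detections`, `matrix`, `network_summary`, `size_summary`,
#' `binning`, `stability`, `stability_ratio_tbl`, `verdicts`, `nulls`,
#' `saturation`, plus `provenance` (always).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list()
  report$provenance <- list(
    seed = config$seed,
    stages = config$stages,
    package_version = as.character(utils::packageVersion("flocknet")),
    config_hash = rlang::hash(unclass(config))
  )
  st <- function(name) name %in% config$stages

  phenotypes <- NULL; detections <- NULL; truth <- NULL
  if (st("simulate")) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    sim <- simulate_detections(do.call(sim_config, sim_args))
    phenotypes <- sim$population
    detections <- sim$detections
    truth <- sim$truth
    report$population <- phenotypes
    report$detections <- detections
    report$planted_effect_labels <- sim$planted_effect_labels
    say("simulate: %d individuals, %d detections, %d true groups",
        nrow(phenotypes), nrow(detections), nrow(truth$groups))
  } else if (!is.null(config$paths$detections)) {
    detections <- read_detections(config$paths$detections)
    phenotypes <- read_phenotypes(config$paths$phenotypes)
    say("read: %d detections, %d phenotype rows", nrow(detections),
        nrow(phenotypes))
  }

  mat <- NULL
  if (st("infer")) {
    if (is.null(detections)) stop("infer stage needs detections",
                                  call. = FALSE)
    inf <- infer_groups(detections, k_max = config$infer$k_max,
                        min_component_weight =
                          config$infer$min_component_weight)
    mat <- inf$matrix
    report$gatherings <- inf$gatherings
    say("infer: %d groups over %d individuals", nrow(mat$incidence),
        ncol(mat$incidence))
  } else if (!is.null(truth)) {
    mat <- group_matrix(truth$memberships, truth$groups)
  }
  if (!is.null(mat)) report$matrix <- mat
  if (!is.null(mat) && !is.null(phenotypes) && !is.null(detections)) {
    phenotypes <- flag_unknown_individuals(detections, phenotypes)
  }

  net <- NULL
  if (st("network") && !is.null(mat)) {
    net <- build_network(mat)
    report$network <- net
    report$network_summary <- tibble::tibble(
      n_nodes = nrow(net),
      n_edges = sum(net[upper.tri(net)] > 0),
      density = network_density(net))
    say("network: %d nodes, density %.3f", nrow(net),
        report$network_summary$density)
  }

  binning <- NULL
  if (st("stats") && !is.null(mat)) {
    report$size_summary <- group_size_summaries(mat)
    binning <- bin_group_sizes(mat, config$stats$start_binning_at,
                               config$stats$min_share)
    report$binning <- binning
    lag_bins <- config$stats$lag_bins %||% log_lag_bins()
    report$stability <- stability_curve(mat, lag_bins,
                                        min_shared = config$stats$min_shared)
    say("stats: mean size %.2f, typical %.2f",
        report$size_summary$mean_size, report$size_summary$typical_size)
  }

  if (st("nulls") && !is.null(mat) && !is.null(phenotypes)) {
    verdicts <- list(); nulls <- list()
    for (trait in config$nulls$traits) {
      fn <- assortativity_statistic(trait)
      node <- node_permutation_null(mat, phenotypes, fn,
                                    n_iter = config$nulls$node_iter,
                                    seed = derive_seed(config$seed,
                                                       paste0("node.", trait)))
      stream <- datastream_permutation_null(
        mat, fn, phenotypes, n_iter = config$nulls$stream_iter,
        sample_every = config$nulls$sample_every,
        seed = derive_seed(config$seed, paste0("stream.", trait)))
      verdicts[[trait]] <- classify_effect(node$observed, node, stream,
                                           trait = trait)
      nulls[[trait]] <- list(node = node, stream = stream)
      say("nulls: %s r = %.3f -> %s", trait, node$observed,
          verdicts[[trait]]$verdict)
    }
    report$verdicts <- dplyr::bind_rows(verdicts)
    report$nulls <- nulls
    if (st("stats")) {
      ## stability ratio against the final matrix of the last chain
      final_mat <- nulls[[length(nulls)]]$stream$final_matrix
      lag_bins <- config$stats$lag_bins %||% log_lag_bins()
      perm_curve <- stability_curve(final_mat, lag_bins,
                                    min_shared = config$stats$min_shared)
      report$stability_ratio_tbl <- stability_ratio(report$stability,
                                                    perm_curve)
    }
  }

  if (st("saturation") && !is.null(mat)) {
    records <- local_population_table(mat)
    report$local_population <- records
    report$saturation <- fit_saturation(records,
                                        config$saturation$response)
    if (report$saturation$converged) {
      say("saturation: K = %.1f, delta AIC = %.1f",
          coef(report$saturation$logistic)["K"],
          report$saturation$delta_aic)
    }
  }

  if (!is.null(config$paths$out_dir)) {
    write_report_files(report, config$paths$out_dir)
  }
  class(report) <- "run_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report_files <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(report$detections)) {
    write_detections(report$detections, p("detections.csv"))
  }
  if (!is.null(report$population)) {
    write_phenotypes(report$population, p("phenotypes.csv"))
  }
  if (!is.null(report$matrix)) {
    write_groups(report$matrix, p("groups.csv"), p("groups_meta.csv"))
  }
  if (!is.null(report$network)) {
    write_network(report$network, graphml = p("network.graphml"))
  }
  summary_json <- list(
    provenance = report$provenance,
    size_summary = report$size_summary,
    network_summary = report$network_summary,
    verdicts = report$verdicts,
    saturation = if (!is.null(report$saturation)) {
      glance(report$saturation)
    }
  )
  jsonlite::write_json(summary_json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  seed:", x$provenance$seed, "\n")
  if (!is.null(x$size_summary)) {
    cat(sprintf("  groups: %d, mean size %.2f, typical %.2f\n",
                nrow(x$matrix$incidence), x$size_summary$mean_size,
                x$size_summary$typical_size))
  }
  if (!is.null(x$verdicts)) {
    cat("  verdicts:\n")
    for (i in seq_len(nrow(x$verdicts))) {
      cat(sprintf("    %-10s r outside node null: %s, stream null: %s -> %s\n",
                  x$verdicts$trait[i], x$verdicts$outside_node_null[i],
                  x$verdicts$outside_stream_null[i], x$verdicts$verdict[i]))
    }
  }
  invisible(x)
}
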