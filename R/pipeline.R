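#' Pipeline configuration
#'
#' One configuration object drives the full analysis: simulate (or read)
#' trials, preprocess, compute measures, cluster, fit the global models and
#' the time courses, and write a report directory. Accepts a YAML file path
#' or a named list; unspecified settings take the defaults below.
#'
#' @param config Path to a YAML file or a named list with any of:
#'   `metadata_path`/`samples_path` (read an existing dataset),
#'   `simulation` (list of [sim_config()] arguments for a synthetic run),
#'   `layout` (list of [screen_layout()] arguments), `k`, `x_threshold`,
#'   `linkage`, `ci_global`, `ci_step`, `min_run`, `timecourse_measures`,
#'   `seed`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    metadata_path = NULL, samples_path = NULL,
    simulation = list(), layout = list(),
    k = 8, x_threshold = 0.05, linkage = "ward.D",
    ci_global = 0.99, ci_step = 0.95, min_run = 10,
    timecourse_measures = c("deviation", "x_coordinate"),
    seed = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  if (!is.numeric(cfg$ci_global) || cfg$ci_global <= 0 || cfg$ci_global >= 1 ||
      !is.numeric(cfg$ci_step) || cfg$ci_step <= 0 || cfg$ci_step >= 1) {
    abort("Invalid config: ci levels must lie in (0, 1)")
  }
  if (!is.numeric(cfg$min_run) || cfg$min_run < 1) {
    abort("Invalid config: min_run must be >= 1")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full mouse-tracking Stroop pipeline
#'
#' Executes simulate/read, exclusion filtering, trajectory alignment, time
#' and space normalization, trial measures and profiles, partial-error
#' clustering, the global mixed models for initiation time, response time,
#' maximum deviation and partial-error rates with their eight-component
#' decompositions, and the deviation and x-coordinate component time
#' courses. Writes all result tables plus a machine-readable run manifest to
#' `out_dir` and returns the assembled results invisibly. Runs with the same
#' configuration and seed are byte-identical.
#'
#' @param config A [pipeline_config()], list, or YAML path.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with every intermediate and final table.
#' @export
run_pipeline <- function(config = list(), out_dir, quiet = FALSE) {
  cfg <- pipeline_config(unclass(config))
  say <- function(...) if (!quiet) message("[strooptrace] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  layout <- stage("layout", do.call(screen_layout, cfg$layout))
  if (!is.null(cfg$metadata_path)) {
    say("reading trials from ", cfg$metadata_path)
    dat <- stage("read", read_trials(cfg$metadata_path, cfg$samples_path))
  } else {
    sim_args <- cfg$simulation
    if (!is.null(cfg$seed)) sim_args$seed <- cfg$seed
    scfg <- stage("config", do.call(sim_config, sim_args))
    say("simulating ", scfg$n_participants, " participants")
    dat <- stage("simulate", simulate_trials(scfg, layout))
  }
  say(nrow(dat$trials), " trials, ", nrow(dat$samples), " samples")

  kept <- stage("filter", filter_trials(dat$trials))
  excl <- exclusion_report(kept)
  say("kept ", nrow(kept), " of ", excl$n_total, " trials")

  aligned <- stage("align", remap_and_align(dat$samples, kept, layout))
  tnorm <- stage("time_normalize", time_normalize(aligned))
  snorm <- stage("space_normalize", space_normalize(aligned))
  measures <- stage("measures", trial_measures(aligned, kept))
  profiles <- stage("profiles", trajectory_profiles(tnorm, kept))

  say("clustering trajectories (k = ", cfg$k, ")")
  clusters <- stage("cluster", {
    m <- cluster_trajectories(snorm, k = cfg$k, linkage = cfg$linkage)
    m$pe_clusters <- label_partial_error_clusters(m, cfg$x_threshold)
    m
  })
  pe <- stage("pe_rates", pe_rates(clusters, kept))

  global_inputs <- list(
    it = list(data = measures, col = "it_ms"),
    rt = list(data = measures, col = "rt_ms"),
    md = list(data = measures, col = "md_above"),
    pe = list(data = pe, col = "pe_rate")
  )
  fits <- purrr::imap(global_inputs, function(inp, nm) {
    say("fitting mixed model: ", nm)
    stage(paste0("fit_", nm), {
      structure <- select_random_structure(inp$data, inp$col)
      fit_lmm(inp$data, inp$col, structure)
    })
  })
  mmeans <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(marginal_means(f, ci_level = cfg$ci_global),
                  measure = nm, .before = 1)
  })
  components <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(component_contrasts(f, ci_level = cfg$ci_global),
                  measure = nm, .before = 1)
  })

  timecourses <- purrr::map(
    setNames(cfg$timecourse_measures, cfg$timecourse_measures),
    function(m) {
      say("time course: ", m)
      stage(paste0("timecourse_", m),
            fit_timecourse(profiles, measure = m, ci_level = cfg$ci_step,
                           min_run = cfg$min_run))
    }
  )

  results <- list(
    config = cfg, layout = layout, trials = dat$trials, kept = kept,
    exclusions = excl, measures = measures, profiles = profiles,
    clusters = clusters, pe = pe, fits = fits, marginal_means = mmeans,
    components = components, timecourses = timecourses
  )
  write_report(results, out_dir)
  say("report written to ", out_dir)
  invisible(results)
}

#' Write the pipeline report directory
#'
#' Emits plain-CSV tables for every pipeline product - exclusions, marginal
#' means in the style of a descriptives table, the eight-component
#' decomposition per measure with additivity residuals, cluster assignments
#' and mean paths, partial-error rates, per-step time courses and sustained
#' intervals - plus a JSON run manifest (package version, seed, configuration
#' hash, trial accounting) sufficient to re-run the analysis bit-identically.
#'
#' @param results Result list assembled by [run_pipeline()].
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(results$exclusions$counts, p("exclusions.csv"))
  readr::write_csv(results$exclusions$by_participant,
                   p("exclusions_by_participant.csv"))
  readr::write_csv(results$measures, p("trial_measures.csv"))
  readr::write_csv(results$profiles, p("profiles.csv"))
  readr::write_csv(results$marginal_means, p("marginal_means.csv"))
  readr::write_csv(tibble::as_tibble(results$components), p("components.csv"))
  readr::write_csv(additivity_residuals(results$components), p("additivity.csv"))
  readr::write_csv(tidy(results$clusters), p("cluster_assignments.csv"))
  readr::write_csv(results$clusters$mean_paths, p("cluster_means.csv"))
  readr::write_csv(results$pe, p("pe_rates.csv"))
  for (m in names(results$timecourses)) {
    tc <- results$timecourses[[m]]
    readr::write_csv(tc$steps, p(paste0("timecourse_", m, ".csv")))
    readr::write_csv(tc$intervals, p(paste0("intervals_", m, ".csv")))
  }
  manifest <- list(
    package = "strooptrace",
    version = as.character(utils::packageVersion("strooptrace")),
    seed = results$config$seed,
    config_hash = rlang::hash(unclass(results$config)),
    n_trials = nrow(results$trials),
    n_kept = nrow(results$kept),
    pe_clusters = results$clusters$pe_clusters
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list.files(out_dir, full.names = TRUE))
}

#' Additivity residuals of a component table
#'
#' For each measure, the telescoping identities that the decomposition must
#' satisfy exactly: interference + facilitation - total, the three conflict
#' components minus interference, and the two facilitation components minus
#' facilitation.
#'
#' @param components Component tibble with `measure`, `component`,
#'   `estimate` columns (a `stroop_components` for a single measure also
#'   works).
#' @return Tibble: `measure`, `identity`, `residual`.
#' @export
additivity_residuals <- function(components) {
  d <- tibble::as_tibble(components)
  if (!"measure" %in% names(d)) d$measure <- attr(components, "measure") %||% "value"
  if (nrow(d) == 0) {
    return(tibble::tibble(measure = character(), identity = character(),
                          residual = numeric()))
  }
  purrr::imap_dfr(split(d, d$measure), function(g, m) {
    e <- setNames(g$estimate, g$component)
    tibble::tibble(
      measure = m,
      identity = c("interference+facilitation-total",
                   "conflicts-interference",
                   "facilitations-facilitation"),
      residual = unname(c(
        e["interference"] + e["facilitation"] - e["total_stroop"],
        e["response_conflict"] + e["semantic_relevance"] +
          e["semantic_conflict"] - e["interference"],
        e["response_facilitation"] + e["semantic_facilitation"] -
          e["facilitation"]
      ))
    )
  })
}
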