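# End-to-end orchestration: generate or load trajectories, fit candidate
# decisional models, census attractors, search consensus interventions,
# write reports and a manifest.

# per-stage seeds derived from one master seed (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009L + 97L * as.numeric(k)) %% 2147483629)
}

#' Assemble and validate a pipeline run configuration
#'
#' Collects every tunable of the pipeline in one (serializable) object.
#' Defaults mirror the study conditions the pipeline emulates: 1,000
#' random restarts over a 50-iteration horizon for the attractor census,
#' one decisional step per annual assessment interval, a 0.75 transition
#' coverage threshold for retaining candidate models, and intervention
#' sets of at most two clamped mediators.
#'
#' @param network `"fixture"` (the packaged adherence circuit) or a path to
#'   a network TSV file.
#' @param trajectories optional path to a trajectory CSV; when `NULL`, a
#'   synthetic cohort is generated from a seeded random ground-truth
#'   parameter set.
#' @param out_dir output directory for all reports.
#' @param synthetic list of cohort-generation settings:
#'   `n_participants` (82), `n_assessments` (`3:7`), `steps_between` (1),
#'   `noise_rate` (0.05), `missing_rate` (0.1).
#' @param fitting list: `K` (1), `coverage_min` (0.75), `max_models` (100),
#'   `weight_domain` (`c(1, 2)`), `theta_domain` (`NULL`), `strict`
#'   (`FALSE`).
#' @param simulation list: `n_inits` (1000), `max_steps` (50).
#' @param intervention list: `max_size` (2), `hold_steps` (5),
#'   `noise_prob` (0.05), `n_replicates` (100), `min_basin` (0),
#'   `max_states` (20).
#' @param seed master seed; all stage seeds derive from it
#'   deterministically.
#' @return An object of class `run_config`.
#' @export
run_config <- function(network = "fixture", trajectories = NULL,
                       out_dir = "results", synthetic = list(),
                       fitting = list(), simulation = list(),
                       intervention = list(), seed = 1L) {
  merge_block <- function(defaults, given, block) {
    extra <- setdiff(names(given), names(defaults))
    if (length(extra)) {
      stop("unknown ", block, " setting(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    # keep explicit NULLs (e.g. an unrestricted theta domain)
    for (nm in names(given)) defaults[nm] <- list(given[[nm]])
    defaults
  }
  cfg <- structure(list(
    network = network,
    trajectories = trajectories,
    out_dir = out_dir,
    synthetic = merge_block(
      list(n_participants = 82L, n_assessments = 3:7, steps_between = 1L,
           noise_rate = 0.05, missing_rate = 0.1),
      synthetic, "synthetic"),
    fitting = merge_block(
      list(K = 1L, coverage_min = 0.75, max_models = 100L,
           weight_domain = c(1L, 2L), theta_domain = NULL, strict = FALSE),
      fitting, "fitting"),
    simulation = merge_block(
      list(n_inits = 1000L, max_steps = 50L), simulation, "simulation"),
    intervention = merge_block(
      list(max_size = 2L, hold_steps = 5L, noise_prob = 0.05,
           n_replicates = 100L, min_basin = 0, max_states = 20L), intervention,
      "intervention"),
    seed = as.integer(seed)
  ), class = "run_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!identical(network, "fixture") && !file.exists(network)) {
      stop("network file not found: ", network, call. = FALSE)
    }
    if (!is.null(trajectories) && !file.exists(trajectories)) {
      stop("trajectory file not found: ", trajectories, call. = FALSE)
    }
    stopifnot(synthetic$n_participants >= 1,
              all(synthetic$n_assessments >= 3),
              synthetic$steps_between >= 1,
              synthetic$noise_rate >= 0, synthetic$noise_rate < 1,
              synthetic$missing_rate >= 0, synthetic$missing_rate < 1,
              fitting$K >= 1,
              fitting$coverage_min > 0, fitting$coverage_min <= 1,
              fitting$max_models >= 1,
              simulation$n_inits >= 1, simulation$max_steps >= 1,
              intervention$max_size >= 1, intervention$hold_steps >= 1,
              intervention$noise_prob >= 0, intervention$noise_prob < 1,
              intervention$n_replicates >= 1)
  })
  cfg
}

#' Read / write a run configuration (YAML or JSON)
#'
#' The configuration round-trips unchanged through serialization.
#'
#' @param cfg a [run_config()].
#' @param path file path (`.yml`/`.yaml`/`.json`).
#' @return `read_config()` a `run_config`; `write_config()` the path,
#'   invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order — network loading, trajectory generation or
#' loading, candidate-model fitting, attractor census across candidate
#' models, consensus minimal-intervention search — and writes the reports
#' to `cfg$out_dir`:
#' `cohort.csv` (+ YAML sidecar), `models.tsv`, `node_error.csv`,
#' `trajectory_balance.csv`, `attractor_census.csv`, `consensus_mis.csv`
#' and `manifest.yml` (configuration echo, seed, package version, stage
#' timings and a content digest of every output). Identical configuration
#' and seed give identical result files.
#'
#' @param cfg a [run_config()].
#' @return The run report, invisibly: a list with the fitted
#'   `candidate_models`, the pooled `attractor_set` census rows, the
#'   `consensus_interventions`, counts, and the manifest.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  net <- stage("network", {
    if (identical(cfg$network, "fixture")) adherence_network() else
      read_network(cfg$network)
  })

  data_stage <- stage("data", {
    if (!is.null(cfg$trajectories)) {
      list(trajectories = read_trajectories(cfg$trajectories),
           ground_truth = NULL)
    } else {
      truth <- random_parameters(net, seed = derive_seed(cfg$seed, 1L),
                                 weight_domain = cfg$fitting$weight_domain)
      traj <- simulate_cohort(
        net, truth,
        n_participants = cfg$synthetic$n_participants,
        n_assessments = cfg$synthetic$n_assessments,
        steps_between = cfg$synthetic$steps_between,
        noise_rate = cfg$synthetic$noise_rate,
        missing_rate = cfg$synthetic$missing_rate,
        seed = derive_seed(cfg$seed, 2L))
      attr(traj, "generation") <- list(
        seed = derive_seed(cfg$seed, 2L),
        n_participants = cfg$synthetic$n_participants,
        noise_rate = cfg$synthetic$noise_rate,
        missing_rate = cfg$synthetic$missing_rate,
        steps_between = cfg$synthetic$steps_between)
      list(trajectories = traj, ground_truth = truth)
    }
  })
  trajectories <- data_stage$trajectories

  fit <- stage("fit", {
    fit_network(net, trajectories, K = cfg$fitting$K,
                theta_domain = cfg$fitting$theta_domain,
                weight_domain = cfg$fitting$weight_domain,
                coverage_min = cfg$fitting$coverage_min,
                max_models = cfg$fitting$max_models,
                strict = cfg$fitting$strict)
  })
  if (!length(fit$models)) {
    stop(sprintf(
      "pipeline stage 'fit' retained no model: best achievable coverage %.3f is below coverage_min %.2f",
      fit$best_coverage, cfg$fitting$coverage_min), call. = FALSE)
  }

  # pooled attractor census over all enumerated candidate models
  census <- stage("attractors", {
    rows <- list()
    for (mi in seq_along(fit$models)) {
      atts <- sample_attractors(net, fit$models[[mi]],
                                n_inits = cfg$simulation$n_inits,
                                max_steps = cfg$simulation$max_steps,
                                seed = derive_seed(cfg$seed, 100L + mi))
      df <- as.data.frame(atts)
      if (nrow(df)) {
        df <- cbind(model_id = mi, df,
                    unconverged = attr(atts, "unconverged"))
      }
      rows[[mi]] <- df
    }
    rows <- Filter(function(d) is.data.frame(d) && nrow(d) > 0, rows)
    if (!length(rows)) {
      data.frame(model_id = integer(), id = character(), period = integer(),
                 adherent = logical(), basin_frequency = numeric(),
                 unconverged = numeric())
    } else {
      do.call(rbind, rows)
    }
  })

  consensus <- stage("interventions", {
    consensus_interventions(
      net, fit, max_size = cfg$intervention$max_size,
      hold_steps = cfg$intervention$hold_steps,
      max_steps = cfg$simulation$max_steps,
      n_inits = cfg$simulation$n_inits,
      sim_max_steps = cfg$simulation$max_steps,
      min_basin = cfg$intervention$min_basin,
      max_states = cfg$intervention$max_states,
      seed = derive_seed(cfg$seed, 200L))
  })

  report <- stage("report", {
    paths <- c(
      cohort = file.path(cfg$out_dir, "cohort.csv"),
      models = file.path(cfg$out_dir, "models.tsv"),
      node_error = file.path(cfg$out_dir, "node_error.csv"),
      trajectory_balance = file.path(cfg$out_dir, "trajectory_balance.csv"),
      attractor_census = file.path(cfg$out_dir, "attractor_census.csv"),
      consensus_mis = file.path(cfg$out_dir, "consensus_mis.csv"))
    write_trajectories(trajectories, paths[["cohort"]])
    write_models(fit, paths[["models"]])
    ae <- alignment_error(net, fit$models[[1L]], trajectories,
                          K = cfg$fitting$K)
    utils::write.csv(ae$by_node, paths[["node_error"]], row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(fit$trajectory_balance, paths[["trajectory_balance"]],
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(census, paths[["attractor_census"]], row.names = FALSE,
                     quote = FALSE)
    write_consensus(consensus, paths[["consensus_mis"]])
    list(paths = paths, alignment = ae)
  })

  manifest <- list(
    package = as.character(utils::packageVersion("adherenet")),
    seed = cfg$seed,
    config = unclass(cfg),
    counts = list(
      participants = length(unique(trajectories$participant_id)),
      models_enumerated = length(fit$models),
      candidate_space = fit$n_candidates,
      coverage = if (length(fit$coverage)) max(fit$coverage) else NA,
      attractors = length(unique(census$id)),
      nonadherent_states = consensus$n_nonadherent_states,
      rescued_states = consensus$n_rescued_states,
      unanimous_strategies = sum(consensus$table$unanimous)),
    timings = timings,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(report$paths)), basename(report$paths))))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yml"))

  invisible(list(network = net, trajectories = trajectories, fit = fit,
                 census = census, consensus = consensus,
                 ground_truth = data_stage$ground_truth,
                 manifest = manifest))
}
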