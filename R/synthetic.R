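#' Discretize raw psychometric scores into qualitative levels
#'
#' Maps each raw score to the index of the first cut-point it falls below
#' (the last level if it is at or above all cut-points), i.e. with
#' cut-points `(c1, ..., c_{L-1})` a score `x` gets level
#' `sum(x >= c)`. Missing raw values map to missing markers (`NA`) and are
#' excluded from downstream error scoring; the `participant_id`,
#' `timepoint` and `adherence` columns pass through unchanged.
#'
#' @param raw data.frame with columns `participant_id`, `timepoint`,
#'   `adherence` and one numeric column per node to discretize.
#' @param cutpoints named list: for each node column, a strictly increasing
#'   numeric vector of cut-points (length `n_levels - 1`). See
#'   [tertile_cutpoints()] for a data-driven default.
#' @return `raw` with the listed node columns replaced by integer levels.
#' @examples
#' raw <- data.frame(participant_id = "p1", timepoint = 1:3,
#'                   adherence = "adherent", qol = c(1.5, 3.2, 5.0))
#' discretize_scores(raw, list(qol = c(2, 4)))$qol  # 0 1 2
#' @export
discretize_scores <- function(raw, cutpoints) {
  stopifnot(is.data.frame(raw), is.list(cutpoints))
  missing_cols <- setdiff(names(cutpoints), names(raw))
  if (length(missing_cols)) {
    stop("cutpoints name columns absent from the table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (node in names(cutpoints)) {
    cp <- cutpoints[[node]]
    if (length(cp) < 1L || is.unsorted(cp, strictly = TRUE)) {
      stop("cut-points for '", node, "' must be strictly increasing",
           call. = FALSE)
    }
    x <- raw[[node]]
    raw[[node]] <- ifelse(is.na(x), NA_integer_,
                          vapply(x, function(v) sum(v >= cp), numeric(1)))
    raw[[node]] <- as.integer(raw[[node]])
  }
  raw
}

#' Rank-based cut-points splitting scores into equal-frequency levels
#'
#' Returns the `(1:(n_levels-1))/n_levels` quantiles of `x` — tertiles by
#' default — for use with [discretize_scores()].
#'
#' @param x numeric scores (NAs ignored).
#' @param n_levels number of target levels (default 3).
#' @return Numeric vector of `n_levels - 1` cut-points.
#' @export
tertile_cutpoints <- function(x, n_levels = 3L) {
  stopifnot(n_levels >= 2L)
  stats::quantile(x, probs = seq_len(n_levels - 1L) / n_levels,
                  na.rm = TRUE, names = FALSE)
}

#' Characteristic discontinuation subtype
#'
#' The four course shapes used to structure reference trajectories:
#' early, mid-course and late persistent discontinuation, and transient
#' discontinuation with subsequent recovery of adherence.
#'
#' @param subtype one of `"early_persistent"`, `"mid_persistent"`,
#'   `"late_persistent"`, `"transient_recovery"`.
#' @param discontinue_at 1-based assessment index of the first discontinued
#'   assessment.
#' @param recover_at for the transient subtype, the assessment index at
#'   which adherence resumes (must exceed `discontinue_at`).
#' @param n_assessments number of annual assessments in the trajectory.
#' @return An object of class `subtype_spec`.
#' @export
subtype_spec <- function(subtype = c("early_persistent", "mid_persistent",
                                     "late_persistent", "transient_recovery"),
                         discontinue_at, recover_at = NULL,
                         n_assessments = 7L) {
  subtype <- match.arg(subtype)
  discontinue_at <- as.integer(discontinue_at)
  n_assessments <- as.integer(n_assessments)
  if (discontinue_at < 1L || discontinue_at > n_assessments) {
    stop("discontinue_at must lie within the assessment range", call. = FALSE)
  }
  if (subtype == "transient_recovery") {
    if (is.null(recover_at)) stop("transient subtype needs recover_at",
                                  call. = FALSE)
    recover_at <- as.integer(recover_at)
    if (recover_at <= discontinue_at || recover_at > n_assessments) {
      stop("recover_at must lie after discontinue_at within the range",
           call. = FALSE)
    }
  } else {
    recover_at <- NA_integer_
  }
  structure(list(subtype = subtype, discontinue_at = discontinue_at,
                 recover_at = recover_at, n_assessments = n_assessments),
            class = "subtype_spec")
}

# adherence status pattern implied by a subtype, as a logical vector
subtype_pattern <- function(spec) {
  t <- seq_len(spec$n_assessments)
  adherent <- t < spec$discontinue_at
  if (spec$subtype == "transient_recovery") {
    adherent[t >= spec$recover_at] <- TRUE
  }
  adherent
}

default_subtype_specs <- function(n_assessments = 7L) {
  list(
    subtype_spec("early_persistent", 2L, n_assessments = n_assessments),
    subtype_spec("mid_persistent", 4L, n_assessments = n_assessments),
    subtype_spec("late_persistent", n_assessments - 1L,
                 n_assessments = n_assessments),
    subtype_spec("transient_recovery", 3L, 5L, n_assessments = n_assessments)
  )
}

adherence_status <- function(level, amax) {
  ifelse(level == amax, "adherent", "discontinued")
}

#' Simulate a discretized longitudinal adherence cohort
#'
#' Emulates the shape of an annual-assessment adherence study: each
#' participant receives a random demographic (input-node) profile and a
#' random dynamic start, the model is advanced `steps_between` synchronous
#' decisional steps between consecutive annual assessments, and the state
#' is recorded at each assessment. Observation noise flips a recorded level
#' by one (within range) with probability `noise_rate`; records go missing
#' with probability `missing_rate`. The adherence status column derives
#' from the recorded adherence-node level when that node is observed (so
#' status and level never disagree) and from the underlying state
#' otherwise.
#'
#' @inheritParams network_image
#' @param n_participants cohort size (default 82).
#' @param n_assessments assessments per participant; a vector is sampled
#'   uniformly per participant (default `3:7`, at least 3 each).
#' @param steps_between internal synchronous steps per assessment interval
#'   (default 1).
#' @param noise_rate per-record probability of a one-level flip, in `[0,1)`.
#' @param missing_rate per-record probability of a missing marker, in
#'   `[0,1)`.
#' @param seed optional integer seed; fixed seeds reproduce the cohort.
#' @return A data.frame with columns `participant_id`, `timepoint`,
#'   `adherence`, then one integer column per node (`NA` = missing).
#' @export
simulate_cohort <- function(net, params, n_participants = 82L,
                            n_assessments = 3:7, steps_between = 1L,
                            noise_rate = 0, missing_rate = 0, seed = NULL) {
  stopifnot(n_participants >= 1L, steps_between >= 1L,
            noise_rate >= 0, noise_rate < 1,
            missing_rate >= 0, missing_rate < 1,
            all(n_assessments >= 3L))
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes(net)
  Lmax <- max_levels(net)
  ai <- node_index(net, net$adherence_node)
  rows <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    n_a <- if (length(n_assessments) > 1L)
      sample(n_assessments, 1L) else n_assessments
    s <- vapply(net$nodes$n_levels, function(L) sample.int(L, 1L) - 1L,
                integer(1))
    rec <- matrix(NA_integer_, n_a, n)
    status <- character(n_a)
    for (t in seq_len(n_a)) {
      obs <- corrupt_observation(s, Lmax, noise_rate, missing_rate)
      rec[t, ] <- obs
      status[t] <- adherence_status(
        if (is.na(obs[ai])) s[ai] else obs[ai], Lmax[ai])
      if (t < n_a) {
        for (k in seq_len(steps_between)) s <- step_synchronous(net, params, s)
      }
    }
    colnames(rec) <- net$nodes$name
    rows[[p]] <- cbind(
      data.frame(participant_id = sprintf("p%03d", p),
                 timepoint = seq_len(n_a), adherence = status),
      as.data.frame(rec))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

corrupt_observation <- function(s, Lmax, noise_rate, missing_rate) {
  obs <- s
  if (noise_rate > 0) {
    flip <- stats::runif(length(s)) < noise_rate
    if (any(flip)) {
      dir <- sample(c(-1L, 1L), sum(flip), replace = TRUE)
      v <- obs[flip] + dir
      # reflect off the ends of the scale so the flip always moves one level
      v <- ifelse(v < 0L, 1L, v)
      v <- ifelse(v > Lmax[flip], Lmax[flip] - 1L, v)
      obs[flip] <- v
    }
  }
  if (missing_rate > 0) {
    obs[stats::runif(length(s)) < missing_rate] <- NA_integer_
  }
  obs
}

#' The eight reference trajectories: four subtypes, two contrasting profiles
#'
#' Builds one trajectory per characteristic discontinuation subtype and per
#' maximally contrasting demographic profile (all input nodes low vs. all
#' high), eight in total. Dynamic nodes start adherent-side at random and
#' evolve under the model, while the adherence node is pinned to the
#' subtype's status pattern — adherent until the discontinuation index,
#' then discontinued, with the transient subtype recovering — so every
#' trajectory realizes its course shape exactly.
#'
#' @inheritParams simulate_cohort
#' @param subtypes list of [subtype_spec()]s (default: discontinuation at
#'   assessment 2, 4 and `n - 1` plus a transient course discontinuing at 3
#'   and recovering at 5, over 7 assessments).
#' @param n_assessments assessments per trajectory (default 7).
#' @return A trajectory data.frame as in [simulate_cohort()], with a
#'   `subtype` attribute mapping participant ids to subtype names.
#' @export
characteristic_trajectories <- function(net, params, seed = NULL,
                                        n_assessments = 7L,
                                        subtypes = NULL,
                                        steps_between = 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(subtypes)) subtypes <- default_subtype_specs(n_assessments)
  n <- n_nodes(net)
  Lmax <- max_levels(net)
  ai <- node_index(net, net$adherence_node)
  input <- !dynamic_mask(net)
  rows <- list()
  labels <- character(0)
  for (sp in subtypes) {
    pattern <- subtype_pattern(sp)
    for (profile in c("low", "high")) {
      s <- vapply(net$nodes$n_levels, function(L) sample.int(L, 1L) - 1L,
                  integer(1))
      s[input] <- if (profile == "low") 0L else Lmax[input]
      pid <- sprintf("%s_%s", sp$subtype, profile)
      labels[pid] <- sp$subtype
      rec <- matrix(NA_integer_, sp$n_assessments, n)
      for (t in seq_len(sp$n_assessments)) {
        s[ai] <- if (pattern[t]) Lmax[ai] else 0L
        rec[t, ] <- s
        if (t < sp$n_assessments) {
          for (k in seq_len(steps_between)) {
            s <- step_synchronous(net, params, s)
          }
        }
      }
      colnames(rec) <- net$nodes$name
      rows[[pid]] <- cbind(
        data.frame(participant_id = pid,
                   timepoint = seq_len(sp$n_assessments),
                   adherence = adherence_status(rec[, ai], Lmax[ai])),
        as.data.frame(rec))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "subtype") <- labels
  out
}

#' Validate a trajectory table against a network
#'
#' Checks the column contract, that each participant has at least three
#' assessments at strictly increasing timepoints, that observed levels are
#' in range, and that the adherence status column agrees with the
#' adherence-node level wherever that node is observed.
#'
#' @inheritParams network_image
#' @param trajectories a trajectory data.frame (see [simulate_cohort()]).
#' @param min_assessments minimum assessments per participant (default 3).
#' @return `trajectories`, invisibly.
#' @export
validate_trajectories <- function(net, trajectories, min_assessments = 3L) {
  need <- c("participant_id", "timepoint", "adherence", net$nodes$name)
  absent <- setdiff(need, names(trajectories))
  if (length(absent)) {
    stop("trajectory table lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  Lmax <- max_levels(net)
  for (j in seq_along(net$nodes$name)) {
    v <- trajectories[[net$nodes$name[j]]]
    if (any(v < 0L | v > Lmax[j], na.rm = TRUE)) {
      stop("levels out of range for node ", net$nodes$name[j], call. = FALSE)
    }
  }
  by_p <- split(trajectories, trajectories$participant_id)
  ai_name <- net$adherence_node
  amax <- Lmax[node_index(net, ai_name)]
  for (tr in by_p) {
    if (nrow(tr) < min_assessments) {
      stop("participant ", tr$participant_id[1], " has fewer than ",
           min_assessments, " assessments", call. = FALSE)
    }
    if (is.unsorted(tr$timepoint, strictly = TRUE)) {
      stop("timepoints not strictly increasing for participant ",
           tr$participant_id[1], call. = FALSE)
    }
    lev <- tr[[ai_name]]
    seen <- !is.na(lev)
    if (any(adherence_status(lev[seen], amax) != tr$adherence[seen])) {
      stop("adherence status inconsistent with adherence-node level for ",
           tr$participant_id[1], call. = FALSE)
    }
  }
  invisible(trajectories)
}

#' Read / write trajectory CSV files
#'
#' Columns `participant_id, timepoint, adherence, <one per node>`; missing
#' values empty. `write_trajectories()` also writes a YAML sidecar
#' (`<path>.yml`) recording any generation parameters attached to the table
#' as attribute `"generation"`.
#'
#' @param trajectories a trajectory data.frame.
#' @param path CSV file path.
#' @return `read_trajectories()` the data.frame; `write_trajectories()` the
#'   path, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE, quote = FALSE,
                   na = "")
  gen <- attr(trajectories, "generation")
  if (!is.null(gen)) yaml::write_yaml(gen, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".yml")
  if (file.exists(side)) attr(out, "generation") <- yaml::read_yaml(side)
  out
}
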