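# Minimal intervention sets: clamp combinations on targetable nodes that
# move a persistent non-adherent state back to sustained adherence.

#' Intervention actions
#'
#' An action clamps one targetable node at an extreme level: direction
#' `"up"` holds it at its maximum level, `"down"` at 0.
#'
#' @param node character vector of targetable node names.
#' @param direction matching vector of `"up"`/`"down"`.
#' @return A data.frame with columns `node` and `direction`.
#' @export
intervention_actions <- function(node, direction) {
  stopifnot(length(node) == length(direction),
            all(direction %in% c("up", "down")))
  data.frame(node = as.character(node), direction = as.character(direction))
}

validate_actions <- function(net, actions) {
  if (!nrow(actions)) return(invisible(actions))
  idx <- node_index(net, actions$node)
  ok <- net$nodes$targetable[idx]
  if (!all(ok)) {
    stop("action on non-targetable node(s): ",
         paste(actions$node[!ok], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(actions$node)) {
    stop("a node may appear in at most one action", call. = FALSE)
  }
  invisible(actions)
}

clamp_levels <- function(net, actions) {
  idx <- node_index(net, actions$node)
  ifelse(actions$direction == "up", max_levels(net)[idx], 0L)
}

first_state <- function(attractor_or_state) {
  if (inherits(attractor_or_state, "attractor")) {
    attractor_or_state$states[1L, ]
  } else {
    attractor_or_state
  }
}

#' Apply an intervention and test for sustained adherence
#'
#' Clamps each action's node at its extreme level, holds the clamp for
#' `hold_steps` synchronous steps, then (in the default release mode)
#' releases it and lets the network settle into an attractor within
#' `max_steps` further steps. The intervention succeeds if the final
#' attractor is adherent — the adherence node sits at its maximum level in
#' every state of the cycle — i.e. the behavioral trap has been broken in
#' favor of a sustained return to adherence. In sustained mode
#' (`release = FALSE`) the clamp is never lifted and the clamped dynamics
#' must settle into an adherent attractor.
#'
#' With `noise_prob > 0`, every dynamic node is additionally perturbed by
#' one level with that probability at each step of the clamped and
#' transient phases (clamped nodes are re-imposed); the run then finishes
#' with a noise-free descent to an attractor before success is judged.
#'
#' @inheritParams network_image
#' @param state a non-transient starting state: an
#'   [attractor][enumerate_attractors()] (its first cycle state is used) or
#'   a state vector.
#' @param actions data.frame from [intervention_actions()]; may be empty.
#' @param hold_steps steps the clamp is held (default 5).
#' @param max_steps post-release settling horizon (default 50).
#' @param release lift the clamp after `hold_steps` (default `TRUE`).
#' @param noise_prob per-step, per-node perturbation probability.
#' @return A list of class `intervention_outcome`:
#'   * `success`: reached and maintains adherence,
#'   * `promptness`: steps from clamp onset until the adherence node first
#'     attains its maximum (`NA` if never),
#'   * `attractor`: the attractor finally reached (`NULL` if unconverged),
#'   * `states`: the full visited state matrix.
#' @export
apply_intervention <- function(net, params, state, actions,
                               hold_steps = 5L, max_steps = 50L,
                               release = TRUE, noise_prob = 0) {
  stopifnot(hold_steps >= 1L, max_steps >= 1L,
            noise_prob >= 0, noise_prob < 1)
  validate_actions(net, actions)
  s <- validate_state(net, first_state(state))
  idx <- if (nrow(actions)) node_index(net, actions$node) else integer(0)
  lv <- clamp_levels(net, actions)
  ai <- node_index(net, net$adherence_node)
  amax <- max_levels(net)[ai]
  dyn <- which(dynamic_mask(net))
  Lmax <- max_levels(net)

  s[idx] <- lv
  states <- matrix(s, nrow = 1L)
  promptness <- if (s[ai] == amax) 0L else NA_integer_
  step_noisy <- function(s, clamp) {
    s <- step_synchronous(net, params, s)
    if (noise_prob > 0) {
      flip <- dyn[stats::runif(length(dyn)) < noise_prob]
      if (length(flip)) {
        d <- sample(c(-1L, 1L), length(flip), replace = TRUE)
        s[flip] <- pmin(pmax(s[flip] + d, 0L), Lmax[flip])
      }
    }
    if (clamp) s[idx] <- lv
    s
  }
  t <- 0L
  for (k in seq_len(hold_steps)) {
    s <- step_noisy(s, clamp = TRUE)
    t <- t + 1L
    states <- rbind(states, s)
    if (is.na(promptness) && s[ai] == amax) promptness <- t
  }
  if (release) {
    if (noise_prob > 0) {
      for (k in seq_len(max_steps)) {
        s <- step_noisy(s, clamp = FALSE)
        t <- t + 1L
        states <- rbind(states, s)
        if (is.na(promptness) && s[ai] == amax) promptness <- t
      }
    }
    final <- simulate_network(net, params, s, max_steps = max_steps)
    att <- final$attractor
  } else {
    # settle under a sustained clamp: clamped nodes become effective inputs
    seen <- new.env(parent = emptyenv())
    assign(state_key(s), 1L, envir = seen)
    att <- NULL
    cyc_states <- matrix(s, nrow = 1L)
    for (k in seq_len(max_steps)) {
      s <- step_noisy(s, clamp = TRUE)
      t <- t + 1L
      states <- rbind(states, s)
      if (is.na(promptness) && s[ai] == amax) promptness <- t
      key <- state_key(s)
      first <- get0(key, envir = seen)
      if (!is.null(first) && noise_prob == 0) {
        att <- make_attractor(
          net, cyc_states[first:nrow(cyc_states), , drop = FALSE])
        break
      }
      assign(key, nrow(cyc_states) + 1L, envir = seen)
      cyc_states <- rbind(cyc_states, s)
    }
  }
  if (!is.null(att)) {
    if (is.na(promptness) && any(att$states[, ai] == amax)) {
      # adherence attained inside the final attractor descent
      promptness <- t
    }
  }
  success <- !is.null(att) && att$adherent
  colnames(states) <- net$nodes$name
  rownames(states) <- NULL
  structure(list(success = success, promptness = promptness,
                 attractor = att, states = states),
            class = "intervention_outcome")
}

#' @export
print.intervention_outcome <- function(x, ...) {
  cat(sprintf("<intervention_outcome> %s, promptness %s\n",
              if (x$success) "success" else "failure",
              ifelse(is.na(x$promptness), "-", x$promptness)))
  invisible(x)
}

action_label <- function(actions) {
  if (!nrow(actions)) return("(none)")
  paste(sprintf("%s%s", ifelse(actions$direction == "up", "\u2191", "\u2193"),
                actions$node),
        collapse = " + ")
}

#' Find minimal intervention sets for a persistent non-adherent state
#'
#' Searches combinations of clamped targetable nodes in increasing size
#' (singletons first, then pairs, up to `max_size`) and returns every
#' *minimal* successful set: a combination succeeds and none of its strict
#' subsets does. The search is exhaustive within the size bound; supersets
#' of already-successful sets are skipped, which is exactly the minimality
#' filter. An adherent source state yields a single empty-set result marked
#' `already_adherent`; an empty result means the state is untreatable
#' within the size bound under this model.
#'
#' @inheritParams apply_intervention
#' @param attractor source attractor (or one of its states).
#' @param max_size largest action-set size searched (default 2, i.e. one or
#'   two clinically actionable mediators).
#' @return An object of class `mis_set`: a list of results, each with
#'   `actions`, `label`, `size`, `promptness` and `already_adherent`;
#'   ordered by size, then promptness, then label.
#' @export
find_mis <- function(net, params, attractor, max_size = 2L, hold_steps = 5L,
                     max_steps = 50L, release = TRUE) {
  stopifnot(max_size >= 1L)
  s0 <- validate_state(net, first_state(attractor))
  ai <- node_index(net, net$adherence_node)
  amax <- max_levels(net)[ai]
  adherent_now <- if (inherits(attractor, "attractor"))
    attractor$adherent else s0[ai] == amax
  if (adherent_now) {
    return(structure(list(list(
      actions = intervention_actions(character(0), character(0)),
      label = "(none)", size = 0L, promptness = 0L,
      already_adherent = TRUE)), class = "mis_set"))
  }
  targets <- net$nodes$name[net$nodes$targetable]
  if (!length(targets)) return(structure(list(), class = "mis_set"))
  singles <- expand.grid(node = targets, direction = c("up", "down"),
                         stringsAsFactors = FALSE)
  singles <- singles[order(singles$node, singles$direction), ]
  results <- list()
  success_sets <- list()  # lists of row indices into `singles`
  for (size in seq_len(min(max_size, length(targets)))) {
    combos <- utils::combn(nrow(singles), size, simplify = FALSE)
    for (cmb in combos) {
      acts <- singles[cmb, , drop = FALSE]
      if (anyDuplicated(acts$node)) next  # one clamp per node
      if (any(vapply(success_sets, function(w) all(w %in% cmb), logical(1))))
        next  # strict superset of a known success: not minimal
      out <- apply_intervention(net, params, s0,
                                intervention_actions(acts$node,
                                                     acts$direction),
                                hold_steps = hold_steps,
                                max_steps = max_steps, release = release)
      if (out$success) {
        success_sets[[length(success_sets) + 1L]] <- cmb
        results[[length(results) + 1L]] <- list(
          actions = acts[, c("node", "direction")],
          label = action_label(acts), size = size,
          promptness = out$promptness, already_adherent = FALSE)
      }
    }
  }
  ord <- order(vapply(results, `[[`, integer(1), "size"),
               vapply(results, function(r)
                 ifelse(is.na(r$promptness), Inf, r$promptness), numeric(1)),
               vapply(results, `[[`, character(1), "label"))
  structure(results[ord], class = "mis_set")
}

#' @export
print.mis_set <- function(x, ...) {
  cat(sprintf("<mis_set> %d minimal intervention set(s)\n", length(x)))
  for (r in x) {
    cat(sprintf("  %s (size %d, promptness %s)%s\n", r$label, r$size,
                ifelse(is.na(r$promptness), "-", r$promptness),
                if (isTRUE(r$already_adherent)) " [already adherent]" else ""))
  }
  invisible(x)
}

#' Robustness of an intervention to observation/actuation noise
#'
#' Repeats [apply_intervention()] under per-step, per-node one-level
#' perturbations occurring with probability `noise_prob` and returns the
#' fraction of replicates that still end in sustained adherence. Seeded and
#' reproducible.
#'
#' @inheritParams apply_intervention
#' @param actions the action set to score (or a `find_mis()` result
#'   element, whose `$actions` are used).
#' @param noise_prob perturbation probability per node and step
#'   (default 0.05).
#' @param n_replicates Monte Carlo replicates (default 100).
#' @param seed optional integer seed.
#' @return Fraction in `[0, 1]`.
#' @export
score_robustness <- function(net, params, state, actions,
                             noise_prob = 0.05, n_replicates = 100L,
                             seed = NULL, hold_steps = 5L, max_steps = 50L,
                             release = TRUE) {
  stopifnot(n_replicates >= 1L, noise_prob >= 0, noise_prob < 1)
  if (is.list(actions) && !is.data.frame(actions) &&
      !is.null(actions$actions)) {
    actions <- actions$actions
  }
  if (!is.null(seed)) set.seed(seed)
  ok <- 0L
  for (r in seq_len(n_replicates)) {
    out <- apply_intervention(net, params, state, actions,
                              hold_steps = hold_steps, max_steps = max_steps,
                              release = release, noise_prob = noise_prob)
    ok <- ok + out$success
  }
  ok / n_replicates
}

#' Consensus intervention table across candidate models
#'
#' Runs the minimal-intervention-set search under every candidate model:
#' for each model, the persistent non-adherent end-states are estimated by
#' repeated simulation, each is subjected to [find_mis()], and the
#' successful strategies are pooled. The result mirrors an idealized
#' intervention table: one row per strategy (action combination) with the
#' number of distinct non-adherent states it rescues overall and within
#' each demographic stratum (each input node x level), the number of
#' supporting models, and whether support is unanimous.
#'
#' @inheritParams find_mis
#' @param models a `candidate_models` object or list of parameter sets.
#' @param n_inits,sim_max_steps restarts and horizon for the per-model
#'   attractor estimation (defaults 1000 and 50).
#' @param min_basin smallest basin frequency (behavioral inertia) for a
#'   non-adherent end-state to enter the intervention search (default 0).
#' @param max_states at most this many non-adherent end-states per model
#'   enter the search, taken in decreasing order of behavioral inertia
#'   (default 20); rarer states are reported in the census but not
#'   targeted.
#' @param seed optional integer seed for the attractor sampling.
#' @return A list of class `consensus_interventions`:
#'   * `table`: the strategy x stratum data.frame (`strategy`, `size`, one
#'     `<input>.<level>` column per stratum, `total_rescued`,
#'     `supporting_models`, `unanimous`),
#'   * `n_models`, `n_models_with_traps` (models whose targeted state list
#'     was non-empty; unanimity is judged against these),
#'     `n_nonadherent_states`, `n_rescued_states`,
#'   * `details`: per-model, per-attractor MIS results.
#' @export
consensus_interventions <- function(net, models, max_size = 2L,
                                    hold_steps = 5L, max_steps = 50L,
                                    release = TRUE, n_inits = 1000L,
                                    sim_max_steps = 50L, min_basin = 0,
                                    max_states = 20L, seed = NULL) {
  if (inherits(models, "candidate_models")) models <- models$models
  stopifnot(length(models) >= 1L)
  input_nodes <- net$nodes$name[!dynamic_mask(net)]
  details <- list()
  # strategy label -> environment bookkeeping
  rescued_by <- new.env(parent = emptyenv())   # label -> state keys
  support_by <- new.env(parent = emptyenv())   # label -> model indices
  meta_by <- new.env(parent = emptyenv())      # label -> actions/size
  state_profiles <- new.env(parent = emptyenv())
  n_nonadherent <- character(0)

  models_with_traps <- integer(0)
  for (mi in seq_along(models)) {
    att_seed <- if (is.null(seed)) NULL else derive_seed(seed, mi)
    atts <- sample_attractors(net, models[[mi]], n_inits = n_inits,
                              max_steps = sim_max_steps, seed = att_seed)
    nonadh <- Filter(function(a)
      !a$adherent && a$basin_frequency >= min_basin, atts)
    if (length(nonadh) > max_states) nonadh <- nonadh[seq_len(max_states)]
    if (length(nonadh)) models_with_traps <- c(models_with_traps, mi)
    for (a in nonadh) {
      n_nonadherent <- union(n_nonadherent, a$id)
      profile <- a$states[1L, match(input_nodes, colnames(a$states))]
      assign(a$id, profile, envir = state_profiles)
      mis <- find_mis(net, models[[mi]], a, max_size = max_size,
                      hold_steps = hold_steps, max_steps = max_steps,
                      release = release)
      details[[length(details) + 1L]] <-
        list(model = mi, attractor = a$id, mis = mis)
      for (r in mis) {
        if (isTRUE(r$already_adherent)) next
        lb <- r$label
        assign(lb, union(get0(lb, envir = rescued_by, ifnotfound = character(0)),
                         a$id), envir = rescued_by)
        assign(lb, union(get0(lb, envir = support_by, ifnotfound = integer(0)),
                         mi), envir = support_by)
        if (is.null(get0(lb, envir = meta_by))) {
          assign(lb, list(actions = r$actions, size = r$size),
                 envir = meta_by)
        }
      }
    }
  }

  labels <- sort(ls(meta_by))
  strat_cols <- unlist(lapply(input_nodes, function(nd) {
    L <- net$nodes$n_levels[node_index(net, nd)]
    stats::setNames(seq_len(L) - 1L, paste0(nd, ".", seq_len(L) - 1L))
  }))
  rows <- lapply(labels, function(lb) {
    ids <- get(lb, envir = rescued_by)
    meta <- get(lb, envir = meta_by)
    support <- get(lb, envir = support_by)
    left <- data.frame(strategy = lb, size = meta$size)
    right <- data.frame(total_rescued = length(ids),
                        supporting_models = length(support),
                        unanimous = all(models_with_traps %in% support))
    if (!length(strat_cols)) return(cbind(left, right))
    counts <- vapply(names(strat_cols), function(cn) {
      nd <- sub("\\.[0-9]+$", "", cn)
      lv <- strat_cols[[cn]]
      sum(vapply(ids, function(id)
        get(id, envir = state_profiles)[[nd]] == lv, logical(1)))
    }, integer(1))
    cbind(left, as.data.frame(as.list(counts), check.names = FALSE), right)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(strategy = character(), size = integer(),
               total_rescued = integer(), supporting_models = integer(),
               unanimous = logical())
  if (nrow(tab)) {
    tab <- tab[order(tab$size, -tab$total_rescued, tab$strategy), ]
    rownames(tab) <- NULL
  }
  all_rescued <- unique(unlist(lapply(labels, get, envir = rescued_by)))
  structure(list(table = tab, n_models = length(models),
                 n_models_with_traps = length(models_with_traps),
                 n_nonadherent_states = length(n_nonadherent),
                 n_rescued_states = length(all_rescued),
                 details = details),
            class = "consensus_interventions")
}

#' @export
print.consensus_interventions <- function(x, ...) {
  cat(sprintf(
    "<consensus_interventions> %d model(s) (%d with targeted traps), %d non-adherent state(s), %d rescuable\n",
    x$n_models, x$n_models_with_traps, x$n_nonadherent_states,
    x$n_rescued_states))
  if (nrow(x$table)) {
    print(x$table[, c("strategy", "size", "total_rescued",
                      "supporting_models", "unanimous")], row.names = FALSE)
  }
  invisible(x)
}

#' Write the consensus intervention table to CSV
#'
#' @param x a `consensus_interventions` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(x, path) {
  utils::write.csv(x$table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
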