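# Model fitting: Manhattan alignment error, transition coverage, and
# exhaustive constraint-satisfaction identification of decisional kinetic
# parameters (perception thresholds and logic weights).

# Build the scored transition contexts of one trajectory table: for every
# consecutive assessment pair, the start state (missing values imputed at the
# nominal level) and the observed levels at the later assessment.
transition_contexts <- function(net, trajectories) {
  validate_trajectories(net, trajectories)
  node_names <- net$nodes$name
  nominal <- nominal_levels(net)
  by_p <- split(trajectories, trajectories$participant_id)
  out <- list()
  for (tr in by_p) {
    if (nrow(tr) < 2L) next
    obs <- as.matrix(tr[, node_names, drop = FALSE])
    storage.mode(obs) <- "integer"
    for (i in seq_len(nrow(tr) - 1L)) {
      start <- obs[i, ]
      miss <- is.na(start)
      start[miss] <- nominal[miss]
      out[[length(out) + 1L]] <- list(
        participant = tr$participant_id[1L],
        timepoint = tr$timepoint[i + 1L],
        start = start,
        observed = obs[i + 1L, ])
    }
  }
  out
}

#' Manhattan alignment error between model and observed trajectories
#'
#' For each consecutive assessment pair, the model starts at the observed
#' state (missing node levels imputed at the nominal, i.e. middle, level),
#' advances `K` synchronous decisional steps, and the predicted state is
#' compared with the later assessment. The error is the Manhattan distance —
#' the summed absolute level difference over dynamic nodes observed at the
#' later assessment — and is decomposed both by node and by observation
#' (participant x timepoint); each decomposition sums back to the total.
#'
#' @inheritParams network_image
#' @param trajectories trajectory data.frame (see [simulate_cohort()]).
#' @param K internal synchronous steps per assessment interval (default 1).
#' @return An object of class `alignment_error`:
#'   * `total`: summed absolute level differences,
#'   * `by_node`: data.frame `node, error, percent` (percent of total),
#'   * `by_observation`: data.frame `participant, timepoint, error`,
#'   * `n_scored`: number of scored (non-missing, dynamic) node-observations,
#'   * `n_mismatch`: scored node-observations predicted at the wrong level,
#'   * `coverage`: `1 - n_mismatch / n_scored`.
#' @export
alignment_error <- function(net, params, trajectories, K = 1L) {
  stopifnot(K >= 1L)
  ctx <- transition_contexts(net, trajectories)
  dyn <- dynamic_mask(net)
  node_err <- stats::setNames(numeric(n_nodes(net)), net$nodes$name)
  obs_rows <- list()
  total <- 0L; n_scored <- 0L; n_mismatch <- 0L
  for (cx in ctx) {
    s <- cx$start
    for (k in seq_len(K)) s <- step_synchronous(net, params, s)
    scored <- dyn & !is.na(cx$observed)
    d <- abs(s[scored] - cx$observed[scored])
    total <- total + sum(d)
    n_scored <- n_scored + sum(scored)
    n_mismatch <- n_mismatch + sum(d > 0L)
    node_err[scored] <- node_err[scored] + d
    obs_rows[[length(obs_rows) + 1L]] <- data.frame(
      participant = cx$participant, timepoint = cx$timepoint,
      error = sum(d))
  }
  by_obs <- if (length(obs_rows)) do.call(rbind, obs_rows) else
    data.frame(participant = character(), timepoint = integer(),
               error = numeric())
  by_node <- data.frame(
    node = names(node_err), error = as.numeric(node_err),
    percent = if (total > 0) 100 * node_err / total else 0 * node_err,
    row.names = NULL)
  structure(
    list(total = as.numeric(total), by_node = by_node,
         by_observation = by_obs, n_scored = n_scored,
         n_mismatch = n_mismatch,
         coverage = if (n_scored > 0) 1 - n_mismatch / n_scored else 1),
    class = "alignment_error")
}

#' @export
print.alignment_error <- function(x, ...) {
  cat(sprintf(
    "<alignment_error> total %g over %d scored node-observations (coverage %.3f)\n",
    x$total, x$n_scored, x$coverage))
  worst <- x$by_node[order(-x$by_node$error), ]
  worst <- worst[worst$error > 0, ]
  if (nrow(worst)) {
    cat("  highest-error nodes:",
        paste(sprintf("%s (%.1f%%)", utils::head(worst$node, 3),
                      utils::head(worst$percent, 3)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fraction of observed node transitions the model predicts correctly
#'
#' The share of scored node-observations whose predicted level equals the
#' observed level — the coverage of "coordinated changes" the candidate
#' decisional logic accounts for. Equals
#' `1 - n_mismatch / n_scored` from [alignment_error()]. Vacuously 1 when
#' nothing is scored.
#'
#' @inheritParams alignment_error
#' @return A single fraction in `[0, 1]`.
#' @export
transition_coverage <- function(net, params, trajectories, K = 1L) {
  alignment_error(net, params, trajectories, K = K)$coverage
}

# enumerate the (theta, weight) assignment grid for a set of edges,
# lexicographic over edges then domains; returns a data.frame with columns
# theta.<k>/weight.<k> (0-column, 1-row frame for zero edges)
assignment_grid <- function(net, edge_idx, theta_domain = NULL,
                            weight_domain = c(1L, 2L)) {
  m <- length(edge_idx)
  if (m == 0L) return(data.frame(row.names = 1L)[, FALSE, drop = FALSE])
  src_max <- max_levels(net)[net$edges$.src[edge_idx]]
  doms <- list()
  for (k in seq_len(m)) {
    th <- seq_len(src_max[k])
    if (!is.null(theta_domain)) th <- intersect(th, as.integer(theta_domain))
    if (!length(th)) stop("empty theta domain for an edge", call. = FALSE)
    doms[[paste0("theta.", k)]] <- as.integer(th)
    doms[[paste0("weight.", k)]] <- sort(as.integer(weight_domain))
  }
  # expand.grid varies the first factor fastest; reverse for lexicographic
  # order over (edge1 theta, edge1 weight, edge2 theta, ...)
  g <- expand.grid(rev(doms), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(names(g)), drop = FALSE]
  g[do.call(order, g), , drop = FALSE]
}

# predicted next level of one node given in-edge levels and an assignment
predict_node_level <- function(cur, src_levels, signs, theta, weight, lmax) {
  perceived <- src_levels >= theta
  force <- sum(signs[perceived] * weight[perceived])
  min(max(cur + sign(force), 0L), lmax)
}

#' Exhaustively fit one node's in-edge parameters by constraint satisfaction
#'
#' Enumerates every (threshold, weight) assignment over the target node's
#' in-edges and keeps those whose one-step prediction reproduces every
#' scored observed transition of that node across the trajectories. With
#' one decisional step per assessment interval (`K = 1`) each node's next
#' level depends only on its own in-edges, so the network-wide search
#' decomposes exactly into these per-node problems. Missing start levels
#' are imputed at the nominal level; assessments where the target itself is
#' unobserved are not scored. An empty solution set is a legal outcome
#' (contradictory observations); a node with no scored transitions returns
#' the full domain (vacuous constraints).
#'
#' @inheritParams alignment_error
#' @param target_node name of a dynamic node.
#' @param theta_domain optional integer vector restricting thresholds
#'   (intersected with each edge's `1:(n_levels(source) - 1)`).
#' @param weight_domain admissible weights (default `c(1, 2)`).
#' @return An object of class `node_csp`:
#'   * `target`, `edges` (in-edge data.frame),
#'   * `assignments`: the full grid, one row per assignment
#'     (columns `theta.k`/`weight.k` per in-edge, lexicographic order),
#'   * `mismatches`: per-assignment count of violated transitions,
#'   * `solutions`: rows of `assignments` with zero mismatches,
#'   * `n_scored`: number of scored transitions of this node.
#' @export
fit_node_csp <- function(net, target_node, trajectories, K = 1L,
                         theta_domain = NULL, weight_domain = c(1L, 2L)) {
  if (K != 1L) {
    stop("the per-node CSP decomposition requires K = 1; use fit_network() ",
         "for multi-step fitting", call. = FALSE)
  }
  ti <- node_index(net, target_node)
  if (net$nodes$kind[ti] != "dynamic") {
    stop("target node must be dynamic", call. = FALSE)
  }
  edge_idx <- which(net$edges$.tgt == ti)
  ctx <- transition_contexts(net, trajectories)
  grid <- assignment_grid(net, edge_idx, theta_domain, weight_domain)
  lmax <- max_levels(net)[ti]
  signs <- net$edges$.sign[edge_idx]
  srcs <- net$edges$.src[edge_idx]
  m <- length(edge_idx)
  th_cols <- if (m) paste0("theta.", seq_len(m)) else character(0)
  w_cols <- if (m) paste0("weight.", seq_len(m)) else character(0)

  # deduplicate contexts: identical (current level, source levels, observed
  # next level) triples constrain identically, so carry a multiplicity
  n_grid <- nrow(grid)
  TH <- as.matrix(grid[, th_cols, drop = FALSE])
  # fold the edge sign into the weight once
  WS <- as.matrix(grid[, w_cols, drop = FALSE]) *
    matrix(signs, n_grid, m, byrow = TRUE)
  tallies <- new.env(parent = emptyenv())
  n_scored <- 0L
  for (cx in ctx) {
    if (is.na(cx$observed[ti])) next
    n_scored <- n_scored + 1L
    key <- paste(cx$start[ti], paste(cx$start[srcs], collapse = ","),
                 cx$observed[ti], sep = "|")
    assign(key, get0(key, envir = tallies, ifnotfound = 0L) + 1L,
           envir = tallies)
  }
  mism <- integer(n_grid)
  for (key in ls(tallies)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    cur <- as.integer(parts[1])
    src_levels <- as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    obs <- as.integer(parts[3])
    mult <- get(key, envir = tallies)
    if (m > 0L) {
      P <- matrix(src_levels, n_grid, m, byrow = TRUE) >= TH
      force <- rowSums(P * WS)
    } else {
      force <- numeric(n_grid)
    }
    pred <- pmin(pmax(cur + sign(force), 0L), lmax)
    mism <- mism + mult * (pred != obs)
  }
  structure(
    list(target = target_node,
         edges = net$edges[edge_idx, c("source", "target", "mode")],
         assignments = grid, mismatches = mism,
         solutions = grid[mism == 0L, , drop = FALSE],
         n_scored = n_scored),
    class = "node_csp")
}

#' @export
print.node_csp <- function(x, ...) {
  cat(sprintf(
    "<node_csp> %s: %d in-edge(s), %d/%d assignments satisfy %d scored transitions\n",
    x$target, nrow(x$edges), nrow(x$solutions), nrow(x$assignments),
    x$n_scored))
  invisible(x)
}

#' Enumerate candidate decisional models for the whole network
#'
#' Identifies all parameter sets (perception thresholds and logic weights)
#' whose predictions account for the observed trajectories. At `K = 1` the
#' search decomposes exactly into per-node constraint-satisfaction problems
#' ([fit_node_csp()]); the per-node assignments retained are those with the
#' fewest violated transitions for their node (the hard-constraint
#' solutions whenever a node is perfectly satisfiable), and candidate
#' models are their Cartesian product, enumerated lazily in lexicographic
#' order up to `max_models`. Models are retained only if their transition
#' coverage reaches `coverage_min` (`strict = TRUE` forces
#' `coverage_min = 1`). For `K > 1` the decomposition no longer holds and a
#' depth-first global search with a mismatch-budget bound is used; this is
#' exact but exponential and intended for small circuits.
#'
#' @inheritParams fit_node_csp
#' @param coverage_min minimum transition coverage to retain a model
#'   (default 0.75).
#' @param max_models cap on the number of models enumerated (default 100);
#'   the full candidate count is reported separately.
#' @param strict require every scored transition to be reproduced.
#' @return An object of class `candidate_models`:
#'   * `models`: list of [parameter_set()]s (length <= `max_models`),
#'   * `coverage`: per-model transition coverage,
#'   * `n_candidates`: total size of the candidate space (may exceed the
#'     enumerated count),
#'   * `per_node`: the `node_csp` objects,
#'   * `trajectory_balance`: per-participant error of the first model, for
#'     checking that no single trajectory is represented more poorly than
#'     the others,
#'   * `best_coverage`: highest achievable coverage (diagnostic when the
#'     result is empty),
#'   * `config`: fit configuration echo.
#' @export
fit_network <- function(net, trajectories, K = 1L, theta_domain = NULL,
                        weight_domain = c(1L, 2L), coverage_min = 0.75,
                        max_models = 100L, strict = FALSE) {
  stopifnot(coverage_min > 0, coverage_min <= 1, max_models >= 1L)
  if (strict) coverage_min <- 1
  config <- list(K = K, theta_domain = theta_domain,
                 weight_domain = weight_domain, coverage_min = coverage_min,
                 max_models = max_models, strict = strict)
  if (K == 1L) {
    fit <- fit_network_k1(net, trajectories, theta_domain, weight_domain,
                          coverage_min, max_models)
  } else {
    fit <- fit_network_global(net, trajectories, K, theta_domain,
                              weight_domain, coverage_min, max_models)
  }
  balance <- NULL
  if (length(fit$models)) {
    ae <- alignment_error(net, fit$models[[1L]], trajectories, K = K)
    balance <- stats::aggregate(error ~ participant, ae$by_observation, sum)
  }
  structure(c(fit, list(trajectory_balance = balance, config = config)),
            class = "candidate_models")
}

fit_network_k1 <- function(net, trajectories, theta_domain, weight_domain,
                           coverage_min, max_models) {
  dyn_nodes <- net$nodes$name[dynamic_mask(net)]
  csps <- lapply(dyn_nodes, function(v)
    fit_node_csp(net, v, trajectories, K = 1L, theta_domain = theta_domain,
                 weight_domain = weight_domain))
  names(csps) <- dyn_nodes
  n_scored_total <- sum(vapply(csps, `[[`, integer(1), "n_scored"))
  min_mism <- vapply(csps, function(cs) min(cs$mismatches), integer(1))
  best_coverage <- if (n_scored_total > 0)
    1 - sum(min_mism) / n_scored_total else 1

  # per-node retained assignments: fewest violated transitions for the node
  kept <- lapply(csps, function(cs)
    which(cs$mismatches == min(cs$mismatches)))
  sizes <- vapply(kept, length, integer(1))
  n_candidates <- prod(as.numeric(sizes))

  if (best_coverage < coverage_min) {
    return(list(models = list(), coverage = numeric(0),
                n_candidates = 0, per_node = csps,
                best_coverage = best_coverage))
  }
  n_out <- min(max_models, n_candidates)
  models <- vector("list", n_out)
  counter <- rep(1L, length(csps))  # mixed-radix, first node slowest
  for (i in seq_len(n_out)) {
    models[[i]] <- compose_model(net, csps, kept, counter, weight_domain)
    counter <- increment_counter(counter, sizes)
  }
  list(models = models, coverage = rep(best_coverage, n_out),
       n_candidates = n_candidates, per_node = csps,
       best_coverage = best_coverage)
}

increment_counter <- function(counter, sizes) {
  for (j in rev(seq_along(counter))) {
    if (counter[j] < sizes[j]) {
      counter[j] <- counter[j] + 1L
      return(counter)
    }
    counter[j] <- 1L
  }
  counter
}

compose_model <- function(net, csps, kept, counter, weight_domain) {
  theta <- integer(nrow(net$edges))
  weight <- integer(nrow(net$edges))
  theta[] <- 1L; weight[] <- 1L
  for (j in seq_along(csps)) {
    cs <- csps[[j]]
    m <- nrow(cs$edges)
    if (m == 0L) next
    row <- cs$assignments[kept[[j]][counter[j]], , drop = FALSE]
    ti <- node_index(net, cs$target)
    edge_idx <- which(net$edges$.tgt == ti)
    theta[edge_idx] <- as.integer(row[, paste0("theta.", seq_len(m))])
    weight[edge_idx] <- as.integer(row[, paste0("weight.", seq_len(m))])
  }
  parameter_set(net, theta, weight, weight_domain = weight_domain)
}

# K > 1: depth-first search over per-node assignment blocks with a global
# mismatch budget. Exact but exponential; for small circuits only.
fit_network_global <- function(net, trajectories, K, theta_domain,
                               weight_domain, coverage_min, max_models) {
  dyn_nodes <- net$nodes$name[dynamic_mask(net)]
  grids <- lapply(dyn_nodes, function(v) {
    ti <- node_index(net, v)
    assignment_grid(net, which(net$edges$.tgt == ti), theta_domain,
                    weight_domain)
  })
  names(grids) <- dyn_nodes
  sizes <- vapply(grids, nrow, integer(1))
  total_space <- prod(as.numeric(sizes))
  if (total_space > 1e6) {
    stop(sprintf(
      "global search space has %.3g assignments; reduce the network or use K = 1",
      total_space), call. = FALSE)
  }
  ctx <- transition_contexts(net, trajectories)
  n_scored_total <- sum(vapply(ctx, function(cx)
    sum(dynamic_mask(net) & !is.na(cx$observed)), integer(1)))
  budget <- floor((1 - coverage_min) * n_scored_total + 1e-9)

  counter <- rep(1L, length(grids))
  models <- list(); coverage <- numeric(0)
  best_mism <- Inf
  repeat {
    params <- compose_model_grids(net, grids, counter, weight_domain)
    mism <- model_mismatches(net, params, ctx, K)
    best_mism <- min(best_mism, mism)
    if (mism <= budget) {
      models[[length(models) + 1L]] <- params
      coverage <- c(coverage,
                    if (n_scored_total > 0) 1 - mism / n_scored_total else 1)
      if (length(models) >= max_models) break
    }
    counter <- increment_counter(counter, sizes)
    if (all(counter == 1L)) break
  }
  list(models = models, coverage = coverage,
       n_candidates = length(models), per_node = NULL,
       best_coverage = if (n_scored_total > 0)
         1 - best_mism / n_scored_total else 1)
}

compose_model_grids <- function(net, grids, counter, weight_domain) {
  theta <- rep(1L, nrow(net$edges)); weight <- rep(1L, nrow(net$edges))
  for (j in seq_along(grids)) {
    g <- grids[[j]]
    m <- ncol(g) / 2L
    if (m == 0L) next
    ti <- node_index(net, names(grids)[j])
    edge_idx <- which(net$edges$.tgt == ti)
    row <- g[counter[j], , drop = FALSE]
    theta[edge_idx] <- as.integer(row[, paste0("theta.", seq_len(m))])
    weight[edge_idx] <- as.integer(row[, paste0("weight.", seq_len(m))])
  }
  parameter_set(net, theta, weight, weight_domain = weight_domain)
}

model_mismatches <- function(net, params, ctx, K) {
  dyn <- dynamic_mask(net)
  mism <- 0L
  for (cx in ctx) {
    s <- cx$start
    for (k in seq_len(K)) s <- step_synchronous(net, params, s)
    scored <- dyn & !is.na(cx$observed)
    mism <- mism + sum(s[scored] != cx$observed[scored])
  }
  mism
}

#' @export
print.candidate_models <- function(x, ...) {
  cat(sprintf(
    "<candidate_models> %d enumerated of %s candidate(s), coverage %s\n",
    length(x$models), format(x$n_candidates, big.mark = ","),
    if (length(x$coverage)) sprintf("%.3f", max(x$coverage)) else
      sprintf("(best achievable %.3f < threshold)", x$best_coverage)))
  invisible(x)
}

#' Is a given parameter set among the fitted candidates?
#'
#' Membership is decided against the per-node retained assignment sets, so
#' it is exact even when the Cartesian product was only partially
#' enumerated under `max_models`. Falls back to comparing enumerated models
#' when per-node sets are unavailable (`K > 1` fits).
#'
#' @param candidates a `candidate_models` object from [fit_network()].
#' @param params a [parameter_set()].
#' @param net the network both are bound to.
#' @return `TRUE` or `FALSE`.
#' @export
contains_model <- function(candidates, params, net) {
  pw <- align_parameters(net, params)
  if (!is.null(candidates$per_node)) {
    for (cs in candidates$per_node) {
      m <- nrow(cs$edges)
      ti <- node_index(net, cs$target)
      edge_idx <- which(net$edges$.tgt == ti)
      keep <- which(cs$mismatches == min(cs$mismatches))
      if (m == 0L) next
      tgt_row <- c(pw$theta[edge_idx], pw$weight[edge_idx])
      grid <- cs$assignments[keep, c(paste0("theta.", seq_len(m)),
                                     paste0("weight.", seq_len(m))),
                             drop = FALSE]
      hit <- apply(grid, 1L, function(r) all(as.integer(r) == tgt_row))
      if (!any(hit)) return(FALSE)
    }
    return(TRUE)
  }
  for (mdl in candidates$models) {
    mw <- align_parameters(net, mdl)
    if (identical(mw$theta, pw$theta) && identical(mw$weight, pw$weight)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Read / write candidate models as long-format TSV
#'
#' One row per model and edge: `model_id, source, target, theta, weight`.
#'
#' @param candidates a `candidate_models` object (or list of parameter
#'   sets).
#' @param path file path.
#' @param net network to bind models to on read.
#' @return `write_models()` the path, invisibly; `read_models()` a list of
#'   [parameter_set()]s.
#' @export
write_models <- function(candidates, path) {
  models <- if (inherits(candidates, "candidate_models"))
    candidates$models else candidates
  rows <- lapply(seq_along(models), function(i)
    cbind(model_id = i, as.data.frame(models[[i]])))
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path, net) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  lapply(split(tab, tab$model_id), function(m) {
    pw <- align_parameters(net, m)
    parameter_set(net, pw$theta, pw$weight,
                  weight_domain = sort(unique(pw$weight)))
  })
}
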