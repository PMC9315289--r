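# Shared fixtures and independent oracles for the test suite.
# The oracles deliberately re-derive the decisional rule with plain loops,
# independent of the package's vectorized kernels.

toy_chain <- function() {
  # A activates B activates C; C is the adherence readout
  logic_network(
    nodes = data.frame(name = c("A", "B", "C"),
                       targetable = c(TRUE, TRUE, FALSE)),
    edges = data.frame(source = c("A", "B"), target = c("B", "C"),
                       mode = "activate"),
    adherence_node = "C")
}

self_activator <- function() {
  logic_network(
    nodes = data.frame(name = "A"),
    edges = data.frame(source = "A", target = "A", mode = "activate"),
    adherence_node = "A")
}

mutual_inhibition <- function() {
  logic_network(
    nodes = data.frame(name = c("A", "B")),
    edges = data.frame(source = c("A", "B"), target = c("B", "A"),
                       mode = "inhibit"),
    adherence_node = "A")
}

# random ternary network: n_dyn dynamic + n_input input nodes, random signed
# edges (unique source-target pairs, targets dynamic, no self-loop bias)
random_network <- function(n_dyn, n_input = 0, n_edges = NULL,
                           targetable = 0) {
  names_dyn <- paste0("d", seq_len(n_dyn))
  names_in <- if (n_input > 0) paste0("i", seq_len(n_input)) else character(0)
  all_names <- c(names_dyn, names_in)
  pairs <- expand.grid(source = all_names, target = names_dyn,
                       stringsAsFactors = FALSE)
  if (is.null(n_edges)) n_edges <- min(nrow(pairs), 2L * n_dyn)
  pick <- sample.int(nrow(pairs), min(n_edges, nrow(pairs)))
  edges <- pairs[pick, ]
  edges$mode <- sample(c("activate", "inhibit"), nrow(edges), replace = TRUE)
  tg <- rep(FALSE, length(all_names))
  if (targetable > 0) tg[seq_len(min(targetable, n_dyn))] <- TRUE
  logic_network(
    nodes = data.frame(name = all_names,
                       kind = c(rep("dynamic", n_dyn),
                                rep("input", n_input)),
                       n_levels = 3L, targetable = tg),
    edges = edges,
    adherence_node = names_dyn[1])
}

# independent reimplementation of the decisional update rule
oracle_image <- function(net, params, s) {
  out <- as.integer(s)
  for (i in seq_len(nrow(net$nodes))) {
    if (net$nodes$kind[i] != "dynamic") next
    a_sum <- 0; b_sum <- 0
    for (j in seq_len(nrow(net$edges))) {
      if (net$edges$target[j] != net$nodes$name[i]) next
      # look the edge's parameters up by name, not position
      k <- which(params$source == net$edges$source[j] &
                   params$target == net$edges$target[j])
      si <- match(net$edges$source[j], net$nodes$name)
      if (s[si] >= params$theta[k]) {
        if (net$edges$mode[j] == "activate") {
          a_sum <- a_sum + params$weight[k]
        } else {
          b_sum <- b_sum + params$weight[k]
        }
      }
    }
    lv <- as.integer(s[i])
    if (a_sum > b_sum) lv <- lv + 1L
    if (b_sum > a_sum) lv <- lv - 1L
    out[i] <- max(0L, min(net$nodes$n_levels[i] - 1L, lv))
  }
  out
}

# brute-force filter of the full (theta, weight) grid for one node's
# in-edges against observed transitions; contexts are lists with
# $start (full state), $observed (target's next level)
oracle_node_solutions <- function(net, target, contexts,
                                  weight_domain = c(1L, 2L)) {
  ti <- match(target, net$nodes$name)
  in_edges <- which(net$edges$target == target)
  m <- length(in_edges)
  doms <- list()
  for (k in seq_len(m)) {
    src <- net$edges$source[in_edges[k]]
    smax <- net$nodes$n_levels[match(src, net$nodes$name)] - 1L
    doms[[2 * k - 1]] <- seq_len(smax)
    doms[[2 * k]] <- as.integer(weight_domain)
  }
  grid <- if (m) expand.grid(doms) else data.frame(row.names = 1)
  ok <- logical(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    good <- TRUE
    for (cx in contexts) {
      a_sum <- 0; b_sum <- 0
      for (k in seq_len(m)) {
        j <- in_edges[k]
        si <- match(net$edges$source[j], net$nodes$name)
        if (cx$start[si] >= grid[g, 2 * k - 1]) {
          if (net$edges$mode[j] == "activate") {
            a_sum <- a_sum + grid[g, 2 * k]
          } else {
            b_sum <- b_sum + grid[g, 2 * k]
          }
        }
      }
      lv <- as.integer(cx$start[ti])
      if (a_sum > b_sum) lv <- lv + 1L
      if (b_sum > a_sum) lv <- lv - 1L
      lv <- max(0L, min(net$nodes$n_levels[ti] - 1L, lv))
      if (lv != cx$observed) { good <- FALSE; break }
    }
    ok[g] <- good
  }
  grid[ok, , drop = FALSE]
}

# turn per-node contexts into a minimal 2-assessment trajectory table
contexts_to_trajectories <- function(net, contexts, target) {
  ti <- match(target, net$nodes$name)
  if (!length(contexts)) {
    # one participant, three fully missing assessments: nothing is scored
    contexts <- list(list(start = rep(NA_integer_, nrow(net$nodes)),
                          observed = NA_integer_))
    contexts[[1]]$start[] <- 0L
    contexts[[1]]$start[ti] <- NA_integer_
  }
  rows <- list()
  for (i in seq_along(contexts)) {
    cx <- contexts[[i]]
    s0 <- cx$start
    s1 <- rep(NA_integer_, nrow(net$nodes))
    s1[ti] <- cx$observed
    for (t in 1:3) {  # pad to the 3-assessment minimum with missing rows
      lev <- if (t == 1) s0 else if (t == 2) s1 else rep(NA_integer_,
                                                         nrow(net$nodes))
      ai <- match(net$adherence_node, net$nodes$name)
      amax <- net$nodes$n_levels[ai] - 1L
      status <- if (!is.na(lev[ai]) && lev[ai] == amax) "adherent" else
        "discontinued"
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(participant_id = sprintf("c%03d", i), timepoint = t,
                   adherence = status),
        as.data.frame(as.list(stats::setNames(lev, net$nodes$name))))
    }
  }
  do.call(rbind, rows)
}

# exhaustive intervention-subset search (independent of find_mis pruning):
# evaluates every action subset up to max_size, then filters to minimal sets
oracle_mis <- function(net, params, state, max_size = 2L, hold_steps = 5L,
                       max_steps = 50L) {
  targets <- net$nodes$name[net$nodes$targetable]
  singles <- expand.grid(node = targets, direction = c("up", "down"),
                         stringsAsFactors = FALSE)
  singles <- singles[order(singles$node, singles$direction), ]
  subsets <- list()
  for (size in seq_len(max_size)) {
    for (cmb in utils::combn(nrow(singles), size, simplify = FALSE)) {
      acts <- singles[cmb, , drop = FALSE]
      if (anyDuplicated(acts$node)) next
      subsets[[length(subsets) + 1L]] <- cmb
    }
  }
  success <- vapply(subsets, function(cmb) {
    acts <- singles[cmb, , drop = FALSE]
    apply_intervention(net, params, state,
                       intervention_actions(acts$node, acts$direction),
                       hold_steps = hold_steps,
                       max_steps = max_steps)$success
  }, logical(1))
  winners <- subsets[success]
  minimal <- Filter(function(w) {
    !any(vapply(winners, function(v)
      length(v) < length(w) && all(v %in% w), logical(1)))
  }, winners)
  sort(vapply(minimal, function(cmb) {
    acts <- singles[cmb, , drop = FALSE]
    action_label_test(acts)
  }, character(1)))
}

action_label_test <- function(acts) {
  paste(sprintf("%s%s", ifelse(acts$direction == "up", "↑", "↓"),
                acts$node), collapse = " + ")
}

mis_labels <- function(mis) {
  sort(vapply(Filter(function(r) !isTRUE(r$already_adherent), mis),
              `[[`, character(1), "label"))
}

# random (possibly partial) trajectory table valid for `net`
random_trajectories <- function(net, n_participants = 3L,
                                n_assessments = 3:5, missing_rate = 0.2) {
  amax <- net$nodes$n_levels[match(net$adherence_node, net$nodes$name)] - 1L
  rows <- list()
  for (p in seq_len(n_participants)) {
    n_a <- sample(n_assessments, 1)
    for (t in seq_len(n_a)) {
      lev <- vapply(net$nodes$n_levels,
                    function(L) sample.int(L, 1L) - 1L, integer(1))
      lev[stats::runif(length(lev)) < missing_rate] <- NA_integer_
      ai <- match(net$adherence_node, net$nodes$name)
      status <- if (!is.na(lev[ai])) {
        if (lev[ai] == amax) "adherent" else "discontinued"
      } else {
        sample(c("adherent", "discontinued"), 1)
      }
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(participant_id = sprintf("r%02d", p), timepoint = t,
                   adherence = status),
        as.data.frame(as.list(stats::setNames(lev, net$nodes$name))))
    }
  }
  do.call(rbind, rows)
}

# every state of a (small) network, one per row
decode_all_states <- function(net) {
  as.matrix(expand.grid(lapply(net$nodes$n_levels, function(L) 0:(L - 1))))
}
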