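#' Network image: the suggested next state
#'
#' For each dynamic node, the perceived upstream mediators are the in-edges
#' whose source level is at or above the edge's perception threshold. Let
#' `A` be the summed weight of perceived activators and `B` that of
#' perceived inhibitors. The node's suggested next level is its current
#' level plus one (capped at the maximum) if `A > B`, minus one (floored at
#' 0) if `B > A`, and unchanged on a tie or when no mediator is perceived.
#' Input nodes are copied unchanged. The vector of suggested levels for all
#' nodes is the network image: the state toward which the network should
#' progress.
#'
#' @param net a `logic_network`.
#' @param params a [parameter_set()] bound to `net`.
#' @param state integer vector of node levels in network node order.
#' @return The image state, an integer vector named like the nodes.
#' @export
network_image <- function(net, params, state) {
  state <- validate_state(net, state)
  pw <- align_parameters(net, params)
  e <- net$edges
  n <- n_nodes(net)
  delta <- integer(n)
  if (nrow(e)) {
    perceived <- state[e$.src] >= pw$theta
    if (any(perceived)) {
      contrib <- (e$.sign * pw$weight)[perceived]
      agg <- rowsum(contrib, e$.tgt[perceived])
      delta[as.integer(rownames(agg))] <- sign(agg[, 1L])
    }
  }
  delta[!dynamic_mask(net)] <- 0L
  img <- pmin(pmax(state + delta, 0L), max_levels(net))
  names(img) <- net$nodes$name
  img
}

validate_state <- function(net, state) {
  if (length(state) != n_nodes(net)) {
    stop("state length does not match node count", call. = FALSE)
  }
  state <- as.integer(state)
  if (anyNA(state) || any(state < 0L) || any(state > max_levels(net))) {
    stop("state levels out of range for this network", call. = FALSE)
  }
  state
}

#' One synchronous update step
#'
#' Applies the suggested change of [network_image()] to all nodes
#' simultaneously. Under synchronous updating the step *is* the image, so
#' every node moves by at most one level per step.
#'
#' @inheritParams network_image
#' @return The next state.
#' @export
step_synchronous <- function(net, params, state) {
  network_image(net, params, state)
}

#' One asynchronous update step
#'
#' Applies the image change to a single randomly chosen dynamic node,
#' leaving the rest untouched. Provided for exploration of update-scheme
#' sensitivity; the main pipeline uses the synchronous scheme.
#'
#' @inheritParams network_image
#' @return The next state.
#' @export
step_asynchronous <- function(net, params, state) {
  img <- network_image(net, params, state)
  dyn <- which(dynamic_mask(net))
  pick <- dyn[sample.int(length(dyn), 1L)]
  state <- validate_state(net, state)
  state[pick] <- img[pick]
  names(state) <- net$nodes$name
  state
}

# image for a matrix of states (rows = states); core of the batch kernels
image_matrix <- function(net, params, S) {
  pw <- align_parameters(net, params)
  e <- net$edges
  n <- n_nodes(net)
  delta <- matrix(0, nrow(S), n)
  if (nrow(e)) {
    perc <- S[, e$.src, drop = FALSE] >=
      matrix(pw$theta, nrow(S), nrow(e), byrow = TRUE)
    W <- matrix(0, nrow(e), n)
    W[cbind(seq_len(nrow(e)), e$.tgt)] <- e$.sign * pw$weight
    delta <- sign(perc %*% W)
  }
  if (any(!dynamic_mask(net))) delta[, !dynamic_mask(net)] <- 0
  img <- S + delta
  img <- pmin(pmax(img, 0), matrix(max_levels(net), nrow(S), n, byrow = TRUE))
  storage.mode(img) <- "integer"
  img
}

state_key <- function(state) paste(state, collapse = ",")

#' Simulate a trajectory of the synchronous dynamics
#'
#' Iterates the update from `s0` for at most `max_steps` steps, stopping
#' early as soon as a previously visited state recurs (an attractor — fixed
#' point or cycle — has been entered). The default horizon is 50 iterations.
#'
#' @inheritParams network_image
#' @param s0 initial state.
#' @param max_steps maximum number of update steps (default 50).
#' @param scheme `"synchronous"` (default) or `"asynchronous"`.
#' @return A list of class `network_trajectory`:
#'   * `states`: matrix, one row per visited state (including `s0`),
#'   * `converged`: `TRUE` if a state recurred within the horizon,
#'   * `attractor`: the [attractor][enumerate_attractors()] entered, or
#'     `NULL` when unconverged (always `NULL` for the asynchronous scheme,
#'     whose recurrences are scheme-dependent).
#' @export
simulate_network <- function(net, params, s0, max_steps = 50L,
                             scheme = c("synchronous", "asynchronous")) {
  scheme <- match.arg(scheme)
  stopifnot(max_steps >= 1L)
  s <- validate_state(net, s0)
  seen <- new.env(parent = emptyenv())
  assign(state_key(s), 1L, envir = seen)
  states <- matrix(s, nrow = 1L)
  converged <- FALSE
  attractor <- NULL
  for (t in seq_len(max_steps)) {
    s <- if (scheme == "synchronous") step_synchronous(net, params, s) else
      step_asynchronous(net, params, s)
    states <- rbind(states, s)
    k <- state_key(s)
    first <- get0(k, envir = seen)
    if (!is.null(first)) {
      converged <- TRUE
      if (scheme == "synchronous") {
        cyc <- states[first:t, , drop = FALSE]
        attractor <- make_attractor(net, cyc)
      }
      break
    }
    assign(k, t + 1L, envir = seen)
  }
  colnames(states) <- net$nodes$name
  rownames(states) <- NULL
  structure(list(states = states, converged = converged,
                 attractor = attractor),
            class = "network_trajectory")
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat(sprintf("<network_trajectory> %d states, %s\n", nrow(x$states),
              if (x$converged) "attractor reached" else "unconverged"))
  invisible(x)
}

# canonical attractor from its cycle states (last row NOT repeated)
make_attractor <- function(net, cycle_states) {
  p <- nrow(cycle_states)
  keys <- apply(cycle_states, 1L, state_key)
  rot <- which(keys == min(keys))[1L]  # lexicographic canonical rotation
  ord <- ((rot - 1L + seq_len(p) - 1L) %% p) + 1L
  states <- cycle_states[ord, , drop = FALSE]
  colnames(states) <- net$nodes$name
  rownames(states) <- NULL
  ai <- node_index(net, net$adherence_node)
  amax <- max_levels(net)[ai]
  structure(
    list(states = states, period = p,
         adherent = all(states[, ai] == amax),
         basin_frequency = NA_real_,
         id = paste(keys[ord], collapse = "|")),
    class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("<attractor> period %d, %s, basin %s\n", x$period,
              if (x$adherent) "adherent" else "non-adherent",
              ifelse(is.na(x$basin_frequency), "?",
                     format(x$basin_frequency, digits = 3))))
  invisible(x)
}

# ---- exhaustive attractor enumeration -------------------------------------

# mixed-radix encode/decode between states and 1-based integers
encode_states <- function(S, radix) as.integer(S %*% cumprod(c(1, radix[-length(radix)])) + 1)

decode_states <- function(idx, radix) {
  n <- length(radix)
  S <- matrix(0L, length(idx), n)
  x <- idx - 1L
  for (j in seq_len(n)) {
    S[, j] <- as.integer(x %% radix[j])
    x <- x %/% radix[j]
  }
  S
}

#' Enumerate all attractors exactly
#'
#' Visits the complete state space, computes the synchronous successor of
#' every state in one vectorized pass, and extracts all attractors of the
#' resulting transition function together with their exact basin fractions
#' (which partition the state space, so they sum to 1). Intended as the
#' ground-truth oracle for small circuits; refuses state spaces larger than
#' `cap`.
#'
#' @inheritParams network_image
#' @param cap largest admissible state-space size (default `3^10`).
#' @return An object of class `attractor_set`: a list of
#'   [attractor][simulate_network()] objects sorted by decreasing basin
#'   fraction, with attributes `n_states`, `method = "exact"` and
#'   `unconverged = 0`.
#' @export
enumerate_attractors <- function(net, params, cap = 3^10) {
  radix <- net$nodes$n_levels
  N <- prod(radix)
  if (N > cap) {
    stop(sprintf("state space has %s states, above the cap of %s",
                 format(N, big.mark = ","), format(cap, big.mark = ",")),
         call. = FALSE)
  }
  S <- decode_states(seq_len(N), radix)
  succ <- encode_states(image_matrix(net, params, S), radix)

  aid <- integer(N)       # 0 = unresolved, else attractor index
  onpath <- integer(N)    # position on the current walk, 0 otherwise
  attractors <- list()
  for (i in seq_len(N)) {
    if (aid[i] > 0L) next
    path <- integer(0)
    j <- i
    while (aid[j] == 0L && onpath[j] == 0L) {
      path <- c(path, j)
      onpath[j] <- length(path)
      j <- succ[j]
    }
    if (aid[j] > 0L) {
      a <- aid[j]
    } else {
      # closed a new cycle within the current walk
      cyc <- path[onpath[j]:length(path)]
      attractors[[length(attractors) + 1L]] <-
        make_attractor(net, S[cyc, , drop = FALSE])
      a <- length(attractors)
    }
    aid[path] <- a
    onpath[path] <- 0L
  }
  counts <- tabulate(aid, nbins = length(attractors))
  for (k in seq_along(attractors)) {
    attractors[[k]]$basin_frequency <- counts[k] / N
  }
  new_attractor_set(attractors, n_states = N, method = "exact",
                    unconverged = 0)
}

new_attractor_set <- function(attractors, n_states, method, unconverged) {
  ord <- order(-vapply(attractors, `[[`, numeric(1), "basin_frequency"),
               vapply(attractors, `[[`, character(1), "id"))
  structure(attractors[ord], class = "attractor_set", n_states = n_states,
            method = method, unconverged = unconverged)
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("<attractor_set> %d attractor(s) [%s], %d adherent, unconverged %.3f\n",
              length(x), attr(x, "method"),
              sum(vapply(x, `[[`, logical(1), "adherent")),
              attr(x, "unconverged")))
  for (a in x) print(a)
  invisible(x)
}

#' Estimate attractors by repeated simulation
#'
#' Draws `n_inits` initial states uniformly at random over every node's
#' levels (demographic inputs included), follows each under the synchronous
#' dynamics for up to `max_steps` steps, and tallies the attractors
#' reached. The frequency with which an end-state recurs estimates its
#' basin fraction — the behavioral inertia toward that persistent profile.
#' Defaults are 1,000 restarts and a 50-iteration horizon. Runs with equal
#' seeds are identical.
#'
#' @inheritParams network_image
#' @param n_inits number of random restarts (default 1000).
#' @param max_steps horizon per restart (default 50).
#' @param seed optional integer seed.
#' @param inits optional matrix of initial states (rows), overriding the
#'   random draw; `n_inits` is then ignored.
#' @return An `attractor_set` (see [enumerate_attractors()]); basin
#'   frequencies are computed over converged restarts' share of all
#'   restarts, and the attribute `unconverged` holds the fraction of
#'   restarts that reached no attractor within the horizon.
#' @export
sample_attractors <- function(net, params, n_inits = 1000L, max_steps = 50L,
                              seed = NULL, inits = NULL) {
  stopifnot(max_steps >= 1L)
  if (is.null(inits)) {
    stopifnot(n_inits >= 1L)
    if (!is.null(seed)) set.seed(seed)
    inits <- vapply(net$nodes$n_levels,
                    function(L) sample.int(L, n_inits, replace = TRUE) - 1L,
                    integer(n_inits))
    if (n_inits == 1L) inits <- matrix(inits, nrow = 1L)
  } else {
    inits <- matrix(as.integer(inits), nrow = nrow(inits))
    n_inits <- nrow(inits)
  }

  cache <- new.env(parent = emptyenv())  # state key -> attractor index
  attractors <- list()
  counts <- integer(0)
  unconverged <- 0L

  for (r in seq_len(n_inits)) {
    s <- validate_state(net, inits[r, ])
    path_keys <- character(0)
    pos <- new.env(parent = emptyenv())
    hit <- NA_integer_
    for (t in 0:max_steps) {
      k <- state_key(s)
      known <- get0(k, envir = cache)
      if (!is.null(known)) { hit <- known; break }
      p <- get0(k, envir = pos)
      if (!is.null(p)) {
        # new cycle discovered on this walk
        cyc_keys <- path_keys[p:length(path_keys)]
        cyc <- do.call(rbind, lapply(strsplit(cyc_keys, ",", fixed = TRUE),
                                     as.integer))
        att <- make_attractor(net, cyc)
        idx <- match(att$id, vapply(attractors, `[[`, character(1), "id"))
        if (is.na(idx)) {
          attractors[[length(attractors) + 1L]] <- att
          counts <- c(counts, 0L)
          idx <- length(attractors)
        }
        hit <- idx
        break
      }
      if (t == max_steps) break
      path_keys <- c(path_keys, k)
      assign(k, length(path_keys), envir = pos)
      s <- step_synchronous(net, params, s)
    }
    if (is.na(hit)) {
      unconverged <- unconverged + 1L
    } else {
      counts[hit] <- counts[hit] + 1L
      for (k in path_keys) assign(k, hit, envir = cache)
    }
  }
  for (k in seq_along(attractors)) {
    attractors[[k]]$basin_frequency <- counts[k] / n_inits
  }
  new_attractor_set(attractors, n_states = prod(net$nodes$n_levels),
                    method = "sampled", unconverged = unconverged / n_inits)
}

#' Tabulate an attractor set as a census
#'
#' One row per attractor: id, period, adherent flag, basin frequency, then
#' one column per node giving its level in the attractor (multi-state
#' cycles serialized as `/`-joined levels).
#'
#' @param x an `attractor_set`.
#' @param row.names,optional,... ignored; present for the generic.
#' @return A data.frame.
#' @export
as.data.frame.attractor_set <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  if (!length(x)) {
    return(data.frame(id = character(), period = integer(),
                      adherent = logical(), basin_frequency = numeric()))
  }
  node_names <- colnames(x[[1L]]$states)
  rows <- lapply(seq_along(x), function(i) {
    a <- x[[i]]
    lv <- apply(a$states, 2L, paste, collapse = "/")
    cbind(data.frame(id = a$id, period = a$period, adherent = a$adherent,
                     basin_frequency = a$basin_frequency),
          as.data.frame(as.list(stats::setNames(lv, node_names)),
                        check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an attractor census to CSV
#'
#' @param x an `attractor_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_attractor_census <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
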