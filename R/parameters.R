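#' Decisional kinetic parameters for a logic network
#'
#' A parameter set assigns every edge of a network a perception threshold
#' `theta` and a logic weight `weight`. An edge is perceived by its target
#' only while its source node's level is at least `theta`
#' (`theta` in `1:(n_levels(source) - 1)`); perceived influences are combined
#' additively with weight `weight` (by default 1 = weak or 2 = strong) and
#' activators are weighed against inhibitors to decide the target's next
#' move (see [network_image()]). One parameter set is one candidate
#' "decisional logic" for the circuit.
#'
#' @param net the `logic_network` the parameters belong to.
#' @param theta integer vector of thresholds, one per edge in network edge
#'   order (recycled if length 1).
#' @param weight integer vector of weights, one per edge (recycled if
#'   length 1).
#' @param weight_domain admissible weights, default `c(1, 2)`.
#' @return An object of class `parameter_set`: a data.frame with columns
#'   `source`, `target`, `theta`, `weight`.
#' @export
parameter_set <- function(net, theta, weight, weight_domain = c(1L, 2L)) {
  m <- nrow(net$edges)
  theta <- as.integer(rep_len(theta, m))
  weight <- as.integer(rep_len(weight, m))
  src_max <- max_levels(net)[net$edges$.src]
  if (any(theta < 1L) || any(theta > src_max)) {
    stop("theta must lie in [1, n_levels(source) - 1] for every edge",
         call. = FALSE)
  }
  if (!all(weight %in% as.integer(weight_domain)) || any(weight < 1L)) {
    stop("weight must be a positive integer in the declared domain",
         call. = FALSE)
  }
  structure(
    data.frame(source = net$edges$source, target = net$edges$target,
               theta = theta, weight = weight),
    class = c("parameter_set", "data.frame"),
    edge_key = edge_key(net)
  )
}

edge_key <- function(net) paste(net$edges$source, net$edges$target, sep = "\r")

#' Align a parameter set with a network's edge order
#'
#' Rejects binding to a network whose edge set differs from the one the
#' parameters were built for.
#'
#' @param net a `logic_network`.
#' @param params a `parameter_set` (or plain data.frame with the same
#'   columns).
#' @return List with integer vectors `theta` and `weight` in network edge
#'   order.
#' @export
align_parameters <- function(net, params) {
  key_net <- edge_key(net)
  key_par <- paste(params$source, params$target, sep = "\r")
  idx <- match(key_net, key_par)
  if (anyNA(idx) || length(key_par) != length(key_net)) {
    stop("parameter set does not match the network's edge set", call. = FALSE)
  }
  list(theta = as.integer(params$theta[idx]),
       weight = as.integer(params$weight[idx]))
}

#' Baseline parameters: every influence perceived and weak
#'
#' Sets `theta = 1` and `weight = 1` for every edge, i.e. any expressed
#' source (level >= 1) is perceived and all influences carry equal weight.
#'
#' @param net a `logic_network`.
#' @return A `parameter_set`.
#' @export
default_parameters <- function(net) parameter_set(net, 1L, 1L)

#' Draw a random ground-truth parameter set
#'
#' Samples `theta` uniformly from `1:(n_levels(source) - 1)` (intersected
#' with `theta_domain` if given) and `weight` uniformly from
#' `weight_domain`, independently per edge. Used to define ground truth in
#' parameter-recovery experiments.
#'
#' @param net a `logic_network`.
#' @param seed optional integer seed; equal seeds give identical draws.
#' @param theta_domain optional integer vector restricting thresholds.
#' @param weight_domain admissible weights, default `c(1, 2)`.
#' @return A `parameter_set`.
#' @export
random_parameters <- function(net, seed = NULL, theta_domain = NULL,
                              weight_domain = c(1L, 2L)) {
  if (!is.null(seed)) set.seed(seed)
  src_max <- max_levels(net)[net$edges$.src]
  theta <- vapply(src_max, function(mx) {
    dom <- seq_len(mx)
    if (!is.null(theta_domain)) dom <- intersect(dom, as.integer(theta_domain))
    if (!length(dom)) stop("empty theta domain for an edge", call. = FALSE)
    dom[sample.int(length(dom), 1L)]
  }, integer(1))
  weight <- as.integer(weight_domain)[
    sample.int(length(weight_domain), nrow(net$edges), replace = TRUE)]
  parameter_set(net, theta, weight, weight_domain = weight_domain)
}

#' Read / write parameter sidecar files
#'
#' Plain TSV with columns `source`, `target`, `theta`, `weight`; the format
#' used alongside SIF exports.
#'
#' @param net the network the parameters bind to.
#' @param path file path.
#' @return `read_parameters()` a `parameter_set`; `write_parameters()` the
#'   path, invisibly.
#' @export
read_parameters <- function(net, path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  pw <- align_parameters(net, tab)
  parameter_set(net, pw$theta, pw$weight,
                weight_domain = sort(unique(pw$weight)))
}

#' @rdname read_parameters
#' @param params a `parameter_set`.
#' @export
write_parameters <- function(params, path) {
  utils::write.table(as.data.frame(params), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
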