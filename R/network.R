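#' Construct a decisional logic network
#'
#' A logic network is a directed graph over discrete-valued behavioral,
#' treatment and demographic factors. Each node holds a qualitative activation
#' level in `0:(n_levels - 1)` (for the default 3 levels: low, nominal, high).
#' Each edge carries a mode of action (activating or inhibiting) and, once
#' bound to a [parameter_set()], a perception threshold and a logic weight
#' that govern the discrete decisional dynamics (see [network_image()]).
#'
#' Nodes of kind `"input"` represent fixed demographic or clinical context
#' (e.g. age, education): they condition the logic of downstream nodes but are
#' never updated, so edges targeting an input node are rejected. Nodes flagged
#' `targetable` are the clinically actionable levers considered by the
#' intervention search; they must be dynamic.
#'
#' @param nodes data.frame with columns `name`, `kind` (`"dynamic"` or
#'   `"input"`), `n_levels` (integer >= 2) and `targetable` (logical).
#'   Missing `kind`/`n_levels`/`targetable` columns default to
#'   `"dynamic"`/3/`FALSE`.
#' @param edges data.frame with columns `source`, `target` and `mode`
#'   (`"activate"` or `"inhibit"`; the signs `"+"`/`"-"` are also accepted).
#' @param adherence_node name of the dynamic node whose level encodes
#'   adherence status (adherent = maximum level).
#' @return An object of class `logic_network`.
#' @examples
#' net <- logic_network(
#'   nodes = data.frame(name = c("A", "B")),
#'   edges = data.frame(source = "A", target = "B", mode = "activate"),
#'   adherence_node = "B"
#' )
#' @export
logic_network <- function(nodes, edges, adherence_node) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!"name" %in% names(nodes)) {
    stop("`nodes` must have a `name` column", call. = FALSE)
  }
  nodes$name <- as.character(nodes$name)
  if (is.null(nodes$kind)) nodes$kind <- "dynamic"
  if (is.null(nodes$n_levels)) nodes$n_levels <- 3L
  if (is.null(nodes$targetable)) nodes$targetable <- FALSE
  nodes$kind <- as.character(nodes$kind)
  nodes$n_levels <- as.integer(nodes$n_levels)
  nodes$targetable <- as.logical(nodes$targetable)
  nodes <- nodes[, c("name", "kind", "n_levels", "targetable")]

  if (nrow(edges)) {
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$mode <- canonical_mode(edges$mode)
    keep <- c("source", "target", "mode")
    edges <- edges[, intersect(c(keep, "theta", "weight"), names(edges))]
  } else {
    edges <- data.frame(source = character(), target = character(),
                        mode = character())
  }

  net <- structure(
    list(nodes = nodes, edges = edges,
         adherence_node = as.character(adherence_node)),
    class = "logic_network"
  )
  validate_network(net)
}

canonical_mode <- function(mode) {
  mode <- as.character(mode)
  out <- ifelse(mode %in% c("activate", "+", "activates"), "activate",
         ifelse(mode %in% c("inhibit", "-", "inhibits", "inactivate"),
                "inhibit", NA_character_))
  if (anyNA(out)) {
    stop("edge mode must be one of 'activate'/'+' or 'inhibit'/'-', got: ",
         paste(unique(mode[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Validate a logic network
#'
#' Checks all structural invariants: unique node names, at least two levels
#' per node, targetable nodes dynamic, edge endpoints declared, edge targets
#' dynamic, unique (source, target) pairs, and a dynamic adherence node.
#' Called by [logic_network()]; exposed for networks assembled by hand.
#'
#' @param net a `logic_network`.
#' @return `net`, invisibly augmented with internal edge indices.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  reserved <- c("participant_id", "timepoint", "adherence")
  if (any(nodes$name %in% reserved)) {
    stop("node names ", paste(intersect(nodes$name, reserved), collapse = ", "),
         " collide with reserved trajectory-table columns", call. = FALSE)
  }
  if (anyDuplicated(nodes$name)) {
    stop("duplicate node names: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(nodes$kind %in% c("dynamic", "input"))) {
    stop("node kind must be 'dynamic' or 'input'", call. = FALSE)
  }
  if (any(nodes$n_levels < 2L)) {
    stop("every node needs n_levels >= 2", call. = FALSE)
  }
  bad_target <- nodes$targetable & nodes$kind != "dynamic"
  if (any(bad_target)) {
    stop("targetable nodes must be dynamic: ",
         paste(nodes$name[bad_target], collapse = ", "), call. = FALSE)
  }
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$source, edges$target), nodes$name)
    if (length(unknown)) {
      stop("edge references undeclared node(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    tgt_kind <- nodes$kind[match(edges$target, nodes$name)]
    if (any(tgt_kind != "dynamic")) {
      stop("edges may not target input nodes: ",
           paste(unique(edges$target[tgt_kind != "dynamic"]), collapse = ", "),
           call. = FALSE)
    }
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate edges: ",
           paste(unique(gsub("\r", " -> ", key[duplicated(key)])),
                 collapse = ", "), call. = FALSE)
    }
  }
  if (length(net$adherence_node) != 1L ||
      !net$adherence_node %in% nodes$name) {
    stop("adherence_node must name one declared node", call. = FALSE)
  }
  if (nodes$kind[match(net$adherence_node, nodes$name)] != "dynamic") {
    stop("adherence_node must be dynamic", call. = FALSE)
  }
  # cache integer indices used by the dynamics kernels
  net$edges$.src <- match(edges$source, nodes$name)
  net$edges$.tgt <- match(edges$target, nodes$name)
  net$edges$.sign <- ifelse(edges$mode == "activate", 1L, -1L)
  net
}

#' @export
print.logic_network <- function(x, ...) {
  n_dyn <- sum(x$nodes$kind == "dynamic")
  cat(sprintf(
    "<logic_network> %d nodes (%d dynamic, %d input), %d edges\n",
    nrow(x$nodes), n_dyn, nrow(x$nodes) - n_dyn, nrow(x$edges)))
  cat(sprintf("  adherence node: %s\n", x$adherence_node))
  tg <- x$nodes$name[x$nodes$targetable]
  if (length(tg)) cat("  targetable:", paste(tg, collapse = ", "), "\n")
  invisible(x)
}

n_nodes <- function(net) nrow(net$nodes)

node_index <- function(net, name) {
  i <- match(name, net$nodes$name)
  if (anyNA(i)) {
    stop("unknown node(s): ", paste(name[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

dynamic_mask <- function(net) net$nodes$kind == "dynamic"

max_levels <- function(net) net$nodes$n_levels - 1L

# middle ("nominal") level used when imputing unobserved values
nominal_levels <- function(net) (net$nodes$n_levels - 1L) %/% 2L

#' Read a logic network from a sectioned TSV file
#'
#' The dialect has a `# nodes` section with rows
#' `name<TAB>kind<TAB>n_levels<TAB>targetable` and a `# edges` section with
#' rows `source<TAB>target<TAB>sign` where sign is `+` or `-`; optional 4th
#' and 5th edge columns fix a perception threshold and logic weight for the
#' edge. Lines starting with `##` are comments. The adherence node is marked
#' by a line `# adherence <name>` or passed explicitly.
#'
#' @param path file path.
#' @param adherence_node optional override for the adherence node declared in
#'   the file.
#' @return A `logic_network`; if the file fixes thresholds and weights, the
#'   corresponding [parameter_set()] is attached as attribute `"parameters"`
#'   (retrieve with [network_parameters()]).
#' @seealso [write_network()], [read_sif()]
#' @export
read_network <- function(path, adherence_node = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  section <- NA_character_
  nodes <- list(); edges <- list()
  adh <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]], which = "right")
    if (!nzchar(ln) || startsWith(ln, "##")) next
    if (startsWith(ln, "#")) {
      word <- trimws(sub("^#+", "", ln))
      if (grepl("^nodes\\b", word)) { section <- "nodes"; next }
      if (grepl("^edges\\b", word)) { section <- "edges"; next }
      if (grepl("^adherence\\b", word)) {
        adh <- trimws(sub("^adherence", "", word)); next
      }
      next  # other directives ignored
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (is.na(section)) {
      stop(sprintf("line %d: data row before any section header", i),
           call. = FALSE)
    }
    if (section == "nodes") {
      if (length(f) < 4L || is.na(suppressWarnings(as.integer(f[3])))) {
        stop(sprintf("line %d: malformed node row (need name, kind, n_levels, targetable)", i),
             call. = FALSE)
      }
      nodes[[length(nodes) + 1L]] <- data.frame(
        name = f[1], kind = f[2],
        n_levels = as.integer(f[3]),
        targetable = f[4] %in% c("1", "TRUE", "true", "yes"))
    } else {
      if (length(f) < 3L) {
        stop(sprintf("line %d: malformed edge row (need source, target, sign)", i),
             call. = FALSE)
      }
      e <- data.frame(source = f[1], target = f[2], mode = f[3])
      if (length(f) >= 5L) {
        e$theta <- as.integer(f[4]); e$weight <- as.integer(f[5])
      }
      edges[[length(edges) + 1L]] <- e
    }
  }
  if (!length(nodes)) stop("file declares no nodes: ", path, call. = FALSE)
  nodes <- do.call(rbind, nodes)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(), mode = character())
  if (!is.null(adherence_node)) adh <- adherence_node
  if (is.null(adh)) stop("no adherence node declared in file or argument",
                         call. = FALSE)
  has_params <- nrow(edges) > 0L && !is.null(edges$theta) &&
    !anyNA(edges$theta) && !anyNA(edges$weight)
  net <- logic_network(nodes, edges[, c("source", "target", "mode")], adh)
  if (has_params) {
    attr(net, "parameters") <- parameter_set(
      net, theta = edges$theta, weight = edges$weight)
  }
  net
}

#' Write a logic network to the sectioned TSV format
#'
#' @param net a `logic_network`.
#' @param path output file path.
#' @param params optional [parameter_set()]; when given, per-edge thresholds
#'   and weights are written as the 4th/5th edge columns.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, params = NULL) {
  out <- c("# adherence " , "# nodes")
  out[1] <- paste0("# adherence ", net$adherence_node)
  node_rows <- sprintf("%s\t%s\t%d\t%d", net$nodes$name, net$nodes$kind,
                       net$nodes$n_levels, as.integer(net$nodes$targetable))
  sign <- ifelse(net$edges$mode == "activate", "+", "-")
  if (!is.null(params)) {
    pw <- align_parameters(net, params)
    edge_rows <- sprintf("%s\t%s\t%s\t%d\t%d", net$edges$source,
                         net$edges$target, sign, pw$theta, pw$weight)
  } else {
    edge_rows <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$target,
                         sign)
  }
  writeLines(c(out, node_rows, "# edges", edge_rows), path)
  invisible(path)
}

#' Retrieve parameters attached to a network read from file
#'
#' @param net a `logic_network` returned by [read_network()].
#' @return A [parameter_set()] or `NULL`.
#' @export
network_parameters <- function(net) attr(net, "parameters")

#' Read / write plain SIF interaction files
#'
#' SIF rows are `source<TAB>interaction<TAB>target` with interaction
#' `activate`/`+` or `inhibit`/`-`. SIF carries no node metadata, so node
#' kinds, level counts and targetable flags are supplied as arguments;
#' parameters travel in a sidecar file (see [write_parameters()]).
#'
#' @param path file path.
#' @param adherence_node adherence node name.
#' @param inputs character vector of node names held fixed (kind `"input"`).
#' @param targetable character vector of clinically actionable nodes.
#' @param n_levels levels per node (recycled), default 3.
#' @return `read_sif()` a `logic_network`; `write_sif()` the path, invisibly.
#' @export
read_sif <- function(path, adherence_node, inputs = character(),
                     targetable = character(), n_levels = 3L) {
  rows <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("source", "interaction", "target"),
                            colClasses = "character")
  names_all <- unique(c(rows$source, rows$target))
  nodes <- data.frame(
    name = names_all,
    kind = ifelse(names_all %in% inputs, "input", "dynamic"),
    n_levels = as.integer(n_levels),
    targetable = names_all %in% targetable)
  edges <- data.frame(source = rows$source, target = rows$target,
                      mode = rows$interaction)
  logic_network(nodes, edges, adherence_node)
}

#' @rdname read_sif
#' @param net a `logic_network`.
#' @export
write_sif <- function(net, path) {
  writeLines(sprintf("%s\t%s\t%s", net$edges$source, net$edges$mode,
                     net$edges$target), path)
  invisible(path)
}

#' The packaged adherence circuit
#'
#' Loads the behavioral feedback network shipped with the package: 18
#' demographic, treatment and patient-related factors connected by 43 signed
#' regulatory interactions, with adherence to adjuvant endocrine therapy as
#' the readout node and the eight clinically actionable factors (trust in
#' physician, treatment cost worry, health literacy, quality of life, coping
#' deficit, general anxiety, worry about cancer recurrence, behavioral
#' routines) flagged targetable. Age, education, household income and tumor
#' stage are input nodes: they condition the logic but are never updated.
#'
#' The circuit is a synthetic reconstruction: the published figure of the
#' study network is not machine-readable, so the edge list was written from
#' the causal relations described in the accompanying text (side effects
#' degrade quality of life, mediated by provider helpfulness and age; higher
#' age, lower education, lower disease stage and poor treatment literacy
#' lower perceived recurrence risk; routines and inconsistencies therein
#' drive adherence; coping deficits feed anxiety; and so on). Each edge is
#' annotated in the fixture file
#' (`system.file("extdata", "adherence_circuit_synthetic.tsv",
#' package = "adherenet")`).
#'
#' @return A `logic_network` with 18 nodes and 43 edges.
#' @examples
#' net <- adherence_network()
#' nrow(net$nodes)  # 18
#' nrow(net$edges)  # 43
#' @export
adherence_network <- function() {
  path <- system.file("extdata", "adherence_circuit_synthetic.tsv",
                      package = "adherenet", mustWork = TRUE)
  read_network(path)
}
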