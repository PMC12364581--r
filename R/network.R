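# Signed regulatory network container used throughout the package.
#
# The adjacency matrix is oriented (regulator, target): entry (i, j) is the
# weight of the regulation FROM node i ONTO node j.  Positive weights are
# activations, negative weights inhibitions, zero no interaction.  All state
# vectors and simulation outputs follow the node order of this matrix.

#' Construct a signed regulatory network
#'
#' A `signed_network` bundles a node-labelled, real-valued weighted adjacency
#' matrix with per-node roles and an optional partition of the core nodes into
#' teams. The adjacency is oriented (regulator, target): entry `(i, j)` is the
#' weight of the regulation from node `i` onto node `j`; positive values are
#' activatory, negative inhibitory, zero means no interaction.
#'
#' Node roles distinguish `"core"` nodes (the regulatory circuit of interest,
#' over which k-high statistics are computed), `"embedding"` nodes (host nodes
#' of a random network the circuit was embedded in) and `"cytokine"` nodes
#' (external signals, clamped at the high level during simulation). Cytokine
#' nodes must have an all-zero incoming column: nothing regulates the signal.
#'
#' @param adjacency square numeric matrix; if it has no dimnames, nodes are
#'   named `n1, n2, ...`.
#' @param roles character vector of per-node roles in
#'   `c("core", "embedding", "cytokine")`; defaults to all `"core"`.
#' @param teams optional named character vector mapping every core node to a
#'   team label; must partition exactly the core nodes.
#' @return An object of class `signed_network` with fields `adjacency`,
#'   `nodes`, `roles`, `teams`, and the asymmetric-weight fields `focal`
#'   (focal node name or `NA`) and `focal_w` (weight, default 1); see
#'   [apply_asymmetric_weight()].
#' @seealso [make_toggle()], [read_topo()], [find_steady_states()]
#' @examples
#' net <- signed_network(matrix(c(0, -1, -1, 0), 2, 2,
#'                              dimnames = list(c("A", "B"), c("A", "B"))))
#' net
#' @export
signed_network <- function(adjacency, roles = NULL, teams = NULL) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency))
    stop("adjacency must be a numeric matrix")
  n <- nrow(adjacency)
  if (ncol(adjacency) != n)
    stop("adjacency must be square")
  if (is.null(rownames(adjacency)))
    rownames(adjacency) <- paste0("n", seq_len(n))
  colnames(adjacency) <- rownames(adjacency)
  nodes <- rownames(adjacency)
  if (anyDuplicated(nodes))
    stop("node names must be unique")
  if (is.null(roles)) roles <- rep("core", n)
  if (length(roles) != n)
    stop("roles must have one entry per node")
  if (!all(roles %in% c("core", "embedding", "cytokine")))
    stop("roles must be 'core', 'embedding' or 'cytokine'")
  roles <- setNames(as.character(roles), nodes)
  cyt <- nodes[roles == "cytokine"]
  for (cn in cyt) {
    if (any(adjacency[, cn] != 0))
      stop("cytokine node '", cn, "' must have no incoming regulation")
  }
  if (!is.null(teams)) {
    core <- nodes[roles == "core"]
    if (is.null(names(teams)))
      stop("teams must be a named vector (node -> team label)")
    if (!setequal(names(teams), core))
      stop("teams must partition exactly the core nodes")
    teams <- setNames(as.character(teams[core]), core)
    if (any(table(teams) < 1)) stop("teams must be non-empty")
  }
  structure(
    list(adjacency = adjacency, nodes = nodes, roles = roles, teams = teams,
         focal = NA_character_, focal_w = 1),
    class = "signed_network"
  )
}

#' @export
print.signed_network <- function(x, ...) {
  n <- length(x$nodes)
  tab <- table(factor(x$roles, levels = c("core", "embedding", "cytokine")))
  cat("signed_network with", n, "nodes (",
      paste0(tab, " ", names(tab), collapse = ", "), ")\n")
  nz <- sum(x$adjacency != 0)
  cat("  edges:", sum(x$adjacency > 0), "activating,",
      sum(x$adjacency < 0), "inhibitory (", nz, "total )\n")
  if (!is.null(x$teams))
    cat("  teams:", paste(sprintf("%s(%d)", names(table(x$teams)),
                                  table(x$teams)), collapse = " "), "\n")
  if (!is.na(x$focal))
    cat("  asymmetric weight: W =", x$focal_w, "from", x$focal, "\n")
  invisible(x)
}

#' Number of nodes in a network
#' @param network a [signed_network()]
#' @return integer node count
#' @export
n_nodes <- function(network) length(network$nodes)

#' Names of the core nodes of a network
#' @param network a [signed_network()]
#' @return character vector of core node names
#' @export
core_nodes <- function(network) network$nodes[network$roles == "core"]

.clamped <- function(network) unname(network$roles == "cytokine")

.node_index <- function(network, node) {
  if (is.character(node)) {
    idx <- match(node, network$nodes)
    if (is.na(idx)) stop("unknown node '", node, "'")
    return(idx)
  }
  idx <- as.integer(node)
  if (is.na(idx) || idx < 1 || idx > length(network$nodes))
    stop("node index out of range")
  idx
}

.focal_index0 <- function(network) {
  if (is.na(network$focal)) return(-1L)
  .node_index(network, network$focal) - 1L
}

#' Format a state vector as a compact string
#'
#' Boolean states print as a string over `+`/`-` in node order; multi-level
#' states as comma-separated level values.
#'
#' @param state numeric vector of node values
#' @return character scalar
#' @export
format_state <- function(state) {
  if (all(state %in% c(-1, 1)))
    paste(ifelse(state > 0, "+", "-"), collapse = "")
  else
    paste(state, collapse = ",")
}

#' Names of the nodes that are high in a state
#' @param state numeric state vector named by node
#' @return character vector of node names with positive value
#' @export
high_nodes <- function(state) names(state)[state > 0]
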