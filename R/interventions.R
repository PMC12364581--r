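# Interventions on a network's regulatory strengths: random edge-weight
# scaling, the state-dependent asymmetric (epigenetic) weight from a focal
# node, constitutive cytokine signalling, and 2-D threshold scans for
# directed differentiation.

#' Randomize edge-weight magnitudes
#'
#' Every nonzero adjacency entry is scaled by an independent draw from
#' U(0, 1); signs are preserved and zeros stay zero. Models heterogeneity in
#' the strength of regulatory interactions.
#'
#' @param network a [signed_network()]
#' @param n_sets number of independent weight sets (default 100)
#' @param seed integer seed
#' @return list of `n_sets` re-weighted [signed_network()]s
#' @export
randomize_edge_weights <- function(network, n_sets = 100, seed = 1) {
  stopifnot(n_sets >= 1)
  set.seed(seed)
  nz <- which(network$adjacency != 0)
  lapply(seq_len(n_sets), function(s) {
    net <- network
    net$adjacency[nz] <- net$adjacency[nz] * runif(length(nz))
    net
  })
}

#' Apply a state-dependent asymmetric weight from a focal node
#'
#' Strengthens the inhibitions exerted by the focal node A when A is high:
#' the input that any other node j receives from A is `-W` when `x_A = +1`
#' and `+1` (the unmodified weight) when `x_A = -1`. Contributions from all
#' other regulators, and A's own inputs, are unchanged. `W = 1` leaves the
#' dynamics identical to the unmodified network.
#'
#' The modification is state-dependent, so it is recorded on the network (as
#' `focal` / `focal_w`) and applied inside the update rule rather than by
#' mutating the adjacency; [find_steady_states()] and
#' [enumerate_fixed_points()] share that code path.
#'
#' @param network a [signed_network()]
#' @param focal_node core node name
#' @param W weight multiplier, at least 1
#' @return the network with the asymmetric rule recorded
#' @export
apply_asymmetric_weight <- function(network, focal_node, W) {
  j <- .node_index(network, focal_node)
  if (network$roles[j] == "cytokine")
    stop("the focal node of the asymmetric weight cannot be a cytokine")
  if (!is.numeric(W) || W < 1) stop("W must be >= 1")
  network$focal <- network$nodes[j]
  network$focal_w <- as.numeric(W)
  network
}

#' Attach a constitutively active cytokine to a network
#'
#' Adds one cytokine node, clamped at +1 throughout simulation, with an
#' activating edge of weight `+W_C` onto the target core node. In
#' `"activate_and_inhibit"` mode the cytokine additionally inhibits every
#' other core node with weight `-W_C`. The cytokine receives no regulation
#' (all-zero incoming column), and k-high statistics keep counting core
#' nodes only. With `W_C = 0` the dynamics are identical to the unmodified
#' network.
#'
#' @param network a [signed_network()]
#' @param target core node activated by the cytokine
#' @param W_C signalling strength, at least 0
#' @param mode `"activate_only"` or `"activate_and_inhibit"`
#' @param signs optional named vector over core nodes in `-1, 0, +1`
#'   overriding the mode pattern (lineage-specific wiring); unnamed nodes
#'   keep the mode's sign
#' @param name cytokine node name (default `Cyt_<target>`)
#' @return the extended [signed_network()]
#' @export
attach_cytokine <- function(network, target, W_C,
                            mode = c("activate_only", "activate_and_inhibit"),
                            signs = NULL, name = NULL) {
  mode <- match.arg(mode)
  j <- .node_index(network, target)
  if (network$roles[j] != "core") stop("cytokine target must be a core node")
  if (!is.numeric(W_C) || W_C < 0) stop("W_C must be >= 0")
  if (is.null(name)) name <- paste0("Cyt_", network$nodes[j])
  if (name %in% network$nodes)
    stop("a cytokine named '", name, "' already exists for this target")
  core <- core_nodes(network)
  sgn <- setNames(rep(if (mode == "activate_only") 0 else -1, length(core)),
                  core)
  sgn[network$nodes[j]] <- 1
  if (!is.null(signs)) {
    bad <- setdiff(names(signs), core)
    if (length(bad)) stop("signs given for non-core node(s): ",
                          paste(bad, collapse = ", "))
    sgn[names(signs)] <- signs
  }
  n <- length(network$nodes)
  adj <- rbind(cbind(network$adjacency, 0), 0)
  rownames(adj) <- colnames(adj) <- c(network$nodes, name)
  adj[name, names(sgn)] <- W_C * sgn
  net <- signed_network(adj, roles = c(network$roles, cytokine = "cytokine"),
                        teams = network$teams)
  net$focal <- network$focal
  net$focal_w <- network$focal_w
  net
}

#' 2-D threshold scan over edge weight and signalling strength
#'
#' For every pair (W, W_C) on the grid, simulates the network with the
#' asymmetric weight W from the focal node and a cytokine of strength W_C on
#' it, and records the single-positive frequency `F_A(1)`. The scan then
#' extracts the minimal W for which some W_C in range reaches
#' `F_A(1) = 1`, and the minimal W_C for which some W does (saturation is
#' exact, so the tolerance `eps` is tiny by default).
#'
#' @param network a [signed_network()]
#' @param focal_node core node driven towards the single-positive state
#' @param mode cytokine mode, see [attach_cytokine()]
#' @param w_range edge weights to scan (default 1:10)
#' @param wc_range signalling strengths to scan (default 0:10)
#' @param config a [sim_config()]
#' @param eps tolerance: a cell counts as complete differentiation when
#'   `F_A(1) >= 1 - eps`
#' @param signs optional cytokine wiring override, see [attach_cytokine()]
#' @return an object of class `scan_result`: `grid` (data frame W, W_C,
#'   FA1, converged), `thresholds` (list with `W` and `W_C`, `NA` when never
#'   reached), `monotone` (empirical monotonicity flag along both axes) and
#'   the scan parameters
#' @export
threshold_scan <- function(network, focal_node,
                           mode = c("activate_only", "activate_and_inhibit"),
                           w_range = 1:10, wc_range = 0:10,
                           config = sim_config(), eps = 1e-6, signs = NULL) {
  mode <- match.arg(mode)
  if (length(w_range) == 0 || length(wc_range) == 0)
    stop("scan ranges must be nonempty")
  rows <- list()
  for (W in w_range) {
    for (WC in wc_range) {
      net <- apply_asymmetric_weight(network, focal_node, W)
      net <- attach_cytokine(net, focal_node, WC, mode = mode, signs = signs)
      dist <- find_steady_states(net, config)
      rows[[length(rows) + 1L]] <- data.frame(
        W = W, W_C = WC,
        FA1 = single_positive_frequency(dist, focal_node),
        converged = mean(dist$converged_fraction))
    }
  }
  grid <- do.call(rbind, rows)
  hit <- grid$FA1 >= 1 - eps
  w_thr <- if (any(hit)) min(grid$W[hit]) else NA_real_
  wc_thr <- if (any(hit)) min(grid$W_C[hit]) else NA_real_
  mono <- all(vapply(split(grid, grid$W), function(d)
    !is.unsorted(d$FA1[order(d$W_C)] + 0.03), logical(1)))
  structure(list(grid = grid, thresholds = list(W = w_thr, W_C = wc_thr),
                 monotone = mono, focal = focal_node, mode = mode,
                 eps = eps),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("threshold scan (", x$mode, ") for single-positive", x$focal, "\n")
  cat("  grid:", length(unique(x$grid$W)), "edge weights x",
      length(unique(x$grid$W_C)), "signalling strengths\n")
  cat("  minimal edge weight W reaching F_A(1)=1:", x$thresholds$W, "\n")
  cat("  minimal signalling strength W_C reaching F_A(1)=1:",
      x$thresholds$W_C, "\n")
  if (!x$monotone)
    cat("  note: F_A(1) not monotone along the grid (beyond noise)\n")
  invisible(x)
}
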