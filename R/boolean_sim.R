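# Asynchronous Boolean simulation under the Ising update formalism.
#
# A Boolean state assigns every node a value in {-1, +1} (+1 = ON/high;
# -1 rather than 0 for the low state so that a low regulator still
# contributes to its targets). One time step updates a single node chosen
# uniformly at random: the node takes the sign of the weighted sum of its
# regulators' states and holds its value on a zero sum. Trajectories run
# until the fixed-point test passes or a step cap is reached; trajectories
# that do not converge are discarded from the frequency statistics.

#' Simulation configuration
#'
#' @param n_init number of initial conditions per replicate (default 100000);
#'   initial states are sampled uniformly over the state space with
#'   replacement, cytokine nodes forced high
#' @param max_steps cap on asynchronous single-node updates per trajectory
#'   (default 1000)
#' @param n_replicates independent replicates (default 3); summaries report
#'   the mean and a 95% normal-approximation confidence interval across them
#' @param seed root integer seed; per-replicate child seeds are derived from
#'   it deterministically
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_init = 100000, max_steps = 1000, n_replicates = 3,
                       seed = 1) {
  stopifnot(n_init >= 1, max_steps >= 1, n_replicates >= 1)
  structure(list(n_init = as.integer(n_init),
                 max_steps = as.integer(max_steps),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.child_seeds <- function(config) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, config$n_replicates)
}

#' Asynchronous Ising update of a single node
#'
#' Reference implementation of one update: node `node` takes the sign of
#' `sum_i x_i * Adj[i, node]` when that sum is nonzero and holds its current
#' value otherwise; all other nodes are untouched. Honours the asymmetric
#' focal weight recorded on the network (see [apply_asymmetric_weight()]).
#'
#' @param network a [signed_network()]
#' @param state named numeric vector over the nodes with values in `-1, +1`
#' @param node node name or index to update (must not be cytokine-clamped)
#' @return the updated state vector
#' @examples
#' t2 <- make_toggle(2)
#' ising_update(t2, c(A = 1, B = 1), "B")
#' @export
ising_update <- function(network, state, node) {
  j <- .node_index(network, node)
  if (network$roles[j] == "cytokine")
    stop("node '", network$nodes[j], "' is a clamped cytokine")
  s <- .input_sum(network, state, j)
  if (s > 0) state[j] <- 1 else if (s < 0) state[j] <- -1
  state
}

# Weighted input sum onto node j, with the state-dependent asymmetric weight:
# when the focal node is high, its outgoing edges onto other nodes are scaled
# by focal_w.
.input_sum <- function(network, state, j) {
  w <- network$adjacency[, j]
  if (!is.na(network$focal)) {
    f <- .node_index(network, network$focal)
    if (f != j && state[f] > 0) w[f] <- w[f] * network$focal_w
  }
  sum(w * state)
}

#' Find steady states by asynchronous simulation
#'
#' Per replicate, `n_init` initial conditions are drawn uniformly over
#' `{-1, +1}^n` (cytokine nodes clamped at +1), relaxed by asynchronous
#' single-node updates, and every trajectory that passes the exact
#' fixed-point test within `max_steps` updates is recorded. Frequencies are
#' relative to the converged trajectories of each replicate; the converged
#' fraction is reported separately.
#'
#' @param network a [signed_network()]
#' @param config a [sim_config()]
#' @return an object of class `steady_state_distribution` with fields
#'   `states` (matrix of fixed points, one row per state, values -1/+1),
#'   `freq` (state-by-replicate relative frequencies), `mean` and `ci`
#'   (across-replicate mean and 95% CI half-width), `k` (number of high core
#'   nodes per state), `converged_fraction` (per replicate), `nodes`, `core`
#'   and the `config` used.
#' @seealso [k_frequencies()], [enumerate_fixed_points()]
#' @export
find_steady_states <- function(network, config = sim_config()) {
  seeds <- .child_seeds(config)
  reps <- lapply(seeds, function(s)
    sim_async_cpp(network$adjacency, .clamped(network), 1L,
                  .focal_index0(network), network$focal_w,
                  config$n_init, config$max_steps, s, NULL))
  .assemble_distribution(network, reps, config, levels = 1L)
}

.assemble_distribution <- function(network, reps, config, levels) {
  n <- length(network$nodes)
  keys <- lapply(reps, function(r)
    apply(r$states, 1, paste, collapse = ","))
  all_keys <- unique(unlist(keys))
  nr <- length(reps)
  freq <- matrix(0, length(all_keys), nr,
                 dimnames = list(all_keys, NULL))
  for (r in seq_len(nr)) {
    nc <- reps[[r]]$n_converged
    if (nc > 0)
      freq[keys[[r]], r] <- reps[[r]]$counts / nc
  }
  if (length(all_keys) > 0) {
    states <- do.call(rbind, lapply(strsplit(all_keys, ","), as.integer))
  } else {
    states <- matrix(integer(0), 0, n)
  }
  colnames(states) <- network$nodes
  conv <- vapply(reps, function(r) r$n_converged / r$n_total, numeric(1))
  core <- network$roles == "core"
  vals <- states / levels
  k <- as.integer(rowSums(states[, core, drop = FALSE] == levels))
  m <- rowMeans(freq)
  ci <- if (nr > 1) qnorm(0.975) * apply(freq, 1, stats::sd) / sqrt(nr)
        else rep(NA_real_, nrow(freq))
  structure(list(states = states, values = vals, freq = freq, mean = m,
                 ci = ci, k = k, converged_fraction = conv,
                 nodes = network$nodes, core = core, teams = network$teams,
                 levels = levels, config = config),
            class = "steady_state_distribution")
}

#' @export
print.steady_state_distribution <- function(x, ...) {
  cat("steady_state_distribution:", nrow(x$states), "fixed point(s),",
      "mean converged fraction", round(mean(x$converged_fraction), 4), "\n")
  if (nrow(x$states) > 0) {
    ord <- order(-x$mean)
    show <- utils::head(ord, 12)
    lab <- apply(x$values[show, , drop = FALSE], 1, format_state)
    df <- data.frame(state = lab, k = x$k[show],
                     frequency = signif(x$mean[show], 4),
                     ci95 = signif(x$ci[show], 3))
    print(df, row.names = FALSE)
    if (length(ord) > 12) cat("  ...", length(ord) - 12, "more\n")
  }
  invisible(x)
}

#' Exhaustively enumerate Boolean fixed points
#'
#' Checks every state in `{-1, +1}^n` (cytokine nodes held at +1) against
#' the exact fixed-point test: no single-node update changes the state.
#' Serves as ground truth for [find_steady_states()]; limited to 24 free
#' nodes.
#'
#' @param network a [signed_network()]
#' @return integer matrix of fixed points (rows; values -1/+1), with
#'   columns named by node
#' @export
enumerate_fixed_points <- function(network) {
  st <- enum_fixed_boolean_cpp(network$adjacency, .clamped(network),
                               .focal_index0(network), network$focal_w)
  colnames(st) <- network$nodes
  st
}

#' Build the asynchronous state-transition graph
#'
#' Vertices are all `2^n` Boolean states; there is an edge `u -> v` whenever
#' some single asynchronous node update maps `u` to `v != u`. States with no
#' outgoing edge are the stable fixed points. States that would be fixed
#' points if the self-edges were removed but possess outgoing transitions are
#' classified as meta-stable: they maintain themselves under some update
#' orders yet can escape to other states via their self-regulation.
#'
#' @param network a [signed_network()] with at most 14 free nodes
#' @return a list with `states` (matrix of all states), `graph` (an
#'   [igraph::graph] on state indices), `stable` and `metastable` (logical
#'   per state), and `self_consistent` (state-by-node logical matrix: does
#'   updating that node leave the state unchanged)
#' @export
build_state_transition_graph <- function(network) {
  n <- length(network$nodes)
  free <- which(!.clamped(network))
  if (length(free) > 14)
    stop("state-transition graph limited to 14 free nodes")
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(free))))
  ns <- nrow(grid)
  states <- matrix(1, ns, n, dimnames = list(NULL, network$nodes))
  states[, free] <- grid
  key <- apply(states, 1, paste, collapse = ",")
  idx_of <- setNames(seq_len(ns), key)

  self_ok <- matrix(TRUE, ns, n, dimnames = list(NULL, network$nodes))
  from <- integer(0); to <- integer(0)
  for (s in seq_len(ns)) {
    st <- states[s, ]
    for (j in free) {
      new <- ising_update(network, st, j)
      same <- new[j] == st[j]
      self_ok[s, j] <- same
      if (!same) {
        from <- c(from, s)
        to <- c(to, idx_of[[paste(new, collapse = ",")]])
      }
    }
  }
  stable <- rowSums(!self_ok[, free, drop = FALSE]) == 0

  # meta-stability: fixed point of the same network stripped of self-edges
  nodiag <- network
  diag(nodiag$adjacency) <- 0
  fp_nodiag <- enumerate_fixed_points(nodiag)
  key_nd <- apply(fp_nodiag, 1, paste, collapse = ",")
  metastable <- key %in% key_nd & !stable

  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = TRUE,
    vertices = data.frame(name = seq_len(ns))
  )
  list(states = states, graph = g, stable = stable, metastable = metastable,
       self_consistent = self_ok)
}

#' Relax single-bit perturbations of every fixed point
#'
#' For each fixed point and each single-node flip, the perturbed state is
#' relaxed `n_relax` times under asynchronous dynamics and the distribution
#' of reached fixed points is recorded together with its Hamming distance
#' from the originating fixed point.
#'
#' @param network a [signed_network()]
#' @param config a [sim_config()]; `n_init` is used as the number of
#'   relaxations per perturbation
#' @return data frame with columns `origin`, `flipped`, `reached`,
#'   `frequency`, `hamming` (distance of the reached state from the origin)
#'   and `converged` (fraction of relaxations that converged)
#' @export
hamming_perturbation <- function(network, config = sim_config(n_init = 200)) {
  fps <- enumerate_fixed_points(network)
  free <- which(!.clamped(network))
  seeds <- .child_seeds(config)
  out <- list()
  for (i in seq_len(nrow(fps))) {
    origin <- fps[i, ]
    for (j in free) {
      pert <- origin
      pert[j] <- -pert[j]
      res <- sim_async_cpp(network$adjacency, .clamped(network), 1L,
                           .focal_index0(network), network$focal_w,
                           config$n_init, config$max_steps,
                           seeds[(j %% length(seeds)) + 1L],
                           matrix(pert, 1))
      if (res$n_converged > 0) {
        reached <- res$states
        ham <- rowSums(reached != matrix(origin, nrow(reached),
                                         length(origin), byrow = TRUE))
        out[[length(out) + 1L]] <- data.frame(
          origin = format_state(origin),
          flipped = network$nodes[j],
          reached = apply(reached, 1, format_state),
          frequency = res$counts / res$n_converged,
          hamming = as.integer(ham),
          converged = res$n_converged / res$n_total)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          origin = format_state(origin), flipped = network$nodes[j],
          reached = NA_character_, frequency = NA_real_,
          hamming = NA_integer_, converged = 0)
      }
    }
  }
  do.call(rbind, out)
}

#' k-high frequency summary F(k)
#'
#' `F(k)` is the total relative frequency of converged steady states having
#' exactly `k` core nodes high. With no converged trajectories all `F(k)`
#' are zero; otherwise they sum to 1.
#'
#' @param dist a `steady_state_distribution`
#' @return data frame with columns `k`, `F` (mean across replicates) and
#'   `ci` (95% CI half-width)
#' @seealso [single_positive_frequency()]
#' @export
k_frequencies <- function(dist) {
  n_core <- sum(dist$core)
  ks <- 0:n_core
  fk <- vapply(ks, function(k) sum(dist$mean[dist$k == k]), numeric(1))
  ci <- vapply(ks, function(k) {
    rows <- dist$k == k
    if (!any(rows) || ncol(dist$freq) < 2) return(NA_real_)
    per_rep <- colSums(dist$freq[rows, , drop = FALSE])
    qnorm(0.975) * stats::sd(per_rep) / sqrt(length(per_rep))
  }, numeric(1))
  data.frame(k = ks, F = fk, ci = ci)
}

#' Frequency of the single-positive state of a named node
#'
#' `F_A(1)`: the relative frequency of the steady state in which the focal
#' node `A` is the only high core node.
#'
#' @param dist a `steady_state_distribution`
#' @param node core node name
#' @return numeric scalar in `[0, 1]`
#' @export
single_positive_frequency <- function(dist, node) {
  j <- match(node, dist$nodes)
  if (is.na(j)) stop("unknown node '", node, "'")
  core_idx <- which(dist$core)
  if (!(j %in% core_idx)) stop("'", node, "' is not a core node")
  rows <- dist$states[, j] == dist$levels &
    dist$k == 1L
  sum(dist$mean[rows])
}
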