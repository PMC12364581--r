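# Multi-level extension of the Ising formalism.
#
# With l levels per sign a node takes values in {-1, ..., -1/l, 1/l, ..., 1}
# (2l levels; zero is excluded). One asynchronous update computes the
# normalized input s = sum_i Adj[i,j] x_i / d_j, where d_j counts the node's
# nonzero incoming weights (self-edges included), and maps s into the level
# bracket it falls in: (k-1)/l < s <= k/l gives +k/l, -k/l <= s < -(k-1)/l
# gives -k/l, values beyond +-(l-1)/l give +-1, and s = 0 holds the current
# value. With l = 1 every bracket collapses to the sign and the rule is
# exactly the Boolean Ising update.

#' Multi-level asynchronous update of a single node
#'
#' Reference implementation of one update in the 2l-level state space; see
#' the package vignette for the bracket rule. With `l = 1` this coincides
#' with [ising_update()] for every state and node.
#'
#' @param network a [signed_network()]
#' @param state named numeric vector with values in `{+-k/l, k = 1..l}`
#' @param node node name or index to update
#' @param l levels per sign (l = 2 is the four-level model)
#' @return the updated state vector
#' @examples
#' tm <- make_team_network(c(2, 2))
#' st <- setNames(rep(0.5, 4), tm$nodes)
#' multilevel_update(tm, st, 1, l = 2)
#' @export
multilevel_update <- function(network, state, node, l) {
  j <- .node_index(network, node)
  if (network$roles[j] == "cytokine")
    stop("node '", network$nodes[j], "' is a clamped cytokine")
  l <- as.integer(l)
  stopifnot(l >= 1)
  m <- round(state * l)
  if (any(abs(m) < 1 | abs(m) > l | abs(m - state * l) > 1e-9))
    stop("state values must lie on the level grid {+-k/l, k = 1..l}")
  w <- network$adjacency[, j]
  d <- sum(w != 0)
  if (d == 0) {
    warning("node '", network$nodes[j], "' has no regulators; value held")
    return(state)
  }
  T <- sum(w * m) # = l * d * s
  if (T == 0) return(state)
  k <- min(ceiling(abs(T) / d), l)
  state[j] <- sign(T) * k / l
  state
}

#' Find multi-level steady states by asynchronous simulation
#'
#' Runs the same asynchronous protocol as [find_steady_states()] over the
#' 2l-level state space, with initial conditions uniform over the levels
#' independently per node. For team networks the result additionally carries
#' team scores and discretized team profiles per fixed point (see
#' [discretize_profile()]) and their aggregated frequencies.
#'
#' @param network a [signed_network()]; a warning is issued when it carries
#'   no team annotation, since the multi-level analyses in this package are
#'   designed around team networks
#' @param l levels per sign (l = 2 is the four-level model; l = 1 reduces to
#'   the Boolean engine)
#' @param config a [sim_config()]
#' @param min_mass smallest mean frequency a steady state must carry to
#'   contribute to the attained-maximum expression level used to normalize
#'   team scores (default 0.001); rare tie-held states are still classified,
#'   they just do not set the reference level
#' @return a `steady_state_distribution` whose `values` matrix holds level
#'   fractions; for team networks, extra fields `team_scores` (state-by-team
#'   matrix), `profile` (discretized profile string per state),
#'   `profile_freq` (aggregated mean frequency per profile) and
#'   `max_attained` (the normalization level)
#' @export
find_multilevel_steady_states <- function(network, l, config = sim_config(),
                                          min_mass = 0.001) {
  l <- as.integer(l)
  stopifnot(l >= 1)
  if (is.null(network$teams) && l > 1)
    warning("multi-level simulation of a network without team annotation; ",
            "this territory is untested against the team-network analyses")
  seeds <- .child_seeds(config)
  reps <- lapply(seeds, function(s)
    sim_async_cpp(network$adjacency, .clamped(network), l,
                  .focal_index0(network), network$focal_w,
                  config$n_init, config$max_steps, s, NULL))
  dist <- .assemble_distribution(network, reps, config, levels = l)
  if (!is.null(network$teams) && nrow(dist$states) > 0) {
    # Team scores are normalized by the maximum expression level the
    # dynamics actually sustain: with more levels the steady states settle
    # below the grid maximum, and a state saturating at the attained maximum
    # is a fully polarized (0/2) configuration. The attained maximum is read
    # off the steady states carrying non-negligible mass (>= min_mass), so
    # that rare tie-held mixed states do not distort the reference level.
    major <- dist$mean >= min_mass
    if (!any(major)) major <- rep(TRUE, length(dist$mean))
    dist$max_attained <- max(abs(dist$values[major, , drop = FALSE]))
    profs <- lapply(seq_len(nrow(dist$values)), function(i)
      discretize_profile(dist$values[i, ], network$teams,
                         max_level = dist$max_attained))
    dist$team_scores <- do.call(rbind, lapply(profs, `[[`, "scores"))
    dist$profile <- vapply(profs, `[[`, character(1), "profile")
    agg <- tapply(dist$mean, dist$profile, sum)
    dist$profile_freq <- sort(unlist(as.list(agg)), decreasing = TRUE)
  }
  dist
}

#' Team scores and discretized profile of a multi-level state
#'
#' The team score is the mean expression of the team's member nodes, divided
#' by the maximum expression `max_level`. The discretized symbol is 2 for a
#' normalized score of exactly +1, 0 for exactly -1, and 1 for anything
#' strictly between; the profile string lists the symbols sorted descending
#' (labels like `"22000"`).
#'
#' For a single state the natural reference is the grid maximum
#' (`max_level = 1`). When profiling a whole simulation,
#' [find_multilevel_steady_states()] instead normalizes by the maximum level
#' attained across its steady states, because with finer level grids the
#' dynamics settle below the grid maximum and a team saturating at the
#' attained maximum is a fully polarized configuration.
#'
#' @param state named numeric vector of node values
#' @param teams named character vector node -> team label, or a
#'   [signed_network()] carrying the annotation
#' @param max_level normalization constant (default 1, the grid maximum)
#' @return list with `scores` (per-team normalized mean expression),
#'   `symbols` (per-team 0/1/2) and `profile` (sorted label string)
#' @export
discretize_profile <- function(state, teams, max_level = 1) {
  if (inherits(teams, "signed_network")) teams <- teams$teams
  if (is.null(teams)) stop("no team annotation available")
  if (!all(names(teams) %in% names(state)))
    stop("teams must cover nodes present in the state")
  stopifnot(max_level > 0)
  scores <- tapply(state[names(teams)], teams, mean) / max_level
  sym <- ifelse(scores >= 1 - 1e-9, 2L, ifelse(scores <= -1 + 1e-9, 0L, 1L))
  list(scores = scores, symbols = sym,
       profile = paste(sort(sym, decreasing = TRUE), collapse = ""))
}

#' Exhaustively enumerate multi-level fixed points
#'
#' Checks every state on the 2l-level grid against the fixed-point test of
#' the multi-level update. Intended for small team networks; the state count
#' is `(2l)^n_free` and is limited to 500000.
#'
#' @param network a [signed_network()]
#' @param l levels per sign
#' @return numeric matrix of fixed points (rows; level-fraction values)
#' @export
enumerate_multilevel_fixed_points <- function(network, l) {
  l <- as.integer(l)
  free <- which(!.clamped(network))
  n <- length(network$nodes)
  ns <- (2 * l)^length(free)
  if (ns > 500000) stop("state space too large to enumerate (", ns, " states)")
  lv <- setdiff(seq.int(-l, l), 0L)
  grid <- as.matrix(expand.grid(rep(list(lv), length(free))))
  M <- matrix(l, ns, n, dimnames = list(NULL, network$nodes))
  M[, free] <- grid
  adj <- network$adjacency
  d <- colSums(adj != 0)
  TT <- M %*% adj # state-by-node input sums (times l * d)
  ok <- rep(TRUE, ns)
  for (j in free) {
    if (d[j] == 0) next # isolated node always holds
    Tj <- TT[, j]
    kj <- pmin(ceiling(abs(Tj) / d[j]), l)
    newm <- ifelse(Tj == 0, M[, j], sign(Tj) * kj)
    ok <- ok & newm == M[, j]
  }
  M[ok, , drop = FALSE] / l
}
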