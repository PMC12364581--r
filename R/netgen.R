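# Generators for the network families studied with the toggle-n model:
# pure toggle-n circuits, impurity (sign-flip) variants, team networks, and
# toggle circuits embedded in random host digraphs.

#' Build a toggle-n network
#'
#' A toggle-n (Tn) network is a fully connected circuit of `n` nodes in which
#' every ordered pair of distinct nodes is joined by an inhibitory edge
#' (weight -1). Self-regulation optionally puts `+1` (activation) or `-1`
#' (inhibition) on the diagonal.
#'
#' @param n number of nodes, at least 2
#' @param self_regulation `"none"`, `"activation"` or `"inhibition"`
#' @param node_names optional character vector of node names (default
#'   `A, B, C, ...` then `n7, n8, ...` beyond 26)
#' @return a [signed_network()]
#' @examples
#' make_toggle(3)$adjacency
#' @export
make_toggle <- function(n, self_regulation = c("none", "activation", "inhibition"),
                        node_names = NULL) {
  self_regulation <- match.arg(self_regulation)
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("a toggle network needs at least 2 nodes")
  if (is.null(node_names))
    node_names <- if (n <= 26) LETTERS[seq_len(n)] else paste0("n", seq_len(n))
  if (length(node_names) != n) stop("node_names must have length n")
  adj <- matrix(-1, n, n, dimnames = list(node_names, node_names))
  diag(adj) <- switch(self_regulation, none = 0, activation = 1, inhibition = -1)
  signed_network(adj)
}

#' Generate non-isomorphic impurity variants of a toggle network
#'
#' An impurity replaces an inhibitory off-diagonal edge of a toggle-n network
#' with an activation. All variants with exactly `n_imp` impurities are
#' considered; because of the symmetry of the toggle many are isomorphic, so
#' the list is reduced to pairwise non-isomorphic representatives.
#' Isomorphism is judged on the unweighted digraph formed by the activating
#' edges alone (presence of an edge = activation, absence = inhibition).
#'
#' When all edge combinations can be enumerated they are enumerated, filtered
#' for isomorphism and capped; otherwise combinations are sampled uniformly
#' without replacement and filtered until the cap is reached. Default caps
#' follow the study design: 100 variants for n <= 5, 50 for n = 6; n > 6 is
#' combinatorially infeasible and raises an error.
#'
#' @param n toggle size, 2..6
#' @param n_imp number of impurities, 0..n(n-1)
#' @param max_variants cap on returned variants (default 100 for n <= 5,
#'   50 for n = 6)
#' @param seed integer seed for the sampling path
#' @param enum_limit largest number of edge combinations that is enumerated
#'   exhaustively before falling back to sampling
#' @return list of [signed_network()]s, each with `n_imp` activating
#'   off-diagonal edges, pairwise non-isomorphic
#' @export
make_impurity_variants <- function(n, n_imp, max_variants = NULL, seed = 1,
                                   enum_limit = 20000) {
  n <- as.integer(n)
  if (n < 2) stop("n must be at least 2")
  if (n > 6)
    stop("impurity analysis is combinatorially infeasible for n > 6")
  n_edges <- n * (n - 1L)
  n_imp <- as.integer(n_imp)
  if (is.na(n_imp) || n_imp < 0 || n_imp > n_edges)
    stop("n_imp must be between 0 and n(n-1) = ", n_edges)
  if (is.null(max_variants)) max_variants <- if (n <= 5) 100L else 50L

  base <- make_toggle(n)
  offdiag <- which(row(base$adjacency) != col(base$adjacency))

  flip_net <- function(combo) {
    net <- base
    net$adjacency[offdiag[combo]] <- 1
    net
  }
  act_graph <- function(net) {
    igraph::graph_from_adjacency_matrix((net$adjacency > 0) * 1L,
                                        mode = "directed", diag = TRUE)
  }
  keep <- list()
  keep_g <- list()
  consider <- function(combo) {
    net <- flip_net(combo)
    g <- act_graph(net)
    for (h in keep_g)
      if (igraph::isomorphic(g, h, method = "vf2")) return(FALSE)
    keep[[length(keep) + 1L]] <<- net
    keep_g[[length(keep_g) + 1L]] <<- g
    TRUE
  }

  n_combos <- choose(n_edges, n_imp)
  if (n_combos <= enum_limit) {
    combos <- if (n_imp == 0) list(integer(0)) else
      asplit(combn(n_edges, n_imp), 2)
    for (cb in combos) {
      consider(as.integer(cb))
      if (length(keep) >= max_variants) break
    }
  } else {
    set.seed(seed)
    seen <- new.env(hash = TRUE)
    budget <- 40L * max_variants
    while (length(keep) < max_variants && budget > 0L) {
      budget <- budget - 1L
      cb <- sort(sample.int(n_edges, n_imp))
      key <- paste(cb, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      consider(cb)
    }
  }
  keep
}

#' Specify a partition of nodes into teams
#'
#' @param sizes integer vector of per-team member counts, all at least 1
#' @return an object of class `team_spec` with fields `n_teams` and `sizes`
#' @export
team_spec <- function(sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1 || any(is.na(sizes)) || any(sizes < 1))
    stop("all team sizes must be integers >= 1")
  structure(list(n_teams = length(sizes), sizes = sizes), class = "team_spec")
}

#' Build a team network
#'
#' A team network is a fully connected circuit whose nodes are partitioned
#' into teams: members of the same team activate each other (+1), members of
#' different teams inhibit each other (-1), and the diagonal is zero. With
#' every team of size 1 this reduces exactly to the toggle network.
#'
#' @param spec a [team_spec()] or an integer vector of team sizes
#' @return a [signed_network()] with the team partition recorded
#' @examples
#' make_team_network(c(2, 2))$adjacency
#' @export
make_team_network <- function(spec) {
  if (!inherits(spec, "team_spec")) spec <- team_spec(spec)
  if (spec$n_teams == 1)
    warning("a single team gives an all-activation network (degenerate)")
  team_of <- rep(paste0("T", seq_len(spec$n_teams)), spec$sizes)
  nodes <- unlist(lapply(seq_len(spec$n_teams), function(t)
    paste0("T", t, "_", seq_len(spec$sizes[t]))))
  n <- length(nodes)
  adj <- outer(team_of, team_of, function(a, b) ifelse(a == b, 1, -1))
  diag(adj) <- 0
  dimnames(adj) <- list(nodes, nodes)
  signed_network(adj, teams = setNames(team_of, nodes))
}

#' Sample unequal team-size splits
#'
#' Draws per-team member counts from a multinomial with `mean_size * n_teams`
#' trials and equal probabilities, rejecting draws in which any team is empty
#' or any team has exactly the average size `mean_size`. The rejection rule
#' guarantees genuinely unequal teams while keeping the total fixed.
#'
#' @param n_teams number of teams, at least 2
#' @param mean_size average team size (the multinomial total is
#'   `n_teams * mean_size`)
#' @param n_networks number of splits to sample
#' @param seed integer seed
#' @param max_tries rejection-sampling budget per split
#' @return list of [team_spec()]s, each summing to `n_teams * mean_size`
#' @export
sample_unequal_teams <- function(n_teams, mean_size, n_networks, seed,
                                 max_tries = 10000) {
  n_teams <- as.integer(n_teams)
  mean_size <- as.integer(mean_size)
  if (n_teams < 2) stop("need at least 2 teams")
  if (mean_size < 1) stop("mean_size must be at least 1")
  set.seed(seed)
  total <- n_teams * mean_size
  out <- vector("list", n_networks)
  for (k in seq_len(n_networks)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      m <- as.integer(rmultinom(1, total, rep(1 / n_teams, n_teams)))
      if (all(m >= 1) && all(m != mean_size)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not satisfy the size constraints (every team non-empty, ",
           "no team of exactly the mean size) in ", max_tries,
           " draws; the constraints may be unsatisfiable for n_teams = ",
           n_teams, ", mean_size = ", mean_size)
    out[[k]] <- team_spec(m)
  }
  out
}

#' Specify a random host graph for embedding
#'
#' @param embedding_size node count of the random host digraph
#' @param embedding_density average number of edges per host node (the host
#'   carries `embedding_size * embedding_density` directed edges)
#' @param n_replicates number of independent random hosts
#' @return an object of class `embedding_spec`
#' @export
embedding_spec <- function(embedding_size = 10, embedding_density = 2,
                           n_replicates = 100) {
  embedding_size <- as.integer(embedding_size)
  embedding_density <- as.numeric(embedding_density)
  n_edges <- round(embedding_size * embedding_density)
  if (embedding_size < 1) stop("embedding_size must be at least 1")
  if (n_edges > embedding_size * (embedding_size - 1))
    stop("requested ", n_edges, " host edges but a simple digraph on ",
         embedding_size, " nodes holds at most ",
         embedding_size * (embedding_size - 1))
  structure(list(embedding_size = embedding_size,
                 embedding_density = embedding_density,
                 n_edges = as.integer(n_edges),
                 n_replicates = as.integer(n_replicates)),
            class = "embedding_spec")
}

#' Embed a network in random host digraphs
#'
#' The core network is merged with a uniformly random simple directed host
#' graph (no self-loops) carrying exactly `size * density` edges, each with a
#' weight drawn uniformly from `{-1, +1}`. Every ordered cross pair
#' (core, host) and (host, core) receives an independent weight drawn
#' uniformly from `{-1, 0, +1}`. Core-internal edges are untouched; host
#' nodes get role `"embedding"`.
#'
#' @param network the core [signed_network()]
#' @param spec an [embedding_spec()]
#' @param seed integer seed; replicate hosts use child seeds derived from it
#' @return list of `spec$n_replicates` embedded [signed_network()]s
#' @export
embed_in_random <- function(network, spec = embedding_spec(), seed = 1) {
  if (!inherits(spec, "embedding_spec")) stop("spec must be an embedding_spec")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, spec$n_replicates)
  nc <- length(network$nodes)
  nh <- spec$embedding_size
  host_names <- paste0("E", seq_len(nh))
  if (any(host_names %in% network$nodes))
    host_names <- paste0("emb", seq_len(nh))
  nodes <- c(network$nodes, host_names)
  lapply(seq_len(spec$n_replicates), function(r) {
    set.seed(child[r])
    adj <- matrix(0, nc + nh, nc + nh, dimnames = list(nodes, nodes))
    adj[seq_len(nc), seq_len(nc)] <- network$adjacency
    # host: uniform simple digraph with exactly n_edges edges
    pairs <- which(diag(nh) == 0)
    picked <- sample(pairs, spec$n_edges)
    hadj <- matrix(0, nh, nh)
    hadj[picked] <- sample(c(-1, 1), spec$n_edges, replace = TRUE)
    adj[nc + seq_len(nh), nc + seq_len(nh)] <- hadj
    # cross edges, every ordered pair in both directions
    adj[seq_len(nc), nc + seq_len(nh)] <-
      sample(c(-1, 0, 1), nc * nh, replace = TRUE)
    adj[nc + seq_len(nh), seq_len(nc)] <-
      sample(c(-1, 0, 1), nc * nh, replace = TRUE)
    signed_network(adj, roles = c(network$roles, rep("embedding", nh)))
  })
}

#' Write a batch of networks with an index file
#'
#' Persists each network as `<prefix><i>.topo` (plus a weight sidecar when
#' the network carries non-unit weights) and writes `<prefix>index.csv`
#' recording id, family, parameters and seed.
#'
#' @param networks list of [signed_network()]s
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @param family label recorded in the index
#' @param parameters single string describing generator parameters
#' @param seed seed recorded in the index
#' @return path of the index CSV, invisibly
#' @export
write_network_batch <- function(networks, dir, prefix = "net", family = "",
                                parameters = "", seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(networks), function(i) {
    net <- networks[[i]]
    id <- sprintf("%s%03d", prefix, i)
    topo <- file.path(dir, paste0(id, ".topo"))
    signed <- net
    signed$adjacency <- sign(net$adjacency)
    write_topo(signed, topo)
    has_w <- any(net$adjacency != 0 & abs(net$adjacency) != 1)
    if (has_w) write_weights(net, file.path(dir, paste0(id, "_weights.json")))
    data.frame(id = id, family = family, parameters = parameters,
               seed = seed, topo = basename(topo),
               weights = if (has_w) paste0(id, "_weights.json") else "")
  })
  idx <- file.path(dir, paste0(prefix, "index.csv"))
  write.table(do.call(rbind, rows), idx, sep = ",", quote = TRUE,
              row.names = FALSE)
  invisible(idx)
}
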