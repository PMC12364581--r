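# Experiment-level drivers: F(k) sweeps across network families, impurity
# sweeps, and the T-helper cell differentiation case study.

#' Sweep F(k) statistics over toggle sizes and self-regulation modes
#'
#' For every combination of network size and self-regulation mode, simulates
#' the toggle network and reports the k-high frequencies of interest:
#' `F(1)`, and `F(n/2)`, `F(n/2 - 1)`, `F(n/2 + 1)` for even n or
#' `F((n-1)/2)`, `F((n+1)/2)` for odd n, each with its 95% CI.
#'
#' @param n_range integer vector of network sizes (default 2:8)
#' @param modes subset of `c("none", "activation", "inhibition")`
#' @param config a [sim_config()]
#' @return data frame with columns `n`, `mode`, `statistic`, `k`, `F`, `ci`,
#'   `converged_fraction`
#' @export
run_fk_sweep <- function(n_range = 2:8, modes = "none",
                         config = sim_config()) {
  rows <- list()
  for (n in n_range) {
    for (mode in modes) {
      net <- make_toggle(n, mode)
      dist <- find_steady_states(net, config)
      fk <- k_frequencies(dist)
      ks <- if (n %% 2 == 0) {
        c(F1 = 1, `F(n/2)` = n / 2, `F(n/2-1)` = n / 2 - 1,
          `F(n/2+1)` = n / 2 + 1)
      } else {
        c(F1 = 1, `F((n-1)/2)` = (n - 1) / 2, `F((n+1)/2)` = (n + 1) / 2)
      }
      for (s in seq_along(ks)) {
        k <- ks[s]
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, mode = mode, statistic = names(ks)[s], k = k,
          F = fk$F[fk$k == k], ci = fk$ci[fk$k == k],
          converged_fraction = mean(dist$converged_fraction))
      }
    }
  }
  do.call(rbind, rows)
}

#' Sweep F(k) over impurity levels of a toggle network
#'
#' At every impurity level `n_imp` in `0..n(n-1)`, non-isomorphic variants
#' are generated, each is simulated, and the mean F(k) across variants is
#' reported with a 95% CI over variants.
#'
#' @param n toggle size, 2..6
#' @param config a [sim_config()]
#' @param max_variants cap on variants per impurity level (see
#'   [make_impurity_variants()])
#' @param seed seed for variant sampling
#' @return data frame with columns `n_imp`, `n_variants`, `k`, `F`, `ci`
#' @export
run_impurity_sweep <- function(n, config = sim_config(), max_variants = NULL,
                               seed = 1) {
  rows <- list()
  for (n_imp in 0:(n * (n - 1))) {
    nets <- make_impurity_variants(n, n_imp, max_variants = max_variants,
                                   seed = seed)
    per_var <- lapply(nets, function(net)
      k_frequencies(find_steady_states(net, config)))
    for (k in 0:n) {
      f_k <- vapply(per_var, function(fk) fk$F[fk$k == k], numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        n_imp = n_imp, n_variants = length(nets), k = k, F = mean(f_k),
        ci = if (length(f_k) > 1)
          qnorm(0.975) * stats::sd(f_k) / sqrt(length(f_k)) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

# canonical lineage order used to compose hybrid-state names
.thelper_lineages <- c(TBX21 = "Th1", GATA3 = "Th2", RORC = "Th17",
                       FOXP3 = "Treg", BCL6 = "TFH")

#' The T-helper master-regulator network
#'
#' Loads the packaged 5-node network of the CD4+ T-cell master regulators
#' TBX21 (Th1), GATA3 (Th2), RORC (Th17), FOXP3 (Treg) and BCL6 (TFH). The
#' wiring is an incomplete toggle-5: the first four regulators mutually
#' inhibit one another (12 edges), TBX21 and BCL6 mutually inhibit (2
#' edges), and BCL6 inhibits GATA3 and RORC (2 edges) -- 16 of the 20
#' possible inhibitory interactions; no regulation of BCL6 by GATA3, RORC or
#' FOXP3 and no BCL6 -> FOXP3 edge has been reported. The
#' `"self_activation"` variant adds self-activation on TBX21, GATA3, RORC
#' and FOXP3, which are documented self-activators.
#'
#' @param variant `"base"` or `"self_activation"`
#' @return a [signed_network()]
#' @export
thelper_network <- function(variant = c("base", "self_activation")) {
  variant <- match.arg(variant)
  net <- read_topo(system.file("extdata", "thelper.topo",
                               package = "togglen", mustWork = TRUE))
  if (variant == "self_activation") {
    for (nd in c("TBX21", "GATA3", "RORC", "FOXP3"))
      net$adjacency[nd, nd] <- 1
  }
  net
}

#' Name a state by the lineages of its high master regulators
#'
#' Multi-high states are named by joining the lineage names of the high
#' nodes with "/" in the canonical order Th1, Th2, Th17, Treg, TFH (for
#' example TBX21+GATA3 high is `"Th1/Th2"`); the all-low state is `"none"`.
#'
#' @param state named numeric vector over (a subset of) the master
#'   regulators
#' @return character scalar
#' @export
thelper_state_label <- function(state) {
  regs <- names(.thelper_lineages)[names(.thelper_lineages) %in% names(state)]
  hi <- regs[state[regs] > 0]
  if (length(hi) == 0) return("none")
  paste(.thelper_lineages[hi], collapse = "/")
}

#' Run the T-helper steady-state case study
#'
#' Simulates the T-helper network (or an ensemble of perturbed versions) and
#' reports the fixed points labelled by hybrid-state names.
#'
#' Variants: `"base"` and `"self_activation"` simulate the fixture network
#' directly; `"random_weights"` averages over `n_sets` U(0,1) edge-weight
#' sets; `"embedded"` averages over hosts generated per `embed_spec`.
#'
#' @param variant one of `"base"`, `"self_activation"`, `"random_weights"`,
#'   `"embedded"`
#' @param config a [sim_config()]
#' @param n_sets number of random weight sets for `"random_weights"`
#' @param embed_spec an [embedding_spec()] for `"embedded"`
#' @return a list with `table` (data frame: label, k, mean frequency, ci)
#'   and `distributions` (the underlying `steady_state_distribution`s)
#' @export
run_thelper_case_study <- function(variant = c("base", "self_activation",
                                               "random_weights", "embedded"),
                                   config = sim_config(), n_sets = 20,
                                   embed_spec = embedding_spec(10, 2, 20)) {
  variant <- match.arg(variant)
  nets <- switch(variant,
    base = list(thelper_network("base")),
    self_activation = list(thelper_network("self_activation")),
    random_weights = randomize_edge_weights(thelper_network("base"),
                                            n_sets = n_sets,
                                            seed = config$seed),
    embedded = embed_in_random(thelper_network("base"), embed_spec,
                               seed = config$seed))
  dists <- lapply(nets, find_steady_states, config = config)
  regs <- names(.thelper_lineages)
  acc <- list()
  for (d in dists) {
    if (nrow(d$states) == 0) next
    lab <- apply(d$states[, regs, drop = FALSE], 1, function(s)
      thelper_state_label(setNames(s, regs)))
    k <- as.integer(rowSums(d$states[, regs, drop = FALSE] > 0))
    acc[[length(acc) + 1L]] <- data.frame(label = lab, k = k, f = d$mean)
  }
  all <- do.call(rbind, acc)
  agg <- stats::aggregate(f ~ label + k, all, sum)
  agg$f <- agg$f / length(dists)
  agg <- agg[order(-agg$f), ]
  names(agg)[3] <- "frequency"
  list(table = agg, distributions = dists)
}

# exogenous cytokines driving each lineage
.thelper_cytokines <- list(Th1 = c("IFNg", "IL12"), Th2 = c("IL4", "IL2"),
                           Th17 = c("TGFb", "IL6", "IL21"),
                           Treg = c("TGFb", "IL2"))

#' Documented deviations of the T-helper cytokine wiring from the toy model
#'
#' The generic model has each of a lineage's cytokines activate its master
#' regulator and inhibit the others. Two reported deviations are provided as
#' per-cytokine overrides for [run_thelper_cytokines()]: IFN-gamma (a Th1
#' cytokine) also activates FOXP3, and TGF-beta (shared by the Treg and Th17
#' milieus) activates RORC, so Treg stimulation carries a side activation of
#' the Th17 regulator. The full literature-derived interaction table is not
#' bundled; these overrides record the assumptions explicitly and further
#' ones can be supplied in the same format.
#'
#' @return named list (by stimulation) of lists (by cytokine) of sign
#'   vectors over master regulators
#' @export
thelper_cytokine_overrides <- function() {
  list(Th1 = list(IFNg = c(FOXP3 = 1)),
       Treg = list(TGFb = c(RORC = 1)))
}

#' Simulate T-helper sub-networks under lineage-specific cytokines
#'
#' Builds the mutually inhibitory sub-network of the first 2, 3 or 4 master
#' regulators (T2 = TBX21/GATA3, T3 = + RORC, T4 = + FOXP3) and attaches one
#' clamped node per exogenous cytokine of the stimulated lineage (Th1:
#' IFN-gamma, IL-12; Th2: IL-4, IL-2; Th17: TGF-beta, IL-6, IL-21; Treg:
#' TGF-beta, IL-2). Each cytokine activates the stimulated lineage's master
#' regulator with strength `W_C` and inhibits the other regulators present,
#' unless a per-cytokine sign override says otherwise. An asymmetric edge
#' weight `W` from the stimulated regulator models epigenetic reinforcement.
#'
#' @param network `"T2"`, `"T3"` or `"T4"`
#' @param stimulation lineage whose cytokines are supplied: `"Th1"`,
#'   `"Th2"`, `"Th17"` or `"Treg"` (its regulator must be in the
#'   sub-network)
#' @param config a [sim_config()]
#' @param W asymmetric edge weight from the stimulated regulator (default 1)
#' @param W_C per-cytokine signalling strength (default 1)
#' @param overrides optional list keyed by cytokine name of named sign
#'   vectors over sub-network regulators, overriding the
#'   activate-one/inhibit-rest pattern (see [thelper_cytokine_overrides()])
#' @return list with `f1` (frequency of the stimulated single-positive
#'   state), `dist` (the full distribution), `regulator` and `cytokines`
#' @export
run_thelper_cytokines <- function(network = c("T2", "T3", "T4"),
                                  stimulation = c("Th1", "Th2", "Th17",
                                                  "Treg"),
                                  config = sim_config(), W = 1, W_C = 1,
                                  overrides = NULL) {
  network <- match.arg(network)
  stimulation <- match.arg(stimulation)
  size <- as.integer(substr(network, 2, 2))
  regs <- names(.thelper_lineages)[seq_len(size)]
  master <- names(.thelper_lineages)[match(stimulation, .thelper_lineages)]
  if (!master %in% regs)
    stop(stimulation, " stimulation needs ", master, ", absent from ",
         network)
  net <- make_toggle(size, node_names = regs)
  if (W > 1) net <- apply_asymmetric_weight(net, master, W)
  cyts <- .thelper_cytokines[[stimulation]]
  for (cy in cyts) {
    ov <- overrides[[cy]]
    if (!is.null(ov)) ov <- ov[names(ov) %in% regs]
    net <- attach_cytokine(net, master, W_C, mode = "activate_and_inhibit",
                           signs = ov, name = cy)
  }
  dist <- find_steady_states(net, config)
  list(f1 = single_positive_frequency(dist, master), dist = dist,
       regulator = master, cytokines = cyts)
}
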