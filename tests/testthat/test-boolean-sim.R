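test_that("ising_update follows the sign-of-input rule with hold on ties", {
  t2 <- make_toggle(2)
  expect_equal(ising_update(t2, c(A = 1, B = 1), "B"), c(A = 1, B = -1))
  # toggle-3, state (+1,-1,-1): input to A is +2, A stays high
  t3 <- make_toggle(3)
  st <- c(A = 1, B = -1, C = -1)
  expect_equal(ising_update(t3, st, "A"), st)
  # zero input sum holds the current value
  z <- make_toggle(2)
  z$adjacency["B", "A"] <- 0
  expect_equal(ising_update(z, c(A = 1, B = 1), "A")[["A"]], 1)
  expect_error(ising_update(t2, c(A = 1, B = 1), 5), "out of range")
})

test_that("exhaustive enumeration matches the known fixed-point structure", {
  # toggle-4: exactly the six 2-high states
  fp4 <- enumerate_fixed_points(make_toggle(4))
  expect_equal(nrow(fp4), 6)
  expect_true(all(rowSums(fp4 > 0) == 2))
  # toggle-2 with self-activation gains the 0-high and 2-high states
  fp2a <- enumerate_fixed_points(make_toggle(2, "activation"))
  expect_setequal(rowSums(fp2a > 0), c(0, 1, 2))
  expect_equal(nrow(fp2a), 4)
  # full impurity (all activations): only the two uniform states
  allact <- make_toggle(3)
  allact$adjacency[] <- 1
  diag(allact$adjacency) <- 0
  fpa <- enumerate_fixed_points(allact)
  expect_same_states(fpa, rbind(rep(1L, 3), rep(-1L, 3)))
})

test_that("every toggle fixed point has k = n/2 (even) or (n+-1)/2 (odd) for n = 2..8", {
  for (n in 2:8) {
    fp <- enumerate_fixed_points(make_toggle(n))
    ks <- rowSums(fp > 0)
    allowed <- if (n %% 2 == 0) n / 2 else c((n - 1) / 2, (n + 1) / 2)
    expect_true(all(ks %in% allowed), info = paste("n =", n))
    # and all such states are fixed: the count matches the binomials
    expect_equal(nrow(fp), sum(choose(n, allowed)), info = paste("n =", n))
  }
})

test_that("odd-n self-inhibition toggles have no fixed points at all", {
  for (n in c(3, 5)) {
    expect_equal(nrow(enumerate_fixed_points(make_toggle(n, "inhibition"))), 0)
    d <- find_steady_states(make_toggle(n, "inhibition"), quick_config(2))
    expect_equal(unname(d$converged_fraction), rep(0, 2))
    expect_equal(nrow(k_frequencies(d)), n + 1)
    expect_true(all(k_frequencies(d)$F == 0))
  }
})

test_that("simulated steady-state frequencies match the toggle theory", {
  cfg <- sim_config(n_init = 10000, n_replicates = 3, seed = 71)
  d2 <- find_steady_states(make_toggle(2), cfg)
  expect_equal(nrow(d2$states), 2)
  fk2 <- k_frequencies(d2)
  expect_equal(fk2$F[fk2$k == 1], 1, tolerance = 1e-9)
  expect_equal(sort(unname(d2$mean)), c(0.5, 0.5), tolerance = 0.05)

  d5 <- find_steady_states(make_toggle(5), cfg)
  fk5 <- k_frequencies(d5)
  expect_equal(fk5$F[fk5$k == 2], 0.5, tolerance = 0.02)
  expect_equal(fk5$F[fk5$k == 3], 0.5, tolerance = 0.02)
  expect_true(all(d5$converged_fraction == 1))
})

test_that("Monte-Carlo support equals the exhaustive oracle on assorted networks", {
  nets <- list(
    make_toggle(3), make_toggle(4, "activation"), make_toggle(5),
    make_toggle(4, "inhibition"), make_team_network(c(2, 2)),
    make_team_network(c(2, 2, 2)), thelper_network("base"),
    make_impurity_variants(4, 3, max_variants = 2, seed = 2)[[2]],
    embed_in_random(make_toggle(3), embedding_spec(8, 2, 1), seed = 6)[[1]]
  )
  for (net in nets) {
    d <- find_steady_states(net, quick_config(13, n_init = 4000, reps = 1))
    expect_same_states(d$states, enumerate_fixed_points(net))
  }
})

test_that("F(k) is symmetric under k -> n - k for pure toggles", {
  for (n in c(4, 5)) {
    d <- find_steady_states(make_toggle(n), sim_config(10000, seed = 23))
    fk <- k_frequencies(d)
    for (k in 0:n)
      expect_equal(fk$F[fk$k == k], fk$F[fk$k == n - k], tolerance = 0.03)
  }
})

test_that("relabelling the nodes of a toggle leaves the k-distribution unchanged", {
  n <- 4
  net <- make_toggle(n)
  perm <- c(3, 1, 4, 2)
  pnet <- net
  pnet$adjacency <- net$adjacency[perm, perm]
  d1 <- k_frequencies(find_steady_states(net, sim_config(5000, seed = 8)))
  d2 <- k_frequencies(find_steady_states(pnet, sim_config(5000, seed = 8)))
  expect_equal(d1$F, d2$F, tolerance = 0.03)
})

test_that("convergence is complete for pure toggles and improves with step budget", {
  short <- find_steady_states(make_toggle(6), sim_config(2000, max_steps = 3,
                                                         seed = 3))
  long <- find_steady_states(make_toggle(6), sim_config(2000, max_steps = 1000,
                                                        seed = 3))
  expect_lt(mean(short$converged_fraction), mean(long$converged_fraction))
  expect_equal(mean(long$converged_fraction), 1)
})

test_that("state-transition graphs classify stable and meta-stable states", {
  stg2 <- build_state_transition_graph(make_toggle(2))
  fixed <- stg2$states[stg2$stable, , drop = FALSE]
  expect_same_states(fixed, rbind(c(-1, 1), c(1, -1)))
  expect_equal(unname(igraph::degree(stg2$graph, mode = "out")[stg2$stable]),
               c(0, 0))
  # odd self-inhibition: nothing stable, the toggle fixed points become
  # meta-stable (they hold without their self-edges but can escape)
  stg3 <- build_state_transition_graph(make_toggle(3, "inhibition"))
  expect_equal(sum(stg3$stable), 0)
  meta <- stg3$states[stg3$metastable, , drop = FALSE]
  expect_true(all(rowSums(meta > 0) %in% c(1, 2)))
  expect_equal(nrow(meta), 6)
  # even self-inhibition keeps its half-high states stable
  stg4 <- build_state_transition_graph(make_toggle(4, "inhibition"))
  expect_true(all(rowSums(stg4$states[stg4$stable, ] > 0) == 2))
})

test_that("single-bit perturbations relax as the network parity dictates", {
  # toggle-2: flipping B of (+1,-1) returns to (+1,-1) or lands on (-1,+1)
  hp2 <- hamming_perturbation(make_toggle(2), sim_config(200, seed = 31))
  sub <- hp2[hp2$origin == "+-" & hp2$flipped == "B", ]
  expect_setequal(sub$reached, c("+-", "-+"))
  expect_equal(sum(sub$frequency), 1)
  # toggle-4 (even): every flip returns to its origin with the exact mass
  # 1/3 (the origin ties with the two other adjacent half-high states)
  hp4 <- hamming_perturbation(make_toggle(4), sim_config(1000, seed = 31))
  for (key in unique(paste(hp4$origin, hp4$flipped))) {
    sub <- hp4[paste(hp4$origin, hp4$flipped) == key, ]
    expect_equal(sub$frequency[sub$hamming == 0], 1 / 3, tolerance = 0.15)
    expect_true(all(sub$hamming <= 2))
  }
  # toggle-5 (odd): some perturbations settle at Hamming distance 1
  hp5 <- hamming_perturbation(make_toggle(5), sim_config(200, seed = 31))
  expect_true(any(hp5$hamming == 1 & hp5$frequency > 0))
})

test_that("identical seeds reproduce a simulation bit for bit", {
  a <- find_steady_states(make_toggle(5), sim_config(2000, seed = 99))
  b <- find_steady_states(make_toggle(5), sim_config(2000, seed = 99))
  expect_identical(a$freq, b$freq)
  expect_identical(a$states, b$states)
})
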