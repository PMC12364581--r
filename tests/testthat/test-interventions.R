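test_that("randomized edge weights preserve signs and stay in (0, 1) magnitude", {
  sets <- randomize_edge_weights(make_toggle(3), n_sets = 100, seed = 2)
  expect_length(sets, 100)
  base <- make_toggle(3)$adjacency
  for (net in sets[c(1, 50, 100)]) {
    expect_identical(sign(net$adjacency), sign(base))
    nz <- net$adjacency[base != 0]
    expect_true(all(nz > -1 & nz < 0))
  }
  # the same seed reproduces the ensemble
  again <- randomize_edge_weights(make_toggle(3), n_sets = 100, seed = 2)
  expect_identical(sets[[37]]$adjacency, again[[37]]$adjacency)
})

test_that("random weights can stabilize odd self-inhibition networks", {
  # with equal weights the T3 self-inhibition circuit never converges; some
  # random weight sets break the escape routes and stabilize states
  sets <- randomize_edge_weights(make_toggle(3, "inhibition"), 20, seed = 8)
  conv <- vapply(sets, function(net)
    mean(find_steady_states(net, quick_config(3, 500, 1))$converged_fraction),
    numeric(1))
  expect_true(any(conv > 0))
})

test_that("the asymmetric weight is state-dependent and W = 1 is the identity", {
  t5 <- make_toggle(5)
  w1 <- apply_asymmetric_weight(t5, "A", 1)
  cfg <- quick_config(41, 2000, 2)
  expect_identical(find_steady_states(w1, cfg)$freq,
                   find_steady_states(t5, cfg)$freq)
  # update inputs: with A high the inhibition is scaled, with A low it is not
  w5 <- apply_asymmetric_weight(t5, "A", 5)
  hi <- setNames(c(1, 1, -1, -1, -1), t5$nodes)
  expect_equal(ising_update(w5, hi, "B")[["B"]], -1) # -5 + 2 < 0 flips B
  expect_equal(ising_update(t5, hi, "B")[["B"]], 1)  # -1 + 2 > 0 keeps B
  # toggle-2 fixed points are unchanged by any W
  expect_same_states(
    enumerate_fixed_points(apply_asymmetric_weight(make_toggle(2), "A", 5)),
    enumerate_fixed_points(make_toggle(2)))
  expect_error(apply_asymmetric_weight(t5, "A", 0.5), ">= 1")
})

test_that("asymmetric weight alone saturates F_A(1) at one half", {
  net <- apply_asymmetric_weight(make_toggle(5), "A", 10)
  d <- find_steady_states(net, sim_config(10000, seed = 51))
  expect_equal(single_positive_frequency(d, "A"), 0.5, tolerance = 0.02)
  expect_lt(single_positive_frequency(d, "A") + 0.05, 1)
})

test_that("cytokine attachment is wired per mode and W_C = 0 is inert", {
  t4 <- make_toggle(4)
  act <- attach_cytokine(t4, "A", 3, "activate_only")
  expect_equal(unname(act$roles["Cyt_A"]), "cytokine")
  expect_equal(unname(act$adjacency["Cyt_A", ]), c(3, 0, 0, 0, 0))
  expect_true(all(act$adjacency[, "Cyt_A"] == 0))
  both <- attach_cytokine(t4, "A", 2, "activate_and_inhibit")
  expect_equal(unname(both$adjacency["Cyt_A", ]), c(2, -2, -2, -2, 0))
  expect_error(attach_cytokine(act, "A", 1), "already exists")
  # zero strength leaves the trajectories identical under shared seeds
  cfg <- quick_config(43, 2000, 2)
  base <- find_steady_states(t4, cfg)
  inert <- find_steady_states(attach_cytokine(t4, "A", 0, "activate_only"),
                              cfg)
  kb <- apply(base$states, 1, paste, collapse = ",")
  ki <- apply(inert$states[, t4$nodes, drop = FALSE], 1, paste, collapse = ",")
  expect_setequal(kb, ki)
  expect_identical(unname(base$freq[order(kb), , drop = FALSE]),
                   unname(inert$freq[order(ki), , drop = FALSE]))
})

test_that("an activating-only cytokine cannot raise F_A(1) at baseline weights", {
  t5 <- make_toggle(5)
  cfg <- sim_config(5000, seed = 47)
  base <- single_positive_frequency(find_steady_states(t5, cfg), "A")
  for (wc in c(2, 6, 10)) {
    d <- find_steady_states(attach_cytokine(t5, "A", wc, "activate_only"), cfg)
    expect_lte(single_positive_frequency(d, "A"), base + 0.03)
  }
})

test_that("threshold scans recover the toggle-3 thresholds", {
  s <- threshold_scan(make_toggle(3), "A", "activate_only",
                      w_range = 1:4, wc_range = 0:4,
                      config = sim_config(3000, n_replicates = 1, seed = 53))
  expect_equal(s$thresholds$W, 2)
  expect_equal(s$thresholds$W_C, 3)
  expect_true(all(s$grid$FA1 >= 0 & s$grid$FA1 <= 1))
})

test_that("stronger edge weights compensate for weaker signalling", {
  cfg <- sim_config(3000, n_replicates = 1, seed = 59)
  g <- threshold_scan(make_toggle(6), "A", "activate_and_inhibit",
                      w_range = c(1, 4), wc_range = 0:6, config = cfg)$grid
  min_wc <- vapply(c(1, 4), function(W) {
    h <- g$W == W & g$FA1 >= 1 - 1e-6
    if (any(h)) min(g$W_C[h]) else NA_real_
  }, numeric(1))
  expect_true(all(!is.na(min_wc)))
  expect_lt(min_wc[2], min_wc[1])
})
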