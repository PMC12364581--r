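test_that("make_toggle builds the stated adjacency patterns", {
  expect_identical(unname(make_toggle(2)$adjacency),
                   matrix(c(0, -1, -1, 0), 2, 2))
  t3a <- make_toggle(3, "activation")$adjacency
  expect_true(all(diag(t3a) == 1) && all(t3a[row(t3a) != col(t3a)] == -1))
  expect_true(all(make_toggle(4, "inhibition")$adjacency == -1))
  expect_error(make_toggle(1), "at least 2")
})

test_that("toggle networks are invariant under node permutation", {
  for (n in c(3, 5)) {
    adj <- make_toggle(n)$adjacency
    p <- sample(n)
    expect_identical(unname(adj[p, p]), unname(adj))
  }
})

test_that("impurity variants are non-isomorphic and respect the caps", {
  # no choice at the extremes
  expect_length(make_impurity_variants(3, 0), 1)
  expect_length(make_impurity_variants(3, 6), 1)
  expect_true(all(make_impurity_variants(3, 6)[[1]]$adjacency[
    row(diag(3)) != col(diag(3))] == 1))
  # all single-flip toggle triads are isomorphic: exactly one class
  v <- make_impurity_variants(3, 1)
  expect_length(v, 1)
  expect_equal(sum(v[[1]]$adjacency == 1), 1)
  # mid-level impurity on the triad: flips of 3 of 6 edges
  v3 <- make_impurity_variants(3, 3)
  expect_true(all(vapply(v3, function(net)
    sum(net$adjacency == 1), numeric(1)) == 3))
  expect_lte(length(v3), 100)
  # pairwise non-isomorphism on the activation digraph
  gs <- lapply(v3, function(net)
    igraph::graph_from_adjacency_matrix((net$adjacency > 0) * 1L, "directed"))
  for (i in seq_along(gs)) for (j in seq_len(i - 1))
    expect_false(igraph::isomorphic(gs[[i]], gs[[j]], method = "vf2"))
  expect_error(make_impurity_variants(7, 1), "n > 6")
  expect_error(make_impurity_variants(3, 7), "between 0 and")
})

test_that("sampled impurity combinations also yield valid variant sets", {
  v <- make_impurity_variants(5, 10, max_variants = 8, seed = 3,
                              enum_limit = 100)
  expect_lte(length(v), 8)
  expect_gt(length(v), 1)
  expect_true(all(vapply(v, function(net)
    sum(net$adjacency == 1), numeric(1)) == 10))
})

test_that("team networks have intra-team activation and inter-team inhibition", {
  tm <- make_team_network(c(2, 2))
  a <- tm$adjacency
  expect_identical(unname(a[1:2, 1:2]), matrix(c(0, 1, 1, 0), 2, 2))
  expect_true(all(a[1:2, 3:4] == -1) && all(a[3:4, 1:2] == -1))
  expect_identical(unname(tm$teams), c("T1", "T1", "T2", "T2"))
  # teams of size one reduce exactly to the toggle
  t1 <- make_team_network(rep(1, 4))
  expect_identical(unname(t1$adjacency), unname(make_toggle(4)$adjacency))
  expect_warning(make_team_network(3), "single team")
})

test_that("unequal team splits obey the rejection constraints", {
  specs <- sample_unequal_teams(5, 2, 50, seed = 11)
  for (sp in specs) {
    expect_equal(sum(sp$sizes), 10)
    expect_true(all(sp$sizes >= 1))
    expect_true(all(sp$sizes != 2))
  }
  # with 2 teams of mean 2 only the splits (1,3) and (3,1) are feasible
  many <- sample_unequal_teams(2, 2, 200, seed = 5)
  seen <- unique(vapply(many, function(s) paste(s$sizes, collapse = ","),
                        character(1)))
  expect_setequal(seen, c("1,3", "3,1"))
  # total 2 with both constraints is infeasible
  expect_error(sample_unequal_teams(2, 1, 1, seed = 1), "unsatisfiable|constraints")
})

test_that("embedding preserves the core and builds the requested host", {
  t4 <- make_toggle(4)
  nets <- embed_in_random(t4, embedding_spec(10, 2, 5), seed = 9)
  expect_length(nets, 5)
  for (net in nets) {
    expect_equal(length(net$nodes), 14)
    expect_identical(net$adjacency[1:4, 1:4], t4$adjacency)
    expect_identical(unname(net$roles), c(rep("core", 4), rep("embedding", 10)))
    host <- net$adjacency[5:14, 5:14]
    expect_equal(sum(host != 0), 20)           # size * density edges
    expect_true(all(diag(host) == 0))          # no self-loops
    expect_true(all(host %in% c(-1, 0, 1)))
    cross <- c(net$adjacency[1:4, 5:14], net$adjacency[5:14, 1:4])
    expect_length(cross, 2 * 4 * 10)
    expect_true(all(cross %in% c(-1, 0, 1)))
  }
  # two replicates from one seed differ; same seed reproduces
  again <- embed_in_random(t4, embedding_spec(10, 2, 5), seed = 9)
  expect_identical(nets[[2]]$adjacency, again[[2]]$adjacency)
  expect_false(identical(nets[[1]]$adjacency, nets[[2]]$adjacency))
  expect_error(embedding_spec(4, 5, 1), "at most")
})

test_that("network batches persist through topo plus sidecar", {
  dir <- withr::local_tempdir()
  nets <- list(make_toggle(3), randomize_edge_weights(make_toggle(3), 1, 4)[[1]])
  idx <- write_network_batch(nets, dir, prefix = "tgl", family = "toggle")
  tab <- read.csv(idx)
  expect_equal(nrow(tab), 2)
  back <- read_topo(file.path(dir, tab$topo[1]))
  expect_identical(back$adjacency, nets[[1]]$adjacency)
  back2 <- read_topo(file.path(dir, tab$topo[2]),
                     weights = file.path(dir, tab$weights[2]))
  expect_equal(back2$adjacency, nets[[2]]$adjacency)
})
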