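test_that("supra-adjacency construction yields the designed blocks and null", {
  layers <- random_layers(4, 3, seed = 30)
  net <- build_supra(layers, omega = 0.7, gamma = 1)
  b <- triplenet:::modularity_matrix(net)
  # coupling entries only between same node in adjacent layers
  expect_equal(b[1, 5], 0.7)            # node 1, layers 1-2
  expect_equal(b[5, 9], 0.7)            # node 1, layers 2-3
  expect_equal(b[1, 9], 0)              # layers 1-3 not adjacent
  expect_equal(b[1, 6], 0)              # different nodes across layers

  # Newman-Girvan null per layer sums to the layer's total weight
  for (l in 1:3) {
    a <- net$intra[[l]]
    expect_equal(sum(net$null[[l]]), sum(a))
    expect_equal(net$null[[l]], t(net$null[[l]]))
  }
  # mu = sum of layer strengths + total coupling weight
  expect_equal(net$mu, sum(vapply(net$intra, sum, 0)) / 2 + 0.7 * 4 * 2)

  net0 <- build_supra(layers, omega = 0)
  b0 <- triplenet:::modularity_matrix(net0)
  off <- b0
  for (l in 1:3) off[(l - 1) * 4 + 1:4, (l - 1) * 4 + 1:4] <- 0
  expect_equal(max(abs(off)), 0)        # block diagonal when omega = 0

  two <- build_supra(random_layers(2, 2, seed = 31), omega = 1)
  b2 <- triplenet:::modularity_matrix(two)
  expect_equal(sum(b2[1:2, 3:4] != 0), 2)  # exactly 2 coupling edges

  zero_layer <- list(matrix(0, 3, 3), random_layers(3, 1, seed = 1)[[1]])
  expect_error(build_supra(zero_layer), "layer 1")
})

test_that("negative-weight policies transform signed connectivity as documented", {
  m <- matrix(c(0, -0.5, 0.2, -0.5, 0, 0.4, 0.2, 0.4, 0), 3, 3)
  net_clip <- build_supra(list(m, m), negative_policy = "clip_zero")
  expect_equal(net_clip$intra[[1]][1, 2], 0)
  net_abs <- build_supra(list(m, m), negative_policy = "absolute")
  expect_equal(net_abs$intra[[1]][1, 2], 0.5)
})

test_that("modularity matches the analytic toy values", {
  net1 <- build_supra(list(two_triangles()), omega = 0, gamma = 1)
  expect_equal(modularity_Q(net1, matrix(1, 6, 1)), 0, tolerance = 1e-12)
  expect_equal(modularity_Q(net1, matrix(c(1, 1, 1, 2, 2, 2), 6, 1)), 0.5,
               tolerance = 1e-12)
  expect_error(modularity_Q(net1, matrix(1, 5, 1)), "partition")
})

test_that("structured modularity equals the naive double-loop on random instances", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(2:4, 1)
    w <- sample(1:3, 1)
    net <- build_supra(random_layers(n, w, seed = 100 + s),
                       omega = runif(1, 0, 2), gamma = runif(1, 0.5, 1.5))
    part <- matrix(sample.int(3, n * w, replace = TRUE), n, w)
    expect_equal(modularity_Q(net, part), naive_modularity_Q(net, part),
                 tolerance = 1e-12)
  }
})

test_that("the optimizer finds the known optima of the toys", {
  net1 <- build_supra(list(two_triangles()), omega = 0, gamma = 1)
  res <- genlouvain_optimize(net1, seed = 4)
  expect_equal(res$Q, 0.5, tolerance = 1e-12)
  expect_equal(res$Q, brute_force_optimum(net1), tolerance = 1e-12)
  expect_length(unique(as.vector(res$partition)), 2)
  expect_equal(res$Q, modularity_Q(net1, res$partition))

  cmpl <- matrix(1, 5, 5); diag(cmpl) <- 0
  netc <- build_supra(list(cmpl), omega = 0)
  resc <- genlouvain_optimize(netc, seed = 4)
  expect_length(unique(as.vector(resc$partition)), 1)
  expect_equal(resc$Q, 0, tolerance = 1e-12)
})

test_that("best-of-20-seeds matches exhaustive search on a 3x3 multilayer instance", {
  net <- build_supra(random_layers(3, 3, seed = 9), omega = 1)
  best_louvain <- max(vapply(1:20, function(s)
    genlouvain_optimize(net, seed = s)$Q, numeric(1)))
  expect_equal(best_louvain, brute_force_optimum(net), tolerance = 1e-10)
})

test_that("Q and allegiance are invariant to community relabeling", {
  net <- build_supra(random_layers(3, 2, seed = 40), omega = 0.5)
  part <- matrix(c(1, 1, 2, 2, 1, 3), 3, 2)
  relab <- matrix(c(7, 7, 5, 5, 7, 9), 3, 2)
  expect_equal(modularity_Q(net, part), modularity_Q(net, relab))
  mp1 <- structure(list(partition = part, Q = 0, seed = 1L),
                   class = "multilayer_partition")
  mp2 <- structure(list(partition = relab, Q = 0, seed = 1L),
                   class = "multilayer_partition")
  expect_equal(module_allegiance(mp1), module_allegiance(mp2))
})

test_that("with zero coupling the layers decouple", {
  layers <- random_layers(4, 2, seed = 41)
  net0 <- build_supra(layers, omega = 0)
  res <- genlouvain_optimize(net0, seed = 2)
  # per-layer independent optimization attains the same total quality
  per_layer_q <- vapply(1:2, function(l) {
    nl <- build_supra(layers[l], omega = 0)
    genlouvain_optimize(nl, seed = 2)$Q * 2 * nl$mu
  }, numeric(1))
  expect_equal(res$Q, sum(per_layer_q) / (2 * net0$mu), tolerance = 1e-10)
})

test_that("ensembles are deterministic and consistent on a toy with a unique optimum", {
  net <- build_supra(list(two_triangles(), two_triangles()), omega = 0.1)
  ens1 <- run_ensemble(net, n_runs = 10, base_seed = 3)
  ens2 <- run_ensemble(net, n_runs = 10, base_seed = 3)
  expect_identical(ens1, ens2)
  # all runs agree up to relabeling: co-assignment matrices identical
  coassign <- lapply(ens1$partitions, function(g)
    outer(g[, 1], g[, 1], "==") & outer(g[, 2], g[, 2], "=="))
  for (i in 2:10) expect_identical(coassign[[i]], coassign[[1]])

  single <- run_ensemble(net, n_runs = 1, base_seed = 5)
  expect_equal(mean(single$Q_values), single$Q_values[1])
})

test_that("module allegiance counts co-assignment frequencies", {
  g_all <- matrix(1, 4, 3)
  mp <- structure(list(partition = g_all, Q = 0, seed = 1L),
                  class = "multilayer_partition")
  expect_equal(module_allegiance(mp), matrix(1, 4, 4), ignore_attr = TRUE)

  g_split <- matrix(c(1, 1, 2, 2), 4, 3)
  mp2 <- structure(list(partition = g_split, Q = 0, seed = 1L),
                   class = "multilayer_partition")
  p2 <- module_allegiance(mp2)
  expect_equal(unname(p2), rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                                 c(0, 0, 1, 1), c(0, 0, 1, 1)))

  # together in exactly one of two layers -> 0.5
  g_half <- cbind(c(1, 1), c(1, 2))
  mp3 <- structure(list(partition = g_half, Q = 0, seed = 1L),
                   class = "multilayer_partition")
  expect_equal(module_allegiance(mp3)[1, 2], 0.5)
})

test_that("integration summaries match hand-computed means", {
  membership <- c(a1 = "X", a2 = "X", b1 = "Y", b2 = "Y")
  ones <- matrix(1, 4, 4, dimnames = list(names(membership), names(membership)))
  int1 <- integration(ones, membership)
  expect_equal(unname(int1$node_integration), rep(1, 4))
  expect_equal(unname(int1$rsn_integration), c(1, 1))
  expect_equal(unname(int1$rsn_pair_integration), 1)

  blockdiag <- ones
  blockdiag[1:2, 3:4] <- 0; blockdiag[3:4, 1:2] <- 0
  int0 <- integration(blockdiag, membership)
  expect_equal(unname(int0$node_integration), rep(0, 4))

  # printed 4x4 fixture, means computed by hand:
  #      a1    a2    b1    b2
  # a1  1.0   0.8   0.4   0.2
  # a2  0.8   1.0   0.6   0.0
  # b1  0.4   0.6   1.0   0.9
  # b2  0.2   0.0   0.9   1.0
  p <- matrix(c(1, .8, .4, .2,
                .8, 1, .6, 0,
                .4, .6, 1, .9,
                .2, 0, .9, 1), 4, 4, byrow = TRUE,
              dimnames = list(names(membership), names(membership)))
  s <- integration(p, membership, Q = 0.25)
  expect_equal(unname(s$node_integration), c(0.3, 0.3, 0.5, 0.1))
  expect_equal(unname(s$rsn_integration), c(0.3, 0.3))
  expect_equal(unname(s$rsn_pair_integration), 0.3)
  expect_equal(s$modularity_Q, 0.25)

  expect_error(integration(p, c(a1 = "X", a2 = "X")), "cover")
})

test_that("cross-network mixing raises pair integration over segregated dynamics", {
  # two networks of two nodes; segregated layers keep within-network blocks,
  # mixed layers couple one node of each network instead
  seg_layer <- matrix(0, 4, 4); seg_layer[1, 2] <- seg_layer[3, 4] <- 1
  seg_layer <- seg_layer + t(seg_layer)
  mix_layer <- matrix(0, 4, 4); mix_layer[1, 3] <- mix_layer[2, 4] <- 1
  mix_layer <- mix_layer + t(mix_layer)
  dimnames(seg_layer) <- dimnames(mix_layer) <-
    list(c("a1", "a2", "b1", "b2"), c("a1", "a2", "b1", "b2"))
  membership <- c(a1 = "X", a2 = "X", b1 = "Y", b2 = "Y")
  pair_int <- function(layers, seed) {
    net <- build_supra(layers, omega = 0.1)
    ens <- run_ensemble(net, n_runs = 5, base_seed = seed)
    integration(module_allegiance(ens), membership)$rsn_pair_integration[[1]]
  }
  diffs <- vapply(1:20, function(s) {
    pair_int(list(mix_layer, mix_layer, mix_layer), s) -
      pair_int(list(seg_layer, seg_layer, seg_layer), s)
  }, numeric(1))
  expect_true(all(diffs > 0))
})
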