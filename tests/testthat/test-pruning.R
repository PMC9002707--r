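bank <- build_pattern_bank()
pat <- function(k) bank[, , k]

# filters whose every input-channel slice is a positive multiple of one
# binary pattern; distinct patterns guarantee distinct clusters
pattern_filters <- function(patterns, n_channels = 1, scale = NULL) {
  n <- length(patterns)
  w <- array(0, c(n, n_channels, 3, 3))
  for (i in seq_len(n)) for (c in seq_len(n_channels))
    w[i, c, , ] <- (if (is.null(scale)) runif(1, 0.5, 2) else scale) *
      pat(patterns[i])
  w
}

test_that("the pattern bank is a bijection with the nonzero 9-bit integers", {
  expect_equal(dim(bank), c(3, 3, 511))
  codes <- apply(bank, 3, function(p) {
    bits <- as.vector(t(p))             # row-major cells -> bits 0..8
    sum(bits * 2^(0:8))
  })
  expect_equal(sort(codes), 1:511)      # all distinct, zero absent
  expect_true(any(apply(bank, 3, function(p) all(p == 1))))
  expect_false(any(apply(bank, 3, function(p) all(p == 0))))
})

test_that("filter scores are pattern inner products and scale linearly", {
  p <- pat(273)  # diagonal-ish pattern
  f <- array(0, c(1, 3, 3)); f[1, , ] <- p
  expect_equal(score_filter(f, p), sum(p))
  # a filter equal to a pattern scores its popcount, maximal over the bank
  scores <- apply(bank, 3, function(q) score_filter(f, q))
  expect_equal(max(scores), sum(p))
  expect_equal(which.max(scores), 273L)  # supersets have larger indices
  z <- array(0, c(2, 3, 3))
  expect_true(all(apply(bank, 3, function(q) score_filter(z, q)) == 0))
  g <- array(rnorm(2 * 9), c(2, 3, 3))
  q <- pat(77)
  expect_equal(score_filter(g * 2, q), 2 * score_filter(g, q))
  expect_error(score_filter(matrix(0, 2, 2), q), "3x3")
})

test_that("identical filters collapse to one cluster; distinct patterns all survive", {
  set.seed(31)
  w <- array(0, c(5, 2, 3, 3))                    # 5 identical filters
  base <- array(rnorm(2 * 9), c(2, 3, 3))
  for (i in 1:5) w[i, , , ] <- base
  rep_ <- cluster_layer(w, bank)
  expect_length(unique(rep_$assignment), 1)
  expect_length(rep_$kept_filters, 1)

  ks <- c(7, 56, 273, 448)
  w2 <- pattern_filters(ks, n_channels = 3)
  rep2 <- cluster_layer(w2, bank)
  expect_equal(rep2$assignment, ks)
  expect_equal(rep2$kept_filters, 1:4)

  # pigeonhole: never more clusters than min(filters, 511)
  set.seed(32)
  w3 <- array(rnorm(40 * 2 * 9), c(40, 2, 3, 3))
  expect_lte(length(cluster_layer(w3, bank)$kept_filters), 40)
})

test_that("cluster assignment is permutation-equivariant", {
  set.seed(33)
  w <- array(rnorm(8 * 2 * 9), c(8, 2, 3, 3))
  rep_ <- cluster_layer(w, bank)
  perm <- sample(8)
  rep_p <- cluster_layer(w[perm, , , , drop = FALSE], bank)
  expect_equal(rep_p$assignment, rep_$assignment[perm])
  # representatives map to the same physical filters
  phys <- sort(perm[rep_p$kept_filters])
  expect_equal(phys, sort(rep_$kept_filters))
})

test_that("pruning a duplicate filter removes the matching input channel downstream", {
  set.seed(34)
  g <- layer_graph(list(conv_layer(0, 4, 3, 1), conv_layer(1, 3, 3, 1)),
                   input_shape = c(8L, 8L, 1L))
  w0 <- pattern_filters(c(7, 7, 56, 273), scale = 2)  # filters 1,2 identical
  b0 <- rnorm(4)
  w1 <- array(rnorm(3 * 4 * 9), c(3, 4, 3, 3)); b1 <- rnorm(3)
  pr <- prune_network(g, list("0" = list(w = w0, b = b0),
                              "1" = list(w = w1, b = b1)))
  expect_equal(pr$channel_maps[[1]], c(1L, 3L, 4L))
  expect_equal(dim(pr$weights[["1"]]$w), c(3, 3, 3, 3))
  expect_equal(pr$graph$layers[[1]]$filters, 3)

  # forward-pass equivalence up to the removed duplicate: the pruned net
  # equals the original net restricted to surviving channels
  input <- matrix(rnorm(64), 8, 8)
  full0 <- oracle_conv_forward(list(input), w0, b0)
  pruned0 <- oracle_conv_forward(list(input), pr$weights[["0"]]$w,
                                 pr$weights[["0"]]$b)
  for (k in 1:3)
    expect_equal(pruned0[[k]], full0[[pr$channel_maps[[1]][k]]],
                 tolerance = 1e-12)
  restricted1 <- oracle_conv_forward(full0[pr$channel_maps[[1]]],
                                     w1[, pr$channel_maps[[1]], , ,
                                        drop = FALSE], b1)
  pruned1 <- oracle_conv_forward(pruned0, pr$weights[["1"]]$w,
                                 pr$weights[["1"]]$b)
  for (k in 1:3) expect_equal(pruned1[[k]], restricted1[[k]],
                              tolerance = 1e-12)
  # pruned graph still propagates cleanly
  sh <- propagate_shapes(pr$graph)
  expect_false(any(sh$mismatch))
  expect_equal(sh$c, c(3, 3))
})

test_that("pruning is identity on duplicate-free layers and idempotent", {
  set.seed(35)
  g <- layer_graph(list(conv_layer(0, 4, 3, 1), conv_layer(1, 3, 3, 1)),
                   input_shape = c(8L, 8L, 1L))
  wl <- list("0" = list(w = pattern_filters(c(3, 12, 48, 200))),
             "1" = list(w = pattern_filters(c(9, 130, 500), n_channels = 4)))
  pr <- prune_network(g, wl)
  expect_equal(pr$weights[["0"]]$w, wl[["0"]]$w)
  expect_equal(pr$weights[["1"]]$w, wl[["1"]]$w)
  # with a duplicate present, a second pass removes nothing more
  wl2 <- wl
  wl2[["0"]]$w[4, , , ] <- wl2[["0"]]$w[3, , , ]
  p1 <- prune_network(g, wl2)
  p2 <- prune_network(p1$graph, p1$weights)
  expect_equal(lapply(p2$weights, `[[`, "w"), lapply(p1$weights, `[[`, "w"))
})

test_that("split routes keep only surviving channels of the routed half", {
  set.seed(36)
  g <- layer_graph(list(conv_layer(0, 5, 3, 1),
                        route_layer(1, 0, split = TRUE),
                        conv_layer(2, 3, 3, 1)),
                   input_shape = c(8L, 8L, 1L))
  # the split half is filters 4:5; make them duplicates
  w0 <- pattern_filters(c(3, 12, 48, 200, 200), scale = 2)
  w2 <- array(rnorm(3 * 2 * 9), c(3, 2, 3, 3))
  pr <- prune_network(g, list("0" = list(w = w0), "2" = list(w = w2)))
  expect_equal(pr$channel_maps[[1]], 1:4)        # filter 5 pruned
  expect_equal(pr$channel_maps[[2]], 1L)         # only channel 4 survives
  expect_equal(dim(pr$weights[["2"]]$w)[2], 1)
  p2 <- prune_network(pr$graph, pr$weights)
  expect_equal(p2$weights[["2"]]$w, pr$weights[["2"]]$w)
})

test_that("pruning the full hallway network preserves a valid graph", {
  set.seed(37)
  g <- hallway_net_graph()
  # random weights for every conv layer at the declared sizes
  shapes <- propagate_shapes(g)
  weights <- list()
  for (i in seq_along(g$layers)) {
    ly <- g$layers[[i]]
    if (ly$type != "conv") next
    cin <- if (i == 1) g$input_shape[3] else shapes$c[i - 1]
    weights[[as.character(ly$id)]] <-
      list(w = array(rnorm(ly$filters * cin * ly$size^2),
                     c(ly$filters, cin, ly$size, ly$size)))
  }
  pr <- prune_network(g, weights)
  sh <- propagate_shapes(pr$graph)
  expect_false(any(vapply(pr$channel_maps, length, 1L) == 0))
  # pruned channel counts consistent with the pruned weight tensors
  for (id in names(pr$reports)) {
    i <- as.integer(id) + 1L
    expect_equal(dim(pr$weights[[id]]$w)[1], pr$graph$layers[[i]]$filters)
  }
})
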