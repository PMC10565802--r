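test_that("snn_grad3d defaults to the winning class and keeps the input shape", {
  net <- tiny_dense_net(seed = 6)
  inp <- random_spike_tensor(c(1, 2, 2, 6), p = 0.5, seed = 2)
  winner <- class_scores(simulate_forward(net, inp))$winner
  m <- snn_grad3d(net, inp)
  expect_equal(attr(m, "target_class"), winner)
  expect_equal(dim(m), dim(inp))
  expect_identical(unclass(unname(m))[seq_along(m)],
                   input_gradient(net, inp, winner)[seq_along(m)])
})

test_that("integrated gradients degenerate to the plain gradient", {
  net <- build_network(toy_network_spec(), seed = 1)
  enc <- encoder_config("poisson", n_timesteps = 12L, seed = 4L)
  img <- make_toy_images(toy_dataset_config(seed = 2,
                                            n_samples_per_class = 1))$image[[1]]
  g <- snn_grad3d(net, encode_image(img, enc))
  # n = 1: the image path is just the input itself
  ig1 <- snn_ig2d(net, img, enc, ig_path_config(n_steps = 1))
  expect_equal(as.numeric(ig1), as.numeric(g), tolerance = 1e-12)
  # baseline = input: every path image equals the input
  igb <- snn_ig2d(net, img, enc, ig_path_config(n_steps = 4, baseline = img))
  expect_equal(as.numeric(igb), as.numeric(g), tolerance = 1e-12)
  # 3D path with one step is the full event stream
  st <- encode_image(img, enc)
  for (h in c("stride", "prefix")) {
    ig3 <- snn_ig3d(net, st, ig_path_config(n_steps = 1,
                                            sampling_heuristic = h))
    expect_equal(as.numeric(ig3), as.numeric(g), tolerance = 1e-12)
  }
  expect_error(snn_ig3d(net, st, ig_path_config(n_steps = 999)), "exceed")
})

test_that("the stride sampling rule enumerates the frozen timestep sets", {
  # T = 8, n = 4: brute-force enumeration of evenly spaced subsets
  expected <- list(c(0, 4), c(0, 2, 4, 6), c(0, 1, 2, 4, 5, 6), 0:7)
  for (k in 1:4) {
    expect_equal(snnxattr:::ig3d_kept_timesteps(8, k, 4, "stride") - 1,
                 expected[[k]])
  }
  # prefix keeps the leading ceil(T k / n) steps; step n is the full input
  expect_equal(snnxattr:::ig3d_kept_timesteps(8, 3, 4, "prefix"), 1:6)
  expect_equal(snnxattr:::ig3d_kept_timesteps(8, 4, 4, "prefix"), 1:8)
})

test_that("near-constant surrogate slope makes IG and Grad agree (linear case)", {
  # with a flat surrogate and subtract reset, backprop becomes input
  # independent, so the path average of gradients collapses onto the
  # endpoint gradient
  spec <- network_spec(list(
    layer_dense(3, neuron_params(threshold = 1, leak_factor = 1,
                                 surrogate_sharpness = 1e-5))
  ), input_shape = c(1, 2, 2), n_classes = 3)
  net <- build_network(spec, seed = 2)
  inp <- random_spike_tensor(c(1, 2, 2, 10), p = 0.5, seed = 3)
  g <- snn_grad3d(net, inp, target_class = 1)
  ig <- snn_ig3d(net, inp, ig_path_config(n_steps = 5))
  # same target: force it
  ig_t <- input_gradient(net, inp, 1)
  acc <- 0
  for (k in 1:5) {
    kept <- snnxattr:::ig3d_kept_timesteps(10, k, 5, "stride")
    step <- array(0, dim = dim(inp)); step[, , , kept] <- inp[, , , kept]
    acc <- acc + input_gradient(net, spike_tensor(step), 1)
  }
  expect_equal(as.numeric(acc / 5), as.numeric(g), tolerance = 1e-2)
})

test_that("SAM traces decay exponentially and ISAM is its exact negation", {
  net <- tiny_conv_net(seed = 2, size = 6)
  inp <- random_spike_tensor(c(1, 6, 6, 8), p = 0.3, seed = 7)
  m <- sam(net, inp, layer_index = 1, gamma = 1)
  expect_true(all(m >= 0))                       # sums of exponentials
  mi <- isam(net, inp, layer_index = 1, gamma = 1)
  expect_identical(as.numeric(mi), -as.numeric(m))
  # silence in, zeros out
  for (li in seq_along(net$layers)) net$layers[[li]]$weights[] <- 0
  expect_true(all(sam(net, inp, 1, 1) == 0))
  expect_true(all(isam(net, inp, 1, 1) == 0))
  # restricted to convolutional layers
  expect_error(sam(net, inp, layer_index = 3, gamma = 1), "convolutional")
  expect_error(sam(net, inp, layer_index = 1, gamma = 0), "gamma")
})

test_that("a single spike leaves the closed-form trace exp(-(t - t')/gamma)", {
  # one conv neuron chain arranged so layer 1 spikes exactly once at t = 0
  spec <- network_spec(list(
    layer_conv(1, kernel = 1, stride = 1, pad = 0,
               params = neuron_params(threshold = 0.6, leak_factor = 1)),
    layer_dense(1, neuron_params())
  ), input_shape = c(1, 1, 1), n_classes = 1)
  net <- build_network(spec, seed = 1)
  net$layers[[1]]$weights[] <- 1
  inp <- spike_tensor(array(c(1, 0, 0, 0), dim = c(1, 1, 1, 4)))
  m <- sam(net, inp, 1, gamma = 1)
  expect_equal(m[1, 1, 1, ], c(0, exp(-1), exp(-2), exp(-3)),
               tolerance = 1e-12)
})

test_that("ISAM ranks features in exactly the reverse order of SAM", {
  net <- tiny_conv_net(seed = 4, size = 6)
  inp <- random_spike_tensor(c(1, 6, 6, 8), p = 0.4, seed = 9)
  m <- sam(net, inp, 1, 1)
  mi <- isam(net, inp, 1, 1)
  r <- rank_features(m, mode = "signed")
  ri <- rank_features(mi, mode = "signed")
  # compare by score groups to be robust to ties
  expect_equal(r$score[order(r$idx)], -ri$score[order(ri$idx)])
  expect_equal(sort(unique(r$score)), sort(-unique(ri$score)))
  # the top-scoring SAM cells are the bottom-scoring ISAM cells
  k <- 10
  top_sam <- r$idx[seq_len(k)]
  bottom_isam <- ri$idx[(nrow(ri) - k + 1):nrow(ri)]
  expect_equal(sort(abs(m[top_sam])), sort(abs(mi[bottom_isam])))
})

test_that("bilinear upscaling preserves grid values and constants", {
  src <- attribution_map2d(matrix(c(1, 3, 2, 8), 2, 2))
  expect_equal(as.matrix(upscale_layer_map(src, c(2, 2))), as.matrix(src))
  up <- upscale_layer_map(src, c(4, 4))
  expect_equal(dim(up), c(4, 4))
  # corners preserved
  expect_equal(up[1, 1], src[1, 1]); expect_equal(up[4, 4], src[2, 2])
  expect_equal(up[1, 4], src[1, 2]); expect_equal(up[4, 1], src[2, 1])
  # interior follows the bilinear formula: midpoint of row 1 at x = 2 is
  # 1 + (1/3) * (2 - 1)
  expect_equal(up[1, 2], src[1, 1] + (src[1, 2] - src[1, 1]) / 3,
               tolerance = 1e-12)
  cons <- attribution_map2d(matrix(7, 2, 2))
  expect_true(all(upscale_layer_map(cons, c(5, 5)) == 7))
  expect_error(upscale_layer_map(src, c(1, 1)), "at least")
})

test_that("time collapse conserves mass, is linear, and max picks maxima", {
  set.seed(13)
  arr <- array(rnorm(2 * 3 * 3 * 4), dim = c(2, 3, 3, 4))
  m <- attribution_map3d(arr)
  s <- collapse_time(m, "sum")
  expect_equal(sum(s), sum(arr), tolerance = 1e-12)
  expect_equal(as.matrix(collapse_time(m, "max")),
               apply(arr, c(2, 3), max))
  expect_equal(as.matrix(collapse_time(m, "avg")),
               apply(arr, c(2, 3), mean))
  # T = 1, single channel: the 2D map is the 3D slice
  one <- attribution_map3d(array(1:9, dim = c(1, 3, 3, 1)))
  expect_equal(as.numeric(collapse_time(one, "sum")), as.numeric(1:9))
  # linearity of the sum collapse
  arr2 <- array(rnorm(2 * 3 * 3 * 4), dim = c(2, 3, 3, 4))
  lhs <- collapse_time(attribution_map3d(2 * arr - 3 * arr2), "sum")
  rhs <- 2 * as.matrix(collapse_time(m, "sum")) -
    3 * as.matrix(collapse_time(attribution_map3d(arr2), "sum"))
  expect_equal(as.matrix(lhs), rhs, tolerance = 1e-12)
})

test_that("IG completeness scaling multiplies the collapsed map by the delta", {
  net <- build_network(toy_network_spec(), seed = 1)
  enc <- encoder_config("poisson", n_timesteps = 10L, seed = 4L)
  img <- make_toy_images(toy_dataset_config(seed = 2,
                                            n_samples_per_class = 1))$image[[1]]
  plain <- snn_ig2d(net, img, enc, ig_path_config(n_steps = 2))
  scaled <- snn_ig2d(net, img, enc,
                     ig_path_config(n_steps = 2, scale_by_input_delta = TRUE))
  c_plain <- collapse_time(plain, "sum")
  c_scaled <- collapse_time(scaled, "sum")
  expect_equal(as.matrix(c_scaled),
               as.matrix(c_plain) * (as.matrix(img) / 255),
               tolerance = 1e-12)
})

test_that("map normalization follows |(H - min)/(max - min)|", {
  H <- attribution_map2d(matrix(c(2, 3, 4, 2), 2, 2))  # [[2,4],[3,2]]
  expect_equal(as.matrix(normalize_map(H)),
               matrix(c(0, 0.5, 1, 0), 2, 2))
  set.seed(21)
  R <- attribution_map3d(array(rnorm(24), dim = c(1, 2, 3, 4)))
  nr <- normalize_map(R)
  expect_true(all(nr >= 0 & nr <= 1))
  expect_equal(min(nr), 0); expect_equal(max(nr), 1)
  expect_true(all(normalize_map(attribution_map2d(matrix(5, 3, 3))) == 0))
})

test_that("abs and signed rankings differ only when entries are negative", {
  pos <- attribution_map2d(matrix(c(3, 1, 4, 2), 2, 2))
  expect_equal(rank_features(pos, "abs")$idx, rank_features(pos, "signed")$idx)
  mixed <- attribution_map2d(matrix(c(3, -5, 1, 0), 2, 2))
  expect_false(identical(rank_features(mixed, "abs")$idx,
                         rank_features(mixed, "signed")$idx))
})
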