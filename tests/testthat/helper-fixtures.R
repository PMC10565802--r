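# Shared fixtures, built once per test session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# small fully connected net with random weights, for oracle/identity tests
tiny_dense_net <- function(seed = 3, reset = "subtract", surrogate = "exp",
                           leak = 0.9) {
  spec <- network_spec(list(
    layer_dense(5, neuron_params(threshold = 0.8, leak_factor = leak,
                                 surrogate_sharpness = 2, reset_mode = reset,
                                 surrogate = surrogate)),
    layer_dense(2, neuron_params(threshold = 0.6, leak_factor = 0.95,
                                 reset_mode = reset, surrogate = surrogate))
  ), input_shape = c(1, 2, 2), n_classes = 2)
  build_network(spec, seed = seed)
}

tiny_conv_net <- function(seed = 2, size = 6) {
  build_network(toy_conv_network_spec(image_size = size, n_classes = 3,
                                      conv_channels = 2),
                seed = seed)
}

# central finite differences of the relaxed class score
fd_gradient <- function(net, x, target, eps = 1e-4) {
  f <- function(z) snnxattr:::relaxed_class_score(net, z, target)
  g <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# the quantitative-protocol fixture: TTFS-coded oriented bars and a
# network trained to high accuracy on them
ttfs_fixture <- function() {
  memo("ttfs_fixture", function() {
    cfg <- toy_dataset_config(seed = 7)
    data <- encode_dataset(make_toy_images(cfg), encoder_config("ttfs"))
    net <- build_network(toy_network_spec(), seed = 1)
    net <- train_snn(net, data, train_config(
      epochs = 15, learning_rate = 2e-4, target_high = 10, target_low = 1,
      seed = 5))
    samples <- purrr::map2(data$input, data$label,
                           function(i, l) list(input = i, label = l))
    list(net = net, data = data, samples = samples,
         history = attr(net, "history"))
  })
}

# faster rate-coded fixture for the noise sweeps
poisson_fixture <- function() {
  memo("poisson_fixture", function() {
    cfg <- toy_dataset_config(seed = 7)
    data <- encode_dataset(make_toy_images(cfg),
                           encoder_config("poisson", n_timesteps = 20L,
                                          seed = 11L))
    net <- build_network(toy_network_spec(), seed = 1)
    net <- train_snn(net, data, train_config(epochs = 20, seed = 5))
    samples <- purrr::map2(data$input, data$label,
                           function(i, l) list(input = i, label = l))
    list(net = net, data = data, samples = samples)
  })
}

random_spike_tensor <- function(dims, p = 0.3, seed = 1) {
  set.seed(seed)
  spike_tensor(array(as.numeric(stats::runif(prod(dims)) < p), dim = dims))
}
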