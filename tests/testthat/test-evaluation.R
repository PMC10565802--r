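test_that("feature ranking orders by score with lexicographic tie-breaks", {
  m <- attribution_map2d(matrix(c(3, -5), 1, 2))  # [[3, -5]]
  r_abs <- rank_features(m, "abs")
  expect_equal(r_abs$x[1], 2)        # |-5| > 3
  r_sgn <- rank_features(m, "signed")
  expect_equal(r_sgn$x[1], 1)        # 3 > -5
  # all-equal map: pure lexicographic order (y, then x)
  flat <- rank_features(attribution_map2d(matrix(1, 2, 2)), "signed")
  expect_equal(flat$y, c(1, 1, 2, 2))
  expect_equal(flat$x, c(1, 2, 1, 2))
  # every coordinate appears exactly once
  big <- rank_features(attribution_map3d(array(rnorm(24), c(1, 2, 3, 4))))
  expect_equal(sort(big$idx), 1:24)
})

test_that("spike perturbation endpoints and counting arithmetic", {
  inp <- random_spike_tensor(c(1, 4, 4, 10), p = 0.4, seed = 3)
  map <- attribution_map3d(array(rnorm(length(inp)), dim = dim(inp)))
  r <- rank_features(map, "abs")
  expect_identical(unclass(perturb_spikes(inp, r, 0, "delete")),
                   unclass(inp))
  expect_true(all(perturb_spikes(inp, r, 0, "insert") == 0))
  expect_true(all(perturb_spikes(inp, r, 1, "delete") == 0))
  expect_identical(unclass(perturb_spikes(inp, r, 1, "insert")),
                   unclass(inp))
  # 4x4x1x10 tensor, k = 0.05 -> floor(0.05 * 160) = 8 cells touched
  del <- perturb_spikes(inp, r, 0.05, "delete")
  touched <- r$idx[1:8]
  expect_true(all(del[touched] == 0))
  expect_identical(del[-touched], unclass(inp)[-touched])
  # inputs are never mutated in place
  before <- as.numeric(inp)
  invisible(perturb_spikes(inp, r, 0.5, "delete"))
  expect_identical(as.numeric(inp), before)
})

test_that("delete and insert act on complementary feature sets", {
  inp <- random_spike_tensor(c(1, 4, 4, 5), p = 0.5, seed = 8)
  n <- length(inp)
  map <- attribution_map3d(array(rnorm(n), dim = dim(inp)))
  r <- rank_features(map, "abs")
  for (k in c(0, 16, 40, n)) {           # exact fractions of n = 80
    f <- k / n
    del <- perturb_spikes(inp, r, f, "delete")
    ins <- perturb_spikes(inp, r, f, "insert")
    # at the same fraction, deletion zeroes exactly the cells insertion
    # restores: the two results partition the input's spikes
    expect_equal(unclass(del) + unclass(ins), unclass(inp),
                 ignore_attr = TRUE)
    expect_equal(sum(del * ins), 0)
  }
})

test_that("pixel perturbation uses the named baselines", {
  img <- gray_image(matrix(seq(10L, 160L, by = 10L), 4, 4))
  map <- attribution_map2d(matrix(rnorm(16), 4, 4))
  r <- rank_features(map)
  expect_identical(as.matrix(perturb_pixels(img, r, 0, "delete")),
                   as.matrix(img))
  expect_true(all(perturb_pixels(img, r, 1, "delete", "black") == 0))
  expect_true(all(perturb_pixels(img, r, 1, "delete", "gray") == 128))
  expect_true(all(perturb_pixels(img, r, 1, "delete", "white") == 255))
  for (b in c("black", "gray", "white")) {
    expect_identical(as.matrix(perturb_pixels(img, r, 1, "insert", b)),
                     as.matrix(img))
  }
  half <- perturb_pixels(img, r, 0.5, "insert", "gray")
  expect_equal(sum(as.matrix(half) != 128), 8)  # no source pixel equals 128
})

test_that("curve AUC is the trapezoidal area", {
  flat <- tibble::tibble(fraction = c(0, 0.5, 1), accuracy = c(1, 1, 1),
                         winning_class_score = c(2, 2, 2))
  expect_equal(curve_auc(flat), 1)
  lin <- tibble::tibble(fraction = c(0, 1), accuracy = c(1, 0),
                        winning_class_score = c(4, 0))
  expect_equal(curve_auc(lin), 0.5)
  expect_equal(curve_auc(lin, "winning_class_score"), 2)
  crafted <- tibble::tibble(fraction = c(0, 0.25, 1),
                            accuracy = c(1, 0.5, 0.25),
                            winning_class_score = c(3, 1, 0))
  hand <- 0.25 * (1 + 0.5) / 2 + 0.75 * (0.5 + 0.25) / 2
  expect_equal(curve_auc(crafted), hand)
  skip_if_not_installed("pracma")
  expect_equal(curve_auc(crafted),
               pracma::trapz(crafted$fraction, crafted$accuracy))
  expect_error(curve_auc(crafted[1, ]), "two")
})

test_that("jitter displaces spikes uniformly and only merges, never adds", {
  inp <- random_spike_tensor(c(2, 5, 5, 12), p = 0.3, seed = 5)
  expect_identical(apply_jitter(inp, 0, seed = 1), inp)
  for (s in 1:5) {
    out <- apply_jitter(inp, 2, seed = s)
    expect_lte(sum(out), sum(inp))
    expect_true(all(out %in% c(0, 1)))
  }
  # single interior spike: landing distribution uniform over {t-1, t, t+1}
  single <- array(0, dim = c(1, 1, 1, 9)); single[1, 1, 1, 5] <- 1
  single <- spike_tensor(single)
  n_rep <- 900
  lands <- vapply(seq_len(n_rep), function(s)
    which(apply_jitter(single, 1, seed = s)[1, 1, 1, ] == 1), numeric(1))
  counts <- table(factor(lands, levels = 4:6))
  p <- 1 / 3
  sigma <- sqrt(n_rep * p * (1 - p))
  expect_true(all(abs(counts - n_rep * p) < 3 * sigma))
  # boundary clipping: a spike at t = 0 never leaves the window
  edge <- array(0, dim = c(1, 1, 1, 4)); edge[1, 1, 1, 1] <- 1
  for (s in 1:10) {
    expect_equal(sum(apply_jitter(spike_tensor(edge), 3, seed = s)), 1)
  }
})

test_that("deletion noise thins spikes binomially", {
  inp <- random_spike_tensor(c(1, 10, 10, 10), p = 1, seed = 1)  # 1000 spikes
  expect_identical(apply_deletion_noise(inp, 0, seed = 1), inp)
  expect_equal(sum(apply_deletion_noise(inp, 1, seed = 1)), 0)
  survivors <- sum(apply_deletion_noise(inp, 0.3, seed = 7))
  expect_lt(abs(survivors - 1000 * 0.7), 3 * sqrt(1000 * 0.3 * 0.7))
})

test_that("perturbation curves start clean and reproduce endpoints", {
  fx <- poisson_fixture()
  fr <- c(0, 0.5, 1)
  cur <- run_perturbation_experiment(fx$net, fx$samples,
                                     function(n, i) snn_grad3d(n, i),
                                     level = "spike", direction = "delete",
                                     fractions = fr, seed = 2)
  expect_equal(cur$accuracy[1], 1)        # fraction 0 on the correct subset
  # full deletion leaves the empty stream: all samples collapse onto the
  # empty-input prediction
  empty_winner <- class_scores(
    simulate_forward(fx$net, empty_like(fx$samples[[1]]$input)))$winner
  kept_labels <- vapply(fx$samples, function(s) {
    ok <- class_scores(simulate_forward(fx$net, s$input))$winner == s$label
    if (ok) s$label else NA_integer_
  }, integer(1))
  kept_labels <- kept_labels[!is.na(kept_labels)]
  expect_equal(cur$accuracy[3], mean(kept_labels == empty_winner))
  ins <- run_perturbation_experiment(fx$net, fx$samples, "random",
                                     level = "spike", direction = "insert",
                                     fractions = fr, seed = 2)
  expect_equal(ins$accuracy[3], 1)        # full insertion restores the input
  expect_error(run_perturbation_experiment(fx$net, list(
    list(input = empty_like(fx$samples[[1]]$input), label = 2)),
    "random", fractions = fr), "correctly classified")
})

test_that("pixel-level curves run end to end with baselines", {
  fx <- poisson_fixture()
  enc <- encoder_config("poisson", n_timesteps = 20L, seed = 11L)
  imgs <- make_toy_images(toy_dataset_config(seed = 7,
                                             n_samples_per_class = 2))
  samples <- purrr::map2(imgs$image, imgs$label,
                         function(im, l) list(image = im, label = l))
  cur <- run_perturbation_experiment(
    fx$net, samples, function(n, im) collapse_time(
      snn_grad3d(n, encode_image(im, enc)), "sum"),
    level = "pixel", direction = "delete", fractions = c(0, 0.5, 1),
    baseline = "black", encoder = enc, seed = 3)
  expect_equal(cur$accuracy[1], 1)
  expect_true(all(cur$accuracy >= 0 & cur$accuracy <= 1))
})

test_that("noise sweeps report exact unity at level zero", {
  fx <- poisson_fixture()
  grid <- expand.grid(kind = c("jitter", "deletion"), level = 0,
                      site = c("input", "network"),
                      stringsAsFactors = FALSE)
  sweep <- run_noise_sweep(fx$net, fx$samples, grid, seed = 4)
  expect_true(all(sweep$relative_accuracy == 1))
  # deletion degrades accuracy as p grows (coarse check at extremes)
  g2 <- expand.grid(kind = "deletion", level = c(0, 0.9), site = "input",
                    stringsAsFactors = FALSE)
  s2 <- run_noise_sweep(fx$net, fx$samples, g2, seed = 4)
  expect_lte(s2$relative_accuracy[2], s2$relative_accuracy[1])
})
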