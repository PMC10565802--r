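#' Rank features by attribution score
#'
#' Produces the deterministic total order used by the deletion/insertion
#' protocol: descending score (descending absolute score in `"abs"` mode),
#' ties broken lexicographically by coordinate. Every cell of the map
#' appears exactly once.
#'
#' @param map an [attribution_map2d()] (pixels) or [attribution_map3d()]
#'   (spike cells).
#' @param mode `"abs"` (rank by magnitude) or `"signed"`.
#' @return a `feature_ranking` tibble, one row per feature in rank order,
#'   with coordinate columns (`y, x` or `c, y, x, t`), the raw `score`,
#'   and the linear array index `idx`.
#' @export
rank_features <- function(map, mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  d <- dim(map)
  v <- as.numeric(map)
  if (length(d) == 2L) {
    co <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]))
    tb <- tibble::tibble(y = co$y, x = co$x, score = v,
                         idx = seq_along(v))
    key <- if (mode == "abs") abs(tb$score) else tb$score
    tb <- tb[order(-key, tb$y, tb$x), ]
  } else {
    co <- expand.grid(c = seq_len(d[1]), y = seq_len(d[2]),
                      x = seq_len(d[3]), t = seq_len(d[4]))
    tb <- tibble::tibble(c = co$c, y = co$y, x = co$x, t = co$t,
                         score = v, idx = seq_along(v))
    key <- if (mode == "abs") abs(tb$score) else tb$score
    tb <- tb[order(-key, tb$c, tb$y, tb$x, tb$t), ]
  }
  tb$rank <- seq_len(nrow(tb))
  structure(tb, class = c("feature_ranking", class(tibble::tibble())),
            mode = mode)
}

# a seeded uniformly random ranking over n cells, the control ranking
random_ranking <- function(n) {
  tibble::tibble(idx = sample(n), rank = seq_len(n))
}

#' Delete or insert ranked spike cells
#'
#' `delete`: the top `floor(k_frac * n_cells)` ranked cells are set to 0
#' in a copy of the input ("no spike" is the spike-level baseline).
#' `insert`: starting from the empty stream, the top ranked cells take the
#' input's values. The ranking must cover all potential spike locations,
#' i.e. every `(c, y, x, t)` cell.
#'
#' @param input a [spike_tensor()].
#' @param ranking a [rank_features()] result (or any tibble with `idx` in
#'   rank order) over the input's cells.
#' @param k_frac fraction of cells to perturb, in `[0, 1]`.
#' @param direction `"delete"` or `"insert"`.
#' @return a new [spike_tensor()]; the input is never modified.
#' @export
perturb_spikes <- function(input, ranking, k_frac,
                           direction = c("delete", "insert")) {
  direction <- match.arg(direction)
  stopifnot(k_frac >= 0, k_frac <= 1)
  n_cells <- length(input)
  if (nrow(ranking) != n_cells) {
    stop("ranking must cover every spike cell of the input", call. = FALSE)
  }
  k <- floor(k_frac * n_cells)
  top <- ranking$idx[seq_len(k)]
  arr <- as_plain_array(input)
  if (direction == "delete") {
    arr[top] <- 0
  } else {
    full <- arr
    arr <- array(0, dim = dim(full))
    arr[top] <- full[top]
  }
  spike_tensor(arr)
}

baseline_value <- function(baseline) {
  if (is.numeric(baseline)) return(as.integer(baseline))
  switch(baseline, black = 0L, gray = 128L, white = 255L,
         stop("unknown baseline: ", baseline, call. = FALSE))
}

#' Delete or insert ranked pixels
#'
#' `delete`: the top-ranked fraction of pixels is replaced by the baseline
#' intensity. `insert`: all pixels start at the baseline and the
#' top-ranked fraction is restored to the original values.
#'
#' @param img a [gray_image()].
#' @param ranking a [rank_features()] result over the image's pixels.
#' @param k_frac fraction of pixels to perturb.
#' @param direction `"delete"` or `"insert"`.
#' @param baseline `"black"` (0), `"gray"` (128), `"white"` (255), or an
#'   integer intensity.
#' @return a new [gray_image()].
#' @export
perturb_pixels <- function(img, ranking, k_frac,
                           direction = c("delete", "insert"),
                           baseline = "black") {
  direction <- match.arg(direction)
  img <- as_gray(img)
  bval <- baseline_value(baseline)
  n <- length(img)
  if (nrow(ranking) != n) {
    stop("ranking must cover every pixel", call. = FALSE)
  }
  k <- floor(k_frac * n)
  top <- ranking$idx[seq_len(k)]
  px <- as.matrix(img)
  if (direction == "delete") {
    px[top] <- bval
  } else {
    orig <- px
    px[] <- bval
    px[top] <- orig[top]
  }
  gray_image(px)
}

default_fraction_grid <- function() {
  c(0, 0.01, 0.02, 0.05, seq(0.1, 0.9, by = 0.1), 1)
}

#' Deletion/insertion perturbation experiment
#'
#' For each perturbation fraction k, the top-k features of every sample
#' (ranked by its own attribution map, or by a seeded random control) are
#' deleted or inserted, the network is re-run, and the mean class-recall
#' accuracy and the mean spike count of the originally winning class are
#' recorded. Samples the network misclassifies are dropped first, so the
#' deletion curve starts at accuracy 1; attribution maps of wrong
#' predictions would not be meaningfully evaluable.
#'
#' @param net an `snn_network`.
#' @param samples list of `list(input = spike_tensor, label = class)`; for
#'   `level = "pixel"` each sample instead carries `image = gray_image`.
#' @param attr_fn `function(net, input) -> attribution map`, or the string
#'   `"random"` for the uniform-ranking control.
#' @param level `"spike"` (3D cells, no-spike baseline) or `"pixel"`
#'   (image pixels replaced by `baseline`, then re-encoded via `encoder`).
#' @param direction `"delete"` or `"insert"`.
#' @param fractions increasing perturbation fractions starting at 0.
#' @param baseline pixel baseline (ignored at spike level).
#' @param encoder an [encoder_config()], required at pixel level.
#' @param rank_mode `"abs"` or `"signed"` feature ordering.
#' @param seed seed for the random control ranking.
#' @return a `perturbation_curve` tibble: `fraction`, `accuracy`,
#'   `winning_class_score`, plus `n_samples`/method metadata attributes.
#' @export
run_perturbation_experiment <- function(net, samples, attr_fn,
                                        level = c("spike", "pixel"),
                                        direction = c("delete", "insert"),
                                        fractions = default_fraction_grid(),
                                        baseline = "black",
                                        encoder = NULL,
                                        rank_mode = "abs",
                                        seed = 1L) {
  level <- match.arg(level)
  direction <- match.arg(direction)
  stopifnot(all(diff(fractions) > 0), fractions[1] == 0)
  if (level == "pixel" && is.null(encoder)) {
    stop("pixel-level perturbation needs an encoder", call. = FALSE)
  }
  get_input <- function(s) {
    if (level == "spike") s$input else encode_image(s$image, encoder)
  }
  # keep only correctly classified samples; remember each clean winner
  keep <- list()
  for (s in samples) {
    inp <- get_input(s)
    win <- class_scores(simulate_forward(net, inp))$winner
    if (win == s$label) {
      s$clean_input <- inp
      s$clean_winner <- win
      keep[[length(keep) + 1]] <- s
    }
  }
  if (length(keep) == 0) {
    stop("no correctly classified samples to evaluate", call. = FALSE)
  }
  set.seed(seed)
  rankings <- lapply(keep, function(s) {
    n_cells <- if (level == "spike") length(s$clean_input) else length(s$image)
    if (identical(attr_fn, "random")) {
      random_ranking(n_cells)
    } else {
      target <- if (level == "spike") s$clean_input else s$image
      rank_features(attr_fn(net, target), mode = rank_mode)
    }
  })
  rows <- lapply(fractions, function(f) {
    acc <- 0; score <- 0
    for (i in seq_along(keep)) {
      s <- keep[[i]]
      inp <- if (level == "spike") {
        perturb_spikes(s$clean_input, rankings[[i]], f, direction)
      } else {
        encode_image(
          perturb_pixels(s$image, rankings[[i]], f, direction, baseline),
          encoder)
      }
      cs <- class_scores(simulate_forward(net, inp))
      acc <- acc + as.numeric(cs$winner == s$label)
      score <- score + cs$scores[s$clean_winner]
    }
    tibble::tibble(fraction = f, accuracy = acc / length(keep),
                   winning_class_score = score / length(keep))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("perturbation_curve", class(out)),
            level = level, direction = direction,
            method = if (is.character(attr_fn)) attr_fn else "attribution",
            n_samples = length(keep))
}

#' Area under a perturbation curve
#'
#' Trapezoidal area of the chosen metric over the perturbation fraction.
#' Lower deletion AUC / higher insertion AUC indicates a better
#' attribution method.
#'
#' @param curve a `perturbation_curve`.
#' @param metric `"accuracy"` or `"winning_class_score"`.
#' @return a single number.
#' @export
curve_auc <- function(curve, metric = c("accuracy", "winning_class_score")) {
  metric <- match.arg(metric)
  x <- curve$fraction
  y <- curve[[metric]]
  if (length(x) < 2) stop("need at least two fractions", call. = FALSE)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Temporal jitter noise
#'
#' Each spike is independently displaced by an integer drawn uniformly
#' from `[-j, +j]` timesteps (so spikes may occur earlier or later);
#' displacements landing outside the window are clipped to its boundary,
#' and colliding spikes merge by OR (the count can only shrink).
#'
#' @param spikes a [spike_tensor()].
#' @param j maximum jitter in timesteps (j = 0 is the identity).
#' @param seed integer seed.
#' @return a new [spike_tensor()].
#' @export
apply_jitter <- function(spikes, j, seed) {
  stopifnot(is_spike_tensor(spikes), j >= 0)
  if (j == 0) return(spikes)
  d <- dim(spikes)
  T <- d[4]
  arr <- as_plain_array(spikes)
  idx <- which(arr == 1)
  if (length(idx) == 0) return(spikes)
  ncyx <- prod(d[1:3])
  t0 <- ((idx - 1) %/% ncyx) + 1
  cell <- ((idx - 1) %% ncyx) + 1
  set.seed(seed)
  shift <- sample(seq(-j, j), length(idx), replace = TRUE)
  t1 <- pmin(pmax(t0 + shift, 1L), T)
  out <- array(0, dim = d)
  out[cell + (t1 - 1) * ncyx] <- 1
  spike_tensor(out)
}

#' Spike-deletion noise
#'
#' Each spike is independently kept with probability `1 - p`, emulating a
#' sensor or neuron failing to fire.
#'
#' @param spikes a [spike_tensor()].
#' @param p deletion probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a new [spike_tensor()].
#' @export
apply_deletion_noise <- function(spikes, p, seed) {
  stopifnot(is_spike_tensor(spikes), p >= 0, p <= 1)
  if (p == 0) return(spikes)
  arr <- as_plain_array(spikes)
  idx <- which(arr == 1)
  if (length(idx) > 0) {
    set.seed(seed)
    arr[idx[stats::runif(length(idx)) < p]] <- 0
  }
  spike_tensor(arr)
}

#' Noise-robustness sweep
#'
#' Measures relative accuracy (perturbed accuracy divided by clean
#' accuracy) over a grid of noise configurations, on the subset of samples
#' the clean network classifies correctly — so relative accuracy is
#' exactly 1 at level 0 and comparisons across configurations share the
#' same samples. Noise is applied at the input (tensor perturbed before
#' simulation) or inside the network (each hidden layer's delivered
#' spikes perturbed per timestep, see [network_noise()]).
#'
#' @param net an `snn_network`.
#' @param samples list of `list(input = spike_tensor, label = class)`.
#' @param grid a data frame with columns `kind` ("jitter"/"deletion"),
#'   `level`, and `site` ("input"/"network").
#' @param seed base seed; each grid row and sample uses a derived seed.
#' @return a tibble `kind, level, site, relative_accuracy, n_samples`.
#' @export
run_noise_sweep <- function(net, samples, grid, seed = 1L) {
  stopifnot(all(c("kind", "level", "site") %in% names(grid)))
  clean_ok <- vapply(samples, function(s) {
    class_scores(simulate_forward(net, s$input))$winner == s$label
  }, logical(1))
  keep <- samples[clean_ok]
  if (length(keep) == 0) {
    stop("clean accuracy is zero; relative accuracy undefined", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(grid)), function(gi) {
    kind <- as.character(grid$kind[gi])
    level <- grid$level[gi]
    site <- as.character(grid$site[gi])
    correct <- 0
    for (si in seq_along(keep)) {
      s <- keep[[si]]
      sub_seed <- (seed * 10007L + gi * 101L + si) %% .Machine$integer.max
      if (site == "input") {
        inp <- if (kind == "jitter") apply_jitter(s$input, level, sub_seed)
               else apply_deletion_noise(s$input, level, sub_seed)
        rec <- simulate_forward(net, inp)
      } else {
        nz <- network_noise(kind = kind, level = level, seed = sub_seed)
        rec <- simulate_forward(net, s$input, noise = nz)
      }
      if (class_scores(rec)$winner == s$label) correct <- correct + 1
    }
    tibble::tibble(kind = kind, level = level, site = site,
                   relative_accuracy = correct / length(keep),
                   n_samples = length(keep))
  })
  dplyr::bind_rows(rows)
}
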