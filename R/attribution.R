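#' Attribution map containers
#'
#' 3D maps score every spike cell `(channel, y, x, t)` of an input tensor;
#' 2D maps score pixels `(y, x)` of the source image. Both are plain
#' numeric arrays with a class attribute so they print compactly and plot
#' via [ggplot2::autoplot()].
#'
#' @param scores numeric array `(channel, y, x, t)` (3D) or matrix (2D).
#' @param target_class class index the map explains.
#' @param method_tag short method name, e.g. `"snn-grad3d"`.
#' @param mapping_used time-collapse reducer for a 2D map.
#' @return an `attribution_map3d` / `attribution_map2d`.
#' @export
attribution_map3d <- function(scores, target_class = NA_integer_,
                              method_tag = "custom") {
  stopifnot(length(dim(scores)) == 4L, all(is.finite(scores)))
  structure(scores, class = c("attribution_map3d", "array"),
            target_class = target_class, method_tag = method_tag)
}

#' @rdname attribution_map3d
#' @export
attribution_map2d <- function(scores, mapping_used = "sum",
                              method_tag = "custom",
                              target_class = NA_integer_) {
  stopifnot(is.matrix(scores), all(is.finite(scores)))
  structure(scores, class = c("attribution_map2d", "matrix"),
            mapping_used = mapping_used, method_tag = method_tag,
            target_class = target_class)
}

#' @export
print.attribution_map3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<attribution_map3d> %s, class %s, dims %s, range [%.4g, %.4g]\n",
    attr(x, "method_tag"), attr(x, "target_class"),
    paste(d, collapse = "x"), min(x), max(x)))
  invisible(x)
}

#' @export
print.attribution_map2d <- function(x, ...) {
  cat(sprintf(
    "<attribution_map2d> %s (%s collapse), %d x %d, range [%.4g, %.4g]\n",
    attr(x, "method_tag"), attr(x, "mapping_used"),
    nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# pick the explanation target: the most-spiking output neuron
default_target <- function(net, input) {
  class_scores(simulate_forward(net, input))$winner
}

#' Spike-level gradient attribution (SNN-Grad3D)
#'
#' The gradient of the class score (output spike count) with respect to
#' every input spike cell, computed by surrogate-gradient backpropagation
#' through time. When `target_class` is omitted the winning class (the
#' most-spiking output neuron) is explained.
#'
#' @param net an `snn_network`.
#' @param input a [spike_tensor()].
#' @param target_class optional 1-based class index.
#' @return an [attribution_map3d()] with the input's shape.
#' @export
snn_grad3d <- function(net, input, target_class = NULL) {
  target <- target_class %||% default_target(net, input)
  g <- input_gradient(net, input, target)
  attribution_map3d(g, target_class = target, method_tag = "snn-grad3d")
}

#' Integrated-gradients path configuration
#'
#' @param n_steps number of path steps n (the image pipeline default of 50
#'   matches the configuration the method is usually timed at).
#' @param baseline for the image path: a [gray_image()]; `NULL` means the
#'   all-black image. The event path always starts from the empty stream.
#' @param sampling_heuristic how the event path grows the stream:
#'   `"stride"` keeps evenly spaced timesteps, `"prefix"` the leading
#'   ones.
#' @param scale_by_input_delta if `TRUE`, the time-collapsed 2D map is
#'   multiplied elementwise by `(image - baseline) / 255`, the classical
#'   integrated-gradients completeness form.
#' @return an `ig_path_config` list.
#' @export
ig_path_config <- function(n_steps = 50L, baseline = NULL,
                           sampling_heuristic = c("stride", "prefix"),
                           scale_by_input_delta = FALSE) {
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  structure(list(n_steps = as.integer(n_steps), baseline = baseline,
                 sampling_heuristic = match.arg(sampling_heuristic),
                 scale_by_input_delta = scale_by_input_delta),
            class = "ig_path_config")
}

round_half_up <- function(x) floor(x + 0.5)

#' Integrated gradients for real-valued images (SNN-IG2D)
#'
#' Builds a straight path of images from a baseline (default: all black)
#' to the source image, encodes every image on the path into a spike
#' tensor, computes the spike-level gradient of each with respect to the
#' winning class of the *original* input, and averages the gradients along
#' the path. Path images are rounded half-up to integers because the
#' encoders consume 8-bit intensities.
#'
#' @param net an `snn_network`.
#' @param img a [gray_image()].
#' @param encoder an [encoder_config()].
#' @param path an [ig_path_config()].
#' @return an [attribution_map3d()] over the encoded input's shape; the
#'   `(image - baseline)/255` delta is carried along for the optional
#'   completeness scaling applied by [collapse_time()].
#' @export
snn_ig2d <- function(net, img, encoder, path = ig_path_config()) {
  img <- as_gray(img)
  B <- path$baseline %||% gray_image(matrix(0L, nrow(img), ncol(img)))
  if (!all(dim(B) == dim(img))) {
    stop("baseline shape must match the image", call. = FALSE)
  }
  full <- encode_image(img, encoder)
  target <- default_target(net, full)
  n <- path$n_steps
  acc <- NULL
  for (k in seq_len(n)) {
    ik <- round_half_up(as.numeric(B) + (k / n) * (as.numeric(img) - as.numeric(B)))
    imgk <- gray_image(matrix(as.integer(ik), nrow(img), ncol(img)))
    g <- input_gradient(net, encode_image(imgk, encoder), target)
    acc <- if (is.null(acc)) g else acc + g
  }
  map <- attribution_map3d(acc / n, target_class = target,
                           method_tag = "snn-ig2d")
  attr(map, "input_delta") <- (as.matrix(img) - as.matrix(B)) / 255
  attr(map, "scale_by_input_delta") <- path$scale_by_input_delta
  map
}

# timesteps (1-based) kept at path step k of n for a window of T steps
ig3d_kept_timesteps <- function(T, k, n, heuristic) {
  m <- ceiling(T * k / n)
  if (heuristic == "prefix") seq_len(m)
  else unique(floor(T * (seq_len(m) - 1) / m)) + 1L
}

#' Integrated gradients for event data (SNN-IG3D)
#'
#' Event streams are binary, so the path runs along the time axis instead
#' of along intensities: from the empty stream ("no spike" baseline) to
#' the full input, by sampling timesteps with iteratively increasing
#' sampling rate. Gradients at each intermediate stream (taken at the
#' winning class of the full input) are averaged along the path.
#'
#' @param net an `snn_network`.
#' @param input a [spike_tensor()].
#' @param path an [ig_path_config()]; `n_steps` must not exceed the
#'   window T.
#' @return an [attribution_map3d()].
#' @export
snn_ig3d <- function(net, input, path = ig_path_config(n_steps = 10L)) {
  input <- if (is_spike_tensor(input)) input else spike_tensor(input)
  T <- n_timesteps(input)
  n <- path$n_steps
  if (n > T) stop("n_steps cannot exceed the number of timesteps", call. = FALSE)
  target <- default_target(net, input)
  arr <- as_plain_array(input)
  acc <- NULL
  for (k in seq_len(n)) {
    kept <- ig3d_kept_timesteps(T, k, n, path$sampling_heuristic)
    step <- array(0, dim = dim(arr))
    step[, , , kept] <- arr[, , , kept]
    g <- input_gradient(net, spike_tensor(step), target)
    acc <- if (is.null(acc)) g else acc + g
  }
  attribution_map3d(acc / n, target_class = target, method_tag = "snn-ig3d")
}

#' Spike activation map (SAM) and its inversion (ISAM)
#'
#' A forward-only activation map: each neuron's contribution score at time
#' t sums exponentially decaying traces of its past spikes,
#' \deqn{NCS(t) = \sum_{t' < t,\; s(t') = 1} e^{-(t - t')/\gamma},}
#' and the map is the channel-sum of NCS over the chosen convolutional
#' layer's spatial grid across time. ISAM is the elementwise negation of
#' SAM, ranking the least-contributing cells first. Both are restricted to
#' convolutional layers.
#'
#' @param net an `snn_network`.
#' @param input a [spike_tensor()].
#' @param layer_index index of a convolutional layer in `net`.
#' @param gamma decay time constant in timesteps.
#' @return an [attribution_map3d()] at the layer's spatial resolution
#'   (single channel after channel aggregation).
#' @export
sam <- function(net, input, layer_index = 1L, gamma = 1) {
  stopifnot(inherits(net, "snn_network"))
  if (layer_index < 1 || layer_index > length(net$layers) ||
      net$layers[[layer_index]]$type != "conv") {
    stop("sam is limited to convolutional layers", call. = FALSE)
  }
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  rec <- simulate_forward(net, input)
  S <- rec$layers[[layer_index]]$S
  T <- ncol(S)
  decay <- exp(-1 / gamma)
  ncs <- matrix(0, nrow(S), T)
  for (t in seq_len(T)[-1]) {
    ncs[, t] <- decay * (ncs[, t - 1] + S[, t - 1])
  }
  os <- net$layers[[layer_index]]$out_shape
  ncs_arr <- array(ncs, dim = c(os[1], os[2], os[3], T))
  chan_sum <- apply(ncs_arr, c(2, 3, 4), sum)
  dim(chan_sum) <- c(1L, dim(chan_sum))
  map <- attribution_map3d(chan_sum,
                           target_class = class_scores(rec)$winner,
                           method_tag = "sam")
  attr(map, "layer_index") <- layer_index
  map
}

#' @rdname sam
#' @export
isam <- function(net, input, layer_index = 1L, gamma = 1) {
  m <- sam(net, input, layer_index = layer_index, gamma = gamma)
  out <- attribution_map3d(-as_plain_array(m),
                           target_class = attr(m, "target_class"),
                           method_tag = "isam")
  attr(out, "layer_index") <- attr(m, "layer_index")
  out
}

#' Bilinear upscaling of a layer-resolution map
#'
#' Activation maps live at the spatial resolution of a hidden layer and
#' must be scaled to the input image size for superposition. Corners are
#' aligned, so values at grid points are preserved exactly.
#'
#' @param map an [attribution_map2d()] or plain matrix.
#' @param target integer `(height, width)`, at least the source size.
#' @return an [attribution_map2d()] of the target size.
#' @export
upscale_layer_map <- function(map, target) {
  src <- as.matrix(map)
  Hs <- nrow(src); Ws <- ncol(src)
  Ht <- target[1]; Wt <- target[2]
  if (Ht < Hs || Wt < Ws) stop("target must be at least the source size", call. = FALSE)
  ry <- if (Ht == 1L) rep(1, Ht) else 1 + (seq_len(Ht) - 1) * (Hs - 1) / (Ht - 1)
  rx <- if (Wt == 1L) rep(1, Wt) else 1 + (seq_len(Wt) - 1) * (Ws - 1) / (Wt - 1)
  y0 <- pmax(1L, pmin(floor(ry), Hs - 1L))
  x0 <- pmax(1L, pmin(floor(rx), Ws - 1L))
  fy <- ry - y0; fx <- rx - x0
  y1 <- pmin(y0 + 1L, Hs); x1 <- pmin(x0 + 1L, Ws)
  out <- matrix(0, Ht, Wt)
  for (i in seq_len(Ht)) {
    a <- src[y0[i], ] * (1 - fy[i]) + src[y1[i], ] * fy[i]
    out[i, ] <- a[x0] * (1 - fx) + a[x1] * fx
  }
  attribution_map2d(out, mapping_used = attr(map, "mapping_used") %||% "sum",
                    method_tag = attr(map, "method_tag") %||% "custom",
                    target_class = attr(map, "target_class") %||% NA_integer_)
}

#' Collapse a 3D attribution map over channel and time
#'
#' Maps the spike-level attribution box back to the 2D input space by
#' reducing the channel and time axes with the chosen reducer. Summation
#' is the default (the best-performing mapping for the gradient and
#' integrated-gradient pipelines). If the map carries an
#' integrated-gradients input delta and requested completeness scaling,
#' the collapsed map is multiplied elementwise by `(image - baseline)/255`.
#'
#' @param map an [attribution_map3d()].
#' @param strategy `"sum"`, `"max"` or `"avg"`.
#' @return an [attribution_map2d()].
#' @export
collapse_time <- function(map, strategy = c("sum", "max", "avg")) {
  strategy <- match.arg(strategy)
  stopifnot(length(dim(map)) == 4L)
  reducer <- switch(strategy, sum = sum, max = max, avg = mean)
  out <- apply(as_plain_array(map), c(2, 3), reducer)
  if (isTRUE(attr(map, "scale_by_input_delta")) &&
      !is.null(attr(map, "input_delta"))) {
    out <- out * attr(map, "input_delta")
  }
  attribution_map2d(out, mapping_used = strategy,
                    method_tag = attr(map, "method_tag") %||% "custom",
                    target_class = attr(map, "target_class") %||% NA_integer_)
}

#' Normalize an attribution map to [0, 1]
#'
#' Linear min-max normalization followed by the absolute value,
#' \eqn{H' = |(H - H_{min}) / (H_{max} - H_{min})|}; a constant map
#' returns all zeros by convention.
#'
#' @param H an attribution map (2D or 3D) or plain numeric array.
#' @return same shape and class, values in `[0, 1]`.
#' @export
normalize_map <- function(H) {
  v <- as.numeric(H)
  lo <- min(v); hi <- max(v)
  out <- if (hi == lo) rep(0, length(v)) else abs((v - lo) / (hi - lo))
  res <- H
  res[] <- out
  res
}

#' @export
as.matrix.attribution_map2d <- function(x, ...) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x))
  y
}
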