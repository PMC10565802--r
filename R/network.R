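#' Leaky integrate-and-fire neuron parameters
#'
#' Each spiking layer carries its own neuron parameters. Membrane dynamics
#' per neuron and discrete timestep are
#' \deqn{U(t) = \lambda \cdot U^{reset}(t-1) + a(t), \qquad
#'       s(t) = [U(t) \ge \theta],}
#' where `a(t)` is the weighted synaptic input, `\lambda` the per-timestep
#' leak factor and `\theta` the firing threshold. After a spike the
#' potential is either reduced by `\theta` (`"subtract"`, soft reset,
#' default) or zeroed (`"zero"`, hard reset).
#'
#' @param threshold firing threshold \eqn{\theta > 0} (potential units).
#' @param leak_factor multiplicative leak \eqn{\lambda \in (0, 1]} applied
#'   per timestep; 1 means a perfect (non-leaky) integrator.
#' @param surrogate_sharpness sharpness \eqn{\alpha > 0} of the surrogate
#'   derivative used during backpropagation.
#' @param reset_mode `"subtract"` or `"zero"`.
#' @param surrogate surrogate family: `"exp"` (exponential of
#'   \eqn{|U-\theta|}, default) or `"fast_sigmoid"`.
#' @return a `neuron_params` list.
#' @export
neuron_params <- function(threshold = 1, leak_factor = 0.9,
                          surrogate_sharpness = 2,
                          reset_mode = c("subtract", "zero"),
                          surrogate = c("exp", "fast_sigmoid")) {
  reset_mode <- match.arg(reset_mode)
  surrogate <- match.arg(surrogate)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (leak_factor <= 0 || leak_factor > 1) {
    stop("leak_factor must lie in (0, 1]", call. = FALSE)
  }
  if (surrogate_sharpness <= 0) {
    stop("surrogate_sharpness must be > 0", call. = FALSE)
  }
  structure(list(
    threshold = threshold, leak_factor = leak_factor,
    surrogate_sharpness = surrogate_sharpness,
    reset_mode = reset_mode, surrogate = surrogate
  ), class = "neuron_params")
}

#' Surrogate spike derivative
#'
#' Smooth stand-in \eqn{\rho(u)} for the derivative of the non-differentiable
#' threshold function, evaluated at membrane potential `u`. The default
#' exponential family is
#' \deqn{\rho(u) = \frac{\alpha}{2} e^{-\alpha |u - \theta|},}
#' maximal (value \eqn{\alpha/2}) at the threshold and symmetric around it.
#' The fast-sigmoid alternative is
#' \eqn{\rho(u) = \alpha / (2 (1 + \alpha|u-\theta|)^2)}.
#'
#' @param u membrane potential(s).
#' @param params a [neuron_params()] object.
#' @return \eqn{\rho(u)}, strictly positive, same shape as `u`.
#' @export
surrogate_spike_derivative <- function(u, params) {
  a <- params$surrogate_sharpness
  d <- abs(u - params$threshold)
  switch(params$surrogate,
    exp = a / 2 * exp(-a * d),
    fast_sigmoid = a / (2 * (1 + a * d)^2)
  )
}

# antiderivative of the surrogate: the relaxed (soft) spike function,
# a sigmoid rising from 0 to 1 through 1/2 at threshold. Used by the
# relaxed forward mode so that BPTT is the exact gradient of a smooth map.
surrogate_spike_soft <- function(u, params) {
  a <- params$surrogate_sharpness
  z <- u - params$threshold
  switch(params$surrogate,
    exp = ifelse(z < 0, 0.5 * exp(a * z), 1 - 0.5 * exp(-a * z)),
    fast_sigmoid = {
      az <- a * z
      0.5 * (1 + az / (1 + abs(az)))
    }
  )
}

#' Layer descriptors
#'
#' Building blocks for [network_spec()]: 2D spiking convolution, average
#' pooling (a fixed linear map, no neurons) and a fully connected spiking
#' layer.
#'
#' @param out_channels,kernel,stride,pad convolution geometry.
#' @param params a [neuron_params()] object for the layer's LIF neurons.
#' @param window pooling window (also the stride).
#' @param units number of output units of a dense layer.
#' @return a layer descriptor list.
#' @name layers
NULL

#' @rdname layers
#' @export
layer_conv <- function(out_channels, kernel = 3, stride = 1, pad = 1,
                       params = neuron_params()) {
  list(type = "conv", out_channels = as.integer(out_channels),
       kernel = as.integer(kernel), stride = as.integer(stride),
       pad = as.integer(pad), params = params)
}

#' @rdname layers
#' @export
layer_pool <- function(window = 2) {
  list(type = "pool", window = as.integer(window))
}

#' @rdname layers
#' @export
layer_dense <- function(units, params = neuron_params()) {
  list(type = "dense", units = as.integer(units), params = params)
}

#' Network specification
#'
#' An ordered list of layer descriptors plus the input shape and the number
#' of classes. The last layer must be dense with `units == n_classes`; its
#' output spike trains define the class scores.
#'
#' @param layers list of [layer_conv()] / [layer_pool()] / [layer_dense()]
#'   descriptors.
#' @param input_shape integer vector `(channels, height, width)`.
#' @param n_classes number of output classes.
#' @return a `network_spec` object (not yet carrying weights; see
#'   [build_network()]).
#' @export
network_spec <- function(layers, input_shape, n_classes) {
  stopifnot(length(input_shape) == 3, n_classes >= 1)
  last <- layers[[length(layers)]]
  if (last$type != "dense" || last$units != n_classes) {
    stop("last layer must be dense with units == n_classes", call. = FALSE)
  }
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes)),
            class = "network_spec")
}

# ---- shape chaining and linear operators ------------------------------

conv_out_hw <- function(h, w, k, stride, pad) {
  oh <- (h + 2L * pad - k) %/% stride + 1L
  ow <- (w + 2L * pad - k) %/% stride + 1L
  if (oh < 1L || ow < 1L) stop("conv layer collapses spatial dims", call. = FALSE)
  c(oh, ow)
}

# flat index into a (C, H, W) volume, all args 1-based vectors
flat_idx <- function(c, y, x, C, H) c + C * (y - 1L) + C * H * (x - 1L)

# triplet representation of a conv layer as a sparse matrix with tied
# weights: out row i, in col j, kernel weight index widx
conv_triplets <- function(in_shape, out_channels, k, stride, pad) {
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  hw <- conv_out_hw(H, W, k, stride, pad)
  OH <- hw[1]; OW <- hw[2]; OC <- out_channels
  g <- expand.grid(oc = seq_len(OC), oy = seq_len(OH), ox = seq_len(OW),
                   ic = seq_len(C), ky = seq_len(k), kx = seq_len(k))
  iy <- (g$oy - 1L) * stride - pad + g$ky   # 1-based input row
  ix <- (g$ox - 1L) * stride - pad + g$kx
  keep <- iy >= 1L & iy <= H & ix >= 1L & ix <= W
  g <- g[keep, ]; iy <- iy[keep]; ix <- ix[keep]
  list(
    i = flat_idx(g$oc, g$oy, g$ox, OC, OH),
    j = flat_idx(g$ic, iy, ix, C, H),
    widx = g$oc + OC * (g$ic - 1L) + OC * C * (g$ky - 1L) +
      OC * C * k * (g$kx - 1L),
    n_out = OC * OH * OW, n_in = C * H * W,
    n_weights = OC * C * k * k, out_shape = c(OC, OH, OW)
  )
}

# fixed average-pooling operator (window x window, stride = window),
# channels preserved; drops trailing rows/cols that do not fill a window
pool_matrix <- function(in_shape, window) {
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  OH <- H %/% window; OW <- W %/% window
  if (OH < 1L || OW < 1L) stop("pool window larger than input", call. = FALSE)
  g <- expand.grid(c = seq_len(C), oy = seq_len(OH), ox = seq_len(OW),
                   wy = seq_len(window), wx = seq_len(window))
  i <- flat_idx(g$c, g$oy, g$ox, C, OH)
  j <- flat_idx(g$c, (g$oy - 1L) * window + g$wy,
                (g$ox - 1L) * window + g$wx, C, H)
  list(P = Matrix::sparseMatrix(i = i, j = j, x = 1 / window^2,
                                dims = c(C * OH * OW, C * H * W)),
       out_shape = c(C, OH, OW))
}

#' Build a network from a specification
#'
#' Chains layer shapes, allocates weights (scaled-uniform Glorot-style
#' initialization, deterministic per seed) and precomputes the sparse
#' linear operators each layer applies per timestep.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for weight initialization.
#' @param init_gain multiplier on the Glorot uniform bound; spiking layers
#'   need somewhat larger weights than rate networks for spikes to
#'   propagate at all, hence the default of 3.
#' @return an `snn_network` object with fitted-size (untrained) weights.
#' @export
build_network <- function(spec, seed = 1L, init_gain = 3) {
  stopifnot(inherits(spec, "network_spec"))
  rng <- local({ set.seed(seed); function(n, bound) stats::runif(n, -bound, bound) })
  shape <- spec$input_shape
  built <- vector("list", length(spec$layers))
  for (li in seq_along(spec$layers)) {
    ld <- spec$layers[[li]]
    if (ld$type == "conv") {
      tr <- conv_triplets(shape, ld$out_channels, ld$kernel, ld$stride, ld$pad)
      fan_in <- prod(shape[1]) * ld$kernel^2
      fan_out <- ld$out_channels * ld$kernel^2
      bound <- init_gain * sqrt(6 / (fan_in + fan_out))
      built[[li]] <- list(type = "conv", triplets = tr,
                          weights = rng(tr$n_weights, bound),
                          params = ld$params, in_shape = shape,
                          out_shape = tr$out_shape, desc = ld)
      shape <- tr$out_shape
    } else if (ld$type == "pool") {
      pm <- pool_matrix(shape, ld$window)
      built[[li]] <- list(type = "pool", P = pm$P, in_shape = shape,
                          out_shape = pm$out_shape, desc = ld)
      shape <- pm$out_shape
    } else if (ld$type == "dense") {
      n_in <- prod(shape)
      bound <- init_gain * sqrt(6 / (n_in + ld$units))
      built[[li]] <- list(type = "dense",
                          weights = matrix(rng(ld$units * n_in, bound),
                                           nrow = ld$units),
                          params = ld$params, in_shape = shape,
                          out_shape = c(ld$units, 1L, 1L), desc = ld)
      shape <- c(ld$units, 1L, 1L)
    } else stop("unknown layer type: ", ld$type, call. = FALSE)
  }
  structure(list(spec = spec, layers = built, seed = as.integer(seed)),
            class = "snn_network")
}

# materialize the per-timestep linear operator of a layer
layer_operator <- function(layer) {
  switch(layer$type,
    conv = {
      tr <- layer$triplets
      Matrix::sparseMatrix(i = tr$i, j = tr$j, x = layer$weights[tr$widx],
                           dims = c(tr$n_out, tr$n_in))
    },
    pool = layer$P,
    dense = layer$weights
  )
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("<snn_network> input (%s), %d classes, %d layers\n",
              paste(x$spec$input_shape, collapse = "x"),
              x$spec$n_classes, length(x$layers)))
  for (l in x$layers) {
    cat(sprintf("  %-5s -> (%s)\n", l$type,
                paste(l$out_shape, collapse = "x")))
  }
  invisible(x)
}

#' Save / load a fitted network
#'
#' The network is stored as a single archive: the layer configuration as a
#' plain list plus one named weight array per trainable layer.
#'
#' @param net an `snn_network`.
#' @param path file path (`.rds` archive).
#' @return `read_network` returns the `snn_network`; `write_network`
#'   returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "snn_network"))
  weights <- lapply(net$layers, function(l) l$weights)
  names(weights) <- sprintf("layer%02d_%s", seq_along(net$layers),
                            vapply(net$layers, `[[`, "", "type"))
  saveRDS(list(config = network_to_config(net$spec), seed = net$seed,
               weights = weights), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  arc <- readRDS(path)
  net <- build_network(config_to_network(arc$config), seed = arc$seed)
  for (li in seq_along(net$layers)) {
    w <- arc$weights[[li]]
    if (!is.null(w)) net$layers[[li]]$weights <- w
  }
  net
}

#' Network specification as a plain config list (YAML-ready)
#'
#' @param spec a [network_spec()].
#' @param config a list produced by `network_to_config` (or parsed from
#'   YAML/JSON).
#' @return `network_to_config` a plain list; `config_to_network` a
#'   [network_spec()].
#' @export
network_to_config <- function(spec) {
  list(
    input_shape = as.integer(spec$input_shape),
    n_classes = spec$n_classes,
    layers = lapply(spec$layers, function(ld) {
      out <- ld[setdiff(names(ld), "params")]
      if (!is.null(ld$params)) out$params <- unclass(ld$params)
      out
    })
  )
}

#' @rdname network_to_config
#' @export
config_to_network <- function(config) {
  layers <- lapply(config$layers, function(ld) {
    p <- if (!is.null(ld$params)) do.call(neuron_params, ld$params)
    switch(ld$type,
      conv = layer_conv(ld$out_channels, ld$kernel, ld$stride, ld$pad, p),
      pool = layer_pool(ld$window),
      dense = layer_dense(ld$units, p),
      stop("unknown layer type in config: ", ld$type, call. = FALSE)
    )
  })
  network_spec(layers, config$input_shape, config$n_classes)
}
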