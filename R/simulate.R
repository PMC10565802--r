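#' Simulate a spiking forward pass
#'
#' Runs the discrete-time leaky integrate-and-fire recurrence through every
#' layer and records membrane potentials and spike trains. Within one
#' timestep activity flows through all layers (no axonal delay); across
#' timesteps each LIF neuron integrates, leaks and resets.
#'
#' @param net an `snn_network` from [build_network()] (possibly trained).
#' @param input a [spike_tensor()] whose `(channel, y, x)` shape matches
#'   `net$spec$input_shape`. In `mode = "relaxed"` a real-valued array of
#'   the same shape is accepted.
#' @param mode `"spike"` (binary threshold dynamics, default) or
#'   `"relaxed"`: the hard threshold is replaced by the surrogate's smooth
#'   antiderivative so the whole pass is differentiable; used by the
#'   finite-difference diagnostics.
#' @param noise optional network-level noise injected into the spikes each
#'   hidden LIF layer delivers downstream; a list as produced by
#'   [network_noise()].
#' @return an `snn_forward_record`: per-layer membrane potentials `U`
#'   (neurons x T) and spike trains `S`, plus `output_spikes`
#'   (n_classes x T).
#' @export
simulate_forward <- function(net, input, mode = c("spike", "relaxed"),
                             noise = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "snn_network"))
  if (mode == "spike") {
    if (!is_spike_tensor(input)) input <- spike_tensor(input)
  } else if (length(dim(input)) == 3L) {
    dim(input) <- c(1L, dim(input))
  }
  d <- dim(input)
  if (!all(d[1:3] == net$spec$input_shape)) {
    stop(sprintf("input shape (%s) does not match network input (%s)",
                 paste(d[1:3], collapse = "x"),
                 paste(net$spec$input_shape, collapse = "x")),
         call. = FALSE)
  }
  T <- d[4]
  S_prev <- matrix(as.numeric(input), nrow = prod(d[1:3]), ncol = T)
  n_layers <- length(net$layers)
  rec <- vector("list", n_layers)
  if (!is.null(noise)) noise_rng <- noise_stream(noise)
  for (li in seq_len(n_layers)) {
    layer <- net$layers[[li]]
    W <- layer_operator(layer)
    A <- as.matrix(W %*% S_prev)
    if (layer$type == "pool") {
      S <- A
      rec[[li]] <- list(type = "pool", S = S)
    } else {
      p <- layer$params
      n <- nrow(A)
      U <- matrix(0, n, T)
      S <- matrix(0, n, T)
      u_carry <- numeric(n)
      for (t in seq_len(T)) {
        u <- p$leak_factor * u_carry + A[, t]
        s <- if (mode == "spike") as.numeric(u >= p$threshold)
             else surrogate_spike_soft(u, p)
        U[, t] <- u
        S[, t] <- s
        u_carry <- if (p$reset_mode == "subtract") u - p$threshold * s
                   else u * (1 - s)
      }
      rec[[li]] <- list(type = layer$type, U = U, S = S)
      # network-level noise perturbs only the spikes delivered downstream,
      # never the layer's own membrane/reset dynamics or the readout layer
      if (!is.null(noise) && li < n_layers && layer$type != "pool") {
        S <- perturb_layer_spikes(S, noise, noise_rng, li)
      }
    }
    S_prev <- S
  }
  out <- rec[[n_layers]]$S
  structure(list(layers = rec, output_spikes = out, T = T, mode = mode,
                 input_dim = d),
            class = "snn_forward_record")
}

#' @export
print.snn_forward_record <- function(x, ...) {
  cat(sprintf("<snn_forward_record> %d layers, T = %d, mode = %s\n",
              length(x$layers), x$T, x$mode))
  cat(sprintf("  output spike counts: %s\n",
              paste(round(rowSums(x$output_spikes), 3), collapse = ", ")))
  invisible(x)
}

#' Class scores from a forward record
#'
#' The class score of output neuron `c` is its total spike count over the
#' simulation window; the decision is the most-spiking output neuron, with
#' ties broken toward the lowest class index.
#'
#' @param record an `snn_forward_record`.
#' @return a `class_scores` list: `scores` (numeric vector, one per class)
#'   and `winner` (1-based class index).
#' @export
class_scores <- function(record) {
  stopifnot(inherits(record, "snn_forward_record"))
  scores <- rowSums(record$output_spikes)
  structure(list(scores = unname(scores), winner = which.max(scores)),
            class = "class_scores")
}

#' @export
print.class_scores <- function(x, ...) {
  cat(sprintf("<class_scores> winner = class %d; scores: %s\n", x$winner,
              paste(round(x$scores, 3), collapse = ", ")))
  invisible(x)
}

#' Network-level noise configuration
#'
#' Describes noise injected into the spike trains hidden layers deliver to
#' their successors during [simulate_forward()]. Deletion drops each
#' delivered spike independently with probability `level`. Jitter delays
#' each delivered spike by `max(0, d)` timesteps with `d` uniform on
#' `[-level, level]`; an online simulation cannot advance a spike into its
#' own past, so negative draws act as no delay. Delays beyond the window
#' are clipped to the last timestep; colliding spikes merge by OR.
#'
#' @param kind `"deletion"` or `"jitter"`.
#' @param level deletion probability in `[0, 1]`, or maximum jitter in
#'   timesteps.
#' @param seed integer seed; the draw stream is private to one forward
#'   pass.
#' @param layers optional integer vector restricting which hidden layers
#'   are perturbed (default: all).
#' @return a `network_noise` list accepted by [simulate_forward()].
#' @export
network_noise <- function(kind = c("deletion", "jitter"), level, seed,
                          layers = NULL) {
  kind <- match.arg(kind)
  if (kind == "deletion" && (level < 0 || level > 1)) {
    stop("deletion level is a probability in [0, 1]", call. = FALSE)
  }
  if (kind == "jitter" && level < 0) stop("jitter level must be >= 0", call. = FALSE)
  structure(list(kind = kind, level = level, seed = as.integer(seed),
                 layers = layers),
            class = "network_noise")
}

# a private RNG stream so forward-pass noise never disturbs the caller's RNG
noise_stream <- function(noise) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(noise$seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    s
  })
  env
}

with_noise_stream <- function(env, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  assign(".Random.seed", env$state, globalenv())
  on.exit({
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

perturb_layer_spikes <- function(S, noise, rng, layer_index) {
  if (!is.null(noise$layers) && !(layer_index %in% noise$layers)) return(S)
  if (noise$level == 0) return(S)
  with_noise_stream(rng, {
    idx <- which(S == 1)
    if (length(idx) == 0) {
      S
    } else if (noise$kind == "deletion") {
      drop <- stats::runif(length(idx)) < noise$level
      S[idx[drop]] <- 0
      S
    } else {
      T <- ncol(S); n <- nrow(S)
      t0 <- ((idx - 1) %/% n) + 1
      neuron <- ((idx - 1) %% n) + 1
      shift <- pmax(0L, sample(seq(-noise$level, noise$level),
                               length(idx), replace = TRUE))
      t1 <- pmin(T, t0 + shift)
      out <- matrix(0, n, T)
      out[cbind(neuron, t1)] <- 1
      out
    }
  })
}
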