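# Backpropagation through time.
#
# Gradients flow along three routes per LIF layer: (i) spike -> downstream
# synaptic input at the same timestep, (ii) membrane -> next-timestep
# membrane via the leak, (iii) spike -> next-timestep membrane via the
# reset. The non-differentiable threshold is replaced by the surrogate
# derivative rho(U) evaluated on the recorded membrane trajectory.
#
# g_out: (n_classes x T) gradient of the objective w.r.t. the output
# spike train. Returns the gradient w.r.t. the input (n_in x T) and,
# optionally, per-layer weight gradients.
snn_backward <- function(net, record, input, g_out, want_weights = FALSE) {
  d <- record$input_dim
  S0 <- matrix(as.numeric(input), nrow = prod(d[1:3]), ncol = d[4])
  T <- d[4]
  n_layers <- length(net$layers)
  S_below <- c(list(S0), lapply(record$layers[-n_layers], `[[`, "S"))
  G <- g_out
  wgrads <- vector("list", n_layers)
  for (li in rev(seq_len(n_layers))) {
    layer <- net$layers[[li]]
    if (layer$type == "pool") {
      G <- as.matrix(Matrix::t(layer$P) %*% G)
      next
    }
    p <- layer$params
    U <- record$layers[[li]]$U
    S <- record$layers[[li]]$S
    n <- nrow(U)
    GU <- matrix(0, n, T)
    gU_next <- numeric(n)
    lam <- p$leak_factor
    for (t in rev(seq_len(T))) {
      if (p$reset_mode == "subtract") {
        gs <- G[, t] - lam * p$threshold * gU_next
        gU <- gs * surrogate_spike_derivative(U[, t], p) + lam * gU_next
      } else {
        gs <- G[, t] - lam * U[, t] * gU_next
        gU <- gs * surrogate_spike_derivative(U[, t], p) +
          lam * (1 - S[, t]) * gU_next
      }
      GU[, t] <- gU
      gU_next <- gU
    }
    if (want_weights) {
      S_prev <- S_below[[li]]
      if (layer$type == "dense") {
        wgrads[[li]] <- GU %*% t(S_prev)
      } else {
        tr <- layer$triplets
        contrib <- rowSums(GU[tr$i, , drop = FALSE] *
                             S_prev[tr$j, , drop = FALSE])
        gw <- numeric(tr$n_weights)
        agg <- rowsum(contrib, tr$widx)
        gw[as.integer(rownames(agg))] <- agg
        wgrads[[li]] <- gw
      }
    }
    W <- layer_operator(layer)
    G <- as.matrix(Matrix::t(W) %*% GU)
  }
  list(input_grad = G, weight_grads = wgrads)
}

#' Gradient of the class score with respect to the input
#'
#' Backpropagates \eqn{\partial S_C / \partial \mathrm{input}} through time
#' using the surrogate spike derivative at every threshold crossing, where
#' \eqn{S_C} is the spike count of output neuron `target_class`. Each entry
#' `(c, y, x, t)` of the result estimates how much the class score would
#' change if a spike could be added or removed at that point of the 3D
#' input space.
#'
#' @param net an `snn_network`.
#' @param input a [spike_tensor()] (or, in relaxed mode, a real array of
#'   the same shape).
#' @param target_class 1-based class index.
#' @param mode forwarded to [simulate_forward()]; `"relaxed"` makes the
#'   pass smooth so the gradient is checkable by finite differences.
#' @return numeric array with the input's `(channel, y, x, t)` shape.
#' @export
input_gradient <- function(net, input, target_class,
                           mode = c("spike", "relaxed")) {
  mode <- match.arg(mode)
  n_classes <- net$spec$n_classes
  if (!is.numeric(target_class) || length(target_class) != 1 ||
      target_class < 1 || target_class > n_classes) {
    stop(sprintf("target_class must be in 1..%d", n_classes), call. = FALSE)
  }
  rec <- simulate_forward(net, input, mode = mode)
  g_out <- matrix(0, n_classes, rec$T)
  g_out[target_class, ] <- 1
  g <- snn_backward(net, rec, input, g_out)$input_grad
  array(g, dim = rec$input_dim)
}

# class score of the relaxed (smooth) pass; the target of the
# finite-difference oracle used in the tests
relaxed_class_score <- function(net, input, target_class) {
  rec <- simulate_forward(net, input, mode = "relaxed")
  sum(rec$output_spikes[target_class, ])
}

#' Training configuration
#'
#' Training minimizes the squared error between each output neuron's spike
#' count and a per-class target: the true class is driven toward
#' `target_high` spikes, all other classes toward `target_low`. This is
#' the standard count-target objective for surrogate-gradient SNN
#' classifiers.
#'
#' @param epochs number of passes over the data.
#' @param learning_rate SGD step size. Gradients of the count loss sum
#'   over the whole window, so steps are small; larger rates tend to
#'   silence or saturate the spiking layers.
#' @param target_high,target_low desired output spike counts for the true
#'   class and the other classes; `NULL` picks 50% / 5% of the simulation
#'   window at fit time.
#' @param seed RNG seed controlling shuffling (training is bit-reproducible
#'   per seed).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 20, learning_rate = 2e-4,
                         target_high = NULL, target_low = NULL, seed = 1L) {
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 target_high = target_high, target_low = target_low,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a spiking network on labeled spike tensors
#'
#' Plain stochastic gradient descent with surrogate-gradient
#' backpropagation through time on the spike-count target loss (see
#' [train_config()]).
#'
#' @param net an `snn_network` (its initial weights are the starting
#'   point).
#' @param dataset a list of `list(input = spike_tensor, label = class)`
#'   samples, or a data frame / tibble with list-column `input` and column
#'   `label`.
#' @param config a [train_config()].
#' @return the fitted `snn_network`; the per-epoch loss/accuracy log is a
#'   tibble in `attr(net, "history")` and via [glance()].
#' @export
train_snn <- function(net, dataset, config = train_config()) {
  samples <- as_sample_list(dataset)
  if (length(samples) == 0) stop("dataset is empty", call. = FALSE)
  T <- n_timesteps(samples[[1]]$input)
  n_classes <- net$spec$n_classes
  hi <- config$target_high %||% max(2, round(0.5 * T))
  lo <- config$target_low %||% round(0.05 * T)
  set.seed(config$seed)
  lr <- config$learning_rate
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(samples))
    loss <- 0; correct <- 0
    for (si in ord) {
      smp <- samples[[si]]
      rec <- simulate_forward(net, smp$input)
      counts <- rowSums(rec$output_spikes)
      targets <- rep(lo, n_classes)
      targets[smp$label] <- hi
      resid <- counts - targets
      loss <- loss + sum(resid^2)
      if (which.max(counts) == smp$label) correct <- correct + 1
      g_out <- matrix(2 * resid, n_classes, rec$T)
      bw <- snn_backward(net, rec, smp$input, g_out, want_weights = TRUE)
      for (li in seq_along(net$layers)) {
        gw <- bw$weight_grads[[li]]
        if (!is.null(gw)) {
          net$layers[[li]]$weights <- net$layers[[li]]$weights - lr * gw
        }
      }
    }
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = loss / length(samples),
      accuracy = correct / length(samples)
    )
  }
  attr(net, "history") <- dplyr::bind_rows(hist)
  attr(net, "train_config") <- config
  net
}

as_sample_list <- function(dataset) {
  if (is.data.frame(dataset)) {
    purrr::map2(dataset$input, dataset$label,
                function(i, l) list(input = i, label = l))
  } else {
    dataset
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summaries of a fitted spiking network
#'
#' `tidy()` returns one row per layer; `glance()` returns a one-row
#' summary including the final training loss and accuracy when the network
#' has been fitted with [train_snn()].
#'
#' @param x an `snn_network`.
#' @param ... unused.
#' @export
tidy.snn_network <- function(x, ...) {
  tibble::tibble(
    layer = seq_along(x$layers),
    type = vapply(x$layers, `[[`, "", "type"),
    out_shape = vapply(x$layers, function(l)
      paste(l$out_shape, collapse = "x"), ""),
    n_weights = vapply(x$layers, function(l)
      length(l$weights %||% numeric()), integer(1))
  )
}

#' @rdname tidy.snn_network
#' @export
glance.snn_network <- function(x, ...) {
  h <- attr(x, "history")
  tibble::tibble(
    n_layers = length(x$layers),
    n_weights = sum(tidy(x)$n_weights),
    n_classes = x$spec$n_classes,
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_accuracy = if (is.null(h)) NA_real_ else h$accuracy[nrow(h)]
  )
}
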