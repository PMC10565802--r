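#' Binary spike tensor
#'
#' The universal spiking currency of the package: a binary array indexed
#' `(channel, y, x, t)`. A spike tensor is what the neural encoders emit,
#' what networks consume, and the domain over which 3D attribution maps
#' are defined.
#'
#' @param values numeric array with 4 dimensions `(channel, y, x, t)`;
#'   every entry must be 0 or 1. A 3D array `(y, x, t)` is promoted to a
#'   single channel.
#' @return an object of class `spike_tensor` (a 4D 0/1 array with class
#'   attribute).
#' @examples
#' st <- spike_tensor(array(0, dim = c(1, 2, 2, 4)))
#' n_timesteps(st)
#' @export
spike_tensor <- function(values) {
  if (is.null(dim(values))) stop("`values` must be an array", call. = FALSE)
  if (length(dim(values)) == 3L) {
    dim(values) <- c(1L, dim(values))
  }
  if (length(dim(values)) != 4L) {
    stop("`values` must have dims (channel, y, x, t)", call. = FALSE)
  }
  if (dim(values)[4] < 1L) stop("need at least one timestep", call. = FALSE)
  if (!all(values %in% c(0, 1))) {
    stop("spike tensor entries must be binary (0/1)", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(values, class = c("spike_tensor", "array"))
}

#' @rdname spike_tensor
#' @param x object to test / query.
#' @export
is_spike_tensor <- function(x) inherits(x, "spike_tensor")

#' @rdname spike_tensor
#' @export
n_timesteps <- function(x) dim(x)[4]

#' @export
print.spike_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<spike_tensor> %d channel(s), %d x %d grid, %d timesteps, %d spikes\n",
    d[1], d[2], d[3], d[4], sum(x)
  ))
  invisible(x)
}

# strip class, return plain 4D array (internal)
as_plain_array <- function(x) {
  y <- unclass(x)
  attr(y, "class") <- NULL
  y
}

#' Empty spike tensor of a given shape
#'
#' The canonical "no spike" baseline used by the integrated-gradients path
#' for event data and by spike-level insertion experiments.
#'
#' @param shape integer vector `(channel, y, x, t)` or a `spike_tensor`
#'   whose shape is copied.
#' @return all-zero `spike_tensor`.
#' @export
empty_like <- function(shape) {
  if (is_spike_tensor(shape)) shape <- dim(shape)
  spike_tensor(array(0, dim = shape))
}

#' Grayscale image container
#'
#' @param pixels integer-valued matrix (height x width), values 0..255.
#' @return a `gray_image`: an integer matrix with class attribute.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (any(pixels != round(pixels))) {
    stop("pixel values must be integers", call. = FALSE)
  }
  if (any(pixels < 0 | pixels > 255)) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, range [%d, %d]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
as.matrix.gray_image <- function(x, ...) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x))
  y
}
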