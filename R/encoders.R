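#' Encoder configuration
#'
#' Bundles the choice of neural coding and its parameters so pipelines can
#' pass "how images become spikes" around as a value.
#'
#' @param coding one of `"ttfs"`, `"phase"`, `"poisson"`, `"burst"`.
#' @param n_timesteps simulation window T. Defaults to 256 for every
#'   coding so cross-coding comparisons share a time axis (time-to-first-
#'   spike needs the full 0..255 window).
#' @param seed integer seed; required for the stochastic Poisson coding.
#' @param phase_period bits per oscillation cycle (phase coding).
#' @param burst_max_spikes maximum spikes per burst (burst coding).
#' @param ttfs_invert if `TRUE`, bright pixels fire first (the common
#'   latency-coding convention); default `FALSE`: the spike time equals
#'   the pixel value, so black fires at t = 0.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(coding = c("ttfs", "phase", "poisson", "burst"),
                           n_timesteps = 256L, seed = NULL,
                           phase_period = 8L, burst_max_spikes = 5L,
                           ttfs_invert = FALSE) {
  coding <- match.arg(coding)
  if (coding == "poisson" && is.null(seed)) {
    stop("poisson coding requires a seed", call. = FALSE)
  }
  if (n_timesteps < 1) stop("n_timesteps must be >= 1", call. = FALSE)
  structure(list(coding = coding, n_timesteps = as.integer(n_timesteps),
                 seed = if (!is.null(seed)) as.integer(seed),
                 phase_period = as.integer(phase_period),
                 burst_max_spikes = as.integer(burst_max_spikes),
                 ttfs_invert = ttfs_invert),
            class = "encoder_config")
}

#' Encode a grayscale image as spikes
#'
#' Dispatches on `config$coding`; see [ttfs_encode()], [phase_encode()],
#' [poisson_encode()], [burst_encode()].
#'
#' @param img a [gray_image()] (or a plain 0..255 integer matrix).
#' @param config an [encoder_config()].
#' @return a single-channel [spike_tensor()].
#' @export
encode_image <- function(img, config) {
  stopifnot(inherits(config, "encoder_config"))
  switch(config$coding,
    ttfs = ttfs_encode(img, invert = config$ttfs_invert),
    phase = phase_encode(img, T = config$n_timesteps,
                         period = config$phase_period),
    poisson = poisson_encode(img, T = config$n_timesteps,
                             seed = config$seed),
    burst = burst_encode(img, T = config$n_timesteps,
                         max_spikes = config$burst_max_spikes)
  )
}

as_gray <- function(img) {
  if (!inherits(img, "gray_image")) img <- gray_image(img)
  img
}

#' Time-to-first-spike (latency) coding
#'
#' Each pixel emits exactly one spike at the timestep equal to its value,
#' over a window of 256 timesteps: the equivalent of a black pixel is a
#' spike at the earliest time, a white pixel fires at the last timestep.
#' With `invert = TRUE` the mapping is reversed (bright pixels fire
#' first), the convention common elsewhere in the latency-coding
#' literature.
#'
#' @param img a [gray_image()].
#' @param invert reverse the value-to-latency mapping.
#' @return a [spike_tensor()] of shape `(1, height, width, 256)` with one
#'   spike per pixel.
#' @export
ttfs_encode <- function(img, invert = FALSE) {
  img <- as_gray(img)
  H <- nrow(img); W <- ncol(img)
  v <- as.integer(img)
  if (invert) v <- 255L - v
  arr <- array(0, dim = c(1L, H, W, 256L))
  yy <- rep(seq_len(H), times = W)
  xx <- rep(seq_len(W), each = H)
  arr[cbind(1L, yy, xx, v + 1L)] <- 1
  st <- spike_tensor(arr)
  attr(st, "ttfs_invert") <- invert
  st
}

#' Decode a time-to-first-spike tensor back to an image
#'
#' Inverse of [ttfs_encode()] for round-trip checks: the pixel value is
#' the spike's timestep.
#'
#' @param spikes a [spike_tensor()] with at most one spike per pixel.
#' @param invert must match the encoding direction (taken from the
#'   tensor's attribute when present).
#' @param missing value for pixels with no spike: `"error"` (default) or
#'   an integer sentinel in 0..255.
#' @return a [gray_image()].
#' @export
ttfs_decode <- function(spikes, invert = attr(spikes, "ttfs_invert") %||% FALSE,
                        missing = "error") {
  stopifnot(is_spike_tensor(spikes), dim(spikes)[1] == 1L)
  d <- dim(spikes)
  H <- d[2]; W <- d[3]
  counts <- apply(spikes, c(2, 3), sum)
  if (any(counts > 1)) {
    stop("ttfs_decode: some pixels carry more than one spike", call. = FALSE)
  }
  if (any(counts == 0)) {
    if (identical(missing, "error")) {
      stop("ttfs_decode: some pixels carry no spike", call. = FALSE)
    }
  }
  # first (only) spike time per pixel, 0-based
  tfirst <- apply(spikes, c(2, 3), function(tr) {
    w <- which(tr == 1)
    if (length(w) == 0) NA_integer_ else w[1] - 1L
  })
  if (anyNA(tfirst)) tfirst[is.na(tfirst)] <- as.integer(missing)
  v <- tfirst
  if (invert) v <- 255L - v
  gray_image(matrix(as.integer(v), H, W))
}

#' Poisson (rate) coding
#'
#' Every cell `(y, x, t)` is an independent Bernoulli draw with spike
#' probability `v / 255`, so the firing rate codes the intensity.
#' Bit-reproducible per seed.
#'
#' @param img a [gray_image()].
#' @param T number of timesteps.
#' @param seed integer seed.
#' @return a [spike_tensor()] of shape `(1, height, width, T)`.
#' @export
poisson_encode <- function(img, T = 256L, seed) {
  img <- as_gray(img)
  if (missing(seed) || is.null(seed)) {
    stop("poisson_encode requires a seed", call. = FALSE)
  }
  H <- nrow(img); W <- ncol(img)
  p <- as.numeric(img) / 255
  set.seed(seed)
  draws <- array(stats::runif(H * W * T), dim = c(H, W, T))
  arr <- array(as.numeric(draws < rep(array(p, dim = c(H, W)), times = T)),
               dim = c(H, W, T))
  dim(arr) <- c(1L, H, W, T)
  spike_tensor(arr)
}

#' Phase coding
#'
#' The 8-bit binary expansion of the pixel value is played out over the
#' phases of an oscillation cycle: within each period of `period`
#' timesteps, a spike occurs at phase p iff bit p of the value is set
#' (most-significant bit first), and the pattern repeats for T / period
#' cycles. Spikes per period therefore equal the popcount of the value.
#'
#' @param img a [gray_image()].
#' @param T number of timesteps; must be a multiple of `period`.
#' @param period bits per cycle (default 8, matching 8-bit intensities).
#' @return a [spike_tensor()].
#' @export
phase_encode <- function(img, T = 256L, period = 8L) {
  img <- as_gray(img)
  if (T %% period != 0) {
    stop("T must be a multiple of the phase period", call. = FALSE)
  }
  H <- nrow(img); W <- ncol(img)
  v <- as.integer(img)
  # bit p (0 = MSB) of an 8-bit value; phases beyond 8 bits are silent
  arr <- array(0, dim = c(H, W, T))
  for (ph in seq_len(min(period, 8L))) {
    bit <- bitwAnd(bitwShiftR(v, 8L - ph), 1L)
    if (any(bit == 1L)) {
      for (cyc in seq_len(T %/% period)) {
        t <- (cyc - 1L) * period + ph
        arr[, , t] <- arr[, , t] + matrix(bit, H, W)
      }
    }
  }
  dim(arr) <- c(1L, H, W, T)
  spike_tensor(pmin(arr, 1))
}

#' Burst coding
#'
#' The intensity is coded jointly by spike count and inter-spike interval:
#' a pixel of value v emits `N(v) = ceiling(max_spikes * v / 255)` spikes
#' starting at t = 0, with inter-spike interval
#' `ISI(v) = max(1, ceiling((T - 1) * (1 - v / 255)))` — brighter pixels
#' burst more spikes at shorter intervals.
#'
#' @param img a [gray_image()].
#' @param T number of timesteps.
#' @param max_spikes maximum spikes per burst (value 255).
#' @return a [spike_tensor()].
#' @export
burst_encode <- function(img, T = 256L, max_spikes = 5L) {
  img <- as_gray(img)
  if (max_spikes < 1) stop("max_spikes must be >= 1", call. = FALSE)
  H <- nrow(img); W <- ncol(img)
  arr <- array(0, dim = c(1L, H, W, T))
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      v <- img[y, x]
      n <- ceiling(max_spikes * v / 255)
      if (n == 0) next
      isi <- if (n > 1) max(1L, ceiling((T - 1) * (1 - v / 255))) else 1L
      times <- (seq_len(n) - 1L) * isi   # 0-based
      if (max(times) > T - 1L) {
        stop(sprintf(
          "burst_encode: %d spikes at interval %d do not fit in T = %d",
          n, isi, T), call. = FALSE)
      }
      arr[1L, y, x, times + 1L] <- 1
    }
  }
  spike_tensor(arr)
}
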