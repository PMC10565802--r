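#' Toy dataset configuration
#'
#' Parameters of the synthetic fixtures that stand in for external image
#' and event-camera datasets: class-separable oriented-bar images and
#' moving-dot event streams. Generators are pure functions of this config
#' (bit-reproducible per seed).
#'
#' @param n_classes number of classes (>= 2).
#' @param n_samples_per_class samples generated per class.
#' @param image_size square image / sensor side length (>= 8).
#' @param noise_level salt-noise probability per pixel (images) /
#'   noise-event rate (event streams), in `[0, 1]`.
#' @param n_timesteps window length T for event streams.
#' @param seed integer seed.
#' @return a `toy_dataset_config` list.
#' @export
toy_dataset_config <- function(n_classes = 3L, n_samples_per_class = 10L,
                               image_size = 8L, noise_level = 0.1,
                               n_timesteps = 20L, seed = 1L) {
  stopifnot(n_classes >= 2, image_size >= 8, noise_level >= 0,
            noise_level <= 1)
  structure(list(n_classes = as.integer(n_classes),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 image_size = as.integer(image_size),
                 noise_level = noise_level,
                 n_timesteps = as.integer(n_timesteps),
                 seed = as.integer(seed)),
            class = "toy_dataset_config")
}

#' Oriented-bar class template
#'
#' Class `c` of `n_classes` is a bar through the image center at angle
#' `180 * (c - 1) / n_classes` degrees, intensity 200 on background 30.
#'
#' @param class 1-based class index.
#' @param n_classes number of classes.
#' @param image_size side length.
#' @return a [gray_image()].
#' @export
toy_image_template <- function(class, n_classes, image_size) {
  theta <- pi * (class - 1) / n_classes
  ctr <- (image_size + 1) / 2
  # distance of each pixel center from the bar's axis
  g <- expand.grid(y = seq_len(image_size), x = seq_len(image_size))
  dist <- abs(-sin(theta) * (g$x - ctr) + cos(theta) * (g$y - ctr))
  px <- matrix(30L, image_size, image_size)
  px[cbind(g$y, g$x)[dist <= image_size / 8, , drop = FALSE]] <- 200L
  gray_image(px)
}

#' Generate labeled toy images
#'
#' Each sample is its class template with salt noise: every pixel is
#' independently replaced by 255 with probability `noise_level`.
#'
#' @param cfg a [toy_dataset_config()].
#' @return a tibble with list-column `image` ([gray_image()]s) and column
#'   `label` (1-based class).
#' @export
make_toy_images <- function(cfg) {
  stopifnot(inherits(cfg, "toy_dataset_config"))
  set.seed(cfg$seed)
  rows <- list()
  for (cl in seq_len(cfg$n_classes)) {
    tmpl <- as.matrix(toy_image_template(cl, cfg$n_classes, cfg$image_size))
    for (s in seq_len(cfg$n_samples_per_class)) {
      px <- tmpl
      if (cfg$noise_level > 0) {
        salt <- matrix(stats::runif(length(px)) < cfg$noise_level,
                       nrow(px), ncol(px))
        px[salt] <- 255L
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        image = list(gray_image(px)), label = cl)
    }
  }
  dplyr::bind_rows(rows)
}

#' Event-stream container
#'
#' A sparse list of DVS-style events, one record per row, 0-based
#' coordinates, sorted by `t`, then `y`, then `x`.
#'
#' @param records a data frame with integer columns `x`, `y`, `t`,
#'   `polarity` (0 = OFF, 1 = ON).
#' @param sensor_shape integer `(height, width, T)`.
#' @return an `event_stream` tibble with a `sensor_shape` attribute.
#' @export
event_stream <- function(records, sensor_shape) {
  stopifnot(all(c("x", "y", "t", "polarity") %in% names(records)),
            length(sensor_shape) == 3)
  H <- sensor_shape[1]; W <- sensor_shape[2]; T <- sensor_shape[3]
  rc <- tibble::as_tibble(records)[, c("x", "y", "t", "polarity")]
  if (nrow(rc) > 0) {
    if (any(rc$x < 0 | rc$x >= W | rc$y < 0 | rc$y >= H |
            rc$t < 0 | rc$t >= T)) {
      stop("event out of sensor bounds", call. = FALSE)
    }
    if (!all(rc$polarity %in% c(0, 1))) {
      stop("polarity must be 0 or 1", call. = FALSE)
    }
    rc <- rc[order(rc$t, rc$y, rc$x), ]
  }
  structure(rc, class = c("event_stream", class(tibble::tibble())),
            sensor_shape = as.integer(sensor_shape))
}

#' Generate labeled toy event streams
#'
#' Class `c` is a bright dot translating in direction
#' `360 * (c - 1) / n_classes` degrees across the sensor over T timesteps,
#' starting at the center with unit speed and clamped at the borders. The
#' dot emits an ON event at its position each timestep and an OFF event at
#' its previous position from the second timestep on, so a noise-free
#' stream has exactly `1 + 2 (T - 1)` events. Noise adds
#' `floor(noise_level * 2 * T)` spurious events at uniformly random
#' coordinates and polarity.
#'
#' @param cfg a [toy_dataset_config()].
#' @return a tibble with list-column `stream` (`event_stream`s) and column
#'   `label`.
#' @export
make_toy_event_streams <- function(cfg) {
  stopifnot(inherits(cfg, "toy_dataset_config"))
  set.seed(cfg$seed)
  sz <- cfg$image_size; T <- cfg$n_timesteps
  rows <- list()
  for (cl in seq_len(cfg$n_classes)) {
    phi <- 2 * pi * (cl - 1) / cfg$n_classes
    for (s in seq_len(cfg$n_samples_per_class)) {
      ctr <- (sz - 1) / 2
      pos <- matrix(NA_integer_, T, 2)   # (x, y), 0-based
      for (t in seq_len(T)) {
        px <- round(ctr + (t - 1) * cos(phi))
        py <- round(ctr + (t - 1) * sin(phi))
        pos[t, ] <- c(min(max(px, 0), sz - 1), min(max(py, 0), sz - 1))
      }
      ev <- data.frame(x = pos[1, 1], y = pos[1, 2], t = 0L, polarity = 1L)
      for (t in 2:T) {
        ev <- rbind(ev,
          data.frame(x = pos[t - 1, 1], y = pos[t - 1, 2], t = t - 1L,
                     polarity = 0L),
          data.frame(x = pos[t, 1], y = pos[t, 2], t = t - 1L,
                     polarity = 1L))
      }
      n_noise <- floor(cfg$noise_level * 2 * T)
      if (n_noise > 0) {
        ev <- rbind(ev, data.frame(
          x = sample.int(sz, n_noise, replace = TRUE) - 1L,
          y = sample.int(sz, n_noise, replace = TRUE) - 1L,
          t = sample.int(T, n_noise, replace = TRUE) - 1L,
          polarity = sample(c(0L, 1L), n_noise, replace = TRUE)))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        stream = list(event_stream(ev, c(sz, sz, T))), label = cl)
    }
  }
  dplyr::bind_rows(rows)
}

#' Convert between event streams and spike tensors
#'
#' Polarity maps to the channel axis (OFF -> channel 1, ON -> channel 2,
#' the two-channel DVS convention); coinciding events merge by OR, so the
#' round trip is exact for deduplicated streams.
#'
#' @param stream an [event_stream()].
#' @return `events_to_tensor`: a `(2, height, width, T)` [spike_tensor()];
#'   `tensor_to_events`: an [event_stream()].
#' @export
events_to_tensor <- function(stream) {
  shp <- attr(stream, "sensor_shape")
  stopifnot(!is.null(shp))
  arr <- array(0, dim = c(2L, shp[1], shp[2], shp[3]))
  if (nrow(stream) > 0) {
    arr[cbind(stream$polarity + 1L, stream$y + 1L, stream$x + 1L,
              stream$t + 1L)] <- 1
  }
  spike_tensor(arr)
}

#' @rdname events_to_tensor
#' @param tensor a two-channel [spike_tensor()].
#' @export
tensor_to_events <- function(tensor) {
  stopifnot(is_spike_tensor(tensor), dim(tensor)[1] == 2L)
  d <- dim(tensor)
  idx <- which(as_plain_array(tensor) == 1, arr.ind = TRUE)
  ev <- data.frame(x = idx[, 3] - 1L, y = idx[, 2] - 1L,
                   t = idx[, 4] - 1L, polarity = idx[, 1] - 1L)
  event_stream(ev, c(d[2], d[3], d[4]))
}

#' Read and write event streams as CSV
#'
#' Plain-text dialect: a preamble comment line `# height width T`, a
#' header `x,y,t,polarity`, then one record per line. `write_events`
#' followed by `read_events` is the identity.
#'
#' @param stream an [event_stream()].
#' @param path file path.
#' @return `read_events` an `event_stream`; `write_events` the path,
#'   invisibly.
#' @export
write_events <- function(stream, path) {
  shp <- attr(stream, "sensor_shape")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d %d", shp[1], shp[2], shp[3]), con)
  writeLines("x,y,t,polarity", con)
  if (nrow(stream) > 0) {
    writeLines(sprintf("%d,%d,%d,%d", stream$x, stream$y, stream$t,
                       stream$polarity), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !grepl("^# ", lines[1])) {
    stop("line 1: expected preamble '# height width T'", call. = FALSE)
  }
  shp <- suppressWarnings(as.integer(strsplit(sub("^# ", "", lines[1]),
                                              "\\s+")[[1]]))
  if (length(shp) != 3 || anyNA(shp)) {
    stop("line 1: malformed preamble", call. = FALSE)
  }
  if (trimws(lines[2]) != "x,y,t,polarity") {
    stop("line 2: expected header 'x,y,t,polarity'", call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(event_stream(data.frame(x = integer(), y = integer(),
                                   t = integer(), polarity = integer()),
                        shp))
  }
  parts <- strsplit(body, ",")
  bad <- which(lengths(parts) != 4)
  if (length(bad) > 0) {
    stop(sprintf("line %d: expected 4 comma-separated fields", bad[1] + 2L),
         call. = FALSE)
  }
  m <- suppressWarnings(matrix(as.integer(unlist(parts)), ncol = 4,
                               byrow = TRUE))
  if (anyNA(m)) {
    stop(sprintf("line %d: non-integer field",
                 which(rowSums(is.na(m)) > 0)[1] + 2L), call. = FALSE)
  }
  ev <- data.frame(x = m[, 1], y = m[, 2], t = m[, 3], polarity = m[, 4])
  oob <- which(ev$x < 0 | ev$x >= shp[2] | ev$y < 0 | ev$y >= shp[1] |
                 ev$t < 0 | ev$t >= shp[3] | !(ev$polarity %in% 0:1))
  if (length(oob) > 0) {
    stop(sprintf("line %d: record out of bounds", oob[1] + 2L), call. = FALSE)
  }
  event_stream(ev, shp)
}

#' Read and write grayscale images
#'
#' PNG (8-bit grayscale, via the png package) and a plain-text array
#' format (whitespace-separated integers, one image row per line).
#'
#' @param img a [gray_image()].
#' @param path file path.
#' @return readers return a [gray_image()]; writers the path, invisibly.
#' @export
write_image_png <- function(img, path) {
  img <- as_gray(img)
  png::writePNG(as.matrix(img) / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  gray_image(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)))
}

#' @rdname write_image_png
#' @export
write_image_text <- function(img, path) {
  img <- as_gray(img)
  utils::write.table(as.matrix(img), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_text <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  gray_image(m)
}

#' Encode a toy image table into labeled spike tensors
#'
#' Convenience bridge from [make_toy_images()] to [train_snn()].
#'
#' @param images tibble with list-column `image` and column `label`.
#' @param encoder an [encoder_config()].
#' @return a tibble with list-column `input` (spike tensors) and `label`.
#' @details For the stochastic Poisson coding each row is encoded with a
#'   seed derived from the config seed and the row index, so samples get
#'   independent spike patterns while the table stays reproducible.
#' @export
encode_dataset <- function(images, encoder) {
  inputs <- purrr::imap(images$image, function(im, i) {
    cfg <- encoder
    if (cfg$coding == "poisson") cfg$seed <- cfg$seed + as.integer(i)
    encode_image(im, cfg)
  })
  tibble::tibble(input = inputs, label = images$label)
}

#' Reference toy network architectures
#'
#' Small architectures sized for the synthetic fixtures: a two-layer
#' fully connected spiking classifier (`toy_network_spec`) and a
#' convolutional variant with a pooling stage (`toy_conv_network_spec`)
#' for methods restricted to convolutional layers.
#'
#' @param image_size input side length.
#' @param n_classes number of classes.
#' @param hidden hidden units of the dense variant.
#' @param channels input channels (2 for polarity-coded event tensors).
#' @param conv_channels feature maps of the conv variant.
#' @return a [network_spec()].
#' @export
toy_network_spec <- function(image_size = 8L, n_classes = 3L,
                             hidden = 16L, channels = 1L) {
  network_spec(list(
    layer_dense(hidden, neuron_params(threshold = 1, leak_factor = 0.9,
                                      surrogate_sharpness = 2)),
    layer_dense(n_classes, neuron_params(threshold = 1, leak_factor = 0.9,
                                         surrogate_sharpness = 2))
  ), input_shape = c(channels, image_size, image_size),
  n_classes = n_classes)
}

#' @rdname toy_network_spec
#' @export
toy_conv_network_spec <- function(image_size = 8L, n_classes = 3L,
                                  channels = 1L, conv_channels = 4L) {
  network_spec(list(
    layer_conv(conv_channels, kernel = 3, stride = 1, pad = 1,
               params = neuron_params(threshold = 1, leak_factor = 0.9,
                                      surrogate_sharpness = 2)),
    layer_pool(2),
    layer_dense(n_classes, neuron_params(threshold = 1, leak_factor = 0.9,
                                         surrogate_sharpness = 2))
  ), input_shape = c(channels, image_size, image_size),
  n_classes = n_classes)
}
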