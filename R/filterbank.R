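#' Gabor kernel parameters
#'
#' Parameter container for a single oriented Gabor kernel. The kernel is the
#' real part of a complex Gabor function: a cosine grating of wavelength
#' `lam` and phase `phi`, oriented at `theta`, under a Gaussian envelope of
#' standard deviation `sigma` and aspect ratio `gamma`.
#'
#' Defaults for the envelope follow common spiking-vision front ends:
#' `lam = window / 2`, `sigma = 0.8 * lam`, `gamma = 0.3`, `phi = 0`. The
#' zero-mean normalization applied at construction makes the overall kernel
#' scale second-order for downstream rank-order coding.
#'
#' @param window Odd kernel side length in pixels (>= 3).
#' @param theta Orientation in radians.
#' @param lam Wavelength of the cosine factor in pixels (> 0).
#' @param sigma Standard deviation of the Gaussian envelope in pixels (> 0).
#' @param gamma Spatial aspect ratio (> 0).
#' @param phi Phase offset in radians.
#' @return An object of class `gabor_params`.
#' @seealso [make_gabor_kernel()]
#' @export
gabor_params <- function(window, theta, lam = window / 2,
                         sigma = 0.8 * lam, gamma = 0.3, phi = 0) {
  check_odd_window(window)
  stopifnot(lam > 0, sigma > 0, gamma > 0)
  structure(
    list(window = as.integer(window), theta = theta, lam = lam,
         sigma = sigma, gamma = gamma, phi = phi),
    class = "gabor_params"
  )
}

#' Difference-of-Gaussians kernel parameters
#'
#' A DoG kernel is the difference of two centered isotropic Gaussians with
#' standard deviations `delta1` (center) and `delta2` (surround). With
#' `delta1 < delta2` the kernel is on-center (excitatory center, inhibitory
#' surround); swapping the two gives the off-center variant.
#'
#' @param window Odd kernel side length in pixels (>= 3).
#' @param delta1,delta2 Gaussian standard deviations in pixels (> 0).
#' @return An object of class `dog_params`.
#' @seealso [make_dog_kernel()]
#' @export
dog_params <- function(window, delta1, delta2) {
  check_odd_window(window)
  if (delta1 <= 0 || delta2 <= 0) {
    stop("DoG standard deviations must be positive", call. = FALSE)
  }
  structure(
    list(window = as.integer(window), delta1 = delta1, delta2 = delta2),
    class = "dog_params"
  )
}

check_odd_window <- function(window) {
  if (length(window) != 1 || is.na(window) || window < 3 || window %% 2 != 1) {
    stop("`window` must be a single odd integer >= 3", call. = FALSE)
  }
  invisible(window)
}

# centered coordinate grids for a square odd window; x increases with column,
# y increases with row, origin at the kernel midpoint
kernel_grid <- function(window) {
  half <- (window - 1L) / 2L
  ax <- seq.int(-half, half)
  list(x = matrix(rep(ax, each = window), window, window),
       y = matrix(rep(ax, times = window), window, window))
}

# subtract mean, divide by the max of the mean-subtracted kernel
normalize_kernel <- function(k) {
  k <- k - mean(k)
  m <- max(k)
  if (m <= .Machine$double.eps) {
    stop("degenerate kernel: zero after mean subtraction", call. = FALSE)
  }
  k / m
}

#' Construct a normalized Gabor kernel
#'
#' Builds the real-valued Gabor kernel
#' \deqn{G(x, y) = \exp\!\left(-\frac{X^2 + \gamma^2 Y^2}{2\sigma^2}\right)
#'   \cos\!\left(\frac{2\pi X}{\lambda} + \phi\right)}
#' with rotated coordinates \eqn{X = x\cos\theta + y\sin\theta},
#' \eqn{Y = -x\sin\theta + y\cos\theta}, then normalizes it to zero mean and
#' unit positive peak: subtract the kernel mean and divide by the maximum of
#' the mean-subtracted kernel.
#'
#' @param p A [gabor_params()] object.
#' @return A `window x window` numeric matrix with mean 0.
#' @examples
#' k <- make_gabor_kernel(gabor_params(15, theta = 3 * pi / 8))
#' abs(mean(k)) < 1e-9
#' @export
make_gabor_kernel <- function(p) {
  stopifnot(inherits(p, "gabor_params"))
  g <- kernel_grid(p$window)
  X <- g$x * cos(p$theta) + g$y * sin(p$theta)
  Y <- -g$x * sin(p$theta) + g$y * cos(p$theta)
  raw <- exp(-(X^2 + p$gamma^2 * Y^2) / (2 * p$sigma^2)) *
    cos(2 * pi * X / p$lam + p$phi)
  normalize_kernel(raw)
}

#' Construct a normalized difference-of-Gaussians kernel
#'
#' Builds \deqn{D(x, y) = \frac{1}{2\pi\delta_1^2}
#'   e^{-(x^2+y^2)/2\delta_1^2} - \frac{1}{2\pi\delta_2^2}
#'   e^{-(x^2+y^2)/2\delta_2^2}} on a centered grid and applies the same
#' zero-mean / unit-positive-peak normalization as [make_gabor_kernel()].
#' `delta1 == delta2` cancels identically and is rejected.
#'
#' @param p A [dog_params()] object.
#' @param normalize If `FALSE`, return the raw (unnormalized) kernel.
#' @return A `window x window` numeric matrix.
#' @export
make_dog_kernel <- function(p, normalize = TRUE) {
  stopifnot(inherits(p, "dog_params"))
  if (p$delta1 == p$delta2) {
    stop("delta1 == delta2 gives an identically zero DoG kernel", call. = FALSE)
  }
  g <- kernel_grid(p$window)
  r2 <- g$x^2 + g$y^2
  raw <- exp(-r2 / (2 * p$delta1^2)) / (2 * pi * p$delta1^2) -
    exp(-r2 / (2 * p$delta2^2)) / (2 * pi * p$delta2^2)
  if (!normalize) return(raw)
  normalize_kernel(raw)
}

#' Assemble a Gabor + DoG filter bank
#'
#' The default bank reproduces the reference front end: four 15x15 Gabor
#' kernels at orientations 3pi/8, 5pi/8, 7pi/8, 9pi/8 followed by two 7x7 DoG
#' kernels with (delta1, delta2) = (1, 2) (on-center) and (2, 1) (off-center).
#' All kernels are zero-mean by construction.
#'
#' @param gabor_window Gabor kernel side length (odd), default 15.
#' @param orientations Numeric vector of Gabor orientations in radians.
#' @param dog_window DoG kernel side length (odd), default 7.
#' @param dog_pairs List of `c(delta1, delta2)` pairs.
#' @param cutoff Nonnegative response threshold applied on the rescaled 0-255
#'   response scale; default 50.
#' @param ... Extra arguments passed to [gabor_params()] (e.g. `lam`, `sigma`,
#'   `gamma`, `phi`).
#' @return An object of class `filter_bank`: list with `kernels`, `params`,
#'   `cutoff`.
#' @examples
#' fb <- filter_bank()
#' length(fb$kernels)  # 6 channels
#' @export
filter_bank <- function(gabor_window = 15,
                        orientations = c(3, 5, 7, 9) * pi / 8,
                        dog_window = 7,
                        dog_pairs = list(c(1, 2), c(2, 1)),
                        cutoff = 50, ...) {
  stopifnot(cutoff >= 0)
  params <- c(
    lapply(orientations, function(th) gabor_params(gabor_window, theta = th, ...)),
    lapply(dog_pairs, function(dd) dog_params(dog_window, dd[1], dd[2]))
  )
  kernels <- lapply(params, function(p) {
    if (inherits(p, "gabor_params")) make_gabor_kernel(p) else make_dog_kernel(p)
  })
  meta <- vapply(params, function(p) {
    if (inherits(p, "gabor_params")) {
      sprintf("gabor_theta%.4f", p$theta)
    } else {
      sprintf("dog_%g_%g", p$delta1, p$delta2)
    }
  }, character(1))
  structure(list(kernels = kernels, params = params, cutoff = cutoff,
                 channel_meta = meta),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank> ", length(x$kernels), " kernels, cutoff ", x$cutoff, "\n",
      sep = "")
  for (i in seq_along(x$kernels)) {
    cat(sprintf("  [%d] %s (%dx%d)\n", i, x$channel_meta[i],
                nrow(x$kernels[[i]]), ncol(x$kernels[[i]])))
  }
  invisible(x)
}

# "same" zero-padded cross-correlation of image (matrix) with kernel (odd square)
cross_correlate_same <- function(image, kernel) {
  kh <- nrow(kernel)
  half <- (kh - 1L) / 2L
  H <- nrow(image); W <- ncol(image)
  padded <- matrix(0, H + 2L * half, W + 2L * half)
  padded[(half + 1L):(half + H), (half + 1L):(half + W)] <- image
  out <- matrix(0, H, W)
  # accumulate shifted copies: out += k[di,dj] * padded[i+di-1, j+dj-1]
  for (di in seq_len(kh)) {
    for (dj in seq_len(kh)) {
      kv <- kernel[di, dj]
      if (kv != 0) {
        out <- out + kv * padded[(di):(di + H - 1L), (dj):(dj + W - 1L)]
      }
    }
  }
  out
}

#' Apply a filter bank to a grayscale image
#'
#' Each kernel is applied by cross-correlation (sliding dot product, no kernel
#' flip) with "same" zero padding, so every response map has the geometry of
#' the input. Negative responses are clipped to zero, each channel is rescaled
#' so its maximum maps to 255 (channels that are identically zero stay zero),
#' and rescaled values below `bank$cutoff` are set to zero. The cutoff
#' suppresses low-intensity responses that would otherwise be encoded as
#' late, uninformative spikes.
#'
#' @param image Numeric matrix, values in `[0, 255]`.
#' @param bank A [filter_bank()].
#' @return An `intensity_maps` object: list with `data` (array `F x H x W`,
#'   nonnegative) and `channel_meta`.
#' @export
apply_filter_bank <- function(image, bank) {
  stopifnot(inherits(bank, "filter_bank"))
  if (!is.matrix(image) || length(image) == 0) {
    stop("`image` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (length(bank$kernels) == 0) stop("filter bank has no kernels", call. = FALSE)
  nf <- length(bank$kernels)
  H <- nrow(image); W <- ncol(image)
  data <- array(0, dim = c(nf, H, W))
  for (f in seq_len(nf)) {
    resp <- cross_correlate_same(image, bank$kernels[[f]])
    resp[resp < 0] <- 0
    mx <- max(resp)
    # channels whose rectified response is only floating-point residue
    # (e.g. zero-mean kernels on near-constant input) stay silent instead of
    # having noise amplified to full scale by the rescale
    if (mx > 1e-6) resp <- resp * (255 / mx) else resp[] <- 0
    resp[resp < bank$cutoff] <- 0
    data[f, , ] <- resp
  }
  intensity_maps(data, bank$channel_meta)
}

#' Intensity-map container
#'
#' @param data Numeric array `F x H x W`, nonnegative and finite.
#' @param channel_meta Character vector describing each channel's provenance.
#' @return An `intensity_maps` object.
#' @keywords internal
#' @export
intensity_maps <- function(data, channel_meta = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("intensity maps must be finite and nonnegative", call. = FALSE)
  }
  if (is.null(channel_meta)) channel_meta <- paste0("channel", seq_len(dim(data)[1]))
  structure(list(data = data, channel_meta = channel_meta),
            class = "intensity_maps")
}

#' Export filter-bank kernels as CSV files
#'
#' Writes one CSV per channel (no header, plain numeric grid) for inspection.
#'
#' @param bank A [filter_bank()].
#' @param dir Output directory, created if missing.
#' @return Invisibly, the written file paths.
#' @export
export_kernels_csv <- function(bank, dir) {
  stopifnot(inherits(bank, "filter_bank"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(bank$kernels))
  for (i in seq_along(bank$kernels)) {
    paths[i] <- file.path(dir, sprintf("kernel_%02d_%s.csv", i, bank$channel_meta[i]))
    utils::write.table(bank$kernels[[i]], paths[i], sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
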