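#' Specification of a synthetic vein-image dataset
#'
#' Describes a dataset of grayscale images emulating finger-vein ROIs:
#' per class, a fixed template of `veins_per_class` smooth random spline
#' paths rendered as bright curvilinear ridges with a Gaussian cross-section
#' over a darker background; per sample, small geometric and intensity
#' jitter plus fresh additive Gaussian noise. Veins are bright on dark to
#' match near-infrared ROI imagery in which vein regions show higher pixel
#' intensity than the background; set `invert = TRUE` for the opposite
#' polarity.
#'
#' @param n_classes Number of identities.
#' @param n_per_class Samples per identity (>= 2, so train/test splits exist).
#' @param size `c(H, W)` image size in pixels.
#' @param veins_per_class Number of vein paths per class template.
#' @param vein_width Gaussian cross-section standard deviation (pixels).
#' @param fg,bg Foreground (vein peak) and background mean intensities in
#'   `[0, 255]`.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param max_shift Maximum per-sample translation (pixels, each axis).
#' @param max_rotation Maximum per-sample rotation (degrees).
#' @param intensity_jitter Maximum relative vein-intensity perturbation.
#' @param invert Render dark veins on a bright background instead.
#' @param seed Master seed; all per-class and per-sample draws derive from
#'   it through independent substreams.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_classes = 10, n_per_class = 10, size = c(48, 48),
                           veins_per_class = 4, vein_width = 1.5,
                           fg = 200, bg = 60, noise_sigma = 10,
                           max_shift = 2, max_rotation = 3,
                           intensity_jitter = 0.1, invert = FALSE, seed = 1) {
  stopifnot(n_classes >= 1, n_per_class >= 2, length(size) == 2)
  if (fg < 0 || fg > 255 || bg < 0 || bg > 255) {
    stop("fg/bg intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 size = as.integer(size),
                 veins_per_class = as.integer(veins_per_class),
                 vein_width = vein_width, fg = fg, bg = bg,
                 noise_sigma = noise_sigma, max_shift = max_shift,
                 max_rotation = max_rotation,
                 intensity_jitter = intensity_jitter,
                 invert = invert, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# run expr under a dedicated RNG substream, restoring the caller's state
with_substream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# smooth random vein centerlines for one class: list of dense (x, y) point
# matrices spanning the image width
vein_template <- function(spec) {
  H <- spec$size[1]; W <- spec$size[2]
  lapply(seq_len(spec$veins_per_class), function(k) {
    ncp <- 5L
    cx <- seq(1, W, length.out = ncp)
    cy <- stats::runif(ncp, 0.12 * H, 0.88 * H)
    dense_x <- seq(1, W, by = 0.5)
    dense_y <- stats::spline(cx, cy, xout = dense_x)$y
    cbind(x = dense_x, y = pmin(pmax(dense_y, 1), H))
  })
}

render_vein_image <- function(template, spec, shift, rot_deg, int_factor, noise) {
  H <- spec$size[1]; W <- spec$size[2]
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  th <- rot_deg * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  px <- rep(seq_len(W), each = H)   # pixel coords, col-major over (row, col)
  py <- rep(seq_len(H), times = W)
  dmin2 <- rep(Inf, H * W)
  for (pts in template) {
    q <- cbind(pts[, "x"] - cx, pts[, "y"] - cy) %*% t(Rm)
    qx <- q[, 1] + cx + shift[2]
    qy <- q[, 2] + cy + shift[1]
    d2 <- outer(px, qx, "-")^2 + outer(py, qy, "-")^2
    dmin2 <- pmin(dmin2, do.call(pmin, as.data.frame(d2)))
  }
  profile <- exp(-dmin2 / (2 * spec$vein_width^2))
  amp <- (spec$fg - spec$bg) * int_factor
  img <- spec$bg + amp * profile + noise
  img <- matrix(pmin(pmax(img, 0), 255), H, W)
  if (spec$invert) img <- 255 - img
  img
}

#' Generate a synthetic vein-image dataset
#'
#' Fully deterministic given the spec: class templates and per-sample jitter
#' are drawn from independent substreams keyed by `(seed, class, sample)`,
#' so regenerating the spec gives bit-identical pixels and adding classes
#' does not perturb existing ones.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with columns `class` (integer label), `sample` (index
#'   within class) and `image` (list-column of `H x W` matrices in
#'   `[0, 255]`).
#' @examples
#' d <- generate_synthetic_dataset(synthetic_spec(n_classes = 2, n_per_class = 2))
#' dim(d$image[[1]])
#' @export
generate_synthetic_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- vector("list", spec$n_classes * spec$n_per_class)
  k <- 1L
  for (cls in seq_len(spec$n_classes)) {
    template <- with_substream(spec$seed + 1000003L + 4001L * cls,
                               vein_template(spec))
    for (smp in seq_len(spec$n_per_class)) {
      img <- with_substream(spec$seed + 2000003L + 4001L * cls + smp, {
        shift <- stats::runif(2, -spec$max_shift, spec$max_shift)
        rot <- stats::runif(1, -spec$max_rotation, spec$max_rotation)
        fac <- 1 + stats::runif(1, -spec$intensity_jitter, spec$intensity_jitter)
        noise <- if (spec$noise_sigma > 0) {
          stats::rnorm(prod(spec$size), 0, spec$noise_sigma)
        } else 0
        if (spec$max_shift == 0) shift <- c(0, 0)
        if (spec$max_rotation == 0) rot <- 0
        if (spec$intensity_jitter == 0) fac <- 1
        render_vein_image(template, spec, shift, rot, fac, noise)
      })
      rows[[k]] <- tibble::tibble(class = cls, sample = smp, image = list(img))
      k <- k + 1L
    }
  }
  dplyr::bind_rows(rows)
}

#' Split a dataset tibble into train and test partitions
#'
#' Deterministic protocol used throughout: for each class the first
#' `n_train` samples (by `sample` index) are training images and the rest
#' are test images.
#'
#' @param data Tibble with `class`, `sample`, `image` columns.
#' @param n_train Training samples per class.
#' @return The input tibble with an added `split` column
#'   (`"train"`/`"test"`).
#' @export
split_dataset <- function(data, n_train) {
  stopifnot(all(c("class", "sample", "image") %in% names(data)))
  dplyr::mutate(data, split = ifelse(.data$sample <= n_train, "train", "test"))
}
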