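#' Load and preprocess a grayscale ROI image
#'
#' Reads a PNG image, converts it to grayscale luminance (ITU-R BT.601
#' weights 0.299/0.587/0.114) on the 0-255 scale, optionally rotates it 90
#' degrees counterclockwise (the convention used to align some acquisition
#' devices' finger orientation), and bilinearly resizes it to `target_size`.
#'
#' @param path Path to an 8-bit PNG file.
#' @param target_size `c(H, W)` output size, or `NULL` to keep the input size.
#' @param rotate90 Rotate counterclockwise by 90 degrees before resizing.
#' @return Numeric matrix in `[0, 255]`.
#' @export
load_and_preprocess <- function(path, target_size = c(48, 48), rotate90 = FALSE) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  if (!grepl("\\.png$", path, ignore.case = TRUE)) {
    stop("only PNG input is supported (got ", basename(path), ")", call. = FALSE)
  }
  raw <- png::readPNG(path)
  img <- to_gray255(raw)
  if (rotate90) img <- rotate_ccw90(img)
  if (!is.null(target_size)) {
    if (any(target_size < 1)) stop("zero-size resize target", call. = FALSE)
    img <- resize_bilinear(img, target_size[1], target_size[2])
  }
  img
}

to_gray255 <- function(raw) {
  if (length(dim(raw)) == 2) {
    m <- raw
  } else {
    nc <- dim(raw)[3]
    m <- if (nc >= 3) {
      0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      raw[, , 1]
    }
  }
  m * 255
}

# counterclockwise quarter rotation: out[i, j] = m[j, W + 1 - i]
rotate_ccw90 <- function(m) {
  t(m)[ncol(m):1, , drop = FALSE]
}

# bilinear resize via EBImage; EBImage's first margin plays the role of our
# row index, so no transposition is needed
resize_bilinear <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = h, h = w))
  matrix(out, h, w)
}

#' Canny edge detection
#'
#' Compact Canny implementation used by [extract_roi_canny()]: Sobel
#' gradients, non-maximum suppression with the gradient direction quantized
#' to four bins, and hysteresis thresholding at `low`/`high` fractions of
#' the maximum gradient magnitude (weak edges are kept only when their
#' connected component contains a strong edge).
#'
#' @param m Numeric image matrix.
#' @param low,high Hysteresis thresholds as fractions of the maximum
#'   gradient magnitude (defaults 0.1 and 0.3).
#' @return Logical edge matrix of the same size.
#' @export
canny_edges <- function(m, low = 0.1, high = 0.3) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  # replicate borders so gradients at the frame are meaningful
  pad[1, ] <- pad[2, ]; pad[H + 2, ] <- pad[H + 1, ]
  pad[, 1] <- pad[, 2]; pad[, W + 2] <- pad[, W + 1]
  sh <- function(di, dj) pad[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, H, W))
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)   # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  magp <- matrix(0, H + 2, W + 2)
  magp[2:(H + 1), 2:(W + 1)] <- mag
  shm <- function(di, dj) magp[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  n1 <- mag; n2 <- mag
  n1[sector == 0] <- shm(0, 1)[sector == 0];  n2[sector == 0] <- shm(0, -1)[sector == 0]
  n1[sector == 1] <- shm(-1, 1)[sector == 1]; n2[sector == 1] <- shm(1, -1)[sector == 1]
  n1[sector == 2] <- shm(-1, 0)[sector == 2]; n2[sector == 2] <- shm(1, 0)[sector == 2]
  n1[sector == 3] <- shm(-1, -1)[sector == 3]; n2[sector == 3] <- shm(1, 1)[sector == 3]
  keep <- mag >= n1 & mag >= n2
  weak <- keep & (mag >= low * mmax)
  strong <- keep & (mag >= high * mmax)
  if (!any(strong)) return(matrix(FALSE, H, W))
  lab <- EBImage::bwlabel(EBImage::Image(weak * 1))
  lab <- matrix(EBImage::imageData(lab), H, W)
  good <- sort(unique(lab[strong]))
  good <- good[good > 0]
  matrix(lab %in% good, H, W) & weak
}

#' ROI extraction from a raw finger image
#'
#' Reproduces the contour-based ROI procedure: crop a fixed number of rows
#' from the top and bottom (removing acquisition-device edges), detect
#' edges with [canny_edges()], discard near-vertical edge runs (connected
#' components whose vertical extent exceeds 3x their horizontal extent,
#' typically device borders), locate the topmost and bottommost remaining
#' edge row in each column, take the column-wise medians as the upper and
#' lower finger contours, crop between them and bilinearly resize to
#' `target_size`.
#'
#' @param raw Numeric matrix in `[0, 255]` (raw finger image).
#' @param top_crop,bottom_crop Rows removed before contour detection
#'   (defaults 45 and 25).
#' @param target_size `c(H, W)` output size.
#' @param low,high Canny hysteresis fractions.
#' @param vertical_aspect Aspect-ratio threshold above which an edge
#'   component is discarded as a vertical device contour.
#' @return Numeric matrix of size `target_size`.
#' @export
extract_roi_canny <- function(raw, top_crop = 45, bottom_crop = 25,
                              target_size = c(48, 48),
                              low = 0.1, high = 0.3, vertical_aspect = 3) {
  stopifnot(is.matrix(raw))
  if (nrow(raw) <= top_crop + bottom_crop) {
    stop("image not taller than top_crop + bottom_crop", call. = FALSE)
  }
  cropped <- raw[(top_crop + 1):(nrow(raw) - bottom_crop), , drop = FALSE]
  edges <- canny_edges(cropped, low, high)
  if (!any(edges)) stop("ROI extraction failed: no detectable contours", call. = FALSE)
  lab <- matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(edges * 1))),
                nrow(edges), ncol(edges))
  for (id in seq_len(max(lab))) {
    px <- which(lab == id, arr.ind = TRUE)
    vert <- diff(range(px[, 1])) + 1
    horiz <- diff(range(px[, 2])) + 1
    if (vert > vertical_aspect * horiz) edges[lab == id] <- FALSE
  }
  if (!any(edges)) stop("ROI extraction failed: only vertical contours found", call. = FALSE)
  tops <- apply(edges, 2, function(col) if (any(col)) which(col)[1] else NA_integer_)
  bots <- apply(edges, 2, function(col) if (any(col)) max(which(col)) else NA_integer_)
  upper <- stats::median(tops, na.rm = TRUE)
  lower <- stats::median(bots, na.rm = TRUE)
  if (!is.finite(upper) || !is.finite(lower) || lower - upper < 2) {
    stop("ROI extraction failed: contours collapse", call. = FALSE)
  }
  roi <- cropped[ceiling(upper):floor(lower), , drop = FALSE]
  resize_bilinear(roi, target_size[1], target_size[2])
}

#' Write a dataset tibble as PNG files
#'
#' Lays images out as `dir/<class>/<sample>.png` and returns a split
#' manifest tibble (path, class, split when present).
#'
#' @param data Tibble with `class`, `sample`, `image` (and optionally
#'   `split`) columns.
#' @param dir Output directory.
#' @return Tibble manifest invisibly.
#' @export
write_dataset_png <- function(data, dir) {
  stopifnot(all(c("class", "sample", "image") %in% names(data)))
  paths <- character(nrow(data))
  for (i in seq_len(nrow(data))) {
    cdir <- file.path(dir, sprintf("%03d", data$class[i]))
    if (!dir.exists(cdir)) dir.create(cdir, recursive = TRUE)
    paths[i] <- file.path(cdir, sprintf("%03d.png", data$sample[i]))
    png::writePNG(data$image[[i]] / 255, paths[i])
  }
  out <- tibble::tibble(path = paths, class = data$class,
                        split = if ("split" %in% names(data)) data$split else NA)
  utils::write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(out)
}
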