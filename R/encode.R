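#' Spike-wave tensor
#'
#' A cumulative binary tensor `s[t, f, r, c]` of dimension
#' `Tmax x F x H x W`: entry 1 means the neuron at `(f, r, c)` has fired at
#' or before time step `t` (0-based time internally exposed as the first
#' array margin). Cumulativity (`s[t] <= s[t+1]`) is what lets all time
#' steps be processed in one pass downstream.
#'
#' @param s Numeric array `Tmax x F x H x W` with values in `{0, 1}`.
#' @param t_first Optional integer array `F x H x W` of first-spike times
#'   (0-based; `NA` = never fires).
#' @return A `spike_wave` object.
#' @export
spike_wave <- function(s, t_first = NULL) {
  stopifnot(is.array(s), length(dim(s)) == 4)
  structure(list(s = s, t_first = t_first, dim = dim(s)), class = "spike_wave")
}

#' @export
print.spike_wave <- function(x, ...) {
  d <- x$dim
  cat(sprintf("<spike_wave> Tmax=%d F=%d H=%d W=%d, %d/%d neurons fire\n",
              d[1], d[2], d[3], d[4],
              sum(x$s[d[1], , , , drop = FALSE] > 0), prod(d[-1])))
  invisible(x)
}

#' Check spike-wave invariants
#'
#' Asserts binarity and temporal cumulativity; used throughout the test
#' suite and cheap enough to call on pipeline outputs.
#'
#' @param sw A [spike_wave()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_spike_wave <- function(sw) {
  s <- sw$s
  if (!all(s %in% c(0, 1))) stop("spike wave is not binary", call. = FALSE)
  tm <- dim(s)[1]
  if (tm > 1) {
    for (t in seq_len(tm - 1)) {
      if (any(s[t, , , ] > s[t + 1, , , ])) {
        stop("spike wave is not cumulative at t = ", t, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# box mean with zero padding via integral image; divisor is the full window
# area so border windows see padded zeros
box_mean_zeropad <- function(m, radius) {
  H <- nrow(m); W <- ncol(m)
  k <- 2L * radius + 1L
  p <- matrix(0, H + 2L * radius, W + 2L * radius)
  p[(radius + 1L):(radius + H), (radius + 1L):(radius + W)] <- m
  # summed-area table with a leading zero row/col
  sat <- rbind(0, cbind(0, t(apply(apply(p, 2, cumsum), 1, cumsum))))
  i1 <- 1:H; j1 <- 1:W
  (sat[i1 + k, j1 + k, drop = FALSE] - sat[i1, j1 + k, drop = FALSE] -
      sat[i1 + k, j1, drop = FALSE] + sat[i1, j1, drop = FALSE]) / (k * k)
}

#' Local contrast normalization
#'
#' Divides every value by the mean of its `(2 * radius + 1)^2` zero-padded
#' neighborhood (plus a small `eps` guarding all-zero regions), channel by
#' channel. This accentuates locally salient responses while suppressing
#' slow illumination gradients before latency coding.
#'
#' @param maps An [intensity_maps()] object.
#' @param radius Neighborhood radius in pixels (>= 1), default 8.
#' @param eps Stabilizer added to the denominator.
#' @return An [intensity_maps()] object of the same shape.
#' @export
local_normalize <- function(maps, radius = 8, eps = 1e-12) {
  stopifnot(inherits(maps, "intensity_maps"), radius >= 1)
  d <- dim(maps$data)
  out <- maps$data
  for (f in seq_len(d[1])) {
    ch <- matrix(maps$data[f, , ], d[2], d[3])
    out[f, , ] <- ch / (box_mean_zeropad(ch, as.integer(radius)) + eps)
  }
  intensity_maps(out, maps$channel_meta)
}

#' Cross-channel pointwise inhibition
#'
#' At every spatial location, only the channel with the maximal intensity
#' keeps its value; all other channels are zeroed (ties go to the lowest
#' channel index). Mimics lateral inhibition among retinal ganglion cells
#' and guarantees at most one spike train per pixel position.
#'
#' @param maps An [intensity_maps()] object.
#' @return An [intensity_maps()] object of the same shape.
#' @export
pointwise_intensity_inhibition <- function(maps) {
  stopifnot(inherits(maps, "intensity_maps"))
  d <- dim(maps$data)
  if (d[1] == 1) return(maps)
  m <- matrix(maps$data, d[1], d[2] * d[3])  # F x (H*W), F varies fastest
  winner <- max.col(t(m), ties.method = "first")
  res <- matrix(0, d[1], d[2] * d[3])
  idx <- cbind(winner, seq_len(ncol(m)))
  res[idx] <- m[idx]
  intensity_maps(array(res, d), maps$channel_meta)
}

#' Intensity-to-latency spike encoding
#'
#' Converts nonnegative intensity maps into a cumulative spike-wave tensor:
#' the stronger a stimulus, the earlier its spike. All strictly positive
#' values are ranked in descending order (ties broken lexicographically by
#' channel, then row, then column) and the ranking is split into `t_max`
#' contiguous, near-equal-count bins; the bin index is the neuron's
#' first-spike latency. Zero-intensity inputs never fire. With
#' `binning = "linear"` the latency is instead proportional to
#' `1 - value / max(value)`, binned into `t_max` steps.
#'
#' @param maps An [intensity_maps()] object (nonnegative).
#' @param t_max Number of time steps, default 15.
#' @param binning `"rank"` (default) or `"linear"`.
#' @return A list with `t_first` (integer array `F x H x W`, `NA` = no
#'   spike) and `wave` (a [spike_wave()]).
#' @export
encode_to_spike_wave <- function(maps, t_max = 15, binning = c("rank", "linear")) {
  stopifnot(inherits(maps, "intensity_maps"), t_max >= 1)
  binning <- match.arg(binning)
  d <- dim(maps$data)
  nf <- d[1]; H <- d[2]; W <- d[3]
  v <- maps$data
  t_first <- array(NA_integer_, dim = d)
  pos <- which(v > 0)
  n <- length(pos)
  if (n > 0) {
    if (binning == "rank") {
      # lexicographic (channel, row, col) tie-break key
      ai <- arrayInd(pos, d)
      lex <- (ai[, 1] - 1) * (H * W) + (ai[, 2] - 1) * W + (ai[, 3] - 1)
      ord <- order(-v[pos], lex)
      ranks0 <- seq_len(n) - 1L
      bins <- as.integer(floor(ranks0 * t_max / n))
      t_first[pos[ord]] <- bins
    } else {
      mx <- max(v[pos])
      bins <- as.integer(floor((1 - v[pos] / mx) * t_max))
      bins[bins >= t_max] <- t_max - 1L
      t_first[pos] <- bins
    }
  }
  s <- array(0, dim = c(t_max, nf, H, W))
  for (t in seq_len(t_max)) {
    fired <- !is.na(t_first) & t_first <= (t - 1L)
    s[t, , , ] <- as.numeric(fired)
  }
  list(t_first = t_first, wave = spike_wave(s, t_first))
}

# first-spike times (1-based; Inf = never) from a cumulative spike wave
first_spike_times <- function(s) {
  d <- dim(s)
  counts <- colSums(s)                  # cumulative => count = T - t0
  tf <- d[1] - counts + 1
  tf[counts == 0] <- Inf
  tf
}
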