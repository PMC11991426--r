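#' Initialize synaptic weights
#'
#' Draws i.i.d. normal weights with mean `mu` and standard deviation `sigma`
#' and clamps them to `[lb, ub]`. Shape convention is
#' `Fout x Fin x kh x kw`: one `Fin x kh x kw` kernel per output feature map.
#'
#' @param shape Integer vector `c(Fout, Fin, kh, kw)`.
#' @param mu,sigma Normal mean and standard deviation (defaults 0.8, 0.05).
#' @param lb,ub Weight bounds (defaults 0, 1).
#' @param seed Optional integer seed; when given the global RNG state is
#'   saved and restored, so the draw is reproducible and side-effect free.
#' @return Numeric array of dimension `shape`.
#' @export
init_weights <- function(shape, mu = 0.8, sigma = 0.05, lb = 0, ub = 1,
                         seed = NULL) {
  stopifnot(length(shape) == 4, all(shape >= 1))
  if (sigma < 0) stop("`sigma` must be nonnegative", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  w <- array(stats::rnorm(prod(shape), mu, sigma), dim = shape)
  w[w < lb] <- lb
  w[w > ub] <- ub
  w
}

# separable im2col index map: rows run over (fin, di, dj), fin fastest;
# columns over output positions (i, j), i fastest; memoized on geometry
.im2col_cache <- new.env(parent = emptyenv())

im2col_indices <- function(fin, H, W, kh, kw) {
  ho <- H - kh + 1L; wo <- W - kw + 1L
  if (ho < 1 || wo < 1) stop("kernel larger than input", call. = FALSE)
  key <- paste(fin, H, W, kh, kw, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- seq_len(fin)
  base <- as.vector(outer(outer(f, fin * (seq_len(kh) - 1L), "+"),
                          fin * H * (seq_len(kw) - 1L), "+"))
  pos <- as.vector(outer(fin * (seq_len(ho) - 1L), fin * H * (seq_len(wo) - 1L), "+"))
  out <- list(idx = as.vector(outer(base, pos, "+")),
              nr = length(base), nc = length(pos), ho = ho, wo = wo)
  .im2col_cache[[key]] <- out
  out
}

#' Membrane potentials of an integrate-and-fire convolution layer
#'
#' For every time step the potential of each output neuron is the weighted
#' sum of the presynaptic spikes in its receptive field:
#' \deqn{V_i(t) = \sum_j W_{j,i} S_j(t)} computed as a valid (no padding)
#' cross-correlation of the spike slice at time `t` with the weight tensor.
#' With cumulative spike input and nonnegative weights the potentials are
#' themselves non-decreasing in time.
#'
#' @param sw A [spike_wave()] with `Fin` channels.
#' @param w Weight array `Fout x Fin x kh x kw`.
#' @return Numeric potential array `Tmax x Fout x H' x W'` with
#'   `H' = H - kh + 1`, `W' = W - kw + 1`.
#' @export
conv_potentials <- function(sw, w) {
  stopifnot(inherits(sw, "spike_wave"), length(dim(w)) == 4)
  d <- dim(sw$s)
  tm <- d[1]; fin <- d[2]; H <- d[3]; W <- d[4]
  fout <- dim(w)[1]
  if (dim(w)[2] != fin) stop("weight Fin does not match spike channels", call. = FALSE)
  kh <- dim(w)[3]; kw <- dim(w)[4]
  ic <- im2col_indices(fin, H, W, kh, kw)
  wmat <- matrix(aperm(w, c(2, 3, 4, 1)), nrow = fin * kh * kw, ncol = fout)
  v <- array(0, dim = c(tm, fout, ic$ho, ic$wo))
  s <- sw$s
  nslice <- fin * H * W
  for (t in seq_len(tm)) {
    xt <- s[seq.int(t, by = tm, length.out = nslice)]
    patches <- xt[ic$idx]
    dim(patches) <- c(ic$nr, ic$nc)
    v[t, , , ] <- t(crossprod(patches, wmat))
  }
  v
}

#' Batch-normalization state for one layer
#'
#' Tracks per-output-channel running mean and variance used at inference.
#' No learned affine transform exists (there is no gradient training), so
#' normalization is a pure standardization.
#'
#' @param n_channels Number of output feature maps.
#' @param momentum Running-statistics update factor in `[0, 1)`, default 0.1.
#' @param eps Variance floor, default 1e-5.
#' @param enabled Logical switch.
#' @return A `bn_state` object.
#' @export
bn_state <- function(n_channels, momentum = 0.1, eps = 1e-5, enabled = TRUE) {
  stopifnot(n_channels >= 1, momentum >= 0, momentum < 1, eps > 0)
  structure(list(running_mean = rep(0, n_channels),
                 running_var = rep(1, n_channels),
                 momentum = momentum, eps = eps, enabled = enabled),
            class = "bn_state")
}

#' Batch-normalize a potential tensor
#'
#' Standardizes each output channel over its `time x space` entries. In
#' training mode the current sample's statistics are used (single-sample
#' online training) and the running statistics are updated with the BN
#' momentum; in inference mode the stored running statistics are applied.
#'
#' @param v Potential array `T x Fout x H x W`.
#' @param bn A [bn_state()].
#' @param training Logical.
#' @return List with `v` (normalized tensor) and `bn` (updated state).
#' @export
batch_norm_potentials <- function(v, bn, training = TRUE) {
  stopifnot(inherits(bn, "bn_state"))
  if (!bn$enabled) stop("batch_norm_potentials called with bn disabled", call. = FALSE)
  d <- dim(v)
  out <- v
  for (f in seq_len(d[2])) {
    ch <- v[, f, , ]
    if (training) {
      m <- mean(ch)
      va <- mean((ch - m)^2)
      bn$running_mean[f] <- (1 - bn$momentum) * bn$running_mean[f] + bn$momentum * m
      bn$running_var[f] <- (1 - bn$momentum) * bn$running_var[f] + bn$momentum * va
    } else {
      m <- bn$running_mean[f]
      va <- bn$running_var[f]
    }
    out[, f, , ] <- (ch - m) / sqrt(va + bn$eps)
  }
  list(v = out, bn = bn)
}

#' Firing-threshold state
#'
#' In adaptive mode the per-sample training threshold is the mean of the
#' sample's potential tensor, and the test-time threshold is an exponential
#' moving average of those training thresholds (momentum `M`, default 0.9),
#' initialized to the adaptive threshold of the first training image. Fixed
#' mode applies `fixed_value` throughout.
#'
#' @param mode `"adaptive"` or `"fixed"`.
#' @param fixed_value Threshold used in fixed mode.
#' @param momentum EMA momentum `M` in `[0, 1)`.
#' @return A `threshold_state` object.
#' @export
threshold_state <- function(mode = c("adaptive", "fixed"), fixed_value = 1,
                            momentum = 0.9) {
  mode <- match.arg(mode)
  stopifnot(momentum >= 0, momentum < 1)
  structure(list(mode = mode, fixed_value = fixed_value,
                 test_threshold = NA_real_, momentum = momentum,
                 initialized = FALSE),
            class = "threshold_state")
}

#' Per-sample adaptive threshold
#'
#' The adaptive firing threshold of a sample is the arithmetic mean over all
#' entries of its membrane-potential tensor (all time steps, channels and
#' positions).
#'
#' @param v Nonempty numeric potential array.
#' @return Scalar threshold.
#' @export
sample_threshold <- function(v) {
  if (length(v) == 0) stop("empty potential tensor", call. = FALSE)
  mean(v)
}

#' Track the test-time threshold
#'
#' Applies the exponential moving average
#' `test <- test * M + train * (1 - M)`; the first call simply initializes
#' the test threshold to the training threshold.
#'
#' @param state A [threshold_state()] in adaptive mode.
#' @param train_threshold The current sample's adaptive threshold.
#' @return Updated `threshold_state`.
#' @export
update_test_threshold <- function(state, train_threshold) {
  stopifnot(inherits(state, "threshold_state"), state$mode == "adaptive")
  if (!state$initialized) {
    state$test_threshold <- train_threshold
    state$initialized <- TRUE
  } else {
    state$test_threshold <- state$test_threshold * state$momentum +
      train_threshold * (1 - state$momentum)
  }
  state
}

#' Threshold potentials into spikes
#'
#' A neuron emits a spike wherever its potential reaches the firing
#' threshold (`>=`, so a neuron exactly at threshold fires). Returns both
#' the thresholded potential tensor (potential where spiking, else 0) and
#' the binary spike tensor; if the potentials are non-decreasing in time the
#' emitted spike wave is cumulative.
#'
#' @param v Potential array `T x F x H x W`.
#' @param threshold Finite scalar.
#' @return List with `potentials` (thresholded tensor) and `wave`
#'   (a [spike_wave()]).
#' @export
fire <- function(v, threshold) {
  stopifnot(is.finite(threshold))
  spikes <- (v >= threshold) * 1
  list(potentials = v * spikes, wave = spike_wave(spikes))
}
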