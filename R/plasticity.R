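#' Winner-take-all competition settings
#'
#' @param kwta Number of winners selected per sample (>= 1).
#' @param inhibition_radius Chebyshev radius `r` (pixels, >= 0) inhibited
#'   around each winner across all feature maps.
#' @return A `competition_config` object.
#' @export
competition_config <- function(kwta, inhibition_radius) {
  stopifnot(kwta >= 1, inhibition_radius >= 0)
  structure(list(kwta = as.integer(kwta),
                 inhibition_radius = as.integer(inhibition_radius)),
            class = "competition_config")
}

#' Stabilized-STDP settings
#'
#' `a_plus` / `a_minus` are the potentiation and depression rates (defaults
#' 0.004 and -0.003). The stabilizer multiplies updates by
#' `(W - lb) * (ub - w)`, freezing weights at the bounds. `double_every`
#' and `rate_cap` drive the learning-rate schedule: `a_plus` doubles every
#' `double_every` training images while it stays below `rate_cap`, with the
#' initial `a_minus / a_plus` ratio preserved; `double_every = 0` disables
#' the schedule.
#'
#' @param a_plus Potentiation rate (> 0).
#' @param a_minus Depression rate (< 0).
#' @param lb,ub Weight bounds.
#' @param eta Global learning-rate multiplier.
#' @param use_stabilizer Logical.
#' @param double_every Images between doublings (0 = off).
#' @param rate_cap Ceiling on `a_plus` for the schedule.
#' @return A `plasticity_config` object.
#' @export
plasticity_config <- function(a_plus = 0.004, a_minus = -0.003, lb = 0, ub = 1,
                              eta = 1, use_stabilizer = TRUE,
                              double_every = 0, rate_cap = 0.15) {
  stopifnot(a_plus > 0, a_minus < 0, lb < ub, eta > 0, double_every >= 0)
  structure(list(a_plus = a_plus, a_minus = a_minus, lb = lb, ub = ub,
                 eta = eta, use_stabilizer = use_stabilizer,
                 double_every = as.integer(double_every), rate_cap = rate_cap,
                 initial_ratio = a_minus / a_plus),
            class = "plasticity_config")
}

# potential of each neuron at its own first spike time (NA where never fired),
# plus the first-spike-time array itself (Inf = never)
gather_first_spike <- function(tp, spikes) {
  d <- dim(spikes)
  tf <- first_spike_times(spikes)          # F x H x W, 1-based, Inf = never
  pot <- array(-Inf, dim = d[-1])
  fired <- is.finite(tf)
  if (any(fired)) {
    fi <- which(fired)
    ai <- arrayInd(fi, d[-1])
    lin <- tf[fi] + d[1] * ((ai[, 1] - 1) + d[2] * ((ai[, 2] - 1) + d[3] * (ai[, 3] - 1)))
    pot[fi] <- tp[lin]
  }
  list(t_first = tf, pot_first = pot)
}

# per-pixel winning channel under the (earliest spike, highest potential,
# lowest channel) rule; 0 where no channel fired
winner_channel_map <- function(tp, spikes) {
  d <- dim(spikes)
  gf <- gather_first_spike(tp, spikes)
  npix <- d[3] * d[4]
  TF <- matrix(gf$t_first, d[2], npix)
  P <- matrix(gf$pot_first, d[2], npix)
  min_tf <- suppressWarnings(apply(TF, 2, min))      # Inf where nothing fired
  cand <- sweep(TF, 2, min_tf, "==")
  Pm <- ifelse(cand, P, -Inf)
  win <- max.col(t(Pm), ties.method = "first")
  win[!is.finite(min_tf)] <- 0L
  win
}

#' Lateral inhibition of thresholded potentials
#'
#' Enforces that at most one feature map stays active at each spatial
#' location: the channel whose neuron fired earliest wins (ties broken by
#' the larger potential at that time, then by the lower channel index); all
#' other channels are zeroed in both the thresholded-potential tensor and
#' the spike tensor.
#'
#' @param tp Thresholded potential array `T x F x H x W`.
#' @param sw A [spike_wave()] aligned with `tp`.
#' @return List with `potentials` and `wave` after inhibition.
#' @export
lateral_inhibit_potentials <- function(tp, sw) {
  d <- dim(sw$s)
  if (d[2] == 1) return(list(potentials = tp, wave = sw))
  win <- winner_channel_map(tp, sw$s)
  keep <- matrix(0, d[2], d[3] * d[4])
  fired <- win > 0L
  keep[cbind(win[fired], which(fired))] <- 1
  mask <- array(rep(keep, each = d[1]), dim = d)
  list(potentials = tp * mask, wave = spike_wave(sw$s * mask))
}

#' Cross-channel spike inhibition between layers
#'
#' Applies the same winner rule as [lateral_inhibit_potentials()] to a spike
#' wave about to feed the next convolutional layer, so at most one channel
#' per pixel carries spikes forward. Inhibition only removes spikes, never
#' adds them.
#'
#' @param sw A [spike_wave()].
#' @param tp Thresholded potential array used for tie-breaking.
#' @return A [spike_wave()].
#' @export
pointwise_spike_inhibition <- function(sw, tp) {
  lateral_inhibit_potentials(tp, sw)$wave
}

#' Winner-take-all selection
#'
#' Iteratively selects up to `cfg$kwta` winning neurons from a thresholded
#' potential tensor. Each pick takes the eligible neuron with the earliest
#' first-spike time, ties broken by the highest potential at that time, then
#' by lexicographic `(f, h, w)` order. After a pick, the winner's entire
#' feature map and the Chebyshev-`r` spatial neighborhood across all maps
#' become ineligible. Selection stops early when no eligible neuron fired.
#'
#' @param tp Thresholded potential array `T x F x H x W`.
#' @param cfg A [competition_config()].
#' @param sw The [spike_wave()] emitted with `tp`.
#' @return A [tibble::tibble] with integer columns `f`, `h`, `w` (1-based),
#'   zero rows if nothing fired.
#' @export
get_k_winners <- function(tp, cfg, sw) {
  stopifnot(inherits(cfg, "competition_config"))
  d <- dim(sw$s)
  gf <- gather_first_spike(tp, sw$s)
  tf <- gf$t_first
  pot <- gf$pot_first
  elig <- is.finite(tf)
  r <- cfg$inhibition_radius
  H <- d[3]; W <- d[4]
  win_f <- win_h <- win_w <- integer(0)
  for (k in seq_len(cfg$kwta)) {
    if (!any(elig)) break
    cand <- which(elig & tf == min(tf[elig]))
    cand <- cand[pot[cand] == max(pot[cand])]
    if (length(cand) > 1) {
      ai <- arrayInd(cand, d[-1])
      lex <- (ai[, 1] - 1) * (H * W) + (ai[, 2] - 1) * W + (ai[, 3] - 1)
      cand <- cand[which.min(lex)]
    }
    ai <- arrayInd(cand[1], d[-1])
    f <- ai[1]; h <- ai[2]; w <- ai[3]
    win_f <- c(win_f, f); win_h <- c(win_h, h); win_w <- c(win_w, w)
    elig[f, , ] <- FALSE
    if (r > 0) {
      hr <- max(1, h - r):min(H, h + r)
      wr <- max(1, w - r):min(W, w + r)
      elig[, hr, wr] <- FALSE
    }
  }
  tibble::tibble(f = as.integer(win_f), h = as.integer(win_h),
                 w = as.integer(win_w))
}

#' Stabilized STDP weight update
#'
#' For each winner `(f, h, w)` the receptive-field synapses of feature map
#' `f` are updated by spike order alone: a synapse whose presynaptic neuron
#' fired no later than the postsynaptic neuron is potentiated by `a_plus`,
#' otherwise depressed by `a_minus`. Under cumulative coding the order test
#' is equivalent to comparing spike counts (`sum_t pre >= sum_t post`).
#' With the stabilizer enabled, updates scale by `(W - lb) * (ub - W)`;
#' weights are finally clamped to `[lb, ub]`. Only winning feature maps'
#' kernels change.
#'
#' @param input_sw Presynaptic [spike_wave()] (`Fin` channels).
#' @param output_sw Postsynaptic [spike_wave()] emitted by the layer.
#' @param winners Tibble from [get_k_winners()].
#' @param w Weight array `Fout x Fin x kh x kw`.
#' @param cfg A [plasticity_config()].
#' @return Updated weight array.
#' @export
stdp_update <- function(input_sw, output_sw, winners, w, cfg) {
  stopifnot(inherits(cfg, "plasticity_config"))
  if (nrow(winners) == 0) return(w)
  kh <- dim(w)[3]; kw <- dim(w)[4]
  din <- dim(input_sw$s)
  cnt_in <- colSums(input_sw$s)            # Fin x H x W spike counts
  cnt_out <- colSums(output_sw$s)          # Fout x H' x W'
  for (i in seq_len(nrow(winners))) {
    f <- winners$f[i]; h <- winners$h[i]; wp <- winners$w[i]
    if (h + kh - 1 > din[3] || wp + kw - 1 > din[4]) {
      stop("winner receptive field out of bounds", call. = FALSE)
    }
    tau_post <- cnt_out[f, h, wp]
    pre <- cnt_in[, h:(h + kh - 1), wp:(wp + kw - 1), drop = FALSE]
    kshape <- c(din[2], kh, kw)
    dw <- array(ifelse(pre >= tau_post, cfg$a_plus, cfg$a_minus), kshape)
    wf <- array(w[f, , , ], kshape)
    if (cfg$use_stabilizer) dw <- dw * (wf - cfg$lb) * (cfg$ub - wf)
    wf <- wf + cfg$eta * dw
    wf[wf < cfg$lb] <- cfg$lb
    wf[wf > cfg$ub] <- cfg$ub
    w[f, , , ] <- wf
  }
  w
}

#' Learning-rate doubling schedule
#'
#' While `a_plus` is below `rate_cap`, the potentiation rate doubles every
#' `double_every` training images and `a_minus` is rescaled so the initial
#' `a_minus / a_plus` ratio is preserved.
#'
#' @param cfg A [plasticity_config()].
#' @param images_seen Nonnegative count of training images processed so far.
#' @return Possibly updated `plasticity_config`.
#' @export
lr_schedule_step <- function(cfg, images_seen) {
  stopifnot(inherits(cfg, "plasticity_config"), images_seen >= 0)
  if (cfg$double_every > 0 && images_seen > 0 &&
      images_seen %% cfg$double_every == 0 && cfg$a_plus < cfg$rate_cap) {
    cfg$a_plus <- 2 * cfg$a_plus
    cfg$a_minus <- cfg$a_plus * cfg$initial_ratio
  }
  cfg
}
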