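#' Max-pool a spike wave
#'
#' Zero-padded max pooling applied independently to every time slice and
#' feature map. With the default `window = 2, stride = 2, padding = 1`
#' (the reference setting) a 44x44 map pools to 23x23 and a 22x22 map to
#' 12x12. Pooling a binary cumulative tensor yields a binary cumulative
#' tensor.
#'
#' @param sw A [spike_wave()].
#' @param window,stride,padding Pooling geometry (defaults 2, 2, 1).
#' @return A pooled [spike_wave()].
#' @export
pool_spikes <- function(sw, window = 2, stride = 2, padding = 1) {
  spike_wave(pool_tensor(sw$s, window, stride, padding))
}

# max pooling of a T x F x H x W tensor over its two spatial margins
pool_tensor <- function(x, window = 2, stride = 2, padding = 1) {
  d <- dim(x)
  H <- d[3]; W <- d[4]
  hp <- H + 2L * padding; wp <- W + 2L * padding
  if (window > hp || window > wp) stop("pooling window exceeds padded input", call. = FALSE)
  ho <- (hp - window) %/% stride + 1L
  wo <- (wp - window) %/% stride + 1L
  pad <- array(0, dim = c(d[1], d[2], hp, wp))
  pad[, , (padding + 1):(padding + H), (padding + 1):(padding + W)] <- x
  out <- array(-Inf, dim = c(d[1], d[2], ho, wo))
  ri <- (seq_len(ho) - 1L) * stride
  ci <- (seq_len(wo) - 1L) * stride
  for (di in seq_len(window)) {
    for (dj in seq_len(window)) {
      out <- pmax(out, pad[, , ri + di, ci + dj, drop = FALSE])
    }
  }
  out
}

#' One spiking convolutional layer's state
#'
#' Bundles weights, threshold state, batch-normalization state, competition
#' and plasticity settings for a layer of non-leaky integrate-and-fire
#' neurons.
#'
#' @param in_channels,out_channels Feature-map counts.
#' @param kernel Square convolution window size.
#' @param kwta,inhibition_radius Winner-take-all settings.
#' @param threshold_mode `"adaptive"` or `"fixed"`.
#' @param fixed_value Fixed threshold (used when `threshold_mode = "fixed"`).
#' @param threshold_momentum EMA momentum for the test threshold.
#' @param bn_enabled Attach a batch-normalization stage.
#' @param lateral_inhibition Apply lateral inhibition to this layer's output.
#' @param threshold_source `"post_bn"` or `"pre_bn"`: the tensor the firing
#'   threshold is computed on and applied to when BN is enabled.
#' @param plasticity A [plasticity_config()].
#' @param epochs Training epochs for this layer.
#' @param seed Weight-initialization seed.
#' @return A `layer_state` object.
#' @export
layer_state <- function(in_channels, out_channels, kernel,
                        kwta, inhibition_radius,
                        threshold_mode = "adaptive", fixed_value = 1,
                        threshold_momentum = 0.9,
                        bn_enabled = TRUE, lateral_inhibition = TRUE,
                        threshold_source = c("post_bn", "pre_bn"),
                        plasticity = plasticity_config(),
                        epochs = 1, seed = NULL) {
  threshold_source <- match.arg(threshold_source)
  structure(list(
    weights = init_weights(c(out_channels, in_channels, kernel, kernel),
                           lb = plasticity$lb, ub = plasticity$ub, seed = seed),
    threshold = threshold_state(threshold_mode, fixed_value, threshold_momentum),
    bn = bn_state(out_channels, enabled = bn_enabled),
    competition = competition_config(kwta, inhibition_radius),
    plasticity = plasticity,
    lateral_inhibition = lateral_inhibition,
    threshold_source = threshold_source,
    kernel = as.integer(kernel),
    epochs = as.integer(epochs),
    trained = FALSE
  ), class = "layer_state")
}

#' Network configuration
#'
#' Default values reproduce the reference two-layer architecture: a
#' 6-channel Gabor+DoG front end on 48x48 inputs, 15 time steps, a first
#' layer of 16 maps with 5x5 kernels (5 winners, inhibition radius 2,
#' 2 epochs, learning-rate doubling every 500 images) and a second layer of
#' 20 maps with 2x2 kernels (8 winners, radius 1, 20 epochs), 2x2/stride
#' 2/padding 1 pooling after each layer, and cross-channel spike inhibition
#' between the layers.
#'
#' @param input_size Side length of the (square) input ROI, default 48.
#' @param t_max Number of encoding time steps, default 15.
#' @param bank A [filter_bank()].
#' @param norm_radius Local-normalization radius, default 8.
#' @param binning Latency binning scheme, `"rank"` or `"linear"`.
#' @param layers List of per-layer option lists; see Details.
#' @param pool List with `window`, `stride`, `padding`.
#' @param spike_inhibition Apply cross-channel spike inhibition between
#'   layers.
#' @param seed Integer seed controlling weight initialization.
#' @details Each element of `layers` may set `out_channels`, `kernel`,
#' `epochs`, `kwta`, `inhibition_radius`, `threshold_mode`, `fixed_value`,
#' `threshold_momentum`, `bn_enabled`, `lateral_inhibition`,
#' `threshold_source`, and plasticity fields `a_plus`, `a_minus`, `lb`,
#' `ub`, `eta`, `use_stabilizer`, `double_every`, `rate_cap`.
#' @return An `atsnn_config` object.
#' @export
atsnn_config <- function(input_size = 48, t_max = 15,
                         bank = filter_bank(), norm_radius = 8,
                         binning = "rank",
                         layers = NULL,
                         pool = list(window = 2, stride = 2, padding = 1),
                         spike_inhibition = TRUE,
                         seed = 42) {
  default_layers <- list(
    list(out_channels = 16, kernel = 5, epochs = 2, kwta = 5,
         inhibition_radius = 2, double_every = 500),
    list(out_channels = 20, kernel = 2, epochs = 20, kwta = 8,
         inhibition_radius = 1, double_every = 0)
  )
  if (is.null(layers)) {
    layers <- default_layers
  } else {
    layers <- lapply(seq_along(layers), function(i) {
      base <- if (i <= length(default_layers)) default_layers[[i]] else list()
      utils::modifyList(base, layers[[i]])
    })
  }
  structure(list(input_size = input_size, t_max = t_max, bank = bank,
                 norm_radius = norm_radius, binning = binning,
                 layers = layers, pool = pool,
                 spike_inhibition = spike_inhibition, seed = seed),
            class = "atsnn_config")
}

layer_from_spec <- function(spec, in_channels, seed) {
  pl_args <- spec[names(spec) %in% c("a_plus", "a_minus", "lb", "ub", "eta",
                                     "use_stabilizer", "double_every", "rate_cap")]
  layer_state(
    in_channels = in_channels,
    out_channels = spec$out_channels,
    kernel = spec$kernel,
    kwta = spec$kwta,
    inhibition_radius = spec$inhibition_radius,
    threshold_mode = spec$threshold_mode %||% "adaptive",
    fixed_value = spec$fixed_value %||% 1,
    threshold_momentum = spec$threshold_momentum %||% 0.9,
    bn_enabled = spec$bn_enabled %||% TRUE,
    lateral_inhibition = spec$lateral_inhibition %||% TRUE,
    threshold_source = spec$threshold_source %||% "post_bn",
    plasticity = do.call(plasticity_config, pl_args),
    epochs = spec$epochs %||% 1,
    seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode one image into a spike wave
#'
#' Runs the fixed preprocessing chain: filter bank (with rectification,
#' per-channel 0-255 rescaling and cutoff), local normalization,
#' cross-channel pointwise inhibition, then intensity-to-latency coding.
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param cfg An [atsnn_config()].
#' @return A list with `t_first` and `wave` as in [encode_to_spike_wave()].
#' @export
encode_image <- function(image, cfg) {
  maps <- apply_filter_bank(image, cfg$bank)
  maps <- local_normalize(maps, radius = cfg$norm_radius)
  maps <- pointwise_intensity_inhibition(maps)
  encode_to_spike_wave(maps, t_max = cfg$t_max, binning = cfg$binning)
}

# rebuild a cumulative spike wave from a cached latency map
wave_from_tfirst <- function(t_first, t_max) {
  d <- dim(t_first)
  s <- array(0, dim = c(t_max, d))
  for (t in seq_len(t_max)) {
    s[t, , , ] <- as.numeric(!is.na(t_first) & t_first <= (t - 1L))
  }
  spike_wave(s, t_first)
}

# latency map of a cumulative wave (0-based, NA = never), inverse of the above
tfirst_from_wave <- function(sw) {
  tf <- first_spike_times(sw$s) - 1
  tf[!is.finite(tf)] <- NA
  array(as.integer(tf), dim = dim(sw$s)[-1])
}

#' Forward pass through one spiking convolutional layer
#'
#' Composes convolution, batch normalization (when enabled), threshold
#' selection, firing and lateral inhibition. In training mode the adaptive
#' threshold is the mean of the current sample's potential tensor and the
#' test threshold EMA is advanced; in inference mode the stored test
#' threshold (or the fixed value) is applied.
#'
#' @param sw_in Input [spike_wave()].
#' @param layer A [layer_state()].
#' @param training Logical.
#' @return List with `wave` (output spikes after inhibition), `potentials`
#'   (the tensor the threshold was applied to), `thresholded` (potentials
#'   where spiking, else 0, after inhibition), `threshold` (value used) and
#'   `layer` (updated state).
#' @export
forward_layer <- function(sw_in, layer, training = FALSE) {
  stopifnot(inherits(layer, "layer_state"))
  v <- conv_potentials(sw_in, layer$weights)
  v_used <- v
  if (layer$bn$enabled) {
    bn_out <- batch_norm_potentials(v, layer$bn, training = training)
    if (training) layer$bn <- bn_out$bn
    if (layer$threshold_source == "post_bn") v_used <- bn_out$v
  }
  if (layer$threshold$mode == "adaptive") {
    if (training) {
      thr <- sample_threshold(v_used)
      layer$threshold <- update_test_threshold(layer$threshold, thr)
    } else {
      if (!layer$threshold$initialized) {
        stop("adaptive layer used at inference before training", call. = FALSE)
      }
      thr <- layer$threshold$test_threshold
    }
  } else {
    thr <- layer$threshold$fixed_value
  }
  fired <- fire(v_used, thr)
  if (layer$lateral_inhibition) {
    inh <- lateral_inhibit_potentials(fired$potentials, fired$wave)
  } else {
    inh <- list(potentials = fired$potentials, wave = fired$wave)
  }
  list(wave = inh$wave, potentials = v_used, thresholded = inh$potentials,
       threshold = thr, layer = layer)
}

# inference through trained layers 1..k, returning the spike wave (and
# pooled thresholded potentials) that feed layer k+1
forward_frozen <- function(sw, layers, cfg, upto) {
  for (li in seq_len(upto)) {
    fl <- forward_layer(sw, layers[[li]], training = FALSE)
    pw <- pool_spikes(fl$wave, cfg$pool$window, cfg$pool$stride, cfg$pool$padding)
    pt <- pool_tensor(fl$thresholded, cfg$pool$window, cfg$pool$stride, cfg$pool$padding)
    if (cfg$spike_inhibition && li < length(layers)) {
      pw <- pointwise_spike_inhibition(pw, pt)
    }
    sw <- pw
  }
  sw
}

#' Train the network layer by layer
#'
#' Unsupervised, label-free training: each layer is trained to completion
#' (its configured number of epochs, one image at a time) before the next
#' layer starts; earlier layers stay frozen. Per image the pipeline is:
#' encode, forward through frozen earlier layers (pooling plus cross-channel
#' spike inhibition between layers), forward the current layer in training
#' mode, winner-take-all selection, STDP update, learning-rate schedule
#' step. Per-image encodings and frozen-layer outputs are cached across
#' epochs, which leaves results bit-identical to recomputation because
#' frozen layers use fixed thresholds and running statistics.
#'
#' @param images List of numeric matrices in `[0, 255]`, or a data frame
#'   with an `image` list-column (as returned by
#'   [generate_synthetic_dataset()]).
#' @param cfg An [atsnn_config()].
#' @param verbose Print per-layer progress.
#' @return An `atsnn_model` object: list with `config`, `layers`, `trained`.
#' @export
train_layerwise <- function(images, cfg = atsnn_config(), verbose = FALSE) {
  images <- as_image_list(images)
  if (length(images) == 0) stop("empty training set", call. = FALSE)
  n_in <- length(cfg$bank$kernels)
  layers <- vector("list", length(cfg$layers))
  in_ch <- n_in
  for (li in seq_along(cfg$layers)) {
    layers[[li]] <- layer_from_spec(cfg$layers[[li]], in_ch, seed = cfg$seed + 101L * li)
    in_ch <- cfg$layers[[li]]$out_channels
  }
  # cache of per-image latency maps feeding the layer currently in training
  cache <- lapply(images, function(img) encode_image(img, cfg)$t_first)
  t_max <- cfg$t_max
  for (li in seq_along(layers)) {
    if (verbose) message("training layer ", li, " (", layers[[li]]$epochs, " epochs)")
    images_seen <- 0L
    for (ep in seq_len(layers[[li]]$epochs)) {
      for (i in seq_along(cache)) {
        sw_in <- wave_from_tfirst(cache[[i]], t_max)
        fl <- forward_layer(sw_in, layers[[li]], training = TRUE)
        layers[[li]] <- fl$layer
        winners <- get_k_winners(fl$thresholded, layers[[li]]$competition, fl$wave)
        layers[[li]]$weights <- stdp_update(sw_in, fl$wave, winners,
                                            layers[[li]]$weights,
                                            layers[[li]]$plasticity)
        images_seen <- images_seen + 1L
        layers[[li]]$plasticity <- lr_schedule_step(layers[[li]]$plasticity, images_seen)
      }
    }
    layers[[li]]$trained <- TRUE
    if (li < length(layers)) {
      # freeze and push every image one layer forward for the next stage
      cache <- lapply(cache, function(tf) {
        tfirst_from_wave(forward_frozen(wave_from_tfirst(tf, t_max),
                                        layers, cfg, upto = li))
      })
    }
  }
  structure(list(config = cfg, layers = layers, trained = TRUE),
            class = "atsnn_model")
}

#' @export
print.atsnn_model <- function(x, ...) {
  cat("<atsnn_model> ", length(x$layers), " spiking conv layers, ",
      sum(model_summary(x)$n_weights), " trainable synapses\n", sep = "")
  print(model_summary(x))
  invisible(x)
}

as_image_list <- function(images) {
  if (is.data.frame(images)) {
    stopifnot("image" %in% names(images))
    return(images$image)
  }
  if (is.matrix(images)) return(list(images))
  stopifnot(is.list(images))
  images
}

#' Extract the final spike feature vector of one image
#'
#' Full inference pass: encoding, both trained layers with pooling and
#' inter-layer spike inhibition, then compression of the final pooled spike
#' wave over the temporal dimension by taking the maximum across time
#' (equal, under cumulative coding, to the last time slice). The binary
#' result is flattened in `(channel, row, column)` order.
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param model A trained `atsnn_model`.
#' @return Binary numeric vector.
#' @export
extract_features <- function(image, model) {
  stopifnot(inherits(model, "atsnn_model"))
  if (!all(vapply(model$layers, function(l) l$trained, logical(1)))) {
    stop("model has untrained layers", call. = FALSE)
  }
  cfg <- model$config
  sw <- encode_image(image, cfg)$wave
  for (li in seq_along(model$layers)) {
    fl <- forward_layer(sw, model$layers[[li]], training = FALSE)
    pw <- pool_spikes(fl$wave, cfg$pool$window, cfg$pool$stride, cfg$pool$padding)
    if (cfg$spike_inhibition && li < length(model$layers)) {
      pt <- pool_tensor(fl$thresholded, cfg$pool$window, cfg$pool$stride, cfg$pool$padding)
      pw <- pointwise_spike_inhibition(pw, pt)
    }
    sw <- pw
  }
  # temporal max == last slice for cumulative waves
  final <- apply(sw$s, c(2, 3, 4), max)
  as.vector(aperm(final, c(3, 2, 1)))
}

#' Extract features for a set of images
#'
#' @param images List of image matrices or data frame with an `image`
#'   list-column.
#' @param model A trained `atsnn_model`.
#' @return Numeric matrix, one row per image.
#' @export
extract_feature_matrix <- function(images, model) {
  images <- as_image_list(images)
  t(vapply(images, extract_features, numeric(feature_length(model$config)),
           model = model))
}

#' Feature dimensionality and layer shapes implied by a configuration
#'
#' Walks the convolution/pooling shape arithmetic: a convolution with kernel
#' `k` maps `n` to `n - k + 1`; pooling maps `n` to
#' `floor((n + 2 * padding - window) / stride) + 1`.
#'
#' @param cfg An [atsnn_config()].
#' @return Integer feature-vector length.
#' @export
feature_length <- function(cfg) {
  n <- cfg$input_size
  for (spec in cfg$layers) {
    n <- n - spec$kernel + 1L
    n <- (n + 2L * cfg$pool$padding - cfg$pool$window) %/% cfg$pool$stride + 1L
  }
  as.integer(utils::tail(vapply(cfg$layers, function(s) s$out_channels, numeric(1)), 1) * n * n)
}

#' Model summary: per-layer shapes and trainable synapse counts
#'
#' @param x An `atsnn_model` or `atsnn_config`.
#' @return A tibble with one row per layer: `layer`, `out_channels`,
#'   `kernel`, `in_channels`, `n_weights`; the total synapse count is
#'   `sum(n_weights)` (the architecture has no biases).
#' @export
model_summary <- function(x) {
  cfg <- if (inherits(x, "atsnn_model")) x$config else x
  stopifnot(inherits(cfg, "atsnn_config"))
  in_ch <- length(cfg$bank$kernels)
  rows <- lapply(seq_along(cfg$layers), function(i) {
    spec <- cfg$layers[[i]]
    r <- tibble::tibble(layer = i, out_channels = spec$out_channels,
                        kernel = spec$kernel, in_channels = in_ch,
                        n_weights = spec$out_channels * in_ch * spec$kernel^2)
    in_ch <<- spec$out_channels
    r
  })
  dplyr::bind_rows(rows)
}

#' Trainable parameter count
#'
#' @param x An `atsnn_model` or `atsnn_config`.
#' @param unit `"synapses"` for the raw count or `"thousands"` for the
#'   truncated count in units of 10^3 (the convention used when quoting
#'   model sizes).
#' @return Integer.
#' @export
param_count <- function(x, unit = c("synapses", "thousands")) {
  unit <- match.arg(unit)
  total <- sum(model_summary(x)$n_weights)
  if (unit == "thousands") total %/% 1000 else as.integer(total)
}
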