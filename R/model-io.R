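#' Save a trained model as plain text
#'
#' Writes a JSON manifest (architecture, thresholds, batch-normalization
#' statistics, filter-bank parameters, seed) plus one CSV of flattened
#' weights per layer, all human-readable.
#'
#' @param model An `atsnn_model`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "atsnn_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- model$config
  bank_params <- lapply(cfg$bank$params, function(p) {
    if (inherits(p, "gabor_params")) c(list(type = "gabor"), unclass(p))
    else c(list(type = "dog"), unclass(p))
  })
  manifest <- list(
    package = "spikevein",
    config = list(input_size = cfg$input_size, t_max = cfg$t_max,
                  norm_radius = cfg$norm_radius, binning = cfg$binning,
                  cutoff = cfg$bank$cutoff, pool = cfg$pool,
                  spike_inhibition = cfg$spike_inhibition, seed = cfg$seed,
                  layers = cfg$layers),
    bank = bank_params,
    layers = lapply(model$layers, function(l) {
      list(dim = dim(l$weights),
           threshold = unclass(l$threshold),
           bn = unclass(l$bn),
           plasticity = unclass(l$plasticity),
           competition = unclass(l$competition),
           lateral_inhibition = l$lateral_inhibition,
           threshold_source = l$threshold_source,
           kernel = l$kernel, epochs = l$epochs, trained = l$trained)
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (li in seq_along(model$layers)) {
    w <- model$layers[[li]]$weights
    m <- matrix(w, nrow = dim(w)[1])   # Fout rows, flattened kernel columns
    utils::write.table(m, file.path(dir, sprintf("weights_layer%d.csv", li)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(file.path(dir, "manifest.json"))
}

#' Load a model saved with [save_model()]
#'
#' @param dir Directory containing `manifest.json` and weight CSVs.
#' @return An `atsnn_model`.
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE, simplifyDataFrame = FALSE)
  mc <- manifest$config
  bank_params <- manifest$bank
  gab <- Filter(function(p) p$type == "gabor", bank_params)
  dog <- Filter(function(p) p$type == "dog", bank_params)
  bank <- filter_bank(
    gabor_window = gab[[1]]$window,
    orientations = vapply(gab, function(p) p$theta, numeric(1)),
    dog_window = dog[[1]]$window,
    dog_pairs = lapply(dog, function(p) c(p$delta1, p$delta2)),
    cutoff = mc$cutoff,
    lam = gab[[1]]$lam, sigma = gab[[1]]$sigma,
    gamma = gab[[1]]$gamma, phi = gab[[1]]$phi
  )
  cfg <- atsnn_config(input_size = mc$input_size, t_max = mc$t_max,
                      bank = bank, norm_radius = mc$norm_radius,
                      binning = mc$binning, layers = mc$layers,
                      pool = mc$pool, spike_inhibition = mc$spike_inhibition,
                      seed = mc$seed)
  layers <- lapply(seq_along(manifest$layers), function(li) {
    ml <- manifest$layers[[li]]
    wdim <- unlist(ml$dim)
    m <- as.matrix(utils::read.table(
      file.path(dir, sprintf("weights_layer%d.csv", li)), sep = ","))
    l <- layer_state(in_channels = wdim[2], out_channels = wdim[1],
                     kernel = ml$kernel,
                     kwta = ml$competition$kwta,
                     inhibition_radius = ml$competition$inhibition_radius,
                     threshold_mode = ml$threshold$mode,
                     fixed_value = ml$threshold$fixed_value,
                     threshold_momentum = ml$threshold$momentum,
                     bn_enabled = ml$bn$enabled,
                     lateral_inhibition = ml$lateral_inhibition,
                     threshold_source = ml$threshold_source,
                     plasticity = plasticity_config(
                       a_plus = ml$plasticity$a_plus,
                       a_minus = ml$plasticity$a_minus,
                       lb = ml$plasticity$lb, ub = ml$plasticity$ub,
                       eta = ml$plasticity$eta,
                       use_stabilizer = ml$plasticity$use_stabilizer,
                       double_every = ml$plasticity$double_every,
                       rate_cap = ml$plasticity$rate_cap),
                     epochs = ml$epochs, seed = 0)
    l$weights <- array(as.numeric(m), dim = wdim)
    l$threshold$test_threshold <- ml$threshold$test_threshold
    l$threshold$initialized <- ml$threshold$initialized
    l$bn$running_mean <- as.numeric(unlist(ml$bn$running_mean))
    l$bn$running_var <- as.numeric(unlist(ml$bn$running_var))
    l$bn$momentum <- ml$bn$momentum
    l$bn$eps <- ml$bn$eps
    l$plasticity$initial_ratio <- ml$plasticity$initial_ratio
    l$trained <- isTRUE(ml$trained)
    l
  })
  structure(list(config = cfg, layers = layers, trained = TRUE),
            class = "atsnn_model")
}

#' Build a configuration from a YAML file
#'
#' Recognized keys mirror the exported constructors:
#' `filters.gabor.window`, `filters.gabor.orientations`,
#' `filters.dog.window`, `filters.dog.pairs`, `filters.cutoff`,
#' `encode.t_max`, `encode.norm_radius`, `encode.binning`,
#' `pool.window/stride/padding`, `input_size`, `seed`, `spike_inhibition`,
#' and per-layer blocks `layer1`, `layer2` with the fields of
#' [atsnn_config()]'s `layers` entries plus `stdp.*` defaults shared by all
#' layers.
#'
#' @param path YAML file path.
#' @return An [atsnn_config()].
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  fb_args <- list()
  if (!is.null(y$filters)) {
    f <- y$filters
    if (!is.null(f$gabor$window)) fb_args$gabor_window <- f$gabor$window
    if (!is.null(f$gabor$orientations)) fb_args$orientations <- unlist(f$gabor$orientations)
    if (!is.null(f$dog$window)) fb_args$dog_window <- f$dog$window
    if (!is.null(f$dog$pairs)) fb_args$dog_pairs <- lapply(f$dog$pairs, unlist)
    if (!is.null(f$cutoff)) fb_args$cutoff <- f$cutoff
  }
  bank <- do.call(filter_bank, fb_args)
  stdp <- y$stdp %||% list()
  layer_keys <- grep("^layer[0-9]+$", names(y), value = TRUE)
  layers <- NULL
  if (length(layer_keys) > 0) {
    layer_keys <- layer_keys[order(as.integer(sub("layer", "", layer_keys)))]
    layers <- lapply(layer_keys, function(k) utils::modifyList(stdp, y[[k]]))
  }
  atsnn_config(
    input_size = y$input_size %||% 48,
    t_max = y$encode$t_max %||% 15,
    bank = bank,
    norm_radius = y$encode$norm_radius %||% 8,
    binning = y$encode$binning %||% "rank",
    layers = layers,
    pool = utils::modifyList(list(window = 2, stride = 2, padding = 1),
                             y$pool %||% list()),
    spike_inhibition = y$spike_inhibition %||% TRUE,
    seed = y$seed %||% 42
  )
}
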