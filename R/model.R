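#' Dense U-Net architecture configuration
#'
#' The network is an encoder-decoder with skip connections in which every
#' block is dense: layer l of a block convolves (3x3) the concatenation of
#' the block input and all previous layer outputs, adding `growth_rate`
#' feature maps, and a 1x1 transition convolution compresses the
#' concatenation. Each encoder level ends in 2x2 max pooling; each decoder
#' level starts with 2x nearest-neighbour upsampling and concatenates the
#' matching encoder feature map. The head is a 1x1 convolution to 8 classes
#' with per-pixel softmax.
#'
#' Defaults are the desk-scale preset (base 16 filters, 128 px input); the
#' original-scale geometry (512 px) is available by configuration.
#'
#' @param depth Encoder levels (spatial halvings).
#' @param base_filters Stem output channels; level widths grow from this,
#'   capped at `4 * base_filters`.
#' @param dense_block_layers Convolutions per dense block.
#' @param growth_rate Feature maps added by each dense layer.
#' @param n_classes Output classes; the tissue protocol fixes 8.
#' @param input_size Default square input size; inputs of other sizes are
#'   accepted when divisible by `2^depth` (otherwise reflect-padded at
#'   prediction time).
#' @return Object of class `model_config`.
#' @export
model_config <- function(depth = 4, base_filters = 16,
                         dense_block_layers = 2, growth_rate = 8,
                         n_classes = 8, input_size = 128) {
  if (n_classes != 8)
    stop("the tissue protocol fixes n_classes = 8 (background + 7 tissues)")
  if (input_size %% (2^depth) != 0)
    stop("input_size must be divisible by 2^depth")
  stopifnot(depth >= 1, base_filters >= 1, dense_block_layers >= 1,
            growth_rate >= 1)
  structure(
    list(depth = as.integer(depth), base_filters = as.integer(base_filters),
         dense_block_layers = as.integer(dense_block_layers),
         growth_rate = as.integer(growth_rate),
         n_classes = as.integer(n_classes),
         input_size = as.integer(input_size)),
    class = "model_config")
}

#' Training configuration
#'
#' The `"paper"` preset is the original training recipe: Adam, batch size 2,
#' learning rate 1e-4, 200 epochs, categorical cross-entropy. The `"desk"`
#' preset keeps the optimizer, batch size and loss but runs 30 epochs at
#' learning rate 2e-3: with roughly 20x fewer optimizer steps than the
#' original schedule, the step size is scaled up so that training converges
#' on a single CPU in minutes (see the methods vignette). On a 60-phantom
#' desk cohort this schedule reaches training loss ~1e-3.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param batch_size,learning_rate,epochs Override the preset values.
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @param validation_fraction Reserved fraction reported in the log (no early
#'   stopping is performed).
#' @return Object of class `train_config`.
#' @export
train_config <- function(preset = c("desk", "paper"), batch_size = 2,
                         learning_rate = NULL, epochs = NULL, seed = NULL,
                         validation_fraction = 0) {
  preset <- match.arg(preset)
  if (is.null(learning_rate))
    learning_rate <- if (preset == "desk") 2e-3 else 1e-4
  if (is.null(epochs)) epochs <- if (preset == "desk") 30L else 200L
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(
    list(preset = preset, batch_size = as.integer(batch_size),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         optimizer = "adam", loss = "categorical_crossentropy",
         seed = seed, validation_fraction = validation_fraction),
    class = "train_config")
}

#' Build an untrained Dense U-Net
#'
#' @param config A [model_config()].
#' @param skip_connections Set `FALSE` to drop the encoder-decoder skip
#'   connections (for ablation; changes the parameter count).
#' @param seed Seed for He-normal weight initialization.
#' @return Object of class `dense_unet` holding the native network.
#' @export
build_dense_unet <- function(config = model_config(), skip_connections = TRUE,
                             seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  ptr <- unet_create(config$depth, config$base_filters,
                     config$dense_block_layers, config$growth_rate,
                     config$n_classes, config$input_size, skip_connections)
  structure(list(ptr = ptr, config = config,
                 skip_connections = skip_connections),
            class = "dense_unet")
}

#' Number of trainable parameters
#' @param model A `dense_unet` or `trained_unet`.
#' @return Numeric parameter count.
#' @export
count_params <- function(model) {
  if (inherits(model, "trained_unet")) model <- model$model
  stopifnot(inherits(model, "dense_unet"))
  unet_n_params(model$ptr)
}

# HU -> [0, 1]: clip to the clinically meaningful range and rescale
normalize_hu <- function(values) {
  (pmin(pmax(values, -1024), 1500) + 1024) / 2524
}

# accepts phantom_sample or list(image=, labels=); returns list(img matrix,
# lab 0-based integer matrix)
training_pair <- function(sample) {
  img <- sample$image
  lab <- sample$labels
  if (inherits(img, "ct_image")) img <- img$values
  if (inherits(lab, "label_mask")) lab <- lab$classes
  if (!is.matrix(img))
    stop("training samples must be 2-D; see cohort_slices()")
  if (!identical(dim(img), dim(lab)))
    stop("image and mask shapes differ")
  list(img = normalize_hu(img), lab = lab)
}

#' Flatten a cohort of (possibly 3-D) samples into 2-D training samples
#'
#' @param cohort List of `phantom_sample`s (or image/mask pairs).
#' @param which `"center"` extracts the central slice of each stack, `"all"`
#'   every slice (metadata is copied; slices of one subject keep its id).
#' @return List of 2-D samples.
#' @export
cohort_slices <- function(cohort, which = c("center", "all")) {
  which <- match.arg(which)
  out <- list()
  for (s in cohort) {
    ns <- n_slices(s$image)
    idx <- if (which == "center") (ns + 1) %/% 2 else seq_len(ns)
    for (i in idx) {
      out[[length(out) + 1L]] <- structure(
        list(image = get_slice(s$image, i), labels = get_slice(s$labels, i),
             compartments = NULL, meta = s$meta),
        class = "phantom_sample")
    }
  }
  out
}

#' Train a Dense U-Net
#'
#' Mini-batch stochastic gradient descent with Adam and categorical
#' cross-entropy, per the training recipe. Deterministic for a fixed
#' `tc$seed` (weight initialization and batch shuffling both draw from R's
#' RNG).
#'
#' @param model A [build_dense_unet()] network (trained in place: the
#'   returned object shares its weights).
#' @param samples List of 2-D samples: `phantom_sample`s or
#'   `list(image=, labels=)` pairs.
#' @param tc A [train_config()].
#' @return Object of class `trained_unet`: the model, the config, a per-epoch
#'   loss log and provenance (sample ids, seed).
#' @export
train_unet <- function(model, samples, tc = train_config()) {
  stopifnot(inherits(model, "dense_unet"), inherits(tc, "train_config"))
  if (length(samples) < 1) stop("need at least one training sample")
  if (!is.null(tc$seed)) set.seed(tc$seed)
  pairs <- lapply(samples, training_pair)
  losses <- unet_train(model$ptr,
                       lapply(pairs, `[[`, "img"),
                       lapply(pairs, `[[`, "lab"),
                       tc$epochs, tc$batch_size, tc$learning_rate)
  ids <- vapply(samples, function(s)
    if (!is.null(s$meta$subject_id)) s$meta$subject_id else NA_character_,
    character(1))
  structure(
    list(model = model, train_config = tc,
         log = data.frame(epoch = seq_len(tc$epochs), loss = losses),
         provenance = list(n_samples = length(samples), subject_ids = ids,
                           seed = tc$seed)),
    class = "trained_unet")
}

#' @export
print.trained_unet <- function(x, ...) {
  cat(sprintf(
    "<trained_unet> %d params, %d samples, %d epochs (loss %.4f -> %.4f)\n",
    as.integer(count_params(x)), x$provenance$n_samples, nrow(x$log),
    x$log$loss[1], x$log$loss[nrow(x$log)]))
  invisible(x)
}

# reflect-pad a matrix so both dims are multiples of m
reflect_pad <- function(x, m) {
  pr <- (m - nrow(x) %% m) %% m
  pc <- (m - ncol(x) %% m) %% m
  if (pr > 0) x <- rbind(x, x[nrow(x) - seq_len(pr) + 1, , drop = FALSE])
  if (pc > 0) x <- cbind(x, x[, ncol(x) - seq_len(pc) + 1, drop = FALSE])
  x
}

#' Predict a segmentation
#'
#' Runs the network and returns the per-pixel class probability mask and the
#' argmax label mask (ties broken toward the lower class code). Inputs whose
#' dimensions are not divisible by `2^depth` are reflect-padded and the
#' output cropped back.
#'
#' @param object A `trained_unet` (or untrained `dense_unet`).
#' @param image A [ct_image()] (2-D) or numeric HU matrix.
#' @param ... Unused.
#' @return List with `prob` (H x W x 8 array) and `labels` (a
#'   [label_mask()]).
#' @export
predict.trained_unet <- function(object, image, ...) {
  model <- object$model
  spacing <- c(NA_real_, NA_real_)
  thickness <- NA_real_
  if (inherits(image, "ct_image")) {
    spacing <- image$pixel_spacing
    thickness <- image$slice_thickness
    image <- image$values
  }
  if (!is.matrix(image)) stop("predict expects a single 2-D slice")
  if (any(is.na(spacing)))
    warning("no spacing metadata: physical metrics (ASSD mm, areas) will be ",
            "unavailable downstream")
  H <- nrow(image); W <- ncol(image)
  m <- 2^model$config$depth
  x <- reflect_pad(normalize_hu(image), m)
  prob <- unet_forward(model$ptr, x)   # (Hp*Wp) x ncls, pixels column-major
  ncls <- model$config$n_classes
  # argmax with ties toward the lower class code
  lab <- max.col(prob, ties.method = "first") - 1L
  parr <- array(prob, c(nrow(x), ncol(x), ncls))
  lmat <- matrix(as.integer(lab), nrow(x), ncol(x))
  parr <- parr[seq_len(H), seq_len(W), , drop = FALSE]
  lmat <- lmat[seq_len(H), seq_len(W), drop = FALSE]
  list(prob = parr,
       labels = label_mask(lmat, spacing,
                           if (is.na(thickness)) 3 else thickness))
}

#' @export
predict.dense_unet <- function(object, image, ...) {
  predict.trained_unet(list(model = object), image, ...)
}

#' Save / load a trained model
#'
#' Weights and configuration are serialized with `saveRDS`; a JSON manifest
#' (config, seed, provenance, package version) is written alongside.
#'
#' @param trained A `trained_unet`.
#' @param path Output `.rds` path.
#' @return `path` invisibly (for `save_model`); a `trained_unet` (for
#'   `load_model`).
#' @export
save_model <- function(trained, path) {
  stopifnot(inherits(trained, "trained_unet"))
  obj <- list(weights = unet_get_weights(trained$model$ptr),
              config = trained$model$config,
              skip_connections = trained$model$skip_connections,
              train_config = trained$train_config,
              log = trained$log, provenance = trained$provenance)
  saveRDS(obj, path)
  manifest <- list(config = unclass(obj$config),
                   train_config = unclass(obj$train_config),
                   provenance = obj$provenance,
                   package_version = as.character(utils::packageVersion("hipseg")))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_dense_unet(do.call(model_config, unclass(obj$config)),
                            skip_connections = obj$skip_connections)
  unet_set_weights(model$ptr, obj$weights)
  structure(list(model = model, train_config = obj$train_config,
                 log = obj$log, provenance = obj$provenance),
            class = "trained_unet")
}
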