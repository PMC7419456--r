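# The inclination regressor: a deliberately small convolutional network
# mapping a 200x200 single-channel image to the two label components.
# Architecture contract: 4 convolutional + 3 fully connected layers, final
# layer 2 linear units with no output squashing, leaky-ReLU activations,
# dropout 0.2 on layers 3-6, max-pooling with stride 2 in layers 3 and 4.
# Channel counts and kernel sizes are configuration, not contract.

#' Network architecture specification
#'
#' Describes the 4-conv/3-FC regressor. The layer counts, the 2-unit linear
#' output, leaky-ReLU activations, the stride-2 max-pooling in convolutional
#' layers 3 and 4 and the 20% dropout on layers 3 to 6 are fixed invariants;
#' channel widths and kernel sizes are tunable.
#'
#' @param input_px input image side in pixels (images are single channel,
#'   square).
#' @param conv_channels 4 output channel counts.
#' @param conv_kernel 4 square kernel sizes.
#' @param conv_stride 4 convolution strides.
#' @param fc_units hidden unit counts of the first two fully connected
#'   layers (the third always has 2 linear units).
#' @param alpha leaky-ReLU negative slope.
#' @return A `network_spec` list.
#' @export
network_spec <- function(input_px = 200L,
                         conv_channels = c(12L, 24L, 32L, 64L),
                         conv_kernel = c(5L, 3L, 3L, 3L),
                         conv_stride = c(3L, 2L, 1L, 1L),
                         fc_units = c(128L, 64L),
                         alpha = 0.1) {
  stopifnot(length(conv_channels) == 4L, length(conv_kernel) == 4L,
            length(conv_stride) == 4L, length(fc_units) == 2L,
            input_px >= 64L, alpha > 0)
  spec <- list(
    input_px = as.integer(input_px),
    alpha = alpha,
    conv_channels = as.integer(conv_channels),
    conv_kernel = as.integer(conv_kernel),
    conv_stride = as.integer(conv_stride),
    conv_pool = c(1L, 1L, 2L, 2L),          # stride-2 max-pooling, layers 3-4
    conv_dropout = c(0, 0, 0.2, 0.2),       # dropout on layers 3-6
    fc_dims = c(as.integer(fc_units), 2L),
    fc_dropout = c(0.2, 0.2, 0)
  )
  class(spec) <- "network_spec"
  validate_network_spec(spec)
  spec_geometry(spec)  # errors early if the stack collapses spatially
  spec
}

validate_network_spec <- function(spec) {
  stopifnot(length(spec$conv_channels) == 4L,
            length(spec$fc_dims) == 3L,
            spec$fc_dims[3] == 2L,
            identical(spec$conv_pool[3:4], c(2L, 2L)),
            all(spec$conv_dropout == c(0, 0, 0.2, 0.2)),
            all(spec$fc_dropout == c(0.2, 0.2, 0)))
  invisible(spec)
}

# Spatial sizes through the conv stack
spec_geometry <- function(spec) {
  px <- spec$input_px
  sizes <- integer(0)
  for (i in 1:4) {
    px <- (px - spec$conv_kernel[i]) %/% spec$conv_stride[i] + 1L
    if (spec$conv_pool[i] > 1L) px <- px %/% spec$conv_pool[i]
    if (px < 1L) {
      stop(sprintf(paste0(
        "convolutional layer %d collapses to zero spatial size for a %d-px ",
        "input; use a larger input or smaller kernels/strides"),
        i, spec$input_px))
    }
    sizes <- c(sizes, px)
  }
  list(conv_px = sizes, flat = sizes[4]^2 * spec$conv_channels[4])
}

#' Build an untrained network
#'
#' He-style random initialization, fully determined by `seed`.
#'
#' @param spec a [network_spec()].
#' @param seed integer RNG seed for the initial weights.
#' @return A `trained_model` object (untrained weights).
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  validate_network_spec(spec)
  geo <- spec_geometry(spec)
  params <- with_preserved_seed(seed, {
    conv_w <- list(); conv_b <- list()
    in_ch <- 1L
    for (i in 1:4) {
      fan_in <- spec$conv_kernel[i]^2 * in_ch
      conv_w[[i]] <- matrix(rnorm(spec$conv_channels[i] * fan_in,
                                  sd = sqrt(2 / fan_in)),
                            spec$conv_channels[i], fan_in)
      conv_b[[i]] <- numeric(spec$conv_channels[i])
      in_ch <- spec$conv_channels[i]
    }
    fc_w <- list(); fc_b <- list()
    fan <- geo$flat
    for (i in 1:3) {
      fc_w[[i]] <- matrix(rnorm(spec$fc_dims[i] * fan, sd = sqrt(2 / fan)),
                          spec$fc_dims[i], fan)
      fc_b[[i]] <- numeric(spec$fc_dims[i])
      fan <- spec$fc_dims[i]
    }
    list(conv_w = conv_w, conv_b = conv_b, fc_w = fc_w, fc_b = fc_b)
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 preprocessing = "grayscale [0,1], 200x200 unless spec differs",
                 history = NULL),
            class = "trained_model")
}

#' Training configuration
#'
#' Defaults follow the training recipe used throughout: Adam, learning rate
#' 1e-4, batch size 100, with early stopping on validation loss.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience in epochs (Inf disables).
#' @param seed RNG seed for shuffling and dropout.
#' @param init_from optional `trained_model` whose weights initialize this
#'   run (transfer initialization); its spec must match.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 100L,
                            epochs = 100L, patience = 10L, seed = 1L,
                            init_from = NULL) {
  stopifnot(learning_rate > 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = patience, seed = as.integer(seed),
                 init_from = init_from),
            class = "training_config")
}

# Stack preprocessed images (list of px x px matrices) into a pixel x n
# matrix for the C++ kernels.
stack_images <- function(images, px) {
  n <- length(images)
  X <- matrix(0, px * px, n)
  for (i in seq_len(n)) {
    img <- images[[i]]
    stopifnot(nrow(img) == px, ncol(img) == px)
    # column-major with y (row index) fastest: transpose not needed, R
    # matrices are already column-major so as.numeric gives x-major planes
    # of px columns with y fastest -- matching the C++ layout.
    X[, i] <- as.numeric(img)
  }
  X
}

#' Train the regressor
#'
#' Minimizes mean-squared error between predicted and true label components
#' with Adam. Logs per-epoch train and validation loss and retains the
#' parameters with the best validation loss.
#'
#' @param model a `trained_model` from [build_network()] (or partially
#'   trained).
#' @param train_data,val_data dataset manifests (see
#'   [generate_dataset()] / [load_dataset()]) with in-memory images, or
#'   lists with elements `images` (list of matrices) and `labels` (n x 2).
#' @param cfg a [training_config()].
#' @param verbose print per-epoch losses.
#' @return The trained model with a `history` data frame attached.
#' @export
train_network <- function(model, train_data, val_data = NULL,
                          cfg = training_config(), verbose = FALSE) {
  stopifnot(inherits(model, "trained_model"))
  if (!is.null(cfg$init_from)) {
    stopifnot(inherits(cfg$init_from, "trained_model"))
    model$params <- cfg$init_from$params
  }
  px <- model$spec$input_px
  tr <- as_training_set(train_data, px)
  if (is.null(tr$X) || ncol(tr$X) == 0) stop("empty training dataset")
  if (any(abs(tr$Y) > 1)) stop("training labels outside [-1, 1]")
  va <- if (!is.null(val_data)) as_training_set(val_data, px)

  spec <- unclass(model$spec)
  fit <- cnn_fit(model$params, spec, tr$X, t(tr$Y),
                 if (!is.null(va)) va$X, if (!is.null(va)) t(va$Y),
                 epochs = cfg$epochs, lr = cfg$learning_rate,
                 batch_size = cfg$batch_size,
                 patience = if (is.finite(cfg$patience)) cfg$patience else 0L,
                 seed = cfg$seed, verbose = verbose)
  model$params <- fit$params
  model$history <- data.frame(epoch = seq_along(fit$train_loss),
                              train_loss = fit$train_loss,
                              val_loss = fit$val_loss)
  model$training <- cfg[c("learning_rate", "batch_size", "epochs", "seed")]
  model
}

predict_matrix <- function(params, spec, X, chunk = 200L) {
  out <- matrix(0, 2, ncol(X))
  for (start in seq(1, ncol(X), by = chunk)) {
    idx <- start:min(ncol(X), start + chunk - 1)
    out[, idx] <- cnn_forward(params, spec, X[, idx, drop = FALSE],
                              training = FALSE, seed = 0)
  }
  out
}

#' Predict the inclination label for one image
#'
#' Deterministic (dropout disabled); the output is clamped to the closed
#' unit disc so it can be used directly as a control error signal.
#'
#' @param object a `trained_model`.
#' @param image a preprocessed single-channel matrix matching the model's
#'   input size (see [preprocess_image()]), or a raw image which will be
#'   preprocessed.
#' @param ... unused.
#' @return Numeric length-2 label.
#' @export
predict.trained_model <- function(object, image, ...) {
  px <- object$spec$input_px
  if (!is.matrix(image) || nrow(image) != px || ncol(image) != px) {
    image <- preprocess_image(image, px = px)
  }
  p <- cnn_forward(object$params, unclass(object$spec),
                   matrix(as.numeric(image), ncol = 1),
                   training = FALSE, seed = 0)
  clamp_label(c(p[1, 1], p[2, 1]))
}

#' Evaluate a model on a labeled test set
#'
#' Applies the both-angles rule: a sample is accurate when both per-axis
#' arcsine angles of the prediction are within `tol` degrees of the truth.
#'
#' @param model a `trained_model`.
#' @param test_data a dataset manifest with in-memory images, or a list with
#'   `images` and `labels`.
#' @param tol accuracy half-width in degrees.
#' @param dataset_id identifier recorded in the report.
#' @return An `eval_report`: list with `accuracy` (percent), `per_sample`
#'   data frame (predictions and per-axis angular errors), `tol`, and
#'   `dataset_id`.
#' @export
evaluate_model <- function(model, test_data, tol = 5, dataset_id = "test") {
  px <- model$spec$input_px
  te <- as_training_set(test_data, px)
  if (is.null(te$X) || ncol(te$X) == 0) stop("empty test dataset")
  pred <- predict_matrix(model$params, unclass(model$spec), te$X)
  # same inference contract as predict(): outputs clamped to the unit disc
  nrm <- sqrt(colSums(pred^2))
  over <- nrm > 1
  if (any(over)) pred[, over] <- sweep(pred[, over, drop = FALSE], 2,
                                       nrm[over], `/`)
  n <- ncol(te$X)
  ang <- function(v) rad2deg(asin(pmin(1, pmax(-1, v))))
  err_x <- ang(pred[1, ]) - ang(te$Y[, 1])
  err_y <- ang(pred[2, ]) - ang(te$Y[, 2])
  ok <- abs(err_x) <= tol & abs(err_y) <= tol
  per_sample <- data.frame(
    pred_x = pred[1, ], pred_y = pred[2, ],
    true_x = te$Y[, 1], true_y = te$Y[, 2],
    err_angle_x = err_x, err_angle_y = err_y, accurate = ok)
  structure(list(accuracy = 100 * mean(ok), per_sample = per_sample,
                 tol = tol, dataset_id = dataset_id, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on '%s': %d samples, %.1f%% within +/-%g deg on both axes\n",
              x$dataset_id, x$n, x$accuracy, x$tol))
  cat(sprintf("  per-axis angular error RMS: x %.2f deg, y %.2f deg\n",
              sqrt(mean(x$per_sample$err_angle_x^2)),
              sqrt(mean(x$per_sample$err_angle_y^2))))
  invisible(x)
}

# Accept either a manifest (with $images and $samples) or a bare
# list(images=, labels=).
as_training_set <- function(data, px) {
  if (!is.null(data$samples) && !is.null(data$images)) {
    labs <- as.matrix(data$samples[, c("x_component", "y_component")])
    imgs <- data$images
  } else if (!is.null(data$images) && !is.null(data$labels)) {
    labs <- as.matrix(data$labels)
    imgs <- data$images
  } else {
    stop("unrecognized dataset container")
  }
  imgs <- lapply(imgs, function(im)
    if (nrow(im) == px && ncol(im) == px && length(dim(im)) == 2L) im
    else preprocess_image(im, px = px))
  list(X = stack_images(imgs, px), Y = labs)
}

#' Save / load a trained model
#'
#' The checkpoint is a plain-text JSON file containing the architecture,
#' preprocessing contract, training configuration and all weights.
#'
#' @param model a `trained_model`.
#' @param path file path.
#' @return `load_model` returns the model; `save_model` the path, invisibly.
#' @export
save_model <- function(model, path) {
  payload <- list(
    spec = unclass(model$spec),
    preprocessing = model$preprocessing,
    seed = model$seed,
    training = model$training,
    params = model$params
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- payload$spec
  spec$conv_channels <- as.integer(spec$conv_channels)
  spec$conv_kernel <- as.integer(spec$conv_kernel)
  spec$conv_stride <- as.integer(spec$conv_stride)
  spec$conv_pool <- as.integer(spec$conv_pool)
  spec$fc_dims <- as.integer(spec$fc_dims)
  spec$input_px <- as.integer(spec$input_px)
  class(spec) <- "network_spec"
  params <- payload$params
  params$conv_w <- lapply(params$conv_w, as.matrix)
  params$fc_w <- lapply(params$fc_w, as.matrix)
  params$conv_b <- lapply(params$conv_b, as.numeric)
  params$fc_b <- lapply(params$fc_b, as.numeric)
  structure(list(spec = spec, params = params, seed = payload$seed,
                 preprocessing = payload$preprocessing,
                 training = payload$training, history = NULL),
            class = "trained_model")
}
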