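#' Training hyperparameters
#'
#' Stochastic gradient descent with momentum and step learning-rate decay.
#' `iterations` counts optimizer iterations (mini-batch steps). Validation
#' top-1 accuracy is evaluated every `validation_interval` iterations (and
#' at the final iteration); the checkpoint with the highest recorded
#' validation accuracy is the model returned, ties resolved towards the
#' earliest iteration.
#'
#' @param iterations Number of mini-batch SGD steps.
#' @param batch_size Mini-batch size.
#' @param learning_rate Initial learning rate.
#' @param lr_decay Multiplicative decay factor applied every `lr_step`
#'   iterations.
#' @param lr_step Iterations between learning-rate decays.
#' @param momentum Classical momentum coefficient.
#' @param weight_decay L2 weight penalty coefficient.
#' @param validation_interval Iterations between validation evaluations.
#' @param seed Integer seed driving weight initialization, batch shuffling
#'   and dropout masks.
#' @return A `hyperparams` list.
#' @export
hyperparams <- function(iterations = 2000L, batch_size = 24L,
                        learning_rate = 0.01, lr_decay = 0.5,
                        lr_step = 800L, momentum = 0.9,
                        weight_decay = 5e-4, validation_interval = 100L,
                        seed = 1L) {
  stopifnot(iterations >= 0, batch_size >= 1, learning_rate > 0,
            lr_decay > 0, lr_step >= 1, momentum >= 0, momentum < 1,
            weight_decay >= 0, validation_interval >= 1)
  if (iterations > 0 && validation_interval > iterations) {
    validation_interval <- iterations
  }
  structure(
    list(iterations = as.integer(iterations),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate,
         lr_decay = lr_decay,
         lr_step = as.integer(lr_step),
         momentum = momentum,
         weight_decay = weight_decay,
         validation_interval = as.integer(validation_interval),
         seed = as.integer(seed)),
    class = "hyperparams"
  )
}

new_trained_model <- function(architecture, weights, regime, view,
                              label_names, provenance, history,
                              best_iteration, best_accuracy) {
  structure(
    list(architecture = architecture, weights = weights, regime = regime,
         view = view, label_names = label_names, provenance = provenance,
         history = history, best_iteration = best_iteration,
         best_accuracy = best_accuracy),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> regime ", x$regime,
      if (!is.null(x$view)) paste0(" (view ", x$view, ")"),
      ", ", length(x$label_names), " labels, best iteration ",
      x$best_iteration,
      if (!is.na(x$best_accuracy))
        sprintf(" (validation top-1 %.3f)", x$best_accuracy),
      "\n", sep = "")
  invisible(x)
}

history_tibble <- function(hmat) {
  tibble::tibble(iteration = as.integer(hmat[, 1]),
                 train_loss = hmat[, 2],
                 val_accuracy = hmat[, 3])
}

# Shared trainer behind the three regimes.
train_model <- function(split, arch, hp, regime, views, view = NULL,
                        init_weights = NULL, parent_ref = NULL) {
  stopifnot(inherits(arch, "architecture"), inherits(hp, "hyperparams"))
  train_samples <- flatten_to_samples(split$train, views)
  if (nrow(train_samples) == 0L) {
    stop("no training images",
         if (!is.null(view)) paste0(" for view ", view), call. = FALSE)
  }
  if (split$train$n_labels != arch$n_labels) {
    stop("architecture output dimension (", arch$n_labels,
         ") does not match dataset labels (", split$train$n_labels, ")",
         call. = FALSE)
  }
  val_samples <- flatten_to_samples(split$validation, views)

  X <- samples_to_array(train_samples, arch$input_size)
  y <- as.integer(train_samples$genus) - 1L
  Xval <- samples_to_array(val_samples, arch$input_size)
  yval <- as.integer(val_samples$genus) - 1L
  if (nrow(val_samples) == 0L) {
    Xval <- array(0, dim = c(arch$input_size, arch$input_size, 0))
    yval <- integer(0)
  }

  if (is.null(init_weights)) {
    init_weights <- cpp_cnn_init(as.data.frame(arch$layers),
                                 arch$input_size, arch$input_channels,
                                 hash_seed(hp$seed, "init", regime,
                                           view %||% "all"))
  }

  provenance <- list(hyperparams = hp, parent = parent_ref)
  if (hp$iterations == 0L) {
    acc0 <- if (nrow(val_samples) > 0) {
      sc <- cpp_cnn_forward(as.data.frame(arch$layers), init_weights, Xval,
                            arch$input_size, arch$input_channels, FALSE)$scores
      mean(max.col(sc, ties.method = "first") - 1L == yval)
    } else NA_real_
    hist <- tibble::tibble(iteration = 0L, train_loss = NA_real_,
                           val_accuracy = acc0)
    return(new_trained_model(arch, init_weights, regime, view,
                             split$train$label_names, provenance, hist,
                             0L, acc0))
  }

  fit <- cpp_cnn_train(as.data.frame(arch$layers), init_weights, X, y,
                       Xval, yval, unclass(hp), arch$input_size,
                       arch$input_channels,
                       hash_seed(hp$seed, "sgd", regime, view %||% "all"))
  new_trained_model(arch, fit$best_weights, regime, view,
                    split$train$label_names, provenance,
                    history_tibble(fit$history),
                    as.integer(fit$best_iteration), fit$best_accuracy)
}

#' Train the general-purpose classifier
#'
#' One model trained on the pooled pictures of all three views, so that a
#' single network classifies the genus from any perspective. The returned
#' model is the validation-selected checkpoint; its per-validation-point
#' history is available via [generics::tidy()].
#'
#' @param split A [split_dataset()] result.
#' @param arch An [architecture()] whose output dimension matches the
#'   dataset's label count.
#' @param hp A [hyperparams()].
#' @return A `trained_model`.
#' @export
train_general <- function(split, arch, hp = hyperparams()) {
  train_model(split, arch, hp, regime = "general", views = NULL)
}

#' Train a view-specific classifier
#'
#' Same procedure as [train_general()] but with training and validation
#' restricted to a single view's pictures.
#'
#' @inheritParams train_general
#' @param view One of [mv_views()].
#' @return A `trained_model`.
#' @export
train_specific <- function(split, view, arch, hp = hyperparams()) {
  view <- as_view(view)
  train_model(split, arch, hp, regime = "specific", views = view,
              view = view)
}

#' Fine-tune the general model on one view (transfer learning)
#'
#' Initializes a view-specific model with the trained general-purpose
#' model's weights and continues training on that view's pictures only.
#' With `hp$iterations = 0` the returned weights equal the parent's
#' exactly (warm-start equality).
#'
#' @param parent A general-purpose `trained_model`.
#' @inheritParams train_specific
#' @return A `trained_model` with regime `"transfer"`; the provenance
#'   records the parent.
#' @export
train_transfer <- function(parent, split, view, hp = hyperparams()) {
  if (!inherits(parent, "trained_model") || parent$regime != "general") {
    stop("`parent` must be a general-purpose trained model", call. = FALSE)
  }
  view <- as_view(view)
  parent_ref <- list(regime = parent$regime,
                     best_iteration = parent$best_iteration)
  train_model(split, parent$architecture, hp, regime = "transfer",
              views = view, view = view, init_weights = parent$weights,
              parent_ref = parent_ref)
}

# ---------------------------------------------------------------------------
# scoring

#' Softmax score vector for one image
#'
#' @param model A `trained_model`.
#' @param image A grayscale matrix (conformed to the model's input size if
#'   needed).
#' @return A named numeric vector of length L summing to 1.
#' @export
score_image <- function(model, image) {
  drop(score_images(model, list(image)))
}

#' Softmax score matrix for a batch of images
#'
#' @param model A `trained_model`.
#' @param images A list of grayscale matrices, or a tibble from
#'   [flatten_to_samples()] (its `pixels` column is used).
#' @return An `N x L` matrix of softmax scores; rows sum to 1.
#' @export
score_images <- function(model, images) {
  if (is.data.frame(images)) images <- images$pixels
  arch <- model$architecture
  n <- length(images)
  X <- array(0, dim = c(arch$input_size, arch$input_size, max(n, 1L)))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (nrow(img) != arch$input_size || ncol(img) != arch$input_size) {
      img <- conform_image(img, arch$input_size)
    }
    X[, , i] <- img
  }
  sc <- cpp_cnn_forward(as.data.frame(arch$layers), model$weights, X,
                        arch$input_size, arch$input_channels, FALSE)$scores
  colnames(sc) <- model$label_names
  sc
}

#' Penultimate-layer feature vectors
#'
#' Extracts the activations feeding the final fully-connected classifier
#' (the second fully-connected layer's rectified output), the standard
#' deep-feature representation of an image.
#'
#' @param model A `trained_model` whose architecture has at least two
#'   fully-connected layers.
#' @param image A grayscale matrix.
#' @return A numeric feature vector (length = penultimate layer width).
#' @export
extract_penultimate_features <- function(model, image) {
  arch <- model$architecture
  n_fc <- sum(arch$layers$kind == "fully_connected")
  if (n_fc < 2L) {
    stop("architecture has fewer than two fully-connected layers",
         call. = FALSE)
  }
  if (nrow(image) != arch$input_size || ncol(image) != arch$input_size) {
    image <- conform_image(image, arch$input_size)
  }
  X <- array(image, dim = c(arch$input_size, arch$input_size, 1L))
  drop(cpp_cnn_forward(as.data.frame(arch$layers), model$weights, X,
                       arch$input_size, arch$input_channels, TRUE)$features)
}

# ---------------------------------------------------------------------------
# checkpoints

#' Save a trained model
#'
#' Writes the model (weights included) as an RDS file plus a JSON sidecar
#' `<path>.json` carrying the human-readable provenance: architecture,
#' regime, view, hyperparameters and training history.
#'
#' @param model A `trained_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  sidecar <- list(
    regime = model$regime,
    view = model$view,
    n_labels = model$architecture$n_labels,
    input_size = model$architecture$input_size,
    hyperparams = unclass(model$provenance$hyperparams),
    parent = model$provenance$parent,
    best_iteration = model$best_iteration,
    best_accuracy = model$best_accuracy,
    history = model$history
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "rows", na = "null",
                       digits = NA)
  invisible(path)
}

#' Load a trained model saved by [save_model()]
#' @param path File path.
#' @return A `trained_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_model")) {
    stop("not a trained_model checkpoint: ", path, call. = FALSE)
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
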