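#' Training schedule parameters
#'
#' Deterministic arithmetic describing a detector training run: total
#' optimizer steps, batch size and training-set image count, from which the
#' epoch count follows as `steps * batch / train_set_size`.
#'
#' @param total_steps total optimizer steps.
#' @param batch_size images per step; when `n_gpus` is given it must divide
#'   the batch size evenly.
#' @param train_set_size training-set image count.
#' @param base_lr initial learning rate (default 0.05).
#' @param n_gpus optional GPU count, used only for the divisibility check.
#' @return An object of class `schedule_params`.
#' @export
schedule_params <- function(total_steps, batch_size, train_set_size,
                            base_lr = 0.05, n_gpus = NULL) {
  stop_if_not_count(total_steps, "total_steps")
  stop_if_not_count(batch_size, "batch_size")
  stop_if_not_count(train_set_size, "train_set_size")
  if (!is.numeric(base_lr) || base_lr <= 0)
    stop("`base_lr` must be positive", call. = FALSE)
  if (!is.null(n_gpus)) {
    stop_if_not_count(n_gpus, "n_gpus")
    if (batch_size %% n_gpus != 0)
      stop("batch_size must be divisible by the number of GPUs", call. = FALSE)
  }
  structure(list(total_steps = total_steps, batch_size = batch_size,
                 train_set_size = train_set_size, base_lr = base_lr,
                 n_gpus = n_gpus),
            class = "schedule_params")
}

#' Epochs implied by a step budget
#'
#' `total_steps * batch_size / train_set_size`, the number of passes through
#' the training set. Reported values round to the nearest integer.
#'
#' @param params a [schedule_params()].
#' @return numeric epoch count (real; round for reporting).
#' @examples
#' epochs(schedule_params(200000, 32, 39592)) # 161.65 -> reported as 162
#' @export
epochs <- function(params) {
  stopifnot(inherits(params, "schedule_params"))
  params$total_steps * params$batch_size / params$train_set_size
}

#' Cosine learning-rate decay
#'
#' `base_lr * (1 + cos(pi * step / total_steps)) / 2`: starts at `base_lr`,
#' decays monotonically to 0 at the final step, no warmup. Vectorized over
#' `step`.
#'
#' @param step current step(s), in `[0, total_steps]`.
#' @param total_steps schedule length.
#' @param base_lr initial learning rate.
#' @return learning rate(s).
#' @export
cosine_lr <- function(step, total_steps, base_lr = 0.05) {
  stop_if_not_count(total_steps, "total_steps")
  if (any(!is.finite(step)) || any(step < 0) || any(step > total_steps))
    stop("`step` must lie in [0, total_steps]", call. = FALSE)
  base_lr * 0.5 * (1 + cos(pi * step / total_steps))
}

#' Uniform weight-initialization limit
#'
#' The half-width of the symmetric uniform distribution used to initialize a
#' layer with fan-in `n`: `sqrt(3 / n)`, which gives the weights variance
#' `1 / n`. Weights are drawn uniformly in `(-limit, +limit)`.
#'
#' @param n fan-in (input unit count), `>= 1`. Vectorized.
#' @return the limit(s).
#' @examples
#' init_limit(3)  # 1
#' init_limit(12) # 0.5
#' @export
init_limit <- function(n) {
  stop_if_not_count(n, "n")
  sqrt(3 / n)
}

#' Data augmentation settings
#'
#' The stochastic transform set applied during training: independent 50%
#' chances of a horizontal flip, a vertical flip and a 90-degree rotation,
#' plus a brightness shift (uniform in `+-max_brightness_delta`) and a
#' contrast multiplier (uniform in `contrast_range`, applied to the
#' deviation from the image mean).
#'
#' @param p_hflip,p_vflip,p_rot90 per-transform probabilities.
#' @param max_brightness_delta maximum additive brightness change.
#' @param contrast_range length-2 increasing vector of contrast multipliers.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(p_hflip = 0.5, p_vflip = 0.5, p_rot90 = 0.5,
                              max_brightness_delta = 0.05,
                              contrast_range = c(0.5, 0.95)) {
  p <- c(p_hflip, p_vflip, p_rot90)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (length(contrast_range) != 2L || contrast_range[1] > contrast_range[2])
    stop("`contrast_range` must be an ordered pair", call. = FALSE)
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip, p_rot90 = p_rot90,
                 max_brightness_delta = max_brightness_delta,
                 contrast_range = contrast_range),
            class = "augmentation_spec")
}

# box transforms for a square frame of side `size` (0-based half-open)
flip_box_horizontal <- function(box, size) {
  box2d(box["row_min"], size - box["col_max"], box["row_max"], size - box["col_min"])
}
flip_box_vertical <- function(box, size) {
  box2d(size - box["row_max"], box["col_min"], size - box["row_min"], box["col_max"])
}
# 90 degrees clockwise: pixel (r, c) -> (c, size - 1 - r)
rotate_box_90 <- function(box, size) {
  box2d(box["col_min"], size - box["row_max"], box["col_max"], size - box["row_min"])
}

#' Apply the augmentation transforms to an image and its boxes
#'
#' Geometric transforms (flips, 90-degree clockwise rotation) are applied to
#' the image and its boxes consistently; photometric transforms (brightness,
#' contrast) touch only the pixels. Each transform fires independently with
#' its spec probability; deterministic under `seed`.
#'
#' @param image square numeric matrix with values in `[0, 1]`.
#' @param boxes list of [box2d()] valid for `image`.
#' @param spec an [augmentation_spec()].
#' @param seed RNG seed.
#' @return list with `image`, `boxes` and `ops` (character vector of the
#'   transforms that fired).
#' @export
apply_augmentation <- function(image, boxes, spec = augmentation_spec(), seed = 1L) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image),
            inherits(spec, "augmentation_spec"))
  size <- nrow(image)
  with_seed(seed, {
    draws <- stats::runif(5)
    ops <- character()
    if (draws[1] < spec$p_hflip) {
      image <- image[, size:1, drop = FALSE]
      boxes <- lapply(boxes, flip_box_horizontal, size = size)
      ops <- c(ops, "hflip")
    }
    if (draws[2] < spec$p_vflip) {
      image <- image[size:1, , drop = FALSE]
      boxes <- lapply(boxes, flip_box_vertical, size = size)
      ops <- c(ops, "vflip")
    }
    if (draws[3] < spec$p_rot90) {
      image <- t(image[size:1, , drop = FALSE]) # 90 degrees clockwise
      boxes <- lapply(boxes, rotate_box_90, size = size)
      ops <- c(ops, "rot90")
    }
    delta <- stats::runif(1, -spec$max_brightness_delta, spec$max_brightness_delta)
    u <- stats::runif(1, spec$contrast_range[1], spec$contrast_range[2])
    m <- mean(image)
    image <- clamp(m + (image - m) * u + delta, 0, 1)
    list(image = image, boxes = boxes, ops = c(ops, "brightness", "contrast"))
  })
}

#' Emit a plain-text training-configuration summary
#'
#' Writes a YAML audit file with the step/batch/epoch arithmetic, a sampled
#' learning-rate table and the augmentation settings.
#'
#' @param params a [schedule_params()].
#' @param aug an [augmentation_spec()].
#' @param path output YAML path.
#' @param lr_points number of evenly spaced steps at which to tabulate the
#'   learning rate.
#' @return `path`, invisibly.
#' @export
write_training_config <- function(params, aug = augmentation_spec(), path,
                                  lr_points = 11L) {
  stopifnot(inherits(params, "schedule_params"))
  steps <- round(seq(0, params$total_steps, length.out = lr_points))
  cfg <- list(
    total_steps = params$total_steps,
    batch_size = params$batch_size,
    train_set_size = params$train_set_size,
    epochs = round(epochs(params), 2),
    epochs_reported = as.integer(round(epochs(params))),
    learning_rate = list(schedule = "cosine_decay", base = params$base_lr,
                         warmup_steps = 0L,
                         table = lapply(seq_along(steps), function(i) {
                           list(step = steps[i],
                                lr = signif(cosine_lr(steps[i], params$total_steps,
                                                      params$base_lr), 6))
                         })),
    augmentation = unclass(aug)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
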