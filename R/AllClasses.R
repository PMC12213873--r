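# ---------------------------------------------------------------------------
# S4 containers for the user-facing objects.
# ---------------------------------------------------------------------------

#' Model architecture configuration
#'
#' Five-stage dual-encoder configuration. `channels` is the per-stage
#' width schedule, `depths` the number of transformer and Mamba blocks per
#' stage (both branches use the same depth), `heads` the attention head
#' count per stage, `sw` the strip width of the cross-shape attention.
#'
#' @slot channels integer(5), strictly increasing stage widths.
#' @slot depths integer(5), blocks per stage in each encoder branch.
#' @slot heads integer(5), even head counts dividing `channels`.
#' @slot sw integer(5), strip widths.
#' @slot mlp_ratio numeric(1), MLP hidden-width multiplier.
#' @slot d_state,expand,ssm_kernel integer(1), selective-SSM dimensions.
#' @slot dws_kernel integer(1), depthwise-separable auxiliary kernel size.
#' @slot input_size integer(1), training/profiling input resolution.
#' @slot out_channels integer(1), output channels (1 = binary logits).
#' @exportClass ModelConfig
setClass("ModelConfig", representation(
  channels = "integer", depths = "integer", heads = "integer",
  sw = "integer", mlp_ratio = "numeric", d_state = "integer",
  expand = "integer", ssm_kernel = "integer", dws_kernel = "integer",
  input_size = "integer", out_channels = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@channels) != 5L) msg <- c(msg, "channels must have 5 stages")
    if (any(diff(object@channels) <= 0))
      msg <- c(msg, "channels must be strictly increasing")
    for (nm in c("depths", "heads", "sw"))
      if (length(slot(object, nm)) != 5L)
        msg <- c(msg, paste(nm, "must have 5 stages"))
    if (any(object@heads %% 2L != 0L)) msg <- c(msg, "head counts must be even")
    if (any(object@channels %% object@heads != 0L))
      msg <- c(msg, "heads must divide channels")
    if (object@input_size %% 32L != 0L)
      msg <- c(msg, "input_size must be divisible by 32")
    if (length(msg)) msg else TRUE
  })

#' Training configuration
#'
#' @slot lr numeric(1), base Adam learning rate.
#' @slot max_iters integer(1), training iterations.
#' @slot batch_size integer(1).
#' @slot resize integer(1), square input resolution (divisible by 32).
#' @slot alpha,beta numeric(1), BCE and Dice loss weights.
#' @slot schedule_power numeric(1), polynomial LR decay exponent.
#' @slot augment list of augmentation switches and magnitudes.
#' @slot seed integer(1).
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  lr = "numeric", max_iters = "integer", batch_size = "integer",
  resize = "integer", alpha = "numeric", beta = "numeric",
  schedule_power = "numeric", augment = "list", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@lr <= 0) msg <- c(msg, "lr must be > 0")
    if (object@max_iters < 1L) msg <- c(msg, "max_iters must be >= 1")
    if (object@resize %% 32L != 0L) msg <- c(msg, "resize must be divisible by 32")
    if (object@alpha < 0 || object@beta < 0)
      msg <- c(msg, "loss weights must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Synthetic data generator configuration
#'
#' Controls the seeded generator of polyp-like image/mask pairs: smooth
#' random blobs with adjustable size, lesion/background contrast and
#' boundary blur on a textured endoscopy-palette background.
#'
#' @slot image_size integer(1), square output size in pixels.
#' @slot n_polyps_range integer(2), lesions per image (inclusive range).
#' @slot area_fraction_range numeric(2) in (0, 1), lesion area as a
#'   fraction of the image.
#' @slot contrast numeric(1), mean intensity offset of lesion vs
#'   background (0 = invisible lesion).
#' @slot boundary_blur_sigma numeric(1), Gaussian sigma (pixels) applied
#'   to the lesion boundary in the image (the mask stays crisp).
#' @slot background_texture_scale numeric(1), amplitude of the
#'   multi-octave background texture.
#' @exportClass SynthConfig
setClass("SynthConfig", representation(
  image_size = "integer", n_polyps_range = "integer",
  area_fraction_range = "numeric", contrast = "numeric",
  boundary_blur_sigma = "numeric", background_texture_scale = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@area_fraction_range <= 0) ||
        any(object@area_fraction_range >= 1))
      msg <- c(msg, "area_fraction_range must lie in (0, 1)")
    if (object@boundary_blur_sigma < 0)
      msg <- c(msg, "boundary_blur_sigma must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' A paired image/mask segmentation sample
#'
#' @slot image `H x W x 3` array in `[0, 1]`.
#' @slot mask `H x W` binary matrix (0/1).
#' @slot provenance list recording the seed and generator configuration
#'   hash, or the source file paths.
#' @exportClass SegSample
setClass("SegSample", representation(
  image = "array", mask = "matrix", provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (!all(object@mask %in% c(0, 1))) msg <- c(msg, "mask must be binary")
    if (!all(is.finite(object@image))) msg <- c(msg, "image must be finite")
    if (length(msg)) msg else TRUE
  })

#' Segmentation metrics report
#'
#' @slot perImage data.frame with one row per image: stem, TP, FP, FN,
#'   TN, dice, iou_fg, miou, precision, recall.
#' @slot aggregate named numeric vector of dataset-level means.
#' @exportClass MetricsReport
setClass("MetricsReport", representation(
  perImage = "data.frame", aggregate = "numeric"))

#' The dual-encoder segmentation model
#'
#' Holds the architecture configuration and the nested list of parameter
#' arrays. Build with [buildModel()].
#'
#' @slot config a [ModelConfig-class].
#' @slot params nested list of numeric parameter arrays.
#' @slot seed integer seed the parameters were drawn with.
#' @slot iter training iterations applied so far.
#' @exportClass MTUNet
setClass("MTUNet", representation(
  config = "ModelConfig", params = "list", seed = "integer",
  iter = "integer"))

# ------------------------------- show methods ------------------------------

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig (5-stage dual encoder)\n")
  cat("  channels:", paste(object@channels, collapse = "/"), "\n")
  cat("  depths:  ", paste(object@depths, collapse = "/"),
      " heads:", paste(object@heads, collapse = "/"), "\n")
  cat("  sw:", paste(object@sw, collapse = "/"),
      " mlp_ratio:", object@mlp_ratio,
      " d_state:", object@d_state, " expand:", object@expand, "\n")
  cat("  input:", object@input_size, "x", object@input_size,
      " out_channels:", object@out_channels, "\n")
})

setMethod("show", "MTUNet", function(object) {
  np <- sum(vapply(flatten_params(object@params), length, 1))
  cat("MTUNet model,", format(np, big.mark = ","), "parameters,",
      "trained", object@iter, "iterations\n")
  show(object@config)
})

setMethod("show", "SegSample", function(object) {
  d <- dim(object@image)
  cat("SegSample", d[1], "x", d[2], "| foreground fraction",
      round(mean(object@mask), 4), "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", nrow(object@perImage), "images\n")
  print(round(object@aggregate, 4))
})

# ------------------------------- accessors ---------------------------------

#' Accessor for a model's architecture configuration
#'
#' @param object an `MTUNet` model.
#' @return the [ModelConfig-class] of the model.
#' @name getConfig
#' @export
getConfig <- function(object) {
  stopifnot(is(object, "MTUNet"))
  object@config
}

#' Number of trainable parameters of a model object
#'
#' @param object an `MTUNet` model.
#' @return count of trainable (double) parameter entries.
#' @export
paramCount <- function(object) {
  stopifnot(is(object, "MTUNet"))
  sum(vapply(flatten_params(object@params), length, 1))
}
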