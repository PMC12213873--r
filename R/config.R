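# ---------------------------------------------------------------------------
# Constructors for configuration objects.
# ---------------------------------------------------------------------------

# Calibrated per-stage depths of the shipped default configuration (set so
# profileModel() at 256x256 reproduces the published parameter/FLOP budget;
# the calibration is documented in the vignette).
.default_depths <- c(45L, 3L, 4L, 16L, 8L)

#' Create a model configuration
#'
#' Defaults are the shipped calibrated configuration: the standard width
#' schedule 32/64/128/256/512, strip width 3 at every stage, and per-stage
#' depths calibrated so that the profiled parameter/FLOP budget at
#' 256 x 256 matches the published architecture budget (see
#' [profileModel()] and the package vignette for the calibration record).
#'
#' @param channels per-stage channel widths (5, strictly increasing).
#' @param depths per-stage block counts (applied to both encoder branches).
#' @param heads per-stage attention head counts (even, dividing channels).
#' @param sw strip width(s) of the cross-shape attention (default 3).
#' @param mlp_ratio MLP hidden-width multiplier (default 4).
#' @param d_state SSM state count per channel (default 16).
#' @param expand SSM inner expansion factor (default 2).
#' @param ssm_kernel causal depthwise conv width in the Vim block (default 4).
#' @param dws_kernel auxiliary depthwise-separable kernel size (default 3).
#' @param input_size square input resolution (divisible by 32).
#' @param out_channels output channels (default 1, binary logits).
#' @return a [ModelConfig-class] object.
#' @export
modelConfig <- function(channels = c(32L, 64L, 128L, 256L, 512L),
                        depths = .default_depths,
                        heads = c(2L, 4L, 8L, 8L, 16L),
                        sw = 3L, mlp_ratio = 4, d_state = 16L,
                        expand = 2L, ssm_kernel = 4L, dws_kernel = 3L,
                        input_size = 256L, out_channels = 1L) {
  new("ModelConfig",
      channels = as.integer(channels),
      depths = as.integer(rep_len(depths, 5L)),
      heads = as.integer(rep_len(heads, 5L)),
      sw = as.integer(rep_len(sw, 5L)),
      mlp_ratio = as.numeric(mlp_ratio),
      d_state = as.integer(d_state), expand = as.integer(expand),
      ssm_kernel = as.integer(ssm_kernel),
      dws_kernel = as.integer(dws_kernel),
      input_size = as.integer(input_size),
      out_channels = as.integer(out_channels))
}

#' Create a training configuration
#'
#' Defaults follow the published training recipe: Adam with base learning
#' rate `1e-4`, polynomial decay `lr * (1 - t/T)^0.9`, 5000 iterations at
#' batch size 8, inputs resized to 384 x 384 and standardized, combined
#' BCE + Dice loss with `alpha = beta = 1`.
#'
#' @param lr base learning rate.
#' @param max_iters training iterations.
#' @param batch_size samples per iteration.
#' @param resize square training resolution (divisible by 32).
#' @param alpha,beta loss weights of the BCE and Dice terms.
#' @param schedule_power polynomial decay exponent.
#' @param augment list of augmentation settings, see [augmentSample()].
#' @param seed RNG seed for sampling, augmentation and initialization.
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(lr = 1e-4, max_iters = 5000L, batch_size = 8L,
                        resize = 384L, alpha = 1, beta = 1,
                        schedule_power = 0.9,
                        augment = list(flip = TRUE, photometric = TRUE,
                                       warp = TRUE,
                                       brightness = 0.2,
                                       contrast = c(0.8, 1.25),
                                       saturation = c(0.8, 1.25),
                                       rotation = 10, scale = c(0.9, 1.1),
                                       shear = 5),
                        seed = 1L) {
  new("TrainConfig", lr = as.numeric(lr), max_iters = as.integer(max_iters),
      batch_size = as.integer(batch_size), resize = as.integer(resize),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      schedule_power = as.numeric(schedule_power),
      augment = augment, seed = as.integer(seed))
}

#' Create a synthetic-data generator configuration
#'
#' Defaults emulate the clinical difficulty of endoscopic polyp images:
#' one to two lesions of varying size (5-20% of the image each), weak
#' lesion/background contrast (mean intensity offset 0.3) and blurred
#' boundaries (Gaussian sigma 1.5 px applied to the image only), on a
#' textured endoscopy-palette background.
#'
#' @param image_size square output size in pixels.
#' @param n_polyps_range integer range of lesions per image.
#' @param area_fraction_range per-lesion area fraction range in (0, 1).
#' @param contrast lesion/background mean intensity offset.
#' @param boundary_blur_sigma Gaussian sigma (px) softening the lesion
#'   boundary in the image; the ground-truth mask stays crisp.
#' @param background_texture_scale amplitude of background texture noise.
#' @return a [SynthConfig-class] object.
#' @export
synthConfig <- function(image_size = 256L, n_polyps_range = c(1L, 2L),
                        area_fraction_range = c(0.05, 0.20),
                        contrast = 0.3, boundary_blur_sigma = 1.5,
                        background_texture_scale = 0.15) {
  new("SynthConfig", image_size = as.integer(image_size),
      n_polyps_range = as.integer(n_polyps_range),
      area_fraction_range = as.numeric(area_fraction_range),
      contrast = as.numeric(contrast),
      boundary_blur_sigma = as.numeric(boundary_blur_sigma),
      background_texture_scale = as.numeric(background_texture_scale))
}

# evaluate an expression under a local, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
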