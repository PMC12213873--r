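# ---------------------------------------------------------------------------
# Seeded generator of polyp-like image/mask pairs: smooth Fourier-modulated
# elliptical blobs on multi-octave textured backgrounds in an
# endoscopy-like palette. The mask is rasterized crisp; only the image
# gets a softened lesion boundary, so the ground truth stays unambiguous
# while the image boundary is not.
# ---------------------------------------------------------------------------

gblur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- min(2L * as.integer(ceiling(3 * sigma)) + 1L,
           (min(dim(m)) - 1L) %/% 2L * 2L - 1L)
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma, radius = r))
}

#' Generate one smooth blob mask
#'
#' Draws a randomly placed ellipse whose radius is modulated by a
#' low-order random Fourier series (harmonics 2-6), rasterizes it,
#' applies a morphological closing and keeps the largest 4-connected
#' component, so the returned region is a single connected smooth blob of
#' roughly the requested area. Consumes the current RNG stream.
#'
#' @param size square image extent in pixels.
#' @param area_fraction target blob area as a fraction of the image
#'   (`<= 0` returns an empty mask).
#' @return `size x size` binary matrix.
#' @export
genBlobMask <- function(size, area_fraction) {
  if (area_fraction <= 0) return(matrix(0, size, size))
  r0 <- sqrt(area_fraction * size * size / pi)
  cx <- stats::runif(1, 0.3, 0.7) * size
  cy <- stats::runif(1, 0.3, 0.7) * size
  aspect <- stats::runif(1, 0.7, 1.4)
  phi <- stats::runif(1, 0, pi)
  nh <- 5L                      # harmonics 2..6
  amp <- stats::rnorm(nh, sd = 0.06 / sqrt(seq_len(nh)))
  pha <- stats::runif(nh, 0, 2 * pi)
  xs <- matrix(rep(seq_len(size), each = size), size) - cx   # rows = h
  ys <- matrix(rep(seq_len(size), size), size) - cy
  ca <- cos(phi); sa <- sin(phi)
  u <- (xs * ca + ys * sa) * sqrt(aspect)
  v <- (-xs * sa + ys * ca) / sqrt(aspect)
  rho <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  rmod <- r0 * (1 + Reduce(`+`, lapply(seq_len(nh), function(j)
    amp[j] * cos((j + 1L) * th + pha[j]))))
  m <- (rho <= rmod) * 1
  m <- as.matrix(EBImage::closing(EBImage::Image(m),
                                  EBImage::makeBrush(3, "box")))
  lab <- EBImage::bwlabel(EBImage::Image(m))
  tab <- tabulate(as.integer(lab))
  if (length(tab) == 0L) return(matrix(0, size, size))
  (as.matrix(lab) == which.max(tab)) * 1
}

octave_noise <- function(size, sigmas = c(2, 6, 14), weights = c(1, 2, 4)) {
  f <- matrix(0, size, size)
  for (i in seq_along(sigmas)) {
    n <- gblur_mat(matrix(stats::rnorm(size * size), size), sigmas[i])
    if (stats::sd(n) > 0) n <- n / stats::sd(n)
    f <- f + weights[i] * n
  }
  f / sum(weights)
}

#' Generate one synthetic image/mask pair
#'
#' The background is smoothed multi-octave noise tinted to an
#' endoscopy-like reddish palette; each lesion region is shifted by
#' `contrast` along a lesion tint, with the boundary softened in the
#' image by a Gaussian of `boundary_blur_sigma` (the mask stays crisp).
#' Deterministic in `(cfg, seed)`.
#'
#' @param cfg a [synthConfig()] object.
#' @param seed integer seed.
#' @return a [SegSample-class] with image in `[0, 1]` and binary mask.
#' @export
genSample <- function(cfg, seed) {
  with_seed(seed, {
    n <- cfg@image_size
    npol <- sample(seq(cfg@n_polyps_range[1], cfg@n_polyps_range[2]), 1)
    mask <- matrix(0, n, n)
    for (j in seq_len(npol)) {
      af <- stats::runif(1, cfg@area_fraction_range[1],
                         cfg@area_fraction_range[2])
      mask <- pmax(mask, genBlobMask(n, af))
    }
    base <- c(0.62, 0.36, 0.33) + stats::rnorm(3, sd = 0.04)
    tex <- octave_noise(n) * cfg@background_texture_scale
    tint <- c(1.0, 0.78, 0.72)
    soft <- gblur_mat(mask, cfg@boundary_blur_sigma)
    img <- array(0, c(n, n, 3))
    for (ch in 1:3) {
      img[, , ch] <- base[ch] + tex +
        cfg@contrast * tint[ch] * soft +
        matrix(stats::rnorm(n * n, sd = 0.01), n)
    }
    img <- pmin(pmax(img, 0), 1)
    new("SegSample", image = img, mask = mask,
        provenance = list(seed = seed, config = synth_config_string(cfg)))
  })
}

synth_config_string <- function(cfg) {
  paste(cfg@image_size, paste(cfg@n_polyps_range, collapse = "-"),
        paste(cfg@area_fraction_range, collapse = "-"), cfg@contrast,
        cfg@boundary_blur_sigma, cfg@background_texture_scale, sep = "|")
}

#' Generate a dataset of PNG image/mask pairs
#'
#' Writes `images/00001.png` ... and `masks/00001.png` ... (8-bit;
#' masks use 0/255) plus a plain-text `manifest.txt` recording the
#' configuration and per-sample seeds. The layout matches the common
#' public polyp datasets (`images/` + `masks/` with matching stems), so
#' real data drops in unchanged.
#'
#' @param cfg a [synthConfig()] object.
#' @param n number of samples.
#' @param out_dir output directory.
#' @param seed base seed; sample `i` uses `seed + i - 1`.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, the vector of sample seeds.
#' @export
genDataset <- function(cfg, n, out_dir, seed = 1L, overwrite = FALSE) {
  if (dir.exists(out_dir) &&
      length(list.files(out_dir, recursive = TRUE)) > 0 && !overwrite)
    stop("genDataset: output directory is not empty (use overwrite = TRUE)")
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  seeds <- seed + seq_len(n) - 1L
  for (i in seq_len(n)) {
    s <- genSample(cfg, seeds[i])
    stem <- sprintf("%05d", i)
    png::writePNG(s@image, file.path(out_dir, "images",
                                     paste0(stem, ".png")))
    png::writePNG(s@mask, file.path(out_dir, "masks",
                                    paste0(stem, ".png")))
  }
  writeLines(c(paste0("config: ", synth_config_string(cfg)),
               paste0("n: ", n), paste0("base_seed: ", seed),
               paste0("seeds: ", paste(seeds, collapse = ","))),
             file.path(out_dir, "manifest.txt"))
  invisible(seeds)
}
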