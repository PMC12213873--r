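# ---------------------------------------------------------------------------
# Dataset reading (images/ + masks/ with matching stems) and training-time
# augmentation.
# ---------------------------------------------------------------------------

read_image_file <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Load an image/mask dataset
#'
#' Expects `root/images/` and `root/masks/` with matching file stems.
#' Pairs are stem-sorted; masks are binarized at 127/255; images are kept
#' in `[0, 1]` (standardization happens at training/prediction time).
#'
#' @param root dataset directory.
#' @return list of [SegSample-class] objects.
#' @export
loadDataset <- function(root) {
  idir <- file.path(root, "images"); mdir <- file.path(root, "masks")
  if (!dir.exists(idir) || !dir.exists(mdir))
    stop("loadDataset: expected 'images/' and 'masks/' under ", root)
  stem <- function(f) sub("\\.[^.]+$", "", f)
  ifs <- sort(list.files(idir)); mfs <- sort(list.files(mdir))
  orphans <- c(setdiff(stem(ifs), stem(mfs)), setdiff(stem(mfs), stem(ifs)))
  if (length(orphans))
    stop("loadDataset: unmatched stems: ", paste(orphans, collapse = ", "))
  lapply(seq_along(ifs), function(i) {
    ip <- file.path(idir, ifs[i]); mp <- file.path(mdir, mfs[i])
    img <- tryCatch(read_image_file(ip),
                    error = function(e) stop("loadDataset: unreadable ", ip))
    m <- tryCatch(png::readPNG(mp),
                  error = function(e) stop("loadDataset: unreadable ", mp))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    new("SegSample", image = img, mask = (m > 127 / 255) * 1,
        provenance = list(image = ip, mask = mp, stem = stem(ifs[i])))
  })
}

resize_image <- function(img, Ho, Wo) {
  d <- dim(img)
  if (d[1] == Ho && d[2] == Wo) return(img)
  tokens_to_fm(as.matrix(resize_op(d[1], d[2], Ho, Wo) %*%
                           fm_to_tokens(img)), Ho, Wo)
}

resize_mask <- function(mask, Ho, Wo) {
  d <- dim(mask)
  if (d[1] == Ho && d[2] == Wo) return(mask)
  # nearest neighbor keeps the mask binary
  ih <- pmin(pmax(round((seq_len(Ho) - 0.5) * d[1] / Ho + 0.5), 1), d[1])
  iw <- pmin(pmax(round((seq_len(Wo) - 0.5) * d[2] / Wo + 0.5), 1), d[2])
  mask[ih, iw, drop = FALSE]
}

# standardize each channel to mean 0 / sd 1 (per image)
standardize_image <- function(img) {
  for (ch in seq_len(dim(img)[3])) {
    v <- img[, , ch]
    s <- stats::sd(v)
    img[, , ch] <- (v - mean(v)) / max(s, 1e-6)
  }
  img
}

# sample an image (bilinear, edge clamp) and mask (nearest, 0 outside)
# at source coordinates hs, ws (matrices of target shape)
warp_sample <- function(img, mask, hs, ws) {
  d <- dim(img)
  h0 <- floor(hs); w0 <- floor(ws)
  fh <- as.vector(hs - h0); fw <- as.vector(ws - w0)
  cl <- function(v, n) pmin.int(pmax.int(as.vector(v), 1), n)
  h0c <- cl(h0, d[1]); h1c <- cl(h0 + 1, d[1])
  w0c <- cl(w0, d[2]); w1c <- cl(w0 + 1, d[2])
  i00 <- (w0c - 1) * d[1] + h0c; i01 <- (w1c - 1) * d[1] + h0c
  i10 <- (w0c - 1) * d[1] + h1c; i11 <- (w1c - 1) * d[1] + h1c
  wa <- (1 - fh) * (1 - fw); wb <- (1 - fh) * fw
  wc <- fh * (1 - fw); wd <- fh * fw
  out <- img
  for (ch in 1:3) {
    m <- img[, , ch]
    out[, , ch] <- matrix(wa * m[i00] + wb * m[i01] + wc * m[i10] +
                            wd * m[i11], d[1], d[2])
  }
  hn <- round(hs); wn <- round(ws)
  inside <- hn >= 1 & hn <= d[1] & wn >= 1 & wn <= d[2]
  mv <- numeric(length(hn))
  mv[inside] <- mask[cbind(as.vector(hn)[inside], as.vector(wn)[inside])]
  list(image = out, mask = matrix(mv, d[1], d[2]))
}

#' Augment a segmentation sample
#'
#' In order: random horizontal/vertical flips (p = 0.5 each, applied
#' jointly to image and mask); photometric distortion (brightness,
#' contrast, saturation; image only); reflect-padding up to `target` if
#' needed (mask zero-padded); random affine warp (rotation, isotropic
#' scale, shear) with bilinear image resampling and nearest-neighbor mask
#' resampling, so the mask stays strictly binary. Consumes the current
#' RNG stream.
#'
#' @param s a [SegSample-class].
#' @param aug augmentation settings list, see [trainConfig()].
#' @param target optional `c(H, W)` padding target.
#' @return augmented [SegSample-class].
#' @export
augmentSample <- function(s, aug = trainConfig()@augment, target = NULL) {
  img <- s@image; mask <- s@mask
  if (isTRUE(aug$flip)) {
    if (stats::runif(1) < 0.5) {        # horizontal: reverse columns
      img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
      mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
    }
    if (stats::runif(1) < 0.5) {        # vertical: reverse rows
      img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
      mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
    }
  }
  if (isTRUE(aug$photometric)) {
    img <- img + stats::runif(1, -aug$brightness, aug$brightness)
    f <- stats::runif(1, aug$contrast[1], aug$contrast[2])
    img <- (img - 0.5) * f + 0.5
    gray <- array(rep((img[, , 1] + img[, , 2] + img[, , 3]) / 3, 3),
                  dim(img))
    sf <- stats::runif(1, aug$saturation[1], aug$saturation[2])
    img <- gray + (img - gray) * sf
    img <- pmin(pmax(img, 0), 1)
  }
  if (!is.null(target)) {
    d <- dim(img)
    if (d[1] < target[1] || d[2] < target[2]) {
      Hp <- max(d[1], target[1]); Wp <- max(d[2], target[2])
      img <- reflect_pad_hw(img, Hp, Wp)
      mp <- matrix(0, Hp, Wp); mp[seq_len(d[1]), seq_len(d[2])] <- mask
      mask <- mp
    }
  }
  if (isTRUE(aug$warp)) {
    d <- dim(img)
    th <- stats::runif(1, -aug$rotation, aug$rotation) * pi / 180
    sc <- stats::runif(1, aug$scale[1], aug$scale[2])
    sh <- tan(stats::runif(1, -aug$shear, aug$shear) * pi / 180)
    # inverse map: target -> source
    Mf <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) %*%
      matrix(c(1, 0, sh, 1), 2) * sc
    Mi <- solve(Mf)
    ch0 <- (d[1] + 1) / 2; cw0 <- (d[2] + 1) / 2
    hg <- matrix(rep(seq_len(d[1]), d[2]), d[1]) - ch0
    wg <- matrix(rep(seq_len(d[2]), each = d[1]), d[1]) - cw0
    hs <- Mi[1, 1] * hg + Mi[1, 2] * wg + ch0
    ws <- Mi[2, 1] * hg + Mi[2, 2] * wg + cw0
    wp <- warp_sample(img, mask, hs, ws)
    img <- wp$image; mask <- wp$mask
  }
  new("SegSample", image = img, mask = mask, provenance = s@provenance)
}
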