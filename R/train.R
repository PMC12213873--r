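# ---------------------------------------------------------------------------
# Training loop (Adam + polynomial LR decay + combined BCE/Dice loss),
# prediction and evaluation.
# ---------------------------------------------------------------------------

#' Polynomial learning-rate schedule
#'
#' `lr * (1 - iter / max_iters)^power`: the base rate at iteration 0,
#' decaying to 0 at `max_iters`.
#'
#' @param lr base learning rate.
#' @param iter current iteration (0-based).
#' @param max_iters total iterations.
#' @param power decay exponent (default 0.9).
#' @return learning rate for the iteration.
#' @export
polyLR <- function(lr, iter, max_iters, power = 0.9) {
  lr * (1 - iter / max_iters)^power
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like)
  else if (is.double(p)) array(0, dim = dim0(p))
  else NULL
}

# one Adam step over the nested parameter tree (in place structurally)
adam_step <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- adam_step(p[[i]], g[[i]], m[[i]], v[[i]], lr, t, b1, b2, eps)
      p[i] <- list(r$p); m[i] <- list(r$m); v[i] <- list(r$v)
    }
    return(list(p = p, m = m, v = v))
  }
  if (!is.double(p)) return(list(p = p, m = m, v = v))
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

prepare_samples <- function(data, size) {
  samples <- if (is.character(data)) loadDataset(data) else data
  lapply(samples, function(s) {
    d <- dim(s@image)
    if (d[1] != size || d[2] != size) {
      new("SegSample", image = resize_image(s@image, size, size),
          mask = resize_mask(s@mask, size, size),
          provenance = s@provenance)
    } else s
  })
}

#' Train a model
#'
#' Adam with polynomial learning-rate decay
#' `lr * (1 - t/T)^power` and the combined BCE + Dice objective. Batches
#' are drawn with replacement from the (optionally augmented) training
#' set; every source of randomness derives from `train_cfg@seed`. A
#' non-finite loss aborts with a diagnostic. With `out_dir`, the final
#' checkpoint and the per-iteration loss log are written there.
#'
#' @param model an [MTUNet-class] (its `input_size` must equal
#'   `train_cfg@resize`).
#' @param train_cfg a [TrainConfig-class].
#' @param data dataset directory or list of [SegSample-class] objects.
#' @param out_dir optional output directory.
#' @param augment apply the configured augmentations.
#' @param verbose print progress every 50 iterations.
#' @return list with the trained `model` and the loss `log` data frame.
#' @export
trainModel <- function(model, train_cfg, data, out_dir = NULL,
                       augment = TRUE, verbose = FALSE) {
  cfg <- model@config
  if (cfg@input_size != train_cfg@resize)
    stop(sprintf(paste0("trainModel: model input_size (%d) and training",
                        " resize (%d) differ"),
                 cfg@input_size, train_cfg@resize))
  size <- train_cfg@resize
  samples <- prepare_samples(data, size)
  n <- length(samples)
  params <- model@params
  mstate <- zeros_like(params); vstate <- zeros_like(params)
  Tmax <- train_cfg@max_iters
  B <- train_cfg@batch_size
  log <- data.frame(iter = integer(Tmax), loss = numeric(Tmax),
                    lr = numeric(Tmax))
  with_seed(train_cfg@seed, {
    for (it in seq_len(Tmax)) {
      idx <- sample.int(n, B, replace = TRUE)
      xs <- vector("list", B); ys <- vector("list", B)
      for (b in seq_len(B)) {
        s <- samples[[idx[b]]]
        if (augment) s <- augmentSample(s, train_cfg@augment)
        xs[[b]] <- fm_to_tokens(standardize_image(s@image))
        ys[[b]] <- fm_to_tokens(s@mask)
      }
      x <- do.call(rbind, xs)
      y <- do.call(rbind, ys)
      tp <- new_tape()
      pn <- wrap_params(params)
      out <- .forward(tp, pn, cfg, x, B, size, size)
      loss <- op_seg_loss(tp, out, y, train_cfg@alpha, train_cfg@beta)
      if (!is.finite(loss$val))
        stop(sprintf("trainModel: non-finite loss at iteration %d", it))
      backward(tp, loss)
      lr_t <- polyLR(train_cfg@lr, it - 1L, Tmax, train_cfg@schedule_power)
      st <- adam_step(params, grad_of(pn), mstate, vstate, lr_t, it)
      params <- st$p; mstate <- st$m; vstate <- st$v
      log$iter[it] <- it; log$loss[it] <- loss$val; log$lr[it] <- lr_t
      if (verbose && it %% 50L == 0L)
        message(sprintf("iter %d  loss %.4f  lr %.2e", it, loss$val, lr_t))
    }
  })
  model@params <- params
  model@iter <- model@iter + Tmax
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveCheckpoint(model, file.path(out_dir, "checkpoint.rds"))
    utils::write.csv(log, file.path(out_dir, "train_log.csv"),
                     row.names = FALSE)
  }
  list(model = model, log = log)
}

#' Predict probability maps and binary masks
#'
#' Each input is resized to the model resolution, standardized, passed
#' through the network, and the sigmoid probability map is resized back
#' to the original extent and thresholded. With `out_dir`, per-image
#' probability maps (`prob_<stem>.png`) and binary masks
#' (`mask_<stem>.png`) are written.
#'
#' @param model an [MTUNet-class].
#' @param images dataset directory (with `images/`), a directory of PNG
#'   files, or a list of [SegSample-class] / image arrays.
#' @param out_dir optional output directory.
#' @param threshold binarization threshold on the probabilities.
#' @return list per image: `stem`, `prob` matrix, `mask` binary matrix.
#' @export
predictMasks <- function(model, images, out_dir = NULL, threshold = 0.5) {
  if (is.character(images)) {
    idir <- if (dir.exists(file.path(images, "images")))
      file.path(images, "images") else images
    fs <- sort(list.files(idir, pattern = "\\.png$", full.names = TRUE))
    items <- lapply(fs, function(f)
      list(img = read_image_file(f), stem = sub("\\.png$", "", basename(f))))
  } else {
    items <- lapply(seq_along(images), function(i) {
      x <- images[[i]]
      if (is(x, "SegSample"))
        list(img = x@image,
             stem = x@provenance$stem %||% sprintf("%05d", i))
      else list(img = x, stem = sprintf("%05d", i))
    })
  }
  size <- model@config@input_size
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lapply(items, function(it) {
    d <- dim(it$img)
    x <- standardize_image(resize_image(it$img, size, size))
    logits <- mtuForward(model, x)
    prob <- 1 / (1 + exp(-logits[, , 1]))
    prob <- resize_image(array(prob, c(size, size, 1)), d[1], d[2])[, , 1]
    mk <- (prob >= threshold) * 1
    if (!is.null(out_dir)) {
      png::writePNG(prob, file.path(out_dir, paste0("prob_", it$stem, ".png")))
      png::writePNG(mk, file.path(out_dir, paste0("mask_", it$stem, ".png")))
    }
    list(stem = it$stem, prob = prob, mask = mk)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a model on a dataset
#'
#' Runs [predictMasks()] over the dataset and computes per-image and
#' aggregated segmentation metrics against the ground-truth masks.
#'
#' @param model an [MTUNet-class].
#' @param data dataset directory or list of [SegSample-class] objects.
#' @param threshold binarization threshold.
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, data, threshold = 0.5) {
  samples <- if (is.character(data)) loadDataset(data) else data
  preds <- predictMasks(model, samples, threshold = threshold)
  rows <- lapply(seq_along(samples), function(i) {
    r <- segMetrics(preds[[i]]$mask, samples[[i]]@mask)
    r$stem <- preds[[i]]$stem
    r
  })
  metrics_report(rows)
}
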