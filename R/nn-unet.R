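# U-net: configurable-depth encoder-decoder with skip connections, softmax
# head and soft-Dice training loss. Depth-6 at width 64 mirrors the full
# architecture; reduced depth/width profiles keep CPU training tractable.

unet_channels <- function(depth, width) width * 2^(seq_len(depth) - 1L)

unet_init <- function(depth, width, in_ch = 1L, n_classes = 3L,
                      upsample = "nearest") {
  ch <- unet_channels(depth, width)
  chb <- width * 2^depth
  enc <- list()
  prev <- in_ch
  for (i in seq_len(depth)) {
    enc[[as.character(i)]] <- list(
      a = conv_param(3L, 3L, prev, ch[i]),
      b = conv_param(3L, 3L, ch[i], ch[i])
    )
    prev <- ch[i]
  }
  bott <- list(a = conv_param(3L, 3L, ch[depth], chb),
               b = conv_param(3L, 3L, chb, chb))
  dec <- list()
  prev <- chb
  for (i in rev(seq_len(depth))) {
    dec[[as.character(i)]] <- list(
      up = conv_param(3L, 3L, prev, ch[i]),
      c = conv_param(3L, 3L, 2L * ch[i], ch[i]),
      d = conv_param(3L, 3L, ch[i], ch[i])
    )
    prev <- ch[i]
  }
  final <- conv_param(1L, 1L, ch[1], n_classes)
  list(enc = enc, bott = bott, dec = dec, final = final,
       depth = depth, width = width, in_ch = in_ch, n_classes = n_classes,
       upsample = upsample)
}

unet_forward <- function(params, x, H, W, N, keep_cache = TRUE) {
  depth <- params$depth
  caches <- list(enc = list(), dec = list())
  skips <- list()
  h <- H; w <- W
  for (i in seq_len(depth)) {
    key <- as.character(i)
    p <- params$enc[[key]]
    ca <- conv_fwd(x, h, w, N, p$a); ra <- relu_fwd(ca$y)
    cb <- conv_fwd(ra$y, h, w, N, p$b); rb <- relu_fwd(cb$y)
    skips[[key]] <- rb$y
    po <- pool_fwd(rb$y, h, w, N)
    if (keep_cache) {
      caches$enc[[key]] <- list(ca = ca$cache, ma = ra$cache,
                                cb = cb$cache, mb = rb$cache,
                                pool = po$cache, h = h, w = w)
    }
    x <- po$y
    h <- h %/% 2L; w <- w %/% 2L
  }
  p <- params$bott
  ca <- conv_fwd(x, h, w, N, p$a); ra <- relu_fwd(ca$y)
  cb <- conv_fwd(ra$y, h, w, N, p$b); rb <- relu_fwd(cb$y)
  if (keep_cache) {
    caches$bott <- list(ca = ca$cache, ma = ra$cache,
                        cb = cb$cache, mb = rb$cache, h = h, w = w)
  }
  x <- rb$y
  for (i in rev(seq_len(depth))) {
    key <- as.character(i)
    p <- params$dec[[key]]
    up <- if (identical(params$upsample, "bilinear")) {
      upsample_bilinear_fwd(x, h, w, N)
    } else {
      upsample_fwd(x, h, w, N)
    }
    h <- h * 2L; w <- w * 2L
    cu <- conv_fwd(up$y, h, w, N, p$up); ru <- relu_fwd(cu$y)
    xc <- cbind(ru$y, skips[[key]])
    cc <- conv_fwd(xc, h, w, N, p$c); rc <- relu_fwd(cc$y)
    cd <- conv_fwd(rc$y, h, w, N, p$d); rd <- relu_fwd(cd$y)
    if (keep_cache) {
      caches$dec[[key]] <- list(up_map = up$cache, cu = cu$cache, mu = ru$cache,
                                cc = cc$cache, mc = rc$cache,
                                cd = cd$cache, md = rd$cache,
                                n_up = ncol(ru$y), h = h, w = w)
    }
    x <- rd$y
  }
  cf <- conv_fwd(x, H, W, N, params$final)
  probs <- softmax_rows(cf$y)
  if (keep_cache) caches$final <- cf$cache
  list(probs = probs, logits = cf$y, caches = caches, skips = if (keep_cache) skips)
}

unet_backward <- function(params, fwd, dprobs, N) {
  depth <- params$depth
  grads <- list(enc = list(), bott = NULL, dec = list(), final = NULL)
  dlogits <- softmax_bwd(dprobs, fwd$probs)
  gf <- conv_bwd(dlogits, fwd$caches$final, params$final)
  grads$final <- list(W = gf$dW, b = gf$db)
  dx <- gf$dx
  dskips <- list()
  for (i in seq_len(depth)) {
    key <- as.character(i)
    p <- params$dec[[key]]; cc <- fwd$caches$dec[[key]]
    dd <- conv_bwd(relu_bwd(dx, cc$md), cc$cd, p$d)
    dc <- conv_bwd(relu_bwd(dd$dx, cc$mc), cc$cc, p$c)
    n_up <- cc$n_up
    d_up_branch <- dc$dx[, seq_len(n_up), drop = FALSE]
    dskips[[key]] <- dc$dx[, -seq_len(n_up), drop = FALSE]
    du <- conv_bwd(relu_bwd(d_up_branch, cc$mu), cc$cu, p$up)
    dx <- if (identical(params$upsample, "bilinear")) {
      upsample_bilinear_bwd(du$dx, cc$up_map)
    } else {
      upsample_bwd(du$dx, cc$up_map)
    }
    grads$dec[[key]] <- list(up = list(W = du$dW, b = du$db),
                             c = list(W = dc$dW, b = dc$db),
                             d = list(W = dd$dW, b = dd$db))
  }
  p <- params$bott; cc <- fwd$caches$bott
  db_ <- conv_bwd(relu_bwd(dx, cc$mb), cc$cb, p$b)
  da_ <- conv_bwd(relu_bwd(db_$dx, cc$ma), cc$ca, p$a)
  grads$bott <- list(a = list(W = da_$dW, b = da_$db),
                     b = list(W = db_$dW, b = db_$db))
  dx <- da_$dx
  for (i in rev(seq_len(depth))) {
    key <- as.character(i)
    p <- params$enc[[key]]; cc <- fwd$caches$enc[[key]]
    d_pool <- pool_bwd(dx, cc$pool)
    d_out <- d_pool + dskips[[key]]
    db_ <- conv_bwd(relu_bwd(d_out, cc$mb), cc$cb, p$b)
    da_ <- conv_bwd(relu_bwd(db_$dx, cc$ma), cc$ca, p$a)
    grads$enc[[key]] <- list(a = list(W = da_$dW, b = da_$db),
                             b = list(W = db_$dW, b = db_$db))
    dx <- da_$dx
  }
  grads
}

#' Train the heart/lung segmentation U-net
#'
#' Fits an encoder-decoder segmentation network to Hounsfield-unit slices and
#' per-pixel class labels, minimising one minus the mean per-class soft Dice
#' coefficient. Pixels labelled `255` (unassigned) are excluded from the loss.
#'
#' @param images numeric array `H x W x N` of HU slices.
#' @param labels integer array `H x W x N` with classes 0 (background),
#'   1 (heart), 2 (lung) and 255 (unassigned / masked out).
#' @param depth number of contracting (and expansive) modules; the image edge
#'   must be divisible by `2^depth`.
#' @param width filter count of the first module; module `i` uses
#'   `width * 2^(i-1)` filters.
#' @param epochs,batch_size,lr Adam training schedule.
#' @param clip_norm gradients are rescaled when their global L2 norm
#'   exceeds this value; guards the small heart class against collapse
#'   under aggressive learning rates.
#' @param upsample decoder upsampling: `"nearest"` (default) or
#'   `"bilinear"`.
#' @param lr_decay multiplicative learning-rate decay per epoch (1 = none).
#' @param max_restarts the Dice objective occasionally collapses a small
#'   class early in training (the class is never predicted and the batch
#'   Dice sits in a poor basin); training monitors per-class hard Dice on
#'   a training subsample and reinitialises with a shifted seed when a
#'   class present in the labels has collapsed. At most this many
#'   restarts are attempted before the last model is returned.
#' @param augment_flip randomly mirror training batches left-right (the
#'   thorax is approximately bilaterally symmetric, so the flipped slice
#'   is a plausible animal); labels are flipped with the images.
#' @param seed integer seed controlling initialisation and batch order.
#' @param verbose print per-epoch loss.
#' @return an object of class `unet_model`.
#' @export
train_unet <- function(images, labels, depth = 6L, width = 64L, epochs = 15L,
                       batch_size = 8L, lr = 1e-3, clip_norm = Inf,
                       upsample = c("nearest", "bilinear"), lr_decay = 1,
                       augment_flip = FALSE, max_restarts = 2L, seed = 1L,
                       verbose = FALSE) {
  upsample <- match.arg(upsample)
  stopifnot(length(dim(images)) == 3L, all(dim(images) == dim(labels)))
  H <- dim(images)[1]; W <- dim(images)[2]; N <- dim(images)[3]
  if (H %% 2^depth != 0L || W %% 2^depth != 0L) {
    stop("image edge (", H, "x", W, ") not divisible by 2^depth = ", 2^depth,
         "; pad images to ", 2^depth * ceiling(H / 2^depth), " or reduce depth",
         call. = FALSE)
  }
  lab_vals <- unique(as.vector(labels))
  if (length(setdiff(lab_vals, 255)) < 2L) {
    stop("need at least two classes present in the labels", call. = FALSE)
  }
  K <- 3L
  present <- setdiff(sort(unique(as.integer(labels))), 255L)
  probe_n <- min(40L, N)
  run_once <- function(run_seed) {
    history <- numeric(0)
    params <- NULL
    best_params <- NULL
    best_score <- -Inf
    collapsed <- FALSE
    with_local_seed(run_seed, {
      params <- unet_init(depth, width, 1L, K, upsample)
      state <- adam_init(params)
      for (ep in seq_len(epochs)) {
        ord <- sample.int(N)
        ep_loss <- 0; nb <- 0L
        for (start in seq(1L, N, by = batch_size)) {
          idx <- ord[start:min(start + batch_size - 1L, N)]
          nb_i <- length(idx)
          img_b <- images[, , idx, drop = FALSE]
          lab_b <- labels[, , idx, drop = FALSE]
          if (augment_flip && stats::runif(1) < 0.5) {
            img_b <- img_b[, W:1, , drop = FALSE]
            lab_b <- lab_b[, W:1, , drop = FALSE]
          }
          x <- matrix(hu_normalise(as.numeric(img_b)), ncol = 1L)
          lab <- as.integer(lab_b)
          mask <- lab != 255L
          target <- matrix(0, length(lab), K)
          target[cbind(which(mask), lab[mask] + 1L)] <- 1
          fwd <- unet_forward(params, x, H, W, nb_i)
          ls <- soft_dice_loss(fwd$probs, target, mask)
          grads <- unet_backward(params, fwd, ls$dprobs, nb_i)
          if (is.finite(clip_norm)) grads <- clip_gradients(grads, clip_norm)
          st <- adam_step(params, grads, state, lr = lr * lr_decay^(ep - 1))
          params <- st$params; state <- st$state
          ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
        }
        history[ep] <- ep_loss / nb
        # score this epoch's checkpoint on a training subsample and keep
        # the best: per-epoch quality fluctuates under the Dice objective,
        # so the final epoch is not reliably the best one
        model_tmp <- structure(
          list(params = params, depth = depth, width = width,
               n_classes = K, input_size = c(H, W)),
          class = "unet_model")
        pr <- predict_unet_probs(model_tmp, images[, , seq_len(probe_n),
                                                   drop = FALSE])
        hard <- predict_classes(probs = pr)$labels
        truth <- labels[, , seq_len(probe_n), drop = FALSE]
        keep <- truth != 255L
        class_dice <- vapply(present, function(cls) {
          dice(hard[keep] == cls, truth[keep] == cls)
        }, numeric(1))
        score <- mean(class_dice)
        if (verbose) {
          message(sprintf("epoch %d  dice-loss %.4f  min train dice %.3f",
                          ep, history[ep], score))
        }
        if (score > best_score) {
          best_score <- score
          best_params <- params
        }
      }
      # a run whose best checkpoint still has a dead class is restarted
      collapsed <- best_score < (length(present) - 1 + 0.05) / length(present)
    })
    list(params = best_params %||% params, history = history,
         collapsed = collapsed, best_score = best_score)
  }
  attempt <- 0L
  repeat {
    res <- run_once(seed + attempt * 1009L)
    if (!res$collapsed || attempt >= max_restarts) break
    attempt <- attempt + 1L
    if (verbose) message("class collapse detected; restarting (attempt ",
                         attempt, ")")
  }
  structure(
    list(params = res$params, depth = depth, width = width, n_classes = K,
         input_size = c(H, W), seed = seed, loss_history = res$history,
         restarts = attempt, collapsed = res$collapsed,
         train_score = res$best_score),
    class = "unet_model"
  )
}

#' Per-pixel class probabilities from a trained U-net
#'
#' @param model a `unet_model`.
#' @param slices numeric array `H x W x N` (or a single `H x W` matrix) of HU
#'   values.
#' @param batch_size slices scored per forward pass.
#' @return array `H x W x n_classes x N` of class probabilities.
#' @export
predict_unet_probs <- function(model, slices, batch_size = 16L) {
  if (length(dim(slices)) == 2L) dim(slices) <- c(dim(slices), 1L)
  H <- dim(slices)[1]; W <- dim(slices)[2]; N <- dim(slices)[3]
  stopifnot(all(c(H, W) == model$input_size))
  K <- model$n_classes
  out <- array(0, c(H, W, K, N))
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    x <- matrix(hu_normalise(as.numeric(slices[, , idx])), ncol = 1L)
    fwd <- unet_forward(model$params, x, H, W, length(idx), keep_cache = FALSE)
    out[, , , idx] <- aperm(array(fwd$probs, c(H, W, length(idx), K)),
                            c(1, 2, 4, 3))
  }
  out
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "<unet_model> depth %d, width %d, %dx%d input, %d classes; final dice-loss %.4f\n",
    x$depth, x$width, x$input_size[1], x$input_size[2], x$n_classes,
    utils::tail(x$loss_history, 1)))
  invisible(x)
}
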