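# Internal CPU neural-net engine.
#
# Feature maps are (H*W*N) x C matrices, rows flattened column-major within
# each slice (i + H*j + H*W*n). Convolutions go through im2col (C++) and a
# single BLAS matmul; backprop is handwritten per layer and checked against
# finite differences in the test suite.

#' @useDynLib ctpheno, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# -- deterministic local RNG ---------------------------------------------

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# -- layers ---------------------------------------------------------------

conv_param <- function(kh, kw, c_in, c_out) {
  # He-normal fan-in initialisation
  sd <- sqrt(2 / (kh * kw * c_in))
  list(
    W = matrix(stats::rnorm(kh * kw * c_in * c_out, sd = sd),
               nrow = kh * kw * c_in, ncol = c_out),
    b = numeric(c_out),
    kh = kh, kw = kw, c_in = c_in, c_out = c_out, pad = (kh - 1L) %/% 2L
  )
}

conv_fwd <- function(x, H, W, N, p) {
  cols <- cpp_im2col(x, H, W, N, p$kh, p$kw, p$pad)
  y <- cols %*% p$W
  y <- sweep(y, 2L, p$b, "+")
  list(y = y, cache = list(cols = cols, H = H, W = W, N = N))
}

conv_bwd <- function(dy, cache, p) {
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(p$W)
  dx <- cpp_col2im(dcols, cache$H, cache$W, cache$N, p$kh, p$kw, p$pad, p$c_in)
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, cache = m)
}
relu_bwd <- function(dy, m) dy * m

pool_fwd <- function(x, H, W, N) {
  out <- cpp_maxpool2(x, H, W, N)
  list(y = out$y, cache = list(idx = out$idx, nrow_x = nrow(x)))
}
pool_bwd <- function(dy, cache) cpp_maxpool2_backward(dy, cache$idx, cache$nrow_x)

upsample_map <- function(H, W, N) {
  # row map from the upsampled (2H x 2W) grid back to the source grid
  i <- rep_len(rep(seq_len(2L * H), times = 2L * W), 4L * H * W)
  j <- rep(seq_len(2L * W), each = 2L * H)
  base <- ((i - 1L) %/% 2L) + H * ((j - 1L) %/% 2L)
  per_slice <- base + 1L
  map <- rep(per_slice, times = N) + rep((seq_len(N) - 1L) * H * W, each = 4L * H * W)
  map
}

upsample_fwd <- function(x, H, W, N) {
  map <- upsample_map(H, W, N)
  list(y = x[map, , drop = FALSE], cache = map)
}
upsample_bwd <- function(dy, map) rowsum(dy, map, reorder = TRUE)

# 2x bilinear upsampling as a cached sparse operator (half-pixel centres)
bilinear_cache <- new.env(parent = emptyenv())

bilinear_matrix <- function(H, W, N) {
  key <- paste(H, W, N, sep = "x")
  hit <- bilinear_cache[[key]]
  if (!is.null(hit)) return(hit)
  axis_weights <- function(n) {
    fo <- (seq_len(2L * n) - 1) / 2 - 0.25
    i0 <- pmin(pmax(floor(fo), 0), n - 1)
    i1 <- pmin(i0 + 1, n - 1)
    w1 <- pmin(pmax(fo - i0, 0), 1)
    list(i0 = i0, i1 = i1, w0 = 1 - w1, w1 = w1)
  }
  ay <- axis_weights(H); ax <- axis_weights(W)
  Ho <- 2L * H; Wo <- 2L * W
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  out_i <- rep(seq_len(Ho), times = Wo)
  out_j <- rep(seq_len(Wo), each = Ho)
  orow <- seq_len(Ho * Wo)
  for (ii in 1:2) {
    iy <- if (ii == 1) ay$i0 else ay$i1
    wy <- if (ii == 1) ay$w0 else ay$w1
    for (jj in 1:2) {
      jx <- if (jj == 1) ax$i0 else ax$i1
      wx <- if (jj == 1) ax$w0 else ax$w1
      w <- wy[out_i] * wx[out_j]
      keep <- w > 0
      rows <- c(rows, orow[keep])
      cols <- c(cols, (iy[out_i] + H * jx[out_j] + 1L)[keep])
      vals <- c(vals, w[keep])
    }
  }
  S1 <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                             dims = c(Ho * Wo, H * W))
  S <- Matrix::bdiag(rep(list(S1), N))
  bilinear_cache[[key]] <- S
  S
}

upsample_bilinear_fwd <- function(x, H, W, N) {
  S <- bilinear_matrix(H, W, N)
  list(y = as.matrix(S %*% x), cache = S)
}
upsample_bilinear_bwd <- function(dy, S) as.matrix(Matrix::crossprod(S, dy))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# gradient of loss wrt logits given gradient wrt probabilities
softmax_bwd <- function(dp, p) p * (dp - rowSums(dp * p))

# rescale a nested gradient list so its global L2 norm is at most max_norm
clip_gradients <- function(grads, max_norm) {
  sq <- function(g) {
    if (is.list(g)) sum(vapply(g, sq, numeric(1))) else sum(g^2)
  }
  total <- sqrt(sq(grads))
  if (!is.finite(total) || total <= max_norm) return(grads)
  scale <- max_norm / total
  mul <- function(g) {
    if (is.list(g)) lapply(g, mul) else g * scale
  }
  mul(grads)
}

# -- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like)
    else if (is.numeric(p)) p * 0
    else p
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (!nm %in% c("W", "b") && !is.list(p[[nm]])) next
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# -- losses ---------------------------------------------------------------

# Soft multi-class Dice. probs: (npx x K); target: one-hot (npx x K);
# mask: logical npx (FALSE rows excluded from the loss entirely).
soft_dice_loss <- function(probs, target, mask = NULL, eps = 1e-6) {
  if (!is.null(mask)) {
    probs_m <- probs[mask, , drop = FALSE]
    target_m <- target[mask, , drop = FALSE]
  } else {
    probs_m <- probs
    target_m <- target
  }
  K <- ncol(probs)
  num <- 2 * colSums(probs_m * target_m) + eps
  den <- colSums(probs_m) + colSums(target_m) + eps
  d <- num / den
  loss <- 1 - mean(d)
  # d(loss)/d(probs) on included rows
  g <- matrix(0, nrow(probs), K)
  gm <- -(sweep(target_m, 2L, 2 * den, "*") - matrix(num, nrow(probs_m), K, byrow = TRUE)) /
    matrix(den^2, nrow(probs_m), K, byrow = TRUE) / K
  if (!is.null(mask)) g[mask, ] <- gm else g <- gm
  list(loss = loss, dprobs = g, dice = d)
}

# Binary cross-entropy on logits (combined with sigmoid for stability).
bce_logit_loss <- function(logit, y) {
  p <- 1 / (1 + exp(-logit))
  loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, dlogit = (p - y) / length(y), p = p)
}

# normalise HU to [0, 1] for network input
hu_normalise <- function(hu, lo = -1000, hi = 400) {
  (pmin(pmax(hu, lo), hi) - lo) / (hi - lo)
}
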