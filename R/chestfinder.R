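# Chest localisation: a small CNN scores each transversal slice with the
# probability of being part of the chest; the raw profile is smoothed by the
# globally optimal three-level piecewise-constant fit and thresholded at 0.5,
# which yields one contiguous chest interval by construction.

classifier_init <- function(widths, in_ch = 1L) {
  list(
    c1 = conv_param(5L, 5L, in_ch, widths[1]),
    c2 = conv_param(5L, 5L, widths[1], widths[2]),
    c3 = conv_param(5L, 5L, widths[2], widths[3]),
    dense = list(
      W = matrix(stats::rnorm(2L * widths[3], sd = sqrt(1 / widths[3])),
                 ncol = 1L),
      b = 0
    ),
    widths = widths
  )
}

classifier_forward <- function(params, x, H, W, N, keep_cache = TRUE) {
  c1 <- conv_fwd(x, H, W, N, params$c1); r1 <- relu_fwd(c1$y)
  p1 <- pool_fwd(r1$y, H, W, N); h <- H %/% 2L; w <- W %/% 2L
  c2 <- conv_fwd(p1$y, h, w, N, params$c2); r2 <- relu_fwd(c2$y)
  p2 <- pool_fwd(r2$y, h, w, N); h <- h %/% 2L; w <- w %/% 2L
  c3 <- conv_fwd(p2$y, h, w, N, params$c3); r3 <- relu_fwd(c3$y)
  # global average + max pooling over pixels within each sample
  sample_of_row <- rep(seq_len(N), each = h * w)
  pooled_avg <- rowsum(r3$y, sample_of_row, reorder = TRUE) / (h * w)
  C3 <- ncol(r3$y)
  pooled_max <- matrix(0, N, C3)
  argmax <- matrix(0L, N, C3)
  for (n in seq_len(N)) {
    rows <- (n - 1L) * h * w + seq_len(h * w)
    block <- r3$y[rows, , drop = FALSE]
    am <- max.col(t(block), ties.method = "first")
    argmax[n, ] <- rows[am]
    pooled_max[n, ] <- block[cbind(am, seq_len(C3))]
  }
  pooled <- cbind(pooled_avg, pooled_max)
  logit <- drop(pooled %*% params$dense$W) + params$dense$b
  cache <- if (keep_cache) {
    list(c1 = c1$cache, m1 = r1$cache, p1 = p1$cache,
         c2 = c2$cache, m2 = r2$cache, p2 = p2$cache,
         c3 = c3$cache, m3 = r3$cache,
         pooled = pooled, sample_of_row = sample_of_row, hw = h * w, N = N,
         argmax = argmax, C3 = C3, nrow3 = nrow(r3$y))
  }
  list(logit = logit, cache = cache)
}

classifier_backward <- function(params, cache, dlogit) {
  dW_dense <- crossprod(cache$pooled, dlogit)
  db_dense <- sum(dlogit)
  dpooled <- dlogit %*% t(params$dense$W)
  C3 <- cache$C3
  d_avg <- dpooled[, seq_len(C3), drop = FALSE]
  d_max <- dpooled[, C3 + seq_len(C3), drop = FALSE]
  dr3 <- d_avg[cache$sample_of_row, , drop = FALSE] / cache$hw
  for (n in seq_len(nrow(d_max))) {
    dr3[cbind(cache$argmax[n, ], seq_len(C3))] <-
      dr3[cbind(cache$argmax[n, ], seq_len(C3))] + d_max[n, ]
  }
  g3 <- conv_bwd(relu_bwd(dr3, cache$m3), cache$c3, params$c3)
  dp2 <- pool_bwd(g3$dx, cache$p2)
  g2 <- conv_bwd(relu_bwd(dp2, cache$m2), cache$c2, params$c2)
  dp1 <- pool_bwd(g2$dx, cache$p1)
  g1 <- conv_bwd(relu_bwd(dp1, cache$m1), cache$c1, params$c1)
  list(c1 = list(W = g1$dW, b = g1$db),
       c2 = list(W = g2$dW, b = g2$db),
       c3 = list(W = g3$dW, b = g3$db),
       dense = list(W = dW_dense, b = db_dense))
}

#' Train the chest/not-chest slice classifier
#'
#' Three 5x5 convolutional layers (64, 128 and 256 filters at full width;
#' scale down with `widths` for desk-scale training), each followed by ReLU
#' and 2x2 max pooling, then concatenated global average and global max
#' pooling and a dense sigmoid output trained with binary cross-entropy
#' (the max-pool branch lets a single strong air-pocket response mark a
#' slice even when the lung cross-section is small).
#'
#' @param slices numeric array `H x W x N` of HU slices.
#' @param chest integer/logical vector of length `N`; 1 = chest slice.
#' @param widths filter counts of the three convolutional layers.
#' @param epochs,batch_size,lr Adam schedule.
#' @param seed integer seed.
#' @param verbose print per-epoch loss.
#' @return an object of class `slice_classifier`.
#' @export
train_slice_classifier <- function(slices, chest, widths = c(64L, 128L, 256L),
                                   epochs = 5L, batch_size = 16L, lr = 1e-3,
                                   seed = 1L, verbose = FALSE) {
  stopifnot(length(dim(slices)) == 3L, dim(slices)[3] == length(chest))
  chest <- as.integer(chest)
  if (length(unique(chest)) < 2L) {
    stop("training data must contain both chest and not-chest slices",
         call. = FALSE)
  }
  H <- dim(slices)[1]; W <- dim(slices)[2]; N <- dim(slices)[3]
  history <- numeric(0)
  params <- NULL
  with_local_seed(seed, {
    params <- classifier_init(widths)
    state <- adam_init(params)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, N, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, N)]
        x <- matrix(hu_normalise(as.numeric(slices[, , idx])), ncol = 1L)
        fwd <- classifier_forward(params, x, H, W, length(idx))
        ls <- bce_logit_loss(fwd$logit, chest[idx])
        grads <- classifier_backward(params, fwd$cache, matrix(ls$dlogit, ncol = 1L))
        st <- adam_step(params, grads, state, lr = lr)
        params <- st$params; state <- st$state
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d  bce %.4f", ep, history[ep]))
    }
  })
  structure(
    list(params = params, widths = widths, input_size = c(H, W), seed = seed,
         loss_history = history),
    class = "slice_classifier"
  )
}

#' Chest probability for a batch of slices
#'
#' @param model a `slice_classifier`.
#' @param slices `H x W x N` array (or single matrix) of HU values.
#' @return numeric vector of chest probabilities in `[0, 1]`.
#' @export
predict_chest_prob <- function(model, slices) {
  if (length(dim(slices)) == 2L) dim(slices) <- c(dim(slices), 1L)
  H <- dim(slices)[1]; W <- dim(slices)[2]; N <- dim(slices)[3]
  stopifnot(all(c(H, W) == model$input_size))
  out <- numeric(N)
  for (start in seq(1L, N, by = 64L)) {
    idx <- start:min(start + 63L, N)
    x <- matrix(hu_normalise(as.numeric(slices[, , idx])), ncol = 1L)
    fwd <- classifier_forward(model$params, x, H, W, length(idx),
                              keep_cache = FALSE)
    out[idx] <- 1 / (1 + exp(-fwd$logit))
  }
  out
}

#' @export
print.slice_classifier <- function(x, ...) {
  cat(sprintf("<slice_classifier> widths (%s), %dx%d input; final bce %.4f\n",
              paste(x$widths, collapse = ", "), x$input_size[1],
              x$input_size[2], utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Score a slice range of a CT volume
#'
#' Applies the slice classifier to a 0-based half-open slice range of the
#' stack (default `[300, 800)`, the window known to bracket the chest in a
#' full-length stack). A range extending beyond the stack is clipped with a
#' warning.
#'
#' @param model a `slice_classifier`.
#' @param volume a `ct_volume`.
#' @param slice_range half-open 0-based `c(first, end)` slice range.
#' @return a `slice_profile`: tibble of `slice` (0-based index) and `prob`,
#'   with the first scored slice in attribute `slice_offset`.
#' @export
score_stack <- function(model, volume, slice_range = c(300L, 800L)) {
  stopifnot(inherits(volume, "ct_volume"))
  nz <- dim(volume$hu)[3]
  rng <- as.integer(slice_range)
  if (rng[1] < 0L || rng[2] > nz) {
    rng <- c(max(rng[1], 0L), min(rng[2], nz))
    warning("slice range clipped to stack: [", rng[1], ", ", rng[2], ")",
            call. = FALSE)
  }
  if (rng[2] <= rng[1]) stop("empty slice range", call. = FALSE)
  idx <- (rng[1] + 1L):rng[2]
  probs <- predict_chest_prob(model, volume$hu[, , idx, drop = FALSE])
  structure(
    tibble::tibble(slice = idx - 1L, prob = probs),
    slice_offset = rng[1],
    class = c("slice_profile", class(tibble::tibble()))
  )
}

#' Optimal three-level piecewise-constant fit of a probability profile
#'
#' Finds the two breakpoints `0 <= b1 <= b2 <= n` minimising the total
#' squared error of a three-segment constant fit (levels = segment means),
#' by exhaustive search over all breakpoint pairs. This realises the
#' three-level regression-tree smoothing of the slice probability profile
#' (above chest / chest / below chest) at its global optimum; ties are
#' broken towards the smallest `(b1, b2)`. Empty segments inherit the level
#' of the nearest non-empty segment.
#'
#' @param profile a `slice_profile` from [score_stack()], or a numeric vector
#'   of probabilities.
#' @param method `"exhaustive"` (global optimum, default) or `"greedy"`
#'   (recursive binary splitting as a CART-style regressor would do).
#' @return an object of class `three_level_fit`: breakpoints (0-based, local
#'   to the profile), levels, sse, and the profile's slice offset.
#' @export
fit_three_levels <- function(profile, method = c("exhaustive", "greedy")) {
  method <- match.arg(method)
  if (inherits(profile, "slice_profile")) {
    probs <- profile$prob
    offset <- attr(profile, "slice_offset")
  } else {
    probs <- as.numeric(profile)
    offset <- 0L
  }
  n <- length(probs)
  if (n < 3L) stop("profile must contain at least 3 slices", call. = FALSE)
  stopifnot(all(probs >= 0 & probs <= 1))

  if (method == "exhaustive") {
    cs <- c(0, cumsum(probs))
    cs2 <- c(0, cumsum(probs^2))
    seg_cost <- function(a, b) { # [a, b) 0-based, vectorised
      len <- b - a
      s <- cs[b + 1] - cs[a + 1]
      q <- cs2[b + 1] - cs2[a + 1]
      ifelse(len > 0, q - s^2 / pmax(len, 1), 0)
    }
    best <- list(sse = Inf, b1 = 0L, b2 = 0L)
    for (b1 in 0:n) {
      b2 <- b1:n
      sse <- pmax(seg_cost(0L, b1) + seg_cost(b1, b2) + seg_cost(b2, n), 0)
      j <- which.min(sse) # first minimum: smallest b2 on ties
      if (sse[j] < best$sse - 1e-12) {
        best <- list(sse = sse[j], b1 = b1, b2 = b2[j])
      }
    }
    b1 <- best$b1; b2 <- best$b2; sse <- best$sse
  } else {
    # greedy CART-style: best single split, then best split of a child
    best_split <- function(a, b) { # returns split point and cost decrease
      if (b - a < 2L) return(NULL)
      cs <- c(0, cumsum(probs))
      cs2 <- c(0, cumsum(probs^2))
      cost <- function(a0, b0) {
        s <- cs[b0 + 1] - cs[a0 + 1]; q <- cs2[b0 + 1] - cs2[a0 + 1]
        if (b0 > a0) q - s^2 / (b0 - a0) else 0
      }
      base <- cost(a, b)
      cands <- (a + 1L):(b - 1L)
      costs <- vapply(cands, function(m) cost(a, m) + cost(m, b), numeric(1))
      m <- cands[which.min(costs)]
      list(at = m, gain = base - min(costs))
    }
    s1 <- best_split(0L, n)
    left <- best_split(0L, s1$at)
    right <- best_split(s1$at, n)
    gl <- if (is.null(left)) -Inf else left$gain
    gr <- if (is.null(right)) -Inf else right$gain
    cuts <- sort(c(s1$at, if (gl >= gr) left$at else right$at))
    b1 <- cuts[1]; b2 <- cuts[2]
    m <- function(a, b) if (b > a) mean(probs[(a + 1):b]) else NA_real_
    sse <- sum((probs[seq_len(b1)] - m(0, b1))^2, na.rm = TRUE) +
      (if (b2 > b1) sum((probs[(b1 + 1):b2] - m(b1, b2))^2) else 0) +
      (if (n > b2) sum((probs[(b2 + 1):n] - m(b2, n))^2) else 0)
  }

  seg_mean <- function(a, b) if (b > a) mean(probs[(a + 1):b]) else NA_real_
  levels <- c(seg_mean(0L, b1), seg_mean(b1, b2), seg_mean(b2, n))
  # empty segments inherit the nearest non-empty level
  for (i in which(is.na(levels))) {
    cand <- c(levels[-i][!is.na(levels[-i])])
    nxt <- if (i < 3 && !is.na(levels[i + 1])) levels[i + 1]
           else if (i > 1 && !is.na(levels[i - 1])) levels[i - 1]
           else cand[1]
    levels[i] <- nxt
  }
  structure(
    list(breakpoints = c(b1, b2), levels = levels, sse = sse, n = n,
         slice_offset = offset, method = method),
    class = "three_level_fit"
  )
}

#' @export
print.three_level_fit <- function(x, ...) {
  cat(sprintf(
    "<three_level_fit> breakpoints (%d, %d) of %d, levels (%.3f, %.3f, %.3f), sse %.4g\n",
    x$breakpoints[1], x$breakpoints[2], x$n, x$levels[1], x$levels[2],
    x$levels[3], x$sse))
  invisible(x)
}

#' Chest interval from a three-level fit
#'
#' Segments whose fitted level strictly exceeds the threshold are classified
#' as chest; adjacent above-threshold segments merge, so the result is one
#' contiguous half-open interval in full-stack coordinates. If the two outer
#' segments exceed the threshold while the middle one does not (a
#' configuration the smoothing cannot represent as one chest), the longer
#' outer segment is returned and flagged.
#'
#' @param fit a `three_level_fit`.
#' @param threshold probability threshold; strictly-above classifies as chest.
#' @return an object of class `chest_interval` with fields `start`, `end`
#'   (0-based half-open, full-stack coordinates), `found`, and `flagged`.
#' @export
chest_interval <- function(fit, threshold = 0.5) {
  stopifnot(inherits(fit, "three_level_fit"))
  b <- fit$breakpoints
  bounds <- rbind(c(0L, b[1]), c(b[1], b[2]), c(b[2], fit$n))
  lens <- bounds[, 2] - bounds[, 1]
  above <- fit$levels > threshold & lens > 0L
  flagged <- FALSE
  if (!any(above)) {
    iv <- c(0L, 0L); found <- FALSE
  } else if (above[1] && above[3] && !above[2] && lens[2] == 0L) {
    iv <- c(0L, fit$n); found <- TRUE # outer segments touch: one interval
  } else if (above[1] && above[3] && !above[2]) {
    pick <- if (lens[1] >= lens[3]) 1L else 3L
    iv <- bounds[pick, ]; found <- TRUE; flagged <- TRUE
  } else {
    segs <- which(above)
    iv <- c(bounds[min(segs), 1], bounds[max(segs), 2])
    found <- TRUE
  }
  structure(
    list(start = iv[1] + fit$slice_offset, end = iv[2] + fit$slice_offset,
         found = found, flagged = flagged, threshold = threshold),
    class = "chest_interval"
  )
}

#' @export
print.chest_interval <- function(x, ...) {
  if (!x$found) {
    cat("<chest_interval> no chest found\n")
  } else {
    cat(sprintf("<chest_interval> [%d, %d)%s\n", x$start, x$end,
                if (x$flagged) " (flagged: split above-threshold segments)" else ""))
  }
  invisible(x)
}
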