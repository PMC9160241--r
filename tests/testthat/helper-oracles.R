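# Independent oracles used across the suite.

# dense tabular-method numerator relationship matrix
tabular_A <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  s <- ifelse(ped$sire == 0, 0L, idx[as.character(ped$sire)])
  d <- ifelse(ped$dam == 0, 0L, idx[as.character(ped$dam)])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, i] <- 1 + (if (s[i] > 0 && d[i] > 0) 0.5 * A[s[i], d[i]] else 0)
    for (j in seq_len(i - 1)) {
      v <- 0
      if (s[i] > 0) v <- v + 0.5 * A[j, s[i]]
      if (d[i] > 0) v <- v + 0.5 * A[j, d[i]]
      A[i, j] <- A[j, i] <- v
    }
  }
  A
}

# brute-force three-level piecewise-constant fit by full enumeration
brute_three_levels <- function(probs) {
  n <- length(probs)
  best <- list(sse = Inf)
  for (b1 in 0:n) for (b2 in b1:n) {
    sse <- 0
    for (seg in list(c(0, b1), c(b1, b2), c(b2, n))) {
      if (seg[2] > seg[1]) {
        v <- probs[(seg[1] + 1):seg[2]]
        sse <- sse + sum((v - mean(v))^2)
      }
    }
    if (sse < best$sse - 1e-12) best <- list(sse = sse, b1 = b1, b2 = b2)
  }
  best
}

# brute-force even-odd point-in-polygon test per pixel centre
brute_point_in_polygon <- function(vertices, image_size) {
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  inpoly <- function(x, y) {
    n <- nrow(vertices); inside <- FALSE; j <- n
    for (i in seq_len(n)) {
      xi <- vertices[i, 1]; yi <- vertices[i, 2]
      xj <- vertices[j, 1]; yj <- vertices[j, 2]
      if ((yi > y) != (yj > y)) {
        xint <- xi + (y - yi) * (xj - xi) / (yj - yi)
        if (x < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }
  out <- matrix(FALSE, image_size[1], image_size[2])
  for (r in seq_len(image_size[1])) {
    for (cc in seq_len(image_size[2])) {
      out[r, cc] <- inpoly(cc - 0.5, r - 0.5)
    }
  }
  out
}

# BFS flood fill (6-connectivity) oracle over a 3-D mask
bfs_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      k <- (v - 1) %/% (d[1] * d[2]); rem <- (v - 1) %% (d[1] * d[2])
      j <- rem %/% d[1]; i <- rem %% d[1]
      for (delta in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                         c(0, 0, -1), c(0, 0, 1))) {
        ii <- i + delta[1]; jj <- j + delta[2]; kk <- k + delta[3]
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] ||
            kk < 0 || kk >= d[3]) next
        w <- kk * d[1] * d[2] + jj * d[1] + ii + 1
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# small pedigree + phenotype fixture shared by the quantgen tests
qg_fixture <- function(seed = 3, h2_target = c(0.35, 0.05, 0.60)) {
  ped <- simulate_pedigree(sim_pedigree_spec(4, 4, 8, 4, seed = seed))
  trait <- sim_trait_spec(h2_target[1], h2_target[2], h2_target[3],
                          gamma = 0.1)
  dat <- simulate_phenotypes(ped, trait, seed = seed + 10)
  list(ped = ped, dat = dat)
}
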