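# Synthetic CT phantoms: ellipsoid body, two ellipsoid lungs and an
# ellipsoid heart rasterized on a calibrated Hounsfield-unit voxel grid.
# Ellipsoids give analytic ground truth (volumes, masks, chest interval)
# for every downstream stage.

#' Specify a CT phantom
#'
#' Defines the geometry and Hounsfield-unit composition of a synthetic
#' thorax phantom. All geometry is in millimetres; voxel coordinates are
#' mapped to mm through `spacing`. The defaults describe a desk-scale
#' 64 x 64 x 120 phantom; the full-scale 512 x 512 x 1200 geometry of a
#' production CT stack is supported by scaling `image_size`, `n_slices`
#' and `spacing`.
#'
#' @param image_size pixels per (square) slice edge.
#' @param n_slices number of transversal slices.
#' @param spacing voxel spacing `c(x, y, z)` in mm (in-plane pixel size and
#'   slice thickness).
#' @param body,heart,lungs lists with `center` (mm, `c(x, y, z)`; for
#'   `lungs` a 2-row matrix), `semi` (ellipsoid semi-axes, mm), `hu_mean`
#'   and `hu_sd` (tissue texture). Lungs default to an air-dominated mean
#'   of -750 HU; the heart (blood pool and myocardium, +50 HU) is slightly
#'   denser than the surrounding mixed soft tissue (muscle and fat,
#'   +20 HU), the modest contrast that makes manual heart annotation
#'   feasible on real CT.
#' @param background_hu air value outside the body.
#' @param noise_sd additive acquisition noise (HU).
#' @param jitter_center_mm,jitter_axes_frac random per-phantom perturbation
#'   of organ centres (additive, mm) and semi-axes (multiplicative
#'   fraction); zero by default so that geometry is exactly the specified
#'   one.
#' @param seed integer seed; the phantom is deterministic given the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L,
                         n_slices = 120L,
                         spacing = c(1, 1, 1),
                         body = list(center = NULL, semi = c(28, 24, 55),
                                     hu_mean = 20, hu_sd = 15),
                         heart = list(center = c(0, 4, 0), semi = c(7, 8.5, 13),
                                      hu_mean = 50, hu_sd = 10),
                         lungs = list(center = rbind(c(-16.5, -4, 0),
                                                     c(16.5, -4, 0)),
                                      semi = c(9, 12.5, 27),
                                      hu_mean = -750, hu_sd = 30),
                         background_hu = -1000,
                         noise_sd = 20,
                         jitter_center_mm = 0,
                         jitter_axes_frac = 0,
                         seed = 1L) {
  spec <- structure(
    list(image_size = as.integer(image_size), n_slices = as.integer(n_slices),
         spacing = as.numeric(spacing), body = body, heart = heart,
         lungs = lungs, background_hu = background_hu, noise_sd = noise_sd,
         jitter_center_mm = jitter_center_mm, jitter_axes_frac = jitter_axes_frac,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$image_size >= 8L, spec$n_slices >= 1L,
            length(spec$spacing) == 3L, all(spec$spacing > 0))
  if (spec$heart$hu_mean <= -400 + 3 * spec$noise_sd) {
    stop("heart HU mean must exceed -400 + 3*noise_sd to keep organ ",
         "contrast compatible with the HU < -400 lung rule", call. = FALSE)
  }
  if (spec$lungs$hu_mean >= -400 - 3 * spec$noise_sd) {
    stop("lung HU mean must lie below -400 - 3*noise_sd", call. = FALSE)
  }
  invisible(spec)
}

# voxel-centre coordinates (mm) along each axis
phantom_grid <- function(spec) {
  list(
    x = (seq_len(spec$image_size) - 0.5) * spec$spacing[1],
    y = (seq_len(spec$image_size) - 0.5) * spec$spacing[2],
    z = (seq_len(spec$n_slices) - 0.5) * spec$spacing[3]
  )
}

# logical H x W x Z mask of an ellipsoid; semi-axes of zero give an empty mask
ellipsoid_mask <- function(grid, center, semi) {
  H <- length(grid$y); W <- length(grid$x); Z <- length(grid$z)
  if (any(semi <= 0)) return(array(FALSE, c(H, W, Z)))
  qx <- ((grid$x - center[1]) / semi[1])^2
  qy <- ((grid$y - center[2]) / semi[2])^2
  qz <- ((grid$z - center[3]) / semi[3])^2
  plane <- outer(qy, qx, "+") # H x W
  arr <- array(rep(plane, Z), c(H, W, Z)) +
    array(rep(qz, each = H * W), c(H, W, Z))
  arr <= 1
}

#' Generate a phantom CT volume with ground truth
#'
#' Rasterizes the phantom described by a [phantom_spec()] into a calibrated
#' HU volume plus a voxel-exact ground-truth label stack. Organ geometry may
#' be jittered (deterministically, from the spec seed) when the jitter
#' fields of the spec are non-zero.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` (a `ct_volume`: HU array plus
#'   `spacing`) and `truth` (a `ground_truth_stack`: label array with
#'   0 = background, 1 = heart, 2 = lung, and the half-open 0-based
#'   `chest_interval` of slices containing lung voxels).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_local_seed(spec$seed, {
    centre_mm <- c(spec$image_size * spec$spacing[1] / 2,
                   spec$image_size * spec$spacing[2] / 2,
                   spec$n_slices * spec$spacing[3] / 2)
    ja <- function(semi) semi * exp(stats::rnorm(length(semi), 0, spec$jitter_axes_frac))
    body_center <- if (is.null(spec$body$center)) centre_mm else centre_mm + spec$body$center
    heart_center <- centre_mm + spec$heart$center + stats::rnorm(3, 0, spec$jitter_center_mm)
    lung_centers <- spec$lungs$center
    lung_centers <- sweep(lung_centers, 2L, centre_mm, "+") +
      matrix(stats::rnorm(6, 0, spec$jitter_center_mm), 2)
    heart_semi <- ja(spec$heart$semi)
    lung_semi <- ja(spec$lungs$semi)

    grid <- phantom_grid(spec)
    body <- ellipsoid_mask(grid, body_center, spec$body$semi)
    heart <- ellipsoid_mask(grid, heart_center, heart_semi)
    lung <- ellipsoid_mask(grid, lung_centers[1, ], lung_semi) |
      ellipsoid_mask(grid, lung_centers[2, ], lung_semi)

    if (any(heart & lung)) {
      stop("phantom spec invalid: heart and lung ellipsoids overlap",
           call. = FALSE)
    }
    if (any(heart & !body) || any(lung & !body)) {
      stop("phantom spec invalid: organs extend outside the body ellipsoid",
           call. = FALSE)
    }

    hu <- array(spec$background_hu, dim(body))
    n_body <- sum(body)
    hu[body] <- stats::rnorm(n_body, spec$body$hu_mean, spec$body$hu_sd)
    hu[heart] <- stats::rnorm(sum(heart), spec$heart$hu_mean, spec$heart$hu_sd)
    hu[lung] <- stats::rnorm(sum(lung), spec$lungs$hu_mean, spec$lungs$hu_sd)
    hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd), dim(hu))

    labels <- array(0L, dim(body))
    labels[heart] <- 1L
    labels[lung] <- 2L

    lung_slices <- which(apply(labels == 2L, 3L, any))
    chest_interval <- if (length(lung_slices)) {
      c(min(lung_slices) - 1L, max(lung_slices)) # 0-based half-open
    } else {
      c(0L, 0L)
    }

    list(
      volume = new_ct_volume(hu, spec$spacing),
      truth = structure(
        list(labels = labels, chest_interval = as.integer(chest_interval)),
        class = "ground_truth_stack"
      )
    )
  })
}

#' CT volume container
#'
#' @param hu numeric array (rows x cols x slices) of Hounsfield units.
#' @param spacing voxel spacing `c(x, y, z)` in mm.
#' @return an object of class `ct_volume`.
#' @export
new_ct_volume <- function(hu, spacing) {
  stopifnot(length(dim(hu)) == 3L, length(spacing) == 3L, all(spacing > 0))
  structure(list(hu = hu, spacing = as.numeric(spacing)), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Phantom slice datasets for training and evaluation
#'
#' Samples 2-D slices (with per-pixel ground-truth labels) from a sequence of
#' geometry-jittered phantoms. `phantom_slice_dataset()` draws chest slices
#' for segmentation training; `phantom_classification_dataset()` draws slices
#' across the whole stack with binary chest / not-chest labels.
#'
#' @param n_slices number of slices to return.
#' @param spec base [phantom_spec()]; per-phantom seeds are derived from
#'   `seed`.
#' @param seed integer seed.
#' @param jitter_center_mm,jitter_axes_frac geometric variability between
#'   phantoms.
#' @return a list with `images` (`H x W x n`), `labels` (`H x W x n`; for the
#'   classification dataset a length-`n` 0/1 vector `chest` instead),
#'   `phantom` and `slice` provenance vectors.
#' @export
phantom_slice_dataset <- function(n_slices, spec = phantom_spec(), seed = 1L,
                                  jitter_center_mm = 1.5, jitter_axes_frac = 0.06) {
  spec$jitter_center_mm <- jitter_center_mm
  spec$jitter_axes_frac <- jitter_axes_frac
  H <- spec$image_size
  images <- array(0, c(H, H, n_slices))
  labels <- array(0L, c(H, H, n_slices))
  phantom_id <- integer(n_slices)
  slice_id <- integer(n_slices)
  got <- 0L
  k <- 0L
  while (got < n_slices) {
    k <- k + 1L
    spec$seed <- seed * 1000L + k
    ph <- tryCatch(generate_phantom(spec), error = function(e) NULL)
    if (is.null(ph)) next # jittered geometry invalid; draw another phantom
    ci <- ph$truth$chest_interval
    sl <- (ci[1] + 1L):ci[2]
    for (s in sl) {
      if (got >= n_slices) break
      got <- got + 1L
      images[, , got] <- ph$volume$hu[, , s]
      labels[, , got] <- ph$truth$labels[, , s]
      phantom_id[got] <- k
      slice_id[got] <- s
    }
  }
  list(images = images, labels = labels, phantom = phantom_id, slice = slice_id)
}

#' @rdname phantom_slice_dataset
#' @export
phantom_classification_dataset <- function(n_slices, spec = phantom_spec(),
                                           seed = 1L, jitter_center_mm = 1.5,
                                           jitter_axes_frac = 0.06) {
  spec$jitter_center_mm <- jitter_center_mm
  spec$jitter_axes_frac <- jitter_axes_frac
  H <- spec$image_size
  images <- array(0, c(H, H, n_slices))
  chest <- integer(n_slices)
  phantom_id <- integer(n_slices)
  slice_id <- integer(n_slices)
  per_phantom <- max(2L, min(24L, ceiling(n_slices / 8)))
  got <- 0L
  k <- 0L
  while (got < n_slices) {
    k <- k + 1L
    spec$seed <- seed * 1000L + k
    ph <- tryCatch(generate_phantom(spec), error = function(e) NULL)
    if (is.null(ph)) next # jittered geometry invalid; draw another phantom
    ci <- ph$truth$chest_interval
    take <- with_local_seed(spec$seed + 1L,
                            sample.int(spec$n_slices, per_phantom))
    for (s in take) {
      if (got >= n_slices) break
      got <- got + 1L
      images[, , got] <- ph$volume$hu[, , s]
      chest[got] <- as.integer(s > ci[1] && s <= ci[2])
      phantom_id[got] <- k
      slice_id[got] <- s
    }
  }
  list(images = images, chest = chest, phantom = phantom_id, slice = slice_id)
}
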