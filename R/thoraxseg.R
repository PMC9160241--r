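# Segmentation data preparation and post-processing.
#
# Training labels come from manual polygon annotations: the heart polygon is
# used directly; the lung mask is the air (HU < -400) part of the combined
# heart+lung polygon; the remaining soft tissue inside the combined polygon
# is left unassigned (excluded from loss and Dice).

LABEL_BACKGROUND <- 0L
LABEL_HEART <- 1L
LABEL_LUNG <- 2L
LABEL_UNASSIGNED <- 255L

#' Rasterize a polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its centre `(col - 0.5, row - 0.5)` (in
#' the annotation's x/y pixel coordinates, origin at the image corner) lies
#' inside the polygon under the even-odd rule.
#'
#' @param vertices two-column matrix (x, y) of polygon vertices in pixel
#'   coordinates.
#' @param image_size `c(rows, cols)` of the target image (a single number is
#'   used for both).
#' @return logical `rows x cols` matrix.
#' @export
rasterize_polygon <- function(vertices, image_size) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) {
    stop("degenerate polygon: need at least 3 vertices", call. = FALSE)
  }
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  nr <- image_size[1]; nc <- image_size[2]
  px <- rep(seq_len(nc) - 0.5, each = nr)   # x = column centre
  py <- rep(seq_len(nr) - 0.5, times = nc)  # y = row centre
  inside <- logical(nr * nc)
  n <- nrow(vertices)
  xi <- vertices[, 1]; yi <- vertices[, 2]
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((yi[i] > py) != (yi[j] > py))
    if (any(crosses)) {
      xint <- xi[i] + (py[crosses] - yi[i]) * (xi[j] - xi[i]) / (yi[j] - yi[i])
      flip <- px[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    j <- i
  }
  matrix(inside, nr, nc)
}

#' Read LabelMe-style polygon annotations
#'
#' Consumes the LabelMe JSON dialect: `imagePath`, and `shapes[].label`
#' (expected values `"heart"` and `"heart_lung"`) with `shapes[].points`.
#'
#' @param path JSON file path.
#' @return a list with `slice_id`, `heart_polygon`, `combined_polygon`.
#' @export
read_labelme <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- list()
  for (sh in js$shapes) {
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    polys[[sh$label]] <- pts
  }
  if (is.null(polys$heart) || is.null(polys$heart_lung)) {
    stop("annotation must contain 'heart' and 'heart_lung' polygons",
         call. = FALSE)
  }
  list(slice_id = js$imagePath, heart_polygon = polys$heart,
       combined_polygon = polys$heart_lung,
       image_size = if (!is.null(js$imageHeight)) {
         c(js$imageHeight, js$imageWidth)
       })
}

#' Build per-pixel training labels from an annotation
#'
#' Heart = heart polygon; lung = air pixels (HU strictly below the
#' threshold) of the combined polygon outside the heart; the remaining
#' combined-polygon pixels are unassigned (class 255, masked from loss and
#' Dice); everything outside the combined polygon is background.
#'
#' @param annotation list with `heart_polygon` and `combined_polygon`
#'   (see [read_labelme()]).
#' @param hu_image numeric matrix of Hounsfield units.
#' @param lung_hu_threshold lung air threshold, default -400 HU.
#' @return integer label matrix (0 background, 1 heart, 2 lung,
#'   255 unassigned).
#' @export
build_labels <- function(annotation, hu_image, lung_hu_threshold = -400) {
  sz <- dim(hu_image)
  if (!is.null(annotation$image_size) &&
      !all(annotation$image_size == sz)) {
    stop("annotation and image sizes do not match", call. = FALSE)
  }
  heart <- rasterize_polygon(annotation$heart_polygon, sz)
  combined <- rasterize_polygon(annotation$combined_polygon, sz)
  lab <- matrix(LABEL_BACKGROUND, sz[1], sz[2])
  air <- hu_image < lung_hu_threshold
  lab[combined & !heart & air] <- LABEL_LUNG
  lab[combined & !heart & !air] <- LABEL_UNASSIGNED
  lab[heart] <- LABEL_HEART
  lab
}

#' Hard class assignment from per-pixel probabilities
#'
#' A pixel is assigned to its most probable class when that probability is
#' at least `prob_threshold`; below the threshold it is set to background
#' (uncertain voxels are not counted as organ). Ties go to the lowest class
#' index.
#'
#' @param model a `unet_model`, or `NULL` when `probs` is supplied.
#' @param slices `H x W x N` HU array (ignored when `probs` given).
#' @param probs optional precomputed `H x W x K x N` probability array.
#' @param prob_threshold assignment threshold, default 0.5.
#' @param provenance optional list stored on the result.
#' @return a `segmentation_stack`: integer label array `H x W x N` with
#'   classes 0/1/2, plus provenance.
#' @export
predict_classes <- function(model = NULL, slices = NULL, probs = NULL,
                            prob_threshold = 0.5, provenance = list()) {
  if (is.null(probs)) {
    stopifnot(inherits(model, "unet_model"))
    probs <- predict_unet_probs(model, slices)
  }
  d <- dim(probs)
  H <- d[1]; W <- d[2]; K <- d[3]; N <- d[4]
  pm <- matrix(aperm(probs, c(1, 2, 4, 3)), ncol = K)
  best <- max.col(pm, ties.method = "first")
  top <- pm[cbind(seq_len(nrow(pm)), best)]
  lab <- ifelse(top >= prob_threshold, best - 1L, LABEL_BACKGROUND)
  labels <- array(as.integer(lab), c(H, W, N))
  new_segmentation_stack(labels, provenance = c(provenance,
    list(prob_threshold = prob_threshold,
         model_seed = if (!is.null(model)) model$seed)))
}

#' @param labels integer array of class labels (0 background, 1 heart,
#'   2 lung).
#' @param provenance free-form provenance list.
#' @rdname predict_classes
#' @export
new_segmentation_stack <- function(labels, provenance = list()) {
  stopifnot(length(dim(labels)) == 3L,
            all(labels %in% c(LABEL_BACKGROUND, LABEL_HEART, LABEL_LUNG)))
  structure(list(labels = labels, provenance = provenance),
            class = "segmentation_stack")
}

#' @export
print.segmentation_stack <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<segmentation_stack> %d x %d x %d; heart %d, lung %d voxels\n",
    d[1], d[2], d[3], sum(x$labels == LABEL_HEART), sum(x$labels == LABEL_LUNG)))
  invisible(x)
}

#' Keep only the largest connected heart component
#'
#' Heart voxels outside the largest connected heart component are relabelled
#' background, so that only voxels physically belonging to one continuous
#' heart region are counted. Connectivity is 3-D 6-neighbour by default; a
#' 2-D per-slice mode is available. Size ties are broken towards the
#' component containing the smallest voxel index.
#'
#' @param stack a `segmentation_stack`.
#' @param connectivity `"3d"` (6-neighbour across slices) or `"2d"`
#'   (4-neighbour within each slice).
#' @return the cleaned `segmentation_stack`; if there are no heart voxels the
#'   stack is returned unchanged with a warning.
#' @export
largest_heart_component <- function(stack, connectivity = c("3d", "2d")) {
  connectivity <- match.arg(connectivity)
  stopifnot(inherits(stack, "segmentation_stack"))
  lab <- stack$labels
  d <- dim(lab)
  mask <- lab == LABEL_HEART
  if (!any(mask)) {
    warning("no heart voxels in stack; returned unchanged", call. = FALSE)
    stack$provenance$largest_component <- "no heart voxels"
    return(stack)
  }
  if (connectivity == "3d") {
    comp <- cpp_label_components_3d(as.logical(mask), d[1], d[2], d[3])
  } else {
    comp <- integer(length(mask))
    offset <- 0L
    for (k in seq_len(d[3])) {
      sl <- cpp_label_components_3d(as.logical(mask[, , k]), d[1], d[2], 1L)
      nlab <- if (any(sl > 0L)) max(sl) else 0L
      sl[sl > 0L] <- sl[sl > 0L] + offset
      comp[(k - 1L) * d[1] * d[2] + seq_len(d[1] * d[2])] <- sl
      offset <- offset + nlab
    }
  }
  sizes <- tabulate(comp)
  biggest <- sizes == max(sizes)
  keep <- which(biggest)[1] # components are numbered in voxel-index order
  drop <- comp > 0L & comp != keep
  lab[array(drop, d)] <- LABEL_BACKGROUND
  stack$labels <- lab
  stack$provenance$largest_component <- connectivity
  stack
}

#' Dice coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks have Dice 1 by convention.
#'
#' @param pred_mask,truth_mask logical arrays of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred_mask, truth_mask) {
  if (!all(dim(pred_mask) == dim(truth_mask))) {
    stop("mask shapes differ", call. = FALSE)
  }
  a <- sum(pred_mask); b <- sum(truth_mask)
  if (a + b == 0) return(1)
  2 * sum(pred_mask & truth_mask) / (a + b)
}

#' Per-class and overall Dice of a predicted labelling
#'
#' Pixels labelled 255 (unassigned) in the truth are excluded. The overall
#' coefficient is reported both voxel-count-weighted (default headline
#' number) and as the unweighted class mean.
#'
#' @param pred,truth integer label arrays (truth may contain 255).
#' @param classes integer class codes to evaluate.
#' @return tibble with one row per class plus `overall` (voxel-weighted) and
#'   `overall_unweighted`.
#' @export
dice_by_class <- function(pred, truth,
                          classes = c(background = LABEL_BACKGROUND,
                                      heart = LABEL_HEART,
                                      lung = LABEL_LUNG)) {
  keep <- truth != LABEL_UNASSIGNED
  p <- pred[keep]; t <- truth[keep]
  per <- vapply(classes, function(k) dice(p == k, t == k), numeric(1))
  wt <- vapply(classes, function(k) sum(p == k) + sum(t == k), numeric(1))
  tibble::tibble(
    class = c(names(classes), "overall", "overall_unweighted"),
    dice = c(per, sum(per * wt) / sum(wt), mean(per))
  )
}

#' 8-bit display windowing of a HU image
#'
#' Utility for visual parity with PNG-converted CT workflows: clamps a HU
#' window and rescales to 0..255.
#'
#' @param hu_image numeric HU matrix.
#' @param center,width window centre and width in HU.
#' @return integer matrix in 0..255.
#' @export
hu_window_u8 <- function(hu_image, center = -300, width = 1400) {
  lo <- center - width / 2; hi <- center + width / 2
  matrix(as.integer(round(255 * (pmin(pmax(hu_image, lo), hi) - lo) / (hi - lo))),
         nrow(hu_image), ncol(hu_image))
}

#' Random train/validation split at image level
#'
#' Shuffles image indices with a fixed seed and assigns a `train_frac`
#' share (rounded to the nearest image) to training, the rest to
#' validation. Splitting 1121 annotated images at 80/20 yields 897
#' training and 224 validation images.
#'
#' @param n number of images (or a vector of ids to split).
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list with `train` and `val` index (or id) vectors.
#' @export
train_val_split <- function(n, train_frac = 0.8, seed = 1L) {
  ids <- if (length(n) == 1L && is.numeric(n)) seq_len(n) else n
  stopifnot(train_frac > 0, train_frac < 1)
  n_train <- round(train_frac * length(ids))
  with_local_seed(seed, {
    ord <- sample(ids)
    list(train = sort(ord[seq_len(n_train)]),
         val = sort(ord[(n_train + 1L):length(ids)]))
  })
}
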