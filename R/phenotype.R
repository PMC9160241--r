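# Organ volumetry: voxel counting times voxel volume, and the end-to-end
# per-animal pipeline (chest localisation -> segmentation -> largest-component
# cleanup -> volumes).

#' Organ volume from a segmentation stack
#'
#' `volume_ml = voxel_count * (x*y*z mm^3) / 1000`: the voxel count of the
#' organ class multiplied by the full voxel volume (in-plane pixel size times
#' slice thickness).
#'
#' @param stack a `segmentation_stack`.
#' @param organ `"heart"` or `"lung"` (or an integer class code).
#' @param spacing voxel spacing `c(x, y, z)` in mm.
#' @return volume in millilitres.
#' @export
organ_volume <- function(stack, organ, spacing) {
  stopifnot(inherits(stack, "segmentation_stack"), all(spacing > 0),
            length(spacing) == 3L)
  code <- if (is.character(organ)) {
    switch(organ, heart = LABEL_HEART, lung = LABEL_LUNG,
           background = LABEL_BACKGROUND,
           stop("unknown organ class: ", organ, call. = FALSE))
  } else {
    if (!organ %in% c(LABEL_BACKGROUND, LABEL_HEART, LABEL_LUNG)) {
      stop("unknown organ class: ", organ, call. = FALSE)
    }
    as.integer(organ)
  }
  sum(stack$labels == code) * prod(spacing) / 1000
}

#' Extract a heart/lung phenotype record from a CT volume
#'
#' Runs the full pipeline: score the slice range with the chest classifier,
#' smooth to one contiguous chest interval, segment the chest slices with the
#' U-net, keep the largest connected heart component, and convert voxel
#' counts to millilitres. A "no chest found" result propagates as a record
#' with missing volumes rather than an error.
#'
#' @param volume a `ct_volume`.
#' @param chest_model a `slice_classifier`.
#' @param seg_model a `unet_model`, or `NULL` with `oracle_labels` to inject
#'   a ground-truth segmentation (used to isolate volumetry from model
#'   error).
#' @param covariates one-row data frame / named list of covariates copied
#'   into the record (e.g. `animal`, `live_weight_kg`, `age_days`,
#'   `herd_year`, `birth_month`, `parity`, `pen`).
#' @param slice_range 0-based half-open slice range scored for chest
#'   probability (clipped to the stack).
#' @param oracle_labels optional `H x W x Z` ground-truth label array used in
#'   place of U-net predictions.
#' @return a one-row tibble with `heart_ml`, `lung_ml`, `chest_start`,
#'   `chest_end`, `chest_found`, plus the covariates.
#' @export
extract_phenotype <- function(volume, chest_model, seg_model,
                              covariates = list(),
                              slice_range = c(300L, 800L),
                              oracle_labels = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  profile <- score_stack(chest_model, volume, slice_range)
  fit <- fit_three_levels(profile)
  iv <- chest_interval(fit)
  cov_tb <- tibble::as_tibble(covariates)
  if (nrow(cov_tb) == 0L) cov_tb <- tibble::tibble(.rows = 1L)
  if (!iv$found) {
    return(dplyr::bind_cols(cov_tb, tibble::tibble(
      heart_ml = NA_real_, lung_ml = NA_real_,
      chest_start = NA_integer_, chest_end = NA_integer_,
      chest_found = FALSE)))
  }
  idx <- (iv$start + 1L):iv$end
  slices <- volume$hu[, , idx, drop = FALSE]
  if (!is.null(oracle_labels)) {
    stack <- new_segmentation_stack(
      oracle_labels[, , idx, drop = FALSE],
      provenance = list(model = "oracle", chest_interval = c(iv$start, iv$end)))
  } else {
    stack <- predict_classes(seg_model, slices,
                             provenance = list(chest_interval = c(iv$start, iv$end)))
  }
  stack <- largest_heart_component(stack)
  dplyr::bind_cols(cov_tb, tibble::tibble(
    heart_ml = organ_volume(stack, "heart", volume$spacing),
    lung_ml = organ_volume(stack, "lung", volume$spacing),
    chest_start = iv$start, chest_end = iv$end,
    chest_found = TRUE))
}
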