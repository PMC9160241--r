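# Plain-text interchange: phantom slice directories with CT metadata,
# pedigree and phenotype CSV dialects, LabelMe JSON (see thoraxseg.R).

#' Write and read a phantom volume as a plain-text slice directory
#'
#' One whitespace-separated integer matrix per slice
#' (`slice_0001.txt`, ...) plus `metadata.json` carrying the CT header
#' fields (Rows, Columns, PixelSpacing, SliceThickness, InstanceNumber
#' range, RescaleSlope/Intercept). HU values are stored as
#' `round((hu - intercept) / slope)` 16-bit-range integers, mirroring how
#' calibrated CT pixel data are rescaled. Slice files are 1-based by
#' `InstanceNumber`; in-memory slice indices are 0-based.
#'
#' @param volume a `ct_volume`.
#' @param dir output directory (created if missing).
#' @param rescale_slope,rescale_intercept HU = slope * stored + intercept.
#' @return `dir`, invisibly.
#' @export
write_ct_dir <- function(volume, dir, rescale_slope = 1,
                         rescale_intercept = -1024) {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$hu)
  meta <- list(
    Rows = d[1], Columns = d[2], NumberOfSlices = d[3],
    PixelSpacing = volume$spacing[1:2], SliceThickness = volume$spacing[3],
    InstanceNumbers = c(1L, d[3]),
    RescaleSlope = rescale_slope, RescaleIntercept = rescale_intercept
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_len(d[3])) {
    stored <- round((volume$hu[, , k] - rescale_intercept) / rescale_slope)
    utils::write.table(stored, file.path(dir, sprintf("slice_%04d.txt", k)),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_ct_dir
#' @export
read_ct_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.txt$",
                           full.names = TRUE))
  stopifnot(length(files) == meta$NumberOfSlices)
  hu <- array(0, c(meta$Rows, meta$Columns, meta$NumberOfSlices))
  for (k in seq_along(files)) {
    stored <- as.matrix(utils::read.table(files[k]))
    hu[, , k] <- meta$RescaleSlope * stored + meta$RescaleIntercept
  }
  new_ct_volume(hu, c(meta$PixelSpacing, meta$SliceThickness))
}

#' Pedigree and phenotype CSV dialects
#'
#' Pedigree CSV columns: `animal_id`, `sire_id`, `dam_id`, `sex`,
#' `birth_year` (0 = unknown parent). Phenotype CSV: `animal_id`, trait
#' columns, `herd_year`, `birth_month`, `parity`, `pen`, `live_weight_kg`,
#' `age_days`.
#'
#' @param ped,pheno tibbles as produced by [simulate_pedigree()] /
#'   [simulate_phenotypes()].
#' @param path file path.
#' @return the read functions return tibbles in the package's internal
#'   column naming (`animal`, `sire`, `dam`, ...).
#' @export
write_pedigree_csv <- function(ped, path) {
  out <- data.frame(animal_id = ped$animal, sire_id = ped$sire,
                    dam_id = ped$dam,
                    sex = if ("sex" %in% names(ped)) ped$sex else NA,
                    birth_year = if ("birth_year" %in% names(ped))
                      ped$birth_year else NA)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  x <- utils::read.csv(path)
  as_pedigree(tibble::tibble(animal = x$animal_id, sire = x$sire_id,
                             dam = x$dam_id, sex = x$sex,
                             birth_year = x$birth_year))
}

#' @rdname write_pedigree_csv
#' @export
write_phenotype_csv <- function(pheno, path) {
  out <- pheno
  names(out)[names(out) == "animal"] <- "animal_id"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_phenotype_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path))
  names(x)[names(x) == "animal_id"] <- "animal"
  x
}

#' Plot a slice probability profile with its three-level fit
#'
#' @param profile a `slice_profile` from [score_stack()].
#' @param fit optional `three_level_fit` overlay.
#' @return a ggplot.
#' @export
plot_slice_profile <- function(profile, fit = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$slice, .data$prob)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "slice (0-based)", y = "chest probability")
  if (!is.null(fit)) {
    b <- fit$breakpoints + fit$slice_offset
    n <- fit$n + fit$slice_offset
    seg <- tibble::tibble(
      x = c(fit$slice_offset, b[1], b[2]), xend = c(b[1], b[2], n),
      y = fit$levels)
    seg <- seg[seg$xend > seg$x, ]
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$y),
      colour = "firebrick", linewidth = 0.9)
  }
  p
}
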