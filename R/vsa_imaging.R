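# Voiding spot assay imaging: detect urine spots on absorbent-pad images
# and classify them as voids, leaks, or excluded splatter.
#
# Classification criteria: a spot of equivalent diameter >= void_min_diameter
# is a void; a smaller spot is a leak only if it is less than
# leak_max_diameter across AND its edge-to-edge distance to every void is at
# least the splatter exclusion distance -- otherwise it is splatter thrown
# off by an active void and excluded.

#' Load a pad image as a grayscale intensity matrix
#'
#' Reads 8- or 16-bit grayscale PNG/TIFF into a numeric matrix in `[0, 1]`.
#' Multi-channel images are averaged to grayscale.
#'
#' @param path Image file path.
#' @return A numeric matrix (rows x columns) of intensities in `[0, 1]`.
#' @export
load_pad_image <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("image not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort_io("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  img
}

#' Detect urine spots on a pad image
#'
#' Binarizes the image (Otsu's method by default; wet regions are bright by
#' convention, set `invert` in the thresholds for dark-wet pads), labels
#' 8-connected components, drops components smaller than
#' `min_spot_area` mm^2, and returns spot geometry in millimetres.  All
#' returned spots carry the label `"unclassified"`; only
#' [classify_spots()] assigns classes.
#'
#' @param image A numeric intensity matrix in `[0, 1]`, or a path to a
#'   PNG/TIFF file.
#' @param calibration Physical size of one pixel, mm/pixel.
#' @param thr A [vsa_thresholds()] list.
#' @return A tibble with columns `spot_id`, `centroid_x_mm`,
#'   `centroid_y_mm`, `area_mm2`, `equiv_diameter_mm`, `label`.
#' @export
detect_spots <- function(image, calibration, thr = vsa_thresholds()) {
  if (is.character(image)) image <- load_pad_image(image)
  if (!is.matrix(image) || !length(image)) {
    abort_validation("image must be a non-empty numeric matrix")
  }
  if (!is_scalar_number(calibration) || calibration <= 0) {
    abort_validation("calibration must be a positive number (mm per pixel)")
  }
  validate_vsa_thresholds(thr)

  cutoff <- if (thr$threshold_method == "fixed") {
    if (!is_scalar_number(thr$fixed_threshold)) {
      abort_detection("threshold_method = 'fixed' requires fixed_threshold")
    }
    thr$fixed_threshold
  } else {
    rng <- range(image)
    if (diff(rng) < .Machine$double.eps) {
      # uniform image: nothing to separate
      return(empty_spots())
    }
    EBImage::otsu(image, range = rng)
  }
  mask <- if (thr$invert) image < cutoff else image > cutoff
  if (!any(mask)) return(empty_spots())
  if (thr$threshold_method == "otsu") {
    # reject Otsu splits of a single-class (stain-free) scene: the two
    # class means must be separated by at least min_contrast
    if (all(mask) ||
        abs(mean(image[mask]) - mean(image[!mask])) < thr$min_contrast) {
      return(empty_spots())
    }
  }

  lab <- label_components8(mask)
  n_lab <- max(lab)
  if (n_lab == 0L) return(empty_spots())

  px <- which(lab > 0L)
  ids <- lab[px]
  rows <- (px - 1L) %% nrow(lab) + 1L
  cols <- (px - 1L) %/% nrow(lab) + 1L
  area_px <- tabulate(ids, nbins = n_lab)
  cx <- tapply(cols, ids, mean)
  cy <- tapply(rows, ids, mean)

  area_mm2 <- area_px * calibration^2
  spots <- tibble::tibble(
    spot_id = seq_len(n_lab),
    centroid_x_mm = as.numeric(cx - 0.5) * calibration,
    centroid_y_mm = as.numeric(cy - 0.5) * calibration,
    area_mm2 = area_mm2,
    equiv_diameter_mm = 2 * sqrt(area_mm2 / pi),
    label = "unclassified"
  )
  spots <- spots[spots$area_mm2 >= thr$min_spot_area, ]
  spots$spot_id <- seq_len(nrow(spots))
  spots
}

empty_spots <- function() {
  tibble::tibble(
    spot_id = integer(), centroid_x_mm = numeric(), centroid_y_mm = numeric(),
    area_mm2 = numeric(), equiv_diameter_mm = numeric(), label = character()
  )
}

# 8-connected component labelling: EBImage::bwlabel gives 4-connected
# components; diagonal touches between distinct labels are then merged with
# a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- uf_new(n)
  # down-right diagonal
  a <- lab[-nr, -nc]; b <- lab[-1L, -1L]
  sel <- which(a > 0L & b > 0L & a != b)
  for (k in sel) parent <- uf_union(parent, a[k], b[k])
  # up-right diagonal
  a <- lab[-1L, -nc]; b <- lab[-nr, -1L]
  sel <- which(a > 0L & b > 0L & a != b)
  for (k in sel) parent <- uf_union(parent, a[k], b[k])
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[out > 0L] <- relabel[lab[lab > 0L]]
  out
}

#' Classify detected spots as voids, leaks or excluded splatter
#'
#' A spot with equivalent diameter at least `void_min_diameter` is a void.
#' A spot smaller than `leak_max_diameter` is a leak when its edge-to-edge
#' distance to every void is at least `splatter_exclusion_distance`;
#' otherwise it is `splatter_excluded` (small stains thrown off by an
#' active void).  Spots falling between the two diameter thresholds (only
#' possible when they are configured apart) are treated as splatter of
#' ambiguous origin and excluded.  Every spot receives exactly one label.
#'
#' @param spots Unclassified spot tibble from [detect_spots()].
#' @param thr A [vsa_thresholds()] list.
#' @return The spot tibble with `label` filled in.
#' @export
classify_spots <- function(spots, thr = vsa_thresholds()) {
  validate_vsa_thresholds(thr)
  spots <- tibble::as_tibble(spots)
  if (!nrow(spots)) return(spots)
  if (any(spots$label != "unclassified")) {
    abort_validation("spots have already been classified")
  }
  d <- spots$equiv_diameter_mm
  is_void <- d >= thr$void_min_diameter
  label <- rep("splatter_excluded", nrow(spots))
  label[is_void] <- "void"

  small <- which(!is_void & d < thr$leak_max_diameter)
  voids <- which(is_void)
  for (i in small) {
    if (!length(voids)) {
      label[i] <- "leak"
      next
    }
    gap <- sqrt((spots$centroid_x_mm[i] - spots$centroid_x_mm[voids])^2 +
                  (spots$centroid_y_mm[i] - spots$centroid_y_mm[voids])^2) -
      (d[i] + d[voids]) / 2
    if (all(gap >= thr$splatter_exclusion_distance)) label[i] <- "leak"
  }
  spots$label <- label
  spots
}

#' Summarize one pad-day into a daily observation
#'
#' Counts voids and leaks, computes the daily micturition mass as the pad
#' mass gain (wet minus dry, grams; 1 g of absorbed urine is treated as
#' 1 mL of voided volume) and the mass per void (absent, not zero, on
#' void-free days), and carries the daily water intake through.
#'
#' @param spots Classified spot tibble.
#' @param pad A one-row pad record (as from [read_pad_table()]).
#' @return A one-row daily-observation tibble.
#' @export
summarize_pad <- function(spots, pad) {
  pad <- tibble::as_tibble(pad)
  if (nrow(pad) != 1L) abort_validation("pad must be a single record")
  n_voids <- sum(spots$label == "void")
  n_leaks <- sum(spots$label == "leak")
  mass <- pad$pad_mass_wet_g - pad$pad_mass_dry_g
  tibble::tibble(
    animal_id = pad$animal_id,
    obs_date = pad$obs_date,
    period = pad$period,
    n_voids = n_voids,
    n_leaks = n_leaks,
    daily_micturition_mass_g = mass,
    mass_per_void_g = if (n_voids > 0) mass / n_voids else NA_real_,
    water_intake_mL = pad$water_intake_mL
  )
}
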