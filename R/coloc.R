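# Object-based two-channel colocalization of synaptic puncta:
# min-max normalization, iterative-threshold connected-component detection,
# and disk-overlap pairing between channels.

#' Detection and colocalization parameters
#'
#' Houses the constants of the puncta pipeline: the cutoff sweep (255 down to
#' 95 in steps of 1), the strict `>25` px component size gate, the nominal
#' 4 px synapse disk radius, and the marker-dependent exclusion margin
#' (10 px for VGAT, 5 px for the denser VGLUT1) drawn around each accepted
#' punctum to suppress further detections.
#'
#' @param max_cutoff,min_cutoff intensity sweep bounds (8-bit scale).
#' @param min_region_px component size gate; components must be strictly
#'   larger to be accepted.
#' @param synapse_radius_px nominal punctum disk radius for the overlap test.
#' @param marker_type optional `"vgat"` or `"vglut1"`; sets the exclusion
#'   margin to 10 or 5 px respectively unless `exclusion_margin_px` is given.
#' @param exclusion_margin_px exclusion margin in px (overrides
#'   `marker_type`).
#' @param connectivity component connectivity, 8 (default) or 4.
#' @param roundness_min optional circularity gate in `(0, 1]`; `NULL`
#'   (default) applies no shape criterion beyond the size gate.
#' @return an object of class `coloc_params`.
#' @export
coloc_params <- function(max_cutoff = 255, min_cutoff = 95,
                         min_region_px = 25, synapse_radius_px = 4,
                         marker_type = NULL, exclusion_margin_px = NULL,
                         connectivity = 8, roundness_min = NULL) {
  check_number(max_cutoff, "max_cutoff", lower = 0, upper = 255, integer = TRUE)
  check_number(min_cutoff, "min_cutoff", lower = 0, upper = max_cutoff,
               integer = TRUE)
  check_number(min_region_px, "min_region_px", lower = 0, integer = TRUE)
  check_number(synapse_radius_px, "synapse_radius_px", lower = 0,
               strict_lower = TRUE)
  if (is.null(exclusion_margin_px)) {
    exclusion_margin_px <- if (is.null(marker_type)) 5 else
      switch(match.arg(tolower(marker_type), c("vgat", "vglut1")),
             vgat = 10, vglut1 = 5)
  }
  check_number(exclusion_margin_px, "exclusion_margin_px", lower = 0,
               strict_lower = TRUE)
  if (!connectivity %in% c(4L, 8L))
    abort("`connectivity` must be 4 or 8", "synq_parameter_error")
  if (!is.null(roundness_min))
    check_number(roundness_min, "roundness_min", lower = 0, upper = 1,
                 strict_lower = TRUE)
  structure(list(max_cutoff = as.integer(max_cutoff),
                 min_cutoff = as.integer(min_cutoff),
                 min_region_px = as.integer(min_region_px),
                 synapse_radius_px = synapse_radius_px,
                 exclusion_margin_px = exclusion_margin_px,
                 connectivity = as.integer(connectivity),
                 roundness_min = roundness_min),
            class = "coloc_params")
}

#' Min-max normalize an image to the 0-255 range
#'
#' Linear per-channel rescale of pixel intensities to `[0, 255]`, rounded to
#' integers. A constant image has no dynamic range and is mapped to all
#' zeros with a warning (no detections can arise from it).
#'
#' @param image numeric matrix of intensities.
#' @return integer-valued numeric matrix in `[0, 255]`.
#' @export
normalize_to_255 <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || !length(image))
    abort("`image` must be a non-empty numeric matrix", "synq_contract_error")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: no dynamic range, normalizing to all zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  round((image - rng[1]) / (rng[2] - rng[1]) * 255)
}

#' Detect synaptic puncta by iterative thresholding
#'
#' Sweeps an intensity cutoff from `max_cutoff` down to `min_cutoff` in steps
#' of one. At each cutoff, unmasked pixels at or above the cutoff are labeled
#' as connected components (row-major scan order); components strictly larger
#' than `min_region_px` whose intensity-weighted centroid (first image
#' moments) is not inside any previously accepted punctum's exclusion margin
#' are accepted, and a disk of radius `exclusion_margin_px` around each
#' accepted center is masked for all subsequent cutoffs. Accepted regions
#' represent synapses as nominal disks of radius `synapse_radius_px` at their
#' centroid; no shape criterion is applied unless `roundness_min` is set.
#'
#' @param image a normalized image (integer values in 0-255, see
#'   [normalize_to_255()]).
#' @param params a [coloc_params()].
#' @return a `puncta_regions` data frame (`row`, `col` 0-based sub-pixel
#'   centroids, `radius_px`, `detection_cutoff`, `area_px`, `roundness`)
#'   sorted by detection cutoff descending then row-major center, with the
#'   image dimensions in `attr(, "image_dim")`.
#' @export
detect_puncta <- function(image, params = coloc_params()) {
  stopifnot(inherits(params, "coloc_params"))
  if (!is.matrix(image) || !is.numeric(image) || !length(image))
    abort("`image` must be a non-empty numeric matrix", "synq_contract_error")
  if (min(image) < 0 || max(image) > 255)
    abort("`image` is not normalized to 0-255; call normalize_to_255() first",
          "synq_contract_error")
  storage.mode(image) <- "integer"
  res <- cpp_detect_puncta(image, params$max_cutoff, params$min_cutoff,
                           params$min_region_px, params$exclusion_margin_px,
                           params$connectivity)
  if (!is.null(params$roundness_min))
    res <- res[res$roundness >= params$roundness_min, , drop = FALSE]
  res$radius_px <- rep(params$synapse_radius_px, nrow(res))
  res <- res[order(-res$detection_cutoff, res$row, res$col), , drop = FALSE]
  rownames(res) <- NULL
  res <- res[, c("row", "col", "radius_px", "detection_cutoff", "area_px",
                 "roundness")]
  structure(res, image_dim = dim(image), params = params,
            class = c("puncta_regions", "data.frame"))
}

#' Colocalize reference puncta with a marker channel
#'
#' A reference punctum counts as colocalized when its nominal disk of radius
#' `synapse_radius_px` overlaps any marker-channel disk, i.e. when the
#' Euclidean center distance is at most `2 * synapse_radius_px` (closed
#' disks: touching counts). One marker punctum may pair with several
#' reference puncta; the fraction is computed over reference puncta.
#'
#' @param reference,marker `puncta_regions` from two channels of the same
#'   field (identical image dimensions).
#' @param params a [coloc_params()] supplying `synapse_radius_px`.
#' @return an object of class `coloc_result`: counts `n_reference`,
#'   `n_marker`, `n_colocalized`, the percentage `fraction_pct`, and the
#'   per-reference logical vector `colocalized`.
#' @export
colocalize <- function(reference, marker, params = coloc_params()) {
  stopifnot(inherits(params, "coloc_params"))
  dref <- attr(reference, "image_dim"); dmar <- attr(marker, "image_dim")
  if (!is.null(dref) && !is.null(dmar) && !identical(dref, dmar))
    abort("reference and marker puncta come from images of different dimensions",
          "synq_contract_error")
  n_ref <- nrow(reference); n_mar <- nrow(marker)
  lim2 <- (2 * params$synapse_radius_px)^2
  coloc <- logical(n_ref)
  if (n_ref > 0 && n_mar > 0) {
    for (i in seq_len(n_ref)) {
      d2 <- (marker$row - reference$row[i])^2 +
        (marker$col - reference$col[i])^2
      coloc[i] <- any(d2 <= lim2)
    }
  }
  structure(list(n_reference = n_ref, n_marker = n_mar,
                 n_colocalized = sum(coloc),
                 fraction_pct = if (n_ref > 0) 100 * sum(coloc) / n_ref
                                else NA_real_,
                 colocalized = coloc),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> %d/%d reference puncta colocalized (%.1f%%), %d marker puncta\n",
    x$n_colocalized, x$n_reference,
    if (is.na(x$fraction_pct)) NaN else x$fraction_pct, x$n_marker))
  invisible(x)
}
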