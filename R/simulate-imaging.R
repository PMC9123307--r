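# Synthetic two-channel puncta fields with planted colocalization truth.

# Draw a point uniformly inside [margin, limit - margin] (0-based, sub-pixel).
runif_center <- function(h, w, margin) {
  c(runif(1, margin, h - 1 - margin), runif(1, margin, w - 1 - margin))
}

min_dist_to <- function(pt, centers) {
  if (!nrow(centers)) return(Inf)
  sqrt(min((centers[, 1] - pt[1])^2 + (centers[, 2] - pt[2])^2))
}

# Additively render one Gaussian spot (sigma = radius/2, truncated at 3 sigma)
# onto `img` at 0-based center (r, c).
render_spot <- function(img, r, c, radius_px, peak) {
  sigma <- radius_px / 2
  ext <- ceiling(3 * sigma)
  rows <- max(0, floor(r) - ext):min(nrow(img) - 1, ceiling(r) + ext)
  cols <- max(0, floor(c) - ext):min(ncol(img) - 1, ceiling(c) + ext)
  d2 <- outer((rows - r)^2, (cols - c)^2, `+`)
  patch <- peak * exp(-d2 / (2 * sigma^2))
  patch[d2 > (3 * sigma)^2] <- 0
  img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + patch
  img
}

#' Generate a planted two-channel puncta image pair
#'
#' Builds two single-channel images (reference channel A, marker channel B)
#' with `round(coloc_fraction * n_puncta_a)` colocalized A/B pairs (centers
#' within `max_center_offset_px`) and all remaining puncta separated by at
#' least `4 * punctum_radius_px` from every other center across both channels.
#' Puncta are rendered as isotropic Gaussians (`sigma = radius/2`, truncated
#' at 3 sigma) on Gaussian background noise.
#'
#' @param spec a [puncta_field_spec()].
#' @param seed integer seed; output is bit-reproducible.
#' @return list with `image_a`, `image_b` (numeric matrices) and `truth`:
#'   data frames `centers_a` / `centers_b` (0-based sub-pixel `row`, `col`,
#'   logical `colocalized`) and `pairs` (indices into the two center tables).
#' @export
gen_puncta_image_pair <- function(spec, seed) {
  stopifnot(inherits(spec, "puncta_field_spec"))
  with_seed(seed, {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    sep <- 4 * spec$punctum_radius_px
    margin <- ceiling(1.5 * spec$punctum_radius_px) + 1
    if (h - 1 - margin <= margin || w - 1 - margin <= margin)
      abort("image too small for the punctum radius", "synq_parameter_error")

    place <- function(existing, min_sep, max_tries = 10000L) {
      for (i in seq_len(max_tries)) {
        pt <- runif_center(h, w, margin)
        if (min_dist_to(pt, existing) >= min_sep) return(pt)
      }
      abort(sprintf(
        "placement failed: cannot keep centers >= %g px (4 * punctum_radius) apart; reduce puncta count or enlarge the image",
        min_sep), "synq_placement_error")
    }

    all_centers <- matrix(numeric(), 0, 2)
    centers_a <- matrix(numeric(), 0, 2)
    centers_b <- matrix(numeric(), 0, 2)

    # colocalized pairs first: A at an anchor, B offset within the stated disk
    for (i in seq_len(spec$n_pairs)) {
      a <- place(all_centers, sep)
      repeat {
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * spec$max_center_offset_px
        b <- a + rad * c(cos(ang), sin(ang))
        if (b[1] >= margin && b[1] <= h - 1 - margin &&
            b[2] >= margin && b[2] <= w - 1 - margin) break
      }
      centers_a <- rbind(centers_a, a)
      centers_b <- rbind(centers_b, b)
      all_centers <- rbind(all_centers, a, b)
    }
    for (i in seq_len(spec$n_puncta_a - spec$n_pairs)) {
      a <- place(all_centers, sep)
      centers_a <- rbind(centers_a, a)
      all_centers <- rbind(all_centers, a)
    }
    for (i in seq_len(spec$n_puncta_b - spec$n_pairs)) {
      b <- place(all_centers, sep)
      centers_b <- rbind(centers_b, b)
      all_centers <- rbind(all_centers, b)
    }

    img_a <- matrix(rnorm(h * w, 0, spec$background_sd), h, w)
    img_b <- matrix(rnorm(h * w, 0, spec$background_sd), h, w)
    for (i in seq_len(nrow(centers_a)))
      img_a <- render_spot(img_a, centers_a[i, 1], centers_a[i, 2],
                           spec$punctum_radius_px, spec$peak_intensity)
    for (i in seq_len(nrow(centers_b)))
      img_b <- render_spot(img_b, centers_b[i, 1], centers_b[i, 2],
                           spec$punctum_radius_px, spec$peak_intensity)

    npr <- spec$n_pairs
    truth <- list(
      centers_a = data.frame(
        row = centers_a[, 1], col = centers_a[, 2],
        colocalized = seq_len(nrow(centers_a)) <= npr),
      centers_b = data.frame(
        row = centers_b[, 1], col = centers_b[, 2],
        colocalized = seq_len(nrow(centers_b)) <= npr),
      pairs = if (npr > 0)
        data.frame(a = seq_len(npr), b = seq_len(npr))
      else data.frame(a = integer(), b = integer()),
      coloc_fraction = if (spec$n_puncta_a > 0) npr / spec$n_puncta_a else NA_real_)
    list(image_a = img_a, image_b = img_b, truth = truth)
  })
}
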