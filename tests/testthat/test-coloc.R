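# Iterative-threshold puncta detection and disk-overlap colocalization.

test_that("normalize_to_255 rescales to the full 8-bit range", {
  expect_equal(sort(unique(as.vector(
    normalize_to_255(matrix(c(10, 20), 2, 2))))), c(0, 255))
  img <- matrix(c(0, 100, 200, 255), 2, 2)
  expect_equal(normalize_to_255(img), img)
  expect_warning(z <- normalize_to_255(matrix(7, 3, 3)), "constant")
  expect_equal(z, matrix(0, 3, 3))
})

test_that("detect_puncta handles degenerate and single-spot images", {
  expect_identical(nrow(detect_puncta(matrix(0, 32, 32))), 0L)
  expect_error(detect_puncta(matrix(300, 8, 8)), class = "synq_contract_error")
  expect_error(detect_puncta(matrix(-1, 8, 8)), class = "synq_contract_error")
  # one bright disk of > 25 px on zero background: exactly one region there
  img <- matrix(0, 64, 64)
  for (r in 1:64) for (c in 1:64)
    if ((r - 33)^2 + (c - 41)^2 <= 18) img[r, c] <- 255
  regs <- detect_puncta(img)
  expect_identical(nrow(regs), 1L)
  expect_equal(regs$row, 32, tolerance = 1e-9)  # 0-based center
  expect_equal(regs$col, 40, tolerance = 1e-9)
  expect_identical(regs$detection_cutoff, 255L)
  expect_gt(regs$area_px, 25)
})

test_that("detect_puncta equals the brute-force oracle on seeded images", {
  for (seed in 1:8) {
    img <- normalize_to_255(make_oracle_image(seed))
    got <- detect_puncta(img)
    ora <- oracle_detect_puncta(img)
    expect_identical(nrow(got), nrow(ora))
    if (nrow(got)) {
      expect_equal(got$row, ora$row, tolerance = 1e-9)
      expect_equal(got$col, ora$col, tolerance = 1e-9)
      expect_identical(as.integer(got$detection_cutoff),
                       as.integer(ora$detection_cutoff))
      expect_identical(as.integer(got$area_px), as.integer(ora$area_px))
    }
  }
})

test_that("detection is invariant to intensity offset and translation", {
  raw <- make_oracle_image(42)
  base <- detect_puncta(normalize_to_255(raw))
  shifted <- detect_puncta(normalize_to_255(raw + 137))
  expect_equal(as.data.frame(base), as.data.frame(shifted))
  # integer translation moves all centers by the shift (interior puncta)
  big <- matrix(0, 96, 96); big[17:80, 17:80] <- raw
  big2 <- matrix(0, 96, 96); big2[22:85, 14:77] <- raw
  d1 <- detect_puncta(normalize_to_255(big))
  d2 <- detect_puncta(normalize_to_255(big2))
  expect_identical(nrow(d1), nrow(d2))
  expect_equal(d2$row - d1$row, rep(5, nrow(d1)), tolerance = 1e-9)
  expect_equal(d2$col - d1$col, rep(-3, nrow(d1)), tolerance = 1e-9)
})

test_that("accepted centers in one channel honour the exclusion margin", {
  for (seed in c(3, 9, 21)) {
    regs <- detect_puncta(normalize_to_255(make_oracle_image(seed)),
                          coloc_params(exclusion_margin_px = 10))
    if (nrow(regs) >= 2) {
      d <- as.matrix(dist(cbind(regs$row, regs$col)))
      diag(d) <- Inf
      expect_gt(min(d), 10)
    }
  }
})

test_that("colocalize applies the closed-disk overlap rule", {
  mk <- function(rows, cols) {
    structure(data.frame(row = rows, col = cols, radius_px = 4,
                         detection_cutoff = 255L,
                         area_px = 30L, roundness = 1),
              image_dim = c(64L, 64L),
              class = c("puncta_regions", "data.frame"))
  }
  p <- coloc_params()
  # identical center lists: 100%
  a <- mk(c(10, 20, 30), c(10, 20, 30))
  expect_equal(colocalize(a, a, p)$fraction_pct, 100)
  # 9 px apart with radius 4: no overlap (9 > 8); exactly 8: touching counts
  expect_equal(colocalize(mk(10, 10), mk(10, 19), p)$n_colocalized, 0L)
  expect_equal(colocalize(mk(10, 10), mk(10, 18), p)$n_colocalized, 1L)
  # pair count symmetric under channel swap; denominator follows reference
  b <- mk(c(10.5, 50), c(10.5, 50))
  r_ab <- colocalize(a, b, p); r_ba <- colocalize(b, a, p)
  expect_identical(r_ab$n_colocalized, 1L)
  expect_identical(r_ba$n_colocalized, 1L)
  expect_equal(r_ab$fraction_pct, 100 / 3)
  expect_equal(r_ba$fraction_pct, 50)
  # mismatched geometry is a contract error
  bad <- mk(10, 10); attr(bad, "image_dim") <- c(32L, 32L)
  expect_error(colocalize(a, bad, p), class = "synq_contract_error")
})

test_that("planted colocalization fraction is recovered end to end", {
  # small-scale version of the recovery criterion (full scale in acceptance)
  spec <- puncta_field_spec(image_size = c(512, 512), n_puncta_a = 40,
                            n_puncta_b = 40, coloc_fraction = 0.3)
  fr <- vapply(1:3, function(seed) {
    res <- gen_puncta_image_pair(spec, seed)
    pa <- detect_puncta(normalize_to_255(res$image_a))
    pb <- detect_puncta(normalize_to_255(res$image_b))
    colocalize(pa, pb)$fraction_pct
  }, 0)
  expect_lt(abs(mean(fr) - 30), 10)
})
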