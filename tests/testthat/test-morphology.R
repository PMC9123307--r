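# Sholl analysis, spine classification, density, vesicle binning, SWC I/O.

test_that("sholl matches the straight-dendrite closed form", {
  prof <- sholl(straight_dendrite(100), 6, 720)
  expect_identical(nrow(prof), 120L)
  expect_identical(prof$radius_um, seq(6, 720, by = 6))
  expect_identical(prof$crossings, as.integer(prof$radius_um < 100))
  expect_error(sholl(straight_dendrite()[0, ]), class = "synq_contract_error")
})

test_that("sholl equals the dense-sampling oracle on seeded trees", {
  for (seed in 1:6) {
    tr <- gen_tree(tree_spec(n_branches = 6, total_length_um = 250,
                             segment_length_um = 8), seed)
    got <- sholl(tr, 6, 120)
    ora <- oracle_sholl_dense(tr, 6, 120)
    expect_identical(got$crossings, as.integer(ora$crossings))
  }
})

test_that("sholl is exactly rotation-invariant about the soma", {
  tr <- gen_tree(tree_spec(n_branches = 5, total_length_um = 200), 9)
  base <- sholl(tr, 6, 240)
  th <- 0.7; ph <- 1.1
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3)
  xyz <- as.matrix(tr[, c("x", "y", "z")]) %*% (rz %*% rx)
  tr2 <- tr; tr2$x <- xyz[, 1]; tr2$y <- xyz[, 2]; tr2$z <- xyz[, 3]
  expect_identical(sholl(tr2, 6, 240)$crossings, base$crossings)
})

test_that("spine classification follows the documented rule set", {
  rec <- data.frame(
    length_um = c(5, 0.8, 1.5, 3.0, 1.5, 0.5, 2.0),
    head_diameter_um = c(0.5, 0.4, 1.0, 0.3, 0.5, 0.1, 0.6),
    neck_diameter_um = c(0.3, NA, 0.4, 0.3, 0.45, NA, 0.4))
  cls <- classify_spines(rec)
  expect_identical(as.character(cls),
                   c("rejected",   # > 4 um length gate
                     "stubby",     # short, no distinguishable neck
                     "mushroom",   # head/neck = 2.5
                     "filopodia",  # long, head equals neck
                     "long_thin",  # remainder
                     "rejected",   # head below 0.2 um minimum
                     "long_thin"))
  # partition: one label each, counts sum to n
  expect_identical(sum(table(cls)), nrow(rec))
  expect_error(classify_spines(data.frame(length_um = -1,
                                          head_diameter_um = 0.5)),
               class = "synq_contract_error")
})

test_that("spine density is spines per micrometre", {
  expect_equal(spine_density(1000, 1000), 1)
  expect_equal(spine_density(0, 50), 0)
  expect_error(spine_density(10, 0), class = "synq_contract_error")
})

test_that("vesicle distances are binned in half-open 50 nm bins", {
  counts <- bin_vesicle_distances(c(10, 60, 120))
  expect_identical(unname(counts[1:3]), c(1L, 1L, 1L))
  expect_identical(sum(counts), 3L)
  expect_identical(names(counts)[1:2], c("0-50", "50-100"))
  expect_identical(sum(bin_vesicle_distances(numeric())), 0L)
  expect_identical(length(bin_vesicle_distances(numeric())), 10L)
  # boundary goes to the upper bin; permutation-invariant and sum-preserving
  expect_identical(unname(bin_vesicle_distances(c(50, 49.999))[1:2]),
                   c(1L, 1L))
  d <- withr::with_seed(4, runif(200, 0, 600))
  expect_identical(bin_vesicle_distances(d), bin_vesicle_distances(rev(d)))
  expect_identical(sum(bin_vesicle_distances(d)), sum(d < 500))
  expect_identical(formals(bin_vesicle_distances)$bin_width_nm, 50)
  expect_error(bin_vesicle_distances(-5), class = "synq_parameter_error")
})

test_that("SWC files round-trip and are validated", {
  tr <- gen_tree(tree_spec(n_branches = 4, total_length_um = 150), 2)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(tr, path)
  back <- read_swc(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
  bad <- tr; bad$parent[5] <- 99
  expect_error(write_swc(bad, path), class = "synq_contract_error")
  expect_error(read_swc("no/such/file.swc"), class = "synq_io_error")
})
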