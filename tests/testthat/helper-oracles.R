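# Independent oracles: deliberately naive reimplementations used to verify
# the package's optimized paths. They share no code with the implementation.

# Literal per-pulse recursion of the depletion model.
oracle_train_recursion <- function(n0, p, r, q, n_pulses, rate_hz) {
  dt <- 1 / rate_hz
  amps <- numeric(n_pulses)
  pool <- n0
  for (k in seq_len(n_pulses)) {
    released <- p * pool
    amps[k] <- q * released
    pool <- pool - released + r * dt
  }
  amps
}

# Naive iterative-threshold detection with stack-based flood fill.
# Scan order, acceptance rule, exclusion check and deferred masking follow
# the documented algorithm but are re-derived from scratch in plain R.
oracle_detect_puncta <- function(img, max_cutoff = 255, min_cutoff = 95,
                                 min_region = 25, margin = 5) {
  h <- nrow(img); w <- ncol(img)
  masked <- matrix(FALSE, h, w)
  acc <- list()
  nbr_dr <- c(-1, 1, 0, 0, -1, -1, 1, 1)
  nbr_dc <- c(0, 0, -1, 1, -1, 1, -1, 1)
  for (cut in seq(max_cutoff, min_cutoff, by = -1)) {
    bin <- img >= cut & !masked
    lab <- matrix(FALSE, h, w)          # visited
    new_centers <- list()
    cand <- which(t(bin))               # row-major candidate order
    for (p0 in cand) {
      r0 <- (p0 - 1) %/% w + 1; c0 <- (p0 - 1) %% w + 1
      if (lab[r0, c0]) next
      # flood fill
      stack <- list(c(r0, c0)); comp_r <- integer(); comp_c <- integer()
      lab[r0, c0] <- TRUE
      while (length(stack)) {
        pt <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        comp_r <- c(comp_r, pt[1]); comp_c <- c(comp_c, pt[2])
        for (k in 1:8) {
          nr <- pt[1] + nbr_dr[k]; nc <- pt[2] + nbr_dc[k]
          if (nr >= 1 && nr <= h && nc >= 1 && nc <= w &&
              bin[nr, nc] && !lab[nr, nc]) {
            lab[nr, nc] <- TRUE
            stack[[length(stack) + 1]] <- c(nr, nc)
          }
        }
      }
      if (length(comp_r) <= min_region) next
      wgt <- img[cbind(comp_r, comp_c)]
      ctr <- c(sum(wgt * (comp_r - 1)), sum(wgt * (comp_c - 1))) / sum(wgt)
      ok <- TRUE
      for (a in acc)
        if (sum((a$center - ctr)^2) <= margin^2) { ok <- FALSE; break }
      if (!ok) next
      acc[[length(acc) + 1]] <- list(center = ctr, cutoff = cut,
                                     area = length(comp_r))
      new_centers[[length(new_centers) + 1]] <- ctr
    }
    for (ctr in new_centers) {
      rs <- max(1, floor(ctr[1] + 1 - margin)):min(h, ceiling(ctr[1] + 1 + margin))
      cs <- max(1, floor(ctr[2] + 1 - margin)):min(w, ceiling(ctr[2] + 1 + margin))
      for (rr in rs) for (cc in cs)
        if ((rr - 1 - ctr[1])^2 + (cc - 1 - ctr[2])^2 <= margin^2)
          masked[rr, cc] <- TRUE
    }
  }
  if (!length(acc))
    return(data.frame(row = numeric(), col = numeric(),
                      detection_cutoff = integer(), area_px = integer()))
  out <- data.frame(row = vapply(acc, function(a) a$center[1], 0),
                    col = vapply(acc, function(a) a$center[2], 0),
                    detection_cutoff = vapply(acc, function(a) a$cutoff, 0),
                    area_px = vapply(acc, function(a) a$area, 0))
  out[order(-out$detection_cutoff, out$row, out$col), , drop = FALSE]
}

# Dense-sampling Sholl oracle: walk each edge in ~0.01 um steps and count
# sign changes of (distance - r).
oracle_sholl_dense <- function(tree, step_um = 6, max_radius_um = 720,
                               ds = 0.01) {
  soma_rows <- tree$type == 1
  if (!any(soma_rows)) soma_rows <- tree$parent == -1
  soma <- c(mean(tree$x[soma_rows]), mean(tree$y[soma_rows]),
            mean(tree$z[soma_rows]))
  radii <- seq_len(floor(max_radius_um / step_um)) * step_um
  counts <- integer(length(radii))
  pidx <- match(tree$parent, tree$id)
  for (i in seq_len(nrow(tree))) {
    if (tree$parent[i] == -1) next
    j <- pidx[i]
    if (tree$type[i] == 1 && tree$type[j] == 1) next
    a <- c(tree$x[j], tree$y[j], tree$z[j]) - soma
    b <- c(tree$x[i], tree$y[i], tree$z[i]) - soma
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / ds) + 1L))
    pts <- outer(ts, b - a) + matrix(a, length(ts), 3, byrow = TRUE)
    d <- sqrt(rowSums(pts^2))
    for (k in seq_along(radii)) {
      s <- d > radii[k]
      counts[k] <- counts[k] + sum(s[-1] != s[-length(s)])
    }
  }
  data.frame(radius_um = radii, crossings = counts)
}

# A soma plus one straight dendrite along x, for closed-form Sholl checks.
straight_dendrite <- function(length_um = 100, n_nodes = 11) {
  xs <- seq(0, length_um, length.out = n_nodes)
  structure(data.frame(id = seq_len(n_nodes),
                       type = c(1L, rep(3L, n_nodes - 1L)),
                       x = xs, y = 0, z = 0, radius = 0.5,
                       parent = c(-1L, seq_len(n_nodes - 1L))),
            class = c("neuron_swc", "data.frame"))
}

# Random 64x64 test image for detector/oracle comparison: unconstrained
# random Gaussian blobs plus noise, min-max normalized to 0-255.
make_oracle_image <- function(seed) {
  withr::with_seed(seed, {
    img <- matrix(rnorm(64 * 64, 0, 15), 64, 64)
    n_blob <- sample(3:6, 1)
    for (i in seq_len(n_blob)) {
      ctr <- runif(2, 8, 55)
      sig <- runif(1, 2, 3.5)
      peak <- runif(1, 400, 1000)
      for (r in 1:64) for (c in 1:64) {
        d2 <- (r - 1 - ctr[1])^2 + (c - 1 - ctr[2])^2
        if (d2 <= (3 * sig)^2) img[r, c] <- img[r, c] + peak * exp(-d2 / (2 * sig^2))
      }
    }
    img
  })
}
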