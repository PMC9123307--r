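# Synthetic two-group samples and random dendritic trees.

#' Generate two-group samples with heavy tails and injectable outliers
#'
#' Draws each group from a shifted/scaled Student-t with `nu` degrees of
#' freedom. For `nu > 2` the scale is SD-matched (the generated variable has
#' standard deviation `sd1`/`sd2`); for `nu <= 2` the stated SD is used as the
#' raw scale parameter. `n_outliers` points of group 1 are overwritten with
#' `mu1 + outlier_sd_offset * sd1`; the truth records which.
#'
#' @param spec a [group_sample_spec()].
#' @param seed integer seed.
#' @return list with `group1`, `group2` numeric vectors and `truth` — a list
#'   with `outlier_idx` (indices into `group1`).
#' @export
gen_group_samples <- function(spec, seed) {
  stopifnot(inherits(spec, "group_sample_spec"))
  with_seed(seed, {
    scale_fac <- if (spec$nu > 2) sqrt((spec$nu - 2) / spec$nu) else 1
    g1 <- spec$mu1 + spec$sd1 * scale_fac * rt(spec$n1, spec$nu)
    g2 <- spec$mu2 + spec$sd2 * scale_fac * rt(spec$n2, spec$nu)
    out_idx <- integer()
    if (spec$n_outliers > 0) {
      out_idx <- sort(sample.int(spec$n1, spec$n_outliers))
      g1[out_idx] <- spec$mu1 + spec$outlier_sd_offset * spec$sd1
    }
    list(group1 = g1, group2 = g2, truth = list(outlier_idx = out_idx))
  })
}

# Rodrigues rotation of unit vector v about unit axis by angle (radians).
rotate3 <- function(v, axis, angle) {
  v * cos(angle) + crossprod3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Rotate `dir` by `angle` radians about a random axis perpendicular to it.
perturb_direction <- function(dir, angle) {
  perp <- crossprod3(dir, random_unit_vector())
  nrm <- sqrt(sum(perp^2))
  if (nrm < 1e-12) return(dir)
  rotate3(dir, perp / nrm, angle)
}

#' Generate a random dendritic tree in SWC form
#'
#' Grows a connected rooted tree of equal-length straight segments from a
#' soma at the origin. Exactly `n_branches` nodes receive a second child;
#' daughter branches leave at `branch_angle_deg` from the local direction,
#' continuations wobble by a small random angle. Segment lengths sum exactly
#' to `total_length_um`.
#'
#' @param spec a [tree_spec()].
#' @param seed integer seed.
#' @return a `neuron_swc` data frame (columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`; soma is node 1 with parent -1).
#' @export
gen_tree <- function(spec, seed) {
  stopifnot(inherits(spec, "tree_spec"))
  with_seed(seed, {
    n_seg <- spec$n_segments
    seg_len <- spec$total_length_um / n_seg
    jitter_sd <- 8 * pi / 180
    branch_angle <- spec$branch_angle_deg * pi / 180

    xyz <- matrix(0, n_seg + 1L, 3)
    parent <- c(-1L, integer(n_seg))
    n_children <- integer(n_seg + 1L)
    dir_in <- vector("list", n_seg + 1L)  # direction of incoming edge
    dir_in[[1]] <- random_unit_vector()

    remaining <- spec$n_branches
    n_nodes <- 1L
    for (step in seq_len(n_seg)) {
      steps_left <- n_seg - step + 1L
      # nodes (excluding soma) with exactly one child can host a bifurcation
      cand <- if (n_nodes >= 2L) which(n_children[2:n_nodes] == 1L) + 1L
              else integer()
      do_branch <- remaining > 0L && length(cand) > 0L && step > 2L &&
        (remaining >= steps_left || runif(1) < remaining / steps_left)
      if (do_branch) {
        node <- if (length(cand) == 1L) cand else sample(cand, 1L)
        dir_new <- perturb_direction(dir_in[[node]], branch_angle)
        remaining <- remaining - 1L
      } else {
        tips <- which(n_children[seq_len(n_nodes)] == 0L)
        node <- if (length(tips) == 1L) tips else sample(tips, 1L)
        dir_new <- perturb_direction(dir_in[[node]], abs(rnorm(1, 0, jitter_sd)))
      }
      n_nodes <- n_nodes + 1L
      xyz[n_nodes, ] <- xyz[node, ] + seg_len * dir_new
      parent[n_nodes] <- node
      n_children[node] <- n_children[node] + 1L
      dir_in[[n_nodes]] <- dir_new
    }
    if (remaining > 0L)
      abort("impossible geometry: could not place all bifurcations",
            "synq_parameter_error")

    structure(data.frame(
      id = seq_len(n_nodes),
      type = c(1L, rep(3L, n_nodes - 1L)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      radius = c(1, rep(0.5, n_nodes - 1L)),
      parent = parent), class = c("neuron_swc", "data.frame"))
  })
}
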