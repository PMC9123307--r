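# Neuronal morphology: SWC I/O, Sholl analysis, spine classification and
# density, presynaptic vesicle distance binning.

validate_swc <- function(tree) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(tree)))
    abort("SWC table must have columns id, type, x, y, z, radius, parent",
          "synq_contract_error")
  if (!nrow(tree)) abort("empty tree", "synq_contract_error")
  roots <- which(tree$parent == -1)
  if (length(roots) != 1L)
    abort("tree must have exactly one root (parent -1)", "synq_contract_error")
  idx <- match(tree$parent, tree$id)
  nonroot <- tree$parent != -1
  if (any(is.na(idx[nonroot])))
    abort("SWC parent ids must refer to existing nodes", "synq_contract_error")
  if (any(idx[nonroot] >= seq_len(nrow(tree))[nonroot]))
    abort("SWC parents must precede their children", "synq_contract_error")
  invisible(tree)
}

#' Read a neuron morphology from an SWC file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; 1-based ids,
#' micrometre units, `#` comments).
#'
#' @param path file path.
#' @return a `neuron_swc` data frame.
#' @export
read_swc <- function(path) {
  if (!file.exists(path))
    abort(sprintf("SWC file not found: %s", path), "synq_io_error")
  tree <- utils::read.table(path, comment.char = "#",
                            col.names = c("id", "type", "x", "y", "z",
                                          "radius", "parent"))
  validate_swc(tree)
  structure(tree, class = c("neuron_swc", "data.frame"))
}

#' Write a neuron morphology to an SWC file
#'
#' @param tree a `neuron_swc` data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_swc <- function(tree, path) {
  validate_swc(tree)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC: id type x y z radius parent", con)
  utils::write.table(tree, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

soma_center <- function(tree) {
  soma_rows <- tree$type == 1
  if (!any(soma_rows)) soma_rows <- tree$parent == -1
  # multi-point somata are collapsed to their centroid
  c(mean(tree$x[soma_rows]), mean(tree$y[soma_rows]), mean(tree$z[soma_rows]))
}

#' Sholl analysis of a neuron tree
#'
#' Counts, for each concentric radius (6, 12, ... by default, out to
#' 720 um), how many times the dendritic tree crosses the sphere of that
#' radius around the soma. Crossings are counted exactly per straight
#' segment from the quadratic `|P(t)|^2 = r^2`: one crossing when the
#' endpoint distances straddle `r`, two when both endpoints lie outside but
#' the segment dips inside in between; an endpoint exactly at `r` counts
#' once (tangential grazing). Distances are 3D Euclidean from the soma
#' centroid.
#'
#' @param tree a `neuron_swc` data frame.
#' @param step_um radius increment, um (default 6).
#' @param max_radius_um largest analysis radius, um (default 720).
#' @return a `sholl_profile` data frame: `radius_um`, `crossings`
#'   (`floor(max/step)` rows).
#' @export
sholl <- function(tree, step_um = 6, max_radius_um = 720) {
  validate_swc(tree)
  check_number(step_um, "step_um", lower = 0, strict_lower = TRUE)
  check_number(max_radius_um, "max_radius_um", lower = step_um)
  soma <- soma_center(tree)
  radii <- seq_len(floor(max_radius_um / step_um)) * step_um

  pidx <- match(tree$parent, tree$id)
  ptype <- tree$type[ifelse(is.na(pidx), 1L, pidx)]
  is_edge <- tree$parent != -1 &
    !(tree$type == 1 & ptype == 1)      # skip intra-soma edges
  if (!any(is_edge))
    return(structure(data.frame(radius_um = radii,
                                crossings = rep(0L, length(radii))),
                     class = c("sholl_profile", "data.frame")))
  a_xyz <- cbind(tree$x[pidx[is_edge]], tree$y[pidx[is_edge]],
                 tree$z[pidx[is_edge]])
  b_xyz <- cbind(tree$x[is_edge], tree$y[is_edge], tree$z[is_edge])
  a_xyz <- sweep(a_xyz, 2, soma); b_xyz <- sweep(b_xyz, 2, soma)

  d <- b_xyz - a_xyz
  aa <- rowSums(d^2)                    # |B-A|^2
  q0 <- rowSums(a_xyz^2)                # squared distance at t = 0
  q1 <- rowSums(b_xyz^2)                # at t = 1
  bb <- 2 * rowSums(a_xyz * d)
  tv <- ifelse(aa > 0, -bb / (2 * aa), NA_real_)
  qmin <- ifelse(aa > 0, q0 - bb^2 / (4 * aa), pmin(q0, q1))

  crossings <- vapply(radii, function(r) {
    r2 <- r^2
    out0 <- q0 > r2; out1 <- q1 > r2
    n1 <- out0 != out1
    n2 <- out0 & out1 & !is.na(tv) & tv > 0 & tv < 1 & qmin < r2
    sum(n1) + 2L * sum(n2)
  }, numeric(1))
  structure(data.frame(radius_um = radii, crossings = as.integer(crossings)),
            class = c("sholl_profile", "data.frame"))
}

#' Classify dendritic spine records
#'
#' Applies the published size gates (maximum spine length 4 um, minimum end
#' diameter 0.2 um) and then a documented surrogate for the commercial
#' classifier's rules, which are not public: stubby = short (< 1 um) with no
#' neck constriction; mushroom = head wider than `head_neck_ratio` times the
#' neck; filopodia = long (> 2 um) without head enlargement; long/thin =
#' remainder. Thresholds are configurable; the rule set is a stand-in
#' validated for internal consistency only.
#'
#' @param records data frame with `length_um`, `head_diameter_um`,
#'   `neck_diameter_um` (the last may be `NA` when no neck is
#'   distinguishable).
#' @param max_length_um rejection gate (default 4).
#' @param min_diameter_um minimum credible end diameter (default 0.2);
#'   smaller measured diameters mark the record `rejected`.
#' @param stubby_max_length_um,head_neck_ratio,filopodia_min_length_um
#'   class thresholds.
#' @return factor with levels `stubby`, `mushroom`, `long_thin`,
#'   `filopodia`, `rejected`; exactly one label per record.
#' @export
classify_spines <- function(records, max_length_um = 4,
                            min_diameter_um = 0.2,
                            stubby_max_length_um = 1,
                            head_neck_ratio = 2,
                            filopodia_min_length_um = 2) {
  if (!all(c("length_um", "head_diameter_um") %in% names(records)))
    abort("records need columns length_um and head_diameter_um",
          "synq_contract_error")
  if (is.null(records$neck_diameter_um))
    records$neck_diameter_um <- NA_real_
  len <- records$length_um
  head_d <- records$head_diameter_um
  neck_d <- records$neck_diameter_um
  if (any(len <= 0) || any(head_d < 0, na.rm = TRUE) ||
      any(neck_d < 0, na.rm = TRUE))
    abort("negative or zero spine geometry", "synq_contract_error")

  n <- nrow(records)
  cls <- character(n)
  no_neck <- is.na(neck_d) | neck_d >= head_d
  for (i in seq_len(n)) {
    cls[i] <- if (len[i] > max_length_um ||
                  (!is.na(head_d[i]) && head_d[i] < min_diameter_um) ||
                  (!is.na(neck_d[i]) && neck_d[i] < min_diameter_um)) {
      "rejected"
    } else if (len[i] < stubby_max_length_um && no_neck[i]) {
      "stubby"
    } else if (!is.na(head_d[i]) && !is.na(neck_d[i]) &&
               head_d[i] > head_neck_ratio * neck_d[i]) {
      "mushroom"
    } else if (len[i] > filopodia_min_length_um &&
               (is.na(head_d[i]) || no_neck[i])) {
      "filopodia"
    } else {
      "long_thin"
    }
  }
  factor(cls, levels = c("stubby", "mushroom", "long_thin", "filopodia",
                         "rejected"))
}

#' Spine density
#'
#' Number of spines per micrometre of dendrite.
#'
#' @param n_spines spine count.
#' @param dendrite_length_um measured dendritic length, um (> 0).
#' @return density in spines per um.
#' @export
spine_density <- function(n_spines, dendrite_length_um) {
  check_number(n_spines, "n_spines", lower = 0)
  if (!is.numeric(dendrite_length_um) || length(dendrite_length_um) != 1L ||
      dendrite_length_um <= 0)
    abort("dendrite length must be positive", "synq_contract_error")
  n_spines / dendrite_length_um
}

#' Bin presynaptic vesicle distances from the synaptic cleft
#'
#' Half-open 50 nm bins `[0, 50), [50, 100), ...` out to `max_nm`.
#'
#' @param distances_nm per-vesicle distances from the cleft, nm
#'   (non-negative).
#' @param bin_width_nm bin width (default 50 nm).
#' @param max_nm largest binned distance (default 500 nm).
#' @return named integer vector of counts per bin.
#' @export
bin_vesicle_distances <- function(distances_nm, bin_width_nm = 50,
                                  max_nm = 500) {
  check_number(bin_width_nm, "bin_width_nm", lower = 0, strict_lower = TRUE)
  check_number(max_nm, "max_nm", lower = bin_width_nm)
  if (any(distances_nm < 0))
    abort("vesicle distances must be non-negative", "synq_parameter_error")
  edges <- seq(0, max_nm, by = bin_width_nm)
  n_bins <- length(edges) - 1L
  idx <- findInterval(distances_nm, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx[idx >= 1L & idx <= n_bins], nbins = n_bins)
  names(counts) <- sprintf("%g-%g", edges[-length(edges)], edges[-1])
  counts
}
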