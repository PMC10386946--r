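# Multi-tube phantom QA: automated tube detection, half-radius central ROIs,
# per-slice joint fitting, and central-slice summaries.

#' Circular tube region of interest
#'
#' @param slice_index axial slice, 1-based.
#' @param center `(x, y)` voxel coordinates (may be half-integer).
#' @param radius voxels, > 0.
#' @param dim image in-plane dimensions `(nx, ny)`.
#' @return List of class `tube_roi` with `member_voxels`, an integer matrix
#'   of `(x, y)` voxel coordinates inside the circle.
#' @export
tube_roi <- function(slice_index, center, radius, dim) {
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  xs <- max(1L, floor(center[1] - radius)):min(dim[1], ceiling(center[1] + radius))
  ys <- max(1L, floor(center[2] - radius)):min(dim[2], ceiling(center[2] + radius))
  g <- expand.grid(x = xs, y = ys)
  g <- g[(g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2, , drop = FALSE]
  structure(list(slice_index = as.integer(slice_index),
                 center = as.numeric(center), radius = radius,
                 member_voxels = as.matrix(g), dim = as.integer(dim[1:2])),
            class = "tube_roi")
}

#' Detect cylindrical tubes in a phantom slice
#'
#' Hough circle search restricted to radii within +/-25% of the expected
#' tube radius; detections are ranked by accumulator strength, truncated to
#' `n_expected`, and finally sorted by `(y, x)` center for stable tube IDs.
#' A warning reports how many expected tubes were not found.
#'
#' @param slice_image 2-D magnitude image.
#' @param expected_radius expected tube radius, voxels (>= 2).
#' @param n_expected number of tubes to look for.
#' @param slice_index recorded in each returned ROI.
#' @return List of `tube_roi`.
#' @export
detect_tubes <- function(slice_image, expected_radius, n_expected,
                         slice_index = 1L) {
  if (expected_radius < 2) stop("`expected_radius` must be >= 2 voxels", call. = FALSE)
  radii <- unique(round(seq(0.75 * expected_radius, 1.25 * expected_radius,
                            length.out = 5)))
  found <- hough_circles(slice_image, radii, n_peaks = n_expected,
                         min_sep = 1.5 * expected_radius)
  if (nrow(found) < n_expected)
    warning(sprintf("found %d of %d expected tubes", nrow(found), n_expected),
            call. = FALSE)
  if (nrow(found) == 0L) return(list())
  # refine each detection on the image itself: within a local window, take
  # the centroid and equivalent-disc radius of the above-threshold pixels
  # (tubes are uniform discs, so this is sub-voxel accurate and rescues
  # accumulator peaks that landed a couple of voxels off-center)
  for (i in seq_len(nrow(found))) {
    ref <- .refine_disc(slice_image, found$cx[i], found$cy[i],
                        expected_radius)
    if (!is.null(ref)) {
      found$cx[i] <- ref$cx; found$cy[i] <- ref$cy
      found$radius[i] <- min(max(ref$radius, 0.75 * expected_radius),
                             1.25 * expected_radius)
    }
  }
  # (y, x) ordering robust to sub-voxel center noise: group detections into
  # rows (gaps in y larger than the expected radius start a new row), then
  # sort by x within each row
  found <- found[order(found$cy), , drop = FALSE]
  row_id <- cumsum(c(1, diff(found$cy) > expected_radius))
  found <- found[order(row_id, found$cx), , drop = FALSE]
  lapply(seq_len(nrow(found)), function(i)
    tube_roi(slice_index, c(found$cx[i], found$cy[i]), found$radius[i],
             dim(slice_image)))
}

#' Shrink a tube ROI to its central region
#'
#' Same center, radius scaled by `fraction` (default one half, the analysis
#' choice that avoids tube-wall partial volume), member voxels recomputed.
#'
#' @param tube a `tube_roi`.
#' @param fraction scale in (0, 1].
#' @export
central_roi <- function(tube, fraction = 0.5) {
  stopifnot(inherits(tube, "tube_roi"))
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]", call. = FALSE)
  r <- tube$radius * fraction
  if (r < 1) stop("shrunken radius is below 1 voxel", call. = FALSE)
  tube_roi(tube$slice_index, tube$center, r, tube$dim)
}

#' Detect tubes on every slice and match IDs across slices
#'
#' Detection runs on the contrast-averaged image of each axial slice.
#' Tube identities are propagated between adjacent slices by nearest-center
#' matching with a maximum displacement of `max_shift` voxels; unmatched
#' detections get fresh IDs.
#'
#' @param series an `image_series`.
#' @param expected_radius,n_expected as in [detect_tubes()].
#' @param max_shift maximum center displacement between adjacent slices.
#' @return List over slices; each element a named list of `tube_roi`
#'   keyed by tube ID (`"1"`, `"2"`, ...).
#' @export
detect_tubes_series <- function(series, expected_radius, n_expected,
                                max_shift = 2) {
  stopifnot(inherits(series, "image_series"))
  nz <- dim(series$data)[3L]
  out <- vector("list", nz)
  prev <- NULL
  next_id <- 1L
  for (z in seq_len(nz)) {
    img <- apply(series$data[, , z, , drop = FALSE], c(1, 2), mean)
    tubes <- detect_tubes(img, expected_radius, n_expected, slice_index = z)
    ids <- character(length(tubes))
    used <- character(0)
    for (i in seq_along(tubes)) {
      id <- NA_character_
      if (!is.null(prev)) {
        ctr <- tubes[[i]]$center
        dists <- vapply(prev, function(p) sqrt(sum((p$center - ctr)^2)), 0)
        dists[names(prev) %in% used] <- Inf
        if (length(dists) && min(dists) <= max_shift)
          id <- names(prev)[which.min(dists)]
      }
      if (is.na(id)) { id <- as.character(next_id); next_id <- next_id + 1L }
      ids[i] <- id
      used <- c(used, id)
    }
    names(tubes) <- ids
    out[[z]] <- tubes
    if (length(tubes)) prev <- tubes
  }
  out
}

# centroid + equivalent-disc radius of thresholded pixels near a candidate
# circle center; NULL when the local patch has no contrast
.refine_disc <- function(img, cx, cy, expected_radius) {
  w <- ceiling(expected_radius * 1.5)
  xs <- max(1, round(cx) - w):min(nrow(img), round(cx) + w)
  ys <- max(1, round(cy) - w):min(ncol(img), round(cy) + w)
  patch <- img[xs, ys, drop = FALSE]
  if (diff(range(patch)) <= 0) return(NULL)
  thr <- otsu_threshold(patch)
  fg <- patch > thr
  if (sum(fg) < 4) return(NULL)
  px <- outer(xs, rep(1, length(ys)))[fg]
  py <- outer(rep(1, length(xs)), ys)[fg]
  keep <- (px - cx)^2 + (py - cy)^2 <= (expected_radius * 1.5)^2
  if (sum(keep) < 4) return(NULL)
  list(cx = mean(px[keep]), cy = mean(py[keep]),
       radius = sqrt(sum(keep) / pi))
}

# linear voxel indices of an ROI in a 3-D volume
.roi_indices <- function(tube, dims3) {
  mv <- tube$member_voxels
  cbind(mv[, 1L], mv[, 2L], tube$slice_index)
}

#' Per-slice tube T1 from joint ROI fits
#'
#' One T1 per tube and slice, fit jointly from all voxels in each tube's
#' (shrunken) ROI.
#'
#' @param series an `image_series` (inversion-recovery data).
#' @param tubes output of [detect_tubes_series()], already shrunk if desired.
#' @param protocol the matching `relax_protocol`.
#' @return data.frame `tube_id`, `slice`, `value_s`, `se_s`, `excluded`.
#' @export
tube_t1_per_slice <- function(series, tubes, protocol) {
  out <- NULL
  for (z in seq_along(tubes)) {
    for (id in names(tubes[[z]])) {
      fr <- fit_roi_joint(series, .roi_indices(tubes[[z]][[id]],
                                               dim(series$data)[1:3]), protocol)
      out <- rbind(out, data.frame(tube_id = id, slice = z,
                                   value_s = fr$estimate, se_s = fr$standard_error,
                                   excluded = fr$excluded))
    }
  }
  out
}

#' Per-slice tube T2 as ROI means of a fitted map
#'
#' The mean of the per-voxel T2 values inside each ROI, one value per tube
#' per slice; excluded voxels are dropped.
#'
#' @param t2_map a `quant_map`.
#' @param tubes output of [detect_tubes_series()].
#' @return data.frame `tube_id`, `slice`, `value_s`.
#' @export
tube_t2_per_slice <- function(t2_map, tubes) {
  stopifnot(inherits(t2_map, "quant_map"))
  out <- NULL
  for (z in seq_along(tubes)) {
    for (id in names(tubes[[z]])) {
      mv <- tubes[[z]][[id]]$member_voxels
      vals <- t2_map$values[cbind(mv[, 1L], mv[, 2L], z)]
      excl <- t2_map$exclusion[cbind(mv[, 1L], mv[, 2L], z)]
      out <- rbind(out, data.frame(tube_id = id, slice = z,
                                   value_s = mean(vals[!excl])))
    }
  }
  out
}

#' Summarize tubes over the central slices
#'
#' Selects the `central_slices` slices nearest the axial midpoint of the
#' slices present (for `n` slices and `c` central ones, slices
#' `floor((n - c)/2) + 1` through `floor((n - c)/2) + c`, matching the
#' "central six slices" convention) and reports each tube's mean and SD of
#' the per-slice values over them.
#'
#' @param per_slice data.frame with `tube_id`, `slice`, `value_s`.
#' @param central_slices number of central slices, default 6.
#' @return data.frame `tube_id`, `mean_s`, `sd_s`, `n_slices`.
#' @export
summarize_tubes <- function(per_slice, central_slices = 6L) {
  slices <- sort(unique(per_slice$slice))
  n <- length(slices)
  if (n < central_slices)
    stop(sprintf("need at least %d slices, have %d", central_slices, n),
         call. = FALSE)
  start <- floor((n - central_slices) / 2) + 1L
  keep <- slices[start:(start + central_slices - 1L)]
  sel <- per_slice[per_slice$slice %in% keep & is.finite(per_slice$value_s), ]
  agg <- stats::aggregate(value_s ~ tube_id, data = sel,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  data.frame(tube_id = agg$tube_id,
             mean_s = agg$value_s[, "mean"],
             sd_s = agg$value_s[, "sd"],
             n_slices = as.integer(agg$value_s[, "n"]))
}

#' End-to-end phantom QA pipeline
#'
#' Detect tubes on every slice, shrink each ROI to half radius, fit one
#' value per tube and slice (joint T1 fit for inversion recovery; ROI mean
#' of the voxel-wise map for spin echo), and summarize over the central six
#' slices.
#'
#' @param series an `image_series`.
#' @param protocol the matching `relax_protocol`.
#' @param expected_radius,n_tubes tube geometry.
#' @param fraction central-ROI shrink factor.
#' @param central_slices slices entering the summary.
#' @return List with `per_slice` and `summary` data.frames and the detected
#'   `tubes`.
#' @export
phantom_qa <- function(series, protocol, expected_radius, n_tubes,
                       fraction = 0.5, central_slices = 6L) {
  tubes <- detect_tubes_series(series, expected_radius, n_tubes)
  shrunk <- lapply(tubes, function(sl) lapply(sl, central_roi, fraction = fraction))
  if (protocol$kind == "inversion_recovery") {
    per_slice <- tube_t1_per_slice(series, shrunk, protocol)
  } else {
    map <- reconstruct_map(series, protocol, mask = .tubes_mask(shrunk, dim(series$data)[1:3]))
    per_slice <- tube_t2_per_slice(map, shrunk)
  }
  list(per_slice = per_slice,
       summary = summarize_tubes(per_slice, central_slices),
       tubes = shrunk)
}

# logical mask covering all tube ROIs (so T2 maps are only fit where needed)
.tubes_mask <- function(tubes, dims3) {
  m <- array(FALSE, dims3)
  for (z in seq_along(tubes))
    for (tb in tubes[[z]])
      m[cbind(tb$member_voxels[, 1L], tb$member_voxels[, 2L], z)] <- TRUE
  m
}
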