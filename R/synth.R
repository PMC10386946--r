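# Digital phantoms and bench-style decay series with known ground truth.

#' Specification of a digital brain phantom
#'
#' Concentric-ellipse head: background, a thin bright skull ring, a dark
#' gap, a GM band, WM interior, two CSF ventricle lobes, and a one-voxel
#' partial-volume band of mixed GM/CSF at the ventricle border. Default
#' tissue values are low-field brain values: T1 0.254/0.377/2.073 s and
#' T2 0.081/0.105/1.172 s for WM/GM/CSF.
#'
#' @param shape `(nx, ny, nz)` voxels.
#' @param t1,t2 named vectors with entries `WM`, `GM`, `CSF`, seconds.
#' @param s0 nominal brain amplitude (all brain tissues share it).
#' @param skull list with `t1`, `t2`, `s0` of the skull ring.
#' @param partial_width width of the mixed band, voxels.
#' @param snr nominal amplitude over per-channel noise SD; `Inf` = noiseless.
#' @param seed integer.
#' @export
brain_phantom_spec <- function(shape = c(96, 96, 1),
                               t1 = c(WM = 0.254, GM = 0.377, CSF = 2.073),
                               t2 = c(WM = 0.081, GM = 0.105, CSF = 1.172),
                               s0 = 1,
                               skull = list(t1 = 0.15, t2 = 0.02, s0 = 0.6),
                               partial_width = 1, snr = 95, seed = 1) {
  stopifnot(all(c("WM", "GM", "CSF") %in% names(t1)),
            all(c("WM", "GM", "CSF") %in% names(t2)),
            all(t1 > 0), all(t2 > 0), s0 > 0, snr > 0)
  structure(list(shape = as.integer(shape), t1 = t1, t2 = t2, s0 = s0,
                 skull = skull, partial_width = partial_width,
                 snr = snr, seed = as.integer(seed)),
            class = "brain_phantom_spec")
}

# label codes used by the brain phantom
.BRAIN_CODES <- c(background = 0L, skull = 1L, WM = 2L, GM = 3L,
                  partial = 4L, CSF = 5L)

.ellipse_mask <- function(nx, ny, cx, cy, rx, ry) {
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

# deterministic label geometry for one slice
.brain_geometry <- function(nx, ny, partial_width) {
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rx <- 0.42 * nx; ry <- 0.46 * ny
  head <- .ellipse_mask(nx, ny, cx, cy, rx, ry)
  inner1 <- .ellipse_mask(nx, ny, cx, cy, rx - 2, ry - 2)
  inner2 <- .ellipse_mask(nx, ny, cx, cy, rx - 4, ry - 4)
  wm_ell <- .ellipse_mask(nx, ny, cx, cy, rx - 9, ry - 9)
  vent <- .ellipse_mask(nx, ny, cx - 0.10 * nx, cy + 0.02 * ny,
                        0.07 * nx, 0.13 * ny) |
          .ellipse_mask(nx, ny, cx + 0.10 * nx, cy + 0.02 * ny,
                        0.07 * nx, 0.13 * ny)
  vent <- vent & wm_ell
  band <- binary_dilate(vent, partial_width) & !vent & wm_ell
  lab <- matrix(.BRAIN_CODES[["background"]], nx, ny)
  lab[head & !inner1] <- .BRAIN_CODES[["skull"]]
  lab[inner2 & !wm_ell] <- .BRAIN_CODES[["GM"]]
  lab[wm_ell] <- .BRAIN_CODES[["WM"]]
  lab[band] <- .BRAIN_CODES[["partial"]]
  lab[vent] <- .BRAIN_CODES[["CSF"]]
  lab
}

#' Generate a digital brain phantom image series
#'
#' Builds the label geometry, assigns each voxel a single relaxation value
#' (partial-band voxels get `f * CSF + (1 - f) * GM` with `f` drawn
#' uniformly in (0.25, 0.75)), simulates the protocol's magnitude signal at
#' every contrast time, and applies Rician noise at
#' `sigma = s0 / snr`. Bit-reproducible under the spec's seed.
#'
#' @param spec a `brain_phantom_spec`.
#' @param protocol a `relax_protocol`; its kind selects the T1 or T2 maps.
#' @return List: `series` (`image_series`), `truth` (`quant_map` of the
#'   generating values; background voxels are excluded), `labels` (integer
#'   array, codes in `attr(, "codes")`), and `spec`.
#' @export
make_brain_phantom <- function(spec, protocol) {
  stopifnot(inherits(spec, "brain_phantom_spec"),
            inherits(protocol, "relax_protocol"))
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  lab2d <- .brain_geometry(nx, ny, spec$partial_width)
  for (tl in c("skull", "WM", "GM", "partial", "CSF"))
    if (!any(lab2d == .BRAIN_CODES[[tl]]))
      stop(sprintf("geometry leaves tissue '%s' empty", tl), call. = FALSE)
  labels <- array(rep(lab2d, nz), c(nx, ny, nz))
  is_t1 <- protocol$kind == "inversion_recovery"
  tval <- if (is_t1) spec$t1 else spec$t2
  skull_val <- if (is_t1) spec$skull$t1 else spec$skull$t2

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)

  values <- array(NA_real_, dim(labels))
  amp <- array(0, dim(labels))
  values[labels == .BRAIN_CODES[["skull"]]] <- skull_val
  amp[labels == .BRAIN_CODES[["skull"]]] <- spec$skull$s0
  for (tl in c("WM", "GM", "CSF")) {
    sel <- labels == .BRAIN_CODES[[tl]]
    values[sel] <- tval[[tl]]
    amp[sel] <- spec$s0
  }
  part <- which(labels == .BRAIN_CODES[["partial"]])
  f <- stats::runif(length(part), 0.25, 0.75)
  values[part] <- f * tval[["CSF"]] + (1 - f) * tval[["GM"]]
  amp[part] <- spec$s0

  nt <- length(protocol$times)
  data <- array(0, c(nx, ny, nz, nt))
  vox <- which(labels > 0L)
  for (i in seq_len(nt)) {
    ti <- protocol$times[i]
    sl <- array(0, dim(labels))
    sl[vox] <- if (is_t1)
      amp[vox] * abs(1 - (1 + protocol$inversion_scale) *
                       exp(-ti / values[vox]) + exp(-protocol$tr / values[vox]))
    else amp[vox] * exp(-ti / values[vox])
    data[, , , i] <- sl
  }
  sigma <- if (is.finite(spec$snr)) spec$s0 / spec$snr else 0
  if (sigma > 0) data[] <- add_rician_noise(as.vector(data), sigma)

  spacing <- c(1.6, 1.6, 5)
  truth <- quant_map(values, array(0, dim(labels)),
                     array(labels == 0L, dim(labels)),
                     kind = if (is_t1) "t1" else "t2", spacing = spacing)
  attr(labels, "codes") <- .BRAIN_CODES
  list(series = image_series(data, protocol$times, spacing),
       truth = truth, labels = labels, spec = spec)
}

#' Specification of a multi-tube phantom
#'
#' Tubes are laid out on a rectangular grid, all slices identical, values
#' spanning the short-T1 to free-water regime (and, for T2, extending past
#' the ~1.27 s ceiling where the imaging protocol is known to struggle).
#'
#' @param n_tubes number of tubes.
#' @param t1,t2 per-tube values, seconds, length `n_tubes`.
#' @param radius tube radius, voxels.
#' @param n_cols tubes per grid row.
#' @param n_slices axial slices.
#' @param snr,seed noise level and seed.
#' @export
tube_phantom_spec <- function(n_tubes = 10,
                              t1 = c(0.1, 0.25, 0.4, 0.6, 0.8,
                                     1.0, 1.5, 2.0, 3.0, 4.0),
                              t2 = c(0.05, 0.081, 0.105, 0.2, 0.35,
                                     0.5, 0.8, 1.0, 1.3, 1.6),
                              radius = 8, n_cols = 4, n_slices = 8,
                              snr = 95, seed = 1) {
  stopifnot(length(t1) == n_tubes, length(t2) == n_tubes,
            all(t1 > 0), all(t2 > 0), radius >= 2, n_slices >= 1)
  structure(list(n_tubes = as.integer(n_tubes), t1 = t1, t2 = t2,
                 radius = radius, n_cols = as.integer(n_cols),
                 n_slices = as.integer(n_slices), snr = snr,
                 seed = as.integer(seed)),
            class = "tube_phantom_spec")
}

#' Generate a multi-tube phantom image series
#'
#' @param spec a `tube_phantom_spec`.
#' @param protocol a `relax_protocol`.
#' @return List: `series`, `truth` (data.frame `tube_id`, `t1_s`, `t2_s`,
#'   `value_s` for the protocol's parameter, `cx`, `cy`), and `spec`.
#'   Tube IDs are assigned in `(y, x)` center order, matching the stable-ID
#'   ordering of [detect_tubes()].
#' @export
make_tube_phantom <- function(spec, protocol) {
  stopifnot(inherits(spec, "tube_phantom_spec"),
            inherits(protocol, "relax_protocol"))
  r <- spec$radius
  pitch <- 3 * r
  n_rows <- ceiling(spec$n_tubes / spec$n_cols)
  margin <- 2 * r
  nx <- (spec$n_cols - 1) * pitch + 2 * margin
  ny <- (n_rows - 1) * pitch + 2 * margin
  centers <- NULL
  for (row in seq_len(n_rows)) for (col in seq_len(spec$n_cols)) {
    if (nrow(rbind(centers)) >= spec$n_tubes && !is.null(centers)) next
    centers <- rbind(centers, c(margin + (col - 1) * pitch,
                                margin + (row - 1) * pitch))
  }
  centers <- centers[seq_len(spec$n_tubes), , drop = FALSE]
  is_t1 <- protocol$kind == "inversion_recovery"
  vals <- if (is_t1) spec$t1 else spec$t2

  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  tube_of <- matrix(0L, nx, ny)
  for (k in seq_len(spec$n_tubes)) {
    inside <- (x - centers[k, 1])^2 + (y - centers[k, 2])^2 <= r^2
    if (any(tube_of[inside] > 0L)) stop("tubes overlap", call. = FALSE)
    tube_of[inside] <- k
  }
  nt <- length(protocol$times)
  sl_stack <- array(0, c(nx, ny, nt))
  for (i in seq_len(nt)) {
    ti <- protocol$times[i]
    sig <- matrix(0, nx, ny)
    for (k in seq_len(spec$n_tubes)) {
      s <- if (is_t1) ir_signal(ti, vals[k], protocol$tr, protocol$inversion_scale)
           else se_signal(ti, vals[k])
      sig[tube_of == k] <- s
    }
    sl_stack[, , i] <- sig
  }
  data <- array(0, c(nx, ny, spec$n_slices, nt))
  for (z in seq_len(spec$n_slices)) data[, , z, ] <- sl_stack

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  sigma <- if (is.finite(spec$snr)) 1 / spec$snr else 0
  if (sigma > 0) data[] <- add_rician_noise(as.vector(data), sigma)

  ord <- order(centers[, 2], centers[, 1])
  truth <- data.frame(tube_id = as.character(seq_len(spec$n_tubes)),
                      t1_s = spec$t1[ord], t2_s = spec$t2[ord],
                      value_s = vals[ord],
                      cx = centers[ord, 1], cy = centers[ord, 2])
  list(series = image_series(data, protocol$times, c(1.6, 1.6, 5)),
       truth = truth, spec = spec)
}

#' Bench (NMR-style) relaxation decay series
#'
#' T1 mode: 20 exponentially increasing inversion times from `0.001 * x` to
#' `x` (constant ratio), full-recovery IR signals. T2 mode: 20 linearly
#' increasing echo times from `0.05 * x` to `x` (steps of `0.05 * x`),
#' monoexponential decay. Rician noise at `sigma = s0 / snr`.
#'
#' @param value generating T1 or T2, seconds.
#' @param x largest time, seconds (see [suggest_x()]).
#' @param mode `"t1"` or `"t2"`.
#' @param n number of samples, default 20.
#' @param snr `Inf` for noiseless.
#' @param d inversion scale (t1 mode).
#' @param s0 amplitude.
#' @param seed optional integer.
#' @return data.frame with `time_s`, `value`.
#' @export
make_nmr_series <- function(value, x, mode = c("t1", "t2"), n = 20L,
                            snr = Inf, d = 0.95, s0 = 1, seed = NULL) {
  mode <- match.arg(mode)
  if (x <= 0) stop("`x` must be > 0", call. = FALSE)
  if (mode == "t1") {
    times <- 0.001 * x * (1000^((seq_len(n) - 1) / (n - 1)))
    sig <- ir_signal_full_recovery(times, value, d, s0)
  } else {
    times <- seq(0.05 * x, x, length.out = n)
    sig <- se_signal(times, value, s0)
  }
  sigma <- if (is.finite(snr)) s0 / snr else 0
  if (sigma > 0) sig <- add_rician_noise(sig, sigma, seed = seed)
  data.frame(time_s = times, value = sig)
}

#' Suggested largest time for a bench decay series
#'
#' T1: five times the expected T1 (the largest TI must exceed 5 T1).
#' T2: 2.75 times the expected T2 (midpoint of the 2.5-3x rule).
#'
#' @param expected expected relaxation time, seconds.
#' @param mode `"t1"` or `"t2"`.
#' @export
suggest_x <- function(expected, mode = c("t1", "t2")) {
  mode <- match.arg(mode)
  if (expected <= 0) stop("`expected` must be > 0", call. = FALSE)
  if (mode == "t1") 5 * expected else 2.75 * expected
}
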