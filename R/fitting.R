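# Least-squares relaxation-time fitting.
#
# Both models are linear in the amplitude S0, so S0 is profiled out in closed
# form and each fit reduces to a 1-D minimization over the relaxation time:
# a coarse scan on a log-spaced grid brackets the optimum, Brent refinement
# polishes it. Standard errors come from the full two-parameter Gauss-Newton
# covariance at the optimum. Plain least squares on the magnitude data is
# used throughout; no Rician noise-floor correction is applied.

.T1_BOUNDS <- c(1e-3, 20)  # seconds; guards runaway estimates on flat surfaces

#' Result of a single relaxation-time fit
#'
#' @param estimate fitted relaxation time, seconds.
#' @param amplitude fitted S0.
#' @param standard_error Gauss-Newton standard error of the estimate, seconds.
#' @param converged logical.
#' @param warning optional character flag (e.g. `"non_decaying"`).
#' @return List of class `fit_result` with an `excluded` flag set by the rule:
#'   a fit is excluded when it did not converge or when its standard error
#'   exceeds the estimate itself.
#' @keywords internal
fit_result <- function(estimate = NA_real_, amplitude = NA_real_,
                       standard_error = NA_real_, converged = FALSE,
                       warning = NA_character_) {
  excluded <- !converged ||
    (is.finite(standard_error) && standard_error > estimate) ||
    !is.finite(standard_error)
  structure(list(estimate = estimate, amplitude = amplitude,
                 standard_error = standard_error, converged = converged,
                 excluded = excluded, warning = warning),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> estimate %.6g s  S0 %.4g  SE %.3g s  %s%s\n",
              x$estimate, x$amplitude, x$standard_error,
              if (x$converged) "converged" else "NOT converged",
              if (x$excluded) "  [excluded]" else ""))
  invisible(x)
}

# |model| basis for IR: f(T1) evaluated at each time; tr may be Inf.
.ir_basis <- function(t1, times, tr, d) {
  abs(1 - (1 + d) * exp(-times / t1) + exp(-tr / t1))
}

# signed inner expression and its T1 derivative (for the Jacobian)
.ir_inner <- function(t1, times, tr, d) {
  1 - (1 + d) * exp(-times / t1) + exp(-tr / t1)
}

.ir_inner_dt1 <- function(t1, times, tr, d) {
  e_tr <- if (is.finite(tr)) (tr / t1^2) * exp(-tr / t1) else 0
  -(1 + d) * (times / t1^2) * exp(-times / t1) + e_tr
}

# Profiled residual sum of squares at a given T1 (or T2 via basis fn).
# Returns list(rss, s0). S0 constrained >= 0.
.profile_rss <- function(y, basis) {
  bb <- sum(basis^2)
  if (bb <= 0) return(list(rss = sum(y^2), s0 = 0))
  s0 <- max(0, sum(y * basis) / bb)
  r <- y - s0 * basis
  list(rss = sum(r * r), s0 = s0)
}

# Generic profiled 1-D fit over tau in .T1_BOUNDS: log-grid scan + Brent.
.fit_profiled <- function(y, basis_fn, n_grid = 48L, init = NULL) {
  lo <- log(.T1_BOUNDS[1]); hi <- log(.T1_BOUNDS[2])
  grid <- exp(seq(lo, hi, length.out = n_grid))
  if (!is.null(init) && is.finite(init) &&
      init > .T1_BOUNDS[1] && init < .T1_BOUNDS[2])
    grid <- sort(c(grid, init))
  rss <- vapply(grid, function(tau) .profile_rss(y, basis_fn(tau))$rss, 0)
  i <- which.min(rss)
  bl <- grid[max(1L, i - 1L)]; bu <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(lt) .profile_rss(y, basis_fn(exp(lt)))$rss,
                         lower = log(bl), upper = log(bu), tol = 1e-10)
  tau <- exp(opt$minimum)
  pr <- .profile_rss(y, basis_fn(tau))
  list(tau = tau, s0 = pr$s0, rss = pr$rss)
}

# Gauss-Newton covariance for (S0, tau); jac_tau = d(model)/d(tau) at fit.
.gn_standard_error <- function(rss, n, basis, jac_tau) {
  p <- 2L
  if (n <= p) return(Inf)
  J <- cbind(basis, jac_tau)
  JtJ <- crossprod(J)
  s2 <- rss / (n - p)
  cov_tau <- tryCatch({
    ok <- solve(JtJ)
    s2 * ok[2L, 2L]
  }, error = function(e) Inf)
  if (!is.finite(cov_tau) || cov_tau < 0) return(Inf)
  sqrt(cov_tau)
}

#' Fit T1 to inversion-recovery magnitude data
#'
#' Least-squares fit of the finite-TR IR magnitude model over `(S0, T1)`,
#' with the inversion scale `d` held fixed. T1 is bounded to `[1 ms, 20 s]`.
#'
#' A fit is flagged `excluded` when its standard error exceeds the estimate
#' (the long-T1 ill-conditioning rule) or when it fails to converge.
#'
#' @param times inversion times, seconds (>= 3 values).
#' @param signal magnitude measurements at `times`.
#' @param tr repetition time, seconds; `Inf` selects the full-recovery model.
#' @param d inversion scale, fixed during the fit.
#' @param init optional starting T1; by default the TI closest to the signal
#'   minimum is inverted through the null-time relation.
#' @return A `fit_result`.
#' @export
fit_t1 <- function(times, signal, tr, d = 0.95, init = NULL) {
  times <- as.numeric(times); y <- as.numeric(signal)
  if (length(times) < 3L)
    stop("T1 fit needs at least 3 samples (S0 and T1 free)", call. = FALSE)
  if (length(y) != length(times))
    stop("`signal` and `times` lengths differ", call. = FALSE)
  if (any(!is.finite(y)) || all(y == 0)) return(fit_result(converged = FALSE))
  if (is.null(init)) init <- .t1_init_from_null(times, y, tr, d)
  basis_fn <- function(t1) .ir_basis(t1, times, tr, d)
  fit <- .fit_profiled(y, basis_fn, init = init)
  if (fit$s0 <= 0) return(fit_result(converged = FALSE))
  b <- basis_fn(fit$tau)
  inner <- .ir_inner(fit$tau, times, tr, d)
  jac <- fit$s0 * sign(inner) * .ir_inner_dt1(fit$tau, times, tr, d)
  se <- .gn_standard_error(fit$rss, length(y), b, jac)
  fit_result(estimate = fit$tau, amplitude = fit$s0,
             standard_error = se, converged = TRUE)
}

# T1 start: the TI nearest the signal minimum approximates the null time;
# invert ti_null(T1) = ti numerically.
.t1_init_from_null <- function(times, y, tr, d) {
  ti0 <- times[which.min(y)]
  f <- function(t1) ir_null_time(t1, tr, d) - ti0
  lo <- .T1_BOUNDS[1]; hi <- .T1_BOUNDS[2]
  if (f(lo) * f(hi) > 0) return(ti0 / log(1 + d))
  tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-8)$root,
           error = function(e) ti0 / log(1 + d))
}

#' @rdname fit_t1
#' @details `fit_t1_full_recovery()` fits the simplified TR >> T1 model
#'   `S0 |1 - (1+d) exp(-TI/T1)|` used for bench NMR series.
#' @export
fit_t1_full_recovery <- function(times, signal, d = 0.95, init = NULL) {
  fit_t1(times, signal, tr = Inf, d = d, init = init)
}

#' Fit T2 to multi-echo magnitude data
#'
#' Least-squares fit of the monoexponential `S0 exp(-TE/T2)` over `(S0, T2)`,
#' T2 bounded to `[1 ms, 20 s]`. The starting value comes from a log-linear
#' regression on the strictly positive samples unless `init` is given.
#' Non-decaying data still converge but carry `warning = "non_decaying"`.
#'
#' @param times echo times, seconds (>= 2 values, at least one positive signal).
#' @param signal magnitude measurements at `times`.
#' @param init optional starting T2, seconds.
#' @return A `fit_result`.
#' @export
fit_t2 <- function(times, signal, init = NULL) {
  times <- as.numeric(times); y <- as.numeric(signal)
  if (length(times) < 2L)
    stop("T2 fit needs at least 2 samples", call. = FALSE)
  if (length(y) != length(times))
    stop("`signal` and `times` lengths differ", call. = FALSE)
  if (any(!is.finite(y)) || !any(y > 0)) return(fit_result(converged = FALSE))
  warn <- NA_character_
  pos <- y > 0
  if (is.null(init) && sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ times[pos]))[2L]
    if (is.finite(sl) && sl < 0) init <- -1 / sl
    if (is.finite(sl) && sl >= 0) warn <- "non_decaying"
  }
  basis_fn <- function(t2) exp(-times / t2)
  fit <- .fit_profiled(y, basis_fn, init = init)
  if (fit$s0 <= 0) return(fit_result(converged = FALSE))
  b <- basis_fn(fit$tau)
  jac <- fit$s0 * (times / fit$tau^2) * b
  se <- .gn_standard_error(fit$rss, length(y), b, jac)
  fit_result(estimate = fit$tau, amplitude = fit$s0,
             standard_error = se, converged = TRUE, warning = warn)
}

#' 4-D magnitude image series
#'
#' Container for a stack of magnitude volumes, one per inversion or echo
#' time: dimensions `(x, y, z, contrast)`.
#'
#' @param data 4-D non-negative array; 3-D input gains a singleton z axis.
#' @param times contrast times (TI or TE), seconds, length `dim(data)[4]`.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @return Object of class `image_series`.
#' @export
image_series <- function(data, times, spacing = c(1.6, 1.6, 5)) {
  data <- as.array(data)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("`data` must be a 4-D array", call. = FALSE)
  if (dim(data)[4L] != length(times))
    stop("contrast axis length must equal length(times)", call. = FALSE)
  if (any(data < 0)) stop("magnitude data must be >= 0", call. = FALSE)
  structure(list(data = data, times = as.numeric(times),
                 spacing = as.numeric(spacing)),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series> %d x %d x %d voxels, %d contrasts (%.3g-%.3g s), spacing %s mm\n",
              d[1], d[2], d[3], d[4], min(x$times), max(x$times),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Quantitative relaxation map
#'
#' @param values,standard_errors 3-D arrays, seconds.
#' @param exclusion 3-D logical array; `TRUE` marks voxels whose fit was
#'   rejected (no convergence, or standard error above the estimate).
#' @param kind `"t1"` or `"t2"`.
#' @param spacing voxel spacing, mm.
#' @export
quant_map <- function(values, standard_errors, exclusion,
                      kind = c("t1", "t2"), spacing = c(1.6, 1.6, 5)) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  structure(list(values = values,
                 standard_errors = as.array(standard_errors),
                 exclusion = as.array(exclusion),
                 kind = kind, spacing = as.numeric(spacing)),
            class = "quant_map")
}

#' @export
print.quant_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<quant_map> %s, %d x %d x %d voxels, %d excluded (%.3g%%)\n",
              toupper(x$kind), d[1], d[2], d[3], sum(x$exclusion),
              100 * mean(x$exclusion)))
  invisible(x)
}

#' Reconstruct a quantitative map voxel by voxel
#'
#' Applies `fit_t1()` (inversion-recovery protocol) or `fit_t2()` (spin-echo
#' protocol) independently to every voxel's signal-versus-time curve. One
#' quantitative value per voxel; partial-volume mixing is not modeled.
#' Voxels whose fit does not converge or whose standard error exceeds the
#' estimate are marked in the exclusion mask and carry `NA` values.
#'
#' @param series an `image_series` whose contrast times match the protocol.
#' @param protocol a `relax_protocol`.
#' @param mask optional logical 3-D array restricting which voxels are fit;
#'   voxels outside are excluded without fitting.
#' @return A `quant_map`.
#' @export
reconstruct_map <- function(series, protocol, mask = NULL) {
  stopifnot(inherits(series, "image_series"), inherits(protocol, "relax_protocol"))
  if (length(series$times) != length(protocol$times) ||
      any(abs(series$times - protocol$times) > 1e-9))
    stop("series contrast times do not match the protocol", call. = FALSE)
  d <- dim(series$data)[1:3]
  nvox <- prod(d)
  ymat <- matrix(series$data, nrow = nvox)  # voxels x contrasts
  vals <- ses <- rep(NA_real_, nvox)
  excl <- rep(TRUE, nvox)
  do_fit <- if (is.null(mask)) rep(TRUE, nvox) else as.logical(mask)
  is_ir <- protocol$kind == "inversion_recovery"
  for (v in which(do_fit)) {
    y <- ymat[v, ]
    fr <- if (is_ir)
      fit_t1(protocol$times, y, tr = protocol$tr, d = protocol$inversion_scale)
    else
      fit_t2(protocol$times, y)
    if (fr$converged) {
      vals[v] <- fr$estimate
      ses[v] <- fr$standard_error
    }
    excl[v] <- fr$excluded
  }
  quant_map(array(vals, d), array(ses, d), array(excl, d),
            kind = if (is_ir) "t1" else "t2", spacing = series$spacing)
}

#' Joint fit over a region of interest
#'
#' Pools the (time, signal) pairs from every voxel in the ROI into a single
#' least-squares fit with one shared amplitude and one shared relaxation
#' time — the per-slice phantom-tube strategy.
#'
#' @param series an `image_series`.
#' @param roi integer matrix of voxel indices (rows are `(x, y, z)`), or a
#'   logical array over the volume.
#' @param protocol a `relax_protocol`.
#' @return A `fit_result`.
#' @export
fit_roi_joint <- function(series, roi, protocol) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$data)[1:3]
  if (is.logical(roi)) roi <- which(array(roi, d))
  else if (is.matrix(roi))
    roi <- roi[, 1L] + d[1L] * (roi[, 2L] - 1L) + d[1L] * d[2L] * (roi[, 3L] - 1L)
  if (length(roi) == 0L) stop("empty ROI", call. = FALSE)
  ymat <- matrix(series$data, nrow = prod(d))[roi, , drop = FALSE]
  times <- rep(protocol$times, each = nrow(ymat))
  y <- as.vector(ymat)
  if (protocol$kind == "inversion_recovery")
    fit_t1(times, y, tr = protocol$tr, d = protocol$inversion_scale)
  else
    fit_t2(times, y)
}
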