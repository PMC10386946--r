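# In vivo pipeline: skull stripping, mixture-of-Gaussians tissue binning
# with a partial-volume bin, manual 2x2 ROIs, and cross-subject summaries.

#' Strip skull and background from a head image
#'
#' Threshold (Otsu's inter-class-variance criterion by default), binary
#' opening to detach the thin skull ring and speckle, binary closing to fill
#' interior gaps, then keep the largest connected component. 3-D inputs are
#' processed slice by slice before the final (3-D) component selection.
#'
#' @param image 2-D matrix or 3-D array; `NA` treated as background. Either
#'   a quantitative map or a raw image may be supplied (the raw inversion
#'   image often gives cleaner skull/brain contrast).
#' @param threshold `"otsu"` or an explicit scalar.
#' @param radius_open,radius_close disc radii in voxels.
#' @param source recorded provenance, `"map"` or `"raw_image"`.
#' @return Object of class `brain_mask`: logical array + `source` attribute.
#' @export
strip_skull <- function(image, threshold = "otsu", radius_open = 2,
                        radius_close = 2, source = c("map", "raw_image")) {
  source <- match.arg(source)
  img <- as.array(image)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  img[!is.finite(img)] <- 0
  thr <- if (identical(threshold, "otsu")) otsu_threshold(img) else threshold
  nz <- dim(img)[3L]
  mask <- array(FALSE, dim(img))
  for (z in seq_len(nz)) {
    m <- img[, , z] > thr
    m <- binary_open(m, radius_open)
    m <- binary_close(m, radius_close)
    mask[, , z] <- m
  }
  if (!any(mask)) stop("empty foreground after threshold", call. = FALSE)
  for (z in seq_len(nz)) mask[, , z] <- largest_component(mask[, , z])
  if (!any(mask)) stop("empty foreground after morphology", call. = FALSE)
  structure(mask, class = "brain_mask", source = source, threshold = thr)
}

#' One-dimensional Gaussian mixture by EM
#'
#' EM is run from a small set of deterministic starts — component means at
#' the `(2i-1)/(2k)` data quantiles, means equally spaced over the data
#' range, and seeded jitters of the quantile start — and the converged fit
#' with the highest log-likelihood wins. Component SDs are floored at 1% of
#' the overall data SD, which blocks the classic single-point variance
#' collapse on near-degenerate peaks.
#'
#' @param x numeric data.
#' @param k number of components.
#' @param seed integer; consumed only by the jittered starts.
#' @param max_iter,tol EM stopping rule on the log-likelihood.
#' @param restarts number of jittered starts.
#' @return List with `means`, `sds`, `weights` (sorted by mean),
#'   `responsibilities` (n x k), `loglik`, `iterations`, `converged`.
#' @export
gmm1d <- function(x, k, seed = 1, max_iter = 500L, tol = 1e-10, restarts = 3L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L * k)
    stop(sprintf("need at least %d observations for %d components", 10L * k, k),
         call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate input: all values identical", call. = FALSE)
  sd_floor <- 0.01 * stats::sd(x)
  run_em <- function(mu) {
    sg <- rep(stats::sd(x) / k, k)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j)
        w[j] * stats::dnorm(x, mu[j], sg[j]), numeric(n))
      rowsum_d <- rowSums(dens)
      if (any(rowsum_d == 0)) rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
      resp <- dens / rowsum_d
      nk <- colSums(resp)
      if (any(nk < 1e-8)) return(NULL)
      mu <- colSums(resp * x) / nk
      sg <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
      sg <- pmax(sg, sd_floor)
      w <- nk / n
      ll <- sum(log(rowsum_d))
      if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
        ord <- order(mu)
        return(list(means = mu[ord], sds = sg[ord], weights = w[ord],
                    responsibilities = resp[, ord, drop = FALSE],
                    loglik = ll, iterations = it, converged = TRUE))
      }
      ll_old <- ll
    }
    ord <- order(mu)
    list(means = mu[ord], sds = sg[ord], weights = w[ord],
         responsibilities = resp[, ord, drop = FALSE],
         loglik = ll_old, iterations = max_iter, converged = FALSE)
  }
  mu0 <- stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
  starts <- list(kmeans1d(x, k), mu0, seq(min(x), max(x), length.out = k))
  old <- get_rng_state(); set.seed(as.integer(seed))
  for (j in seq_len(restarts))
    starts[[2L + j]] <- sort(mu0 + stats::rnorm(k, 0, stats::sd(x) / 2))
  restore_rng_state(old)
  # prefer converged fits whose max-posterior assignment uses every
  # component (no vacuous bins), then the highest log-likelihood
  rank_of <- function(f) {
    filled <- all(tabulate(max.col(f$responsibilities, ties.method = "first"),
                           k) > 0L)
    c(f$converged, filled, f$loglik)
  }
  fit <- NULL
  for (mu in starts) {
    cand <- run_em(mu)
    if (is.null(cand)) next
    if (is.null(fit)) { fit <- cand; next }
    a <- rank_of(cand); b <- rank_of(fit)
    if (a[1] > b[1] || (a[1] == b[1] && (a[2] > b[2] ||
        (a[2] == b[2] && a[3] > b[3])))) fit <- cand
  }
  if (is.null(fit))
    stop("Gaussian mixture failed to converge (component collapse)", call. = FALSE)
  fit
}

#' Exact 1-D k-means on binned data
#'
#' Dynamic-programming solution of the 1-D k-means problem on a weighted
#' histogram of the data (optimal for the binned values, deterministic, no
#' random initialization). Used to seed the mixture EM.
#'
#' @param x numeric data.
#' @param k number of clusters.
#' @param n_bins histogram resolution.
#' @return Sorted cluster centers.
#' @export
kmeans1d <- function(x, k, n_bins = 256L) {
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) {
    centers <- ux
    w <- as.numeric(table(factor(x, levels = ux)))
  } else {
    br <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1))
    br <- unique(br)
    cuts <- cut(x, br, include.lowest = TRUE)
    w <- as.numeric(table(cuts))
    centers <- as.numeric(tapply(x, cuts, mean))
    keep <- w > 0 & is.finite(centers)
    centers <- centers[keep]; w <- w[keep]
  }
  B <- length(centers)
  if (B <= k) return(centers)
  cw <- cumsum(w); cwx <- cumsum(w * centers); cwx2 <- cumsum(w * centers^2)
  # SSE of bins i..j around their weighted mean, vectorized over i
  sse <- function(i, j) {
    W <- cw[j] - ifelse(i > 1, cw[i - 1], 0)
    S <- cwx[j] - ifelse(i > 1, cwx[i - 1], 0)
    Q <- cwx2[j] - ifelse(i > 1, cwx2[i - 1], 0)
    Q - S^2 / W
  }
  D <- matrix(Inf, k, B)
  arg <- matrix(1L, k, B)
  D[1, ] <- vapply(seq_len(B), function(j) sse(1, j), 0)
  for (m in 2:k) {
    for (j in m:B) {
      i <- m:j
      cost <- D[m - 1, i - 1] + sse(i, j)
      best <- which.min(cost)
      D[m, j] <- cost[best]
      arg[m, j] <- i[best]
    }
  }
  # backtrack cluster boundaries
  bounds <- integer(k + 1); bounds[k + 1] <- B
  j <- B
  for (m in k:2) { bounds[m] <- arg[m, j] - 1L; j <- bounds[m] }
  bounds[1] <- 0L
  vapply(seq_len(k), function(m) {
    i <- (bounds[m] + 1L):bounds[m + 1]
    sum(w[i] * centers[i]) / sum(w[i])
  }, 0)
}

.T1_LABELS <- c("WM", "GM", "partial", "CSF")
.T2_LABELS <- c("WM_GM", "partial", "CSF")

#' Bin brain voxels into tissue compartments
#'
#' Fits a one-dimensional Gaussian mixture to the in-mask relaxation values
#' — four components for T1 (WM, GM, partial volume, CSF) or three for T2
#' (combined WM+GM, partial volume, CSF; WM and GM are indistinguishable by
#' T2 here) — and labels each voxel by maximum posterior responsibility.
#' Components are sorted by mean, so labels are a deterministic function of
#' the sorted means. The "partial" bin is the penultimate component and sits
#' between the parenchyma and CSF, absorbing GM/CSF partial-volume voxels.
#' Voxels flagged excluded in the map are removed before fitting and stay
#' unlabeled.
#'
#' @param map a `quant_map`.
#' @param mask a `brain_mask` (or logical array) over the same grid.
#' @param mode `"t1"` (4 bins) or `"t2"` (3 bins); defaults to the map kind.
#' @param seed passed to [gmm1d()] restarts.
#' @return Object of class `segmentation_result`: integer `labels` array
#'   (0 = background/excluded; codes documented in `label_names`),
#'   empirical `bin_means` / `bin_sds` / `bin_counts` per label, and the
#'   underlying `mixture` fit.
#' @export
segment_tissues <- function(map, mask, mode = NULL, seed = 1) {
  stopifnot(inherits(map, "quant_map"))
  if (is.null(mode)) mode <- map$kind
  mode <- match.arg(mode, c("t1", "t2"))
  label_names <- if (mode == "t1") .T1_LABELS else .T2_LABELS
  k <- length(label_names)
  msk <- as.logical(mask) & !as.logical(map$exclusion) & is.finite(map$values)
  dim(msk) <- dim(map$values)
  x <- map$values[msk]
  fit <- gmm1d(x, k, seed = seed)
  assign_k <- max.col(fit$responsibilities, ties.method = "first")
  labels <- array(0L, dim(map$values))
  labels[msk] <- assign_k
  bin_means <- vapply(seq_len(k), function(j) mean(x[assign_k == j]), 0)
  bin_sds <- vapply(seq_len(k), function(j) stats::sd(x[assign_k == j]), 0)
  bin_counts <- tabulate(assign_k, k)
  names(bin_means) <- names(bin_sds) <- names(bin_counts) <- label_names
  structure(list(labels = labels, label_names = label_names, mode = mode,
                 bin_means = bin_means, bin_sds = bin_sds,
                 bin_counts = bin_counts, mixture = fit, seed = seed),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s mode, %d voxels binned\n",
              x$mode, sum(x$bin_counts)))
  for (j in seq_along(x$label_names))
    cat(sprintf("  %-8s mean %.4g s  sd %.3g s  n %d\n", x$label_names[j],
                x$bin_means[j], x$bin_sds[j], x$bin_counts[j]))
  invisible(x)
}

#' Manual square region of interest
#'
#' @param corner `(x, y)` voxel of the lower corner.
#' @param slice axial slice index.
#' @param tissue intended tissue label.
#' @param side `"left"` or `"right"` hemisphere.
#' @param size edge length in voxels (default 2, i.e. a 2x2 patch).
#' @export
manual_roi <- function(corner, slice = 1L, tissue = "WM",
                       side = c("right", "left"), size = 2L) {
  side <- match.arg(side)
  structure(list(corner = as.integer(corner), slice = as.integer(slice),
                 tissue = tissue, side = side, size = as.integer(size)),
            class = "manual_roi")
}

#' Mean and SD of a manual ROI on a quantitative map
#'
#' Arithmetic mean and SD over the ROI's voxels, skipping excluded voxels
#' (an error if all are excluded). When a segmentation is supplied, the ROI
#' must lie entirely inside one auto-segmented region; straddling two labels
#' is a purity violation.
#'
#' @param map a `quant_map`.
#' @param roi a `manual_roi`.
#' @param segmentation optional `segmentation_result` for the purity check.
#' @return List with `mean`, `sd`, `n`, `tissue`, `side`.
#' @export
manual_roi_stats <- function(map, roi, segmentation = NULL) {
  stopifnot(inherits(map, "quant_map"), inherits(roi, "manual_roi"))
  xs <- roi$corner[1] + 0:(roi$size - 1L)
  ys <- roi$corner[2] + 0:(roi$size - 1L)
  d <- dim(map$values)
  if (any(xs < 1L | xs > d[1L]) || any(ys < 1L | ys > d[2L]))
    stop("ROI extends outside the image", call. = FALSE)
  idx <- as.matrix(expand.grid(x = xs, y = ys))
  idx <- cbind(idx, z = roi$slice)
  if (!is.null(segmentation)) {
    labs <- segmentation$labels[idx]
    labs <- labs[labs > 0L]
    if (length(unique(labs)) > 1L)
      stop("purity violation: ROI crosses two auto-segmented regions",
           call. = FALSE)
  }
  vals <- map$values[idx]
  excl <- map$exclusion[idx]
  vals <- vals[!excl & is.finite(vals)]
  if (length(vals) == 0L) stop("all ROI voxels are excluded", call. = FALSE)
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals),
       tissue = roi$tissue, side = roi$side)
}

#' Cross-subject tissue summary
#'
#' Group mean and SD of per-subject tissue values, one row per tissue.
#'
#' @param values data.frame with columns `subject`, `tissue`, `value_s`.
#' @return data.frame `tissue`, `mean_s`, `sd_s`, `n_subjects`.
#' @export
tissue_summary <- function(values) {
  stopifnot(all(c("subject", "tissue", "value_s") %in% names(values)))
  agg <- stats::aggregate(value_s ~ tissue, data = values,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  data.frame(tissue = agg$tissue,
             mean_s = agg$value_s[, "mean"],
             sd_s = agg$value_s[, "sd"],
             n_subjects = as.integer(agg$value_s[, "n"]))
}
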