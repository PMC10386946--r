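# Small 2-D image primitives: Otsu threshold, disc morphology, connected
# components, and a Hough circle transform. Written for the modest matrix
# sizes of quantitative maps (~100-200 voxels per side).

#' Otsu's inter-class-variance threshold
#'
#' @param x numeric values (NA dropped).
#' @param n_bins histogram resolution.
#' @return Threshold value; foreground is `x > threshold`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values", call. = FALSE)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - r[1]) / diff(r) * n_bins)), n_bins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# integer offsets of a disc structuring element of given radius
.disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

# shift a matrix by (dx, dy), padding with `fill`
.shift_mat <- function(m, dx, dy, fill) {
  n <- matrix(fill, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
  xd <- xs + dx; yd <- ys + dy
  ok_x <- xd >= 1 & xd <= nrow(m); ok_y <- yd >= 1 & yd <= ncol(m)
  n[xd[ok_x], yd[ok_y]] <- m[xs[ok_x], ys[ok_y]]
  n
}

#' Binary morphology with a disc structuring element
#'
#' @param mask logical matrix.
#' @param radius disc radius in voxels.
#' @return Logical matrix.
#' @export
binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- .disc_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out | .shift_mat(mask, off$dx[i], off$dy[i], FALSE)
  out
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- .disc_offsets(radius)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out & .shift_mat(mask, off$dx[i], off$dy[i], FALSE)
  out
}

#' @rdname binary_dilate
#' @export
binary_open <- function(mask, radius) binary_dilate(binary_erode(mask, radius), radius)

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, radius) binary_erode(binary_dilate(mask, radius), radius)

#' Label 4-connected components of a binary image
#'
#' @param mask logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  idx_all <- which(mask)
  for (s in idx_all) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0L) {
      v <- queue
      queue <- integer(0)
      x <- (v - 1L) %% nx + 1L
      y <- (v - 1L) %/% nx + 1L
      for (dd in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        xn <- x + dd[1L]; yn <- y + dd[2L]
        ok <- xn >= 1L & xn <= nx & yn >= 1L & yn <= ny
        w <- (yn[ok] - 1L) * nx + xn[ok]
        w <- w[mask[w] & lab[w] == 0L]
        if (length(w)) { lab[w] <- cur; queue <- c(queue, w) }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Keep only the largest connected component
#' @param mask logical matrix.
#' @export
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  keep <- which.max(tabulate(lab[lab > 0L]))
  lab == keep
}

#' Hough transform circle detection
#'
#' Gradient-based accumulator: edge voxels (strong intensity gradient) vote
#' for circle centers one radius away along the gradient direction, in both
#' senses. Votes are pooled over the radius band, peaks extracted with
#' non-maximum suppression.
#'
#' @param img numeric matrix (magnitude image).
#' @param radii candidate radii, voxels.
#' @param n_peaks maximum number of circles to return.
#' @param min_sep minimum center separation between returned circles,
#'   voxels; default 1.5x the largest radius.
#' @param n_edge number of strongest-gradient voxels used as edge votes;
#'   defaults to three times the total expected circumference of `n_peaks`
#'   circles at the largest radius, so faint circles still contribute.
#' @return data.frame with columns `cx`, `cy` (voxel coordinates), `radius`,
#'   `strength`, ordered by decreasing accumulator strength.
#' @export
hough_circles <- function(img, radii, n_peaks = 10L, min_sep = NULL,
                          n_edge = NULL) {
  nx <- nrow(img); ny <- ncol(img)
  if (is.null(min_sep)) min_sep <- 1.5 * max(radii)
  if (is.null(n_edge))
    n_edge <- round(3 * n_peaks * 2 * pi * max(radii))
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (img[3:nx, ] - img[1:(nx - 2), ]) / 2
  gy[, 2:(ny - 1)] <- (img[, 3:ny] - img[, 1:(ny - 2)]) / 2
  gm <- sqrt(gx^2 + gy^2)
  pos <- gm[gm > 0]
  if (length(pos) == 0L)
    return(data.frame(cx = numeric(0), cy = numeric(0),
                      radius = numeric(0), strength = numeric(0)))
  thr <- if (length(pos) > n_edge)
    sort(pos, decreasing = TRUE)[n_edge] else min(pos)
  e <- which(gm >= thr)
  ex <- (e - 1L) %% nx + 1L
  ey <- (e - 1L) %/% nx + 1L
  ux <- gx[e] / gm[e]; uy <- gy[e] / gm[e]
  best <- NULL
  accs <- list()
  for (r in radii) {
    acc <- matrix(0L, nx, ny)
    for (sgn in c(-1, 1)) {
      cx <- round(ex + sgn * r * ux)
      cy <- round(ey + sgn * r * uy)
      ok <- cx >= 1 & cx <= nx & cy >= 1 & cy <= ny
      idx <- (cy[ok] - 1) * nx + cx[ok]
      t <- tabulate(idx, nx * ny)
      acc <- acc + t
    }
    accs[[as.character(r)]] <- acc
    # normalize by circumference so radii are comparable
    cand <- data.frame(idx = which(acc > 0), votes = acc[acc > 0] / r)
    cand$radius <- r
    best <- rbind(best, cand)
  }
  if (is.null(best) || nrow(best) == 0L)
    return(data.frame(cx = numeric(0), cy = numeric(0),
                      radius = numeric(0), strength = numeric(0)))
  best$cx <- (best$idx - 1L) %% nx + 1L
  best$cy <- (best$idx - 1L) %/% nx + 1L
  best <- best[order(-best$votes), ]
  picked <- best[0, ]
  for (i in seq_len(nrow(best))) {
    b <- best[i, ]
    if (nrow(picked) > 0L &&
        any((picked$cx - b$cx)^2 + (picked$cy - b$cy)^2 < min_sep^2)) next
    picked <- rbind(picked, b)
    if (nrow(picked) >= n_peaks) break
  }
  # sub-voxel refinement: vote-weighted centroid in a 3x3 window of the
  # winning radius' accumulator
  for (i in seq_len(nrow(picked))) {
    acc <- accs[[as.character(picked$radius[i])]]
    xs <- max(1, picked$cx[i] - 1):min(nx, picked$cx[i] + 1)
    ys <- max(1, picked$cy[i] - 1):min(ny, picked$cy[i] + 1)
    w <- acc[xs, ys, drop = FALSE]
    if (sum(w) > 0) {
      picked$cx[i] <- sum(outer(xs, rep(1, length(ys))) * w) / sum(w)
      picked$cy[i] <- sum(outer(rep(1, length(xs)), ys) * w) / sum(w)
    }
  }
  data.frame(cx = picked$cx, cy = picked$cy,
             radius = picked$radius, strength = picked$votes)
}
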