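# Skull stripping, mixture segmentation, manual ROIs, group summaries.

test_that("skull stripping keeps the brain disc and drops the ring", {
  nx <- ny <- 80
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  rr <- sqrt((x - 40)^2 + (y - 40)^2)
  disc <- rr <= 24
  ring <- rr >= 30 & rr <= 33
  img <- matrix(0, nx, ny)
  img[disc] <- 1
  img[ring] <- 0.9
  set.seed(2)
  salt <- matrix(runif(nx * ny) < 0.01, nx, ny) & !disc & !ring
  img[salt] <- 1
  mask <- strip_skull(img, radius_open = 2, radius_close = 2)
  m <- mask[, , 1]
  expect_gte(mean(m[disc]), 0.99)
  expect_identical(sum(m[ring]), 0L)
  expect_identical(sum(m[salt]), 0L)
  # idempotence on the masked image
  mask2 <- strip_skull(img * m, radius_open = 2, radius_close = 2)
  expect_identical(as.logical(mask2), as.logical(mask))
  expect_error(strip_skull(matrix(0, 10, 10)), "foreground")
})

test_that("exact 1-D k-means finds well-separated centers", {
  x <- c(rep(0.25, 50), rep(1.0, 30), rep(2.0, 20))
  expect_equal(kmeans1d(x, 3), c(0.25, 1.0, 2.0), tolerance = 1e-9)
  set.seed(3)
  x2 <- c(rnorm(500, 0.3, 0.02), rnorm(300, 1, 0.05), rnorm(200, 2, 0.1))
  expect_equal(kmeans1d(x2, 3), c(0.3, 1, 2), tolerance = 0.05)
})

test_that("mixture binning recovers well-separated tissue clusters", {
  set.seed(4)
  gen_means <- c(0.254, 0.377, 1.0, 2.073)
  gen_sds <- c(0.02, 0.03, 0.2, 0.3)
  x <- unlist(lapply(1:4, function(j) rnorm(1000, gen_means[j], gen_sds[j])))
  truth_lab <- rep(1:4, each = 1000)
  vals <- array(x, c(4000, 1, 1))
  qm <- quant_map(vals, array(0, dim(vals)), array(FALSE, dim(vals)), "t1")
  seg <- segment_tissues(qm, array(TRUE, dim(vals)), mode = "t1", seed = 1)
  got <- seg$labels[cbind(1:4000, 1, 1)]
  expect_gte(mean(got == truth_lab), 0.99)
  expect_lt(max(abs(seg$bin_means - gen_means) / gen_means), 0.05)
  expect_true(all(diff(seg$bin_means) > 0))
  expect_identical(names(seg$bin_means), c("WM", "GM", "partial", "CSF"))
})

test_that("t2 mode uses three bins with merged WM and GM", {
  set.seed(5)
  x <- c(rnorm(800, 0.09, 0.01), rnorm(150, 0.4, 0.08), rnorm(250, 1.1, 0.2))
  vals <- array(x, c(length(x), 1, 1))
  qm <- quant_map(vals, array(0, dim(vals)), array(FALSE, dim(vals)), "t2")
  seg <- segment_tissues(qm, array(TRUE, dim(vals)), seed = 1)
  expect_identical(seg$label_names, c("WM_GM", "partial", "CSF"))
  expect_equal(unname(seg$bin_means[["WM_GM"]]), 0.09, tolerance = 0.05)
  expect_true(all(diff(seg$bin_means) > 0))
})

test_that("degenerate mixture input errors", {
  vals <- array(rep(0.3, 100), c(100, 1, 1))
  qm <- quant_map(vals, array(0, dim(vals)), array(FALSE, dim(vals)), "t1")
  expect_error(segment_tissues(qm, array(TRUE, dim(vals))), "identical")
  expect_error(gmm1d(rnorm(15), 4), "observations")
})

test_that("mixture fit is deterministic under a fixed seed", {
  set.seed(6)
  x <- c(rnorm(500, 0.3, 0.03), rnorm(500, 1.5, 0.3))
  a <- gmm1d(x, 2, seed = 9)
  b <- gmm1d(x, 2, seed = 9)
  expect_identical(a$means, b$means)
  expect_identical(a$loglik, b$loglik)
})

test_that("manual ROI statistics average unexcluded voxels and enforce purity", {
  vals <- array(NA_real_, c(8, 8, 1))
  vals[3:4, 3:4, 1] <- c(0.25, 0.25, 0.26, 0.26)
  excl <- array(FALSE, c(8, 8, 1))
  qm <- quant_map(vals, array(0, dim(vals)), excl, "t1")
  roi <- manual_roi(c(3, 3), slice = 1, tissue = "WM")
  st <- manual_roi_stats(qm, roi)
  expect_equal(st$mean, 0.255)
  expect_equal(st$n, 4L)
  # purity violation across two labels
  seg <- list(labels = array(0L, c(8, 8, 1)))
  seg$labels[3, 3:4, 1] <- 1L
  seg$labels[4, 3:4, 1] <- 2L
  class(seg) <- "segmentation_result"
  expect_error(manual_roi_stats(qm, roi, seg), "purity")
  # all voxels excluded
  excl[3:4, 3:4, 1] <- TRUE
  qm2 <- quant_map(vals, array(0, dim(vals)), excl, "t1")
  expect_error(manual_roi_stats(qm2, roi), "excluded")
  expect_error(manual_roi_stats(qm, manual_roi(c(8, 8))), "outside")
})

test_that("group tissue summaries average subjects", {
  one <- data.frame(subject = 1, tissue = "WM", value_s = 0.25)
  s1 <- tissue_summary(one)
  expect_equal(s1$mean_s, 0.25)
  two <- data.frame(subject = 1:2, tissue = "GM", value_s = c(0.3, 0.5))
  expect_equal(tissue_summary(two)$mean_s, 0.4)
  set.seed(7)
  n <- 10
  gens <- c(WM = 0.254, GM = 0.377, CSF = 2.073)
  df <- do.call(rbind, lapply(names(gens), function(tl)
    data.frame(subject = seq_len(n), tissue = tl,
               value_s = rnorm(n, gens[[tl]], 0.05 * gens[[tl]]))))
  s <- tissue_summary(df)
  for (tl in names(gens)) {
    row <- s[s$tissue == tl, ]
    expect_equal(row$mean_s, gens[[tl]],
                 tolerance = 2 * 0.05 / sqrt(n) * 1.5)
  }
})
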