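# Tube detection, ROI geometry, and phantom summaries.

test_that("discs at known centers are detected within a voxel", {
  centers <- as.matrix(expand.grid(x = c(20, 50, 80), y = c(20, 50, 80)))
  centers <- rbind(centers, c(20, 110))
  img <- disc_image(100, 130, centers, radius = 8)
  found <- detect_tubes(img, expected_radius = 8, n_expected = 10)
  expect_length(found, 10)
  got <- t(vapply(found, function(t) t$center, c(0, 0)))
  ord_truth <- centers[order(centers[, 2], centers[, 1]), ]
  expect_lt(max(abs(got - ord_truth)), 1)
  expect_lt(max(abs(vapply(found, `[[`, 0, "radius") - 8)), 1)
})

test_that("blank and single-disc slices behave", {
  expect_length(hough_circles(matrix(0, 40, 40), 6:10), 4)  # empty frame
  expect_identical(nrow(hough_circles(matrix(0, 40, 40), 6:10)), 0L)
  img <- disc_image(40, 40, matrix(c(20, 20), 1), radius = 8)
  one <- detect_tubes(img, 8, 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$radius, 8, tolerance = 1)
})

test_that("central_roi shrinks geometry consistently", {
  tb <- tube_roi(1, c(20, 20), 10, c(64, 64))
  half <- central_roi(tb, 0.5)
  expect_equal(half$radius, 5)
  expect_equal(nrow(half$member_voxels), pi * 25, tolerance = 0.1)
  # identity at fraction 1
  expect_identical(central_roi(tb, 1)$member_voxels, tb$member_voxels)
  # nested containment
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(half$member_voxels) %in% key(tb$member_voxels)))
  expect_error(central_roi(tube_roi(1, c(5, 5), 1.5, c(20, 20)), 0.5), "1 voxel")
})

test_that("tube T2 values are ROI means of the map", {
  vals <- array(0.5, c(30, 30, 1))
  tb <- tube_roi(1, c(15, 15), 6, c(30, 30))
  qm <- quant_map(vals, array(0, c(30, 30, 1)), array(FALSE, c(30, 30, 1)),
                  kind = "t2")
  tubes <- list(list("1" = tb))
  expect_equal(tube_t2_per_slice(qm, tubes)$value_s, 0.5)
  # half the voxels at a, half at b -> mean (a + b) / 2
  mv <- tb$member_voxels
  vals2 <- vals
  half1 <- seq_len(floor(nrow(mv) / 2))
  vals2[cbind(mv[half1, , drop = FALSE], 1)] <- 0.2
  vals2[cbind(mv[-half1, , drop = FALSE], 1)] <- 0.4
  if (nrow(mv) %% 2 == 1)  # odd voxel count: pin the leftover at the mean
    vals2[cbind(mv[nrow(mv), 1], mv[nrow(mv), 2], 1)] <- 0.3
  qm2 <- quant_map(vals2, array(0, c(30, 30, 1)), array(FALSE, c(30, 30, 1)),
                   kind = "t2")
  expect_equal(tube_t2_per_slice(qm2, tubes)$value_s, 0.3)
})

test_that("central-slice summaries follow the midpoint convention", {
  df <- data.frame(tube_id = "1", slice = 1:8, value_s = 1:8)
  s <- summarize_tubes(df, 6)
  expect_equal(s$mean_s, mean(2:7))  # slices 2-7 of 8
  expect_equal(s$n_slices, 6L)
  same <- data.frame(tube_id = "1", slice = 1:8, value_s = rep(3, 8))
  s2 <- summarize_tubes(same, 6)
  expect_equal(s2$mean_s, 3)
  expect_equal(s2$sd_s, 0)
  expect_error(summarize_tubes(df[df$slice <= 4, ], 6), "at least 6")
})

test_that("noiseless tube phantom round-trips through the full pipeline", {
  ph <- make_tube_phantom(tube_phantom_spec(snr = Inf, seed = 1), ir_p)
  qa <- phantom_qa(ph$series, ir_p, expected_radius = 8, n_tubes = 10)
  merged <- merge(qa$summary, ph$truth, by = "tube_id")
  expect_identical(nrow(merged), 10L)
  expect_lt(max(abs(merged$mean_s - merged$value_s) / merged$value_s), 1e-3)
  # determinism: same seed-fixed input volume, same result
  qa2 <- phantom_qa(ph$series, ir_p, expected_radius = 8, n_tubes = 10)
  expect_identical(qa$summary, qa2$summary)
})

test_that("tube IDs stay matched across slices under noise", {
  ph <- make_tube_phantom(tube_phantom_spec(snr = 95, seed = 4), ir_p)
  tubes <- detect_tubes_series(ph$series, 8, 10)
  ids <- sort(unique(unlist(lapply(tubes, names))))
  expect_identical(ids, sort(as.character(1:10)))
  # every slice sees all ten tubes
  expect_true(all(vapply(tubes, length, 0L) == 10L))
})
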