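test_that("preprocessing removes spikes, thresholds at the ROI mean, drops small objects", {
  # single-pixel spike on flat background disappears before thresholding
  fr <- matrix(10, 20, 20)
  fr[7, 9] <- 1e6
  seg <- preprocess_frame(fr, min_area = 5)
  expect_true(seg$empty)                          # flat after filtering

  # constant image: nothing strictly exceeds the mean
  seg <- preprocess_frame(matrix(42, 15, 15))
  expect_true(seg$empty)
  expect_equal(seg$threshold, 42)

  # area rule at the 50-pixel boundary: the median filter rounds the four
  # corners off a rectangular blob, so a x b segments to a*b - 4 pixels
  fr <- matrix(0, 40, 60)
  fr[6:12, 5:11] <- 100        # 7x7 -> 45 px after filtering: removed
  fr[20:28, 30:35] <- 100      # 9x6 -> exactly 50 px: retained
  seg <- preprocess_frame(fr)
  lab <- clockwave:::label_components(seg$mask)
  expect_equal(max(lab), 1L)
  expect_equal(sum(seg$mask), 50L)
  expect_equal(seg$n_removed, 1L)
})

test_that("centroid is the grey-level-weighted mean of segmented pixels", {
  # one section with pixels at columns 10, 11, 12 and weights 1, 2, 1 -> 11
  mask <- matrix(FALSE, 10, 25)
  filt <- matrix(0, 10, 25)
  for (n in 1:10) {
    mask[n, 10:12] <- TRUE
    filt[n, 10:12] <- c(1, 2, 1)
  }
  cl <- fit_centerline(list(mask = mask, filtered = filt))
  expect_equal(unique(round(cl$centroids, 10)), 11)
  expect_equal(cl$predict(5), 11, tolerance = 1e-6)
  expect_lt(abs(cl$slope(5)), 1e-6)
})

test_that("a straight vertical organ yields a constant centerline", {
  fr <- matrix(0, 30, 30)
  fr[3:28, 13:17] <- 100
  seg <- preprocess_frame(fr, min_area = 30)
  cl <- fit_centerline(seg)
  cent <- cl$centroids[!is.na(cl$centroids)]
  expect_true(all(abs(cent - 15) < 1e-9))
})

test_that("a tilted organ's fitted tangent matches the shear", {
  nr <- 40
  mask <- matrix(FALSE, nr, 60)
  filt <- matrix(0, nr, 60)
  for (n in seq_len(nr)) {
    ctr <- 10 + 0.5 * n
    cols <- round(ctr) + (-2:2)
    mask[n, cols] <- TRUE
    filt[n, cols] <- 50
  }
  cl <- fit_centerline(list(mask = mask, filtered = filt))
  mid <- 10:30
  expect_lt(max(abs(vapply(mid, cl$slope, numeric(1)) - 0.5)), 0.06)
})

test_that("too few valid sections is a centerline error", {
  mask <- matrix(FALSE, 10, 10); filt <- matrix(0, 10, 10)
  mask[1:5, 4:6] <- TRUE; filt[1:5, 4:6] <- 9
  expect_error(fit_centerline(list(mask = mask, filtered = filt)),
               "at least 8")
})

test_that("normals of a vertical centerline are 10-pixel horizontal runs", {
  fr <- matrix(0, 30, 30)
  fr[3:28, 9:23] <- 100
  seg <- preprocess_frame(fr, min_area = 30)
  cl <- fit_centerline(seg)
  pr <- section_profile(cl, seg$filtered, sections = 10:20)
  for (k in seq_along(pr$coords)) {
    sel <- pr$coords[[k]]
    expect_equal(nrow(sel), 10L)
    expect_equal(unique(sel[, "row"]), (10:20)[k])
    expect_equal(sel[, "col"], min(sel[, "col"]):max(sel[, "col"]),
                 ignore_attr = TRUE)
    expect_true(16 %in% sel[, "col"])             # centered on C_n = 16
  }
})

test_that("a uniform-intensity wide organ profiles to exactly that intensity", {
  fr <- matrix(0, 30, 40)
  fr[3:28, 10:29] <- 77                           # 20 px wide: normal inside
  seg <- preprocess_frame(fr, min_area = 30)
  cl <- fit_centerline(seg)
  pr <- section_profile(cl, seg$filtered, sections = 8:22)
  expect_true(all(abs(pr$values - 77) < 1e-9))
})

test_that("kymograph of a straight noiseless seedling equals ground truth", {
  # baseline above the ROI mean keeps every organ row segmented at troughs
  src <- parametric_source(phase_per_row = function(r) -0.04 * (r - 6))
  rc <- render_config(n_frames = 64, baseline = 1500, amplitude = 2000)
  st <- render_stack(src, rc)
  k <- build_kymograph(st, min_area = 30)
  expect_s3_class(k, "kymograph")
  expect_false(anyNA(k$intensity))
  # interior sections: value = baseline + amplitude * (cos(theta)+1)/2,
  # up to integer rounding and the median filter's 3-row phase mixing
  m <- st$metadata
  for (i in seq(5, length(k$sections) - 5, by = 5)) {
    r <- k$sections[i] + 1
    truth <- 1500 + 2000 * (cos(m$truth_section_phase[r, ]) + 1) / 2
    expect_lt(max(abs(k$intensity[i, ] - truth)), 3)
  }
})

test_that("rotating the stack 180 degrees reverses the section order", {
  src <- parametric_source(phase_per_row = function(r) -0.05 * (r - 6))
  st <- render_stack(src, render_config(n_frames = 48, baseline = 1500,
                                        amplitude = 1500))
  k1 <- build_kymograph(st, min_area = 30)
  st2 <- st
  st2$frames <- lapply(st$frames, function(f) f[nrow(f):1, ncol(f):1])
  k2 <- build_kymograph(st2, min_area = 30)
  nr_img <- nrow(st$frames[[1]])
  # map rotated sections back: row -> nr_img + 1 - row (both 0-based + 1)
  common <- intersect(k1$sections, nr_img - 1L - k2$sections)
  i1 <- match(common, k1$sections)
  i2 <- match(nr_img - 1L - common, k2$sections)
  expect_gt(length(common), 30)
  expect_lt(max(abs(k1$intensity[i1, ] - k2$intensity[i2, ])), 1e-9)
})

test_that("adding a constant to all frames adds it to the kymograph", {
  src <- parametric_source()
  st <- render_stack(src, render_config(n_frames = 32, baseline = 250,
                                        amplitude = 1200))
  k1 <- build_kymograph(st, min_area = 30)
  st2 <- st
  st2$frames <- lapply(st$frames, function(f) f + 100L)
  k2 <- build_kymograph(st2, min_area = 30)
  expect_equal(k2$sections, k1$sections)
  expect_equal(k2$intensity, k1$intensity + 100, tolerance = 1e-9)
})

test_that("straight and curved roots give matching kymographs per arc length", {
  src <- parametric_source(ncol_img = 26, organ_cols = 6:21,
                           phase_per_row = function(r) -0.05 * (r - 6))
  rc0 <- render_config(n_frames = 48, baseline = 1500, amplitude = 2000)
  rc1 <- render_config(n_frames = 48, baseline = 1500, amplitude = 2000,
                       curvature = c(5, 3))
  k0 <- build_kymograph(render_stack(src, rc0), min_area = 30)
  k1 <- build_kymograph(render_stack(src, rc1), min_area = 30)
  # the bend shifts rows vertically in the image; compare the overlapping
  # interior sections after aligning by section coordinate
  common <- intersect(k0$sections, k1$sections)
  common <- common[5:(length(common) - 5)]
  i0 <- match(common, k0$sections); i1 <- match(common, k1$sections)
  rel <- abs(k1$intensity[i1, ] - k0$intensity[i0, ]) /
    pmax(k0$intensity[i0, ], 1)
  expect_lt(stats::median(rel), 0.02)
  expect_lt(stats::quantile(rel, 0.95), 0.08)
})

test_that("a requested 16-section window yields 16 sections", {
  src <- parametric_source()
  st <- render_stack(src, render_config(n_frames = 24, baseline = 200,
                                        amplitude = 1000))
  k <- build_kymograph(st, sections = 10:25, min_area = 30)
  expect_equal(nrow(k$intensity), 16L)
})

test_that("an unsegmentable stack fails loudly past the 20% frame budget", {
  frames <- replicate(10, matrix(5, 30, 30), simplify = FALSE)
  st <- structure(list(frames = frames,
                       metadata = list(times = (0:9) * 1.5,
                                       frame_interval = 90)),
                  class = "lum_stack")
  expect_error(build_kymograph(st), "20%")
})
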