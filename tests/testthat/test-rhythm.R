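make_stack <- function(frames, dt_h = 1.5) {
  structure(list(frames = frames,
                 metadata = list(times = (seq_along(frames) - 1) * dt_h,
                                 frame_interval = dt_h * 60)),
            class = "lum_stack")
}

test_that("ROI median minus background mean gives the organ trace", {
  frames <- lapply(1:5, function(f) {
    m <- matrix(20, 40, 40)        # empty plate at 20 counts
    m[10:20, 10:20] <- 100 + f     # organ
    m
  })
  st <- make_stack(frames)
  tr <- extract_trace(st, center = c(15, 15), diameter = 7,
                      background = c(30, 38, 30, 38))
  expect_equal(tr$values, (100 + 1:5) - 20)
  expect_false(tr$excluded)
})

test_that("traces dipping below background are excluded with a reason", {
  frames <- lapply(1:4, function(f) {
    m <- matrix(50, 30, 30)
    m[5:15, 5:15] <- 30            # dimmer than background
    m
  })
  tr <- extract_trace(make_stack(frames), center = c(10, 10), diameter = 5,
                      background = c(25, 29, 25, 29))
  expect_true(tr$excluded)
  expect_match(tr$reason, "below zero|less than zero|minimum")
  expect_error(estimate_period(tr), "excluded")
})

test_that("the ROI median resists salt noise in up to half-minus-one pixels", {
  m <- matrix(100, 30, 30)
  st <- make_stack(list(m))
  base <- extract_trace(st, center = c(15, 15), diameter = 9)$raw
  # count ROI pixels, spike just under half of them
  rad <- 4.5
  gg <- expand.grid(r = 1:30, c = 1:30)
  inside <- (gg$r - 15)^2 + (gg$c - 15)^2 <= rad^2
  n_in <- sum(inside)
  spike_n <- (n_in - 1) %/% 2
  idx <- which(inside)[seq_len(spike_n)]
  m2 <- m
  m2[cbind(gg$r[idx], gg$c[idx])] <- 1e5
  got <- extract_trace(make_stack(list(m2)), center = c(15, 15),
                       diameter = 9)$raw
  expect_equal(got, base)
})

test_that("an ROI leaving the frame names the offending frame", {
  st <- make_stack(lapply(1:3, function(f) matrix(1, 20, 20)))
  path <- cbind(c(10, 10, 19.5), c(10, 10, 10))
  expect_error(extract_trace(st, center = path, diameter = 5), "frame 3")
})

test_that("a trended cosine is recovered as rhythmic at 24 h", {
  t <- seq(0, 144, by = 1.5)
  fit <- estimate_period(5 + 0.03 * t + cos(2 * pi * t / 24), t)
  expect_true(fit$rhythmic)
  expect_lt(abs(fit$period - 24), 0.2)
  expect_lt(fit$confidence, 0.6)
})

test_that("a 40-h cosine fits but is classed non-rhythmic", {
  t <- seq(0, 144, by = 1.5)
  fit <- estimate_period(cos(2 * pi * t / 40), t)
  expect_false(fit$rhythmic)
  expect_lt(abs(fit$period - 40), 2)    # the fit itself succeeds
})

test_that("white noise is almost never classed rhythmic", {
  t <- seq(0, 144, by = 1.5)
  set.seed(2024)
  hits <- sum(replicate(100, estimate_period(stats::rnorm(length(t)), t)$rhythmic))
  expect_lte(hits, 5)                   # >= 95% specificity
})

test_that("period estimation is invariant to affine intensity transforms", {
  t <- seq(0, 144, by = 1.5)
  set.seed(3)
  y <- exp(-0.004 * t) * cos(2 * pi * t / 26 + 1) + stats::rnorm(length(t), 0, 0.1)
  f1 <- estimate_period(y, t)
  f2 <- estimate_period(7.7 * y + 120, t)
  expect_equal(f2$period, f1$period, tolerance = 1e-6)
  expect_equal(f2$confidence, f1$confidence, tolerance = 1e-6)
  expect_equal(f2$rhythmic, f1$rhythmic)
})

test_that("damped cosines at SNR >= 5 are recovered within 2% period error", {
  t <- seq(0, 144, by = 1.5)
  set.seed(77)
  ok <- replicate(60, {
    P <- stats::runif(1, 19, 34)
    y <- exp(-stats::runif(1, 0, 0.01) * t) *
      cos(2 * pi * t / P + stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(length(t), 0, 0.2)
    f <- estimate_period(y, t)
    isTRUE(f$rhythmic) && abs(f$period - P) / P < 0.02
  })
  expect_gte(mean(ok), 0.95)
})

test_that("rhythmicity classification is reported on a labeled synthetic set", {
  t <- seq(0, 144, by = 1.5)
  set.seed(5)
  rhythmic_traces <- replicate(20, cos(2 * pi * t / stats::runif(1, 20, 30)) +
                                 stats::rnorm(length(t), 0, 0.15),
                               simplify = FALSE)
  noise_traces <- replicate(20, stats::rnorm(length(t)), simplify = FALSE)
  sens <- mean(vapply(rhythmic_traces,
                      function(y) estimate_period(y, t)$rhythmic, logical(1)))
  spec <- mean(vapply(noise_traces,
                      function(y) !estimate_period(y, t)$rhythmic, logical(1)))
  cat(sprintf("\n  rhythmicity rule: sensitivity %.2f, specificity %.2f\n",
              sens, spec))
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("analytic cosine peaks inside the window survive the rules", {
  t <- seq(0, 144, by = 0.5)
  pk <- detect_peaks(cos(2 * pi * (t - 12) / 24), t)
  expect_equal(pk$peaks, c(36, 60, 84, 108, 132), tolerance = 0.51)
  expect_true(12 %in% round(pk$discarded$time))   # first peak outside window
})

test_that("doublet peaks closer than 18 h lose the later one", {
  t <- seq(0, 144, by = 0.5)
  y <- cos(2 * pi * (t - 12) / 24)
  y <- y + 0.5 * exp(-((t - 41)^2) / 2)   # shoulder peak 5 h after t = 36
  pk <- detect_peaks(y, t, cutoff_period = 2)   # keep the doublet visible
  gaps <- diff(pk$peaks)
  expect_true(all(gaps >= 18 & gaps <= 36))
  expect_true(any(grepl("below minimum", pk$discarded$reason)))
})

test_that("high-frequency ripple does not change the peak count", {
  t <- seq(0, 144, by = 0.5)
  clean <- cos(2 * pi * (t - 12) / 24)
  noisy <- clean + 0.3 * cos(2 * pi * t / 3)
  expect_equal(length(detect_peaks(noisy, t)$peaks),
               length(detect_peaks(clean, t)$peaks))
})

test_that("cohort rule keeps only cycles completed by all organs", {
  p1 <- structure(list(peaks = c(30, 55, 80), discarded = NULL),
                  class = "peak_set")
  p2 <- structure(list(peaks = c(32, 58), discarded = NULL),
                  class = "peak_set")
  out <- common_cycles(list(a = p1, b = p2))
  expect_equal(lengths(lapply(out, `[[`, "peaks")), c(a = 2L, b = 2L))
})

test_that("summary tables report n, % rhythmic and period statistics", {
  t <- seq(0, 144, by = 1.5)
  mk <- function(P) estimate_period(cos(2 * pi * t / P), t)
  fits <- c(lapply(rep(24, 10), mk), list(mk(40)))
  organs <- c(rep("root", 10), "root")
  tab <- summarize_rhythms(fits, organs)
  expect_equal(tab$n, 11L)
  expect_equal(tab$n_rhythmic, 10L)
  expect_equal(tab$pct_rhythmic, 1000 / 11, tolerance = 0.01)
  expect_equal(tab$mean_period, 24, tolerance = 0.01)
  expect_lt(tab$sd_period, 0.01)
})

test_that("rhythm fits expose model-object methods", {
  t <- seq(0, 144, by = 1.5)
  fit <- estimate_period(3 + cos(2 * pi * t / 24), t)
  cf <- coef(fit)
  expect_named(cf, c("period", "amplitude", "damping", "phase", "confidence"))
  pr <- predict(fit)
  expect_equal(length(pr), length(fit$times))
  expect_lt(mean((pr - fit$values)^2), 0.01)
  expect_output(print(fit), "rhythmic")
})
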