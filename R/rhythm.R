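#' Extract an organ-level trace from a stack
#'
#' Per-frame median of a circular region of interest following an organ
#' centre (a fixed centre or a per-frame path), minus the per-frame mean of
#' a user-designated empty background region. Traces whose post-subtraction
#' minimum falls below zero (very low expression) are marked excluded, with
#' the reason recorded, rather than analyzed.
#'
#' @param stack a `"lum_stack"`.
#' @param center `c(row, col)` or an n_frames x 2 matrix (ROI centre path).
#' @param diameter ROI diameter in pixels.
#' @param background `c(r0, r1, c0, c1)` empty region used for background
#'   subtraction, or NULL for no subtraction.
#' @param organ optional organ label carried into summaries.
#' @return an object of class `"organ_trace"`: list with `times`, `values`
#'   (background-subtracted), `raw`, `background`, `excluded`, `reason`,
#'   `organ`.
#' @export
extract_trace <- function(stack, center, diameter, background = NULL,
                          organ = NA_character_) {
  stopifnot(inherits(stack, "lum_stack"), diameter > 0)
  nf <- length(stack$frames)
  ctr <- if (is.matrix(center)) center else
    matrix(rep(center, each = nf), nf, 2)
  stopifnot(nrow(ctr) == nf)
  d <- dim(stack$frames[[1]])
  rad <- diameter / 2
  raw <- bg <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    cr <- ctr[f, 1]; cc <- ctr[f, 2]
    if (cr - rad < 0.5 || cr + rad > d[1] + 0.5 ||
        cc - rad < 0.5 || cc + rad > d[2] + 0.5)
      stop("ROI leaves the frame at frame ", f)
    rr <- seq(max(1, floor(cr - rad)), min(d[1], ceiling(cr + rad)))
    cs <- seq(max(1, floor(cc - rad)), min(d[2], ceiling(cc + rad)))
    gg <- expand.grid(row = rr, col = cs)
    inside <- (gg$row - cr)^2 + (gg$col - cc)^2 <= rad^2
    px <- stack$frames[[f]][cbind(gg$row[inside], gg$col[inside])]
    raw[f] <- stats::median(px)
    if (!is.null(background))
      bg[f] <- mean(stack$frames[[f]][background[1]:background[2],
                                      background[3]:background[4]])
  }
  values <- if (is.null(background)) raw else raw - bg
  excluded <- min(values) < 0
  structure(list(
    times = stack$metadata$times, values = values, raw = raw,
    background = bg, excluded = excluded,
    reason = if (excluded) "minimum intensity below zero after background subtraction"
             else NA_character_,
    organ = organ
  ), class = "organ_trace")
}

#' @export
print.organ_trace <- function(x, ...) {
  cat("<organ_trace>", if (!is.na(x$organ)) x$organ else "",
      length(x$times), "frames,",
      if (x$excluded) paste("EXCLUDED:", x$reason) else "retained", "\n")
  invisible(x)
}

#' Period estimation by FFT-seeded damped-cosine least squares
#'
#' Estimates the period of a trace on an analysis window (default
#' 24-144 h): the windowed trace is baseline-detrended by subtracting a
#' least-squares polynomial of degree three, the discrete Fourier
#' transform seeds the period, amplitude and phase of a single
#' exponentially damped cosine
#' `a * exp(-d * t) * cos(2 * pi * t / P + phi)`, and Levenberg-Marquardt
#' least squares refines all four parameters. The confidence score is the
#' relative amplitude error (RAE): the half-width of the approximate 95%
#' confidence interval of the amplitude divided by the fitted amplitude,
#' so RAE near 1 means the amplitude is not distinguishable from zero. A
#' trace is classed rhythmic when the period lies in 18-36 h and the RAE
#' is below 0.6. Fit divergence yields a non-rhythmic result with the
#' reason recorded.
#'
#' The relative amplitude error stands in for the confidence score of the
#' multi-component FFT-NLLS implementations used on circadian data
#' servers, whose exact definition is not public; the 0.6 cutoff is
#' applied to it as an analog.
#'
#' @param x numeric trace, or an `"organ_trace"`.
#' @param times time stamps (h).
#' @param window analysis window `c(t_min, t_max)` in hours.
#' @param period_range rhythmic period bounds (h), default `c(18, 36)`.
#' @param conf_max rhythmicity confidence cutoff, default 0.6.
#' @param ... passed between methods.
#' @return an object of class `"rhythm_fit"`: period, amplitude, damping,
#'   phase, confidence, `rhythmic` flag, analysis window, and the fitted
#'   model. `coef()` returns the parameter vector; `predict()` evaluates
#'   the fitted damped cosine (plus baseline) at new times.
#' @examples
#' t <- seq(0, 144, by = 1.5)
#' fit <- estimate_period(cos(2 * pi * t / 24) + 0.01 * t, t)
#' coef(fit)["period"]
#' @export
estimate_period <- function(x, ...) UseMethod("estimate_period")

#' @rdname estimate_period
#' @export
estimate_period.organ_trace <- function(x, ...) {
  if (x$excluded) stop("trace was excluded: ", x$reason)
  estimate_period(x$values, x$times, ...)
}

#' @rdname estimate_period
#' @export
estimate_period.default <- function(x, times, window = c(24, 144),
                                    period_range = c(18, 36),
                                    conf_max = 0.6, ...) {
  stopifnot(length(x) == length(times))
  keep <- times >= window[1] & times <= window[2] & !is.na(x)
  tt <- times[keep] - window[1]
  y <- x[keep]
  if (length(y) < 8) stop("too few points in the analysis window")
  base_fit <- stats::lm(y ~ stats::poly(tt, 3, raw = TRUE))
  yd <- stats::residuals(base_fit)

  n <- length(yd)
  dt <- stats::median(diff(tt))
  sp <- stats::fft(yd)
  k <- seq_len(n %/% 2)                      # positive frequencies
  p_seed_all <- n * dt / k
  k_use <- k[p_seed_all >= 4 & p_seed_all <= n * dt]
  k_best <- k_use[which.max(Mod(sp[k_use + 1L]))]
  start <- list(a = as.numeric(2 * Mod(sp[k_best + 1L]) / n), d = 0,
                P = as.numeric(n * dt / k_best),
                phi = as.numeric(Arg(sp[k_best + 1L])))

  fail <- function(reason) {
    structure(list(period = NA_real_, amplitude = NA_real_,
                   damping = NA_real_, phase = NA_real_,
                   confidence = Inf, rhythmic = FALSE, reason = reason,
                   window = window, times = times[keep], values = y,
                   detrended = yd, baseline = base_fit, fit = NULL),
              class = "rhythm_fit")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yd ~ a * exp(-d * tt) * cos(2 * pi * tt / P + phi),
      start = start,
      lower = c(a = 0, d = -0.5, P = 4, phi = -2 * pi),
      upper = c(a = Inf, d = 0.5, P = 10 * diff(range(tt)), phi = 2 * pi),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear fit did not converge"))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  conf <- unname(stats::qnorm(0.975) * se["a"] / abs(cf["a"]))
  if (!is.finite(conf)) conf <- Inf
  rhythmic <- is.finite(cf["P"]) && cf["P"] >= period_range[1] &&
    cf["P"] <= period_range[2] && conf < conf_max
  structure(list(period = unname(cf["P"]), amplitude = unname(cf["a"]),
                 damping = unname(cf["d"]), phase = unname(cf["phi"]),
                 confidence = conf, rhythmic = rhythmic,
                 reason = if (rhythmic) NA_character_ else
                   "period outside range or confidence above cutoff",
                 window = window, times = times[keep], values = y,
                 detrended = yd, baseline = base_fit, fit = fit),
            class = "rhythm_fit")
}

#' @export
print.rhythm_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    cat("<rhythm_fit> non-rhythmic:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<rhythm_fit> period %.2f h, amplitude %.3g, damping %.3g /h, RAE %.3f -> %s\n",
      x$period, x$amplitude, x$damping, x$confidence,
      if (x$rhythmic) "rhythmic" else paste("non-rhythmic (", x$reason, ")")))
  }
  invisible(x)
}

#' @export
coef.rhythm_fit <- function(object, ...) {
  c(period = object$period, amplitude = object$amplitude,
    damping = object$damping, phase = object$phase,
    confidence = object$confidence)
}

#' @export
predict.rhythm_fit <- function(object, times = object$times, ...) {
  if (is.null(object$fit)) stop("no converged fit to predict from")
  tt <- times - object$window[1]
  base <- stats::predict(object$baseline,
                         newdata = data.frame(tt = tt))
  base + object$amplitude * exp(-object$damping * tt) *
    cos(2 * pi * tt / object$period + object$phase)
}

#' @export
plot.rhythm_fit <- function(x, ...) {
  graphics::plot(x$times, x$values, xlab = "time (h)", ylab = "intensity",
                 ...)
  if (!is.null(x$fit))
    graphics::lines(x$times, predict(x, x$times), col = 2, lwd = 2)
  invisible(x)
}

#' Peak detection with spacing rules
#'
#' Zero-phase (forward-backward) third-order low-pass Butterworth
#' filtering removes high-frequency noise, local maxima are detected, and
#' peaks are then filtered: only peaks inside the analysis window are
#' retained, and a peak is discarded when its spacing from the previously
#' retained peak falls outside 18-36 h. Discarded peaks are reported with
#' reasons.
#'
#' @param x numeric trace, or an `"organ_trace"`.
#' @param times time stamps (h); sampling interval must be <= 3 h.
#' @param window retention window `c(t_min, t_max)` in hours (default
#'   24-144).
#' @param cutoff_period Butterworth low-pass cutoff period (h), default 10.
#' @param spacing allowed consecutive peak spacing `c(min, max)` in hours.
#' @param ... passed between methods.
#' @return an object of class `"peak_set"`: list with `peaks` (times, h)
#'   and `discarded` (data frame of time + reason).
#' @export
detect_peaks <- function(x, ...) UseMethod("detect_peaks")

#' @rdname detect_peaks
#' @export
detect_peaks.organ_trace <- function(x, ...) detect_peaks(x$values, x$times, ...)

#' @rdname detect_peaks
#' @export
detect_peaks.default <- function(x, times, window = c(24, 144),
                                 cutoff_period = 10, spacing = c(18, 36),
                                 ...) {
  stopifnot(length(x) == length(times))
  dt <- stats::median(diff(times))
  if (dt > 3) stop("sampling interval must be <= 3 h for peak analysis")
  wn <- 2 * dt / cutoff_period          # cutoff relative to Nyquist
  filt <- if (wn < 1) {
    bw <- signal::butter(3, wn, type = "low")
    signal::filtfilt(bw, x)
  } else x
  pk <- pracma::findpeaks(as.vector(filt), nups = 1, ndowns = 1)
  empty <- function(reason) structure(
    list(peaks = numeric(0),
         discarded = data.frame(time = numeric(0), reason = character(0)),
         reason = reason),
    class = "peak_set")
  if (is.null(pk)) return(empty("no local maxima detected"))
  pt <- sort(times[pk[, 2]])
  disc <- data.frame(time = numeric(0), reason = character(0))
  inw <- pt >= window[1] & pt <= window[2]
  if (any(!inw))
    disc <- rbind(disc, data.frame(time = pt[!inw], reason = "outside window"))
  pt <- pt[inw]
  keep <- numeric(0)
  for (p in pt) {
    if (!length(keep)) { keep <- p; next }
    gap <- p - keep[length(keep)]
    if (gap < spacing[1]) {
      disc <- rbind(disc, data.frame(time = p, reason = "spacing below minimum"))
    } else if (gap > spacing[2]) {
      disc <- rbind(disc, data.frame(time = p, reason = "spacing above maximum"))
    } else keep <- c(keep, p)
  }
  if (!length(keep)) return(empty("no peak satisfied window and spacing rules"))
  structure(list(peaks = keep, discarded = disc, reason = NA_character_),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set>", length(x$peaks), "retained peaks",
      if (length(x$peaks)) paste0("(", paste(round(x$peaks, 2), collapse = ", "), ")"),
      "-", nrow(x$discarded), "discarded\n")
  invisible(x)
}

#' Retain only cycles completed by every organ
#'
#' Cohort rule for peak-time comparisons: given one peak set per organ of
#' a seedling, keeps the first k peaks of each organ, where k is the
#' smallest retained-peak count across organs, so that every compared
#' cycle is complete in all organs.
#'
#' @param peaksets named list of `"peak_set"` objects.
#' @return the list with each `peaks` truncated to the common cycle count.
#' @export
common_cycles <- function(peaksets) {
  stopifnot(length(peaksets) > 0)
  k <- min(vapply(peaksets, function(p) length(p$peaks), integer(1)))
  lapply(peaksets, function(p) { p$peaks <- utils::head(p$peaks, k); p })
}

#' Summary table across organs and seedlings
#'
#' Descriptive statistics in the reporting style of organ-level rhythm
#' analyses: per organ, the number of traces, percentage rhythmic, mean
#' and SD of rhythmic periods, and quartiles of retained peak times.
#'
#' @param fits list of `"rhythm_fit"` objects.
#' @param organs character vector of organ labels, one per fit.
#' @param peaksets optional list of `"peak_set"` objects, one per fit.
#' @return a data frame, one row per organ.
#' @export
summarize_rhythms <- function(fits, organs, peaksets = NULL) {
  stopifnot(length(fits) == length(organs))
  periods <- vapply(fits, function(f) f$period, numeric(1))
  rhythmic <- vapply(fits, function(f) isTRUE(f$rhythmic), logical(1))
  out <- lapply(unique(organs), function(org) {
    i <- which(organs == org)
    ir <- i[rhythmic[i]]
    pq <- c(NA_real_, NA_real_, NA_real_)
    if (!is.null(peaksets)) {
      pt <- unlist(lapply(peaksets[i], function(p) p$peaks))
      if (length(pt)) pq <- unname(stats::quantile(pt, c(0.25, 0.5, 0.75)))
    }
    data.frame(organ = org, n = length(i), n_rhythmic = length(ir),
               pct_rhythmic = 100 * length(ir) / length(i),
               mean_period = if (length(ir)) mean(periods[ir]) else NA_real_,
               sd_period = if (length(ir) > 1) stats::sd(periods[ir]) else
                 if (length(ir) == 1) 0 else NA_real_,
               peak_q25 = pq[1], peak_median = pq[2], peak_q75 = pq[3])
  })
  do.call(rbind, out)
}
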