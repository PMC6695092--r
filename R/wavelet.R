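#' Morlet mother wavelet
#'
#' Evaluates \eqn{Z(u) = \pi^{-1/4} e^{6iu} e^{-u^2/2}}: a complex
#' exponential of centre frequency 6 under a Gaussian envelope, localized
#' in time and (effectively) zero-mean.
#'
#' @param u dimensionless time.
#' @return complex values of the mother wavelet.
#' @examples
#' morlet(0)            # pi^(-1/4), purely real
#' Mod(morlet(1.3))     # envelope exp(-u^2/2)/pi^(1/4)
#' @export
morlet <- function(u) {
  pi^(-1 / 4) * exp(6i * u) * exp(-u^2 / 2)
}

#' Convert a target period to the matching wavelet scale
#'
#' With centre frequency 6, the transform's phase advances by 6/s per
#' sample, so the wavelet pseudo-period is `2*pi*s*dt/6` hours; the scale
#' matched to a period P sampled every `dt` hours is `6*P/(2*pi*dt)`.
#'
#' @param period target period (h).
#' @param dt sampling interval of the series (h).
#' @return dimensionless scale s.
#' @export
scale_for_period <- function(period, dt) {
  stopifnot(period > 0, dt > 0)
  6 * period / (2 * pi * dt)
}

#' Single-scale continuous wavelet transform phase of a series
#'
#' Direct evaluation of the discrete transform
#' \eqn{W_s(t) = s^{-1/2} \sum_p V_p Z^*((p - t)/s)} at every integer
#' sample index t (no FFT shortcut), returning the instantaneous phase
#' \eqn{\varphi = \arg W_s} wrapped to (-pi, pi] and magnitude
#' \eqn{q = |W_s|}. Since the mother wavelet is zero-mean with a
#' unit-modulus oscillatory factor, the phase is invariant to positive
#' rescaling of the series and (in the interior) to constant offsets. The
#' edge region within `sqrt(2) * s` samples of either end is flagged as
#' cone of influence. An all-constant series has zero magnitude and
#' undefined (NA) phase.
#'
#' @param v numeric series (finite; interpolate gaps first).
#' @param scale dimensionless scale s (> 0); see [scale_for_period()].
#' @return list with `phase`, `magnitude`, `coi` (logical edge flags) and
#'   `scale`.
#' @examples
#' t <- 0:95
#' cw <- cwt_phase(cos(2 * pi * t / 16), scale_for_period(24, 1.5))
#' @export
cwt_phase <- function(v, scale) {
  stopifnot(scale > 0, is.numeric(v))
  if (anyNA(v) || any(!is.finite(v)))
    stop("series must be finite; interpolate missing points first")
  n <- length(v)
  if (stats::sd(v) == 0) {
    return(list(phase = rep(NA_real_, n), magnitude = rep(0, n),
                coi = rep(TRUE, n), scale = scale))
  }
  idx <- seq_len(n)
  U <- (matrix(idx, n, n, byrow = TRUE) - idx) / scale   # (p - t)/s
  K <- Conj(morlet(U)) / sqrt(scale)
  W <- as.vector(K %*% v)
  coi_w <- sqrt(2) * scale
  coi <- (idx - 1) < coi_w | (n - idx) < coi_w
  list(phase = Arg(W), magnitude = Mod(W), coi = coi, scale = scale)
}

#' Phase space-time plot from a kymograph
#'
#' Applies the single-scale Morlet transform to every kymograph row with
#' one scale per organ/condition, chosen so the wavelet pseudo-period
#' matches `period_hint` (when NULL, the hint is estimated from the
#' section-mean trace by damped-cosine fitting, falling back to 24 h).
#' Phases are additionally recomputed at s perturbed by +/-10%; interior
#' sections whose phase moves by 0.1 rad or more are flagged (robustness
#' to the scale choice), not dropped.
#'
#' @param kymo a `"kymograph"`.
#' @param period_hint characteristic period (h) used for scale matching,
#'   or NULL to estimate it.
#' @param max_gap longest missing run interpolated before transforming.
#' @return an object of class `"phase_map"`: list with `phase` (sections x
#'   frames, radians in (-pi, pi]), `magnitude`, `coi` (logical matrix),
#'   `flagged_sections`, `scale`, `period` (h), `sections`, `times`.
#' @export
phase_map <- function(kymo, period_hint = NULL, max_gap = 2L) {
  stopifnot(inherits(kymo, "kymograph"))
  dt <- stats::median(diff(kymo$times))
  if (is.null(period_hint)) {
    mean_trace <- colMeans(kymo$intensity, na.rm = TRUE)
    fit <- tryCatch(
      estimate_period(mean_trace, kymo$times,
                      window = range(kymo$times)),
      error = function(e) NULL)
    period_hint <- if (!is.null(fit) && isTRUE(fit$rhythmic)) fit$period else 24
  }
  s <- scale_for_period(period_hint, dt)
  nr <- nrow(kymo$intensity); nf <- ncol(kymo$intensity)
  ph <- mag <- matrix(NA_real_, nr, nf, dimnames = dimnames(kymo$intensity))
  coi <- matrix(TRUE, nr, nf)
  flagged <- logical(nr)
  for (r in seq_len(nr)) {
    v <- fill_gaps(kymo$intensity[r, ], max_gap = max_gap)
    if (anyNA(v)) { flagged[r] <- TRUE; next }
    w <- cwt_phase(v, s)
    ph[r, ] <- w$phase; mag[r, ] <- w$magnitude; coi[r, ] <- w$coi
    # robustness is judged on a deeper interior (2 scale widths from the
    # edges) than the cone-of-influence flag: the Gaussian envelope still
    # carries ~e^-1 weight at the sqrt(2)*s boundary, inflating the
    # sensitivity to s right at the cone edge
    ii <- seq_len(nf)
    interior <- (ii - 1) >= 2 * s & (nf - ii) >= 2 * s
    if (any(interior)) {
      up <- cwt_phase(v, s * 1.1)$phase
      dn <- cwt_phase(v, s * 0.9)$phase
      dev <- pmax(abs(phase_diff(up[interior], w$phase[interior])),
                  abs(phase_diff(dn[interior], w$phase[interior])))
      if (any(dev >= 0.1, na.rm = TRUE)) flagged[r] <- TRUE
    }
  }
  structure(list(phase = ph, magnitude = mag, coi = coi,
                 flagged_sections = which(flagged), scale = s,
                 period = period_hint, sections = kymo$sections,
                 times = kymo$times),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf(
    "<phase_map> %d sections x %d frames, scale %.2f (period %.2f h), %d flagged\n",
    nrow(x$phase), ncol(x$phase), x$scale, x$period,
    length(x$flagged_sections)))
  invisible(x)
}

#' @param x a `"phase_map"`.
#' @param ... passed to [graphics::image()].
#' @rdname phase_map
#' @export
plot.phase_map <- function(x, ...) {
  graphics::image(x$times, x$sections, t(x$phase),
                  col = grDevices::hsv(seq(0, 1, length.out = 65)[-65]),
                  zlim = c(-pi, pi),
                  xlab = "time (h)", ylab = "section (px from organ top)",
                  ylim = rev(range(x$sections)), ...)
  invisible(x)
}
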