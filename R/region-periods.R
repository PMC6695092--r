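#' Mean peak-to-peak period of a trace
#'
#' Detects local maxima of a (smooth) trace and returns the mean of
#' consecutive peak-to-peak intervals. Traces with fewer than two peaks
#' yield NA.
#'
#' @param values numeric trace.
#' @param times time stamps (h), same length.
#' @return list with `period` (h, NA if < 2 peaks), `peak_times` and
#'   `n_peaks`.
#' @examples
#' t <- seq(0, 120, by = 0.5)
#' peak_to_peak_period(cos(2 * pi * t / 24), t)$period
#' @export
peak_to_peak_period <- function(values, times) {
  stopifnot(length(values) == length(times))
  ok <- !is.na(values)
  v <- values[ok]; tt <- times[ok]
  if (length(v) < 3)
    return(list(period = NA_real_, peak_times = numeric(0), n_peaks = 0L))
  pk <- pracma::findpeaks(as.vector(v), nups = 1, ndowns = 1)
  if (is.null(pk) || nrow(pk) < 2)
    return(list(period = NA_real_,
                peak_times = if (is.null(pk)) numeric(0) else tt[pk[, 2]],
                n_peaks = if (is.null(pk)) 0L else nrow(pk)))
  pt <- sort(tt[pk[, 2]])
  list(period = mean(diff(pt)), peak_times = pt, n_peaks = length(pt))
}

#' Organ-level periods from simulated expression
#'
#' For each organ, takes the median simulated expression trace over a
#' designated 5x5-pixel region (cotyledon, hypocotyl and root regions are
#' static template windows; the root-tip region is the current 5x5 tip
#' block, which advances with growth), detects its peaks and returns the
#' mean peak-to-peak period. Organs whose median trace shows fewer than two
#' peaks are omitted with a warning.
#'
#' @param x a `"clock_sim"` or `"clock_seedling"` object.
#' @param ... unused.
#' @return a data frame with columns `seedling`, `organ`, `period` (h) and
#'   `n_peaks`.
#' @export
region_periods <- function(x, ...) UseMethod("region_periods")

#' @export
region_periods.clock_sim <- function(x, ...) {
  out <- lapply(seq_along(x$seedlings), function(s) {
    df <- region_periods(x$seedlings[[s]])
    df$seedling <- rep(s, nrow(df))
    df
  })
  do.call(rbind, out)[, c("seedling", "organ", "period", "n_peaks")]
}

#' @export
region_periods.clock_seedling <- function(x, ...) {
  tpl <- x$template
  gi <- cos(x$theta) + 1
  cc <- attr(tpl, "center_col")
  half <- 2L

  static_region <- function(organ, center_row) {
    which(tpl$organ == organ & tpl$birth == 0 &
            abs(tpl$row - center_row) <= half & abs(tpl$col - cc) <= half)
  }
  cot <- attr(tpl, "cot_center")
  hyp <- attr(tpl, "hyp_rows"); root <- attr(tpl, "root_rows0")
  regions <- list(
    cotyledon = static_region("cotyledon", cot[["row"]]),
    hypocotyl = static_region("hypocotyl", floor(mean(hyp))),
    root = static_region("root", floor(mean(root)))
  )

  med_trace <- function(idx) apply(gi[idx, , drop = FALSE], 2,
                                   stats::median, na.rm = TRUE)
  res <- lapply(names(regions), function(org) {
    p <- peak_to_peak_period(med_trace(regions[[org]]), x$times)
    data.frame(organ = org, period = p$period, n_peaks = p$n_peaks)
  })

  # root tip: median over the tip block tracked through growth
  tip0 <- attr(tpl, "tip_rows0")
  tip_trace <- vapply(seq_along(x$times), function(si) {
    rows <- tip_rows_at(tpl, x$times[si])
    i <- which(tpl$row %in% rows & !is.na(x$theta[, si]))
    if (!length(i)) return(NA_real_)
    stats::median(gi[i, si])
  }, numeric(1))
  p <- peak_to_peak_period(tip_trace, x$times)
  res <- c(res, list(data.frame(organ = "root_tip", period = p$period,
                                n_peaks = p$n_peaks)))
  out <- do.call(rbind, res)
  drop <- is.na(out$period)
  if (any(drop))
    warning("organs with < 2 expression peaks omitted: ",
            paste(out$organ[drop], collapse = ", "))
  out[!drop, , drop = FALSE]
}

#' Kuramoto order parameter
#'
#' Synchrony of a set of phase oscillators per time point:
#' \eqn{R(t) = |N^{-1} \sum_j e^{i\theta_j(t)}|}, ranging from 0 (complete
#' desynchrony) to 1 (complete synchrony). For simulated seedlings the
#' phasor average runs over hypocotyl and root (including root tip) pixels;
#' cotyledon pixels are excluded.
#'
#' @param x a phase matrix (oscillators x time points, radians) or a
#'   `"clock_seedling"`.
#' @param na.rm for the matrix method: drop undefined phases within a
#'   frame (TRUE) or mark the frame NA and flag it (FALSE, default).
#' @param ... unused.
#' @return numeric vector R(t), one value per time point (attribute
#'   `"flagged"` lists skipped frames for the matrix method).
#' @examples
#' order_parameter(matrix(rep(1.3, 300), nrow = 100))  # identical phases
#' @export
order_parameter <- function(x, ...) UseMethod("order_parameter")

#' @rdname order_parameter
#' @export
order_parameter.matrix <- function(x, na.rm = FALSE, ...) {
  if (nrow(x) < 2) stop("need at least 2 oscillators")
  z <- exp(1i * x)
  if (na.rm) {
    r <- apply(z, 2, function(col) Mod(mean(col[!is.na(col)])))
  } else {
    r <- Mod(colMeans(z))
    flagged <- which(is.na(r))
    attr(r, "flagged") <- flagged
  }
  r
}

#' @rdname order_parameter
#' @export
order_parameter.clock_seedling <- function(x, ...) {
  keep <- x$template$organ != "cotyledon"
  order_parameter(x$theta[keep, , drop = FALSE], na.rm = TRUE)
}
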