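#' Preprocess one luminescence frame
#'
#' Applies the kymograph preprocessing chain to a region of interest:
#' exact 3x3 median filter (removes isolated cosmic-ray spikes), strict
#' thresholding at the ROI mean of the filtered image (constant frames
#' segment to empty), and removal of 8-connected components smaller than
#' `min_area` pixels.
#'
#' @param frame numeric matrix of counts.
#' @param roi integer vector `c(r0, r1, c0, c1)` (inclusive bounds) or NULL
#'   for the whole frame.
#' @param min_area minimum connected-component area kept (px, default 50).
#' @return list with `mask` (logical), `filtered` (median-filtered ROI),
#'   `threshold`, `n_removed` (small components dropped) and `empty`.
#' @export
preprocess_frame <- function(frame, roi = NULL, min_area = 50L) {
  stopifnot(is.matrix(frame))
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4, roi[1] >= 1, roi[3] >= 1,
              roi[2] <= nrow(frame), roi[4] <= ncol(frame),
              roi[1] <= roi[2], roi[3] <= roi[4])
    frame <- frame[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  }
  filt <- median_filter3(frame)
  thr <- mean(filt)
  mask <- filt > thr
  n_removed <- 0L
  if (any(mask)) {
    lab <- label_components(mask, connectivity = 8)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_area)
    if (length(small)) {
      mask[lab %in% small] <- FALSE
      n_removed <- length(small)
    }
  }
  list(mask = mask, filtered = filt, threshold = thr,
       n_removed = n_removed, empty = !any(mask))
}

#' Fit the organ centerline of one frame
#'
#' Computes the grey-level-weighted centroid of the segmented pixels of
#' each vertical section (image row) n,
#' \eqn{C_n = \sum_m m W_{m,n} / \sum_m W_{m,n}} with m the column index
#' and W the filtered intensity, then fits a least-squares polynomial of
#' seventh degree through the centroids (in a centred/scaled row
#' coordinate for conditioning). The analytic derivative of the fit gives
#' the tangent slope at every section; the normal is perpendicular to it.
#'
#' @param seg output of [preprocess_frame()].
#' @param degree polynomial degree (7, per the procedure).
#' @return list of class `"centerline"` with `centroids` (NA where a
#'   section has no mask), `rows` (valid section indices), `predict`
#'   (function row -> fitted column) and `slope` (function row -> dC/dn).
#' @export
fit_centerline <- function(seg, degree = 7L) {
  mask <- seg$mask; w <- seg$filtered
  cent <- rep(NA_real_, nrow(mask))
  for (n in seq_len(nrow(mask))) {
    m <- which(mask[n, ])
    if (!length(m)) next
    wm <- w[n, m]
    cent[n] <- sum(m * wm) / sum(wm)
  }
  rows <- which(!is.na(cent))
  if (length(rows) < degree + 1L)
    stop("centerline fit needs at least ", degree + 1L,
         " sections with segmented pixels (got ", length(rows), ")")
  mu <- mean(rows); sdv <- stats::sd(rows)
  if (sdv == 0) sdv <- 1
  z <- (rows - mu) / sdv
  cf <- pracma::polyfit(z, cent[rows], degree)
  dcf <- pracma::polyder(cf)
  structure(list(
    centroids = cent, rows = rows, degree = degree,
    predict = function(n) pracma::polyval(cf, (n - mu) / sdv),
    slope = function(n) pracma::polyval(dcf, (n - mu) / sdv) / sdv
  ), class = "centerline")
}

#' Intensity profile along normal sections
#'
#' For each requested section (image row), rasterizes the line normal to
#' the fitted centerline through the point (row, C(row)) with the
#' Bresenham algorithm, keeps the `n_keep` rasterized pixels nearest the
#' intersection with the curve (a contiguous run centred on the nearest
#' rasterized pixel), and returns the mean filtered intensity over the
#' kept in-bounds pixels. Normals exiting the image are truncated and
#' flagged.
#'
#' @param cl a `"centerline"` from [fit_centerline()].
#' @param image intensity matrix to sample (typically the filtered ROI).
#' @param sections section rows to profile (default: all rows with a
#'   defined centroid).
#' @param n_keep pixels kept per normal (default 10).
#' @return list with `values` (mean intensity per section, NA where
#'   undefined), `truncated` (logical per section) and `coords` (list of
#'   kept pixel coordinate matrices).
#' @export
section_profile <- function(cl, image, sections = cl$rows, n_keep = 10L) {
  nr <- nrow(image); nc <- ncol(image)
  values <- rep(NA_real_, length(sections))
  truncated <- logical(length(sections))
  coords <- vector("list", length(sections))
  for (k in seq_along(sections)) {
    n <- sections[k]
    C <- cl$predict(n)
    g <- cl$slope(n)
    nrm <- c(-g, 1) / sqrt(1 + g^2)   # (drow, dcol), unit normal
    p0 <- c(n, C) - n_keep * nrm
    p1 <- c(n, C) + n_keep * nrm
    pts <- bresenham(p0[1], p0[2], p1[1], p1[2])
    d2 <- (pts[, 1] - n)^2 + (pts[, 2] - C)^2
    i0 <- which.min(d2)
    lo <- i0 - (n_keep %/% 2L - 1L)
    hi <- i0 + n_keep %/% 2L
    if (lo < 1L) { hi <- hi - lo + 1L; lo <- 1L }
    if (hi > nrow(pts)) { lo <- max(1L, lo - (hi - nrow(pts))); hi <- nrow(pts) }
    sel <- pts[lo:hi, , drop = FALSE]
    inb <- sel[, 1] >= 1 & sel[, 1] <= nr & sel[, 2] >= 1 & sel[, 2] <= nc
    truncated[k] <- any(!inb)
    sel <- sel[inb, , drop = FALSE]
    if (!nrow(sel)) next
    coords[[k]] <- sel
    values[k] <- mean(image[sel])
  }
  list(values = values, sections = sections, truncated = truncated,
       coords = coords)
}

#' Build a space-time intensity plot (kymograph)
#'
#' Runs segmentation, centerline fitting and normal-section profiling on
#' every frame of a stack and assembles the section x time intensity
#' matrix. Per-frame failures (empty mask, too few centroid sections) are
#' recorded; more than 20% failed frames is an error. Sections missing in
#' single frames are linearly interpolated in time for gaps of at most
#' `max_gap` frames, longer gaps stay missing.
#'
#' @param stack a `"lum_stack"` (see [render_stack()] / [read_stack()]).
#' @param roi `c(r0, r1, c0, c1)` region of interest, or NULL for the full
#'   frame.
#' @param sections section rows (1-based, relative to the ROI top) to keep;
#'   NULL keeps every section with a defined value in at least 80% of
#'   frames.
#' @param n_keep pixels averaged per normal section (default 10).
#' @param min_area minimum segmented component area (px).
#' @param max_gap longest missing run (frames) filled by interpolation.
#' @return an object of class `"kymograph"`: list with `intensity`
#'   (sections x frames; rownames are 0-based section coordinates from the
#'   organ top), `sections`, `times` (h) and `qc` (thresholds,
#'   removed-object counts, failed frames).
#' @export
build_kymograph <- function(stack, roi = NULL, sections = NULL,
                            n_keep = 10L, min_area = 50L, max_gap = 2L) {
  stopifnot(inherits(stack, "lum_stack"))
  nf <- length(stack$frames)
  nr <- if (is.null(roi)) nrow(stack$frames[[1]]) else roi[2] - roi[1] + 1L
  vals <- matrix(NA_real_, nr, nf)
  thresholds <- rep(NA_real_, nf)
  removed <- rep(NA_integer_, nf)
  failed <- logical(nf)
  for (f in seq_len(nf)) {
    seg <- preprocess_frame(stack$frames[[f]], roi, min_area)
    thresholds[f] <- seg$threshold
    removed[f] <- seg$n_removed
    if (seg$empty) { failed[f] <- TRUE; next }
    cl <- tryCatch(fit_centerline(seg), error = function(e) NULL)
    if (is.null(cl)) { failed[f] <- TRUE; next }
    pr <- section_profile(cl, seg$filtered, sections = cl$rows,
                          n_keep = n_keep)
    vals[pr$sections, f] <- pr$values
  }
  if (mean(failed) > 0.2)
    stop("more than 20% of frames failed preprocessing (",
         sum(failed), "/", nf, ")")
  keep <- if (is.null(sections)) {
    which(rowMeans(!is.na(vals)) >= 0.8)
  } else sections
  if (!length(keep)) stop("no usable sections")
  intensity <- vals[keep, , drop = FALSE]
  intensity <- t(apply(intensity, 1, fill_gaps, max_gap = max_gap))
  times <- stack$metadata$times %||%
    ((seq_len(nf) - 1) * (stack$metadata$frame_interval %||% 90) / 60)
  dimnames(intensity) <- list(keep - 1L, signif(times, 8))
  structure(list(intensity = intensity, sections = keep - 1L, times = times,
                 roi = roi,
                 qc = list(thresholds = thresholds, removed = removed,
                           failed_frames = which(failed))),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d sections x %d frames (%g-%g h), %d failed frames\n",
              nrow(x$intensity), ncol(x$intensity), min(x$times), max(x$times),
              length(x$qc$failed_frames)))
  invisible(x)
}

#' @param x a `"kymograph"`.
#' @param ... passed to [graphics::image()].
#' @rdname build_kymograph
#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x$times, x$sections, t(x$intensity),
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "time (h)", ylab = "section (px from organ top)",
                  ylim = rev(range(x$sections)), ...)
  invisible(x)
}
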