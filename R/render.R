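#' Render a synthetic luminescence time-lapse stack
#'
#' Produces a multi-frame stack of photon-count images with the statistical
#' structure of real luciferase movies. Inside the (optionally curved)
#' seedling mask the clean pixel value at frame time t is
#' `baseline + amplitude * exp(-damping_rate * t) * (cos(theta) + 1) / 2`
#' (0 outside the mask); noise is applied next, then isolated single-pixel
#' cosmic-ray spikes (`Poisson(spike_rate)` per frame, value
#' `spike_amplitude`). Ground-truth phases travel only in the metadata,
#' never in pixel data.
#'
#' @param source either a `"clock_seedling"` from [simulate_clock()] (frame
#'   times must lie on its storage grid) or a parametric specification: a
#'   list with `mask` (logical matrix), `period` (h; scalar or matrix) and
#'   optional `phase0` (radians at t = 0; scalar or matrix, default 0).
#' @param rcfg a [render_config()].
#' @return an object of class `"lum_stack"`: list with `frames` (list of
#'   integer count matrices) and `metadata` (frame interval, times in h
#'   relative to dawn, config echo, and ground truth: per-pixel phase
#'   matrix plus its per-image-row circular mean `truth_section_phase`).
#' @examples
#' src <- list(mask = matrix(TRUE, 12, 4), period = 24)
#' st <- render_stack(src, render_config(n_frames = 8))
#' st
#' @export
render_stack <- function(source, rcfg) {
  stopifnot(inherits(rcfg, "render_config"))
  set.seed(rcfg$rng_seed)
  times <- (seq_len(rcfg$n_frames) - 1L) * rcfg$frame_interval / 60

  if (inherits(source, "clock_seedling")) {
    tpl <- source$template
    ti <- match(round(times, 6), round(source$times, 6))
    if (anyNA(ti))
      stop("frame times must lie on the simulation storage grid")
    theta <- source$theta[, ti, drop = FALSE]
    rr <- tpl$row; cl <- tpl$col
  } else {
    if (!is.matrix(source$mask))
      stop("parametric source needs a logical 'mask' matrix")
    idx <- which(source$mask)
    rr <- (idx - 1L) %% nrow(source$mask) + 1L
    cl <- (idx - 1L) %/% nrow(source$mask) + 1L
    per <- source$period
    per <- if (is.matrix(per)) per[idx] else rep_len(per, length(idx))
    ph0 <- source$phase0 %||% 0
    ph0 <- if (is.matrix(ph0)) ph0[idx] else rep_len(ph0, length(idx))
    theta <- outer(2 * pi / per, times) + ph0
    theta <- wrap_phase(theta)
  }

  # curvature: horizontal shear below the hypocotyl (or of the whole mask
  # for parametric sources when no organ labels exist)
  rows_img <- rr; cols_img <- cl
  if (any(rcfg$curvature != 0)) {
    if (inherits(source, "clock_seedling")) {
      r0 <- attr(source$template, "root_rows0")[1]
    } else r0 <- min(rr)
    rmax <- max(rr)
    z <- pmax(0, (rr - r0) / max(1, rmax - r0))
    shift <- round(rcfg$curvature[1] * z +
                     (if (length(rcfg$curvature) > 1) rcfg$curvature[2] else 0) * z^2)
    cols_img <- cl + as.integer(shift)
  }
  m <- rcfg$margin
  rows_img <- rows_img - min(rows_img) + 1L + m
  cols_img <- cols_img - min(cols_img) + 1L + m
  nr <- max(rows_img) + m
  nc <- max(cols_img) + m

  lin <- cbind(rows_img, cols_img)
  bg <- rcfg$background_gradient %||% c(0, 0)
  bg_img <- if (any(bg != 0))
    outer(seq_len(nr) * bg[1], rep(1, nc)) +
      outer(rep(1, nr), seq_len(nc) * bg[2]) else 0
  env <- rcfg$amplitude * exp(-rcfg$damping_rate * times)
  frames <- vector("list", rcfg$n_frames)
  clipped <- FALSE
  for (f in seq_len(rcfg$n_frames)) {
    img <- matrix(0, nr, nc)
    val <- rcfg$baseline + env[f] * (cos(theta[, f]) + 1) / 2
    val[is.na(val)] <- 0
    img[lin] <- val
    img <- img + bg_img
    if (!is.null(rcfg$neighbor_offset)) {
      off <- rcfg$neighbor_offset
      r2 <- rows_img + off[1]; c2 <- cols_img + off[2]
      keep <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      img[cbind(r2[keep], c2[keep])] <- img[cbind(r2[keep], c2[keep])] +
        0.2 * val[keep]
    }
    if (rcfg$noise_model == "gaussian" && rcfg$noise_scale > 0) {
      img <- img + matrix(stats::rnorm(nr * nc, 0, rcfg$noise_scale), nr, nc)
    } else if (rcfg$noise_model == "poisson") {
      img <- matrix(stats::rpois(nr * nc, pmax(0, img)), nr, nc)
    }
    nsp <- stats::rpois(1, rcfg$spike_rate)
    if (nsp > 0) {
      sp <- sample.int(nr * nc, min(nsp, nr * nc))
      img[sp] <- rcfg$spike_amplitude
    }
    img <- round(pmax(img, 0))
    frames[[f]] <- matrix(as.integer(img), nr, nc)
  }

  # section-level ground truth: circular mean phase per image row
  truth_section <- matrix(NA_real_, nr, rcfg$n_frames)
  for (r in sort(unique(rows_img))) {
    i <- which(rows_img == r)
    truth_section[r, ] <- Arg(colSums(exp(1i * theta[i, , drop = FALSE]),
                                      na.rm = TRUE))
  }

  structure(list(
    frames = frames,
    metadata = list(frame_interval = rcfg$frame_interval, times = times,
                    t0_after_dawn = 0, regime = "synthetic",
                    config = unclass(rcfg),
                    truth_phase = theta,
                    truth_rows = rows_img, truth_cols = cols_img,
                    truth_section_phase = truth_section)
  ), class = "lum_stack")
}

#' @export
print.lum_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<lum_stack> %d frames of %d x %d px, every %g min\n",
              length(x$frames), d[1], d[2], x$metadata$frame_interval))
  invisible(x)
}

#' Write a luminescence stack to a multi-frame 16-bit TIFF plus sidecar
#'
#' Counts above 65535 are clipped at the writer with a warning. Metadata
#' (acquisition parameters and section-level ground truth, when present)
#' goes to a JSON sidecar at `<path>.json`.
#'
#' @param stack a `"lum_stack"`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "lum_stack"))
  frames <- stack$frames
  mx <- max(vapply(frames, max, numeric(1)))
  if (mx > 65535) {
    warning("counts above 65535 clipped to 16-bit range")
    frames <- lapply(frames, function(f) pmin(f, 65535L))
  }
  tiff::writeTIFF(lapply(frames, function(f) f / 65535),
                  path, bits.per.sample = 16L)
  meta <- stack$metadata
  meta$truth_phase <- NULL   # pixel-level truth stays in memory only
  meta$truth_rows <- NULL
  meta$truth_cols <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a luminescence stack written by [write_stack()]
#'
#' @param path TIFF path; the JSON sidecar `<path>.json` must exist
#'   (missing metadata is an error, never silently defaulted).
#' @return a `"lum_stack"` with integer count frames.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such stack: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("metadata sidecar missing: ", sidecar)
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!is.null(meta$truth_section_phase))
    meta$truth_section_phase <- as.matrix(meta$truth_section_phase)
  if (length(frames) != length(meta$times))
    stop("frame count (", length(frames),
         ") disagrees with sidecar metadata (", length(meta$times), ")")
  structure(list(frames = frames, metadata = meta), class = "lum_stack")
}
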