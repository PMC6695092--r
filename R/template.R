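#' Build the seedling oscillator template
#'
#' Constructs the labeled 2D pixel template of a seedling: a cotyledon disc
#' atop a 3-pixel-wide hypocotyl column, a 3-pixel-wide root and a 5x5 root
#' tip block, with per-pixel intrinsic periods drawn i.i.d. from
#' organ-specific normal distributions (sd = `sd_frac` * mean, truncated
#' below at 0.1 h). Under `variant = "gradient_uncoupled"` the root period
#' means instead follow a piecewise-linear profile: 25.41 h at the
#' hypocotyl/root junction, rising to 28.04 h at mid-root, falling to
#' 26.90 h at the root/root-tip junction.
#'
#' Row indices increase downward (shoot to tip); the occupied region is
#' 4-connected.
#'
#' @param cfg a [clock_config()].
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return an object of class `"seedling_template"`: a data frame with one
#'   row per pixel (columns `row`, `col`, `organ`, `period`, `birth`,
#'   `death`) and attributes `center_col`, `cot_center`, `hyp_rows`,
#'   `root_rows0`, `tip_rows0` and `growth_log`.
#' @examples
#' tpl <- seedling_template(clock_config(sd_frac = 0))
#' table(tpl$organ)
#' @export
seedling_template <- function(cfg, seed = cfg$rng_seed) {
  if (!is.null(seed)) set.seed(seed)
  rad <- cfg$cotyledon_radius
  d <- 2L * as.integer(floor(rad)) + 1L      # cotyledon bounding box side
  cc <- as.integer(floor(rad)) + 1L          # center column
  cr <- cc                                   # center row of the disc
  if (d < cfg$tip_size) stop("cotyledon too narrow to host the root tip")

  grid <- expand.grid(row = seq_len(d), col = seq_len(d))
  disc <- grid[(grid$row - cr)^2 + (grid$col - cc)^2 <= rad^2, ]

  half_w <- (cfg$root_width - 1L) %/% 2L
  hyp_rows <- d + seq_len(cfg$hypocotyl_rows)
  root_rows <- max(hyp_rows) + seq_len(cfg$root_rows)
  tip_rows <- max(root_rows) + seq_len(cfg$tip_size)
  half_tip <- (cfg$tip_size - 1L) %/% 2L

  mk <- function(rows, cols, organ)
    data.frame(expand.grid(col = cols, row = rows)[, 2:1], organ = organ)

  tpl <- rbind(
    data.frame(disc, organ = "cotyledon"),
    mk(hyp_rows, cc + (-half_w:half_w), "hypocotyl"),
    mk(root_rows, cc + (-half_w:half_w), "root"),
    mk(tip_rows, cc + (-half_tip:half_tip), "root_tip")
  )

  draw <- function(n, mean) pmax(0.1, stats::rnorm(n, mean, cfg$sd_frac * mean))
  tpl$period <- NA_real_
  for (org in c("cotyledon", "hypocotyl", "root", "root_tip")) {
    i <- which(tpl$organ == org)
    if (org == "root" && cfg$variant == "gradient_uncoupled") {
      nr <- length(root_rows)
      prof <- stats::approx(x = c(1, (nr + 1) / 2, nr),
                            y = c(cfg$period_means[["hypocotyl"]],
                                  cfg$converted_tip_period_mean,
                                  cfg$period_means[["root_tip"]]),
                            xout = seq_len(nr))$y
      mean_i <- prof[match(tpl$row[i], root_rows)]
      tpl$period[i] <- pmax(0.1, stats::rnorm(length(i), mean_i,
                                              cfg$sd_frac * mean_i))
    } else {
      tpl$period[i] <- draw(length(i), cfg$period_means[[org]])
    }
  }
  tpl$birth <- 0
  tpl$death <- NA_real_
  rownames(tpl) <- NULL

  structure(tpl,
            center_col = cc,
            cot_center = c(row = cr, col = cc),
            hyp_rows = range(hyp_rows),
            root_rows0 = range(root_rows),
            tip_rows0 = range(tip_rows),
            growth_log = data.frame(time = numeric(0), row = integer(0)),
            class = c("seedling_template", "data.frame"))
}

#' @export
print.seedling_template <- function(x, ...) {
  alive <- is.na(x$death)
  cat("<seedling_template>", sum(alive), "occupied pixels\n")
  print(table(organ = x$organ[alive]))
  gl <- attr(x, "growth_log")
  if (nrow(gl)) cat(nrow(gl), "growth events, last at t =", max(gl$time), "h\n")
  invisible(x)
}

#' Root growth event
#'
#' Advances the root tip by one row at time `t`: five new tip pixels appear
#' below the old tip bottom row and inherit the phases of the pixels
#' directly above them bit-for-bit, with intrinsic periods drawn around the
#' tip mean (26.90 h); the middle `root_width` pixels of the formerly
#' uppermost tip row are relabeled as root tissue with periods redrawn
#' around `converted_tip_period_mean` (28.04 h), and the remaining edge
#' pixels of that row leave the occupied set. Net occupancy rises by
#' exactly `root_width` pixels per event and the tip block stays
#' `tip_size` x `tip_size` at all times. The grid extends as needed; growth
#' never errors.
#'
#' @param tpl a [seedling_template()].
#' @param theta numeric phase vector aligned with the rows of `tpl` (NA for
#'   non-occupied pixels).
#' @param t event time (h); must be a positive multiple of
#'   `cfg$growth_interval`.
#' @param cfg the [clock_config()] in force.
#' @return list with elements `template` and `theta`, both extended.
#' @export
grow_root <- function(tpl, theta, t, cfg) {
  if (t <= 0 || abs(t / cfg$growth_interval - round(t / cfg$growth_interval)) > 1e-8)
    stop("growth time must be a positive multiple of growth_interval")
  stopifnot(length(theta) == nrow(tpl))
  alive <- is.na(tpl$death)
  tips <- which(alive & tpl$organ == "root_tip")
  if (!length(tips)) stop("template has no root tip")
  rows <- tpl$row[tips]
  top_row <- min(rows); bot_row <- max(rows)
  cc <- attr(tpl, "center_col")
  half_w <- (cfg$root_width - 1L) %/% 2L

  # formerly uppermost tip row: middle pixels become root, edges vacate
  top <- tips[rows == top_row]
  mid <- top[abs(tpl$col[top] - cc) <= half_w]
  edge <- setdiff(top, mid)
  m_conv <- cfg$converted_tip_period_mean
  tpl$organ[mid] <- "root"
  tpl$period[mid] <- pmax(0.1, stats::rnorm(length(mid), m_conv,
                                            cfg$sd_frac * m_conv))
  if (length(edge)) {
    tpl$death[edge] <- t
    theta[edge] <- NA_real_
  }

  # new tip bottom row inherits phases from the row directly above
  bot <- tips[rows == bot_row]
  bot <- bot[order(tpl$col[bot])]
  m_tip <- cfg$period_means[["root_tip"]]
  new <- data.frame(row = bot_row + 1L, col = tpl$col[bot],
                    organ = "root_tip",
                    period = pmax(0.1, stats::rnorm(length(bot), m_tip,
                                                    cfg$sd_frac * m_tip)),
                    birth = t, death = NA_real_)
  at <- attributes(tpl)
  tpl <- rbind(as.data.frame(tpl), new)
  theta <- c(theta, theta[bot])
  for (a in c("center_col", "cot_center", "hyp_rows", "root_rows0", "tip_rows0"))
    attr(tpl, a) <- at[[a]]
  attr(tpl, "growth_log") <- rbind(at$growth_log,
                                   data.frame(time = t, row = bot_row + 1L))
  class(tpl) <- c("seedling_template", "data.frame")
  list(template = tpl, theta = theta)
}

# Rows occupied by the (moving) tip block at time t.
tip_rows_at <- function(tpl, t) {
  r0 <- attr(tpl, "tip_rows0")
  gl <- attr(tpl, "growth_log")
  shift <- if (nrow(gl)) sum(gl$time <= t + 1e-9) else 0L
  (r0[1] + shift):(r0[2] + shift)
}
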