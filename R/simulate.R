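#' One Euler step of the coupled, forced Kuramoto dynamics
#'
#' Advances phases by one explicit Euler step of
#' \deqn{d\theta_i/dt = \omega_i + K \sum_{j \in N(i)} \sin(\theta_j - \theta_i)
#'   - K_{LD} \sin((2\pi/T_{LD}) t - \theta_i),}
#' where the sum runs over the occupied lattice neighbours of pixel i and
#' the forcing zero-phase coincides with dawn (t = 0). The result is
#' re-wrapped to (-pi, pi]. The negative forcing sign places the entrained
#' expression peak in antiphase to light (at dusk).
#'
#' @param theta numeric vector of current phases (radians).
#' @param omega intrinsic frequencies (rad/h), recycled to `length(theta)`.
#' @param dt step size (h).
#' @param t current time (h).
#' @param K coupling constant (rad/h).
#' @param K_LD light-forcing constant (rad/h).
#' @param forcing_period forcing period (h), default 24.
#' @param edges two-column integer matrix of directed neighbour pairs
#'   `(i, j)`: `sin(theta[j] - theta[i])` is added to oscillator i's
#'   coupling sum. NULL for uncoupled oscillators.
#' @return wrapped phases after one step.
#' @examples
#' kuramoto_step(0, 2 * pi / 24, dt = 0.01, t = 0)
#' @export
kuramoto_step <- function(theta, omega, dt, t, K = 0, K_LD = 0,
                          forcing_period = 24, edges = NULL) {
  drift <- rep_len(omega, length(theta))
  if (K != 0 && !is.null(edges) && nrow(edges)) {
    s <- sin(theta[edges[, 2]] - theta[edges[, 1]])
    cs <- rowsum(s, edges[, 1], reorder = FALSE)
    coup <- numeric(length(theta))
    coup[as.integer(rownames(cs))] <- cs
    drift <- drift + K * coup
  }
  if (K_LD != 0)
    drift <- drift - K_LD * sin(2 * pi / forcing_period * t - theta)
  out <- theta + dt * drift
  bad <- which(!is.finite(out))
  if (length(bad))
    stop("non-finite phase at pixel index ", bad[1], " (t = ", t, " h)")
  wrap_phase(out)
}

# Directed Moore/von-Neumann edges among alive pixels, pre-sorted by source
# with group bookkeeping for a string-free per-step coupling sum.
build_edges <- function(tpl, alive_idx, neighborhood) {
  coords <- cbind(row = tpl$row[alive_idx], col = tpl$col[alive_idx])
  pr <- neighbor_pairs(coords, if (neighborhood == "moore") 8 else 4)
  if (is.null(pr) || !nrow(pr)) {
    return(list(from = integer(0), to = integer(0),
                ufrom = integer(0), ends = integer(0)))
  }
  from <- c(pr[, 1], pr[, 2])
  to <- c(pr[, 2], pr[, 1])
  o <- order(from)
  from <- from[o]; to <- to[o]
  r <- rle(from)
  list(from = from, to = to, ufrom = r$values, ends = cumsum(r$lengths))
}

# Initial phases for a template under the configured regime.
init_phases <- function(tpl, alive, cfg) {
  n <- sum(alive)
  if (cfg$regime == "LL_to_LL") {
    wrap_phase(stats::runif(n, 0, 2 * pi))
  } else if (cfg$theta0_mode == "pixel") {
    wrap_phase(-cfg$first_peak_offset * 2 * pi / tpl$period[alive])
  } else {
    rep(wrap_phase(-cfg$first_peak_offset * 2 * pi / 24), n)
  }
}

#' Simulate seedling clock dynamics
#'
#' Runs the full growing-template simulation for `cfg$n_seedlings`
#' independent seedlings: per-seedling RNG streams derived from
#' `cfg$rng_seed`, organ-specific intrinsic periods, Euler integration of
#' the coupled (and, under LD-to-LD, light-forced) phase dynamics, and root
#' growth events every `cfg$growth_interval` hours. Phases are stored,
#' wrapped to (-pi, pi], on the `cfg$save_dt` time grid.
#'
#' @param cfg a [clock_config()].
#' @return an object of class `"clock_sim"`: list with `config` and
#'   `seedlings`, each seedling a `"clock_seedling"` list with elements
#'   `template` (final [seedling_template()] including pixels born or
#'   retired during growth), `times` (h) and `theta` (pixels x times phase
#'   matrix, NA where a pixel is not yet born or has left the occupied
#'   set).
#' @seealso [gi_readout()], [region_periods()], [order_parameter()]
#' @examples
#' cfg <- clock_config(t_end = 24, dt = 0.05, save_dt = 0.5, root_rows = 10,
#'                     hypocotyl_rows = 4, growth = FALSE)
#' sim <- simulate_clock(cfg)
#' sim
#' @export
simulate_clock <- function(cfg) {
  stopifnot(inherits(cfg, "clock_config"))
  seedlings <- lapply(seq_len(cfg$n_seedlings), function(s) {
    simulate_seedling(cfg, derive_seed(cfg$rng_seed, s))
  })
  structure(list(config = cfg, seedlings = seedlings), class = "clock_sim")
}

simulate_seedling <- function(cfg, seed) {
  set.seed(seed)
  tpl <- seedling_template(cfg, seed = NULL)
  n0 <- nrow(tpl)

  dt <- cfg$dt
  nsteps <- as.integer(round(cfg$t_end / dt))
  save_every <- as.integer(round(cfg$save_dt / dt))
  times <- seq(0, by = cfg$save_dt,
               length.out = nsteps %/% save_every + 1L)
  n_events <- if (cfg$growth)
    max(0L, as.integer(floor((cfg$t_end - 1e-9) / cfg$growth_interval))) else 0L
  n_max <- n0 + cfg$tip_size * n_events

  TH <- matrix(NA_real_, n_max, length(times))
  theta_all <- rep(NA_real_, n_max)
  theta_all[seq_len(n0)] <- init_phases(tpl, rep(TRUE, n0), cfg)

  alive_idx <- seq_len(n0)
  omega <- 2 * pi / tpl$period
  ed <- build_edges(tpl, alive_idx, cfg$neighborhood)
  th <- theta_all[alive_idx]
  om <- omega[alive_idx]

  wf <- 2 * pi / cfg$forcing_period
  K <- cfg$K; K_LD <- cfg$K_LD
  g_next <- cfg$growth_interval
  n_alive <- n0

  for (k in 0:nsteps) {
    if (k %% save_every == 0L) TH[alive_idx, k %/% save_every + 1L] <- th
    if (k == nsteps) break
    t <- k * dt
    drift <- om
    if (K != 0 && length(ed$from)) {
      s <- sin(th[ed$to] - th[ed$from])
      cs <- cumsum(s)[ed$ends]
      coup <- numeric(n_alive)
      coup[ed$ufrom] <- diff(c(0, cs))
      drift <- drift + K * coup
    }
    if (K_LD != 0) drift <- drift - K_LD * sin(wf * t - th)
    th <- wrap_phase(th + dt * drift)
    if (any(!is.finite(th)))
      stop("non-finite phase at pixel index ",
           alive_idx[which(!is.finite(th))[1]], " (t = ", t + dt, " h)")

    t_next <- (k + 1L) * dt
    if (cfg$growth && g_next <= cfg$t_end - 1e-9 &&
        t_next >= g_next - 1e-9) {
      theta_all[alive_idx] <- th
      g <- grow_root(tpl, theta_all[seq_len(nrow(tpl))], g_next, cfg)
      tpl <- g$template
      theta_all[seq_len(nrow(tpl))] <- g$theta
      omega <- 2 * pi / tpl$period
      alive_idx <- which(is.na(tpl$death))
      th <- theta_all[alive_idx]
      om <- omega[alive_idx]
      n_alive <- length(alive_idx)
      ed <- build_edges(tpl, alive_idx, cfg$neighborhood)
      g_next <- g_next + cfg$growth_interval
    }
  }

  structure(list(template = tpl, times = times,
                 theta = TH[seq_len(nrow(tpl)), , drop = FALSE]),
            class = "clock_seedling")
}

#' @export
print.clock_sim <- function(x, ...) {
  cat("<clock_sim>", length(x$seedlings), "seedling(s),",
      x$config$regime, "regime, t_end =", x$config$t_end, "h\n")
  invisible(x)
}

#' @export
print.clock_seedling <- function(x, ...) {
  cat("<clock_seedling>", nrow(x$template), "pixels (",
      sum(is.na(x$template$death)), "occupied at t_end ),",
      length(x$times), "stored time points\n")
  invisible(x)
}

#' Simulated expression readout
#'
#' Computes per-pixel simulated clock gene expression
#' `GI(t) = cos(theta(t)) + 1` (range [0, 2]) and the longitudinal readout
#' `GI_tot(j, t)`: the sum over the `n_j` occupied pixels of each
#' longitudinal row j, normalized so that the maximum over time of every
#' row equals 1.
#'
#' @param seedling a `"clock_seedling"` from [simulate_clock()].
#' @return an object of class `"gi_readout"`: list with `gi_pixel`
#'   (pixels x times), `gi_long` (rows x times, max-normalized per row),
#'   `gi_tot` (unnormalized row sums), `n_j` (occupied width per row and
#'   time), `rows`, `times` and the pixel `template`.
#' @export
gi_readout <- function(seedling) {
  stopifnot(inherits(seedling, "clock_seedling"))
  gi <- cos(seedling$theta) + 1
  tpl <- seedling$template
  rows <- sort(unique(tpl$row))
  nt <- ncol(gi)
  gi_tot <- matrix(NA_real_, length(rows), nt,
                   dimnames = list(rows, seedling$times))
  n_j <- matrix(0L, length(rows), nt)
  for (r in seq_along(rows)) {
    i <- which(tpl$row == rows[r])
    sub <- gi[i, , drop = FALSE]
    n <- colSums(!is.na(sub))
    tot <- colSums(sub, na.rm = TRUE)
    tot[n == 0L] <- NA_real_
    gi_tot[r, ] <- tot
    n_j[r, ] <- n
  }
  norm <- gi_tot / apply(gi_tot, 1, max, na.rm = TRUE)
  structure(list(gi_pixel = gi, gi_long = norm, gi_tot = gi_tot, n_j = n_j,
                 rows = rows, times = seedling$times, template = tpl),
            class = "gi_readout")
}

#' @export
print.gi_readout <- function(x, ...) {
  cat("<gi_readout>", nrow(x$gi_long), "longitudinal rows x",
      ncol(x$gi_long), "time points\n")
  invisible(x)
}

#' @param x a `"gi_readout"`.
#' @param ... passed to [graphics::image()].
#' @rdname gi_readout
#' @export
plot.gi_readout <- function(x, ...) {
  graphics::image(x$times, x$rows, t(x$gi_long),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (h)", ylab = "longitudinal position (px)",
                  ylim = rev(range(x$rows)), ...)
  invisible(x)
}

#' Simulate a single uncoupled oscillator
#'
#' Euler integration of one phase oscillator, optionally under the model's
#' 24-h light-forcing term, with phases stored at every step. Used for
#' entrainment (Adler) analyses and single-pixel period checks.
#'
#' @param period intrinsic period (h).
#' @param K_LD light-forcing constant (rad/h); 0 = free run.
#' @param forcing_period forcing period (h).
#' @param theta0 initial phase (radians); default
#'   `-first_peak_offset * 2 * pi / period` so the free-running expression
#'   peak falls at `first_peak_offset` hours.
#' @param first_peak_offset hours to the first free-running peak (default 11).
#' @param dt Euler step (h).
#' @param t_end simulation length (h).
#' @return list of class `"clock_oscillator"` with `times`, `theta`
#'   (wrapped) and `gi` (= cos(theta) + 1).
#' @examples
#' osc <- simulate_oscillator(24, t_end = 48)
#' osc$times[which.max(osc$gi)]
#' @export
simulate_oscillator <- function(period, K_LD = 0, forcing_period = 24,
                                theta0 = NULL, first_peak_offset = 11,
                                dt = 0.01, t_end = 150) {
  stopifnot(period > 0, dt > 0, t_end > dt)
  omega <- 2 * pi / period
  if (is.null(theta0)) theta0 <- -first_peak_offset * omega
  nsteps <- as.integer(round(t_end / dt))
  theta <- numeric(nsteps + 1L)
  theta[1] <- wrap_phase(theta0)
  wf <- 2 * pi / forcing_period
  th <- theta[1]
  for (k in seq_len(nsteps)) {
    t <- (k - 1L) * dt
    d <- omega
    if (K_LD != 0) d <- d - K_LD * sin(wf * t - th)
    th <- wrap_phase(th + dt * d)
    theta[k + 1L] <- th
  }
  structure(list(times = seq(0, by = dt, length.out = nsteps + 1L),
                 theta = theta, gi = cos(theta) + 1),
            class = "clock_oscillator")
}

#' @export
print.clock_oscillator <- function(x, ...) {
  cat("<clock_oscillator>", length(x$times), "steps, t_end =",
      max(x$times), "h\n")
  invisible(x)
}
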