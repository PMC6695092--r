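#' Simulation configuration for the seedling phase-oscillator model
#'
#' Assembles and validates the parameters of the growing-template Kuramoto
#' simulation: template geometry, organ-specific intrinsic-period
#' distributions, coupling and light-forcing constants, growth rules,
#' initial-phase regime and integration settings.
#'
#' Organ intrinsic periods are drawn i.i.d. from
#' `Normal(mean_organ, sd_frac * mean_organ)`, truncated below at 0.1 h.
#' The default means are 23.82 h (cotyledon), 25.41 h (hypocotyl),
#' 29.04 h (root) and 26.90 h (root tip); rows converted from tip to root
#' tissue during growth are redrawn around `converted_tip_period_mean`
#' (28.04 h).
#'
#' @param regime entrainment regime: `"LD_to_LL"` (entrained start, free
#'   run), `"LD_to_LD"` (entrained start, 24-h light forcing throughout) or
#'   `"LL_to_LL"` (never entrained; uniform random initial phases).
#' @param K nearest-neighbour coupling constant (rad/h), >= 0.
#' @param K_LD light-forcing constant (rad/h); must be 0 unless
#'   `regime = "LD_to_LD"`. Defaults to 1 in that regime, 0 otherwise.
#' @param forcing_period period of the light forcing (h), fixed at 24.
#' @param dt Euler integration step (h); must satisfy 0 < dt <= 0.1.
#' @param t_end simulation length (h).
#' @param save_dt phase storage interval (h); must be a multiple of `dt`.
#' @param growth logical; grow the root by one row every `growth_interval`?
#' @param growth_interval hours between growth events (default 5).
#' @param period_means named vector of organ period means (h):
#'   cotyledon, hypocotyl, root, root_tip.
#' @param converted_tip_period_mean mean period (h) assigned to tip rows
#'   converted to root tissue at growth events.
#' @param sd_frac period standard deviation as a fraction of the mean
#'   (dimensionless, default 0.1).
#' @param variant `"coupled"` (default) or `"gradient_uncoupled"`: the
#'   alternative model with no coupling (K forced to 0) and a
#'   piecewise-linear period gradient along the root.
#' @param first_peak_offset time (h) of the first expression peak after the
#'   start of measurement in LD-entrained regimes (default 11).
#' @param theta0_mode `"pixel"`: initial phase `-first_peak_offset * omega`
#'   per pixel (every pixel's free-running first peak at exactly
#'   `first_peak_offset`); `"common"`: one shared initial phase computed
#'   from the 24-h frequency.
#' @param n_seedlings number of independent seedlings to simulate.
#' @param neighborhood `"moore"` (8 neighbours, default) or
#'   `"von_neumann"` (4 neighbours).
#' @param cotyledon_radius radius (px) of the cotyledon disc.
#' @param hypocotyl_rows,root_rows initial organ lengths (rows).
#' @param root_width root body width (px); the template uses 3.
#' @param tip_size root-tip block side (px); the template uses 5.
#' @param rng_seed integer seed; per-seedling streams are derived from it.
#' @return an object of class `"clock_config"` (a validated list).
#' @seealso [seedling_template()], [simulate_clock()]
#' @examples
#' cfg <- clock_config(regime = "LD_to_LD", t_end = 120)
#' cfg$K_LD
#' @export
clock_config <- function(regime = c("LD_to_LL", "LD_to_LD", "LL_to_LL"),
                         K = 1,
                         K_LD = NULL,
                         forcing_period = 24,
                         dt = 0.01,
                         t_end = 144,
                         save_dt = 0.25,
                         growth = TRUE,
                         growth_interval = 5,
                         period_means = c(cotyledon = 23.82, hypocotyl = 25.41,
                                          root = 29.04, root_tip = 26.90),
                         converted_tip_period_mean = 28.04,
                         sd_frac = 0.1,
                         variant = c("coupled", "gradient_uncoupled"),
                         first_peak_offset = 11,
                         theta0_mode = c("pixel", "common"),
                         n_seedlings = 1L,
                         neighborhood = c("moore", "von_neumann"),
                         cotyledon_radius = 4.5,
                         hypocotyl_rows = 16L,
                         root_rows = 40L,
                         root_width = 3L,
                         tip_size = 5L,
                         rng_seed = 1L) {
  regime <- match.arg(regime)
  variant <- match.arg(variant)
  theta0_mode <- match.arg(theta0_mode)
  neighborhood <- match.arg(neighborhood)
  if (is.null(K_LD)) K_LD <- if (regime == "LD_to_LD") 1 else 0
  if (variant == "gradient_uncoupled" && K != 0) {
    warning("gradient_uncoupled variant forces K = 0")
    K <- 0
  }
  stopifnot(dt > 0, dt <= 0.1, t_end > 0, sd_frac >= 0, K >= 0, K_LD >= 0,
            growth_interval > 0, forcing_period > 0,
            root_width >= 1, tip_size >= 1,
            hypocotyl_rows >= 1, root_rows >= 1, cotyledon_radius > 0,
            n_seedlings >= 1)
  if (K_LD > 0 && regime != "LD_to_LD")
    stop("K_LD must be 0 unless regime = 'LD_to_LD'")
  if (abs(save_dt / dt - round(save_dt / dt)) > 1e-8)
    stop("save_dt must be a multiple of dt")
  need <- c("cotyledon", "hypocotyl", "root", "root_tip")
  if (!all(need %in% names(period_means)) || any(period_means <= 0))
    stop("period_means must name positive cotyledon, hypocotyl, root, root_tip")
  structure(list(
    regime = regime, K = K, K_LD = K_LD, forcing_period = forcing_period,
    dt = dt, t_end = t_end, save_dt = save_dt,
    growth = growth, growth_interval = growth_interval,
    period_means = period_means[need],
    converted_tip_period_mean = converted_tip_period_mean,
    sd_frac = sd_frac, variant = variant,
    first_peak_offset = first_peak_offset, theta0_mode = theta0_mode,
    n_seedlings = as.integer(n_seedlings), neighborhood = neighborhood,
    cotyledon_radius = cotyledon_radius,
    hypocotyl_rows = as.integer(hypocotyl_rows),
    root_rows = as.integer(root_rows),
    root_width = as.integer(root_width), tip_size = as.integer(tip_size),
    rng_seed = as.integer(rng_seed)
  ), class = "clock_config")
}

#' @export
print.clock_config <- function(x, ...) {
  cat("<clock_config>", x$regime,
      sprintf("K=%g K_LD=%g dt=%g t_end=%g growth=%s variant=%s seedlings=%d\n",
              x$K, x$K_LD, x$dt, x$t_end, x$growth, x$variant, x$n_seedlings))
  invisible(x)
}

#' Rendering configuration for synthetic luminescence stacks
#'
#' Parameters of the synthetic time-lapse renderer that emulates the
#' statistical structure of luciferase movies: acquisition cadence, emission
#' model (baseline, amplitude, exponential damping), shot/read noise,
#' isolated cosmic-ray spikes, root-centerline curvature and optional
#' contamination from a dim neighbouring seedling.
#'
#' @param frame_interval minutes between frames (default 90).
#' @param n_frames number of frames.
#' @param baseline dark/background count level inside the seedling mask.
#' @param amplitude peak-to-trough luminescence range (counts); emission is
#'   `baseline + amplitude * exp(-damping_rate * t) * (cos(theta) + 1)/2`.
#' @param damping_rate exponential amplitude decay rate (1/h); 0 = off.
#' @param noise_model `"none"`, `"gaussian"` (sd = `noise_scale`) or
#'   `"poisson"` (counts drawn with the clean value as the rate).
#' @param noise_scale standard deviation of Gaussian noise (counts).
#' @param spike_rate expected cosmic-ray spikes per frame (Poisson).
#' @param spike_amplitude count value written at spiked pixels.
#' @param background_gradient `c(row_slope, col_slope)`: linear background
#'   added to every pixel of every frame, in counts per pixel of row and
#'   column index; `c(0, 0)` (default) keeps the background flat.
#' @param curvature numeric coefficients `c(c1, c2)` of a horizontal bend
#'   applied below the hypocotyl: column shift `c1*z + c2*z^2` at normalized
#'   depth z in [0, 1]. `c(0, 0)` renders a straight seedling.
#' @param neighbor_offset optional `c(drow, dcol)` offset of a dim (20%
#'   amplitude) contaminating copy of the seedling; NULL = off.
#' @param margin blank border (px) around the rendered seedling.
#' @param rng_seed integer seed for noise and spikes.
#' @return an object of class `"render_config"`.
#' @export
render_config <- function(frame_interval = 90,
                          n_frames = 96L,
                          baseline = 200,
                          amplitude = 1000,
                          damping_rate = 0,
                          noise_model = c("none", "gaussian", "poisson"),
                          noise_scale = 0,
                          spike_rate = 0,
                          spike_amplitude = 60000,
                          background_gradient = c(0, 0),
                          curvature = c(0, 0),
                          neighbor_offset = NULL,
                          margin = 6L,
                          rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(frame_interval > 0, n_frames >= 1, baseline >= 0, amplitude >= 0,
            damping_rate >= 0, spike_rate >= 0, spike_amplitude >= 0,
            margin >= 0, length(curvature) >= 1)
  structure(list(
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    baseline = baseline, amplitude = amplitude, damping_rate = damping_rate,
    noise_model = noise_model, noise_scale = noise_scale,
    spike_rate = spike_rate, spike_amplitude = spike_amplitude,
    background_gradient = rep_len(background_gradient, 2),
    curvature = curvature, neighbor_offset = neighbor_offset,
    margin = as.integer(margin), rng_seed = as.integer(rng_seed)
  ), class = "render_config")
}

#' @export
print.render_config <- function(x, ...) {
  cat(sprintf(
    "<render_config> %d frames @ %g min, baseline %g, amplitude %g, noise %s\n",
    x$n_frames, x$frame_interval, x$baseline, x$amplitude, x$noise_model))
  invisible(x)
}
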