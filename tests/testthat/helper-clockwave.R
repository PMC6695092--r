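# Small, fast configurations and synthetic sources shared across tests.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(cotyledon_radius = 2.5, hypocotyl_rows = 6L, root_rows = 12L,
         t_end = 96, dt = 0.05, save_dt = 0.25),
    list(...))
  do.call(clock_config, args)
}

# Straight wide seedling with a per-row phase offset; wide enough that a
# 10-pixel normal section stays inside the organ.
parametric_source <- function(nrow_img = 60, ncol_img = 20, organ_cols = 3:18,
                              organ_rows = 6:55, period = 24,
                              phase_per_row = function(r) 0) {
  mask <- matrix(FALSE, nrow_img, ncol_img)
  mask[organ_rows, organ_cols] <- TRUE
  ph0 <- matrix(0, nrow_img, ncol_img)
  for (r in organ_rows) ph0[r, ] <- phase_per_row(r)
  list(mask = mask, period = period, phase0 = ph0,
       organ_rows = organ_rows, organ_cols = organ_cols)
}

# Circular mean absolute deviation between two wrapped phase vectors.
circ_abs_diff <- function(a, b) abs(phase_diff(a, b))

# Mean absolute wrapped phase difference between adjacent longitudinal rows
# of a simulated seedling at one stored time index (root + hypocotyl rows).
adjacent_row_incoherence <- function(seedling, ti) {
  tpl <- seedling$template
  keep <- tpl$organ != "cotyledon" & !is.na(seedling$theta[, ti])
  rows <- sort(unique(tpl$row[keep]))
  rp <- vapply(rows, function(r) {
    i <- which(keep & tpl$row == r)
    Arg(sum(exp(1i * seedling$theta[i, ti])))
  }, numeric(1))
  mean(abs(phase_diff(rp[-1], rp[-length(rp)])))
}
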