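# Fixational eye-movement simulation: self-avoiding walk on an activation
# lattice with a confining potential, plus optional injected microsaccades.

#' Simulate fixational drift with a self-avoiding walk
#'
#' A walker on a square lattice steps, `step_rate` times per second, to
#' whichever of its four neighbors minimizes the sum of an activation field
#' and a quadratic confining potential.  The site just left receives an
#' activation increment (self-avoidance) and the whole activation field
#' decays multiplicatively each step.  Lattice positions are scaled by
#' `lattice_pitch` to arcmin and linearly resampled to one sample per scan
#' line.  The trace starts at (0, 0).
#'
#' The defaults (0.05 arcmin pitch, 600 steps/s) give a mean drift speed of
#' 0.5 deg/s, typical of human fixational drift, with per-frame excursions
#' resolved finely enough that both components vary within a 33 ms frame.
#'
#' @param duration Trace duration in seconds.
#' @param line_rate Scan-line rate in Hz (one output sample per line).
#' @param lattice_half_width Half-width of the lattice in sites; the lattice
#'   is `(2 * lattice_half_width + 1)^2`.
#' @param activation_increment Activation added to a visited site.
#' @param activation_init Upper bound of the uniform random initial
#'   activation of the lattice.  The quenched random landscape gives the
#'   walk its fine-scale irregularity; `0` starts from a flat lattice and
#'   yields much smoother, orbit-like paths.
#' @param decay_rate Per-step multiplicative decay of activation
#'   (`h <- h * (1 - decay_rate)`).
#' @param potential_slope Strength of the quadratic confining potential at
#'   the lattice edge, in activation units.
#' @param lattice_pitch Lattice spacing in arcmin.
#' @param step_rate Walker steps per second.
#' @param lattice_angle Orientation of the lattice relative to the scanner
#'   axes, in radians.  The lattice orientation is arbitrary; the default
#'   (22.5 degrees) keeps lattice-axis runs from aligning with either
#'   scanner axis.
#' @param seed Optional integer seed.
#' @return An object of class `eye_trace`: data.frame with columns `t`
#'   (seconds), `x`, `y` (arcmin), with the simulation parameters stored in
#'   `attr(, "params")`.
#' @export
simulate_drift <- function(duration, line_rate, lattice_half_width = 50L,
                           activation_increment = 1, activation_init = 1,
                           decay_rate = 0.01, potential_slope = 1,
                           lattice_pitch = 0.05, step_rate = 600,
                           lattice_angle = pi / 8, seed = NULL) {
  if (duration <= 0) stop("`duration` must be positive")
  if (line_rate <= 0) stop("`line_rate` must be positive")
  if (lattice_half_width < 1) stop("`lattice_half_width` must be >= 1")
  if (step_rate <= 0) stop("`step_rate` must be positive")
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(lattice_half_width)
  n_side <- 2L * L + 1L
  ctr <- L + 1L
  idx <- seq_len(n_side) - ctr
  u <- potential_slope * outer(idx^2, idx^2, "+") / L^2
  h <- matrix(runif(n_side^2, 0, activation_init), n_side, n_side)
  n_steps <- ceiling(duration * step_rate) + 1L
  pi_ <- integer(n_steps); pj_ <- integer(n_steps)
  i <- ctr; j <- ctr
  pi_[1] <- i; pj_[1] <- j
  for (s in 2:n_steps) {
    ni <- c(i - 1L, i + 1L, i, i)
    nj <- c(j, j, j - 1L, j + 1L)
    ok <- ni >= 1L & ni <= n_side & nj >= 1L & nj <= n_side
    ni <- ni[ok]; nj <- nj[ok]
    val <- h[cbind(ni, nj)] + u[cbind(ni, nj)]
    best <- which(val == min(val))
    pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
    h[i, j] <- h[i, j] + activation_increment
    i <- ni[pick]; j <- nj[pick]
    if (decay_rate > 0) h <- h * (1 - decay_rate)
    pi_[s] <- i; pj_[s] <- j
  }
  t_steps <- (seq_len(n_steps) - 1L) / step_rate
  # lattice coordinates in arcmin, rotated into the scanner frame
  xl <- (pj_ - ctr) * lattice_pitch
  yl <- (pi_ - ctr) * lattice_pitch
  xs <- cos(lattice_angle) * xl - sin(lattice_angle) * yl
  ys <- sin(lattice_angle) * xl + cos(lattice_angle) * yl
  n_lines <- floor(duration * line_rate) + 1L
  t_out <- (seq_len(n_lines) - 1L) / line_rate
  out <- data.frame(t = t_out,
                    x = approx(t_steps, xs, xout = t_out, rule = 2)$y,
                    y = approx(t_steps, ys, xout = t_out, rule = 2)$y)
  structure(out, class = c("eye_trace", "data.frame"),
            params = list(duration = duration, line_rate = line_rate,
                          lattice_half_width = L,
                          activation_increment = activation_increment,
                          activation_init = activation_init,
                          decay_rate = decay_rate,
                          potential_slope = potential_slope,
                          lattice_pitch = lattice_pitch,
                          step_rate = step_rate,
                          lattice_angle = lattice_angle, seed = seed))
}

#' Inject a microsaccade into an eye trace
#'
#' Adds a displacement with a raised-cosine velocity profile
#' `v(t) = v_peak/2 * (1 - cos(2*pi*t'/D))`, whose duration `D` is set by the
#' requested amplitude (`amplitude = v_peak * D / 2`).  Samples before the
#' onset are unchanged; samples after the saccade carry the full added
#' displacement.
#'
#' @param trace An `eye_trace`.
#' @param onset Saccade onset in seconds (within the trace).
#' @param amplitude Saccade amplitude in arcmin (0 leaves the trace
#'   unchanged).
#' @param direction Direction in radians (0 = +x).
#' @param peak_velocity Peak velocity in deg/s (positive).
#' @return The modified `eye_trace`.
#' @export
inject_microsaccade <- function(trace, onset, amplitude, direction = 0,
                                peak_velocity = 30) {
  stopifnot(inherits(trace, "eye_trace"))
  if (peak_velocity <= 0) stop("`peak_velocity` must be positive")
  if (onset < min(trace$t) || onset > max(trace$t))
    stop("`onset` must lie within the trace")
  if (amplitude == 0) return(trace)
  vp <- peak_velocity * 60  # arcmin/s
  D <- 2 * amplitude / vp
  if (onset + D > max(trace$t))
    warning("saccade extends past the end of the trace; truncated")
  tp <- pmin(pmax(trace$t - onset, 0), D)
  # integral of the raised-cosine velocity profile
  s <- vp / 2 * (tp - D * sin(2 * pi * tp / D) / (2 * pi))
  trace$x <- trace$x + s * cos(direction)
  trace$y <- trace$y + s * sin(direction)
  trace
}

#' Summary statistics of an eye trace
#'
#' @param trace An `eye_trace` (or data.frame with `t`, `x`, `y`) with at
#'   least two samples.
#' @return A list of class `drift_stats`: `amplitude` (max pairwise excursion,
#'   arcmin), `mean_speed` and `max_speed` (deg/s, from first differences).
#' @export
trace_stats <- function(trace) {
  if (nrow(trace) < 2) stop("trace must have at least 2 samples")
  hull <- grDevices::chull(trace$x, trace$y)
  hx <- trace$x[hull]; hy <- trace$y[hull]
  amp <- if (length(hull) < 2) 0 else
    sqrt(max(outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2))
  dt <- diff(trace$t)
  v <- sqrt(diff(trace$x)^2 + diff(trace$y)^2) / dt / 60  # deg/s
  structure(list(amplitude = amp, mean_speed = mean(v), max_speed = max(v)),
            class = "drift_stats")
}

#' @export
print.drift_stats <- function(x, ...) {
  cat(sprintf(
    "<drift_stats> amplitude %.3g arcmin, mean speed %.3g deg/s, max speed %.3g deg/s\n",
    x$amplitude, x$mean_speed, x$max_speed))
  invisible(x)
}
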