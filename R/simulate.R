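#' Draw descent durations from a class duration model
#'
#' Samples from the normal distribution `N(mu, sigma)` truncated to the
#' model's support interval, by inverse-CDF transform of uniform draws.
#' Uses the current RNG stream; wrap in `set.seed()` (or use the seed of a
#' [simulation_config()]) for reproducibility.
#'
#' @param model A [normal_time_model].
#' @param n Number of draws.
#' @return Numeric vector of `n` durations in seconds, all inside the
#'   model's support.
#' @export
sample_duration <- function(model, n = 1L) {
  stopifnot(inherits(model, "normal_time_model"), n >= 0)
  p_lo <- pnorm(model$support[1], model$mu, model$sigma)
  p_hi <- pnorm(model$support[2], model$mu, model$sigma)
  if (p_hi <= p_lo)
    stop("empty truncation interval: support carries no probability mass",
         call. = FALSE)
  qnorm(runif(n, p_lo, p_hi), model$mu, model$sigma)
}

# Shared trajectory builder for both incident classes.
#
# Shapes (time-scaled to the drawn duration T):
#   fall: h(t) = h0 (1 - (t/T)^2)  -- starts at rest, accelerates downward
#   bend: h(t) = h0 (1 - t/T)^2   -- starts at speed 2 h0/T, decelerates to 0
#
# Interior samples sit on the 1/sample_rate grid; the terminal sample is
# forced to exactly (T, 0) so floor contact is well defined at any rate.
# Interior samples whose (noisy) height falls inside the floor band are
# indistinguishable from floor contact and are coalesced into the terminal
# sample, so the realized total time equals T. Noise is clamped so upward
# wiggles stay below the descent tolerance of the incident invariants.
.simulate_profile <- function(shape, h0, duration, sample_rate,
                              height_noise_sd, id, label,
                              h_floor_tol = .FLOOR_TOL,
                              wiggle_tol = .WIGGLE_TOL) {
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be a positive number of seconds", call. = FALSE)
  if (!is.finite(h0) || h0 <= h_floor_tol)
    stop("start height h0 must be above the floor band", call. = FALSE)
  stopifnot(sample_rate > 0, height_noise_sd >= 0)
  tt <- seq(0, duration, by = 1 / sample_rate)
  if (duration - tt[length(tt)] < 1e-9) tt <- tt[-length(tt)]
  u <- tt / duration
  hh <- if (shape == "fall") h0 * (1 - u^2) else h0 * (1 - u)^2
  if (height_noise_sd > 0 && length(hh) > 1L) {
    hh[-1L] <- hh[-1L] + rnorm(length(hh) - 1L, 0, height_noise_sd)
    cap <- 0.75 * wiggle_tol
    for (i in seq_len(length(hh) - 1L)) {
      if (hh[i + 1L] > hh[i] + cap) hh[i + 1L] <- hh[i] + cap
    }
  }
  keep <- hh > h_floor_tol
  keep[1L] <- TRUE
  incident(id, c(tt[keep], duration), c(hh[keep], 0), label)
}

#' Simulate a fall incident
#'
#' Free-fall-shaped (accelerating) descent `h(t) = h0 (1 - (t/T)^2)`,
#' time-scaled to the given duration, sampled at `sample_rate` with an exact
#' terminal sample at `(T, 0)` and additive height noise on interior samples
#' only. The profile starts at rest and speeds up, the kinematic signature
#' of an involuntary fall.
#'
#' @param h0 Start height in meters.
#' @param duration Total descent time `T` in seconds.
#' @param sample_rate Samples per second (default 30).
#' @param height_noise_sd Height noise standard deviation in meters
#'   (default 0, i.e. noise-free).
#' @param id Incident identifier.
#' @return A labeled [incident] (`"FALL"` or `"BEND"` respectively).
#' @export
simulate_fall <- function(h0, duration, sample_rate = 30,
                          height_noise_sd = 0, id = "fall") {
  .simulate_profile("fall", h0, duration, sample_rate, height_noise_sd,
                    id, .FALL)
}

#' Simulate a lean-over (bend) incident
#'
#' Decelerating descent `h(t) = h0 (1 - t/T)^2`: a voluntary movement that
#' starts with speed `2 h0 / T` and slows to zero at floor contact.
#'
#' @inheritParams simulate_fall
#' @rdname simulate_fall
#' @export
simulate_bend <- function(h0, duration, sample_rate = 30,
                          height_noise_sd = 0, id = "bend") {
  .simulate_profile("bend", h0, duration, sample_rate, height_noise_sd,
                    id, .BEND)
}

#' Generate a labeled synthetic incident dataset
#'
#' Draws class-conditional durations from the configured truncated normals
#' and simulates one trajectory per incident. Reproducible from the config
#' seed; the caller's RNG state is left untouched when a seed is set.
#'
#' @param config A [simulation_config()].
#' @return List of [incident] objects (`n_fall` falls with ids `F001...`,
#'   then `n_bend` lean-overs with ids `B001...`).
#' @examples
#' inc <- generate_dataset(simulation_config(n_fall = 2, n_bend = 2, seed = 1))
#' sapply(inc, total_time)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    t_fall <- sample_duration(config$fall_model, config$n_fall)
    t_bend <- sample_duration(config$bend_model, config$n_bend)
    falls <- lapply(seq_len(config$n_fall), function(i)
      simulate_fall(config$h0, t_fall[i], config$sample_rate,
                    config$height_noise_sd, id = sprintf("F%03d", i)))
    bends <- lapply(seq_len(config$n_bend), function(i)
      simulate_bend(config$h0, t_bend[i], config$sample_rate,
                    config$height_noise_sd, id = sprintf("B%03d", i)))
    c(falls, bends)
  })
}
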