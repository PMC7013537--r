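#' Construct a descent incident
#'
#' An incident is one descent event recorded by a wearable altimeter: an
#' ordered sequence of (time, height) samples starting at the moment the
#' descent begins (`t = 0`, height `h0 > 0`) and ending at floor contact
#' (height 0, within the floor tolerance). Heights are in meters, times in
#' seconds.
#'
#' Invariants enforced by [validate_incident()]:
#' * times strictly increasing, first sample at `t = 0`;
#' * first height above the floor band, last height inside it;
#' * heights non-increasing up to a small upward wiggle tolerance
#'   (default 0.02 m) that absorbs sensor noise.
#'
#' @param id Opaque incident identifier (coerced to character).
#' @param t Numeric vector of sample times in seconds.
#' @param h Numeric vector of sample heights in meters, same length as `t`.
#' @param label Optional class label, `"FALL"`, `"BEND"`, or `NA`.
#' @param validate If `TRUE` (default), check the invariants.
#' @return An object of class `"incident"`: a list with elements `id`,
#'   `label`, `t`, `h`.
#' @seealso [total_time()], [checkpoint_times()]
#' @examples
#' inc <- incident("ex1", c(0, 1, 2), c(1.0, 0.5, 0), label = "FALL")
#' total_time(inc)
#' @export
incident <- function(id, t, h, label = NA_character_, validate = TRUE) {
  x <- structure(
    list(id = as.character(id)[1], label = as.character(label)[1],
         t = as.numeric(t), h = as.numeric(h)),
    class = "incident"
  )
  if (validate) validate_incident(x)
  x
}

#' Validate an incident's invariants
#'
#' @param x An `"incident"` object.
#' @param h_floor_tol Floor-contact tolerance in meters (default 0.01).
#' @param wiggle_tol Largest tolerated upward height step in meters
#'   (default 0.02).
#' @return `x`, invisibly. Errors name the offending incident.
#' @export
validate_incident <- function(x, h_floor_tol = .FLOOR_TOL,
                              wiggle_tol = .WIGGLE_TOL) {
  fail <- function(msg) {
    stop(sprintf("incident '%s': %s", x$id, msg), call. = FALSE)
  }
  t <- x$t
  h <- x$h
  if (!is.numeric(t) || !is.numeric(h)) fail("t and h must be numeric")
  if (length(t) != length(h)) fail("t and h differ in length")
  if (length(t) < 2L) fail("needs at least two samples")
  if (anyNA(t) || anyNA(h) || any(!is.finite(t)) || any(!is.finite(h)))
    fail("non-finite sample values")
  if (abs(t[1]) > 1e-9) fail("first sample must be at t = 0")
  if (any(diff(t) <= 0)) fail("times must be strictly increasing")
  if (any(h < -1e-9)) fail("negative heights")
  if (h[1] <= h_floor_tol) fail("start height must be above the floor band")
  if (any(diff(h) > wiggle_tol + 1e-12))
    fail(sprintf("height increases by more than %g m (not a descent)",
                 wiggle_tol))
  if (h[length(h)] > h_floor_tol)
    fail("incomplete incident: floor (h = 0) never reached")
  if (!is.na(x$label) && !x$label %in% c(.FALL, .BEND))
    fail(sprintf("label must be FALL, BEND or NA, got '%s'", x$label))
  invisible(x)
}

#' @export
print.incident <- function(x, ...) {
  cat(sprintf("<incident '%s'> label=%s, %d samples, h0=%.3f m, T=%.3f s\n",
              x$id, ifelse(is.na(x$label), "?", x$label), length(x$t),
              x$h[1], x$t[length(x$t)]))
  invisible(x)
}

#' @export
as.data.frame.incident <- function(x, ...) {
  data.frame(incident_id = x$id,
             label = ifelse(is.na(x$label), "", x$label),
             t_s = x$t, h_m = x$h, stringsAsFactors = FALSE)
}

#' Total descent time of an incident
#'
#' The total incident time is the time of the earliest sample whose height is
#' inside the floor band (`h <= h_floor_tol`); for a monotone descent this is
#' the last sample's time.
#'
#' @inheritParams validate_incident
#' @param incident An `"incident"` object.
#' @return Time of first floor contact, in seconds.
#' @export
total_time <- function(incident, h_floor_tol = .FLOOR_TOL) {
  i <- which(incident$h <= h_floor_tol)[1]
  if (is.na(i))
    stop(sprintf("incident '%s': incomplete incident, floor never reached",
                 incident$id), call. = FALSE)
  incident$t[i]
}

#' Height-checkpoint grid
#'
#' `K` height levels with spacing `h0 / K`, running from one step below the
#' start height down to the floor: `h0 (K-1)/K, ..., h0/K, 0`. The level
#' `h0` itself is excluded because every trajectory crosses it at `t = 0`,
#' which carries no class information. The shared height axis is what makes
#' crossing-time vectors of incidents with different durations comparable.
#'
#' @param h0 Start height in meters.
#' @param K Number of checkpoints (default 20).
#' @return Decreasing numeric vector of length `K` ending at 0.
#' @export
checkpoint_grid <- function(h0, K = 20L) {
  stopifnot(h0 > 0, K >= 2L)
  h0 * ((K - 1L):0L) / K
}

# First-crossing times of decreasing height levels, shared by the batch and
# precomputed classifier paths. Uses the running minimum so that upward
# sensor wiggles cannot "uncross" a level; interpolates linearly between the
# bracketing samples. Levels inside the floor band map to the total time.
.crossing_times <- function(t, h, levels, h_floor_tol = .FLOOR_TOL) {
  hm <- cummin(h)
  n <- length(hm)
  i_floor <- which(h <= h_floor_tol)[1]
  out <- numeric(length(levels))
  # rev(hm) is non-decreasing; findInterval counts entries <= level, so the
  # first index of hm at or below the level is n - count + 1.
  cnt <- findInterval(levels, rev(hm))
  for (k in seq_along(levels)) {
    lv <- levels[k]
    if (lv <= h_floor_tol) {
      out[k] <- t[i_floor]
    } else {
      i <- n - cnt[k] + 1L
      if (cnt[k] == 0L) {
        out[k] <- NA_real_        # never crossed (caller decides)
      } else if (i == 1L) {
        out[k] <- t[1L]           # at or above the first sample's height
      } else {
        out[k] <- t[i - 1L] +
          (hm[i - 1L] - lv) / (hm[i - 1L] - hm[i]) * (t[i] - t[i - 1L])
      }
    }
  }
  out
}

#' First-crossing times of a trajectory at height checkpoints
#'
#' For each checkpoint height, returns the time at which the trajectory first
#' descends to that height, linearly interpolated between the bracketing
#' samples. A checkpoint at (or below) the floor tolerance returns
#' [total_time()]. At 30 Hz sampling the linear interpolation error is far
#' below one sample interval for smooth descent profiles.
#'
#' @inheritParams total_time
#' @param heights Decreasing numeric vector of checkpoint heights in meters,
#'   all at or below the incident's start height.
#' @return An object of class `"checkpoint_profile"`: a list with `heights`
#'   and `times` (seconds), aligned element-wise.
#' @export
checkpoint_times <- function(incident, heights, h_floor_tol = .FLOOR_TOL) {
  heights <- as.numeric(heights)
  if (length(heights) == 0L) stop("no checkpoint heights given", call. = FALSE)
  if (any(diff(heights) >= 0))
    stop("checkpoint heights must be strictly decreasing", call. = FALSE)
  if (any(heights < 0)) stop("negative checkpoint height", call. = FALSE)
  if (heights[1] > incident$h[1] + 1e-9)
    stop(sprintf("incident '%s': checkpoint %.3f m above start height %.3f m",
                 incident$id, heights[1], incident$h[1]), call. = FALSE)
  times <- .crossing_times(incident$t, incident$h, heights, h_floor_tol)
  structure(list(heights = heights, times = times),
            class = "checkpoint_profile")
}

#' @export
print.checkpoint_profile <- function(x, ...) {
  cat(sprintf("<checkpoint_profile> %d checkpoints, %.3f m down to %.3f m\n",
              length(x$heights), x$heights[1], x$heights[length(x$heights)]))
  print(data.frame(h_m = x$heights, t_s = x$times))
  invisible(x)
}
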