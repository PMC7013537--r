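#' Checkpoint majority-vote classifier (CM-II)
#'
#' CM-II evaluates the whole history of a descent rather than only its end.
#' A fixed grid of height checkpoints makes trajectories comparable: at each
#' checkpoint `j` the incident's crossing time `tI_j` is compared with fall
#' and lean-over reference crossing times `tF_j`, `tB_j` through the
#' absolute time distances
#' \deqn{tfall_j = |tI_j - tF_j|, \quad tbend_j = |tI_j - tB_j|.}
#' The checkpoint votes fall when `tfall_j < tbend_j`, else lean-over (ties
#' to lean-over). When the trajectory reaches the floor the votes are
#' compared: the incident is a fall iff the fall votes are in strict
#' majority.
#'
#' @param checkpoints Strictly decreasing height grid (meters), ending at 0.
#' @param t_fall_ref,t_bend_ref Reference crossing times (seconds) at the
#'   checkpoints, one per checkpoint, each strictly increasing.
#' @return An object of class `"cm2"`.
#' @export
cm2_model <- function(checkpoints, t_fall_ref, t_bend_ref) {
  checkpoints <- as.numeric(checkpoints)
  t_fall_ref <- as.numeric(t_fall_ref)
  t_bend_ref <- as.numeric(t_bend_ref)
  K <- length(checkpoints)
  if (K < 2L) stop("need at least 2 checkpoints", call. = FALSE)
  if (any(diff(checkpoints) >= 0))
    stop("checkpoints must be strictly decreasing", call. = FALSE)
  if (length(t_fall_ref) != K || length(t_bend_ref) != K)
    stop("reference vectors must have one entry per checkpoint",
         call. = FALSE)
  if (any(diff(t_fall_ref) <= 0) || any(diff(t_bend_ref) <= 0))
    stop("reference crossing times must be strictly increasing",
         call. = FALSE)
  structure(list(checkpoints = checkpoints, t_fall_ref = t_fall_ref,
                 t_bend_ref = t_bend_ref),
            class = "cm2")
}

#' @export
print.cm2 <- function(x, ...) {
  K <- length(x$checkpoints)
  cat(sprintf(paste0(
    "<cm2> %d checkpoints from %.3f m to 0; reference total times: ",
    "fall %.3f s, lean-over %.3f s\n"),
    K, x$checkpoints[1], x$t_fall_ref[K], x$t_bend_ref[K]))
  invisible(x)
}

#' Fit CM-II from labeled incidents
#'
#' Builds a checkpoint grid of `K` levels from the median training start
#' height down to 0 (see [checkpoint_grid()]) and sets each class's
#' reference vector to the element-wise mean of that class's checkpoint
#' crossing times. Reference vectors are re-estimated on every training fold
#' during cross-validation, so evaluation stays honest.
#'
#' @param incidents List of labeled [incident] objects, at least two per
#'   class.
#' @param K Number of height checkpoints (default 20).
#' @return A `"cm2"` model.
#' @export
fit_cm2 <- function(incidents, K = 20L) {
  labels <- vapply(incidents, function(x) x$label, "")
  if (anyNA(labels)) stop("all training incidents must be labeled",
                          call. = FALSE)
  for (cl in c(.FALL, .BEND)) {
    if (sum(labels == cl) < 2L)
      stop(sprintf("CM-II needs at least 2 training incidents of class %s",
                   cl), call. = FALSE)
  }
  h0 <- median(vapply(incidents, function(x) x$h[1], 0))
  grid <- checkpoint_grid(h0, K)
  tmat <- t(vapply(incidents,
                   function(x) checkpoint_times(x, grid)$times,
                   numeric(length(grid))))
  cm2_model(grid,
            colMeans(tmat[labels == .FALL, , drop = FALSE]),
            colMeans(tmat[labels == .BEND, , drop = FALSE]))
}

# Vote at each checkpoint given incident crossing times; ties go to BEND
# (strict inequality), as does a tied final count.
.cm2_votes <- function(model, t_incident) {
  d_fall <- abs(t_incident - model$t_fall_ref)
  d_bend <- abs(t_incident - model$t_bend_ref)
  votes <- ifelse(d_fall < d_bend, .FALL, .BEND)
  fall_count <- sum(votes == .FALL)
  bend_count <- length(votes) - fall_count
  list(records = data.frame(j = seq_along(votes),
                            checkpoint_h = model$checkpoints,
                            t_incident = t_incident,
                            d_fall = d_fall, d_bend = d_bend,
                            vote = votes, stringsAsFactors = FALSE),
       fall_count = fall_count, bend_count = bend_count,
       decision = if (fall_count > bend_count) .FALL else .BEND)
}

#' Classify one incident with CM-II
#'
#' @param model A fitted `"cm2"` model.
#' @param incident A complete [incident] (floor reached).
#' @return List with `label` (the decision) and `trace`, a `"vote_trace"`
#'   holding per-checkpoint records `(j, checkpoint_h, t_incident, d_fall,
#'   d_bend, vote)`, the vote counts, and the decision.
#' @export
classify_cm2 <- function(model, incident) {
  stopifnot(inherits(model, "cm2"))
  ti <- checkpoint_times(incident, model$checkpoints)$times
  v <- .cm2_votes(model, ti)
  trace <- structure(c(v, list(decided = TRUE)), class = "vote_trace")
  list(label = v$decision, trace = trace)
}

#' @export
print.vote_trace <- function(x, ...) {
  if (isTRUE(x$decided)) {
    cat(sprintf("<vote_trace> decided: %s (fall %d : bend %d)\n",
                x$decision, x$fall_count, x$bend_count))
  } else {
    cat(sprintf("<vote_trace> undecided (fall %d : bend %d so far)\n",
                x$fall_count, x$bend_count))
  }
  invisible(x)
}

#' @param object A fitted `"cm2"` model.
#' @param newdata List of [incident] objects.
#' @param ... Unused.
#' @rdname classify_cm2
#' @return For `predict.cm2`: character vector of predicted labels.
#' @export
predict.cm2 <- function(object, newdata, ...) {
  vapply(newdata, function(x) classify_cm2(object, x)$label, "")
}

#' Streaming CM-II classification
#'
#' `cm2_stream()` opens an incremental classification state;
#' `cm2_stream_update()` feeds one `(t, h)` sample at a time, emitting votes
#' as checkpoints are crossed, and finalizes the decision when the height
#' enters the floor band — exactly the loop bound of the batch classifier
#' ("repeat until h = 0"). `cm2_stream_replay()` replays a whole sample
#' sequence and returns the state after each sample; its final state equals
#' [classify_cm2()] on the assembled incident.
#'
#' A state stopped before floor contact has `decided = FALSE` and partial
#' vote counts; feeding further samples after the decision, or samples with
#' non-increasing timestamps, is an error.
#'
#' @param model A fitted `"cm2"` model.
#' @param h_floor_tol Floor-contact tolerance in meters.
#' @return A `"cm2_stream"` state list with fields `fall_count`,
#'   `bend_count`, `decided`, `decision`, and per-checkpoint `records`.
#' @export
cm2_stream <- function(model, h_floor_tol = .FLOOR_TOL) {
  stopifnot(inherits(model, "cm2"))
  structure(list(model = model, h_floor_tol = h_floor_tol,
                 last_t = NULL, last_hm = NULL, next_j = 1L,
                 rows = list(), fall_count = 0L, bend_count = 0L,
                 decided = FALSE, decision = NA_character_),
            class = "cm2_stream")
}

#' @param state A `"cm2_stream"` state.
#' @param t,h Time (seconds) and height (meters) of the next sample.
#' @rdname cm2_stream
#' @export
cm2_stream_update <- function(state, t, h) {
  stopifnot(inherits(state, "cm2_stream"))
  if (state$decided)
    stop("incident already complete: no samples after floor contact",
         call. = FALSE)
  if (!is.null(state$last_t) && t <= state$last_t)
    stop(sprintf("out-of-order sample: t = %g after t = %g", t, state$last_t),
         call. = FALSE)
  model <- state$model
  cps <- model$checkpoints
  hm_new <- if (is.null(state$last_hm)) h else min(state$last_hm, h)
  at_floor <- h <= state$h_floor_tol
  j <- state$next_j
  while (j <= length(cps)) {
    lv <- cps[j]
    if (lv <= state$h_floor_tol) {
      if (!at_floor) break
      t_cross <- t                       # floor checkpoint: total time
    } else if (hm_new <= lv) {
      if (is.null(state$last_t) || state$last_hm <= lv) {
        t_cross <- if (is.null(state$last_t)) t else state$last_t
      } else {
        t_cross <- state$last_t +
          (state$last_hm - lv) / (state$last_hm - hm_new) * (t - state$last_t)
      }
    } else {
      break
    }
    d_fall <- abs(t_cross - model$t_fall_ref[j])
    d_bend <- abs(t_cross - model$t_bend_ref[j])
    vote <- if (d_fall < d_bend) .FALL else .BEND
    if (vote == .FALL) state$fall_count <- state$fall_count + 1L
    else state$bend_count <- state$bend_count + 1L
    state$rows[[j]] <- data.frame(j = j, checkpoint_h = lv,
                                  t_incident = t_cross, d_fall = d_fall,
                                  d_bend = d_bend, vote = vote,
                                  stringsAsFactors = FALSE)
    j <- j + 1L
  }
  state$next_j <- j
  state$last_t <- t
  state$last_hm <- hm_new
  if (at_floor) {
    state$decided <- TRUE
    state$decision <-
      if (state$fall_count > state$bend_count) .FALL else .BEND
  }
  state
}

#' @rdname cm2_stream
#' @param times,heights Vectors of sample times and heights to replay in
#'   order.
#' @return For `cm2_stream_replay`: list of states, one per sample.
#' @export
cm2_stream_replay <- function(model, times, heights,
                              h_floor_tol = .FLOOR_TOL) {
  stopifnot(length(times) == length(heights))
  state <- cm2_stream(model, h_floor_tol)
  out <- vector("list", length(times))
  for (i in seq_along(times)) {
    state <- cm2_stream_update(state, times[i], heights[i])
    out[[i]] <- state
    if (state$decided) {
      out <- out[seq_len(i)]
      break
    }
  }
  out
}

#' @export
print.cm2_stream <- function(x, ...) {
  if (x$decided) {
    cat(sprintf("<cm2_stream> decided: %s (fall %d : bend %d)\n",
                x$decision, x$fall_count, x$bend_count))
  } else {
    cat(sprintf(
      "<cm2_stream> undecided, %d/%d checkpoints (fall %d : bend %d)\n",
      x$next_j - 1L, length(x$model$checkpoints), x$fall_count,
      x$bend_count))
  }
  invisible(x)
}

# Trace of a completed stream, shaped like the batch vote trace.
.stream_trace <- function(state) {
  structure(list(records = do.call(rbind, state$rows),
                 fall_count = state$fall_count,
                 bend_count = state$bend_count,
                 decision = state$decision,
                 decided = state$decided),
            class = "vote_trace")
}
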