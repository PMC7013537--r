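#' Total-time threshold classifier (CM-I)
#'
#' CM-I classifies a descent incident from a single statistic, its total
#' descent time `tI`, by thresholding at the midpoint of the class mean
#' durations:
#' \deqn{r = (\mu_F + \mu_B) / 2}
#' An incident is a fall when `tI < r`, otherwise a lean-over (the boundary
#' `tI = r` falls to the lean-over branch; strict inequality).
#'
#' @param fall,bend [normal_time_model]s of the fall and lean-over total
#'   descent times; `fall$mu < bend$mu` is required.
#' @return An object of class `"cm1"` with fields `fall`, `bend`, `r`.
#' @examples
#' ps <- pdf_params("section3")
#' m <- cm1_model(ps$fall, ps$bend)
#' m$r  # 2.5
#' @export
cm1_model <- function(fall, bend) {
  stopifnot(inherits(fall, "normal_time_model"),
            inherits(bend, "normal_time_model"))
  if (!(fall$mu < bend$mu))
    stop("fall mean duration must be below the lean-over mean duration",
         call. = FALSE)
  structure(list(fall = fall, bend = bend, r = (fall$mu + bend$mu) / 2),
            class = "cm1")
}

#' @export
print.cm1 <- function(x, ...) {
  cat(sprintf(
    "<cm1> threshold r = %.4g s  (fall mu = %.4g s, lean-over mu = %.4g s)\n",
    x$r, x$fall$mu, x$bend$mu))
  invisible(x)
}

# Fit from precomputed total times; shared with the fast CV engine.
.cm1_from_totals <- function(totals, labels) {
  for (cl in c(.FALL, .BEND)) {
    if (sum(labels == cl) < 2L)
      stop(sprintf("CM-I needs at least 2 training incidents of class %s", cl),
           call. = FALSE)
  }
  fit_one <- function(x) normal_time_model(mean(x), sd(x),
                                           support = range(x),
                                           n_obs = length(x))
  cm1_model(fit_one(totals[labels == .FALL]),
            fit_one(totals[labels == .BEND]))
}

#' Fit CM-I from labeled incidents
#'
#' Estimates the class duration models from the sample mean and standard
#' deviation of the training incidents' total descent times, and sets the
#' classification criterion to the midpoint `r = (mu_F + mu_B) / 2`.
#'
#' @param incidents List of labeled [incident] objects, at least two per
#'   class.
#' @return A `"cm1"` model.
#' @export
fit_cm1 <- function(incidents) {
  labels <- vapply(incidents, function(x) x$label, "")
  if (anyNA(labels)) stop("all training incidents must be labeled",
                          call. = FALSE)
  .cm1_from_totals(vapply(incidents, total_time, 0), labels)
}

#' Classify one incident with CM-I
#'
#' @param model A `"cm1"` model.
#' @param incident An [incident].
#' @return `"FALL"` if the total descent time is strictly below `r`,
#'   else `"BEND"`.
#' @export
classify_cm1 <- function(model, incident) {
  stopifnot(inherits(model, "cm1"))
  if (total_time(incident) < model$r) .FALL else .BEND
}

#' Predict labels for a list of incidents
#'
#' @param object A fitted `"cm1"` model.
#' @param newdata List of [incident] objects.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.cm1 <- function(object, newdata, ...) {
  vapply(newdata, function(x) classify_cm1(object, x), "")
}
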