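#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the step function as a
#' plain table: S(0) = 1, right-continuous steps at event times only.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event).
#' @return Object of class `km_estimate`: data frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (all observed time points; the
#'   estimate changes only at rows with `n_event > 0`).
#' @examples
#' km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' km$surv  # 0.75 0.50 0.25 0.00
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) < 1) stop("at least one subject required")
  if (anyNA(times) || anyNA(events)) stop("missing times or events")
  if (any(times < 0)) stop("negative times")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "none")
  structure(data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                       n_censor = sf$n.censor, surv = sf$surv),
            class = c("km_estimate", "data.frame"))
}

#' Evaluate a Kaplan-Meier estimate at arbitrary times
#'
#' @param km a `km_estimate`.
#' @param t times at which to evaluate S(t).
#' @return S(t); 1 before the first event.
#' @export
km_survival <- function(km, t) {
  steps <- km[km$n_event > 0, , drop = FALSE]
  vapply(t, function(ti) {
    idx <- which(steps$time <= ti)
    if (!length(idx)) 1 else steps$surv[max(idx)]
  }, numeric(1))
}

#' @export
plot.km_estimate <- function(x, add = FALSE, col = 1, lty = 1, xlab = "Months",
                             ylab = "Survival probability", ...) {
  st <- c(0, x$time)
  sv <- c(1, x$surv)
  if (!add) {
    graphics::plot(st, sv, type = "s", ylim = c(0, 1), col = col, lty = lty,
                   xlab = xlab, ylab = ylab, ...)
  } else {
    graphics::lines(st, sv, type = "s", col = col, lty = lty, ...)
  }
  invisible(x)
}
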