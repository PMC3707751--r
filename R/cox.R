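#' Cox proportional-hazards machinery
#'
#' The model is \eqn{\lambda(t|x) = \lambda_0(t) \exp(\sum_j x_j \beta_j)};
#' \eqn{\beta} is estimated by maximizing the log partial likelihood
#' \eqn{l(\beta)}, with Breslow or Efron handling of tied event times.
#' [fit_cox()] performs Newton-Raphson maximization with step-halving and
#' Wald inference; [fit_cox_lasso()] maximizes the L1-penalized partial
#' likelihood \eqn{l(\beta) - \lambda \sum_j |\beta_j|} by cyclic coordinate
#' descent.
#'
#' @name cox_machinery
NULL

# sort by decreasing time, record tie-run boundaries so the risk set of any
# subject is a prefix of the sorted order
.cox_prep <- function(X, times, events) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite covariates")
  n <- nrow(X)
  if (length(times) != n || length(events) != n) stop("dimension mismatch")
  if (anyNA(times) || anyNA(events)) stop("missing times or events")
  if (any(times < 0)) stop("negative times")
  if (sum(events == 1) < 1) stop("at least one event required")
  ord <- order(times, decreasing = TRUE)
  t2 <- times[ord]
  r <- rle(t2)
  b <- rep(cumsum(r$lengths), r$lengths)
  list(X = X[ord, , drop = FALSE], times = t2, events = events[ord],
       b = b, ord = ord, n = n, p = ncol(X))
}

# log partial likelihood, gradient and (optionally) hessian at beta.
# The eta shift by max(eta) cancels exactly in l, grad and hessian.
.cox_parts <- function(beta, prep, ties = "efron", want_hess = FALSE) {
  X <- prep$X
  p <- prep$p
  eta <- drop(X %*% beta)
  etac <- eta - max(eta)
  w <- exp(etac)
  cs0 <- cumsum(w)
  ev <- which(prep$events == 1)
  bev <- prep$b[ev]
  S0 <- cs0[bev]
  d_total <- length(ev)

  ll <- sum(etac[ev]) - sum(log(S0))
  wX <- w * X
  cs1 <- apply(wX, 2, cumsum)
  if (p == 1L) cs1 <- matrix(cs1, ncol = 1)
  S1 <- cs1[bev, , drop = FALSE]
  grad <- colSums(X[ev, , drop = FALSE]) - colSums(S1 / S0)

  info <- NULL
  if (want_hess) {
    info <- matrix(0, p, p)
    u <- S1 / S0
    for (a in seq_len(p)) {
      csa <- apply(wX * X[, a], 2, cumsum)
      if (p == 1L) csa <- matrix(csa, ncol = 1)
      S2a <- csa[bev, , drop = FALSE]
      info[a, ] <- colSums(S2a / S0) - colSums(u[, a] * u)
    }
    info <- (info + t(info)) / 2
  }

  if (ties == "efron") {
    # correct tied-event groups (d >= 2) from Breslow to Efron terms
    runs <- rle(prep$times)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (g in seq_along(ends)) {
      idx <- starts[g]:ends[g]
      D <- idx[prep$events[idx] == 1]
      d <- length(D)
      if (d < 2L) next
      bg <- ends[g]
      S0g <- cs0[bg]
      S1g <- cs1[bg, ]
      WD <- sum(w[D])
      VD <- colSums(wX[D, , drop = FALSE])
      m <- 0:(d - 1)
      A <- S0g - (m / d) * WD
      ll <- ll + d * log(S0g) - sum(log(A))
      R <- (matrix(S1g, d, p, byrow = TRUE) - outer(m / d, VD)) / A
      grad <- grad + d * (S1g / S0g) - colSums(R)
      if (want_hess) {
        XD <- X[D, , drop = FALSE]
        # S2 at the group boundary: sum over the risk-set prefix 1..bg
        pref <- seq_len(bg)
        S2g <- crossprod(sqrt(w[pref]) * X[pref, , drop = FALSE])
        UD <- crossprod(sqrt(w[D]) * XD)
        ug <- S1g / S0g
        info <- info - d * (S2g / S0g - outer(ug, ug))
        for (k in seq_len(d)) {
          Am <- A[k]
          S2m <- S2g - (m[k] / d) * UD
          rm_ <- R[k, ]
          info <- info + S2m / Am - outer(rm_, rm_)
        }
      }
    }
  }
  list(loglik = ll, grad = grad, info = info, nevent = d_total)
}

#' Cox log partial likelihood
#'
#' Evaluates \eqn{l(\beta)} for right-censored data under the Breslow or
#' Efron ties convention. At \eqn{\beta = 0} the value depends only on the
#' risk-set sizes.
#'
#' @param beta coefficient vector (length = `ncol(X)`).
#' @param X covariate matrix (subjects x covariates).
#' @param times,events follow-up times and event indicators (1 = event).
#' @param ties `"breslow"` or `"efron"`.
#' @return scalar log partial likelihood.
#' @examples
#' cox_partial_loglik(0, matrix(0, 3), c(1, 2, 3), c(1, 1, 1))  # -log(6)
#' @export
cox_partial_loglik <- function(beta, X, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  prep <- .cox_prep(X, times, events)
  .cox_parts(as.numeric(beta), prep, ties = ties)$loglik
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the log partial likelihood with
#' step-halving; standard errors from the inverse observed information,
#' Wald z-tests, hazard ratios \eqn{\exp(\beta)} with 95% CIs
#' \eqn{\exp(\beta \pm 1.96\,SE)}. Monotone-likelihood divergence is made
#' visible: coefficients are capped at `|beta| <= 15` and flagged rather than
#' iterated indefinitely.
#'
#' @inheritParams cox_partial_loglik
#' @param ties ties convention; Efron is the default for unpenalized fits.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `survsig_cox` with elements `coefficients`,
#'   `se`, `var`, `loglik`, `loglik_null`, `converged`, `diverged` (per
#'   coefficient), `ties`, `lambda` (0), `n`, `nevent`.
#' @export
fit_cox <- function(X, times, events, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cst <- apply(X, 2, function(col) max(col) - min(col) == 0)
  if (any(cst)) stop("constant covariate: ", paste(colnames(X)[cst], collapse = ", "))
  prep <- .cox_prep(X, times, events)
  p <- prep$p
  beta <- numeric(p)
  cap <- 15
  parts <- .cox_parts(beta, prep, ties, want_hess = TRUE)
  ll0 <- .cox_parts(numeric(p), prep, ties)$loglik
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(parts$info, parts$grad),
                     error = function(e) stop("singular information matrix"))
    ll_old <- parts$loglik
    fac <- 1
    repeat {
      beta_new <- pmin(pmax(beta + fac * step, -cap), cap)
      parts_new <- .cox_parts(beta_new, prep, ties, want_hess = TRUE)
      if (parts_new$loglik >= ll_old - 1e-12 || fac < 2^-30) break
      fac <- fac / 2
    }
    delta_ll <- parts_new$loglik - ll_old
    beta <- beta_new
    parts <- parts_new
    if (abs(delta_ll) < tol) {
      converged <- TRUE
      break
    }
  }
  diverged <- abs(beta) >= cap
  # martingale residuals: observed event minus Breslow cumulative hazard
  eta <- drop(prep$X %*% beta)
  etac <- eta - max(eta)
  w <- exp(etac)
  cs0 <- cumsum(w)
  runs <- rle(prep$times)
  ends <- cumsum(runs$lengths)
  starts <- rep(ends - runs$lengths + 1L, runs$lengths)
  inc <- numeric(prep$n)
  ev <- which(prep$events == 1)
  inc[ev] <- 1 / cs0[prep$b[ev]]
  revcum <- rev(cumsum(rev(inc)))
  cumhaz <- vapply(seq_len(prep$n), function(i) {
    s <- starts[i]
    revcum[s]
  }, numeric(1))
  mart <- prep$events - cumhaz * w
  resid_orig <- numeric(prep$n)
  resid_orig[prep$ord] <- mart
  V <- tryCatch(solve(parts$info), error = function(e) stop("singular information matrix"))
  se <- sqrt(pmax(diag(V), 0))
  names(beta) <- names(se) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  z <- beta / se
  structure(list(coefficients = beta, se = se, var = V,
                 z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 loglik = parts$loglik, loglik_null = ll0,
                 residuals = resid_orig,
                 iter = iter, converged = converged, diverged = diverged,
                 ties = ties, lambda = 0, n = prep$n, nevent = parts$nevent,
                 call = match.call()),
            class = "survsig_cox")
}

#' Hazard ratios with confidence intervals
#'
#' @param fit a `survsig_cox` object.
#' @param level confidence level.
#' @return data frame with `hr`, `lower`, `upper` (exp-scale), one row per
#'   coefficient.
#' @export
hazard_ratios <- function(fit, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  se <- if (is.null(fit$se)) rep(NA_real_, length(b)) else fit$se
  data.frame(hr = exp(b), lower = exp(b - zq * se), upper = exp(b + zq * se),
             row.names = names(b))
}

#' Linear predictor (risk score)
#'
#' Returns \eqn{X\hat\beta}. Adding a constant to a covariate shifts every
#' score equally, so score ranks (and hence the C-index) are unchanged.
#'
#' @param fit a `survsig_cox` object.
#' @param X covariate matrix with columns matching the fit's coefficients.
#' @return numeric vector of per-subject risk scores.
#' @export
linear_predictor <- function(fit, X) {
  X <- as.matrix(X)
  cf <- stats::coef(fit)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(cf)) stop("covariate columns do not match fit")
  } else {
    if (!setequal(colnames(X), names(cf))) {
      stop("covariate columns do not match fit: expected ",
           paste(names(cf), collapse = ", "))
    }
    X <- X[, names(cf), drop = FALSE]
  }
  drop(X %*% cf)
}

#' @export
coef.survsig_cox <- function(object, ...) object$coefficients

#' @export
residuals.survsig_cox <- function(object, ...) {
  if (is.null(object$residuals)) stop("no residuals stored for this fit")
  object$residuals  # martingale scale: event indicator minus expected count
}

#' @export
vcov.survsig_cox <- function(object, ...) object$var

#' @export
logLik.survsig_cox <- function(object, ...) {
  structure(object$loglik, df = sum(object$coefficients != 0), class = "logLik")
}

#' @export
predict.survsig_cox <- function(object, newdata, type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  lp <- linear_predictor(object, newdata)
  if (type == "risk") exp(lp) else lp
}

#' @export
print.survsig_cox <- function(x, ...) {
  kind <- if (x$lambda > 0) sprintf("L1-penalized (lambda = %.4g)" , x$lambda) else "unpenalized"
  cat(sprintf("Cox model (%s, %s ties): n = %d, events = %d\n",
              kind, x$ties, x$n, x$nevent))
  print(round(x$coefficients, 4))
  if (!is.null(x$converged) && !x$converged) cat("warning: did not converge\n")
  if (any(x$diverged)) {
    cat("divergence (monotone likelihood):",
        paste(names(x$coefficients)[x$diverged], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.survsig_cox <- function(object, ...) {
  hr <- hazard_ratios(object)
  tab <- data.frame(coef = object$coefficients, se = object$se,
                    hr = hr$hr, lower95 = hr$lower, upper95 = hr$upper,
                    z = object$z, p = object$p_value)
  structure(list(table = tab, fit = object), class = "summary.survsig_cox")
}

#' @export
print.summary.survsig_cox <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(round(x$table, 4))
  cat(sprintf("\nlog partial likelihood %.4f (null %.4f)\n",
              x$fit$loglik, x$fit$loglik_null))
  invisible(x)
}

#' Serialize a fit to a JSON report
#'
#' @param fit a `survsig_cox` object.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
cox_fit_json <- function(fit, path = NULL) {
  hr <- hazard_ratios(fit)
  nm <- names(fit$coefficients)
  named <- function(v) as.list(stats::setNames(v, nm))
  obj <- list(coefficients = named(fit$coefficients),
              se = if (is.null(fit$se)) NULL else named(fit$se),
              hr = named(hr$hr),
              hr_lower95 = named(hr$lower), hr_upper95 = named(hr$upper),
              loglik = fit$loglik, lambda = fit$lambda, ties = fit$ties,
              converged = fit$converged,
              diverged = as.list(fit$diverged),
              n = fit$n, nevent = fit$nevent)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
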