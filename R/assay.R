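# Enzyme-activity analytics: percent-remaining-activity normalization,
# Michaelis-Menten kinetics, and four-parameter logistic (4PL)
# concentration-response fitting with IC50 and Hill slope.

#' Percent remaining enzyme activity
#'
#' `I = 100 * vi / vo` on background-corrected initial velocities: `vi`
#' measured with the sample present, `vo` with enzyme alone.
#'
#' @param vi Initial velocity with sample (signal/min).
#' @param vo Enzyme-alone velocity (signal/min); must be positive after
#'   background correction.
#' @param background Substrate-only background subtracted from both
#'   (default 0, i.e. velocities already corrected).
#' @return Percent remaining activity (vectorized over `vi`).
#' @export
percent_activity <- function(vi, vo, background = 0) {
  vi <- vi - background
  vo <- vo - background
  if (any(!is.finite(vo)) || any(vo <= 0)) {
    stop("enzyme-alone velocity must be positive after background correction",
         call. = FALSE)
  }
  100 * vi / vo
}

#' The Michaelis-Menten rate law
#'
#' @param S Substrate concentration(s).
#' @param Km Michaelis constant (same units as `S`).
#' @param Vmax Limiting velocity.
#' @return `Vmax * S / (Km + S)`.
#' @export
michaelis_menten <- function(S, Km, Vmax) Vmax * S / (Km + S)

#' Fit Michaelis-Menten kinetics
#'
#' Ordinary least-squares fit of `v = Vmax * S / (Km + S)` by
#' Levenberg-Marquardt with positivity bounds on both parameters.
#' Start values: `Vmax = max(v)`, `Km =` the substrate concentration whose
#' velocity is nearest `Vmax / 2`.
#'
#' @param S Substrate concentrations (>= 4 distinct values).
#' @param v Initial velocities (>= 0, not all zero).
#' @return A list of class `"kinetics_fit"`: `Km`, `Vmax`, standard errors
#'   `se`, `residuals`, `fitted`, `converged`.
#' @examples
#' S <- c(5, 10, 20, 40, 80, 160)
#' fit_michaelis_menten(S, michaelis_menten(S, Km = 42.4, Vmax = 1.5e-4))
#' @export
fit_michaelis_menten <- function(S, v) {
  S <- as.numeric(S); v <- as.numeric(v)
  if (length(S) != length(v) || any(!is.finite(S)) || any(!is.finite(v))) {
    stop("S and v must be equal-length finite numeric vectors",
         call. = FALSE)
  }
  if (length(unique(S)) < 4L) {
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  }
  if (any(v < 0)) stop("velocities must be non-negative", call. = FALSE)
  if (all(v == 0)) stop("all velocities are zero; nothing to fit",
                        call. = FALSE)
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(S[S > 0])
  dat <- data.frame(S = S, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = dat,
                      start = list(Km = km0, Vmax = vmax0),
                      lower = c(Km = 1e-12, Vmax = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(Km = NA_real_, Vmax = NA_real_,
                          se = c(Km = NA_real_, Vmax = NA_real_),
                          residuals = rep(NA_real_, length(v)),
                          fitted = rep(NA_real_, length(v)),
                          converged = FALSE, message = conditionMessage(fit)),
                     class = "kinetics_fit"))
  }
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Km = NA_real_, Vmax = NA_real_))
  structure(
    list(Km = unname(co["Km"]), Vmax = unname(co["Vmax"]),
         se = c(Km = unname(se["Km"]), Vmax = unname(se["Vmax"])),
         residuals = as.numeric(stats::residuals(fit)),
         fitted = as.numeric(stats::fitted(fit)),
         converged = TRUE, message = NULL),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<kinetics_fit> did not converge:", x$message, "\n")
  } else {
    cat(sprintf("<kinetics_fit> Km = %.4g (SE %.2g), Vmax = %.4g (SE %.2g)\n",
                x$Km, x$se["Km"], x$Vmax, x$se["Vmax"]))
  }
  invisible(x)
}

#' The four-parameter logistic (4PL) concentration-response model
#'
#' `Y = Bottom + (Top - Bottom) / (1 + 10^((LogIC50 - X) * HillSlope))`
#' with `X` the log10 concentration.  With `Y` as percent remaining
#' activity, inhibition curves have a negative Hill slope under this
#' parameterization.
#'
#' @param x Log10 concentration(s).
#' @param bottom,top Lower and upper asymptotes.
#' @param log_ic50 Log10 of the half-maximal concentration.
#' @param hill Hill slope (signed).
#' @return Model response.
#' @export
fourpl <- function(x, bottom, top, log_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^((log_ic50 - x) * hill))
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Ordinary least squares on replicate means by default (fitting every
#' replicate point is available via `per_replicate = TRUE`), by
#' Levenberg-Marquardt.  Start values: `Top = max(Y)`, `Bottom = min(Y)`,
#' `LogIC50 =` the `X` whose response is nearest the midpoint, `Hill = -1`;
#' the Hill slope is bounded to \[-10, 10\].  The fit is reported with
#' `bottom <= top` (the 4PL is invariant under swapping the asymptotes and
#' negating the Hill slope, so the convention loses nothing).
#'
#' @param X Log10 concentrations (>= 5 distinct values).  Any concentration
#'   unit may be used; `ic50` is returned in that unit and `log_ic50`
#'   shifts accordingly.
#' @param Y Responses (replicate values allowed: repeat the `X`).
#' @param per_replicate Fit all points instead of replicate means.
#' @return A list of class `"dose_response_fit"`: `log_ic50`, `ic50`
#'   (`10^log_ic50`), `hill_slope`, `top`, `bottom`, `se` (named vector),
#'   `residuals`, `converged`.
#' @examples
#' x <- log10(c(0.1, 0.3, 1, 3, 10, 30, 60))
#' y <- fourpl(x, bottom = 0, top = 100, log_ic50 = log10(4.4), hill = -2.8)
#' fit_4pl(x, y)
#' @export
fit_4pl <- function(X, Y, per_replicate = FALSE) {
  X <- as.numeric(X); Y <- as.numeric(Y)
  if (length(X) != length(Y)) stop("X and Y must have the same length",
                                   call. = FALSE)
  if (any(is.na(X)) || any(is.na(Y)) || any(!is.finite(X)) ||
      any(!is.finite(Y))) {
    stop("NaN/NA inputs are not allowed", call. = FALSE)
  }
  if (length(unique(X)) < 5L) {
    stop("need at least 5 distinct concentrations", call. = FALSE)
  }
  if (!per_replicate) {
    ym <- tapply(Y, X, mean)
    X <- as.numeric(names(ym)); Y <- as.numeric(ym)
  }
  top0 <- max(Y); bottom0 <- min(Y)
  mid <- (top0 + bottom0) / 2
  logic50_0 <- X[which.min(abs(Y - mid))]
  dat <- data.frame(x = X, y = Y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^((logic50 - x) * hill)),
      data = dat,
      start = list(bottom = bottom0, top = top0, logic50 = logic50_0,
                   hill = -1),
      lower = c(bottom = -Inf, top = -Inf, logic50 = -Inf, hill = -10),
      upper = c(bottom = Inf, top = Inf, logic50 = Inf, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  bad <- function(msg) {
    structure(list(log_ic50 = NA_real_, ic50 = NA_real_,
                   hill_slope = NA_real_, top = NA_real_, bottom = NA_real_,
                   se = c(bottom = NA_real_, top = NA_real_,
                          log_ic50 = NA_real_, hill = NA_real_),
                   residuals = rep(NA_real_, length(Y)), converged = FALSE,
                   message = msg),
              class = "dose_response_fit")
  }
  if (inherits(fit, "error")) return(bad(conditionMessage(fit)))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 4),
                                                     names(co)))
  bottom <- unname(co["bottom"]); top <- unname(co["top"])
  hill <- unname(co["hill"]); logic50 <- unname(co["logic50"])
  se_out <- c(bottom = unname(se["bottom"]), top = unname(se["top"]),
              log_ic50 = unname(se["logic50"]), hill = unname(se["hill"]))
  if (bottom > top) {   # canonical orientation: bottom <= top, hill flips
    tmp <- bottom; bottom <- top; top <- tmp
    tmp <- se_out["bottom"]; se_out["bottom"] <- se_out["top"]
    se_out["top"] <- tmp
    hill <- -hill
  }
  # a flat or one-sided curve leaves the midpoint unidentified: flag it
  span <- abs(top - bottom)
  ok <- is.finite(logic50) && span > 1e-8 &&
    logic50 >= min(X) - (max(X) - min(X)) &&
    logic50 <= max(X) + (max(X) - min(X))
  if (!ok) return(bad("IC50 not identifiable from the dose range"))
  structure(
    list(log_ic50 = logic50, ic50 = 10^logic50, hill_slope = hill,
         top = top, bottom = bottom, se = se_out,
         residuals = as.numeric(stats::residuals(fit)), converged = TRUE,
         message = NULL),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<dose_response_fit> did not converge:", x$message, "\n")
  } else {
    cat(sprintf(
      "<dose_response_fit> IC50 = %.4g (logIC50 %.3f, SE %.2g), Hill = %.2f\n",
      x$ic50, x$log_ic50, x$se["log_ic50"], x$hill_slope))
    cat(sprintf("  Top = %.3f, Bottom = %.3f\n", x$top, x$bottom))
  }
  invisible(x)
}

#' Normalize assay responses
#'
#' `to_enzyme_control`: every response is expressed as percent of the mean
#' enzyme-alone control (100% is the uninhibited enzyme activity); requires
#' a logical `control` column marking the control wells.
#' `to_max_response`: responses are rescaled so the maximum is 100.
#'
#' @param raw Data frame with a numeric `response` column (and a logical
#'   `control` column for `to_enzyme_control`).
#' @param mode `"to_enzyme_control"` or `"to_max_response"`.
#' @return The data frame with `response` replaced by the normalized values
#'   (control rows dropped for `to_enzyme_control`); the mode is recorded
#'   in the `"normalization"` attribute.
#' @export
normalize_responses <- function(raw,
                                mode = c("to_enzyme_control",
                                         "to_max_response")) {
  mode <- match.arg(mode)
  if (!is.data.frame(raw) || !"response" %in% names(raw)) {
    stop("raw must be a data frame with a 'response' column", call. = FALSE)
  }
  if (mode == "to_enzyme_control") {
    if (!"control" %in% names(raw)) {
      stop("to_enzyme_control requires a logical 'control' column",
           call. = FALSE)
    }
    ctrl <- raw$response[as.logical(raw$control)]
    if (!length(ctrl) || !is.finite(mean(ctrl)) || mean(ctrl) == 0) {
      stop("no usable control wells for normalization", call. = FALSE)
    }
    out <- raw[!as.logical(raw$control), , drop = FALSE]
    out$response <- out$response / mean(ctrl) * 100
  } else {
    out <- raw
    mx <- max(out$response)
    if (!is.finite(mx) || mx == 0) {
      stop("maximum response is zero; cannot normalize", call. = FALSE)
    }
    out$response <- out$response / mx * 100
  }
  attr(out, "normalization") <- mode
  out
}
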