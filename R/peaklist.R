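# Centroided peak lists: the common container for MALDI-MS signals and
# MS/MS fragment spectra.

#' Construct a peak list
#'
#' A centroided list of (m/z, intensity) pairs, sorted ascending by m/z.
#' Duplicate m/z values (within 1e-6) are rejected: centroided data should
#' carry one entry per signal.
#'
#' @param mz Numeric vector of m/z values (> 0).
#' @param intensity Numeric vector of intensities (>= 0); defaults to 1 for
#'   every peak (intensity is not used by the screening logic).
#' @param label Optional label describing the derivatization state of the
#'   sample: `"native"`, `"reduced"`, `"alkylated"`, `"linearized"`, or
#'   `"msms"` for fragment spectra.
#' @return A data frame of class `"peak_list"` with columns `mz` and
#'   `intensity`, sorted by `mz`, carrying the label as an attribute.
#' @export
peak_list <- function(mz, intensity = NULL, label = NULL) {
  mz <- as.numeric(mz)
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("all m/z values must be finite and positive", call. = FALSE)
  }
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(mz)) {
    stop("mz and intensity must have the same length", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("all intensities must be finite and non-negative", call. = FALSE)
  }
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (length(mz) > 1L && any(diff(mz) < 1e-6)) {
    stop("duplicate m/z values (within 1e-6) in peak list", call. = FALSE)
  }
  if (!is.null(label)) {
    label <- match.arg(label, c("native", "reduced", "alkylated",
                                "linearized", "msms"))
  }
  structure(
    data.frame(mz = mz, intensity = intensity),
    label = label,
    class = c("peak_list", "data.frame")
  )
}

#' @export
print.peak_list <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<peak_list%s> %d peaks",
              if (is.null(lab)) "" else paste0(" ", lab), nrow(x)))
  if (nrow(x)) cat(sprintf(", m/z %.4f - %.4f", min(x$mz), max(x$mz)))
  cat("\n")
  invisible(x)
}

# Index of the peak in sorted `mzs` nearest to `target` and within `tol_abs`
# Da, or NA.  Exact ties broken toward the lower m/z.
.nearest_peak <- function(mzs, target, tol_abs) {
  n <- length(mzs)
  if (!n) return(NA_integer_)
  i <- findInterval(target, mzs)
  cand <- unique(pmin(pmax(c(i, i + 1L), 1L), n))
  d <- abs(mzs[cand] - target)
  best <- cand[order(d, mzs[cand])][1L]
  if (abs(mzs[best] - target) <= tol_abs) best else NA_integer_
}

# Coerce data.frame-like input to a peak_list, checking an expected label.
.as_peak_list <- function(x, expect_label = NULL, arg = "peak list") {
  if (!inherits(x, "peak_list")) {
    if (is.data.frame(x) && "mz" %in% names(x)) {
      x <- peak_list(x$mz, x$intensity, label = expect_label)
    } else {
      stop(arg, " must be a peak_list or a data frame with an 'mz' column",
           call. = FALSE)
    }
  }
  lab <- attr(x, "label")
  if (!is.null(expect_label) && !is.null(lab) && !identical(lab, expect_label)) {
    stop(sprintf("%s is labelled '%s' but '%s' was expected",
                 arg, lab, expect_label), call. = FALSE)
  }
  x
}
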