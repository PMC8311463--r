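# Derivatization-series screening: match native, reduced, alkylated and
# GluC-linearized MALDI peak lists into series, infer the cysteine count,
# and flag six-cysteine cyclic (cyclotide-like) candidates.

#' Screening parameters
#'
#' @param tolerance_mode `"ppm"` (relative to the predicted m/z of each
#'   step) or `"dalton"` (absolute).  The ppm default matches instrument
#'   practice; the dalton mode accommodates peak lists reported at one
#'   decimal, whose rounding error alone can exceed a tight ppm window.
#' @param tolerance_value Tolerance in the chosen unit (default 25 ppm;
#'   typical absolute alternative 0.2 Da).
#' @param cys_candidates Candidate cysteine counts to test (default 1:10;
#'   both even and odd counts are searched since other cystine-rich peptide
#'   families differ from the six of cyclotides).
#' @param require_linearized If `TRUE` (default) a series without a matched
#'   ring-opened (+18 Da) peak is classified `"incomplete"` rather than
#'   cyclic.  If `FALSE` the linearization step is skipped and
#'   classification rests on the cysteine count alone.
#' @param chaining `"from_previous_observed"` (default): each step's
#'   prediction is anchored on the matched peak of the previous step, which
#'   keeps per-step deviations at single-measurement scale.
#'   `"from_native"`: every prediction is anchored on the native peak.
#' @return A list of class `"screen_params"`.
#' @export
screen_params <- function(tolerance_mode = c("ppm", "dalton"),
                          tolerance_value = 25,
                          cys_candidates = 1:10,
                          require_linearized = TRUE,
                          chaining = c("from_previous_observed",
                                       "from_native")) {
  tolerance_mode <- match.arg(tolerance_mode)
  chaining <- match.arg(chaining)
  if (!is.numeric(tolerance_value) || length(tolerance_value) != 1L ||
      !is.finite(tolerance_value) || tolerance_value <= 0) {
    stop("tolerance_value must be a single positive number", call. = FALSE)
  }
  cys_candidates <- sort(unique(as.integer(cys_candidates)))
  if (!length(cys_candidates) || any(is.na(cys_candidates)) ||
      any(cys_candidates < 0L)) {
    stop("cys_candidates must be a non-empty set of non-negative integers",
         call. = FALSE)
  }
  structure(
    list(tolerance_mode = tolerance_mode, tolerance_value = tolerance_value,
         cys_candidates = cys_candidates,
         require_linearized = isTRUE(require_linearized),
         chaining = chaining),
    class = "screen_params"
  )
}

# absolute tolerance window (Da) around a predicted m/z
.tol_abs <- function(predicted, params) {
  if (params$tolerance_mode == "ppm") {
    params$tolerance_value * 1e-6 * predicted
  } else {
    params$tolerance_value
  }
}

# signed deviation in the active tolerance unit
.tol_dev <- function(observed, predicted, params) {
  if (params$tolerance_mode == "ppm") {
    ppm_error(observed, predicted)
  } else {
    observed - predicted
  }
}

# Chain one native peak through reduced/alkylated/linearized lists for a
# given candidate cysteine count.  Returns NULL when the reduced or
# alkylated step has no companion in tolerance.
.chain_candidate <- function(native_mz, n, reduced_mz, alkylated_mz,
                             linearized_mz, params) {
  cst <- mass_constants()
  from_prev <- params$chaining == "from_previous_observed"

  pred_red <- native_mz + n * cst$reduction_delta_per_cys
  i_red <- .nearest_peak(reduced_mz, pred_red, .tol_abs(pred_red, params))
  if (is.na(i_red)) return(NULL)
  obs_red <- reduced_mz[i_red]

  pred_alk <- if (from_prev) obs_red + n * cst$cam_delta else
    native_mz + n * cst$alkylation_from_native_per_cys
  i_alk <- .nearest_peak(alkylated_mz, pred_alk, .tol_abs(pred_alk, params))
  if (is.na(i_alk)) return(NULL)
  obs_alk <- alkylated_mz[i_alk]

  i_lin <- NA_integer_
  dev_lin <- NA_real_
  if (length(linearized_mz)) {
    pred_lin <- if (from_prev) obs_alk + cst$ring_open_delta else
      native_mz + n * cst$alkylation_from_native_per_cys + cst$ring_open_delta
    i_lin <- .nearest_peak(linearized_mz, pred_lin,
                           .tol_abs(pred_lin, params))
    if (!is.na(i_lin)) dev_lin <- .tol_dev(linearized_mz[i_lin], pred_lin,
                                           params)
  }

  devs <- c(reduce = .tol_dev(obs_red, pred_red, params),
            alkylate = .tol_dev(obs_alk, pred_alk, params),
            ring_open = dev_lin)
  list(n = n, i_red = i_red, i_alk = i_alk, i_lin = i_lin, devs = devs,
       total_dev = sum(abs(devs), na.rm = TRUE),
       n_matched = 2L + !is.na(i_lin))
}

#' Match derivatization peak lists into candidate peptide series
#'
#' For every native peak and every candidate cysteine count `n`, looks for a
#' reduced peak at `+n x 1.007825` Da, an alkylated peak at a further
#' `+n x 57.021464` Da, and (unless disabled) a ring-opened peak at a
#' further `+18.010565` Da, each within the configured tolerance.  Among
#' candidate counts with the same number of matched steps, the `n`
#' minimizing the total absolute deviation wins; each native peak yields at
#' most one series, and no reduced/alkylated/linearized peak is claimed by
#' two series (conflicts resolved by smallest total deviation, then lowest
#' native m/z).
#'
#' @param native,reduced,alkylated [peak_list()]s for the four samples.
#'   `linearized` may be `NULL` when `params$require_linearized` is `FALSE`.
#' @param linearized [peak_list()] of the GluC-processed sample, or `NULL`.
#' @param params A [screen_params()] object.
#' @return A data frame of class `"derivatization_series"`, one row per
#'   matched series: the four matched m/z values (`linearized_mz` `NA` when
#'   absent), `inferred_n_cys`, the three signed step deviations in the
#'   active tolerance unit, and `classification` (`"six_cys_cyclic"`,
#'   `"cys_rich_other"`, or `"incomplete"`).
#' @examples
#' p <- screen_params("dalton", 0.2)
#' match_series(peak_list(2948.1, label = "native"),
#'              peak_list(2954.1, label = "reduced"),
#'              peak_list(3296.3, label = "alkylated"),
#'              peak_list(3314.3, label = "linearized"), p)
#' @export
match_series <- function(native, reduced, alkylated, linearized = NULL,
                         params = screen_params()) {
  stopifnot(inherits(params, "screen_params"))
  native <- .as_peak_list(native, "native", "native")
  reduced <- .as_peak_list(reduced, "reduced", "reduced")
  alkylated <- .as_peak_list(alkylated, "alkylated", "alkylated")
  if (!is.null(linearized)) {
    linearized <- .as_peak_list(linearized, "linearized", "linearized")
  } else if (params$require_linearized) {
    stop("a linearized peak list is required when require_linearized = TRUE",
         call. = FALSE)
  }
  lin_mz <- if (is.null(linearized)) numeric(0) else linearized$mz

  empty <- data.frame(
    native_mz = numeric(0), reduced_mz = numeric(0),
    alkylated_mz = numeric(0), linearized_mz = numeric(0),
    inferred_n_cys = integer(0), dev_reduce = numeric(0),
    dev_alkylate = numeric(0), dev_ring_open = numeric(0),
    classification = character(0), stringsAsFactors = FALSE
  )
  class(empty) <- c("derivatization_series", "data.frame")
  if (!nrow(native)) return(empty)

  cands <- vector("list", nrow(native))
  for (i in seq_len(nrow(native))) {
    best <- NULL
    for (n in params$cys_candidates) {
      ch <- .chain_candidate(native$mz[i], n, reduced$mz, alkylated$mz,
                             lin_mz, params)
      if (is.null(ch)) next
      if (is.null(best) ||
          ch$n_matched > best$n_matched ||
          (ch$n_matched == best$n_matched && ch$total_dev < best$total_dev)) {
        best <- ch
      }
    }
    if (!is.null(best)) { best$i_native <- i; cands[[i]] <- best }
  }
  cands <- Filter(Negate(is.null), cands)
  if (!length(cands)) return(empty)

  # injectivity: claim companion peaks greedily.  Complete (three-step)
  # series claim before incomplete ones - a two-step chain always has the
  # smaller deviation sum, so ranking by raw totals would let spurious
  # partial chains steal peaks from genuine full series - then by mean
  # absolute deviation per matched step, then by lowest native m/z.
  ord <- order(-vapply(cands, `[[`, 0L, "n_matched"),
               vapply(cands, function(ch) ch$total_dev / ch$n_matched, 0),
               native$mz[vapply(cands, `[[`, 0L, "i_native")])
  used_red <- logical(nrow(reduced))
  used_alk <- logical(nrow(alkylated))
  used_lin <- logical(length(lin_mz))
  rows <- list()
  for (k in ord) {
    ch <- cands[[k]]
    if (used_red[ch$i_red] || used_alk[ch$i_alk] ||
        (!is.na(ch$i_lin) && used_lin[ch$i_lin])) next
    used_red[ch$i_red] <- TRUE
    used_alk[ch$i_alk] <- TRUE
    if (!is.na(ch$i_lin)) used_lin[ch$i_lin] <- TRUE
    has_lin <- !is.na(ch$i_lin)
    classification <-
      if (!has_lin && params$require_linearized) "incomplete"
      else if (ch$n == 6L) "six_cys_cyclic"
      else "cys_rich_other"
    rows[[length(rows) + 1L]] <- data.frame(
      native_mz = native$mz[ch$i_native],
      reduced_mz = reduced$mz[ch$i_red],
      alkylated_mz = alkylated$mz[ch$i_alk],
      linearized_mz = if (has_lin) lin_mz[ch$i_lin] else NA_real_,
      inferred_n_cys = ch$n,
      dev_reduce = unname(ch$devs["reduce"]),
      dev_alkylate = unname(ch$devs["alkylate"]),
      dev_ring_open = unname(ch$devs["ring_open"]),
      classification = classification,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$native_mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("derivatization_series", "data.frame")
  out
}

#' Summarize a set of matched derivatization series
#'
#' @param series_list Result of [match_series()].
#' @param params The [screen_params()] the series were matched with
#'   (recorded in the report).
#' @return A list of class `"screen_report"`: `counts` (named integer vector
#'   over the three classifications), `n_series`, `series` (the table sorted
#'   by native m/z), and `params`.
#' @export
screen_report <- function(series_list, params = screen_params()) {
  stopifnot(is.data.frame(series_list))
  classes <- c("six_cys_cyclic", "cys_rich_other", "incomplete")
  counts <- vapply(classes,
                   function(cl) sum(series_list$classification == cl), 0L)
  series <- series_list[order(series_list$native_mz), , drop = FALSE]
  rownames(series) <- NULL
  structure(
    list(counts = counts, n_series = nrow(series), series = series,
         params = params),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d series (tolerance %g %s, chaining %s)\n",
              x$n_series, x$params$tolerance_value, x$params$tolerance_mode,
              x$params$chaining))
  for (cl in names(x$counts)) {
    cat(sprintf("  %-15s %d\n", cl, x$counts[[cl]]))
  }
  invisible(x)
}
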