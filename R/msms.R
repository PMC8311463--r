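# Theoretical b/y fragment-ion ladders, spectrum annotation and coverage,
# and Ile/Leu resolution from chymotryptic cleavage evidence.
#
# Only singly charged b and y ions (with optional -17 / -18 neutral losses)
# are modelled: the MALDI post-source-decay context of cyclotide de novo
# sequencing.

.residue_masses_cam <- function(sequence, cys_state) {
  cst <- mass_constants()
  r <- cst$residue_mass[strsplit(sequence, "", fixed = TRUE)[[1L]]]
  if (cys_state == "carbamidomethylated") {
    r[names(r) == "C"] <- r[names(r) == "C"] + cst$cam_delta
  }
  unname(r)
}

#' Theoretical b/y fragment ions of a linear peptide
#'
#' `b_i` is the sum of the first `i` residue masses plus a proton; `y_i`
#' the sum of the last `i` residue masses plus water plus a proton.  Loss
#' variants subtract 17.026549 (NH3) or 18.010565 (H2O).
#'
#' @param linear_sequence Linear amino acid sequence, length >= 2.  Cyclic
#'   peptides must be linearized (digested) first; passing a cyclic
#'   [peptide()] is an error.
#' @param cys_state `"carbamidomethylated"` (default; the state in which
#'   cyclotide MS/MS precursors are prepared) or `"reduced"`.
#' @param losses Include the -17/-18 loss variants (default `TRUE`).
#' @return A data frame with columns `series` ("b"/"y"), `index` (1..n-1),
#'   `loss` ("none"/"NH3"/"H2O"), `mz1`.
#' @export
theoretical_ions <- function(linear_sequence,
                             cys_state = c("carbamidomethylated", "reduced"),
                             losses = TRUE) {
  if (inherits(linear_sequence, "peptide")) {
    if (linear_sequence$topology == "cyclic") {
      stop("cyclic peptides have no terminal b/y ions; linearize first",
           call. = FALSE)
    }
    cys_state <- linear_sequence$cys_state
    linear_sequence <- linear_sequence$sequence
  } else {
    cys_state <- match.arg(cys_state)
  }
  linear_sequence <- .check_sequence(linear_sequence)
  n <- nchar(linear_sequence)
  if (n < 2L) stop("need at least 2 residues for fragment ions",
                   call. = FALSE)
  cst <- mass_constants()
  r <- .residue_masses_cam(linear_sequence, cys_state)
  b <- cumsum(r)[seq_len(n - 1L)] + cst$proton
  y <- cumsum(rev(r))[seq_len(n - 1L)] + cst$water + cst$proton
  base <- data.frame(
    series = rep(c("b", "y"), each = n - 1L),
    index = rep(seq_len(n - 1L), 2L),
    loss = "none",
    mz1 = c(b, y),
    stringsAsFactors = FALSE
  )
  if (!losses) return(base)
  nh3 <- transform(base, loss = "NH3", mz1 = mz1 - cst$nh3)
  h2o <- transform(base, loss = "H2O", mz1 = mz1 - cst$water)
  out <- rbind(base, nh3, h2o)
  rownames(out) <- NULL
  out
}

#' Annotate an MS/MS spectrum with a candidate sequence
#'
#' Matches each theoretical b/y ion (and loss variant) of the candidate to
#' the nearest spectrum peak within tolerance, greedily by smallest
#' absolute error.  A peak may support at most one ion per (series, index)
#' pair, so loss variants of the same ion cannot double-count a single
#' peak.  Residue `j` is supported when a matched ion places a verified
#' bond boundary at `j-1/j` or `j/j+1`; the terminal residues are supported
#' by `b1`/`y1` (boundary 1 resp. n-1).  Coverage is the supported
#' fraction; the de novo acceptance criterion is at least one observed
#' y- or b-series signal for each residue.
#'
#' @param spectrum A [peak_list()] (centroided MS/MS peaks).  An empty
#'   spectrum gives coverage 0, not an error.
#' @param candidate Linear candidate sequence.
#' @param cys_state Cysteine state of the candidate.
#' @param tolerance Matching tolerance in Da (default 0.3, a typical
#'   MALDI-TOF/TOF fragment tolerance).
#' @param losses Consider -17/-18 loss variants (default `TRUE`).
#' @return An object of class `"annotation_result"`: `sequence`,
#'   `matched_ions` (data frame of matched theoretical ions with
#'   `matched_peak_mz` and `error`), `residue_support` (logical vector),
#'   `coverage`, `unsupported_positions`.
#' @export
annotate_spectrum <- function(spectrum, candidate,
                              cys_state = c("carbamidomethylated", "reduced"),
                              tolerance = 0.3, losses = TRUE) {
  cys_state <- match.arg(cys_state)
  candidate <- .check_sequence(candidate, "candidate")
  spectrum <- .as_peak_list(spectrum, arg = "spectrum")
  n <- nchar(candidate)
  ions <- theoretical_ions(candidate, cys_state, losses = losses)

  matched <- ions[0, ]
  matched$matched_peak_mz <- numeric(0)
  matched$error <- numeric(0)
  if (nrow(spectrum)) {
    idx <- vapply(ions$mz1, function(t) {
      .nearest_peak(spectrum$mz, t, tolerance)
    }, 0L)
    hit <- !is.na(idx)
    if (any(hit)) {
      m <- ions[hit, , drop = FALSE]
      m$matched_peak_mz <- spectrum$mz[idx[hit]]
      m$error <- m$matched_peak_mz - m$mz1
      # one peak per (series, index): keep the smallest |error| among loss
      # variants claiming the same peak for the same ion
      key <- paste(m$series, m$index, m$matched_peak_mz)
      m <- m[order(abs(m$error)), , drop = FALSE]
      m <- m[!duplicated(key[order(abs(m$error))]), , drop = FALSE]
      matched <- m[order(m$series, m$index), , drop = FALSE]
      rownames(matched) <- NULL
    }
  }

  support <- logical(n)
  if (nrow(matched)) {
    boundary <- ifelse(matched$series == "b", matched$index,
                       n - matched$index)
    boundary <- unique(boundary[boundary >= 1L & boundary <= n - 1L])
    for (bnd in boundary) support[c(bnd, bnd + 1L)] <- TRUE
  }
  structure(
    list(sequence = candidate, matched_ions = matched,
         residue_support = support, coverage = mean(support),
         unsupported_positions = which(!support)),
    class = "annotation_result"
  )
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %s\n  %d matched ions, coverage %.1f%%\n",
              x$sequence, nrow(x$matched_ions), 100 * x$coverage))
  if (length(x$unsupported_positions)) {
    cat("  unsupported positions:",
        paste(x$unsupported_positions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Combine per-residue support from several linearized forms
#'
#' Different proteases open a cyclic parent at different points; mapping
#' each linear annotation back to cyclic coordinates and OR-ing the support
#' gives the combined evidence (the route by which full-coverage de novo
#' assignment of a cyclic peptide is achieved).
#'
#' @param results List of [annotate_spectrum()] results, all referring to
#'   full-length linearized forms of the same cyclic parent.
#' @param starts Integer vector, same length: for each result, the cyclic
#'   coordinate (1-based, in the parent as written) of the linear form's
#'   first residue.
#' @param parent_length Length of the cyclic parent; every result's
#'   sequence must have this length.
#' @return A list with `support` (logical vector in cyclic coordinates),
#'   `coverage`, and `unsupported_positions`.
#' @export
combine_evidence <- function(results, starts, parent_length) {
  stopifnot(is.list(results), length(results) == length(starts))
  parent_length <- as.integer(parent_length)
  lens <- vapply(results, function(r) nchar(r$sequence), 0L)
  if (any(lens != parent_length)) {
    stop("all results must cover the full parent length (",
         parent_length, "); got lengths ",
         paste(lens, collapse = ", "), call. = FALSE)
  }
  support <- logical(parent_length)
  for (i in seq_along(results)) {
    pos <- ((starts[i] - 1L + seq_len(parent_length) - 1L) %%
              parent_length) + 1L
    support[pos] <- support[pos] | results[[i]]$residue_support
  }
  list(support = support, coverage = mean(support),
       unsupported_positions = which(!support))
}

#' Resolve Ile/Leu ambiguities from chymotryptic fragment evidence
#'
#' Ile and Leu are isobaric and indistinguishable by fragment mass alone,
#' but chymotrypsin cleaves C-terminal to Leu while the beta-branched Ile
#' hinders it.  Positions marked `J` in the candidate are resolved as
#' follows: a `J` is set to `L` when an observed chymotryptic fragment
#' boundary (within tolerance) requires cleavage immediately after it; a
#' `J` never used as a cleavage boundary but covered by observed fragments
#' that span it uncut is set to `I`; everything else stays unresolved.
#' The inference is evidence-graded, not absolute (an incompletely digested
#' Leu can masquerade as Ile), and each call carries an evidence tag;
#' homology-based assignments may be supplied by the caller under their own
#' tag.
#'
#' @param candidate Sequence of the cyclic parent as written, with `J` at
#'   unresolved Ile/Leu positions (only I/L positions may be `J`).
#' @param chymo_observed [peak_list()] of observed chymotryptic fragment
#'   \[M+H\]+ signals.
#' @param cys_state Cysteine state of the digested material (default CAM).
#' @param tolerance Matching tolerance in Da (default 0.2).
#' @param strict Use the strict F/Y/W chymotrypsin specificity for the
#'   non-J sites (default `FALSE`, i.e. F/Y/W/L/M).
#' @return A list of class `"il_resolution"`: `sequence` (with resolved
#'   positions substituted), `resolved` (data frame: `position`, `call`
#'   in I/L/J, `evidence` in chymotryptic_cleavage/none), and
#'   `matched_fragments`.
#' @export
resolve_ile_leu <- function(candidate, chymo_observed,
                            cys_state = c("carbamidomethylated", "reduced"),
                            tolerance = 0.2, strict = FALSE) {
  cys_state <- match.arg(cys_state)
  if (!is.character(candidate) || length(candidate) != 1L) {
    stop("candidate must be a single string", call. = FALSE)
  }
  candidate <- toupper(candidate)
  chars <- strsplit(candidate, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  j_pos <- which(chars == "J")
  bad <- which(!chars %in% c(names(mass_constants()$residue_mass), "J"))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", chars[bad[1L]],
                 bad[1L]), call. = FALSE)
  }
  resolved <- data.frame(position = j_pos, call = rep("J", length(j_pos)),
                         evidence = rep("none", length(j_pos)),
                         stringsAsFactors = FALSE)
  if (!length(j_pos)) {
    return(structure(list(sequence = candidate, resolved = resolved,
                          matched_fragments = NULL),
                     class = "il_resolution"))
  }
  chymo_observed <- .as_peak_list(chymo_observed, arg = "chymo_observed")

  # candidate cleavage boundaries: fixed specificity residues plus every J
  spec <- if (strict) c("F", "Y", "W") else c("F", "Y", "W", "L", "M")
  sites <- which(chars %in% c(spec, "J"))
  k <- length(sites)
  if (!k || !nrow(chymo_observed)) {
    return(structure(list(sequence = candidate, resolved = resolved,
                          matched_fragments = NULL),
                     class = "il_resolution"))
  }

  # all cyclic arcs between candidate boundaries (J treated as I/L mass)
  mass_chars <- chars
  mass_chars[mass_chars == "J"] <- "I"
  arcs <- list()
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      start <- (sites[a] %% n) + 1L
      len <- if (a == b) n else ((sites[b] - sites[a] - 1L) %% n) + 1L
      seq <- .wrap_substring(mass_chars, start, len)
      arcs[[length(arcs) + 1L]] <- data.frame(
        start = start, end = sites[b], length = len,
        sequence = seq, mz1 = mz(.fragment_mass(seq, cys_state), 1L),
        stringsAsFactors = FALSE)
    }
  }
  arcs <- do.call(rbind, arcs)

  # An observed mass can be consistent with several arcs (e.g. every
  # single-cut full-length form shares one mass).  Evidence is only taken
  # where all consistent arcs agree: a boundary call needs every matching
  # arc to end at the same position, and a position counts as spanned
  # uncut only when every matching arc covers it away from its end.
  covered_uncut <- integer(0)
  boundary_after <- integer(0)
  matched <- list()
  for (i in seq_len(nrow(chymo_observed))) {
    d <- abs(chymo_observed$mz[i] - arcs$mz1)
    hits <- which(d <= tolerance)
    if (!length(hits)) next
    m <- arcs[hits, , drop = FALSE]
    m$observed_mz <- chymo_observed$mz[i]
    matched[[length(matched) + 1L]] <- m
    ends <- unique(m$end)
    if (length(ends) == 1L) boundary_after <- c(boundary_after, ends)
    spans <- lapply(seq_len(nrow(m)), function(r) {
      span <- ((m$start[r] - 1L + seq_len(m$length[r]) - 1L) %% n) + 1L
      setdiff(span, m$end[r])
    })
    covered_uncut <- c(covered_uncut, Reduce(intersect, spans))
  }
  if (!length(matched)) {
    return(structure(list(sequence = candidate, resolved = resolved,
                          matched_fragments = NULL),
                     class = "il_resolution"))
  }
  matched <- do.call(rbind, matched)
  is_L <- j_pos %in% boundary_after
  is_I <- !is_L & j_pos %in% covered_uncut
  resolved$call[is_L] <- "L"
  resolved$call[is_I] <- "I"
  resolved$evidence[is_L | is_I] <- "chymotryptic_cleavage"
  chars[resolved$position] <- resolved$call
  structure(
    list(sequence = paste(chars, collapse = ""), resolved = resolved,
         matched_fragments = matched),
    class = "il_resolution"
  )
}

#' @export
print.il_resolution <- function(x, ...) {
  cat(sprintf("<il_resolution> %s\n", x$sequence))
  if (nrow(x$resolved)) {
    for (i in seq_len(nrow(x$resolved))) {
      cat(sprintf("  position %d -> %s (%s)\n", x$resolved$position[i],
                  x$resolved$call[i], x$resolved$evidence[i]))
    }
  }
  invisible(x)
}
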